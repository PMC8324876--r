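# Gabor kernels and filter-bank magnitude responses.

#' Construct a Gabor kernel (even and odd parts)
#'
#' The even (cosine) part is
#' `K * exp(-(i^2 + j^2) / (2 sigma^2)) * cos(2 pi f (i cos(theta) + j sin(theta)))`
#' and the odd (sine) part replaces the cosine with a sine; `(i, j)` are row
#' and column offsets from the kernel centre.
#'
#' @param K Scale factor (dimensionless).
#' @param f Spatial frequency in cycles per pixel (`> 0`).
#' @param theta Orientation in radians.
#' @param sigma Gaussian envelope standard deviation in pixels (`> 0`).
#' @param half_size Kernel half-width; the arrays are `(2 half_size + 1)^2`.
#' @return An object of class `gabor_kernel` with fields `even_part` and
#'   `odd_part` plus the parameters.
#' @examples
#' k <- gabor_kernel(1, 0.25, 0, 2, 5)
#' k$even_part[6, 6]  # K at the origin
#' @export
gabor_kernel <- function(K, f, theta, sigma, half_size) {
  if (!(f > 0)) stop("f must be positive")
  if (!(sigma > 0)) stop("sigma must be positive")
  half_size <- as.integer(half_size)
  if (is.na(half_size) || half_size < 1L) stop("half_size must be >= 1")
  off <- seq.int(-half_size, half_size)
  i <- matrix(off, length(off), length(off))              # row offset
  j <- matrix(off, length(off), length(off), byrow = TRUE) # column offset
  env <- K * exp(-(i^2 + j^2) / (2 * sigma^2))
  arg <- 2 * pi * f * (i * cos(theta) + j * sin(theta))
  structure(
    list(K = K, f = f, theta = theta, sigma = sigma, half_size = half_size,
         even_part = env * cos(arg), odd_part = env * sin(arg)),
    class = "gabor_kernel"
  )
}

#' Default Gabor bank geometry
#'
#' Five equally spaced orientations and four wavelengths spanning 4 to 20
#' pixels per cycle. The rotation bank applied to the original
#' (undecomposed) tile uses five angles spanning 70 to 190 degrees.
#' @name gabor_defaults
#' @return Numeric vectors of degrees / pixels per cycle.
#' @export
default_gabor_orientations <- function() c(0, 36, 72, 108, 144)

#' @rdname gabor_defaults
#' @export
default_gabor_wavelengths <- function() c(4, 28 / 3, 44 / 3, 20)

#' @rdname gabor_defaults
#' @export
default_gabor_rotations <- function() c(70, 100, 130, 160, 190)

#' Gabor filter-bank magnitude responses
#'
#' Convolves the tile with every (orientation, wavelength) kernel pair and
#' returns same-size magnitude maps `sqrt(even^2 + odd^2)`. Convolution uses
#' symmetric reflection padding; frequency is `1 / wavelength`, the envelope
#' width is `sigma = sigma_factor * wavelength` (the default 0.56
#' approximates a one-octave bandwidth) and the kernel half-width is
#' `ceiling(3 sigma)`.
#'
#' @param tile A [tile()] or numeric matrix (any intensity scale).
#' @param orientations Orientations in degrees.
#' @param wavelengths Wavelengths in pixels per cycle.
#' @param K,sigma_factor Kernel scale factor and envelope/wavelength ratio.
#' @return A named list of `length(orientations) * length(wavelengths)`
#'   numeric magnitude matrices, wavelength varying fastest.
#' @export
gabor_bank_responses <- function(tile,
                                 orientations = default_gabor_orientations(),
                                 wavelengths = default_gabor_wavelengths(),
                                 K = 1, sigma_factor = 0.56) {
  img <- tile_pixels(tile)
  if (nrow(img) < 2L || ncol(img) < 2L) stop("tile must be larger than 1x1")
  if (length(orientations) == 0L || length(wavelengths) == 0L) {
    stop("orientations and wavelengths must be nonempty")
  }
  grid <- expand.grid(w = wavelengths, o = orientations,
                      KEEP.OUT.ATTRS = FALSE)
  kernels <- Map(function(w, o) {
    sigma <- sigma_factor * w
    kk <- gabor_kernel(K, 1 / w, o * pi / 180, sigma, ceiling(3 * sigma))
    kk$even_part + 1i * kk$odd_part
  }, grid$w, grid$o)
  hmax <- max(vapply(kernels, function(k) (nrow(k) - 1L) %/% 2L, integer(1)))
  n1 <- next_fast_size(nrow(img) + 2L * hmax)
  n2 <- next_fast_size(ncol(img) + 2L * hmax)
  key <- paste("gabor", n1, n2, K, sigma_factor,
               paste(signif(orientations, 12), collapse = "_"),
               paste(signif(wavelengths, 12), collapse = "_"), sep = "|")
  kffts <- pw_cache_get(key, function() {
    lapply(kernels, function(k) fft(embed_kernel(k, n1, n2)))
  })
  maps <- conv_reflect_bank(img, kernels, kffts)
  maps <- lapply(maps, Mod)
  names(maps) <- sprintf("o%03d_w%04.1f", rep(round(grid$o), 1), grid$w)
  maps
}
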