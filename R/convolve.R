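# FFT-based same-size 2-D convolution with symmetric (half-point) reflection
# padding. The image is embedded in a zero matrix of an FFT-friendly size
# with a reflected margin wide enough for the kernel support, so circular
# wrap-around never reaches the retained output window.

# Smallest 5-smooth integer >= n (keeps R's mixed-radix FFT fast).
next_fast_size <- function(n) {
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

# Pad a matrix by `h` on every side with half-point symmetric reflection,
# then zero-extend to rows x cols (>= n + 2h).
pad_reflect <- function(x, h, rows, cols) {
  ri <- fold_symmetric(seq.int(1L - h, nrow(x) + h), nrow(x))
  ci <- fold_symmetric(seq.int(1L - h, ncol(x) + h), ncol(x))
  p <- matrix(0, rows, cols)
  p[seq_along(ri), seq_along(ci)] <- x[ri, ci]
  p
}

# Embed a (2h+1)^2 kernel in an N1 x N2 zero matrix with its centre wrapped
# to position (1, 1), ready for circular convolution by FFT.
embed_kernel <- function(k, n1, n2) {
  h1 <- (nrow(k) - 1L) %/% 2L
  h2 <- (ncol(k) - 1L) %/% 2L
  z <- matrix(0 + 0i, n1, n2)
  ri <- ((seq.int(-h1, h1)) %% n1) + 1L
  ci <- ((seq.int(-h2, h2)) %% n2) + 1L
  z[ri, ci] <- k
  z
}

# Convolve an image with a list of odd-sized kernels sharing one padded FFT.
# Kernels may be complex (real part = even filter, imaginary = odd filter);
# the returned maps are then complex convolutions of the real image.
# `kernel_ffts`, if supplied, must be the precomputed FFTs of the embedded
# kernels for this padded size.
conv_reflect_bank <- function(img, kernels, kernel_ffts = NULL) {
  hmax <- max(vapply(kernels, function(k) (nrow(k) - 1L) %/% 2L, integer(1)))
  n1 <- next_fast_size(nrow(img) + 2L * hmax)
  n2 <- next_fast_size(ncol(img) + 2L * hmax)
  p <- pad_reflect(img, hmax, n1, n2)
  fp <- fft(p)
  if (is.null(kernel_ffts)) {
    kernel_ffts <- lapply(kernels, function(k) fft(embed_kernel(k, n1, n2)))
  }
  rows <- hmax + seq_len(nrow(img))
  cols <- hmax + seq_len(ncol(img))
  lapply(kernel_ffts, function(fk) {
    full <- fft(fp * fk, inverse = TRUE) / (n1 * n2)
    full[rows, cols]
  })
}

# Isotropic Gaussian blur (reflective boundary), used by the synthetic
# texture generator to impose a correlation length on white noise.
gaussian_blur <- function(img, sigma) {
  h <- max(1L, as.integer(ceiling(3 * sigma)))
  g1 <- exp(-(seq.int(-h, h))^2 / (2 * sigma^2))
  k <- outer(g1, g1)
  k <- k / sum(k)
  Re(conv_reflect_bank(img, list(k))[[1]])
}
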