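# Separable 2-D wavelet-packet decomposition, pure approximation branch.
#
# One analysis step filters rows and columns with the decomposition low-pass
# filter under symmetric half-point extension and keeps every second sample,
# so a side of length n becomes floor((n + m - 1) / 2) for filter length m.
# Applied recursively `level` times this yields the approximation packet
# node; detail sub-bands are never materialised.

# Symmetric half-point fold of 1-based positions onto 1..n
# (... x2 x1 | x1 x2 ... xn | xn xn-1 ...).
fold_symmetric <- function(pos, n) {
  if (n == 1L) return(rep(1L, length(pos)))
  u <- (pos - 1L) %% (2L * n)
  ifelse(u < n, u + 1L, 2L * n - u)
}

# Low-pass analysis step along the row index of a matrix (filters each
# column); returns floor((n + m - 1)/2) rows.
dwt_lo_step <- function(x, h) {
  n <- nrow(x)
  m <- length(h)
  L <- (n + m - 1L) %/% 2L
  ext_rows <- fold_symmetric(seq.int(1L - (m - 1L), n + (m - 1L)), n)
  e <- x[ext_rows, , drop = FALSE]
  out <- matrix(0, L, ncol(x))
  base <- 2L * seq_len(L) - 1L
  for (j in seq_len(m)) {
    out <- out + h[j] * e[base + j, , drop = FALSE]
  }
  out
}

wpt_step_2d <- function(x, h) {
  t(dwt_lo_step(t(dwt_lo_step(x, h)), h))
}

#' Maximum feasible decomposition level for a side length
#'
#' Iterates the side-length recurrence `n -> floor((n + m - 1) / 2)` and
#' counts how many analysis steps are possible. A step requires the current
#' side to be at least the filter length `m` and must leave at least 2
#' samples.
#'
#' @param side Side length in pixels.
#' @param filter_length Length of the decomposition low-pass filter.
#' @return Integer number of feasible levels (0 if the input is too small).
#' @examples
#' max_feasible_level(150, 2) # bior1.1 / haar on a 150-px tile
#' max_feasible_level(10, 2)
#' @export
max_feasible_level <- function(side, filter_length) {
  side <- as.integer(side)
  filter_length <- as.integer(filter_length)
  if (is.na(side) || side < 1L) stop("side must be >= 1")
  if (is.na(filter_length) || filter_length < 2L) stop("filter_length must be >= 2")
  lev <- 0L
  s <- side
  repeat {
    if (s < max(2L, filter_length)) break
    s2 <- (s + filter_length - 1L) %/% 2L
    if (s2 < 2L) break
    s <- s2
    lev <- lev + 1L
  }
  lev
}

#' Wavelet-packet approximation image of a tile
#'
#' Applies the separable low-pass analysis step of the chosen mother wavelet
#' `spec$level` times with symmetric half-point boundary extension and
#' returns the approximation coefficients (the repeated low-low packet
#' node). Coefficients are kept at full floating precision; quantise with
#' [rescale_to_8bit()] before descriptors that need 8-bit intensities.
#'
#' @param tile A [tile()] object or a numeric matrix of intensities.
#' @param spec A [wavelet_spec()].
#' @return An object of class `wpt_approx` with fields `coefficients`
#'   (numeric matrix), `source_id`, `spec` and `side_lengths`.
#' @examples
#' t0 <- tile(matrix(0:24, 5, 5))
#' wpt_approximation(t0, wavelet_spec("haar", 1))
#' @export
wpt_approximation <- function(tile, spec) {
  stopifnot(inherits(spec, "wavelet_spec"))
  px <- tile_pixels(tile)
  if (length(px) == 0L) stop("tile is empty")
  h <- spec$filter
  maxlev <- min(
    max_feasible_level(nrow(px), length(h)),
    max_feasible_level(ncol(px), length(h))
  )
  if (spec$level > maxlev) {
    stop(sprintf(
      "level %d infeasible for a %dx%d tile with filter length %d (max feasible level: %d)",
      spec$level, nrow(px), ncol(px), length(h), maxlev
    ))
  }
  a <- px
  for (l in seq_len(spec$level)) a <- wpt_step_2d(a, h)
  structure(
    list(
      coefficients = a,
      source_id = tile_id(tile),
      spec = spec,
      side_lengths = c(nrow(a), ncol(a))
    ),
    class = "wpt_approx"
  )
}

#' @export
print.wpt_approx <- function(x, ...) {
  cat(sprintf(
    "<wpt_approx> %dx%d coefficients (%s, level %d) from tile '%s'\n",
    x$side_lengths[1], x$side_lengths[2], x$spec$name, x$spec$level,
    if (is.na(x$source_id)) "?" else x$source_id
  ))
  invisible(x)
}

#' Write an approximation image as a PNG for visual inspection
#'
#' The coefficients are quantised with [rescale_to_8bit()] before writing.
#'
#' @param approx A `wpt_approx` object.
#' @param file Output PNG path.
#' @return Invisibly, the file path.
#' @export
write_approx_png <- function(approx, file) {
  stopifnot(inherits(approx, "wpt_approx"))
  png::writePNG(rescale_to_8bit(approx) / 255, file)
  invisible(file)
}

#' Min-max rescale an approximation image to 8-bit intensities
#'
#' Maps the coefficient range linearly onto 0..255 and rounds half-up.
#' A constant input maps to all zeros by convention (ranges below about
#' 1e-8 of the magnitude count as constant, so floating rounding noise on a
#' flat map is never amplified to full scale), keeping downstream
#' co-occurrence and binary-pattern descriptors defined on flat deep-level
#' approximations.
#'
#' @param approx A `wpt_approx` object or a numeric matrix.
#' @return Integer matrix with values in 0..255.
#' @export
rescale_to_8bit <- function(approx) {
  x <- if (inherits(approx, "wpt_approx")) approx$coefficients else approx
  if (!all(is.finite(x))) stop("non-finite coefficients cannot be quantised")
  r <- range(x)
  # a range below ~1e-8 of the magnitude is flat up to FFT rounding noise;
  # rescaling it would amplify that noise to full 8-bit scale
  if (r[2] - r[1] <= 1e-8 * max(abs(r)) + 1e-12) {
    y <- array(0L, dim = dim(x))
  } else {
    y <- as.integer(floor((x - r[1]) / (r[2] - r[1]) * 255 + 0.5))
    dim(y) <- dim(x)
  }
  y
}
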