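# Gray-level co-occurrence matrices and their higher-order statistics.

glcm_offset <- function(angle, distance) {
  switch(as.character(angle),
    "0"   = c(0L, distance),
    "45"  = c(-distance, distance),
    "90"  = c(-distance, 0L),
    "135" = c(-distance, -distance),
    stop("angle must be one of 0, 45, 90, 135 degrees")
  )
}

#' Default GLCM geometry: four angles spanning 0 to 135 degrees and three
#' distances spanning 1 to 5 pixels.
#' @name glcm_defaults
#' @return Numeric vectors (degrees / pixels).
#' @export
default_glcm_angles <- function() c(0, 45, 90, 135)

#' @rdname glcm_defaults
#' @export
default_glcm_distances <- function() c(1, 3, 5)

#' Gray-level co-occurrence matrix
#'
#' Counts ordered pixel pairs `(reference, neighbor)` at the given angle and
#' distance, symmetrises (each pair counted in both directions) and
#' normalises to sum 1. If the offset does not fit inside the image (deep
#' decomposition levels), an empty-flagged matrix is returned and all
#' derived statistics are zero by convention.
#'
#' @param tile8 A [tile()] or integer matrix with intensities `< levels`.
#' @param angle One of 0, 45, 90, 135 (degrees).
#' @param distance Offset length in pixels (`>= 1`).
#' @param levels Number of gray levels (256 for 8-bit input).
#' @return An object of class `glcm_matrix` with fields `P` (levels x levels
#'   normalised counts), `levels`, `angle`, `distance`, `empty`.
#' @export
glcm <- function(tile8, angle, distance, levels = 256L) {
  x <- tile_pixels(tile8)
  distance <- as.integer(distance)
  if (is.na(distance) || distance < 1L) stop("distance must be >= 1")
  if (min(x) < 0 || max(x) >= levels) {
    stop("intensities must lie in [0, levels)")
  }
  off <- glcm_offset(angle, distance)
  nr <- nrow(x); nc <- ncol(x)
  rs <- max(1L, 1L - off[1]):min(nr, nr - off[1])
  cs <- max(1L, 1L - off[2]):min(nc, nc - off[2])
  if (length(rs) < 1L || length(cs) < 1L ||
      rs[1] > rs[length(rs)] || cs[1] > cs[length(cs)] ||
      abs(off[1]) >= nr || abs(off[2]) >= nc) {
    return(structure(
      list(P = matrix(0, levels, levels), levels = levels,
           angle = angle, distance = distance, empty = TRUE),
      class = "glcm_matrix"
    ))
  }
  a <- x[rs, cs, drop = FALSE]
  b <- x[rs + off[1], cs + off[2], drop = FALSE]
  counts <- tabulate(as.vector(a) * levels + as.vector(b) + 1L,
                     nbins = levels * levels)
  P <- matrix(counts, levels, levels, byrow = TRUE)  # row = reference level
  P <- P + t(P)
  P <- P / sum(P)
  structure(
    list(P = P, levels = levels, angle = angle, distance = distance,
         empty = FALSE),
    class = "glcm_matrix"
  )
}

#' @export
print.glcm_matrix <- function(x, ...) {
  cat(sprintf("<glcm_matrix> %d levels, angle %s, distance %d%s\n",
              x$levels, format(x$angle), x$distance,
              if (x$empty) " (empty)" else ""))
  invisible(x)
}

glcm_weight_masks <- function(levels) {
  pw_cache_get(paste0("glcm_w_", levels), function() {
    i <- matrix(0:(levels - 1), levels, levels)
    j <- t(i)
    d <- i - j
    list(contrast = d^2, dissimilarity = abs(d), homogeneity = 1 / (1 + d^2))
  })
}

#' Higher-order statistics of a co-occurrence matrix
#'
#' Computes contrast, dissimilarity, homogeneity, correlation, angular
#' second moment (ASM) and energy (`sqrt(ASM)`) from a normalised GLCM.
#' Conventions for degenerate inputs: an empty-flagged matrix yields all
#' six statistics 0; a zero marginal variance (perfectly predictable image)
#' yields correlation 1.
#'
#' @param m A `glcm_matrix` from [glcm()].
#' @return Named numeric vector `(contrast, dissimilarity, homogeneity,
#'   correlation, ASM, energy)`.
#' @export
glcm_features <- function(m) {
  stopifnot(inherits(m, "glcm_matrix"))
  out <- c(contrast = 0, dissimilarity = 0, homogeneity = 0,
           correlation = 0, ASM = 0, energy = 0)
  if (m$empty) return(out)
  P <- m$P
  w <- glcm_weight_masks(m$levels)
  lev <- 0:(m$levels - 1)
  pi_ <- rowSums(P)
  pj_ <- colSums(P)
  mu_i <- sum(lev * pi_)
  mu_j <- sum(lev * pj_)
  var_i <- sum((lev - mu_i)^2 * pi_)
  var_j <- sum((lev - mu_j)^2 * pj_)
  asm <- sum(P * P)
  corr <- if (var_i <= 0 || var_j <= 0) 1 else
    as.numeric(t(lev - mu_i) %*% P %*% (lev - mu_j)) / sqrt(var_i * var_j)
  out["contrast"] <- sum(P * w$contrast)
  out["dissimilarity"] <- sum(P * w$dissimilarity)
  out["homogeneity"] <- sum(P * w$homogeneity)
  out["correlation"] <- corr
  out["ASM"] <- asm
  out["energy"] <- sqrt(asm)
  out
}

#' First-order statistics of a feature map
#'
#' @param map Nonempty numeric matrix or vector with finite values.
#' @return Named vector `(max, min, mean, std)`; the standard deviation is
#'   the population form (divide by `n`).
#' @export
first_order_stats <- function(map) {
  v <- as.numeric(map)
  if (length(v) == 0L) stop("empty map")
  if (!all(is.finite(v))) stop("map contains non-finite values")
  mu <- mean(v)
  c(max = max(v), min = min(v), mean = mu,
    std = sqrt(mean((v - mu)^2)))
}
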