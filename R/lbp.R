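# Local binary patterns on a circular neighborhood (P neighbors, radius R),
# with bilinear interpolation of off-grid neighbors and symmetric reflection
# at the borders. Neighbor p (p = 0..P-1) sits at angle 2*pi*p/P, i.e. at
# offset (row + R*sin, col + R*cos); the code is sum over p of
# s(i_p - i_c) * 2^p with s(x) = 1 for x >= 0.

lbp_methods <- function() c("raw", "rotation", "variance", "uniform")

# Minimal value over circular bit rotations of each P-bit code.
lbp_ri_table <- function(P = 8L) {
  pw_cache_get(paste0("lbp_ri_", P), function() {
    codes <- 0:(2^P - 1)
    best <- codes
    for (r in seq_len(P - 1L)) {
      rot <- bitwOr(bitwShiftR(codes, r),
                    bitwAnd(bitwShiftL(codes, P - r), 2^P - 1L))
      best <- pmin(best, rot)
    }
    best
  })
}

# Non-rotation-invariant uniform mapping: codes with at most two circular
# 0/1 transitions get ranks 0..57 (ascending code order); the rest share
# bin 58. 59 output codes at P = 8.
lbp_uniform_table <- function(P = 8L) {
  pw_cache_get(paste0("lbp_u_", P), function() {
    codes <- 0:(2^P - 1)
    bits <- sapply(0:(P - 1), function(b) bitwAnd(bitwShiftR(codes, b), 1L))
    trans <- rowSums(bits != bits[, c(2:P, 1)])
    uni <- which(trans <= 2L) - 1L
    out <- rep(length(uni), 2^P)  # non-uniform bin
    out[uni + 1L] <- seq_along(uni) - 1L
    out
  })
}

# Interpolated neighbor map at fixed offset (dr, dc) from a padded image.
neighbor_map <- function(pad, h, nr, nc, dr, dc) {
  shift <- function(a, b) pad[h + a + seq_len(nr), h + b + seq_len(nc)]
  if (abs(dr - round(dr)) < 1e-9 && abs(dc - round(dc)) < 1e-9) {
    return(shift(round(dr), round(dc)))
  }
  r0 <- floor(dr); c0 <- floor(dc)
  fr <- dr - r0;  fc <- dc - c0
  v <- (1 - fr) * (1 - fc) * shift(r0, c0) +
    (1 - fr) * fc * shift(r0, c0 + 1) +
    fr * (1 - fc) * shift(r0 + 1, c0) +
    fr * fc * shift(r0 + 1, c0 + 1)
  # quantise interpolated intensities so exact ties with the centre are not
  # broken by floating rounding of the bilinear weights
  round(v * 1e6) / 1e6
}

#' Local binary pattern map of a tile
#'
#' Computes a per-pixel LBP value over a circle of `P` neighbors at radius
#' `R`. Methods: `"raw"` returns the plain P-bit code; `"rotation"` the
#' rotation-invariant code (minimum over circular bit rotations);
#' `"variance"` the population variance of the interpolated neighbor
#' intensities (a gray-scale contrast measure); `"uniform"` the
#' non-rotation-invariant uniform code (59 bins at P = 8, finer angular
#' quantisation).
#'
#' @param tile A [tile()] or numeric matrix of intensities.
#' @param P Number of circular neighbors.
#' @param R Circle radius in pixels.
#' @param method One of `"raw"`, `"rotation"`, `"variance"`, `"uniform"`.
#' @return Numeric matrix the size of the tile (integer codes, or variances
#'   for `method = "variance"`).
#' @export
lbp_map <- function(tile, P = 8L, R = 1, method = c("raw", "rotation",
                                                    "variance", "uniform")) {
  method <- match.arg(method)
  x <- tile_pixels(tile)
  if (P < 4L) stop("P must be >= 4")
  if (R < 1) stop("R must be >= 1")
  if (nrow(x) < 2 * R + 1 || ncol(x) < 2 * R + 1) {
    stop("tile smaller than the (2R+1)^2 neighborhood")
  }
  nr <- nrow(x); nc <- ncol(x)
  h <- as.integer(ceiling(R)) + 1L
  ri <- fold_symmetric(seq.int(1L - h, nr + h), nr)
  ci <- fold_symmetric(seq.int(1L - h, nc + h), nc)
  pad <- x[ri, ci]
  ang <- 2 * pi * (0:(P - 1)) / P
  if (method == "variance") {
    s1 <- matrix(0, nr, nc); s2 <- matrix(0, nr, nc)
    for (p in seq_len(P)) {
      v <- neighbor_map(pad, h, nr, nc, R * sin(ang[p]), R * cos(ang[p]))
      s1 <- s1 + v; s2 <- s2 + v^2
    }
    return(s2 / P - (s1 / P)^2)
  }
  code <- matrix(0L, nr, nc)
  for (p in seq_len(P)) {
    v <- neighbor_map(pad, h, nr, nc, R * sin(ang[p]), R * cos(ang[p]))
    code <- code + (v >= x) * 2L^(p - 1L)
  }
  switch(method,
    raw = code,
    rotation = matrix(lbp_ri_table(P)[code + 1L], nr, nc),
    uniform = matrix(lbp_uniform_table(P)[code + 1L], nr, nc)
  )
}
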