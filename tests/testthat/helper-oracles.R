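# Brute-force reference implementations, kept deliberately naive and
# independent of the package internals.

# Half-point symmetric index fold (written out with explicit bouncing).
oracle_fold <- function(t, n) {
  if (n == 1) return(1)
  while (t < 1 || t > n) {
    if (t < 1) t <- 1 - t
    if (t > n) t <- 2 * n + 1 - t
  }
  t
}

# Same-size 2-D convolution with reflective boundary, direct sliding sums.
oracle_conv_reflect <- function(img, kernel) {
  h1 <- (nrow(kernel) - 1) / 2
  h2 <- (ncol(kernel) - 1) / 2
  out <- matrix(0, nrow(img), ncol(img))
  for (i in seq_len(nrow(img))) {
    for (j in seq_len(ncol(img))) {
      acc <- 0
      for (u in -h1:h1) {
        for (v in -h2:h2) {
          acc <- acc + kernel[u + h1 + 1, v + h2 + 1] *
            img[oracle_fold(i - u, nrow(img)), oracle_fold(j - v, ncol(img))]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# Ordered-pair counting for a co-occurrence matrix, double loop.
oracle_glcm <- function(x, dr, dc, levels) {
  P <- matrix(0, levels, levels)
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(ncol(x))) {
      i2 <- i + dr; j2 <- j + dc
      if (i2 >= 1 && i2 <= nrow(x) && j2 >= 1 && j2 <= ncol(x)) {
        P[x[i, j] + 1, x[i2, j2] + 1] <- P[x[i, j] + 1, x[i2, j2] + 1] + 1
      }
    }
  }
  P <- P + t(P)
  if (sum(P) > 0) P / sum(P) else P
}

glcm_angle_offset <- function(angle, d) {
  switch(as.character(angle),
         "0" = c(0, d), "45" = c(-d, d), "90" = c(-d, 0), "135" = c(-d, -d))
}

# Per-pixel raw LBP code: threshold each interpolated circular neighbor
# against the centre and sum the powers of two.
oracle_lbp_raw <- function(x, P = 8, R = 1) {
  interp <- function(r, c) {
    r0 <- floor(r); c0 <- floor(c)
    fr <- r - r0; fc <- c - c0
    g <- function(a, b) x[oracle_fold(a, nrow(x)), oracle_fold(b, ncol(x))]
    v <- (1 - fr) * (1 - fc) * g(r0, c0) + (1 - fr) * fc * g(r0, c0 + 1) +
      fr * (1 - fc) * g(r0 + 1, c0) + fr * fc * g(r0 + 1, c0 + 1)
    round(v * 1e6) / 1e6  # same tie-robust quantisation as the descriptor
  }
  out <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(ncol(x))) {
      code <- 0
      for (p in 0:(P - 1)) {
        a <- 2 * pi * p / P
        dr <- R * sin(a); dc <- R * cos(a)
        if (abs(dr - round(dr)) < 1e-9) dr <- round(dr)
        if (abs(dc - round(dc)) < 1e-9) dc <- round(dc)
        v <- interp(i + dr, j + dc)
        if (v >= x[i, j]) code <- code + 2^p
      }
      out[i, j] <- code
    }
  }
  out
}

# 2^L x 2^L block sums of a matrix whose sides are multiples of 2^L.
oracle_block_sum <- function(x, L) {
  s <- 2^L
  out <- matrix(0, nrow(x) / s, ncol(x) / s)
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(ncol(out))) {
      out[i, j] <- sum(x[(i - 1) * s + 1:s, (j - 1) * s + 1:s])
    }
  }
  out
}

random_tile_matrix <- function(n, m = n) {
  matrix(sample(0:255, n * m, replace = TRUE), n, m)
}
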