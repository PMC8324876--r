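test_that("hand-enumerated co-occurrence matrices are reproduced", {
  # [[0,0],[1,1]]: two horizontal pairs, both within a level
  x <- matrix(c(0, 1, 0, 1), 2, 2)  # rows: (0,0) and (1,1)
  m <- glcm(x, 0, 1, levels = 2)
  expect_equal(m$P, matrix(c(0.5, 0, 0, 0.5), 2, 2))
  # constant image: all mass on one diagonal cell
  mc <- glcm(matrix(3L, 4, 4), 0, 1, levels = 4)
  expect_equal(mc$P[4, 4], 1)
  expect_equal(sum(mc$P), 1)
})

test_that("glcm matches the brute-force pair counter everywhere", {
  set.seed(41)
  for (rep in 1:3) {
    x <- matrix(sample(0:3, 36, TRUE), 6, 6)
    for (a in c(0, 45, 90, 135)) {
      for (d in c(1, 3, 5)) {
        m <- glcm(x, a, d, levels = 4)
        off <- glcm_angle_offset(a, d)
        ref <- oracle_glcm(x, off[1], off[2], 4)
        if (m$empty) {
          expect_equal(sum(ref), 0, info = paste(a, d))
        } else {
          expect_equal(m$P, ref, info = paste(a, d))
        }
      }
    }
  }
})

test_that("normalisation and symmetry hold on random inputs", {
  set.seed(42)
  x <- matrix(sample(0:15, 100, TRUE), 10, 10)
  for (a in c(0, 45, 90, 135)) {
    m <- glcm(x, a, 2, levels = 16)
    expect_equal(sum(m$P), 1)
    expect_equal(m$P, t(m$P))
    expect_true(all(m$P >= 0))
  }
  expect_error(glcm(x, 30, 1, levels = 16), "angle")
  expect_error(glcm(x, 0, 1, levels = 8), "levels")
})

test_that("higher-order statistics follow their defining sums", {
  # 0/1 checkerboard at angle 0, d = 1: every pair is (0,1) or (1,0)
  cb <- matrix((outer(1:6, 1:6, "+")) %% 2, 6, 6)
  f <- glcm_features(glcm(cb, 0, 1, levels = 2))
  expect_equal(unname(f["contrast"]), 1)
  expect_equal(unname(f["dissimilarity"]), 1)
  expect_equal(unname(f["homogeneity"]), 0.5)
  expect_equal(unname(f["ASM"]), 0.5)
  expect_equal(unname(f["energy"]), sqrt(0.5))
  expect_equal(unname(f["correlation"]), -1)
  # constant image: flat-image conventions
  fc <- glcm_features(glcm(matrix(7L, 5, 5), 0, 1, levels = 8))
  expect_equal(unname(fc[c("contrast", "dissimilarity")]), c(0, 0))
  expect_equal(unname(fc[c("homogeneity", "correlation", "ASM", "energy")]),
               c(1, 1, 1, 1))
})

test_that("statistic inequalities hold on random matrices", {
  set.seed(43)
  for (rep in 1:5) {
    x <- matrix(sample(0:7, 64, TRUE), 8, 8)
    f <- glcm_features(glcm(x, 45, 1, levels = 8))
    expect_gte(f[["contrast"]], f[["dissimilarity"]])
    expect_true(f[["homogeneity"]] > 0 && f[["homogeneity"]] <= 1)
    expect_true(f[["ASM"]] > 0 && f[["ASM"]] <= 1)
    expect_true(abs(f[["correlation"]]) <= 1 + 1e-12)
    expect_equal(f[["energy"]]^2, f[["ASM"]])
  }
})

test_that("offsets larger than the image give the all-zero convention", {
  m <- glcm(matrix(0:3, 2, 2), 0, 5, levels = 4)
  expect_true(m$empty)
  expect_true(all(glcm_features(m) == 0))
})

test_that("first-order statistics use the population form", {
  expect_equal(first_order_stats(matrix(4.5, 3, 3)),
               c(max = 4.5, min = 4.5, mean = 4.5, std = 0))
  expect_equal(first_order_stats(c(0, 255)),
               c(max = 255, min = 0, mean = 127.5, std = 127.5))
  set.seed(44)
  v <- rnorm(50)
  f <- first_order_stats(v)
  expect_true(f[["min"]] <= f[["mean"]] && f[["mean"]] <= f[["max"]])
  expect_error(first_order_stats(numeric(0)), "empty")
})
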