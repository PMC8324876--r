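test_that("anova_f reproduces hand computations and conventions", {
  r <- anova_f(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(r$F, 16)          # SSB = 16, MSW = 0.5
  expect_identical(c(r$df1, r$df2), c(2L, 3L))
  expect_equal(anova_f(list(c(1, 2, 3), c(1, 2, 3)))$F, 0)
  z <- anova_f(list(c(0, 0, 0), c(1, 1, 1)))
  expect_identical(z$F, Inf)
  expect_identical(z$p, 0)
  flat <- anova_f(list(c(2, 2), c(2, 2)))
  expect_identical(c(flat$F, flat$p), c(0, 1))
  expect_error(anova_f(list(1:3)), "two groups")
})

test_that("anova_f agrees with the classical oracle on random groups", {
  set.seed(61)
  for (rep in 1:5) {
    groups <- lapply(sample(3:6, sample(2:4, 1), replace = TRUE),
                     function(n) rnorm(n, mean = runif(1, 0, 3)))
    r <- anova_f(groups)
    y <- unlist(groups)
    g <- factor(rep(seq_along(groups), lengths(groups)))
    ref <- stats::oneway.test(y ~ g, var.equal = TRUE)
    expect_equal(r$F, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(r$p, unname(ref$p.value), tolerance = 1e-10)
  }
})

test_that("f_critical is the upper quantile with the right limits", {
  expect_equal(f_critical(0.05, 7, 492), 2.03, tolerance = 0.005)
  expect_equal(f_critical(0.05, 1, 1e6), 3.8415, tolerance = 1e-3)
  expect_gt(f_critical(0.05, 3, 10), f_critical(0.05, 3, 50))
  expect_gt(f_critical(0.05, 3, 50), f_critical(0.05, 3, 1000))
  expect_error(f_critical(1.5, 2, 2), "alpha")
  expect_error(f_critical(0.05, 0, 2), "df")
})

make_feature_table <- function(X, labels) {
  colnames(X) <- sprintf("f%03d", seq_len(ncol(X)))
  structure(list(features = X, labels = labels,
                 tile_ids = sprintf("t%03d", seq_len(nrow(X))),
                 wavelet = "none", level = 0L),
            class = "feature_table")
}

test_that("select_features applies the dual criterion per column", {
  set.seed(62)
  n_per <- 20L
  labels <- rep(letters[1:8], each = n_per)
  n <- length(labels)
  X <- matrix(rnorm(n * 30), n, 30)
  X[, 1] <- as.integer(factor(labels))          # class index: infinite F
  X[, 2] <- 7                                    # constant: F = 0
  X[, 3] <- X[, 3] + as.integer(factor(labels)) # strong signal
  tab <- make_feature_table(X, labels)
  sel <- select_features(tab, alpha = 0.05)
  expect_true(sel$keep_mask[1])
  expect_false(sel$keep_mask[2])
  expect_true(sel$keep_mask[3])
  expect_identical(sel$F[[2]], 0)
  # independent column-wise oracle: recompute both criteria from sums
  fc <- qf(0.95, 7, n - 8)
  g <- factor(labels)
  for (j in seq_len(ncol(X))) {
    y <- X[, j]
    gm <- tapply(y, g, mean)
    ssb <- sum(table(g) * (gm - mean(y))^2)
    ssw <- sum((y - gm[g])^2)
    if (ssb <= 1e-12 * max(1, var(y))) {
      keep_ref <- FALSE
    } else if (ssw <= 1e-12) {
      keep_ref <- TRUE  # F = Inf, p = 0
    } else {
      Fj <- (ssb / 7) / (ssw / (n - 8))
      pj <- pf(Fj, 7, n - 8, lower.tail = FALSE)
      keep_ref <- pj < 0.05 && Fj > fc
    }
    expect_identical(unname(sel$keep_mask[j]), keep_ref, info = j)
  }
  expect_identical(sel$df1, 7L)
  expect_identical(sel$df2, n - 8L)
})

test_that("selection is row-order invariant and never refits on other rows", {
  set.seed(63)
  labels <- rep(c("a", "b", "c"), each = 10)
  X <- matrix(rnorm(300), 30, 10)
  tab <- make_feature_table(X, labels)
  sel <- select_features(tab)
  perm <- sample(30)
  tab_perm <- make_feature_table(X[perm, ], labels[perm])
  sel_perm <- select_features(tab_perm)
  expect_identical(sel$keep_mask, sel_perm$keep_mask)
  expect_equal(sel$F, sel_perm$F)
  expect_error(select_features(make_feature_table(X, rep("a", 30))),
               "two classes")
})

test_that("selection results survive a JSON round trip", {
  set.seed(64)
  labels <- rep(c("a", "b", "c", "d"), each = 6)
  X <- matrix(rnorm(24 * 8), 24, 8)
  X[, 4] <- as.integer(factor(labels))  # infinite F exercises encoding
  sel <- select_features(make_feature_table(X, labels))
  f <- withr::local_tempfile(fileext = ".json")
  write_selection_json(sel, f)
  back <- read_selection_json(f)
  expect_identical(back$keep_mask, unname(sel$keep_mask))
  expect_equal(unname(back$F), unname(sel$F))
  expect_equal(back$f_critical, sel$f_critical)
})
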