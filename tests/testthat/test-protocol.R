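test_that("stratified splits partition the data with balanced classes", {
  labels <- rep(letters[1:2], each = 50)
  plan <- make_splits(labels, holdout_frac = 0.1, k = 9, seed = 4)
  expect_length(plan$validation, 10L)
  expect_true(all(lengths(plan$folds) == 10L))
  all_idx <- sort(c(plan$validation, unlist(plan$folds)))
  expect_identical(all_idx, seq_along(labels))        # exact partition
  expect_identical(anyDuplicated(all_idx), 0L)
  # per-class counts within 1 of proportionality in every subset
  for (sub in c(list(plan$validation), plan$folds)) {
    counts <- table(factor(labels[sub], levels = c("a", "b")))
    expect_true(all(abs(counts - length(sub) / 2) <= 1))
  }
  # deterministic per seed
  plan2 <- make_splits(labels, holdout_frac = 0.1, k = 9, seed = 4)
  expect_identical(plan, plan2)
  plan3 <- make_splits(labels, holdout_frac = 0.1, k = 9, seed = 5)
  expect_false(identical(plan$folds, plan3$folds))
})

test_that("undersized classes are reported by name", {
  labels <- c(rep("big", 50), rep("tiny", 4))
  expect_error(make_splits(labels, 0.1, k = 10), "tiny")
})

test_that("accuracy is the fraction of correct predictions", {
  expect_equal(accuracy(c("a", "b"), c("a", "b")), 1)
  expect_equal(accuracy(c("a", "b"), c("b", "a")), 0)
  expect_equal(accuracy(rep("a", 450), c(rep("a", 429), rep("b", 21))),
               429 / 450)
  expect_error(accuracy(character(0), character(0)), "empty")
  expect_error(accuracy("a", c("a", "b")), "equal length")
})

small_sweep_setup <- function() {
  tiles <- fixture_get("sweep_tiles", function() {
    generate_dataset(synth_config(n_per_class = 4, tile_side = 32, seed = 77))
  })
  plan <- make_splits(tile_labels(tiles), holdout_frac = 0.25, k = 2,
                      seed = 77)
  list(tiles = tiles, plan = plan)
}

test_that("run_sweep walks the grid and reruns identically", {
  s <- small_sweep_setup()
  sweep <- run_sweep(s$tiles, c("haar", "db2"), 1:2, "svm_full", s$plan)
  expect_identical(nrow(sweep), 4L)
  expect_setequal(sweep$wavelet, c("haar", "db2"))
  expect_true(all(sweep$std_accuracy >= 0))
  expect_true(all(sweep$mean_accuracy >= 0 & sweep$mean_accuracy <= 1))
  sweep2 <- run_sweep(s$tiles, c("haar", "db2"), 1:2, "svm_full", s$plan)
  expect_equal(sweep$mean_accuracy, sweep2$mean_accuracy)
  # infeasible levels are skipped, not fatal
  expect_message(
    sk <- run_sweep(s$tiles, "haar", c(1, 12), "svm_full", s$plan),
    "infeasible"
  )
  expect_identical(nrow(sk), 1L)
})

test_that("single-class data is rejected by the classifier precondition", {
  s <- small_sweep_setup()
  ft <- extract_batch(s$tiles, wavelet_spec("haar", 1))
  ft$labels <- rep("only", length(ft$labels))
  expect_error(
    run_strategy(NULL, wavelet_spec("haar", 1), "svm_full", s$plan,
                 features = ft),
    "two classes"
  )
})

test_that("sweep summaries bin shares that sum to one per group", {
  sweep <- data.frame(
    wavelet = c("haar", "haar", "db2", "db2", "sym2", "sym2"),
    family = c("haar", "haar", "db", "db", "sym", "sym"),
    level = c(1, 2, 1, 2, 1, 2),
    strategy = "svm_full",
    mean_accuracy = c(0.95, 0.55, 0.85, 0.45, 0.9, 0.5),
    std_accuracy = 0.01,
    n_selected_features = 532
  )
  by_fam <- summarize_sweep(sweep, "family")
  shares <- tapply(by_fam$hist$share, by_fam$hist$group, sum)
  expect_true(all(abs(shares - 1) < 1e-12))
  by_lev <- summarize_sweep(sweep, "level")
  expect_identical(sort(unique(by_lev$hist$group)), c("1", "2"))
  m <- by_lev$means
  expect_equal(m$mean_accuracy[m$group == "1"], mean(c(0.95, 0.85, 0.9)))
  expect_equal(m$mean_accuracy[m$group == "2"], mean(c(0.55, 0.45, 0.5)))
  expect_error(summarize_sweep(sweep, "wavelength"), "arg")
})

test_that("fitted models are frozen against later test-row mutation", {
  s <- small_sweep_setup()
  ft <- extract_batch(s$tiles, wavelet_spec("haar", 1))
  train <- ft; train$features <- ft$features[1:24, , drop = FALSE]
  train$labels <- ft$labels[1:24]; train$tile_ids <- ft$tile_ids[1:24]
  test <- ft; test$features <- ft$features[25:32, , drop = FALSE]
  test$labels <- ft$labels[25:32]; test$tile_ids <- ft$tile_ids[25:32]
  m <- train_svm_rbf(train)
  p1 <- predict(m, test)
  test$features[1, ] <- test$features[1, ] * 0  # mutate after fitting
  p2 <- predict(m, test)
  expect_identical(p1[-1], p2[-1])
})

test_that("models survive a save/load round trip", {
  s <- small_sweep_setup()
  ft <- extract_batch(s$tiles, wavelet_spec("haar", 1))
  sub <- ft_subset_for_test(ft, 1:24)
  m <- train_svm_rbf(sub)
  f <- withr::local_tempfile(fileext = ".bin")
  save_model(m, f)
  back <- load_model(f)
  probe <- ft_subset_for_test(ft, 25:32)
  expect_identical(predict(back, probe), predict(m, probe))
})
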