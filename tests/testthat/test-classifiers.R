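fake_table <- function(X, labels, prefix = "t") {
  colnames(X) <- sprintf("f%02d", seq_len(ncol(X)))
  structure(list(features = X, labels = labels,
                 tile_ids = sprintf("%s%03d", prefix, seq_len(nrow(X))),
                 wavelet = "none", level = 0L),
            class = "feature_table")
}

two_blobs <- function(n = 20, seed = 71) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(2 * n, 0, 0.3), n, 2),
             matrix(rnorm(2 * n, 4, 0.3), n, 2))
  fake_table(X, rep(c("lo", "hi"), each = n))
}

test_that("standardisation uses training statistics only", {
  set.seed(72)
  train <- fake_table(cbind(rnorm(30, 5, 2), rnorm(30, -1, 4), rep(3, 30)),
                      rep(c("a", "b"), 15))
  held <- fake_table(matrix(c(9, 2, 3), 1, 3), "a", prefix = "h")
  std <- standardize_fit_apply(train, held)
  expect_equal(unname(colMeans(std$train$features[, 1:2])), c(0, 0),
               tolerance = 1e-12)
  expect_equal(unname(apply(std$train$features[, 1:2], 2, sd)), c(1, 1),
               tolerance = 1e-12)
  expect_true(all(std$train$features[, 3] == 0))  # constant column
  expect_equal(unname(std$others[[1]]$features[1, 1]),
               (9 - mean(train$features[, 1])) / sd(train$features[, 1]))
})

test_that("the RBF SVM separates well-separated blobs deterministically", {
  train <- two_blobs()
  m <- train_svm_rbf(train)
  expect_identical(predict(m, train), train$labels)
  # duplicating the training rows leaves probe predictions unchanged
  dup <- fake_table(rbind(train$features, train$features),
                    c(train$labels, train$labels))
  m2 <- train_svm_rbf(dup)
  probe <- fake_table(matrix(c(0, 4, 0, 4, 2.4, 1.6), 3, 2), rep("?", 3),
                      prefix = "p")
  expect_identical(predict(m, probe), predict(m2, probe))
  m3 <- train_svm_rbf(train)
  expect_identical(predict(m3, probe), predict(m, probe))
  expect_error(train_svm_rbf(fake_table(train$features,
                                        rep("a", 40))), "two classes")
})

xor_tables <- function(n_rep = 50, noise = 0.05, seed = 73) {
  set.seed(seed)
  base <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE)
  lab <- c("z", "o", "o", "z")
  X <- base[rep(1:4, n_rep), ] + matrix(rnorm(8 * n_rep, 0, noise),
                                        4 * n_rep, 2)
  Xv <- base[rep(1:4, 10), ] + matrix(rnorm(80, 0, noise), 40, 2)
  list(train = fake_table(X, rep(lab, n_rep)),
       val = fake_table(Xv, rep(lab, 10), prefix = "v"))
}

test_that("the feed-forward net learns XOR and honours early stopping", {
  d <- xor_tables()
  spec <- suppressWarnings(ann_spec(neurons_per_layer = 32L,
                                    learning_rate = 5e-3, max_epochs = 400L,
                                    patience = 40L, dropout_rate = 0,
                                    seed = 7L))
  m <- train_ann(d$train, d$val, spec)
  expect_lte(m$epochs_run, spec$max_epochs)
  expect_lte(m$best_epoch, m$epochs_run)
  expect_identical(predict(m, d$train), d$train$labels)
  # seed-reproducible
  m2 <- train_ann(d$train, d$val, spec)
  expect_equal(m$fit, m2$fit)
  expect_identical(m$best_epoch, m2$best_epoch)
})

test_that("ann training demands a disjoint validation set and known labels", {
  d <- xor_tables()
  expect_error(train_ann(d$train, d$train, ann_spec()), "disjoint")
  bad_val <- d$val
  bad_val$labels[1] <- "mystery"
  expect_error(
    suppressWarnings(train_ann(d$train, bad_val,
                               ann_spec(neurons_per_layer = 32L))),
    "outside the training label set"
  )
  expect_warning(ann_spec(neurons_per_layer = 100L), "canonical grid")
})

test_that("prediction is deterministic, order-equivariant and schema-checked", {
  train <- two_blobs(seed = 74)
  m <- train_svm_rbf(train)
  probe <- fake_table(matrix(rnorm(20), 10, 2), rep("?", 10), prefix = "q")
  p1 <- predict(m, probe)
  expect_identical(p1, predict(m, probe))
  perm <- sample(10)
  probe_perm <- fake_table(probe$features[perm, ], probe$labels[perm],
                           prefix = "r")
  expect_identical(predict(m, probe_perm), p1[perm])
  bad <- probe
  colnames(bad$features)[1] <- "other"
  expect_error(predict(m, bad), "columns do not match")
})
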