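# Evaluation protocol: stratified 10% hold-out plus stratified k-fold
# cross-validation, the accuracy metric, the three classification
# strategies (SVM on full features, SVM on ANOVA-selected features, ANN on
# full features) and the exhaustive wavelet-family x level sweep.

# Largest-remainder apportionment of `total` items proportionally to
# `counts`; ties broken by lower index. Deviates from exact proportionality
# by at most 1 per cell.
apportion <- function(counts, total) {
  share <- counts / sum(counts) * total
  base <- floor(share)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(share - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Stratified hold-out and k-fold split plan
#'
#' Reserves `round(holdout_frac * n)` rows as a validation set with
#' largest-remainder per-class apportionment, then partitions the remaining
#' rows into `k` stratified folds. Per-class counts in every subset are
#' within one of exact proportionality, and fold totals are balanced by a
#' rotating assignment of per-class remainders. Deterministic per seed.
#'
#' @param labels Class label per tile (character or factor).
#' @param holdout_frac Fraction held out for validation (default 0.1).
#' @param k Number of cross-validation folds (default 10).
#' @param seed Integer seed.
#' @return An object of class `split_plan`: list with `validation` (integer
#'   indices), `folds` (list of `k` disjoint integer index vectors), `k`,
#'   `seed`.
#' @export
make_splits <- function(labels, holdout_frac = 0.1, k = 10L, seed = 1L) {
  labels <- as.character(labels)
  n <- length(labels)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  cls <- sort(unique(labels))
  n_c <- vapply(cls, function(cl) sum(labels == cl), integer(1))
  n_val <- as.integer(round(holdout_frac * n))
  v_c <- apportion(n_c, n_val)
  short <- which(n_c - v_c < k)
  if (length(short) > 0L) {
    stop("class '", cls[short[1]], "' has fewer than k = ", k,
         " members after hold-out")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  validation <- integer(0)
  folds <- rep(list(integer(0)), k)
  pointer <- 1L
  for (ci in seq_along(cls)) {
    idx <- sample(which(labels == cls[ci]))
    validation <- c(validation, idx[seq_len(v_c[ci])])
    rest <- idx[-seq_len(v_c[ci])]
    if (v_c[ci] == 0L) rest <- idx
    sz <- rep(length(rest) %/% k, k)
    for (j in seq_len(length(rest) %% k)) {
      sz[pointer] <- sz[pointer] + 1L
      pointer <- pointer %% k + 1L
    }
    at <- 0L
    for (f in seq_len(k)) {
      folds[[f]] <- c(folds[[f]], rest[at + seq_len(sz[f])])
      at <- at + sz[f]
    }
  }
  structure(
    list(validation = sort(validation), folds = lapply(folds, sort),
         k = k, seed = as.integer(seed), holdout_frac = holdout_frac),
    class = "split_plan"
  )
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> validation %d, %d folds of sizes %s (seed %d)\n",
              length(x$validation), x$k,
              paste(lengths(x$folds), collapse = "/"), x$seed))
  invisible(x)
}

#' Multiclass classification accuracy
#'
#' Overall fraction of correct predictions, `(TP + TN) / (TP + TN + FP + FN)`
#' in the aggregated confusion-matrix sense.
#'
#' @param true_labels,predicted_labels Equal-length nonempty vectors.
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(true_labels, predicted_labels) {
  if (length(true_labels) == 0L) stop("empty label vectors")
  if (length(true_labels) != length(predicted_labels)) {
    stop("label vectors must have equal length")
  }
  mean(as.character(true_labels) == as.character(predicted_labels))
}

#' Run one classification strategy under a split plan
#'
#' Extracts the 532-feature table once per tile (or reuses `features`),
#' then evaluates the strategy over the plan's folds: each fold serves once
#' as the unseen test set, the remaining folds train the model. For
#' `svm_selected` the ANOVA mask is computed on the validation rows only
#' and applied unchanged to every fold; for `ann_full` the validation rows
#' drive early stopping. Fold accuracies are summarised as mean and
#' standard deviation.
#'
#' @param tiles A [tile_set()] (may be `NULL` when `features` is given).
#' @param spec A [wavelet_spec()].
#' @param strategy One of `"svm_full"`, `"svm_selected"`, `"ann_full"`.
#' @param plan A [make_splits()] plan built for these tiles.
#' @param model_spec An [svm_spec()] or [ann_spec()]; defaults per strategy.
#' @param config Extraction parameters.
#' @param features Optional precomputed `feature_table` for all tiles.
#' @param alpha Selection significance level (`svm_selected` only).
#' @return List with `mean_acc`, `std_acc`, `fold_acc`, `n_selected`.
#' @export
run_strategy <- function(tiles, spec,
                         strategy = c("svm_full", "svm_selected", "ann_full"),
                         plan, model_spec = NULL,
                         config = default_extract_config(),
                         features = NULL, alpha = 0.05) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(plan, "split_plan"))
  if (is.null(features)) features <- extract_batch(tiles, spec, config)
  n <- nrow(features$features)
  all_idx <- sort(c(plan$validation, unlist(plan$folds)))
  if (!identical(all_idx, seq_len(n))) {
    stop("split plan does not cover the feature table rows exactly")
  }
  val_tab <- ft_subset(features, plan$validation)
  n_selected <- ncol(features$features)
  if (strategy == "svm_selected") {
    sel <- select_features(val_tab, alpha)
    if (sel$n_selected == 0L) {
      stop("ANOVA selection kept no features on the validation split")
    }
    n_selected <- sel$n_selected
    keep <- sel$keep_mask
    features$features <- features$features[, keep, drop = FALSE]
    val_tab <- ft_subset(features, plan$validation)
  }
  if (is.null(model_spec)) {
    model_spec <- if (strategy == "ann_full") ann_spec() else svm_spec()
  }
  fold_acc <- numeric(plan$k)
  for (f in seq_len(plan$k)) {
    test_idx <- plan$folds[[f]]
    train_idx <- unlist(plan$folds[-f])
    train_tab <- ft_subset(features, train_idx)
    test_tab <- ft_subset(features, test_idx)
    model <- tryCatch(
      if (strategy == "ann_full") {
        ms <- model_spec
        ms$seed <- model_spec$seed + f
        train_ann(train_tab, val_tab, ms)
      } else {
        train_svm_rbf(train_tab, model_spec)
      },
      error = function(e) stop("fold ", f, ": ", conditionMessage(e),
                               call. = FALSE)
    )
    fold_acc[f] <- accuracy(test_tab$labels, predict(model, test_tab))
  }
  list(mean_acc = mean(fold_acc), std_acc = stats::sd(fold_acc),
       fold_acc = fold_acc, n_selected = n_selected)
}

#' Exhaustive wavelet-family x level x strategy sweep
#'
#' Iterates the full grid, extracting the feature table once per
#' (wavelet, level) and reusing it across strategies. Infeasible
#' (wavelet, level) pairs are skipped with a message. If `file` is given,
#' the result CSV is rewritten after every completed row, so partial
#' results survive an interruption.
#'
#' @param tiles A [tile_set()].
#' @param wavelet_names Character vector of concrete wavelet names.
#' @param levels Integer vector of decomposition levels.
#' @param strategies Subset of `c("svm_full", "svm_selected", "ann_full")`.
#' @param plan A [make_splits()] plan for these tiles.
#' @param config Extraction parameters.
#' @param model_specs Optional named list of `model_spec`s per strategy.
#' @param file Optional CSV path for incremental results.
#' @param verbose Print one line per grid point to stderr.
#' @return A `sweep_result` data frame with columns `wavelet`, `family`,
#'   `level`, `strategy`, `mean_accuracy`, `std_accuracy`,
#'   `n_selected_features`.
#' @export
run_sweep <- function(tiles, wavelet_names, levels, strategies, plan,
                      config = default_extract_config(),
                      model_specs = list(), file = NULL, verbose = FALSE) {
  if (length(wavelet_names) == 0L || length(levels) == 0L ||
      length(strategies) == 0L) {
    stop("wavelet_names, levels and strategies must be nonempty")
  }
  side <- min(dim(tiles$tiles[[1]]$pixels))
  rows <- list()
  for (wname in wavelet_names) {
    flen <- length(wavelet_filter(wname))
    fam <- wavelet_filter_table()$family[
      match(wname, wavelet_filter_table()$name)]
    for (lev in levels) {
      if (lev > max_feasible_level(side, flen)) {
        message(sprintf("skipping %s level %d: infeasible for side %d",
                        wname, lev, side))
        next
      }
      spec <- wavelet_spec(wname, lev)
      features <- extract_batch(tiles, spec, config)
      for (strat in strategies) {
        res <- run_strategy(NULL, spec, strat, plan,
                            model_spec = model_specs[[strat]],
                            config = config, features = features)
        rows[[length(rows) + 1L]] <- data.frame(
          wavelet = wname, family = fam, level = lev, strategy = strat,
          mean_accuracy = res$mean_acc, std_accuracy = res$std_acc,
          n_selected_features = res$n_selected, stringsAsFactors = FALSE
        )
        if (verbose) {
          cat(sprintf("%s L%d %s: %.3f +/- %.3f\n", wname, lev, strat,
                      res$mean_acc, res$std_acc), file = stderr())
        }
        out <- do.call(rbind, rows)
        if (!is.null(file)) write.csv(out, file, row.names = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", class(out))
  out
}

#' Grouped summary of a sweep
#'
#' Bins model accuracies into bands and reports, per wavelet family or per
#' decomposition level, the share of models falling in each band (the
#' grouped-report style of family/level performance charts) together with
#' each group's mean accuracy.
#'
#' @param sweep A `sweep_result` (or any data frame with `family`, `level`,
#'   `mean_accuracy`).
#' @param group_by `"family"` or `"level"`.
#' @param breaks Accuracy band edges (default steps of 0.1 over `[0, 1]`).
#' @param file Optional CSV path for the histogram table.
#' @return List with `hist` (`group`, `band`, `share`) where shares sum to
#'   1 within each group, and `means` (`group`, `mean_accuracy`,
#'   `n_models`).
#' @export
summarize_sweep <- function(sweep, group_by = c("family", "level"),
                            breaks = seq(0, 1, by = 0.1), file = NULL) {
  group_by <- match.arg(group_by)
  if (nrow(sweep) == 0L) stop("empty sweep result")
  g <- as.character(sweep[[group_by]])
  band <- cut(sweep$mean_accuracy, breaks = breaks, include.lowest = TRUE)
  tab <- table(group = g, band = band)
  share <- prop.table(tab, margin = 1L)
  hist_df <- as.data.frame(share, responseName = "share",
                           stringsAsFactors = FALSE)
  means <- aggregate(mean_accuracy ~ group,
                     data = data.frame(group = g,
                                       mean_accuracy = sweep$mean_accuracy),
                     FUN = mean)
  means$n_models <- as.integer(table(g)[means$group])
  if (!is.null(file)) write.csv(hist_df, file, row.names = FALSE)
  list(hist = hist_df, means = means)
}

#' Save / load a trained model
#'
#' Serialises the model spec, standardisation statistics and fitted
#' parameters with a format version tag.
#'
#' @param model A `pw_model`.
#' @param file Path to write/read.
#' @return `load_model()` returns the `pw_model`.
#' @export
save_model <- function(model, file) {
  stopifnot(inherits(model, "pw_model"))
  saveRDS(list(format = "pathowave-model-v1", model = model), file)
  invisible(file)
}

#' @rdname save_model
#' @export
load_model <- function(file) {
  obj <- readRDS(file)
  if (!identical(obj$format, "pathowave-model-v1")) {
    stop("unrecognised model archive format")
  }
  obj$model
}
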