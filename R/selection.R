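# One-way ANOVA F-test feature selection with the dual criterion
# p < alpha AND F > F_critical (the 1 - alpha quantile of F(df1, df2)).

#' One-way ANOVA F statistic
#'
#' Classical closed form `F = MS_between / MS_within` with upper-tail
#' p-value. Degenerate conventions: if every value is identical across all
#' groups, `F = 0, p = 1`; if within-group variance is zero but group means
#' differ, `F = Inf, p = 0`.
#'
#' @param values_by_group List of numeric vectors, one per group (>= 2
#'   groups, at least one group with >= 2 values).
#' @return Named list with `F`, `p`, `df1` (`k - 1`), `df2` (`N - k`).
#' @examples
#' anova_f(list(c(1, 2), c(3, 4), c(5, 6)))  # F = 16
#' @export
anova_f <- function(values_by_group) {
  k <- length(values_by_group)
  if (k < 2L) stop("need at least two groups")
  n_g <- lengths(values_by_group)
  if (any(n_g < 1L)) stop("every group needs at least one value")
  N <- sum(n_g)
  df2 <- N - k
  if (df2 < 1L) stop("need at least one group with two or more values")
  means <- vapply(values_by_group, mean, numeric(1))
  gm <- sum(n_g * means) / N
  ssb <- sum(n_g * (means - gm)^2)
  ssw <- sum(vapply(values_by_group,
                    function(v) sum((v - mean(v))^2), numeric(1)))
  df1 <- k - 1L
  if (ssw <= 0) {
    if (ssb <= 0) return(list(F = 0, p = 1, df1 = df1, df2 = df2))
    return(list(F = Inf, p = 0, df1 = df1, df2 = df2))
  }
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, p = pf(f, df1, df2, lower.tail = FALSE), df1 = df1, df2 = df2)
}

#' F-critical threshold via the percent point function
#'
#' The `1 - alpha` quantile (inverse CDF) of the F distribution with
#' `df1`, `df2` degrees of freedom.
#'
#' @param alpha Significance level in (0, 1).
#' @param df1,df2 Degrees of freedom (>= 1).
#' @return Scalar threshold.
#' @examples
#' f_critical(0.05, 7, 492)  # ~2.03
#' @export
f_critical <- function(alpha, df1, df2) {
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha < 1)) {
    stop("alpha must lie strictly between 0 and 1")
  }
  if (df1 < 1 || df2 < 1) stop("df1 and df2 must be >= 1")
  qf(1 - alpha, df1, df2)
}

#' ANOVA-based feature selection on a feature table
#'
#' Computes the per-feature one-way ANOVA F across the classes of the given
#' rows (intended to be the held-out validation split only) and keeps a
#' feature when both `p < alpha` and `F > f_critical(alpha, k - 1, N - k)`.
#' The returned mask is then applied unchanged to training/testing tables,
#' which stay unseen by the selection. Zero-variance features get `F = 0`
#' and are never selected.
#'
#' @param table A `feature_table` (see [extract_batch()]) with >= 2 classes.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `selection_result`: list with per-feature `F`,
#'   `p`, scalar `f_critical`, logical `keep_mask`, `df1`, `df2`, `alpha`,
#'   `n_selected`.
#' @export
select_features <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "feature_table"))
  g <- factor(table$labels)
  k <- nlevels(g)
  if (k < 2L) stop("feature selection needs at least two classes")
  X <- table$features
  N <- nrow(X)
  df1 <- k - 1L
  df2 <- N - k
  if (df2 < 1L) stop("too few rows for ANOVA")
  n_g <- as.numeric(table(g))
  gsum <- rowsum(X, g)
  gmean <- gsum / n_g
  gm <- colSums(gsum) / N
  Xc <- sweep(X, 2L, gm)
  ssb <- colSums(n_g * (gmean - matrix(gm, k, ncol(X), byrow = TRUE))^2)
  sst <- colSums(Xc^2)
  ssw <- pmax(sst - ssb, 0)
  # guard tiny negative / rounding noise on flat columns
  flat <- sst <= 1e-10 * pmax(1, abs(gm))^2
  Fv <- ifelse(ssw > 0, (ssb / df1) / (ssw / df2), Inf)
  Fv[flat | ssb <= 0] <- 0
  pv <- pf(Fv, df1, df2, lower.tail = FALSE)
  pv[Fv == 0] <- 1
  fc <- f_critical(alpha, df1, df2)
  keep <- (pv < alpha) & (Fv > fc)
  structure(
    list(F = stats::setNames(Fv, colnames(X)), p = stats::setNames(pv, colnames(X)),
         f_critical = fc, keep_mask = keep, df1 = df1, df2 = df2,
         alpha = alpha, n_selected = sum(keep)),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection_result> %d / %d features kept (alpha %.3g, F_crit %.4g, df %d/%d)\n",
    x$n_selected, length(x$keep_mask), x$alpha, x$f_critical, x$df1, x$df2
  ))
  invisible(x)
}

#' Serialise / restore a selection result as JSON
#'
#' @param sel A `selection_result`.
#' @param file JSON path.
#' @return `read_selection_json()` returns a `selection_result`.
#' @export
write_selection_json <- function(sel, file) {
  stopifnot(inherits(sel, "selection_result"))
  jsonlite::write_json(
    list(feature = names(sel$F), F = unname(sel$F), p = unname(sel$p),
         f_critical = sel$f_critical, keep_mask = unname(sel$keep_mask),
         df1 = sel$df1, df2 = sel$df2, alpha = sel$alpha),
    file, auto_unbox = TRUE, digits = NA
  )
  invisible(file)
}

#' @rdname write_selection_json
#' @export
read_selection_json <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  Fv <- stats::setNames(as.numeric(j$F), j$feature)
  Fv[is.na(Fv)] <- Inf  # JSON has no Inf literal; absent value means +Inf
  structure(
    list(F = Fv, p = stats::setNames(as.numeric(j$p), j$feature),
         f_critical = j$f_critical, keep_mask = as.logical(j$keep_mask),
         df1 = j$df1, df2 = j$df2, alpha = j$alpha,
         n_selected = sum(as.logical(j$keep_mask))),
    class = "selection_result"
  )
}
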