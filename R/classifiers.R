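# The two model families evaluated by the protocol: an RBF-kernel SVM on
# (selected or full) pathomics and a feed-forward network with sigmoid
# hidden layers, softmax output and patience-based early stopping on the
# full 532-vector. Both standardise features with training-set statistics.

#' Model specifications
#'
#' `svm_spec()` describes a one-vs-one multiclass RBF SVM (`C = 1`; kernel
#' width `gamma = 1 / (n_features * var(X))` computed on the standardised
#' training matrix unless given). `ann_spec()` describes a feed-forward
#' network: 1 or 2 sigmoid hidden layers of equal width, softmax output
#' over the classes, cross-entropy loss, Adam updates, inverted dropout on
#' hidden activations, and early stopping when the validation loss has not
#' improved for `patience` epochs. The canonical width grid is
#' {64, 128, 256, 512, 1024, 2048} with 1 or 2 layers; values outside it
#' warn but are allowed.
#'
#' @param C,gamma SVM regularisation and kernel width (`NULL` = data rule).
#' @return An object of class `model_spec`.
#' @export
svm_spec <- function(C = 1, gamma = NULL) {
  structure(list(kind = "svm_rbf", C = C, gamma = gamma),
            class = "model_spec")
}

#' @rdname svm_spec
#' @param hidden_layer_count 1 or 2 sigmoid hidden layers.
#' @param neurons_per_layer Width of each hidden layer.
#' @param dropout_rate Dropout probability on hidden activations.
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size.
#' @param max_epochs,patience Epoch budget and early-stopping patience.
#' @param seed Integer seed controlling initialisation, shuffling, dropout.
#' @export
ann_spec <- function(hidden_layer_count = 1L, neurons_per_layer = 64L,
                     dropout_rate = 0.2, learning_rate = 1e-3,
                     batch_size = 32L, max_epochs = 500L, patience = 25L,
                     seed = 0L) {
  if (!(hidden_layer_count %in% c(1L, 2L)) ||
      !(neurons_per_layer %in% c(64L, 128L, 256L, 512L, 1024L, 2048L))) {
    warning("ANN architecture outside the canonical grid ",
            "({64,...,2048} neurons x 1-2 sigmoid layers)")
  }
  structure(
    list(kind = "ann", hidden_layer_count = as.integer(hidden_layer_count),
         neurons_per_layer = as.integer(neurons_per_layer),
         hidden_activation = "sigmoid", dropout_rate = dropout_rate,
         learning_rate = learning_rate, batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs), patience = as.integer(patience),
         seed = as.integer(seed)),
    class = "model_spec"
  )
}

#' Standardise feature tables with training statistics
#'
#' Z-scores every feature using the training rows' mean and standard
#' deviation, then applies the same transform to any further tables.
#' Constant training features (sd 0) are passed through as all zeros.
#'
#' @param train A `feature_table`.
#' @param ... Further `feature_table`s transformed with the training stats.
#' @return List with `center`, `scale`, `train`, and `others` (list).
#' @export
standardize_fit_apply <- function(train, ...) {
  stopifnot(inherits(train, "feature_table"), nrow(train$features) > 0L)
  center <- colMeans(train$features)
  scale <- apply(train$features, 2L, stats::sd)
  scale[!is.finite(scale) | scale <= 0] <- Inf  # constant column -> zeros
  apply_one <- function(tab) {
    tab$features <- sweep(sweep(tab$features, 2L, center), 2L, scale, "/")
    tab
  }
  list(center = center, scale = scale, train = apply_one(train),
       others = lapply(list(...), apply_one))
}

std_apply <- function(model, X) {
  sweep(sweep(X, 2L, model$center), 2L, model$scale, "/")
}

#' Train the RBF-kernel support vector machine
#'
#' Fits a one-vs-one multiclass SVM with radial basis kernel on the
#' standardised training features. Deterministic given the data and spec.
#'
#' @param train A `feature_table` with >= 2 classes.
#' @param spec An [svm_spec()].
#' @return An object of class `pw_model`.
#' @export
train_svm_rbf <- function(train, spec = svm_spec()) {
  stopifnot(inherits(train, "feature_table"))
  y <- factor(train$labels)
  if (nlevels(y) < 2L) stop("training set must contain at least two classes")
  std <- standardize_fit_apply(train)
  X <- std$train$features
  gamma <- spec$gamma
  if (is.null(gamma)) {
    v <- stats::var(as.vector(X))
    gamma <- 1 / (ncol(X) * max(v, 1e-12))
  }
  fit <- e1071::svm(x = X, y = y, type = "C-classification",
                    kernel = "radial", cost = spec$C, gamma = gamma,
                    scale = FALSE)
  structure(
    list(kind = "svm_rbf", spec = spec, center = std$center,
         scale = std$scale, levels = levels(y),
         feature_names = colnames(train$features), fit = fit,
         gamma = gamma),
    class = "pw_model"
  )
}

# ---- feed-forward network internals ------------------------------------

sigmoid <- function(z) 1 / (1 + exp(-z))

nn_init <- function(sizes) {
  lapply(seq_len(length(sizes) - 1L), function(l) {
    fan_in <- sizes[l]; fan_out <- sizes[l + 1L]
    lim <- sqrt(6 / (fan_in + fan_out))
    list(W = matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out),
         b = rep(0, fan_out))
  })
}

nn_forward <- function(params, X, drop_masks = NULL) {
  acts <- list(X)
  L <- length(params)
  a <- X
  for (l in seq_len(L)) {
    z <- a %*% params[[l]]$W
    z <- sweep(z, 2L, params[[l]]$b, "+")
    if (l < L) {
      a <- sigmoid(z)
      if (!is.null(drop_masks)) a <- a * drop_masks[[l]]
    } else {
      z <- sweep(z, 1L, apply(z, 1L, max))
      e <- exp(z)
      a <- e / rowSums(e)
    }
    acts[[l + 1L]] <- a
  }
  acts
}

nn_xent <- function(prob, Y) -mean(rowSums(Y * log(pmax(prob, 1e-12))))

nn_backward <- function(params, acts, Y, drop_masks) {
  L <- length(params)
  n <- nrow(Y)
  grads <- vector("list", L)
  delta <- (acts[[L + 1L]] - Y) / n  # softmax + cross-entropy
  for (l in rev(seq_len(L))) {
    grads[[l]] <- list(W = crossprod(acts[[l]], delta),
                       b = colSums(delta))
    if (l > 1L) {
      a <- acts[[l]]
      delta <- (delta %*% t(params[[l]]$W)) * a * (1 - a)
      if (!is.null(drop_masks)) delta <- delta * drop_masks[[l - 1L]]
    }
  }
  grads
}

#' Train the feed-forward neural network
#'
#' Standardises features with training statistics, then trains a network of
#' 1 or 2 sigmoid hidden layers with softmax output and cross-entropy loss
#' by mini-batch Adam. After every epoch the loss on the (disjoint)
#' validation table is evaluated; training stops once it has not improved
#' for `spec$patience` epochs and the weights of the best validation epoch
#' are returned. Fully reproducible given `spec$seed`.
#'
#' @param train,validation Disjoint `feature_table`s (validation drives
#'   early stopping only).
#' @param spec An [ann_spec()].
#' @return A `pw_model` with fields `epochs_run` and `best_epoch`.
#' @export
train_ann <- function(train, validation, spec = ann_spec()) {
  stopifnot(inherits(train, "feature_table"),
            inherits(validation, "feature_table"))
  if (length(intersect(train$tile_ids, validation$tile_ids)) > 0L) {
    stop("validation set must be disjoint from the training set")
  }
  y <- factor(train$labels)
  if (nlevels(y) < 2L) stop("training set must contain at least two classes")
  lev <- levels(y)
  std <- standardize_fit_apply(train, validation)
  X <- std$train$features
  Xv <- std$others[[1]]$features
  Y <- diag(length(lev))[as.integer(y), , drop = FALSE]
  yv <- factor(validation$labels, levels = lev)
  if (anyNA(yv)) stop("validation labels outside the training label set")
  Yv <- diag(length(lev))[as.integer(yv), , drop = FALSE]

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  sizes <- c(ncol(X), rep(spec$neurons_per_layer, spec$hidden_layer_count),
             length(lev))
  params <- nn_init(sizes)
  mom <- lapply(params, function(p) list(W = p$W * 0, b = p$b * 0))
  vel <- lapply(params, function(p) list(W = p$W * 0, b = p$b * 0))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t_step <- 0L
  n <- nrow(X)
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  epochs_run <- 0L
  for (epoch in seq_len(spec$max_epochs)) {
    idx <- sample.int(n)
    for (s in seq(1L, n, by = spec$batch_size)) {
      bi <- idx[s:min(s + spec$batch_size - 1L, n)]
      masks <- if (spec$dropout_rate > 0) {
        lapply(sizes[-c(1L, length(sizes))], function(w) {
          matrix((runif(length(bi) * w) >= spec$dropout_rate) /
                   (1 - spec$dropout_rate), length(bi), w)
        })
      } else NULL
      acts <- nn_forward(params, X[bi, , drop = FALSE], masks)
      grads <- nn_backward(params, acts, Y[bi, , drop = FALSE], masks)
      t_step <- t_step + 1L
      for (l in seq_along(params)) {
        for (nm in c("W", "b")) {
          g <- grads[[l]][[nm]]
          mom[[l]][[nm]] <- b1 * mom[[l]][[nm]] + (1 - b1) * g
          vel[[l]][[nm]] <- b2 * vel[[l]][[nm]] + (1 - b2) * g^2
          mhat <- mom[[l]][[nm]] / (1 - b1^t_step)
          vhat <- vel[[l]][[nm]] / (1 - b2^t_step)
          params[[l]][[nm]] <- params[[l]][[nm]] -
            spec$learning_rate * mhat / (sqrt(vhat) + eps)
        }
      }
    }
    epochs_run <- epoch
    vloss <- nn_xent(nn_forward(params, Xv)[[length(sizes)]], Yv)
    if (vloss < best$loss - 1e-8) {
      best <- list(loss = vloss, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= spec$patience) break
    }
  }
  structure(
    list(kind = "ann", spec = spec, center = std$center, scale = std$scale,
         levels = lev, feature_names = colnames(train$features),
         fit = best$params, best_epoch = best$epoch,
         epochs_run = epochs_run, best_val_loss = best$loss),
    class = "pw_model"
  )
}

#' @export
print.pw_model <- function(x, ...) {
  cat(sprintf("<pw_model> %s, %d features, classes: %s\n", x$kind,
              length(x$feature_names), paste(x$levels, collapse = ", ")))
  if (x$kind == "ann") {
    cat(sprintf("  best epoch %d of %d (val loss %.4f)\n",
                x$best_epoch, x$epochs_run, x$best_val_loss))
  }
  invisible(x)
}

#' Predict class labels with a trained model
#'
#' @param object A `pw_model`.
#' @param table A `feature_table` (or numeric matrix) whose columns match
#'   the training columns.
#' @param ... Unused.
#' @return Character vector of predicted labels, one per row.
#' @export
predict.pw_model <- function(object, table, ...) {
  X <- if (inherits(table, "feature_table")) table$features else table
  if (!identical(colnames(X), object$feature_names)) {
    stop("feature columns do not match the training columns")
  }
  Xs <- std_apply(object, X)
  if (object$kind == "svm_rbf") {
    as.character(predict(object$fit, Xs))
  } else {
    prob <- nn_forward(object$fit, Xs)[[length(object$fit) + 1L]]
    object$levels[max.col(prob, ties.method = "first")]
  }
}
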