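# Three-model consensus machinery: stratified splitting, grid search with
# repeated k-fold cross-validation (ties broken by held-out AUC), rank-based
# ROC AUC, the confusion-derived metric panel, and final per-negative-set
# model bundles whose prediction is the mean probability over member fits.
#
# The underlying learners come from e1071 (SVM, RBF kernel), randomForest,
# and nnet (single-hidden-layer MLP); this module owns everything around
# them. Note one deliberate convention: MSE is computed on hard 0/1
# predictions, i.e. it equals the misclassification rate, so that
# accuracy + MSE = 1 on every run.

.METHODS <- c("svm", "rf", "mlp")

#' Default hyperparameter grids
#'
#' svm: gamma in \{0.001, 0.01, 0.1\}, cost in \{1, 10, 100\};
#' rf: n_estimators in \{250, 500, 750, 1000\};
#' mlp: hidden in \{128, 256, 512\}, alpha in \{1e-4, 1e-3\}.
#' Each grid contains the reference optimum (svm gamma 0.01 / cost 10,
#' rf 750 trees, mlp hidden 512 / alpha 1e-4).
#'
#' @param method one of `"svm"`, `"rf"`, `"mlp"`.
#' @return named list of candidate values.
#' @export
default_grid <- function(method = .METHODS) {
  method <- match.arg(method)
  switch(method,
    svm = list(gamma = c(0.001, 0.01, 0.1), cost = c(1, 10, 100)),
    rf = list(n_estimators = c(250, 500, 750, 1000)),
    mlp = list(hidden = c(128, 256, 512), alpha = c(1e-4, 1e-3))
  )
}

#' Model specification
#'
#' Bundles a method name, a hyperparameter grid, and (after grid search or
#' by explicit choice) the chosen hyperparameters. Chosen values supplied
#' directly may lie outside the grid (e.g. capacity scaled down for small
#' corpora); values chosen by [grid_search_cv()] always come from the grid.
#'
#' @param method `"svm"`, `"rf"` or `"mlp"`.
#' @param grid named list of candidate values; defaults to
#'   [default_grid()].
#' @param chosen named list of chosen hyperparameters, or `NULL` before
#'   selection. For mlp an optional `maxit` entry caps optimizer iterations
#'   (default 100).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(method = .METHODS, grid = NULL, chosen = NULL) {
  method <- match.arg(method)
  if (is.null(grid)) grid <- default_grid(method)
  structure(list(method = method, grid = grid, chosen = chosen),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  ch <- if (is.null(x$chosen)) "none chosen" else
    paste(sprintf("%s=%s", names(x$chosen), unlist(x$chosen)), collapse = ", ")
  cat(sprintf("<model_spec> %s (%s)\n", x$method, ch))
  invisible(x)
}

.as_dataset <- function(x, y) {
  stopifnot(is.matrix(x), length(y) == nrow(x))
  list(x = x, y = as.integer(y))
}

#' Stratified train/test split
#'
#' Randomly splits a labelled dataset into a training-and-validation part
#' and a test part at the given fraction, stratified by class and
#' reproducible from `seed`.
#'
#' @param dataset list with feature matrix `x` and 0/1 label vector `y`.
#' @param test_frac test fraction in (0, 1) (default 0.2).
#' @param seed integer seed.
#' @return list with elements `train_val` and `test`, each a dataset.
#' @export
split_dataset <- function(dataset, test_frac = 0.2, seed = 1L) {
  stopifnot(is.list(dataset), is.matrix(dataset$x))
  if (test_frac <= 0 || test_frac >= 1)
    stop("`test_frac` must be strictly between 0 and 1", call. = FALSE)
  y <- as.integer(dataset$y)
  if (any(table(factor(y, levels = c(0L, 1L))) < 2L))
    stop("each class needs at least 2 members", call. = FALSE)
  test_idx <- with_seed(seed, {
    unlist(lapply(c(0L, 1L), function(cl) {
      idx <- which(y == cl)
      sample(idx, round(length(idx) * test_frac))
    }))
  })
  list(
    train_val = .as_dataset(dataset$x[-test_idx, , drop = FALSE], y[-test_idx]),
    test = .as_dataset(dataset$x[test_idx, , drop = FALSE], y[test_idx])
  )
}

# fit a single learner; all stochastic fits run under the given seed
.fit_model <- function(method, x, y, params, seed = 1L) {
  yf <- factor(y, levels = c(0L, 1L))
  with_seed(seed, switch(method,
    svm = e1071::svm(x = x, y = yf, kernel = "radial",
                     gamma = params$gamma, cost = params$cost,
                     probability = TRUE, scale = FALSE),
    rf = randomForest::randomForest(x = x, y = yf,
                                    ntree = params$n_estimators),
    mlp = nnet::nnet(x = x, y = y, size = params$hidden,
                     decay = params$alpha,
                     maxit = if (is.null(params$maxit)) 100L else params$maxit,
                     MaxNWts = 10000000L, entropy = TRUE, trace = FALSE)
  ))
}

# predicted probability of the positive class
.predict_prob <- function(method, fit, x) {
  switch(method,
    svm = {
      pr <- attr(stats::predict(fit, x, probability = TRUE), "probabilities")
      unname(pr[, "1"])
    },
    rf = unname(stats::predict(fit, x, type = "prob")[, "1"]),
    mlp = as.numeric(stats::predict(fit, x))
  )
}

#' Rank-based ROC AUC
#'
#' Mann-Whitney statistic with midrank handling of ties; numerically equal
#' to trapezoidal integration of the ROC curve. Returns 0.5 when all scores
#' are tied.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute AUC", call. = FALSE)
  r <- rank(scores)  # midranks for ties
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.safe_div <- function(num, den) if (den == 0) NA_real_ else num / den

#' Metric panel from probabilities and labels
#'
#' Confusion counts at the probability threshold (default 0.5, predictions
#' strictly greater count as positive... see Details) and the seven quality
#' indices: accuracy, precision, sensitivity, specificity, F1 score, AUC,
#' and MSE computed on hard 0/1 predictions (so accuracy + MSE = 1).
#'
#' @details Hard predictions are `probs > threshold`, matching the strict
#' "probability greater than 0.5" convention used for consensus calls.
#'
#' @param probs predicted probabilities of the positive class.
#' @param labels 0/1 labels.
#' @param threshold decision threshold (default 0.5).
#' @return named list with `tp`, `tn`, `fp`, `fn` and the seven indices.
#' @export
evaluate_predictions <- function(probs, labels, threshold = 0.5) {
  if (length(probs) == 0L) stop("empty evaluation set", call. = FALSE)
  labels <- as.integer(labels)
  pred <- as.integer(probs > threshold)
  tp <- sum(pred == 1L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  list(
    tp = tp, tn = tn, fp = fp, fn = fn,
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    precision = .safe_div(tp, tp + fp),
    sensitivity = .safe_div(tp, tp + fn),
    specificity = .safe_div(tn, tn + fp),
    f1 = .safe_div(2 * tp, 2 * tp + fp + fn),
    auc = roc_auc(probs, labels),
    mse = mean((pred - labels)^2)
  )
}

#' Evaluate a fitted model on a test set
#'
#' @param method `"svm"`, `"rf"` or `"mlp"`.
#' @param fit a fitted learner from this package's training functions.
#' @param test dataset (list with `x`, `y`).
#' @param threshold decision threshold (default 0.5).
#' @return metric panel as in [evaluate_predictions()].
#' @export
evaluate_model <- function(method, fit, test, threshold = 0.5) {
  if (nrow(test$x) == 0L) stop("empty test set", call. = FALSE)
  evaluate_predictions(.predict_prob(method, fit, test$x), test$y, threshold)
}

# k-fold CV accuracy for one grid point (folds stratified by class)
.cv_accuracy <- function(method, dataset, params, k, seed) {
  y <- dataset$y
  folds <- with_seed(seed, {
    f <- integer(length(y))
    for (cl in c(0L, 1L)) {
      idx <- which(y == cl)
      f[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    f
  })
  accs <- vapply(seq_len(k), function(fold) {
    tr <- folds != fold
    fit <- .fit_model(method, dataset$x[tr, , drop = FALSE], y[tr], params,
                      seed = seed + fold)
    probs <- .predict_prob(method, fit, dataset$x[!tr, , drop = FALSE])
    mean(as.integer(probs > 0.5) == y[!tr])
  }, numeric(1))
  mean(accs)
}

#' Grid search with repeated k-fold cross-validation
#'
#' For every grid point, computes the mean cross-validation accuracy over
#' `k` folds repeated `n_repeats` times on `train_val`. The winner is the
#' point with maximum mean accuracy; exact ties are broken by the AUC of a
#' temporary model trained on all of `train_val` and evaluated on the
#' held-out `test` set (required only when a tie occurs). Deterministic
#' given `seed`.
#'
#' @param train_val training-and-validation dataset (list with `x`, `y`).
#' @param spec a [model_spec()] with a non-empty grid.
#' @param k number of folds (default 5).
#' @param n_repeats number of CV repetitions (default 10).
#' @param seed integer seed.
#' @param test optional held-out dataset for tie-breaking by AUC.
#' @return the `model_spec` with `chosen` set; the full search table is
#'   attached as attribute `"search"`.
#' @export
grid_search_cv <- function(train_val, spec, k = 5L, n_repeats = 10L,
                           seed = 1L, test = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (length(spec$grid) == 0L || any(lengths(spec$grid) == 0L))
    stop("empty hyperparameter grid", call. = FALSE)
  grid <- expand.grid(spec$grid, KEEP.OUT.ATTRS = FALSE)
  mean_acc <- vapply(seq_len(nrow(grid)), function(g) {
    params <- as.list(grid[g, , drop = FALSE])
    mean(vapply(seq_len(n_repeats), function(rep)
      .cv_accuracy(spec$method, train_val, params, k,
                   seed = seed + 1000L * g + rep),
      numeric(1)))
  }, numeric(1))
  winner <- .pick_optimal(mean_acc, function(idx) {
    if (is.null(test))
      stop("tied mean CV accuracy; supply `test` for AUC tie-breaking",
           call. = FALSE)
    vapply(idx, function(g) {
      params <- as.list(grid[g, , drop = FALSE])
      fit <- .fit_model(spec$method, train_val$x, train_val$y, params,
                        seed = seed + g)
      roc_auc(.predict_prob(spec$method, fit, test$x), test$y)
    }, numeric(1))
  })
  spec$chosen <- as.list(grid[winner, , drop = FALSE])
  search <- grid
  search$mean_cv_accuracy <- mean_acc
  attr(spec, "search") <- search
  spec
}

# winner = maximum mean CV accuracy; exact ties resolved by held-out AUC
# (computed lazily, only for the tied points); remaining ties take the
# earliest grid point
.pick_optimal <- function(mean_acc, auc_of) {
  winners <- which(mean_acc == max(mean_acc))
  if (length(winners) == 1L) return(winners)
  aucs <- auc_of(winners)
  winners[which.max(aucs)]
}

# assemble the per-negative-set dataset (positives + one negative set)
.negative_set_dataset <- function(benchmark, k) {
  neg <- benchmark$negative_sets[[k]]
  ids <- c(benchmark$positives$compound_id, neg$compound_id)
  x <- benchmark$features[ids, , drop = FALSE]
  y <- c(rep(1L, nrow(benchmark$positives)), rep(0L, nrow(neg)))
  .as_dataset(x, y)
}

#' Train the final model bundle
#'
#' Fits one model per negative set (positives plus that negative set, using
#' the chosen hyperparameters). The bundle's predicted probability for a
#' query is the arithmetic mean of the member fits' probabilities.
#'
#' @param benchmark a `benchmark_dataset`.
#' @param spec a [model_spec()] with `chosen` set.
#' @param seed integer seed.
#' @return object of class `model_bundle`.
#' @export
train_final <- function(benchmark, spec, seed = 1L) {
  stopifnot(inherits(benchmark, "benchmark_dataset"),
            inherits(spec, "model_spec"))
  if (is.null(spec$chosen))
    stop("spec has no chosen hyperparameters; run grid_search_cv() or set `chosen`",
         call. = FALSE)
  fits <- lapply(seq_along(benchmark$negative_sets), function(k) {
    d <- .negative_set_dataset(benchmark, k)
    .fit_model(spec$method, d$x, d$y, spec$chosen, seed = seed + k)
  })
  structure(
    list(method = spec$method, chosen = spec$chosen, fits = fits,
         feature_params = benchmark$feature_params, seed = as.integer(seed)),
    class = "model_bundle"
  )
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("<model_bundle> %s, %d member fits\n", x$method,
              length(x$fits)))
  invisible(x)
}

#' Predict with a model bundle
#'
#' @param object a `model_bundle`.
#' @param x feature matrix with the bundle's fingerprint configuration.
#' @param ... unused.
#' @return mean predicted probability of activity per row.
#' @export
predict.model_bundle <- function(object, x, ...) {
  if (ncol(x) != object$feature_params$n_bits)
    stop("feature matrix does not match the bundle's fingerprint configuration",
         call. = FALSE)
  probs <- vapply(object$fits, function(f)
    .predict_prob(object$method, f, x), numeric(nrow(x)))
  if (nrow(x) == 1L) mean(probs) else rowMeans(matrix(probs, nrow = nrow(x)))
}

#' Benchmark study across negative sets
#'
#' For each method and each negative set: stratified 80/20 split, k-fold
#' cross-validation accuracy on the training portion, a fit on the training
#' portion, and the full metric panel on the held-out test portion. Metrics
#' are aggregated as mean and standard deviation over the negative sets.
#'
#' @param benchmark a `benchmark_dataset`.
#' @param specs named list of [model_spec()]s with `chosen` set (names are
#'   methods).
#' @param test_frac held-out fraction (default 0.2).
#' @param k CV folds (default 5).
#' @param seed integer seed.
#' @return object of class `metrics_report`: `per_run` data.frame (method,
#'   negative set, cv accuracy, metric panel) and `summary` data.frame
#'   (method, metric, mean, sd).
#' @export
benchmark_study <- function(benchmark, specs, test_frac = 0.2, k = 5L,
                            seed = 1L) {
  stopifnot(inherits(benchmark, "benchmark_dataset"))
  per_run <- list()
  for (m in names(specs)) {
    spec <- specs[[m]]
    if (is.null(spec$chosen)) stop("spec for ", m, " has no chosen parameters")
    for (s in seq_along(benchmark$negative_sets)) {
      d <- .negative_set_dataset(benchmark, s)
      parts <- split_dataset(d, test_frac = test_frac, seed = seed + s)
      cv_acc <- .cv_accuracy(spec$method, parts$train_val, spec$chosen, k,
                             seed = seed + 100L * s)
      fit <- .fit_model(spec$method, parts$train_val$x, parts$train_val$y,
                        spec$chosen, seed = seed + 200L * s)
      met <- evaluate_model(spec$method, fit, parts$test)
      per_run[[length(per_run) + 1L]] <- data.frame(
        method = m, negative_set = s, cv_accuracy = cv_acc,
        as.data.frame(met), stringsAsFactors = FALSE)
    }
  }
  per_run <- do.call(rbind, per_run)
  metrics <- c("cv_accuracy", "accuracy", "precision", "sensitivity",
               "specificity", "f1", "auc", "mse")
  summary <- do.call(rbind, lapply(unique(per_run$method), function(m) {
    sub <- per_run[per_run$method == m, , drop = FALSE]
    data.frame(method = m, metric = metrics,
               mean = vapply(metrics, function(mt) mean(sub[[mt]]), numeric(1)),
               sd = vapply(metrics, function(mt) stats::sd(sub[[mt]]), numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  structure(list(per_run = per_run, summary = summary),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  s <- x$summary
  for (m in unique(s$method)) {
    sub <- s[s$method == m, ]
    cat(sprintf("  %s: %s\n", m,
                paste(sprintf("%s %.3f+/-%.3f", sub$metric, sub$mean, sub$sd),
                      collapse = ", ")))
  }
  invisible(x)
}
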