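make_dataset <- function(n_per_class = 100L, p = 32L, seed = 1L) {
  set.seed(seed)
  x <- rbind(matrix(rbinom(n_per_class * p, 1, 0.15), n_per_class, p),
             matrix(rbinom(n_per_class * p, 1, 0.15), n_per_class, p))
  # make the classes separable on the first columns
  x[seq_len(n_per_class), 1:4] <- 1
  x[n_per_class + seq_len(n_per_class), 1:4] <- 0
  colnames(x) <- paste0("b", seq_len(p) - 1L)
  list(x = x, y = c(rep(1L, n_per_class), rep(0L, n_per_class)))
}

test_that("stratified splitting preserves class balance and replays from seed", {
  d <- make_dataset(100L)
  parts <- split_dataset(d, test_frac = 0.2, seed = 3L)
  expect_equal(nrow(parts$train_val$x), 160L)
  expect_equal(nrow(parts$test$x), 40L)
  expect_equal(sum(parts$test$y == 1L), 20L)
  expect_equal(sum(parts$test$y == 0L), 20L)
  parts2 <- split_dataset(d, test_frac = 0.2, seed = 3L)
  expect_identical(parts$test$x, parts2$test$x)
  expect_error(split_dataset(d, test_frac = 0), "between 0 and 1")
  expect_error(split_dataset(d, test_frac = 1), "between 0 and 1")
  tiny <- list(x = matrix(0, 3, 2), y = c(1L, 1L, 1L))
  expect_error(split_dataset(tiny), "at least 2")
})

test_that("rank-based AUC agrees with concordant pairs, trapezoids and pROC", {
  expect_equal(roc_auc(c(0.9, 0.3, 0.8, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "both classes")

  trapezoid_auc <- function(scores, labels) {
    th <- sort(unique(scores), decreasing = TRUE)
    tpr <- c(0, vapply(th, function(t) mean(scores[labels == 1] >= t),
                       numeric(1)), 1)
    fpr <- c(0, vapply(th, function(t) mean(scores[labels == 0] >= t),
                       numeric(1)), 1)
    sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  }
  set.seed(9)
  for (k in 1:25) {
    n <- sample(10:60, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- round(runif(n), 2)  # rounding forces ties
    got <- roc_auc(scores, labels)
    expect_equal(got, trapezoid_auc(scores, labels), tolerance = 1e-12)
    expect_equal(got,
                 as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
    expect_equal(roc_auc(scores, labels) + roc_auc(-scores, labels), 1,
                 tolerance = 1e-12)
  }
})

test_that("the metric panel reproduces its defining formulas", {
  # confusion matrix matching a published-style metric column:
  # TP 850, TN 854, FP 146, FN 150
  probs <- c(rep(0.9, 850), rep(0.1, 150), rep(0.9, 146), rep(0.1, 854))
  labels <- c(rep(1, 1000), rep(0, 1000))
  m <- evaluate_predictions(probs, labels)
  expect_equal(c(m$tp, m$tn, m$fp, m$fn), c(850, 854, 146, 150))
  expect_equal(m$accuracy, 0.852)
  expect_equal(m$sensitivity, 0.850)
  expect_equal(m$specificity, 0.854)
  expect_equal(m$precision, 850 / 996, tolerance = 1e-12)
  expect_equal(m$f1, 1700 / 1996, tolerance = 1e-12)
  expect_equal(m$mse, 0.148)
  expect_equal(m$accuracy + m$mse, 1, tolerance = 1e-12)

  perfect <- evaluate_predictions(c(0.99, 0.99, 0.01), c(1, 1, 0))
  expect_true(all(unlist(perfect[c("accuracy", "precision", "sensitivity",
                                   "specificity", "f1", "auc")]) == 1))
  expect_equal(perfect$mse, 0)

  allpos <- evaluate_predictions(rep(0.9, 10), rep(c(1, 0), 5))
  expect_equal(allpos$sensitivity, 1)
  expect_equal(allpos$specificity, 0)
  expect_equal(allpos$accuracy, 0.5)

  expect_error(evaluate_predictions(numeric(0), integer(0)), "empty")
})

test_that("metric identities hold on random prediction panels", {
  set.seed(13)
  for (k in 1:50) {
    n <- sample(20:200, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    probs <- runif(n)
    m <- evaluate_predictions(probs, labels)
    expect_equal(m$accuracy + m$mse, 1, tolerance = 1e-12)
    expect_equal(m$f1, 2 * m$tp / (2 * m$tp + m$fp + m$fn), tolerance = 1e-12)
    # count conservation: sens * P + spec * N = TP + TN
    P <- m$tp + m$fn; N <- m$tn + m$fp
    expect_equal(m$sensitivity * P + m$specificity * N, m$tp + m$tn,
                 tolerance = 1e-12)
  }
})

test_that("model specs carry grids containing the reference optima", {
  for (m in c("svm", "rf", "mlp")) {
    sp <- model_spec(m)
    expect_null(sp$chosen)
  }
  expect_true(0.01 %in% default_grid("svm")$gamma)
  expect_true(10 %in% default_grid("svm")$cost)
  expect_true(750 %in% default_grid("rf")$n_estimators)
  expect_true(512 %in% default_grid("mlp")$hidden)
  expect_true(1e-4 %in% default_grid("mlp")$alpha)
})

test_that("grid-search winner selection maximizes accuracy, then held-out AUC", {
  pick <- abxscreen:::.pick_optimal
  # clear accuracy winner: AUC never computed
  called <- FALSE
  expect_equal(pick(c(0.84, 0.86), function(idx) { called <<- TRUE; 0 }), 2L)
  expect_false(called)
  # exact tie broken by maximum AUC
  expect_equal(pick(c(0.85, 0.85, 0.80),
                    function(idx) c(0.91, 0.93)[match(idx, c(1L, 2L))]), 2L)
  expect_equal(pick(c(0.85, 0.85),
                    function(idx) c(0.93, 0.91)[match(idx, c(1L, 2L))]), 1L)
})

test_that("grid search runs end-to-end, stays in-grid and replays from seed", {
  d <- make_dataset(40L, p = 16L, seed = 2L)
  parts <- split_dataset(d, seed = 2L)
  spec <- model_spec("svm", grid = list(gamma = c(0.01, 0.1), cost = c(1, 10)))
  got <- grid_search_cv(parts$train_val, spec, k = 3L, n_repeats = 2L,
                        seed = 4L, test = parts$test)
  expect_true(got$chosen$gamma %in% c(0.01, 0.1))
  expect_true(got$chosen$cost %in% c(1, 10))
  search <- attr(got, "search")
  expect_equal(nrow(search), 4L)
  expect_true(all(search$mean_cv_accuracy >= 0 &
                    search$mean_cv_accuracy <= 1))
  got2 <- grid_search_cv(parts$train_val, spec, k = 3L, n_repeats = 2L,
                         seed = 4L, test = parts$test)
  expect_identical(got$chosen, got2$chosen)
  expect_error(grid_search_cv(parts$train_val, model_spec("svm", grid = list()),
                              test = parts$test), "empty")
})

test_that("bundles hold one fit per negative set and average probabilities", {
  fx <- study_fixture()
  for (b in fx$bundles) {
    expect_s3_class(b, "model_bundle")
    expect_length(b$fits, length(fx$benchmark$negative_sets))
  }
  # bundle prediction is the mean of member-fit probabilities
  x <- fx$benchmark$features[fx$benchmark$positives$compound_id[1:5], ,
                             drop = FALSE]
  b <- fx$bundles$rf
  manual <- rowMeans(vapply(b$fits, function(f)
    abxscreen:::.predict_prob("rf", f, x), numeric(5)))
  expect_equal(unname(predict(b, x)), unname(manual), tolerance = 1e-12)
  # metric sd over identical negative sets is zero by construction
  expect_error(train_final(fx$benchmark, model_spec("svm")), "chosen")
  wrong <- matrix(0, 2, 16)
  expect_error(predict(b, wrong), "fingerprint configuration")
})
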