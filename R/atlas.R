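# explained variance ratio of predictions: 1 - Var(residual) / Var(truth),
# uniformly averaged over target dimensions (the variance-weighted average
# is returned as an attribute)
explained_variance <- function(truth, pred) {
  truth <- as.matrix(truth); pred <- as.matrix(pred)
  num <- apply(truth - pred, 2, var)
  den <- apply(truth, 2, var)
  ev <- 1 - num / den
  ev[!is.finite(ev)] <- 0
  out <- mean(ev)
  attr(out, "weighted") <- 1 - sum(num) / sum(den)
  out
}

#' Curate training cells for atlas regression
#'
#' Keeps cells whose secondary-channel intensity lies strictly above the
#' given percentile of all intensities, then removes rare extreme outliers
#' in the joint feature space with an isolation forest, dropping the
#' `floor(contamination * n)` highest-scoring survivors.
#'
#' @param features joint shape + target feature matrix (rows = cells).
#' @param secondary_intensity per-cell secondary-channel intensity.
#' @param percentile intensity percentile below which cells are dropped
#'   (default 33; cells strictly above the threshold are kept).
#' @param contamination fraction removed by the isolation forest
#'   (default 0.05).
#' @param min_cells minimum surviving cells (default 30); fewer is an
#'   error.
#' @param seed optional integer seed for the isolation forest.
#' @return Integer vector of retained row indices.
#' @export
select_training_cells <- function(features, secondary_intensity,
                                  percentile = 33, contamination = 0.05,
                                  min_cells = 30, seed = NULL) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(secondary_intensity))
  thr <- as.numeric(quantile(secondary_intensity, percentile / 100))
  keep <- which(secondary_intensity > thr)
  if (length(keep) == 0) keep <- seq_along(secondary_intensity)  # all tied
  m <- length(keep)
  n_drop <- floor(contamination * m)
  if (n_drop > 0) {
    scores <- isolation_forest_scores(features[keep, , drop = FALSE], seed = seed)
    keep <- keep[order(scores, decreasing = TRUE)][-seq_len(n_drop)]
    keep <- sort(keep)
  }
  if (length(keep) < min_cells)
    stop("only ", length(keep), " cells survive curation (minimum ", min_cells, ")")
  keep
}

default_svr_grid <- function(n_features) {
  g0 <- 1 / max(n_features, 1)
  expand.grid(cost = 10^seq(-1, 2), gamma = g0 * 10^seq(-1, 1),
              epsilon = c(0.01, 0.1))
}

fit_multi_svr <- function(x, y, cost, gamma, epsilon) {
  lapply(seq_len(ncol(y)), function(j)
    e1071::svm(x, y[, j], type = "eps-regression", kernel = "radial",
               cost = cost, gamma = gamma, epsilon = epsilon, scale = TRUE))
}

predict_multi_svr <- function(models, x) {
  do.call(cbind, lapply(models, function(m) as.numeric(predict(m, x))))
}

shuffle_splits <- function(n, n_splits, test_fraction) {
  lapply(seq_len(n_splits), function(i) {
    test <- sort(sample.int(n, max(1, round(test_fraction * n))))
    list(train = setdiff(seq_len(n), test), test = test)
  })
}

#' Train a cross-channel atlas regressor
#'
#' Fits a multi-output RBF-kernel support-vector regression predicting a
#' target-channel embedding from a cell-shape embedding (both typically
#' truncated to their first 20 PCs). Hyperparameters are selected on a
#' logarithmic grid by randomly shuffled train/test splits; the model is
#' refit on all rows with the winning combination. Alternative regressors
#' (k-nearest neighbors, random forest-free baselines) can be compared via
#' `regressor = "knn"` or `"linear"`.
#'
#' @param reference shape feature matrix (rows = cells), e.g. first 20 PCs.
#' @param target target-channel feature matrix with matched rows.
#' @param cv_folds number of random shuffle splits (default 3).
#' @param test_fraction held-out fraction per split (default 0.25).
#' @param grid data.frame of `cost`, `gamma`, `epsilon` combinations
#'   (default: log grid around the conventional defaults).
#' @param regressor `"svr"` (default), `"knn"` or `"linear"` (ridge-free
#'   least squares), for the comparison harness.
#' @param seed integer seed for the splits.
#' @return List with `model` (class `atlas_model`) and `report` (class
#'   `regression_report`: per-fold train/test explained variance, fold
#'   definitions, grid searched).
#' @export
train_channel_regressor <- function(reference, target, cv_folds = 3,
                                    test_fraction = 0.25, grid = NULL,
                                    regressor = c("svr", "knn", "linear"),
                                    seed = 1) {
  regressor <- match.arg(regressor)
  x <- as.matrix(reference); y <- as.matrix(target)
  if (nrow(x) != nrow(y)) stop("reference and target must have matched rows")
  n <- nrow(x)
  if (is.null(grid)) grid <- default_svr_grid(ncol(x))
  withr::with_seed(seed, {
    splits <- shuffle_splits(n, cv_folds, test_fraction)
    fit_fun <- switch(regressor,
      svr = function(xt, yt, par) fit_multi_svr(xt, yt, par$cost, par$gamma, par$epsilon),
      knn = function(xt, yt, par) list(x = xt, y = yt, k = 5, knn = TRUE),
      linear = function(xt, yt, par) {
        xt1 <- cbind(1, xt)
        list(beta = qr.solve(crossprod(xt1) + diag(1e-8, ncol(xt1)),
                             crossprod(xt1, yt)), linear = TRUE)
      })
    pred_fun <- function(m, xnew) {
      if (!is.null(m$knn)) knn_regress(m$x, m$y, xnew, m$k)
      else if (!is.null(m$linear)) cbind(1, xnew) %*% m$beta
      else predict_multi_svr(m, xnew)
    }
    search <- if (regressor == "svr") grid else data.frame(dummy = 1)
    cv_scores <- vapply(seq_len(nrow(search)), function(g) {
      mean(vapply(splits, function(sp) {
        m <- fit_fun(x[sp$train, , drop = FALSE], y[sp$train, , drop = FALSE],
                     search[g, ])
        as.numeric(explained_variance(y[sp$test, , drop = FALSE],
                                      pred_fun(m, x[sp$test, , drop = FALSE])))
      }, numeric(1)))
    }, numeric(1))
    best <- which.max(cv_scores)
    par <- search[best, ]
    fold_train <- numeric(cv_folds); fold_test <- numeric(cv_folds)
    for (i in seq_along(splits)) {
      sp <- splits[[i]]
      m <- fit_fun(x[sp$train, , drop = FALSE], y[sp$train, , drop = FALSE], par)
      fold_train[i] <- explained_variance(y[sp$train, , drop = FALSE],
                                          pred_fun(m, x[sp$train, , drop = FALSE]))
      fold_test[i] <- explained_variance(y[sp$test, , drop = FALSE],
                                         pred_fun(m, x[sp$test, , drop = FALSE]))
    }
    final <- fit_fun(x, y, par)
    model <- structure(list(fit = final, regressor = regressor,
                            hyperparameters = par, n_features = ncol(x),
                            n_targets = ncol(y), seed = seed,
                            predict_fun = NULL),
                       class = "atlas_model")
    report <- structure(list(
      ev_train_mean = mean(fold_train), ev_train_sd = sd(fold_train),
      ev_test_mean = mean(fold_test), ev_test_sd = sd(fold_test),
      fold_train = fold_train, fold_test = fold_test,
      folds = splits, grid = search, cv_scores = cv_scores,
      best = par), class = "regression_report")
    list(model = model, report = report)
  })
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("<regression_report> explained variance: train %.3f +/- %.3f, test %.3f +/- %.3f (%d folds)\n",
              x$ev_train_mean, x$ev_train_sd, x$ev_test_mean, x$ev_test_sd,
              length(x$fold_test)))
  invisible(x)
}

#' Predict a target channel from shape features
#'
#' @param model an `atlas_model` from [train_channel_regressor()] or
#'   [train_count_regressor()].
#' @param reference new rows with the model's input dimensionality.
#' @return Predicted target matrix (or vector for count models).
#' @export
predict_channel <- function(model, reference) {
  stopifnot(inherits(model, "atlas_model"))
  x <- as.matrix(reference)
  if (ncol(x) != model$n_features) stop("input dimensionality mismatch")
  m <- model$fit
  if (!is.null(m$knn)) knn_regress(m$x, m$y, x, m$k)
  else if (!is.null(m$linear)) cbind(1, x) %*% m$beta
  else {
    p <- predict_multi_svr(m, x)
    if (model$n_targets == 1) as.numeric(p) else p
  }
}

#' Train a spot-count regressor
#'
#' Regresses per-cell transcript spot counts on a 23-feature input: the
#' first 10 shape TFOR PCs, the first 10 shape CFOR PCs, and the 3 TFOR
#' centroid coordinates. RBF support-vector regression with grid-searched
#' hyperparameters; performance reported over randomly shuffled
#' train/test splits.
#'
#' @param shape_tfor_pcs n x 10 matrix.
#' @param shape_cfor_pcs n x 10 matrix.
#' @param centroids n x 3 TFOR centroid coordinates.
#' @param counts non-negative integer spot counts.
#' @param cv_folds,test_fraction,grid,seed as in
#'   [train_channel_regressor()].
#' @return List with `model` (`atlas_model`) and `report`
#'   (`regression_report`).
#' @export
train_count_regressor <- function(shape_tfor_pcs, shape_cfor_pcs, centroids,
                                  counts, cv_folds = 3, test_fraction = 0.25,
                                  grid = NULL, seed = 1) {
  x <- cbind(as.matrix(shape_tfor_pcs), as.matrix(shape_cfor_pcs),
             as.matrix(centroids))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (nrow(x) != length(counts)) stop("row mismatch")
  train_channel_regressor(x, matrix(as.numeric(counts), ncol = 1),
                          cv_folds = cv_folds, test_fraction = test_fraction,
                          grid = grid, seed = seed)
}

#' Drop samples with too few spots per cell
#'
#' Removes samples whose mean spot count per cell is below `min_mean`
#' (boundary inclusive: a mean of exactly `min_mean` is retained), the
#' filter applied before count regression when a detector underperforms on
#' individual samples.
#'
#' @param counts data.frame with columns `sample_id` and `count`.
#' @param min_mean minimum mean count per cell (default 2).
#' @return Character vector of retained sample ids (warns when empty).
#' @export
filter_samples_by_mean_count <- function(counts, min_mean = 2) {
  stopifnot(all(c("sample_id", "count") %in% names(counts)))
  means <- tapply(counts$count, counts$sample_id, mean)
  keep <- names(means)[means >= min_mean]
  if (length(keep) == 0) warning("no samples pass the mean-count filter")
  keep
}

# brute-force k-nearest-neighbor multivariate regression
knn_regress <- function(x_train, y_train, x_new, k = 5) {
  x_train <- as.matrix(x_train); x_new <- as.matrix(x_new)
  y_train <- as.matrix(y_train)
  t2 <- rowSums(x_train^2)
  out <- matrix(NA_real_, nrow(x_new), ncol(y_train))
  for (i in seq_len(nrow(x_new))) {
    d2 <- t2 - 2 * as.numeric(x_train %*% x_new[i, ]) + sum(x_new[i, ]^2)
    nn <- order(d2)[seq_len(k)]
    out[i, ] <- colMeans(y_train[nn, , drop = FALSE])
  }
  out
}
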