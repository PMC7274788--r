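apply_arch_prep <- function(prep, x) {
  x <- as.matrix(x)
  if (prep$standardize)
    x <- sweep(sweep(x, 2, prep$center), 2, prep$scale, `/`)
  if (!is.null(prep$pca)) x <- x %*% prep$pca
  x
}

#' Train a morphological archetype classifier
#'
#' Fits an RBF-kernel support-vector classifier with probability
#' calibration on manually annotated archetype cells. Preprocessing
#' (feature standardization on/off; PCA keeping 15, 30 or 50 components or
#' none) and the penalty / kernel-coefficient decades are selected by
#' stratified cross-validated grid search on accuracy; the winning
#' configuration is refit on all annotated cells.
#'
#' @param features feature matrix (TFOR or CFOR embedding), rows = cells.
#' @param labels factor (or coercible) of archetype annotations; >= 2
#'   classes with >= 2 cells each.
#' @param cv number of cross-validation folds (default 5).
#' @param standardize_options,pca_options,cost_options,gamma_factor_options
#'   the preprocessing and hyperparameter grid. `pca_options` entries of
#'   `NA` mean no PCA; entries exceeding the feature count are dropped.
#' @param seed integer seed.
#' @return An object of class `archetype_model` with fields `svm`, `prep`,
#'   `classes`, `grid`, `best`, `cv_accuracy`, `seed`.
#' @export
train_archetype_classifier <- function(features, labels, cv = 5,
                                       standardize_options = c(TRUE, FALSE),
                                       pca_options = c(NA, 15, 30, 50),
                                       cost_options = 10^seq(-1, 2),
                                       gamma_factor_options = 10^seq(-1, 1),
                                       seed = 1) {
  x <- as.matrix(features)
  y <- droplevels(as.factor(labels))
  if (nlevels(y) < 2) stop("need at least 2 classes")
  if (any(table(y) < 2)) stop("every class needs at least 2 cells")
  pca_options <- pca_options[is.na(pca_options) | pca_options <= ncol(x)]
  g0 <- 1 / ncol(x)
  grid <- expand.grid(standardize = standardize_options, pca = pca_options,
                      cost = cost_options, gamma = g0 * gamma_factor_options)
  withr::with_seed(seed, {
    folds <- stratified_folds(y, cv)
    prep_for <- function(std, pca_keep, xtr) {
      ctr <- colMeans(xtr); scl <- apply(xtr, 2, sd); scl[scl == 0] <- 1
      xs <- if (std) sweep(sweep(xtr, 2, ctr), 2, scl, `/`) else xtr
      rot <- NULL
      if (!is.na(pca_keep)) {
        p <- prcomp(xs, center = FALSE, scale. = FALSE)
        rot <- p$rotation[, seq_len(min(pca_keep, ncol(p$rotation))), drop = FALSE]
      }
      list(standardize = std, center = ctr, scale = scl, pca = rot)
    }
    acc <- vapply(seq_len(nrow(grid)), function(g) {
      mean(vapply(folds, function(fold) {
        tr <- setdiff(seq_along(y), fold)
        prep <- prep_for(grid$standardize[g], grid$pca[g], x[tr, , drop = FALSE])
        xt <- apply_arch_prep(prep, x[tr, , drop = FALSE])
        fit <- e1071::svm(xt, y[tr], kernel = "radial", cost = grid$cost[g],
                          gamma = grid$gamma[g], scale = FALSE)
        mean(predict(fit, apply_arch_prep(prep, x[fold, , drop = FALSE])) == y[fold])
      }, numeric(1)))
    }, numeric(1))
    best <- which.max(acc)
    prep <- prep_for(grid$standardize[best], grid$pca[best], x)
    fit <- e1071::svm(apply_arch_prep(prep, x), y, kernel = "radial",
                      cost = grid$cost[best], gamma = grid$gamma[best],
                      scale = FALSE, probability = TRUE)
    structure(list(svm = fit, prep = prep, classes = levels(y), grid = grid,
                   best = grid[best, ], cv_accuracy = acc[best], seed = seed),
              class = "archetype_model")
  })
}

#' Predict archetype labels and probabilities
#'
#' @param model an `archetype_model`.
#' @param features new feature rows (model's input dimensionality).
#' @return List with `labels` (factor; the class of maximum probability)
#'   and `probabilities` (rows sum to 1, columns in `model$classes`
#'   order).
#' @export
predict_archetypes <- function(model, features) {
  stopifnot(inherits(model, "archetype_model"))
  x <- as.matrix(features)
  if (ncol(x) != length(model$prep$center)) stop("feature dimensionality mismatch")
  xp <- apply_arch_prep(model$prep, x)
  pred <- predict(model$svm, xp, probability = TRUE)
  probs <- attr(pred, "probabilities")[, model$classes, drop = FALSE]
  probs <- probs / rowSums(probs)
  labels <- factor(model$classes[max.col(probs)], levels = model$classes)
  list(labels = labels, probabilities = probs)
}

# stratified fold assignment: within each class, cells are dealt around
# the folds, preserving class proportions within +/- 1 cell
stratified_folds <- function(y, k) {
  folds <- vector("list", k)
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    grp <- rep(seq_len(k), length.out = length(idx))
    for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], idx[grp == f])
  }
  folds
}

#' Stratified train/test evaluation of the archetype classifier
#'
#' Splits the annotated cells into a training and a test set of the given
#' sizes, preserving class proportions within one cell per class, trains a
#' classifier on the training set and reports the test confusion matrix
#' (rows = true classes) and accuracy.
#'
#' @param features,labels annotated cells.
#' @param train_n,test_n split sizes; `train_n + test_n` must not exceed
#'   the annotated count.
#' @param seed integer seed.
#' @param ... passed to [train_archetype_classifier()] (e.g. a reduced
#'   grid).
#' @return List with `confusion` (matrix), `accuracy`, `train_idx`,
#'   `test_idx`.
#' @export
stratified_evaluation <- function(features, labels, train_n, test_n,
                                  seed = 1, ...) {
  x <- as.matrix(features)
  y <- droplevels(as.factor(labels))
  n <- length(y)
  if (train_n + test_n > n) stop("train_n + test_n exceeds annotated count")
  withr::with_seed(seed, {
    # largest-remainder apportionment of train_n across classes
    cnt <- table(y)
    quota <- as.numeric(cnt) * train_n / n
    base <- floor(quota)
    rem <- train_n - sum(base)
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
    if (any(base < 1) || any(as.numeric(cnt) - base < 1))
      stop("a class is too small for stratification")
    train_idx <- unlist(lapply(seq_along(levels(y)), function(i) {
      sample(which(y == levels(y)[i]), base[i])
    }))
    rest <- setdiff(seq_len(n), train_idx)
    # test set: stratified among the remainder
    quota_t <- as.numeric(table(y[rest])) * test_n / length(rest)
    base_t <- floor(quota_t)
    rem_t <- test_n - sum(base_t)
    if (rem_t > 0) {
      extra <- order(quota_t - base_t, decreasing = TRUE)[seq_len(rem_t)]
      base_t[extra] <- base_t[extra] + 1
    }
    test_idx <- unlist(lapply(seq_along(levels(y)), function(i) {
      sample(intersect(rest, which(y == levels(y)[i])), base_t[i])
    }))
    model <- train_archetype_classifier(x[train_idx, , drop = FALSE],
                                        y[train_idx], ...)
    pred <- predict_archetypes(model, x[test_idx, , drop = FALSE])
    confusion <- table(true = factor(y[test_idx], levels = levels(y)),
                       predicted = factor(pred$labels, levels = levels(y)))
    list(confusion = as.matrix(confusion),
         accuracy = mean(pred$labels == y[test_idx]),
         train_idx = sort(train_idx), test_idx = sort(test_idx),
         model = model)
  })
}

#' Archetype space: PCA of class probabilities
#'
#' Places every cell in a low-dimensional "archetype space" by principal
#' component analysis of its class probabilities. Since C-class
#' probability rows live on a (C-1)-simplex, at most C-1 components are
#' informative.
#'
#' @param probabilities cells x classes probability matrix (rows sum
#'   to 1).
#' @return Object of class `archetype_space` with `coordinates` (cells x
#'   min(3, C-1) scores), `explained_variance_ratios`, `rotation`,
#'   `center`.
#' @export
archetype_space <- function(probabilities) {
  p <- as.matrix(probabilities)
  if (ncol(p) < 2) stop("need at least 2 classes")
  pca <- prcomp(p, center = TRUE, scale. = FALSE)
  evr <- pca$sdev^2 / sum(pca$sdev^2)
  keep <- min(3, ncol(p) - 1)
  structure(list(coordinates = pca$x[, seq_len(keep), drop = FALSE],
                 explained_variance_ratios = evr,
                 rotation = pca$rotation, center = pca$center),
            class = "archetype_space")
}

#' Compare two groups of cells (Mann-Whitney U + Cohen's d)
#'
#' Two-tailed Mann-Whitney U test with optional Bonferroni correction
#' (the raw p-value is multiplied by the declared family size `n_tests`
#' and capped at 1), plus Cohen's d as the effect size (pooled standard
#' deviation). Comparisons with corrected p > 0.01 are flagged as not
#' significant; because large cell numbers make tiny differences
#' "significant", the effect size should always be read alongside p.
#'
#' @param values_a,values_b numeric vectors (non-empty).
#' @param n_tests declared number of tests in the family (default 1 = no
#'   correction).
#' @return Object of class `group_comparison` with `statistic`, `p_value`
#'   (corrected), `p_raw`, `cohens_d`, `significant`, `n_a`, `n_b`.
#' @export
compare_groups <- function(values_a, values_b, n_tests = 1) {
  if (length(values_a) == 0 || length(values_b) == 0) stop("empty group")
  wt <- suppressWarnings(wilcox.test(values_a, values_b,
                                     alternative = "two.sided", exact = FALSE))
  p_adj <- min(1, wt$p.value * n_tests)
  na <- length(values_a); nb <- length(values_b)
  sp2 <- ((na - 1) * var(values_a) + (nb - 1) * var(values_b)) /
    max(na + nb - 2, 1)
  d <- if (sp2 > 0) (mean(values_a) - mean(values_b)) / sqrt(sp2) else 0
  structure(list(statistic = unname(wt$statistic), p_value = p_adj,
                 p_raw = wt$p.value, cohens_d = d,
                 significant = p_adj <= 0.01, n_a = na, n_b = nb),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> U = %.1f, p = %.3g%s, Cohen's d = %.2f (n = %d vs %d)\n",
              x$statistic, x$p_value,
              if (x$significant) " *" else " (n.s.)", x$cohens_d, x$n_a, x$n_b))
  invisible(x)
}

#' Match point annotations to segmented cells
#'
#' Maps manual point annotations (clicked marker coordinates plus a class
#' name) to the enclosing segmented cell: the label at the annotation's
#' voxel. Annotations falling on background are dropped with a warning.
#'
#' @param annotations data.frame with columns `z`, `y`, `x` (voxel
#'   coordinates) and `class`; coordinates are 0-based by default.
#' @param labels a [label_volume()].
#' @param one_based set TRUE when coordinates are 1-based.
#' @return data.frame with columns `cell_id` and `class`.
#' @export
match_annotations <- function(annotations, labels, one_based = FALSE) {
  stopifnot(inherits(labels, "label_volume"),
            all(c("z", "y", "x", "class") %in% names(annotations)))
  off <- if (one_based) 0L else 1L
  d <- dim(labels$voxels)
  zi <- annotations$z + off; yi <- annotations$y + off; xi <- annotations$x + off
  ok <- zi >= 1 & zi <= d[1] & yi >= 1 & yi <= d[2] & xi >= 1 & xi <= d[3]
  ids <- rep(0L, nrow(annotations))
  ids[ok] <- labels$voxels[cbind(zi[ok], yi[ok], xi[ok])]
  drop <- ids == 0
  if (any(drop)) warning(sum(drop), " annotation(s) fell on background; dropped")
  data.frame(cell_id = ids[!drop], class = annotations$class[!drop])
}
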