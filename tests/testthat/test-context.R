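test_that("archetype classifier separates distinct shape families", {
  fam <- three_class_features(seed = 1)
  ev <- do.call(stratified_evaluation,
                c(list(fam$x, fam$y, train_n = 120, test_n = 60, seed = 2),
                  fast_arch_grid))
  expect_gt(ev$accuracy, 0.9)
  # confusion rows sum to the per-class test counts
  expect_identical(unname(rowSums(ev$confusion)), rep(20, 3))

  # shuffled labels: chance-level accuracy
  ys <- withr::with_seed(3, sample(fam$y))
  evs <- do.call(stratified_evaluation,
                 c(list(fam$x, ys, train_n = 120, test_n = 60, seed = 4),
                   fast_arch_grid))
  expect_lt(abs(evs$accuracy - 1 / 3), 0.15)
})

test_that("predictions carry calibrated probabilities", {
  fam <- three_class_features(seed = 5)
  m <- do.call(train_archetype_classifier,
               c(list(fam$x, fam$y, seed = 6), fast_arch_grid))
  pr <- predict_archetypes(m, fam$x)
  expect_true(all(abs(rowSums(pr$probabilities) - 1) < 1e-9))
  expect_identical(ncol(pr$probabilities), 3L)
  # a training cell deep inside its class region keeps its annotation
  expect_identical(as.character(pr$labels[1]), "a")
  expect_identical(as.character(pr$labels[61]), "b")
  expect_error(predict_archetypes(m, fam$x[, 1:3]), "mismatch")
  expect_error(train_archetype_classifier(fam$x, rep("a", nrow(fam$x))),
               "at least 2 classes")
})

test_that("four archetypes give four probability columns and a 436/188 split", {
  # class sizes mirroring a four-archetype annotation of 624 cells
  sizes <- c(leader = 93, outer = 241, inner = 182, between = 108)
  withr::with_seed(7, {
    x <- do.call(rbind, lapply(seq_along(sizes), function(i)
      matrix(rnorm(sizes[i] * 6, mean = 4 * i), ncol = 6)))
    y <- rep(names(sizes), times = sizes)
  })
  ev <- do.call(stratified_evaluation,
                c(list(x, y, train_n = 436, test_n = 188, seed = 8),
                  fast_arch_grid))
  expect_length(ev$train_idx, 436)
  expect_length(ev$test_idx, 188)
  # stratification preserves class proportions within one cell per class
  for (cl in names(sizes)) {
    got <- sum(y[ev$train_idx] == cl)
    expect_lte(abs(got - sizes[[cl]] * 436 / 624), 1)
  }
  m <- do.call(train_archetype_classifier,
               c(list(x, y, seed = 9), fast_arch_grid))
  pr <- predict_archetypes(m, x)
  expect_identical(ncol(pr$probabilities), 4L)

  expect_error(stratified_evaluation(x, y, train_n = 600, test_n = 100),
               "exceeds")
})

test_that("indistinguishable archetypes confuse each other, not the rest", {
  withr::with_seed(10, {
    a <- matrix(rnorm(50 * 6, 0), 50, 6)
    b <- matrix(rnorm(50 * 6, 6), 50, 6)
    b_dup <- matrix(rnorm(50 * 6, 6), 50, 6)   # duplicate family of b
  })
  x <- rbind(a, b, b_dup)
  y <- rep(c("a", "b", "bdup"), each = 50)
  ev <- do.call(stratified_evaluation,
                c(list(x, y, train_n = 90, test_n = 45, seed = 11),
                  fast_arch_grid))
  cm <- ev$confusion
  # class a stays clean; the duplicate pair leaks into each other
  expect_gte(cm["a", "a"], 14)
  leak <- cm["b", "bdup"] + cm["bdup", "b"]
  other <- cm["b", "a"] + cm["bdup", "a"]
  expect_gt(leak, other)
})

test_that("archetype space is a simplex PCA", {
  fam <- three_class_features(n_per_class = 40, seed = 12)
  m <- do.call(train_archetype_classifier,
               c(list(fam$x, fam$y, seed = 13), fast_arch_grid))
  pr <- predict_archetypes(m, fam$x)
  sp <- archetype_space(pr$probabilities)
  # C classes: at most C-1 informative dimensions
  expect_lt(sp$explained_variance_ratios[3], 1e-9)

  # one-hot rows map to extreme corners; a uniform row to their centroid
  probs <- rbind(diag(4), rep(0.25, 4))
  colnames(probs) <- c("w", "x", "y", "z")
  sp2 <- archetype_space(probs)
  corners <- sp2$coordinates[1:4, ]
  centroid_cell <- sp2$coordinates[5, ]
  expect_equal(unname(centroid_cell), unname(colMeans(corners)),
               tolerance = 1e-9)
  d <- as.matrix(dist(sp2$coordinates))
  expect_equal(max(d), max(d[1:4, 1:4]), tolerance = 1e-9)

  expect_error(archetype_space(matrix(1, 5, 1)), "at least 2 classes")
})

test_that("group comparisons: Mann-Whitney U, Bonferroni, Cohen's d", {
  withr::with_seed(14, {
    a <- rnorm(200, 0, 1)
    b <- rnorm(200, 1, 1)
  })
  gc <- compare_groups(a, b)
  expect_lt(abs(abs(gc$cohens_d) - 1), 0.2)
  expect_true(gc$significant)
  expect_lte(gc$p_value, 0.01)

  same <- compare_groups(a, a)
  expect_equal(same$cohens_d, 0, tolerance = 1e-12)
  expect_false(same$significant)

  # Bonferroni: raw p multiplied by the family size, capped at 1
  g5 <- compare_groups(a, b, n_tests = 5)
  expect_equal(g5$p_value, min(1, g5$p_raw * 5))
  weak <- compare_groups(a[1:10], b[1:10] - 0.9, n_tests = 50)
  expect_identical(weak$p_value, 1)

  expect_error(compare_groups(numeric(0), b), "empty group")
})

test_that("point annotations map to the enclosing segmented cell", {
  v <- array(0L, c(6, 6, 6))
  v[2:3, 2:3, 2:3] <- 1L
  v[5:6, 5:6, 5:6] <- 2L
  labs <- label_volume(v, c(1, 1, 1))
  ann <- data.frame(z = c(1, 4, 0), y = c(1, 4, 0), x = c(1, 4, 0),
                    class = c("a", "b", "c"))   # 0-based clicks
  expect_warning(res <- match_annotations(ann, labs), "background")
  expect_identical(res$cell_id, c(1L, 2L))
  expect_identical(as.character(res$class), c("a", "b"))
})
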