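# Isolation forest for outlier removal in feature space.
# Trees isolate points by recursive random axis-aligned splits; anomalous
# points have short average path lengths. Score follows the original
# formulation: s(x) = 2^(-E[h(x)] / c(psi)) with c(psi) the average
# unsuccessful-search path length of a BST of size psi.

avg_path_length <- function(n) {
  if (n <= 1) return(0)
  2 * (log(n - 1) + 0.5772156649) - 2 * (n - 1) / n
}

grow_itree <- function(x, height, limit) {
  n <- nrow(x)
  if (height >= limit || n <= 1) {
    return(list(leaf = TRUE, size = n))
  }
  q <- sample.int(ncol(x), 1)
  rng <- range(x[, q])
  if (rng[1] == rng[2]) return(list(leaf = TRUE, size = n))
  p <- runif(1, rng[1], rng[2])
  left <- x[, q] < p
  list(leaf = FALSE, q = q, p = p,
       l = grow_itree(x[left, , drop = FALSE], height + 1, limit),
       r = grow_itree(x[!left, , drop = FALSE], height + 1, limit))
}

itree_path <- function(tree, x, height = 0) {
  if (tree$leaf) return(height + avg_path_length(tree$size))
  if (x[tree$q] < tree$p) itree_path(tree$l, x, height + 1)
  else itree_path(tree$r, x, height + 1)
}

#' Isolation-forest anomaly scores
#'
#' @param x numeric matrix (rows = observations).
#' @param n_trees number of isolation trees (default 100).
#' @param sample_size subsample per tree (default min(256, n)).
#' @param seed optional integer seed.
#' @return Numeric anomaly scores in (0, 1); higher = more anomalous.
#' @export
isolation_forest_scores <- function(x, n_trees = 100, sample_size = NULL,
                                    seed = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (is.null(sample_size)) sample_size <- min(256L, n)
  run <- function() {
    limit <- ceiling(log2(sample_size))
    trees <- lapply(seq_len(n_trees), function(i) {
      idx <- sample.int(n, sample_size)
      grow_itree(x[idx, , drop = FALSE], 0, limit)
    })
    ph <- vapply(seq_len(n), function(i) {
      mean(vapply(trees, itree_path, numeric(1), x = x[i, ]))
    }, numeric(1))
    2^(-ph / avg_path_length(sample_size))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
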