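# local densities = number of points within `radius` of each point (self
# included). Exact for n <= 50000 (grid-hashed neighbor count); when the
# radius covers the whole bounding box every count is trivially n; for
# larger clouds the count is estimated against a random reference
# subsample of 20000 points and rescaled (unbiased).
local_densities <- function(pts, radius, seed = NULL) {
  n <- nrow(pts)
  diag2 <- sum(apply(pts, 2, function(x) diff(range(x)))^2)
  if (radius^2 >= diag2) return(rep(n, n))
  if (n <= 50000) return(.cpp_count_within_radius(pts, radius))
  m <- 20000L
  run <- function() sample.int(n, m)
  ref <- if (is.null(seed)) run() else withr::with_seed(seed + 7L, run())
  cnt <- .cpp_count_within_radius_ref(pts, pts[ref, , drop = FALSE], radius)
  pmax(1, round(cnt * n / m))
}

# k-means wrapper: k-means++ initialization on unique rows, robust to
# duplicate landmarks (multinomial sampling draws with replacement)
robust_kmeans <- function(x, k, iter.max = 100) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k > n) stop("fewer points than clusters")
  if (k == n) return(list(centers = x))
  if (k == 1) return(list(centers = matrix(colMeans(x), 1)))
  ux <- unique(x)
  if (nrow(ux) < k)
    stop("fewer distinct points (", nrow(ux), ") than clusters (", k, ")")
  # k-means++ seeding
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- ux[sample.int(nrow(ux), 1), ]
  d2 <- rowSums(sweep(ux, 2, centers[1, ])^2)
  for (i in 2:k) {
    probs <- d2 / sum(d2)
    centers[i, ] <- ux[sample.int(nrow(ux), 1, prob = probs), ]
    d2 <- pmin(d2, rowSums(sweep(ux, 2, centers[i, ])^2))
  }
  # Hartigan-Wong routinely reports non-convergence at k in the hundreds;
  # the centers are still usable condensation landmarks, so that specific
  # warning is muffled. Any other warning propagates.
  quiet_kmeans <- function(...) {
    withCallingHandlers(stats::kmeans(...), warning = function(w) {
      if (grepl("did not converge", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  }
  fit <- tryCatch(
    quiet_kmeans(x, centers = centers, iter.max = iter.max),
    error = function(e) quiet_kmeans(x, centers = centers,
                                     iter.max = iter.max,
                                     algorithm = "Lloyd"))
  fit
}

#' Density-dependent downsampling of a point cloud
#'
#' Computes each point's local density LD (number of points within a
#' sphere whose radius is the median pairwise distance times
#' `radius_factor`), sets the target density TD to the `target_percentile`
#' of all local densities, and keeps each point with probability 1 if
#' LD < TD and TD / LD otherwise. If more than `max_points` survive, a
#' uniform random subsample enforces the cap. This flattens local density
#' peaks while preserving the cloud's overall shape.
#'
#' For clouds above 20,000 points the median pairwise distance is
#' estimated from 10^6 randomly sampled pairs.
#'
#' @param cloud a [point_cloud()] or n x 3 matrix, n >= 2.
#' @param radius_factor multiplier on the median pairwise distance
#'   (default 5).
#' @param target_percentile percentile of local densities used as TD
#'   (default 3).
#' @param max_points hard cap on the returned cloud size (default 200000).
#' @param seed optional integer seed.
#' @return A [point_cloud()] of the retained points. Attributes
#'   `local_density`, `target_density` and `kept` record the per-point
#'   densities, the TD and the retained indices.
#' @export
density_dependent_downsample <- function(cloud, radius_factor = 5,
                                         target_percentile = 3,
                                         max_points = 200000, seed = NULL) {
  pts <- cloud_matrix(cloud)
  n <- nrow(pts)
  if (n < 2) stop("need at least 2 points")
  med <- if (n <= 20000) {
    .cpp_median_pairwise(pts)
  } else {
    run <- function() {
      i <- sample.int(n, 1e6, replace = TRUE)
      j <- sample.int(n, 1e6, replace = TRUE)
      ok <- i != j
      median(sqrt(rowSums((pts[i[ok], ] - pts[j[ok], ])^2)))
    }
    if (is.null(seed)) run() else withr::with_seed(seed * 2L + 1L, run())
  }
  radius <- med * radius_factor
  ld <- local_densities(pts, radius, seed = seed)
  td <- as.numeric(quantile(ld, target_percentile / 100))
  p_keep <- ifelse(ld < td, 1, td / ld)
  draw <- function() {
    keep <- runif(n) < p_keep
    kept <- which(keep)
    if (length(kept) > max_points) kept <- sort(sample(kept, max_points))
    kept
  }
  kept <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  out <- point_cloud(pts[kept, , drop = FALSE], frame = cloud_frame(cloud))
  attr(out, "local_density") <- ld
  attr(out, "target_density") <- td
  attr(out, "kept") <- kept
  out
}

#' Condense a point cloud to k representative landmarks
#'
#' Runs k-means on the landmarks and returns the cluster centers as the
#' new, smaller cloud (default 2000 -> 500 before clouds are overlaid for
#' reference-cluster fitting).
#'
#' @param cloud a [point_cloud()] or matrix with at least `k` points.
#' @param k number of centers (default 500).
#' @param seed optional integer seed.
#' @return A [point_cloud()] of the k centers.
#' @export
condense_cloud <- function(cloud, k = 500, seed = NULL) {
  pts <- cloud_matrix(cloud)
  if (nrow(pts) < k) stop("fewer points than clusters")
  run <- function() robust_kmeans(pts, k)$centers
  centers <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  colnames(centers) <- colnames(pts)
  point_cloud(centers, frame = cloud_frame(cloud),
              cell_id = if (inherits(cloud, "point_cloud")) cloud$cell_id else NA,
              sample_id = if (inherits(cloud, "point_cloud")) cloud$sample_id else NA)
}

#' Fit shared reference clusters for cluster-based embedding
#'
#' Centers every cellular cloud on its centroid, condenses each to
#' `condense_to` landmarks, overlays the clouds of a random representative
#' subset of samples (at least `subset_min`, at most `subset_max`),
#' density-downsamples the overlay to at most `max_points` points, and
#' fits k-means with `k` clusters. The resulting centers are the consensus
#' reference points shared by all cells of the dataset.
#'
#' @param clouds list of [point_cloud()] / `pd_cloud` objects (one per
#'   cell), all in the same frame. Sample membership is read from
#'   `sample_id` (cells with NA form one implicit sample).
#' @param k number of reference clusters (default 20).
#' @param subset_min,subset_max bounds on the random sample subset.
#' @param condense_to per-cell condensation size (default 500; clouds at or
#'   below this size are used as-is).
#' @param max_points overlay cap (default 200000).
#' @param seed integer seed.
#' @return Object of class `reference_clusters`: `centers` (k x 3), `k`,
#'   `frame`, `sample_ids` (subset used), `seed`.
#' @export
fit_reference_clusters <- function(clouds, k = 20, subset_min = 10,
                                   subset_max = 25, condense_to = 500,
                                   max_points = 200000, seed = 1) {
  stopifnot(length(clouds) >= 1)
  frames <- vapply(clouds, cloud_frame, character(1))
  frame <- frames[1]
  if (!all(frames == frame)) stop("all clouds must share one frame")
  sids <- vapply(clouds, function(cl)
    as.character(if (is.list(cl) && !is.null(cl$sample_id)) cl$sample_id else NA),
    character(1))
  sids[is.na(sids) | sids == "NA"] <- "sample1"
  samples <- unique(sids)
  withr::with_seed(seed, {
    chosen <- if (length(samples) <= subset_min) samples
              else sample(samples, min(length(samples), subset_max))
    use <- which(sids %in% chosen)
    overlaid <- do.call(rbind, lapply(clouds[use], function(cl) {
      pts <- cloud_matrix(cl)
      pts <- sweep(pts, 2, colMeans(pts))
      if (nrow(pts) > condense_to)
        pts <- cloud_matrix(condense_cloud(pts, condense_to))
      pts
    }))
    if (nrow(overlaid) > k + 1)
      overlaid <- cloud_matrix(density_dependent_downsample(
        overlaid, max_points = max_points))
    if (nrow(overlaid) < k) stop("k exceeds available points")
    centers <- robust_kmeans(overlaid, k)$centers
    structure(list(centers = centers, k = k, frame = frame,
                   sample_ids = chosen, seed = seed),
              class = "reference_clusters")
  })
}

#' Cluster-based embedding features of one point cloud
#'
#' For each shared reference center, finds the `n_neighbors` landmarks of
#' the (centroid-centered) cloud nearest to that center and reports the
#' vector from the center to their centroid — either its 3 components
#' (`variant = "vectors"`, 3k features) or its Euclidean norm
#' (`variant = "magnitudes"`, k features).
#'
#' @param cloud a [point_cloud()] / `pd_cloud` in the same frame as `refs`.
#' @param refs a `reference_clusters` object.
#' @param variant `"vectors"` (default) or `"magnitudes"`.
#' @param n_neighbors neighborhood size (default 25).
#' @param center center the cloud on its centroid first (default TRUE,
#'   matching how clouds enter reference-cluster fitting).
#' @return Named numeric feature row.
#' @export
cbe_features <- function(cloud, refs, variant = c("vectors", "magnitudes"),
                         n_neighbors = 25, center = TRUE) {
  variant <- match.arg(variant)
  stopifnot(inherits(refs, "reference_clusters"))
  pts <- cloud_matrix(cloud)
  if (cloud_frame(cloud) != refs$frame)
    stop("cloud frame '", cloud_frame(cloud), "' does not match reference frame '",
         refs$frame, "'")
  if (nrow(pts) < n_neighbors) stop("cloud smaller than n_neighbors")
  if (center) pts <- sweep(pts, 2, colMeans(pts))
  k <- refs$k
  out <- matrix(NA_real_, k, 3)
  for (j in seq_len(k)) {
    d2 <- (pts[, 1] - refs$centers[j, 1])^2 + (pts[, 2] - refs$centers[j, 2])^2 +
      (pts[, 3] - refs$centers[j, 3])^2
    nn <- order(d2)[seq_len(n_neighbors)]
    out[j, ] <- colMeans(pts[nn, , drop = FALSE]) - refs$centers[j, ]
  }
  if (variant == "vectors") {
    setNames(as.numeric(t(out)),
             paste0("ref", rep(seq_len(k), each = 3), "_", c("z", "y", "x")))
  } else {
    setNames(sqrt(rowSums(out^2)), paste0("ref", seq_len(k), "_mag"))
  }
}

#' Cluster-based embedding of many clouds
#'
#' @param clouds list of clouds (one per cell).
#' @inheritParams cbe_features
#' @return Feature matrix, one row per cloud (row names from `cell_id`
#'   when available).
#' @export
cbe_embed <- function(clouds, refs, variant = "vectors", n_neighbors = 25,
                      center = TRUE) {
  rows <- lapply(clouds, cbe_features, refs = refs, variant = variant,
                 n_neighbors = n_neighbors, center = center)
  m <- do.call(rbind, rows)
  ids <- vapply(clouds, function(cl)
    as.character(if (inherits(cl, "point_cloud")) cl$cell_id
                 else if (inherits(cl, "pd_cloud")) cl$cell_id else NA),
    character(1))
  if (!anyNA(ids) && !any(ids == "NA")) rownames(m) <- ids
  m
}

moment_triples <- function(m) {
  out <- list()
  for (i in m:0) for (j in (m - i):0) {
    k <- m - i - j
    out[[length(out) + 1]] <- c(i, j, k)
  }
  do.call(rbind, out)
}

#' Moments-based baseline embedding (55 features)
#'
#' Computes the raw first moments (3), the centralized second moments (6)
#' and the normalized third to fifth moments (10 + 15 + 21) of a point
#' cloud's coordinates: for every index triple (i, j, k) with
#' i + j + k = m, the mean of the element-wise product
#' (z - mean_z)^i (y - mean_y)^j (x - mean_x)^k, divided for the
#' normalized moments by sd_z^i sd_y^j sd_x^k (population standard
#' deviations). 55 features in total.
#'
#' @param cloud a [point_cloud()] or n x 3 matrix with n >= 2.
#' @return Named numeric vector of length 55 (names like `rM1_100`,
#'   `cM2_110`, `nM4_202`).
#' @export
moments_features <- function(cloud) {
  pts <- cloud_matrix(cloud)
  if (nrow(pts) < 2) stop("need at least 2 points")
  mu <- colMeans(pts)
  cen <- sweep(pts, 2, mu)
  sds <- sqrt(colMeans(cen^2))
  out <- numeric(0)
  # raw 1st moments
  tr <- moment_triples(1)
  vals <- apply(tr, 1, function(e) mean(pts[, 1]^e[1] * pts[, 2]^e[2] * pts[, 3]^e[3]))
  names(vals) <- paste0("rM1_", apply(tr, 1, paste, collapse = ""))
  out <- c(out, vals)
  # centralized 2nd moments
  tr <- moment_triples(2)
  vals <- apply(tr, 1, function(e) mean(cen[, 1]^e[1] * cen[, 2]^e[2] * cen[, 3]^e[3]))
  names(vals) <- paste0("cM2_", apply(tr, 1, paste, collapse = ""))
  out <- c(out, vals)
  # normalized 3rd-5th moments
  if (any(sds == 0))
    stop("zero standard deviation on an axis; normalized moments undefined")
  for (m in 3:5) {
    tr <- moment_triples(m)
    vals <- apply(tr, 1, function(e)
      mean(cen[, 1]^e[1] * cen[, 2]^e[2] * cen[, 3]^e[3]) /
        (sds[1]^e[1] * sds[2]^e[2] * sds[3]^e[3]))
    names(vals) <- paste0("nM", m, "_", apply(tr, 1, paste, collapse = ""))
    out <- c(out, vals)
  }
  out
}

#' Moments embedding of many clouds
#'
#' @param clouds list of clouds.
#' @return Matrix, one 55-feature row per cloud.
#' @export
moments_embed <- function(clouds) {
  t(vapply(clouds, moments_features, numeric(55)))
}

#' Standardize and PCA-reduce a feature matrix
#'
#' Centers and unit-scales every feature (zero-variance features are
#' centered only), projects onto principal components and keeps the first
#' `n_keep`. Principal-component signs are arbitrary; when `sign_anchor`
#' is supplied (a matrix of engineered features with matched rows), each
#' kept PC is flipped if necessary so that it correlates positively with
#' its most defining engineered feature (the one with the largest absolute
#' correlation).
#'
#' @param features samples x features matrix (>= 2 rows).
#' @param n_keep number of PCs to keep (default 20, capped at the rank).
#' @param sign_anchor optional engineered-feature matrix/data.frame.
#' @param standardize center and unit-scale features first (default TRUE).
#' @return List with `scores` (samples x n_kept) and `model` (class
#'   `pca_model`: `rotation`, `center`, `scale`,
#'   `explained_variance_ratios`, `n_kept`, `sign_flips`).
#' @export
pca_reduce <- function(features, n_keep = 20, sign_anchor = NULL,
                       standardize = TRUE) {
  x <- as.matrix(features)
  if (nrow(x) < 2) stop("need at least 2 samples")
  ctr <- colMeans(x)
  scl <- if (standardize) apply(x, 2, sd) else rep(1, ncol(x))
  scl[scl == 0 | !is.finite(scl)] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, `/`)
  p <- prcomp(xs, center = FALSE, scale. = FALSE)
  evr <- p$sdev^2 / sum(p$sdev^2)
  n_kept <- min(n_keep, ncol(p$rotation))
  scores <- p$x[, seq_len(n_kept), drop = FALSE]
  rotation <- p$rotation[, seq_len(n_kept), drop = FALSE]
  flips <- rep(1, n_kept)
  if (!is.null(sign_anchor)) {
    anchor <- as.matrix(sign_anchor)
    if (nrow(anchor) != nrow(x)) stop("sign_anchor rows must match features")
    for (j in seq_len(n_kept)) {
      cors <- suppressWarnings(cor(scores[, j], anchor))
      cors[!is.finite(cors)] <- 0
      best <- which.max(abs(cors))
      if (length(best) && cors[best] < 0) flips[j] <- -1
    }
    scores <- sweep(scores, 2, flips, `*`)
    rotation <- sweep(rotation, 2, flips, `*`)
  }
  model <- structure(list(rotation = rotation, center = ctr, scale = scl,
                          explained_variance_ratios = evr, n_kept = n_kept,
                          sign_flips = flips),
                     class = "pca_model")
  list(scores = scores, model = model)
}

#' Project new feature rows with a fitted PCA model
#'
#' @param model a `pca_model` from [pca_reduce()].
#' @param features new rows with the model's feature dimensionality.
#' @return Score matrix.
#' @export
pca_project <- function(model, features) {
  x <- as.matrix(features)
  if (ncol(x) != length(model$center)) stop("feature dimensionality mismatch")
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, `/`)
  xs %*% model$rotation
}
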