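test_that("density-dependent downsampling obeys the keep-probability rule", {
  cl <- blob_halo_cloud(seed = 1)
  dd0 <- density_dependent_downsample(cl, seed = 1)
  ld <- attr(dd0, "local_density")
  td <- attr(dd0, "target_density")
  sparse_idx <- which(ld < td)
  expect_gt(length(sparse_idx), 0)

  # sparse points (LD < TD) are always retained
  for (s in 1:100) {
    kept <- attr(density_dependent_downsample(cl, seed = s), "kept")
    expect_true(all(sparse_idx %in% kept))
  }

  # a dense blob point is retained with frequency TD / LD
  dense_idx <- which.max(ld)
  p_exp <- td / ld[dense_idx]
  hits <- sum(vapply(1:500, function(s)
    dense_idx %in% attr(density_dependent_downsample(cl, seed = 1000 + s), "kept"),
    logical(1)))
  expect_lt(abs(hits / 500 - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 500))
})

test_that("downsampling caps uniform clouds at max_points", {
  pts <- withr::with_seed(2, matrix(runif(3 * 300000), ncol = 3))
  out <- density_dependent_downsample(point_cloud(pts), seed = 3)
  expect_identical(nrow(out$points), 200000L)
  expect_error(density_dependent_downsample(point_cloud(matrix(0, 1, 3))),
               "at least 2")
})

test_that("cloud condensation returns k-means centers", {
  pts <- withr::with_seed(4, matrix(rnorm(60), 20, 3))
  cl <- point_cloud(pts)
  # k = n: each point is its own cluster (up to order)
  same <- condense_cloud(cl, k = 20, seed = 1)
  expect_equal(same$points[order(same$points[, 1]), ],
               pts[order(pts[, 1]), ], ignore_attr = TRUE)
  # k = 1: the centroid
  one <- condense_cloud(cl, k = 1)
  expect_equal(unname(one$points[1, ]), unname(colMeans(pts)), tolerance = 1e-12)
  # two well-separated blobs, k = 2: centers near the blob means
  blobs <- withr::with_seed(5, rbind(matrix(rnorm(3000, 0, 0.1), 1000, 3),
                                     matrix(rnorm(3000, 10, 0.1), 1000, 3)))
  cc <- condense_cloud(point_cloud(blobs), k = 2, seed = 6)$points
  cc <- cc[order(cc[, 1]), ]
  expect_equal(unname(cc[1, ]), colMeans(blobs[1:1000, ]), tolerance = 0.05)
  expect_equal(unname(cc[2, ]), colMeans(blobs[1001:2000, ]), tolerance = 0.05)
  expect_error(condense_cloud(cl, k = 21), "fewer points")
})

test_that("reference clusters are deterministic and cover the data", {
  # a single repeated-point cell, k = 1: center at the (centered) point
  rep_cl <- point_cloud(matrix(rep(c(1, 2, 3), each = 30), 30, 3))
  refs1 <- fit_reference_clusters(list(rep_cl), k = 1, seed = 1)
  expect_equal(unname(refs1$centers[1, ]), c(0, 0, 0), tolerance = 1e-12)

  ds <- generate_dataset(20, seed = 7, n_points = 300)
  clouds <- lapply(ds$cells, function(x) x$cloud)
  refsA <- fit_reference_clusters(clouds, k = 5, seed = 9)
  refsB <- fit_reference_clusters(clouds, k = 5, seed = 9)
  expect_identical(refsA$centers, refsB$centers)

  # centers stay inside the union of centered cloud bounding boxes
  cen_pts <- do.call(rbind, lapply(clouds, function(cl)
    sweep(cl$points, 2, colMeans(cl$points))))
  rng <- apply(cen_pts, 2, range)
  for (j in 1:3)
    expect_true(all(refsA$centers[, j] >= rng[1, j] &
                    refsA$centers[, j] <= rng[2, j]))
  expect_error(fit_reference_clusters(list(rep_cl), k = 50, seed = 1))
})

test_that("CBE feature rows have the stated geometry", {
  ds <- generate_dataset(3, seed = 10, n_points = 400)
  clouds <- lapply(ds$cells, function(x) x$cloud)
  refs <- fit_reference_clusters(clouds, k = 20, seed = 11)
  row <- cbe_features(clouds[[1]], refs)
  expect_length(row, 60)   # 3k features with k = 20

  # 25 identical points at the origin, one center at (1, 0, 0)
  refs1 <- structure(list(centers = matrix(c(1, 0, 0), 1), k = 1,
                          frame = "raw", sample_ids = "s", seed = 1),
                     class = "reference_clusters")
  cl0 <- point_cloud(matrix(0, 25, 3))
  expect_equal(unname(cbe_features(cl0, refs1, center = FALSE)),
               c(-1, 0, 0))

  # magnitude variant equals the norms of the vector variant
  for (i in 1:3) {
    vec <- cbe_features(clouds[[i]], refs, variant = "vectors")
    mag <- cbe_features(clouds[[i]], refs, variant = "magnitudes")
    expect_equal(unname(mag),
                 unname(sqrt(colSums(matrix(vec, 3)^2))), tolerance = 1e-12)
  }
  expect_error(cbe_features(point_cloud(matrix(0, 5, 3)), refs),
               "smaller than n_neighbors")
  pd <- cfor_pipeline(clouds[[1]])
  expect_error(cbe_features(pd, refs), "does not match")
})

test_that("PCA reduction is standardized, ordered, and sign-anchored", {
  x <- withr::with_seed(12, matrix(rnorm(600), 60, 10))
  red <- pca_reduce(x, n_keep = 5)
  evr <- red$model$explained_variance_ratios
  expect_true(all(diff(evr) <= 1e-12))
  expect_lte(sum(evr), 1 + 1e-9)

  # rank-1 structure: PC1 explains nearly everything
  u <- withr::with_seed(13, rnorm(60)); v <- withr::with_seed(14, rnorm(10))
  r1 <- pca_reduce(outer(u, v) + 1e-4 * x, n_keep = 3, standardize = FALSE)
  expect_gte(r1$model$explained_variance_ratios[1], 0.999)

  # sign anchoring: every kept PC correlates positively with its most
  # defining anchor feature
  anchor <- x[, 1:3] + withr::with_seed(15, matrix(rnorm(180, 0, 0.1), 60, 3))
  red2 <- pca_reduce(x, n_keep = 4, sign_anchor = anchor)
  for (j in 1:4) {
    cors <- cor(red2$scores[, j], anchor)
    expect_gte(cors[which.max(abs(cors))], 0)
  }

  # projection of the training rows reproduces the scores
  expect_equal(pca_project(red2$model, x), red2$scores, tolerance = 1e-9)
  expect_error(pca_project(red2$model, x[, 1:5]), "mismatch")
})

test_that("moments embedding matches Gaussian closed forms and parities", {
  pts <- withr::with_seed(16, matrix(rnorm(3e5), 1e5, 3))
  mf <- moments_features(point_cloud(pts))
  expect_length(mf, 55)
  expect_identical(sum(startsWith(names(mf), "rM1")), 3L)
  expect_identical(sum(startsWith(names(mf), "cM2")), 6L)
  expect_identical(sum(startsWith(names(mf), "nM3")), 10L)
  expect_identical(sum(startsWith(names(mf), "nM4")), 15L)
  expect_identical(sum(startsWith(names(mf), "nM5")), 21L)

  expect_equal(unname(mf[c("cM2_200", "cM2_020", "cM2_002")]), rep(1, 3),
               tolerance = 0.02)
  expect_equal(unname(mf[c("nM4_400", "nM4_040", "nM4_004")]), rep(3, 3),
               tolerance = 0.05)
  expect_lt(max(abs(mf[startsWith(names(mf), "nM3")])), 0.05)

  # mirroring along z flips exactly the odd-z-index normalized moments
  mirrored <- pts; mirrored[, 1] <- -mirrored[, 1]
  mm <- moments_features(point_cloud(mirrored))
  norm_names <- names(mf)[grepl("^nM", names(mf))]
  iz <- as.integer(substr(sub("^nM[345]_", "", norm_names), 1, 1))
  odd <- norm_names[iz %% 2 == 1]
  even <- norm_names[iz %% 2 == 0]
  expect_equal(unname(mm[odd]), unname(-mf[odd]), tolerance = 1e-12)
  expect_equal(unname(mm[even]), unname(mf[even]), tolerance = 1e-12)

  # permutation invariance (up to summation order)
  perm <- withr::with_seed(17, sample.int(nrow(pts)))
  expect_equal(moments_features(point_cloud(pts[perm, ])), mf,
               tolerance = 1e-10)

  flat <- matrix(c(1, 2, 3, 1, 5, 3), 2, 3, byrow = TRUE)
  expect_error(moments_features(point_cloud(flat)), "zero standard deviation")
})
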