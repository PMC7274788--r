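test_that("TFOR recovers the principal axes of an ellipsoidal tissue", {
  dims <- c(40, 80, 160)
  m <- ellipsoid_mask(dims, c(10, 20, 60))   # semi-axes 5, 10, 30 um at 0.5 um
  tf <- fit_tfor(m, spacing = c(0.5, 0.5, 0.5), seed = 1)
  # axis 1 should align with x (longest), axis 3 with z (shortest)
  ang1 <- acos(min(1, abs(tf$rotation[3, 1]))) * 180 / pi
  ang3 <- acos(min(1, abs(tf$rotation[1, 3]))) * 180 / pi
  expect_lt(ang1, 2)
  expect_lt(ang3, 2)
  expect_equal(crossprod(tf$rotation), diag(3), tolerance = 1e-9)

  # frontal-most point at the origin along axis 1
  cl <- sample_landmarks(intensity_volume(array(as.numeric(m), dims),
                                          c(0.5, 0.5, 0.5)), 3000, seed = 1)
  sc <- apply_tfor(cl, tf)
  expect_equal(min(sc$points[, 1]), 0, tolerance = 1e-9)
})

test_that("TFOR is invariant to the acquisition angle", {
  dims <- c(40, 120, 120)
  # an asymmetric tissue: ellipsoid with a bump offset toward one end
  base <- ellipsoid_mask(dims, c(10, 18, 45))
  bump <- ellipsoid_mask(dims, c(8, 30, 14))
  shift <- round(dims[3] * 0.28)
  bump_s <- array(FALSE, dims)
  bump_s[, , (1 + shift):dims[3]] <- bump[, , 1:(dims[3] - shift)]
  m0 <- base | bump_s

  rot <- ellipsoid_mask(dims, c(10, 18, 45), angle = 15 * pi / 180)
  bump_r <- ellipsoid_mask(dims, c(8, 30, 14), angle = 15 * pi / 180)
  # rotate the bump's offset too
  sy <- round(sin(15 * pi / 180) * shift); sx <- round(cos(15 * pi / 180) * shift)
  bump_rs <- array(FALSE, dims)
  bump_rs[, (1 + sy):dims[2], (1 + sx):dims[3]] <-
    bump_r[, 1:(dims[2] - sy), 1:(dims[3] - sx)]
  m15 <- rot | bump_rs

  sp <- c(0.5, 0.5, 0.5)
  tf0 <- fit_tfor(m0, spacing = sp, seed = 2)
  tf15 <- fit_tfor(m15, spacing = sp, seed = 2)
  # the same anatomical landmark (bump tip, at max axis-1 coordinate) must
  # land at a consistent TFOR position
  cl0 <- apply_tfor(sample_landmarks(intensity_volume(array(as.numeric(m0), dims), sp),
                                     3000, seed = 5), tf0)
  cl15 <- apply_tfor(sample_landmarks(intensity_volume(array(as.numeric(m15), dims), sp),
                                      3000, seed = 5), tf15)
  q0 <- apply(cl0$points, 2, quantile, c(0.05, 0.5, 0.95))
  q15 <- apply(cl15$points, 2, quantile, c(0.05, 0.5, 0.95))
  expect_equal(q0, q15, tolerance = 0.6)   # um, Monte-Carlo + voxelization
})

test_that("applying TFOR is rigid and frame-checked", {
  pts <- matrix(rnorm(300), 100, 3)
  cl <- point_cloud(pts)
  ident <- structure(list(rotation = diag(3), center = c(0, 0, 0),
                          translation = c(0, 0, 0), axis_signs = c(1, 1, 1),
                          determinant = 1, sample_id = NA),
                     class = "tfor_transform")
  expect_equal(apply_tfor(cl, ident)$points, cl$points, ignore_attr = TRUE)

  m <- ellipsoid_mask(c(30, 40, 60), c(8, 12, 20))
  tf <- fit_tfor(m, spacing = c(1, 1, 1), seed = 3)
  out <- apply_tfor(cl, tf)
  expect_equal(as.numeric(dist(out$points)), as.numeric(dist(cl$points)),
               tolerance = 1e-9)
  expect_identical(out$frame, "tfor")
  expect_error(apply_tfor(out, tf), "raw frame")
})

test_that("mirrored tissues keep a consistent front-rear orientation", {
  dims <- c(30, 60, 100)
  base <- ellipsoid_mask(dims, c(8, 15, 35))
  bump <- ellipsoid_mask(dims, c(7, 22, 12))
  shift <- 26
  bs <- array(FALSE, dims); bs[, , (1 + shift):dims[3]] <- bump[, , 1:(dims[3] - shift)]
  m <- base | bs
  m_mir <- m[, , dims[3]:1]   # mirror along x
  tf <- fit_tfor(m, spacing = c(1, 1, 1), seed = 4)
  tfm <- fit_tfor(m_mir, spacing = c(1, 1, 1), seed = 4)
  # the bump sits at the rear (positive axis 1) in both cases: axis-1
  # skewness convention prevents a 180-degree flip
  sk <- function(mask, tfx) {
    cl <- apply_tfor(sample_landmarks(intensity_volume(array(as.numeric(mask), dims),
                                                       c(1, 1, 1)), 3000, seed = 6), tfx)
    cloudmorph:::skewness(cl$points[, 1])
  }
  expect_gt(sk(m, tf), 0)
  expect_gt(sk(m_mir, tfm), 0)
})

test_that("CFOR normalization: unit magnitude sum, scale invariance, 2-point case", {
  pts <- matrix(rnorm(600), 200, 3)
  cl <- point_cloud(pts)
  out <- cfor_normalize(cl)
  cen <- sweep(out$points, 2, colMeans(out$points))
  expect_equal(sum(sqrt(rowSums(cen^2))), 1, tolerance = 1e-12)

  out2 <- cfor_normalize(point_cloud(pts * 37.5))
  expect_equal(out$points, out2$points, tolerance = 1e-12)

  # two points at distance d: each ends at magnitude 1/2 from the centroid
  two <- point_cloud(rbind(c(0, 0, 0), c(0, 0, 8)))
  nt <- cfor_normalize(two)$points
  expect_equal(unname(nt[, 3]), c(-0.5, 0.5), tolerance = 1e-12)

  expect_error(cfor_normalize(point_cloud(matrix(1, 5, 3))), "identical")
})

test_that("pairwise-distance representation is invariant and percentile-exact", {
  pts <- matrix(rnorm(450), 150, 3)
  pd1 <- pairwise_distance_representation(point_cloud(pts))$rep
  # rigid motion + mirror (no scaling): representation is bit-stable
  R <- withr::with_seed(8, qr.Q(qr(matrix(rnorm(9), 3))))
  R[, 1] <- -R[, 1]
  pd2 <- pairwise_distance_representation(point_cloud(sweep(pts %*% R, 2, c(3, -4, 5), `+`)))$rep
  expect_equal(pd1, pd2, tolerance = 1e-9)

  # 2-point cloud: every row is (d, d, d)
  pd3 <- pairwise_distance_representation(point_cloud(rbind(c(0, 0, 0), c(0, 3, 4))))$rep
  expect_equal(unname(pd3), matrix(5, 2, 3), ignore_attr = TRUE)

  # brute-force percentile oracle for the 3-point cloud
  tri <- point_cloud(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0)))
  pd4 <- pairwise_distance_representation(tri)$rep
  expect_equal(unname(pd4[1, ]), unname(quantile(c(3, 4), c(0.1, 0.5, 0.9), type = 7)))

  # rows are column-monotone
  expect_true(all(pd1[, 1] <= pd1[, 2] & pd1[, 2] <= pd1[, 3]))
  expect_error(pairwise_distance_representation(point_cloud(matrix(0, 1, 3))),
               "at least 2")
})

test_that("full CFOR pipeline is similarity-invariant", {
  p <- sample_generator_params(seed = 12)
  cl <- generate_cell_cloud(p, n_points = 500, seed = 13)$cloud
  ref <- cfor_pipeline(cl)$rep
  for (s in 1:5) {
    moved <- random_similarity(cl$points, seed = 100 + s)
    expect_lt(max(abs(cfor_pipeline(point_cloud(moved))$rep - ref)), 1e-9)
  }
})

test_that("engineered features match analytic solids", {
  # digital ball of radius 10: sphericity within 5% of 1
  ball <- digital_ball(10)
  lv <- label_volume(array(as.integer(ball), dim(ball)), c(1, 1, 1))
  ef <- engineered_features(lv)
  expect_gt(ef$sphericity, 0.95)
  expect_lte(ef$sphericity, 1)
  expect_equal(ef$volume_um3, sum(ball), tolerance = 1e-12)
  expect_equal(ef$surface_area_um2, 4 * pi * 100, tolerance = 0.05)

  # axis-aligned box 20 x 10 x 5 um: extents match exactly
  bx <- array(0L, c(10, 20, 40)); bx[3:7, 6:15, 11:30] <- 1L
  ef2 <- engineered_features(label_volume(bx, c(1, 1, 1)))
  expect_equal(sort(c(ef2$extent_ax1_um, ef2$extent_ax2_um, ef2$extent_ax3_um),
                    decreasing = TRUE), c(20, 10, 5))

  # 1000 voxels at 0.1 x 0.1 x 0.2 um -> 2.0 um^3
  v3 <- array(0L, c(10, 10, 10)); v3[1:1000] <- 1L
  ef3 <- engineered_features(label_volume(v3, c(0.2, 0.1, 0.1)))
  expect_equal(ef3$volume_um3, 2.0, tolerance = 1e-12)

  expect_error(engineered_features(label_volume(array(0L, c(4, 4, 4)),
                                                c(1, 1, 1))),
               "no cells")
})
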