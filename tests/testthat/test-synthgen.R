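test_that("generator parameters: count, determinism, and distribution means", {
  p <- sample_generator_params(seed = 0)
  v <- as.numeric(p)
  expect_length(v, 17)
  expect_named(v, param_names())
  # exactly 1 size and 2 rotation parameters among the 17
  expect_length(setdiff(param_names(), cloudmorph:::shape_param_names()), 3)

  expect_identical(as.numeric(sample_generator_params(seed = 0)), v)

  # Monte-Carlo check of the configured normal distributions
  hyper <- default_generator_hyper()
  draws <- withr::with_seed(42, {
    t(replicate(10000, as.numeric(sample_generator_params(hyper))))
  })
  for (nm in c("spine_height", "spine_curve_y", "surf_mu_2")) {
    h <- hyper[[nm]]
    se <- h$sd / sqrt(nrow(draws))
    expect_lt(abs(mean(draws[, nm]) - h$mean), 3 * se)
  }
  # uniform parameters stay within their bounds
  for (nm in c("spine_offset_distance", "surf_sigma_1", "size_scale")) {
    h <- hyper[[nm]]
    expect_true(all(draws[, nm] >= h$min & draws[, nm] <= h$max))
  }
})

test_that("invalid hyperparameters are configuration errors", {
  hyper <- default_generator_hyper()
  hyper$spine_height$sd <- -1
  expect_error(sample_generator_params(hyper), "sd must be > 0")
  hyper <- default_generator_hyper()
  hyper$size_scale$min <- 2; hyper$size_scale$max <- 1
  expect_error(sample_generator_params(hyper), "min > max")
})

test_that("logit-normal distance function vanishes at the ends, positive inside", {
  eps <- .Machine$double.eps
  for (mu in c(-0.5, 0, 1)) for (sg in c(0.6, 1)) {
    expect_equal(cloudmorph:::logitnormal_density(c(0, 1), mu, sg), c(0, 0))
    expect_lt(cloudmorph:::logitnormal_density(eps, mu, sg), 1e-10)
    tt <- seq(0.01, 0.99, length.out = 25)
    expect_true(all(cloudmorph:::logitnormal_density(tt, mu, sg) > 0))
  }
})

test_that("cell cloud generation: size linearity, symmetry, radius oracle", {
  p <- sample_generator_params(seed = 3)
  c1 <- generate_cell_cloud(p, seed = 9)
  expect_equal(nrow(c1$cloud$points), 2000)

  v <- as.numeric(p); v["size_scale"] <- v["size_scale"] * 2
  c2 <- generate_cell_cloud(cloudmorph:::params_from_vector(v), seed = 9)
  expect_equal(c2$cloud$points, c1$cloud$points * 2, tolerance = 1e-12)

  # zero offset, identical symmetric logit-normals, no curvature -> cloud
  # statistics symmetric about the z axis
  ps <- generator_params(1, 0, 0, 0, 0, surf_mu = c(0, 0, 0),
                         surf_sigma = c(0.8, 0.8, 0.8),
                         surf_scale = c(0.1, 0.1, 0.1),
                         size_scale = 1, rot_z = 0, rot_y = 0)
  cs <- generate_cell_cloud(ps, n_points = 20000, seed = 5)
  lat <- colMeans(cs$cloud$points)[c("y", "x")]
  expect_lt(max(abs(lat)), 0.005)

  # radius at a defined angle equals scale * logit-normal density (direct
  # evaluation of the density formula as the oracle)
  t0 <- c(0.3, 0.62)
  r <- cloudmorph:::surface_radius(t0, rep(2 * pi / 3, 2), p)
  mu <- p$surf_mu[2]; sg <- p$surf_sigma[2]
  oracle <- p$surf_scale[2] *
    exp(-(log(t0 / (1 - t0)) - mu)^2 / (2 * sg^2)) /
    (sg * sqrt(2 * pi) * t0 * (1 - t0))
  expect_equal(as.numeric(r), oracle, tolerance = 1e-12)
})

test_that("dataset generation is reproducible with a 17-column table", {
  ds <- generate_dataset(5, seed = 11, n_points = 200)
  expect_length(ds$cells, 5)
  expect_identical(dim(ds$params), c(5L, 17L))
  expect_named(ds$params, param_names())
  ds2 <- generate_dataset(5, seed = 11, n_points = 200)
  expect_identical(ds$params, ds2$params)
  expect_error(generate_dataset(0), "n must be >= 1")
})

test_that("synthetic membrane volumes carry ground truth and spacing", {
  tis <- generate_membrane_volume(1, shape = c(24, 24, 24), seed = 2)
  expect_identical(sort(setdiff(unique(as.integer(tis$truth$voxels)), 0L)), 1L)
  # membrane voxels brighter than interior
  mem <- tis$image$voxels > 0
  expect_gt(mean(tis$image$voxels[mem]), mean(tis$image$voxels[!mem]))

  # anisotropic spacing propagates to micron-scaled landmark clouds
  sp <- c(0.225, 0.099, 0.099)
  v <- array(0, c(3, 3, 3)); v[3, 2, 2] <- 1
  pc <- sample_landmarks(intensity_volume(v, sp), 5, seed = 1)
  expect_equal(unname(pc$points[1, ]), c(2 * 0.225, 1 * 0.099, 1 * 0.099))

  expect_error(generate_membrane_volume(50, shape = c(6, 6, 6)),
               "infeasible packing")
})

test_that("paired channels follow the planted link", {
  ref <- matrix(rnorm(200), 50, 4)
  pair <- generate_paired_channels(ref, link = identity, noise_sd = 0)
  expect_identical(pair$target, ref)
  pair2 <- generate_paired_channels(ref, link = function(x) x[, 1:2] * 2,
                                    noise_sd = 0.1, seed = 3)
  expect_identical(dim(pair2$target), c(50L, 2L))
  expect_error(generate_paired_channels(ref, link = function(x) x[1:10, ]),
               "one target row per reference row")
})
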