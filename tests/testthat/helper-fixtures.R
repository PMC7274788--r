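# shared fixture builders (all generated in code; no stored data)

# sparse blobby 3D field emulating a fluorescence channel: smoothed white
# noise thresholded at the q-quantile (default 5% support, nucleus-like)
sparse_field <- function(seed, q = 0.95, d = c(32, 48, 48), amplitude = 200) {
  withr::with_seed(seed, {
    v <- array(rnorm(prod(d)), d)
    s <- cloudmorph:::.cpp_gaussian3d(as.numeric(v), d, c(2, 2, 2))
    s <- pmax(s - quantile(s, q), 0)
    s <- s / max(s) * amplitude
    dim(s) <- d
    s
  })
}

# digital ball mask of radius r voxels in a (2r+11)^3 box
digital_ball <- function(r = 10) {
  n <- 2 * r + 11
  c0 <- (n + 1) / 2
  zz <- (seq_len(n) - c0)
  m <- outer(outer(zz^2, zz^2, `+`), zz^2, `+`) <= r^2
  dim(m) <- c(n, n, n)
  m
}

# axis-aligned ellipsoid mask with voxel semi-axes (a, b, c) along (z, y, x),
# optionally rotated by `angle` radians in the (y, x) plane
ellipsoid_mask <- function(dims, semi_axes, angle = 0) {
  c0 <- (dims + 1) / 2
  idx <- arrayInd(seq_len(prod(dims)), dims)
  z <- idx[, 1] - c0[1]; y <- idx[, 2] - c0[2]; x <- idx[, 3] - c0[3]
  if (angle != 0) {
    y2 <- cos(angle) * y - sin(angle) * x
    x2 <- sin(angle) * y + cos(angle) * x
    y <- y2; x <- x2
  }
  m <- (z / semi_axes[1])^2 + (y / semi_axes[2])^2 + (x / semi_axes[3])^2 <= 1
  dim(m) <- dims
  m
}

# random rigid motion + optional reflection + uniform scaling of a cloud
random_similarity <- function(pts, seed, reflect = NA) {
  withr::with_seed(seed, {
    R <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (is.na(reflect)) reflect <- runif(1) < 0.5
    if (reflect) R[, 1] <- -R[, 1]
    s <- runif(1, 0.2, 5)
    t <- rnorm(3, 0, 10)
    sweep(pts %*% R * s, 2, t, `+`)
  })
}

# dense blob + sparse halo cloud for density-downsampling checks; the halo
# fraction stays below the target-density percentile so that isolated halo
# points sit strictly below TD
blob_halo_cloud <- function(n_blob = 400, n_halo = 8, seed = 1) {
  withr::with_seed(seed, {
    blob <- matrix(rnorm(3 * n_blob, 0, 0.05), n_blob, 3)
    halo <- matrix(rnorm(3 * n_halo, 0, 2), n_halo, 3)
    point_cloud(rbind(blob, halo))
  })
}

# three well-separated shape families in feature space
three_class_features <- function(n_per_class = 60, dim = 10, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per_class * dim, 0), ncol = dim),
               matrix(rnorm(n_per_class * dim, 3), ncol = dim),
               matrix(rnorm(n_per_class * dim, -3), ncol = dim))
    list(x = x, y = rep(c("a", "b", "c"), each = n_per_class))
  })
}

# small grid search for archetype classifiers in tests (keeps runtime low
# without changing the machinery under test)
fast_arch_grid <- list(pca_options = NA, cost_options = c(1, 10),
                       gamma_factor_options = 1)
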