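#' Generator parameters for synthetic cell-like point clouds
#'
#' A synthetic cell is described by exactly 17 scalar parameters:
#' \itemize{
#'   \item spine (5): `spine_height` (z extent), `spine_offset_distance`
#'     and `spine_offset_angle` (lateral displacement of the spine's end
#'     point relative to its start), and one quadratic curvature coefficient
#'     per lateral axis (`spine_curve_y`, `spine_curve_x`; the spine's end
#'     points are pinned, so the quadratic bump `c * t * (1 - t)` adds no
#'     further end-point freedom).
#'   \item surface (9): three logit-normal distance functions, one per
#'     surface angle (0, 120, 240 degrees around the spine), each with a
#'     location `mu`, a width `sigma > 0` and a positive multiplicative
#'     `scale`.
#'   \item size (1): `size_scale`, a uniform multiplier applied after
#'     centering. Affects only size, never shape.
#'   \item rotation (2): `rot_z`, `rot_y`, extrinsic rotations about the
#'     z then the y axis. Affect only orientation, never shape.
#' }
#'
#' @param spine_height,spine_offset_distance,spine_offset_angle,spine_curve_y,spine_curve_x
#'   spine parameters (see above); `spine_offset_angle` in radians.
#' @param surf_mu,surf_sigma,surf_scale length-3 numeric vectors: logit-normal
#'   location, width (> 0) and scale (> 0) at the three surface angles.
#' @param size_scale positive scalar size multiplier.
#' @param rot_z,rot_y rotation angles in radians.
#' @return An object of class `generator_params`. `as.numeric()` yields the
#'   flat 17-vector; `param_names()` gives the canonical column order.
#' @export
generator_params <- function(spine_height, spine_offset_distance,
                             spine_offset_angle, spine_curve_y, spine_curve_x,
                             surf_mu, surf_sigma, surf_scale,
                             size_scale, rot_z, rot_y) {
  stopifnot(length(surf_mu) == 3, length(surf_sigma) == 3, length(surf_scale) == 3)
  if (any(surf_sigma <= 0)) stop("logit-normal sigma must be > 0")
  if (any(surf_scale <= 0)) stop("surface scales must be > 0")
  if (size_scale <= 0) stop("size_scale must be > 0")
  structure(list(
    spine_height = spine_height,
    spine_offset_distance = spine_offset_distance,
    spine_offset_angle = spine_offset_angle,
    spine_curve = c(y = spine_curve_y, x = spine_curve_x),
    surf_mu = as.numeric(surf_mu),
    surf_sigma = as.numeric(surf_sigma),
    surf_scale = as.numeric(surf_scale),
    size_scale = size_scale,
    rotation = c(z = rot_z, y = rot_y)
  ), class = "generator_params")
}

#' @rdname generator_params
#' @export
param_names <- function() {
  c("spine_height", "spine_offset_distance", "spine_offset_angle",
    "spine_curve_y", "spine_curve_x",
    "surf_mu_1", "surf_mu_2", "surf_mu_3",
    "surf_sigma_1", "surf_sigma_2", "surf_sigma_3",
    "surf_scale_1", "surf_scale_2", "surf_scale_3",
    "size_scale", "rot_z", "rot_y")
}

# names of the 14 parameters that change shape (not size, not rotation)
shape_param_names <- function() setdiff(param_names(), c("size_scale", "rot_z", "rot_y"))

#' @export
as.double.generator_params <- function(x, ...) {
  setNames(c(x$spine_height, x$spine_offset_distance, x$spine_offset_angle,
             x$spine_curve[["y"]], x$spine_curve[["x"]],
             x$surf_mu, x$surf_sigma, x$surf_scale,
             x$size_scale, x$rotation[["z"]], x$rotation[["y"]]),
           param_names())
}

params_from_vector <- function(v) {
  v <- setNames(as.numeric(v), param_names())
  g <- function(nm) unname(v[nm])
  generator_params(g("spine_height"), g("spine_offset_distance"),
                   g("spine_offset_angle"), g("spine_curve_y"), g("spine_curve_x"),
                   g(c("surf_mu_1", "surf_mu_2", "surf_mu_3")),
                   g(c("surf_sigma_1", "surf_sigma_2", "surf_sigma_3")),
                   g(c("surf_scale_1", "surf_scale_2", "surf_scale_3")),
                   g("size_scale"), g("rot_z"), g("rot_y"))
}

#' Default hyperparameter distributions of the generator
#'
#' Each of the 17 parameters is drawn from either a normal or a uniform
#' distribution. The defaults were chosen once to yield a varied population
#' of plausible, non-self-intersecting cell shapes (internal units: the
#' spine height is of order 1 and surface radii of order 0.1-0.3). Rotation
#' angles default to Uniform(-pi/3, pi/3): a full-circle range would make
#' orientation non-identifiable (2*pi wrap-around) in parameter-recovery
#' experiments.
#'
#' @return Named list; each element is `list(dist = "normal", mean, sd)` or
#'   `list(dist = "uniform", min, max)`.
#' @export
default_generator_hyper <- function() {
  n <- function(mean, sd) list(dist = "normal", mean = mean, sd = sd)
  u <- function(min, max) list(dist = "uniform", min = min, max = max)
  list(
    spine_height = n(1, 0.1),
    spine_offset_distance = u(0, 0.3),
    spine_offset_angle = u(0, 2 * pi),
    spine_curve_y = n(0, 0.08),
    spine_curve_x = n(0, 0.08),
    surf_mu_1 = n(0, 0.25), surf_mu_2 = n(0, 0.25), surf_mu_3 = n(0, 0.25),
    surf_sigma_1 = u(0.6, 1.1), surf_sigma_2 = u(0.6, 1.1), surf_sigma_3 = u(0.6, 1.1),
    surf_scale_1 = u(0.06, 0.14), surf_scale_2 = u(0.06, 0.14), surf_scale_3 = u(0.06, 0.14),
    size_scale = u(0.6, 1.4),
    rot_z = u(-pi / 3, pi / 3),
    rot_y = u(-pi / 3, pi / 3)
  )
}

check_hyper <- function(hyper) {
  if (!setequal(names(hyper), param_names()))
    stop("hyper must define a distribution for each of the 17 parameters")
  for (nm in names(hyper)) {
    h <- hyper[[nm]]
    if (h$dist == "normal") {
      if (!is.finite(h$sd) || h$sd <= 0)
        stop("invalid hyper for ", nm, ": sd must be > 0")
    } else if (h$dist == "uniform") {
      if (h$min > h$max) stop("invalid hyper for ", nm, ": min > max")
    } else stop("unknown distribution '", h$dist, "' for ", nm)
  }
  invisible(hyper)
}

#' Draw one set of generator parameters
#'
#' @param hyper hyperparameter distributions, see [default_generator_hyper()].
#' @param seed optional integer seed; when given, the draw is a pure function
#'   of `(hyper, seed)` and the caller's RNG state is untouched.
#' @return A [generator_params()] object (17 scalars).
#' @examples
#' p <- sample_generator_params(seed = 1)
#' length(as.numeric(p))
#' @export
sample_generator_params <- function(hyper = default_generator_hyper(), seed = NULL) {
  check_hyper(hyper)
  draw <- function() {
    v <- vapply(param_names(), function(nm) {
      h <- hyper[[nm]]
      if (h$dist == "normal") rnorm(1, h$mean, h$sd) else runif(1, h$min, h$max)
    }, numeric(1))
    params_from_vector(v)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# logit-normal density on (0,1); the generator's radial distance function.
# d(0+) = d(1-) = 0 and d > 0 inside; the normalization constant is absorbed
# by the surface scales.
logitnormal_density <- function(t, mu, sigma) {
  out <- numeric(length(t))
  ok <- t > 0 & t < 1
  tt <- t[ok]
  out[ok] <- exp(-(log(tt / (1 - tt)) - mu)^2 / (2 * sigma^2)) /
    (sigma * sqrt(2 * pi) * tt * (1 - tt))
  out
}

# radius at relative height t and azimuth phi: linear interpolation (in
# angle, periodic) between the logit-normal values at the three defined
# surface angles 0, 120, 240 degrees.
surface_radius <- function(t, phi, params) {
  angles <- c(0, 2 * pi / 3, 4 * pi / 3)
  vals <- sapply(1:3, function(a)
    params$surf_scale[a] * logitnormal_density(t, params$surf_mu[a], params$surf_sigma[a]))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
  step <- 2 * pi / 3
  phi <- phi %% (2 * pi)
  lo <- floor(phi / step)            # 0, 1, 2
  w <- (phi - lo * step) / step
  hi <- (lo + 1) %% 3
  vals[cbind(seq_along(t), lo + 1)] * (1 - w) + vals[cbind(seq_along(t), hi + 1)] * w
}

rot_matrix_zy <- function(alpha, beta) {
  # coordinates ordered (z, y, x); extrinsic rotation about the z axis by
  # alpha (mixing y, x) followed by rotation about the y axis by beta
  # (mixing z, x)
  Rz <- rbind(c(1, 0, 0),
              c(0, cos(alpha), -sin(alpha)),
              c(0, sin(alpha), cos(alpha)))
  Ry <- rbind(c(cos(beta), 0, -sin(beta)),
              c(0, 1, 0),
              c(sin(beta), 0, cos(beta)))
  Ry %*% Rz
}

#' Generate one synthetic cell-like point cloud
#'
#' Four stages: (1) a spine running along z with a laterally offset, curved
#' connecting line; (2) a surface defined by three scaled logit-normal
#' spine-to-surface distance functions at azimuths 0/120/240 degrees;
#' (3) sampling of `n_points` surface points with z-position and azimuth
#' drawn uniformly and the radius obtained by periodic linear interpolation
#' between the two adjacent logit-normals; (4) centering on the centroid,
#' size scaling, and rotation by the two rotation angles.
#'
#' The random draws depend only on `(seed, n_points)`, never on the
#' parameter values, so clouds generated from the same seed correspond
#' point-by-point across parameter changes.
#'
#' @param params a [generator_params()] object.
#' @param n_points number of surface points (default 2000).
#' @param seed optional integer seed.
#' @return A list of class `synthetic_cell` with elements `cloud`
#'   ([point_cloud()], frame "raw"), `params` and `seed`.
#' @examples
#' cell <- generate_cell_cloud(sample_generator_params(seed = 1), seed = 2)
#' nrow(cell$cloud$points)
#' @export
generate_cell_cloud <- function(params, n_points = 2000, seed = NULL) {
  stopifnot(inherits(params, "generator_params"))
  gen <- function() {
    t <- runif(n_points)
    phi <- runif(n_points, 0, 2 * pi)
    h <- params$spine_height
    doff <- params$spine_offset_distance
    aoff <- params$spine_offset_angle
    # spine: endpoints (0,0,0) and (h, doff*cos, doff*sin), quadratic bump
    # pinned at both endpoints
    spine_y <- t * doff * cos(aoff) + params$spine_curve[["y"]] * t * (1 - t)
    spine_x <- t * doff * sin(aoff) + params$spine_curve[["x"]] * t * (1 - t)
    r <- surface_radius(t, phi, params)
    pts <- cbind(z = t * h,
                 y = spine_y + r * cos(phi),
                 x = spine_x + r * sin(phi))
    pts <- sweep(pts, 2, colMeans(pts))      # center on centroid
    pts <- pts * params$size_scale
    pts <- pts %*% t(rot_matrix_zy(params$rotation[["z"]], params$rotation[["y"]]))
    colnames(pts) <- c("z", "y", "x")
    pts
  }
  pts <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  structure(list(cloud = point_cloud(pts, frame = "raw"),
                 params = params, seed = seed),
            class = "synthetic_cell")
}

#' Generate a dataset of synthetic cells with a parameter table
#'
#' @param n number of cells (>= 1).
#' @param hyper hyperparameter distributions, see [default_generator_hyper()].
#' @param n_points points per cloud.
#' @param seed integer seed; the whole dataset is reproducible from it.
#' @return List with `cells` (list of `synthetic_cell`) and `params`
#'   (data.frame, n rows x 17 columns named [param_names()]).
#' @export
generate_dataset <- function(n, hyper = default_generator_hyper(),
                             n_points = 2000, seed = 1) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  check_hyper(hyper)
  withr::with_seed(seed, {
    cells <- vector("list", n)
    tab <- matrix(NA_real_, n, 17, dimnames = list(NULL, param_names()))
    for (i in seq_len(n)) {
      p <- sample_generator_params(hyper)       # uses the stream's RNG
      cells[[i]] <- generate_cell_cloud(p, n_points = n_points)
      cells[[i]]$cloud$cell_id <- i
      # each synthetic cell is its own acquisition: downstream
      # reference-cluster fitting draws its representative subset at the
      # cell level
      cells[[i]]$cloud$sample_id <- paste0("cell", i)
      tab[i, ] <- as.numeric(p)
    }
    list(cells = cells, params = as.data.frame(tab))
  })
}

#' Generate a synthetic membrane-labeled tissue volume with ground truth
#'
#' Builds a Voronoi-like partition of an ellipsoidal tissue region around
#' well-spread seed points (greedy farthest-point selection of perturbed
#' random candidates), then paints the inter-cell and outer boundaries as a
#' bright membrane shell of configurable thickness. The ground-truth label
#' volume assigns every tissue voxel (including membrane voxels) to its
#' cell.
#'
#' @param n_cells number of cells to pack.
#' @param shape volume dimensions c(nz, ny, nx) in voxels. The default
#'   (NULL) scales with `n_cells` so that cells are ~35-40 voxels across,
#'   large enough to survive the segmentation pipeline's fixed smoothing
#'   scale and minimum component size.
#' @param spacing voxel spacing (z, y, x) in microns.
#' @param noise_sd standard deviation of additive Gaussian intensity noise
#'   (8-bit scale; 0 = noise-free).
#' @param membrane_intensity intensity painted on membrane voxels.
#' @param shell_thickness membrane half-thickness in voxels (the boundary is
#'   dilated this many times in 6-connectivity; default 1 gives ~2-voxel
#'   walls).
#' @param secondary `"none"`, `"random"` (per-cell uniform intensity) or
#'   `"gradient"` (intensity increasing along x), for paired-channel tests.
#' @param seed integer seed.
#' @return A list of class `synthetic_tissue`: `image` ([intensity_volume()]),
#'   `truth` ([label_volume()]), `secondary` (or NULL), `seeds_um` (cell seed
#'   coordinates).
#' @export
generate_membrane_volume <- function(n_cells, shape = NULL,
                                     spacing = c(0.225, 0.099, 0.099),
                                     noise_sd = 0, membrane_intensity = 255,
                                     shell_thickness = 1,
                                     secondary = c("none", "random", "gradient"),
                                     seed = 1) {
  secondary <- match.arg(secondary)
  stopifnot(n_cells >= 1)
  if (is.null(shape)) {
    s <- (n_cells * 140000)^(1 / 3)
    shape <- round(c(0.7, 1.075, 1.075) * s)
  }
  stopifnot(length(shape) == 3)
  shape <- as.integer(shape)
  withr::with_seed(seed, {
    nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
    # ellipsoidal tissue mask with a small margin
    zc <- (seq_len(nz) - (nz + 1) / 2) / (nz / 2 - 1.5)
    yc <- (seq_len(ny) - (ny + 1) / 2) / (ny / 2 - 1.5)
    xc <- (seq_len(nx) - (nx + 1) / 2) / (nx / 2 - 1.5)
    mask <- outer(outer(zc^2, yc^2, `+`), xc^2, `+`) <= 1
    dim(mask) <- shape
    inside <- which(mask)
    if (length(inside) < n_cells * 200)
      stop("infeasible packing: volume too small for ", n_cells, " cells")
    # evenly spread interior seeds: k-means centers of random tissue voxels.
    # the partition is computed in voxel space so cells are well-resolved
    # in every axis; with anisotropic spacing this yields columnar cells in
    # physical units, as in real epithelia.
    cand_idx <- sample(inside, min(4000L, length(inside)))
    cand <- arrayInd(cand_idx, shape)
    seeds_vox <- robust_kmeans(cand, n_cells)$centers
    vox <- arrayInd(inside, shape)
    lab <- integer(length(inside))
    best <- rep(Inf, length(inside))
    for (k in seq_len(n_cells)) {
      dk <- (vox[, 1] - seeds_vox[k, 1])^2 + (vox[, 2] - seeds_vox[k, 2])^2 +
        (vox[, 3] - seeds_vox[k, 3])^2
      upd <- dk < best
      best[upd] <- dk[upd]
      lab[upd] <- k
    }
    seeds_um <- sweep(seeds_vox - 1, 2, spacing, `*`)
    colnames(seeds_um) <- c("z", "y", "x")
    truth <- array(0L, shape)
    truth[inside] <- lab
    # membrane = tissue voxels with a 6-neighbour of different label or
    # outside the tissue, dilated shell_thickness times within the mask
    membrane <- boundary_voxels(truth, mask)
    if (shell_thickness > 1) {
      for (i in seq_len(shell_thickness - 1))
        membrane <- dilate6(membrane) & mask
    } else {
      membrane <- dilate6(membrane) & mask   # ~2-voxel walls
    }
    img <- array(0, shape)
    img[membrane] <- membrane_intensity
    if (noise_sd > 0) {
      img <- img + rnorm(length(img), 0, noise_sd)
      img <- pmin(pmax(round(img), 0), 255)
      dim(img) <- shape
    }
    sec <- NULL
    if (secondary != "none") {
      s <- array(0, shape)
      if (secondary == "random") {
        lev <- runif(n_cells, 30, 220)
        s[inside] <- lev[lab]
      } else {
        s[inside] <- 30 + 190 * (vox[, 3] - min(vox[, 3])) /
          max(diff(range(vox[, 3])), 1e-9)
      }
      sec <- intensity_volume(s, spacing, channel = "secondary")
    }
    structure(list(image = intensity_volume(img, spacing, channel = "membrane"),
                   truth = label_volume(truth, spacing),
                   secondary = sec, seeds_um = seeds_um),
              class = "synthetic_tissue")
  })
}

# tissue voxels adjacent (6-conn) to a different label or to outside
boundary_voxels <- function(labels, mask) {
  d <- dim(labels)
  out <- array(FALSE, d)
  for (ax in 1:3) {
    idx_a <- lapply(d, seq_len); idx_b <- idx_a
    idx_a[[ax]] <- seq_len(d[ax] - 1); idx_b[[ax]] <- 2:d[ax]
    la <- do.call(`[`, c(list(labels), idx_a))
    lb <- do.call(`[`, c(list(labels), idx_b))
    diffm <- la != lb
    sub <- do.call(`[`, c(list(out), idx_a)); sub <- sub | diffm
    out <- do.call(`[<-`, c(list(out), idx_a, list(sub)))
    sub <- do.call(`[`, c(list(out), idx_b)); sub <- sub | diffm
    out <- do.call(`[<-`, c(list(out), idx_b, list(sub)))
  }
  out & mask
}

# one 6-connected binary dilation
dilate6 <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (ax in 1:3) {
    idx_a <- lapply(d, seq_len); idx_b <- idx_a
    idx_a[[ax]] <- seq_len(d[ax] - 1); idx_b[[ax]] <- 2:d[ax]
    ma <- do.call(`[`, c(list(mask), idx_a))
    mb <- do.call(`[`, c(list(mask), idx_b))
    sub <- do.call(`[`, c(list(out), idx_a)); sub <- sub | mb
    out <- do.call(`[<-`, c(list(out), idx_a, list(sub)))
    sub <- do.call(`[`, c(list(out), idx_b)); sub <- sub | ma
    out <- do.call(`[<-`, c(list(out), idx_b, list(sub)))
  }
  out
}

#' Generate paired reference/target feature matrices
#'
#' Produces a (reference, target) pair of feature matrices linked by a known
#' functional map plus Gaussian noise, for benchmarking cross-channel
#' regression.
#'
#' @param reference reference feature matrix (rows = cells), or a list of
#'   `synthetic_cell` objects, in which case the moments embedding of their
#'   clouds is used as the reference space.
#' @param link function mapping the reference matrix to a target matrix with
#'   the same number of rows.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param seed integer seed.
#' @return List with matrices `reference` and `target`.
#' @export
generate_paired_channels <- function(reference, link = identity, noise_sd = 0,
                                     seed = 1) {
  if (is.list(reference) && !is.data.frame(reference) && !is.matrix(reference)) {
    stopifnot(all(vapply(reference, inherits, logical(1), "synthetic_cell")))
    reference <- t(vapply(reference, function(cl) moments_features(cl$cloud),
                          numeric(55)))
  }
  reference <- as.matrix(reference)
  target <- as.matrix(link(reference))
  if (nrow(target) != nrow(reference))
    stop("link() must return one target row per reference row")
  if (noise_sd > 0)
    target <- target + withr::with_seed(seed,
      matrix(rnorm(length(target), 0, noise_sd), nrow(target)))
  list(reference = reference, target = target)
}
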