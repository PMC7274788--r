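skewness <- function(x) {
  n <- length(x)
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}

#' Fit a tissue frame of reference (TFOR)
#'
#' Samples landmarks from the tissue's binary segmentation mask with ISLA
#' and fits a principal-axis transform to them. Axes are ordered by
#' variance: for an elongated migrating tissue, axis 1 is the front-rear
#' axis (longest), axis 3 the apicobasal axis (shortest). A deterministic
#' sign convention prevents 180-degree flips between acquisitions: each
#' axis sign is fixed so that the skewness of the tissue landmarks along
#' that axis is non-negative (ties broken toward the sign that minimizes
#' the frontal-most coordinate). Finally the cloud is translated so the
#' frontal-most point (minimum along axis 1) becomes the origin.
#'
#' @param tissue_mask logical 3D array or a [label_volume()] /
#'   [intensity_volume()] whose positive voxels define the tissue.
#' @param spacing voxel spacing in microns; taken from the volume when one
#'   is supplied.
#' @param n_landmarks landmarks sampled from the mask (default 3000).
#' @param seed optional integer seed.
#' @param sample_id identifier stored on the transform.
#' @return An object of class `tfor_transform` with fields `rotation`
#'   (3 x 3 orthonormal, sign convention folded in), `center`,
#'   `translation`, `axis_signs`, `determinant` and `sample_id`.
#' @export
fit_tfor <- function(tissue_mask, spacing = NULL, n_landmarks = 3000,
                     seed = NULL, sample_id = NA) {
  if (inherits(tissue_mask, "volume")) {
    spacing <- tissue_mask$spacing
    tissue_mask <- tissue_mask$voxels > 0
  }
  if (is.null(spacing)) stop("spacing required when mask is a bare array")
  if (!any(tissue_mask)) stop("empty tissue mask")
  vol <- intensity_volume(array(as.numeric(tissue_mask), dim(tissue_mask)),
                          spacing)
  cloud <- sample_landmarks(vol, n_landmarks, seed = seed)
  pts <- cloud$points
  ctr <- colMeans(pts)
  cen <- sweep(pts, 2, ctr)
  cv <- crossprod(cen) / (nrow(cen) - 1)
  ev <- eigen(cv, symmetric = TRUE)
  if (ev$values[3] < 1e-12 * ev$values[1])
    stop("degenerate mask: rank-deficient landmark covariance")
  R <- ev$vectors  # columns ordered by decreasing variance
  scores <- cen %*% R
  signs <- numeric(3)
  for (k in 1:3) {
    sk <- skewness(scores[, k])
    if (abs(sk) >= 1e-6) {
      signs[k] <- sign(sk)
    } else {
      # tie: pick the sign under which the frontal-most coordinate is minimal
      signs[k] <- if (min(scores[, k]) <= min(-scores[, k])) 1 else -1
    }
  }
  R <- R %*% diag(signs)
  scores <- cen %*% R
  frontal <- which.min(scores[, 1])
  translation <- -scores[frontal, ]
  structure(list(rotation = R, center = ctr, translation = translation,
                 axis_signs = signs, determinant = det(R),
                 sample_id = sample_id, n_landmarks = n_landmarks),
            class = "tfor_transform")
}

#' Apply a TFOR transform to point clouds
#'
#' Applies the rigid tissue alignment to one cloud or a list of clouds.
#' Micron units, cell sizes and per-cell orientations are preserved — the
#' tissue frame retains biologically meaningful size and rotation
#' information.
#'
#' @param clouds a [point_cloud()] or list of them, frame `"raw"`.
#' @param transform a `tfor_transform` from [fit_tfor()].
#' @return Cloud(s) with frame `"tfor"`.
#' @export
apply_tfor <- function(clouds, transform) {
  stopifnot(inherits(transform, "tfor_transform"))
  one <- function(cl) {
    stopifnot(inherits(cl, "point_cloud"))
    if (cl$frame != "raw")
      stop("apply_tfor expects clouds in the raw frame, got '", cl$frame, "'")
    if (!is.na(cl$sample_id) && !is.na(transform$sample_id) &&
        !identical(cl$sample_id, transform$sample_id))
      stop("sample_id mismatch between cloud and transform")
    pts <- sweep(cl$points, 2, transform$center) %*% transform$rotation
    pts <- sweep(pts, 2, transform$translation, `+`)
    point_cloud(pts, frame = "tfor", cell_id = cl$cell_id,
                sample_id = cl$sample_id)
  }
  if (inherits(clouds, "point_cloud")) one(clouds) else lapply(clouds, one)
}

#' Normalize a point cloud into the cell frame of reference (CFOR)
#'
#' Centers the cloud on its centroid and scales it uniformly so that the
#' sum of the magnitudes of all centroid-to-landmark vectors equals 1.
#' Output is invariant to translation and uniform scaling of the input.
#'
#' @param cloud a [point_cloud()] with at least 2 distinct points.
#' @return A [point_cloud()] (frame unchanged at this stage; the full CFOR
#'   invariance is completed by [pairwise_distance_representation()]).
#' @export
cfor_normalize <- function(cloud) {
  pts <- cloud_matrix(cloud)
  if (nrow(pts) < 2) stop("need at least 2 points")
  cen <- sweep(pts, 2, colMeans(pts))
  s <- sum(sqrt(rowSums(cen^2)))
  if (s == 0) stop("all points identical; cannot normalize")
  out <- cen / s
  point_cloud(out, frame = cloud_frame(cloud),
              cell_id = if (inherits(cloud, "point_cloud")) cloud$cell_id else NA,
              sample_id = if (inherits(cloud, "point_cloud")) cloud$sample_id else NA)
}

#' Pairwise-distance representation of a point cloud
#'
#' Re-represents each landmark by the 10th, 50th and 90th percentiles of
#' its distances to all other landmarks (linear interpolation between
#' order statistics). The representation is invariant to translation,
#' rotation and reflection by construction, and — applied after
#' [cfor_normalize()] — completes the size-, rotation- and
#' handedness-invariant cell frame of reference.
#'
#' @param cloud a [point_cloud()] with at least 2 points.
#' @param probs the percentiles (default `c(0.1, 0.5, 0.9)`).
#' @return An object of class `pd_cloud`: list with `rep` (n x 3 matrix,
#'   columns ordered by `probs`) and `cell_id`.
#' @export
pairwise_distance_representation <- function(cloud, probs = c(0.1, 0.5, 0.9)) {
  pts <- cloud_matrix(cloud)
  if (nrow(pts) < 2) stop("need at least 2 points")
  rep <- .cpp_pd_percentiles(pts, probs)
  colnames(rep) <- paste0("p", round(100 * probs))
  structure(list(rep = rep,
                 cell_id = if (inherits(cloud, "point_cloud")) cloud$cell_id else NA,
                 sample_id = if (inherits(cloud, "point_cloud")) cloud$sample_id else NA),
            class = "pd_cloud")
}

#' Full CFOR pipeline
#'
#' Convenience wrapper: [cfor_normalize()] followed by
#' [pairwise_distance_representation()].
#'
#' @inheritParams pairwise_distance_representation
#' @return A `pd_cloud`.
#' @export
cfor_pipeline <- function(cloud, probs = c(0.1, 0.5, 0.9)) {
  pairwise_distance_representation(cfor_normalize(cloud), probs = probs)
}

# surface area of a binary mask by the coarea formula: integrate the
# gradient magnitude of a Gaussian-smoothed indicator over the volume.
# For a smoothed step the line integral of |grad| across the interface is
# 1, so the volume integral approximates the interface area. sigma_um is
# the physical smoothing scale.
mask_surface_area <- function(mask, spacing, sigma_um = NULL) {
  d <- dim(mask)
  if (is.null(sigma_um)) sigma_um <- 1.5 * max(spacing)
  sig_vox <- sigma_um / spacing
  sm <- .cpp_gaussian3d(as.numeric(mask), d, sig_vox)
  dim(sm) <- d
  grad2 <- array(0, d)
  for (ax in 1:3) {
    g <- array(0, d)
    idx_all <- lapply(d, seq_len)
    hi <- idx_all; lo <- idx_all
    hi[[ax]] <- c(2:d[ax], d[ax]); lo[[ax]] <- c(1, 1:(d[ax] - 1))
    denom <- rep(2 * spacing[ax], prod(d))
    dim(denom) <- d
    edge <- idx_all
    g <- (do.call(`[`, c(list(sm), hi)) - do.call(`[`, c(list(sm), lo))) / denom
    grad2 <- grad2 + g^2
  }
  sum(sqrt(grad2)) * prod(spacing)
}

#' Engineered per-cell shape features
#'
#' Computes explicitly engineered features for every cell in a label
#' volume: volume (voxel count times voxel volume, um^3), surface area
#' (um^2, coarea estimate on the smoothed cell mask), sphericity
#' (pi^(1/3) (6V)^(2/3) / A, in (0, 1]), extents along the TFOR axes (um),
#' TFOR centroid coordinates (um), orientation of the cell's major
#' principal axis relative to the three TFOR axes (radians), and a surface
#' smoothness proxy (ratio of the cell's surface area to its convex hull's
#' surface area; ~1 for smooth convex cells, larger for rough surfaces).
#'
#' @param labels a [label_volume()].
#' @param transform optional `tfor_transform`; identity when NULL.
#' @param ids label ids to process (default: all).
#' @return data.frame with one row per cell.
#' @export
engineered_features <- function(labels, transform = NULL, ids = NULL) {
  stopifnot(inherits(labels, "label_volume"))
  v <- labels$voxels
  spacing <- labels$spacing
  d <- dim(v)
  if (is.null(ids)) ids <- sort(setdiff(unique(as.integer(v)), 0L))
  if (length(ids) == 0) stop("no cells in label volume")
  voxvol <- prod(spacing)
  rows <- lapply(ids, function(id) {
    idx <- which(v == id)
    if (length(idx) == 0) stop("empty cell ", id)
    pts <- voxel_coords_um(idx, d, spacing)
    if (!is.null(transform)) {
      pts <- sweep(pts, 2, transform$center) %*% transform$rotation
      pts <- sweep(pts, 2, transform$translation, `+`)
      Rm <- transform$rotation
    } else Rm <- diag(3)
    volume <- length(idx) * voxvol
    # crop the cell into its own bounding box for area computation
    sub0 <- arrayInd(idx, d)
    rng <- apply(sub0, 2, range)
    pad <- 3L
    lo <- pmax(rng[1, ] - pad, 1L); hi <- pmin(rng[2, ] + pad, d)
    sub_mask <- array(FALSE, hi - lo + 1L)
    sub_mask[cbind(sub0[, 1] - lo[1] + 1L, sub0[, 2] - lo[2] + 1L,
                   sub0[, 3] - lo[3] + 1L)] <- TRUE
    area <- mask_surface_area(sub_mask, spacing)
    # discretized area estimates can undershoot by a percent or two on
    # near-perfect spheres; cap at the theoretical maximum
    sphericity <- min(1, pi^(1 / 3) * (6 * volume)^(2 / 3) / area)
    # extents along TFOR axes: range of voxel centers plus the projected
    # voxel footprint, so an axis-aligned k-voxel box reports k * spacing
    ext_pad <- colSums(abs(Rm) * spacing)
    extents <- apply(pts, 2, function(x) diff(range(x))) + ext_pad
    centroid <- colMeans(pts)
    # orientation: angles between the cell's major principal axis and the
    # TFOR axes
    cen <- sweep(pts, 2, centroid)
    evec <- eigen(crossprod(cen) / (nrow(cen) - 1), symmetric = TRUE)$vectors[, 1]
    angles <- acos(pmin(1, abs(evec)))
    # smoothness proxy: actual surface area relative to the convex hull's
    # surface area (>= ~1; larger = rougher surface). The hull only needs
    # the cell's boundary voxels.
    bnd <- boundary_inner_hull(sub_mask)
    bsub <- arrayInd(which(bnd), dim(sub_mask))
    bsub <- sweep(bsub, 2, lo - 1L, `+`)    # back to full-volume indices
    bpts <- sweep(bsub - 1, 2, spacing, `*`)
    if (!is.null(transform)) {
      bpts <- sweep(bpts, 2, transform$center) %*% transform$rotation
      bpts <- sweep(bpts, 2, transform$translation, `+`)
    }
    hull_area <- .cpp_convhull_area(bpts)
    smoothness <- if (is.na(hull_area)) NA_real_ else area / hull_area
    data.frame(cell_id = id, volume_um3 = volume, surface_area_um2 = area,
               sphericity = sphericity,
               extent_ax1_um = extents[1], extent_ax2_um = extents[2],
               extent_ax3_um = extents[3],
               centroid_ax1_um = centroid[1], centroid_ax2_um = centroid[2],
               centroid_ax3_um = centroid[3],
               orient_ax1_rad = angles[1], orient_ax2_rad = angles[2],
               orient_ax3_rad = angles[3],
               surface_smoothness = smoothness)
  })
  do.call(rbind, rows)
}
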