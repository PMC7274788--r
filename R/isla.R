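#' Background subtraction within a cell mask
#'
#' Sets voxels outside the mask to zero and subtracts the mean intensity
#' within the mask from every masked voxel, clamping negatives at zero.
#' This prevents landmarks from being assigned to diffuse background
#' signal inside the segmentation mask.
#'
#' @param volume an [intensity_volume()].
#' @param mask logical array of the same shape (the cell's segmentation
#'   mask).
#' @return An [intensity_volume()].
#' @export
subtract_cell_background <- function(volume, mask) {
  stopifnot(inherits(volume, "intensity_volume"))
  if (!identical(dim(volume$voxels), dim(mask))) stop("mask shape mismatch")
  if (!any(mask)) stop("empty mask")
  v <- volume$voxels
  out <- array(0, dim(v))
  inside <- v[mask] - mean(v[mask])
  inside[inside < 0] <- 0
  out[mask] <- inside
  intensity_volume(out, volume$spacing, channel = volume$channel)
}

#' Intensity-biased stochastic landmark assignment (ISLA)
#'
#' Normalizes voxel intensities to sum 1 and treats them as the
#' probabilities of a multinomial distribution from which `n_points`
#' landmarks are drawn with replacement. Landmarks are placed at voxel
#' centers and scaled from pixels to microns using the per-axis voxel
#' spacing, which accounts for anisotropic resolution.
#'
#' @param volume an [intensity_volume()] with at least one positive voxel.
#' @param n_points number of landmarks (default 2000).
#' @param seed optional integer seed.
#' @param cell_id,sample_id identifiers stored on the returned cloud.
#' @return A [point_cloud()] with frame `"raw"`.
#' @examples
#' v <- array(0, c(3, 3, 3)); v[2, 2, 2] <- 5
#' pc <- sample_landmarks(intensity_volume(v, c(1, 1, 1)), 10, seed = 1)
#' unique(pc$points)  # all landmarks at the one positive voxel
#' @export
sample_landmarks <- function(volume, n_points = 2000, seed = NULL,
                             cell_id = NA, sample_id = NA) {
  stopifnot(inherits(volume, "intensity_volume"), n_points >= 1)
  v <- as.numeric(volume$voxels)
  pos <- which(v > 0)
  if (length(pos) == 0) stop("nothing to sample: all intensities are zero")
  p <- v[pos] / sum(v[pos])
  draw <- function() pos[sample.int(length(pos), n_points, replace = TRUE,
                                    prob = p)]
  idx <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  pts <- voxel_coords_um(idx, dim(volume$voxels), volume$spacing)
  point_cloud(pts, frame = "raw", cell_id = cell_id, sample_id = sample_id)
}

#' 6-connected inner hull of a binary mask
#'
#' Returns the mask voxels that have at least one 6-neighbor outside the
#' mask (or lie on the volume edge): the 1-voxel-thick inner boundary
#' shell used as the ISLA input when capturing cell shape.
#'
#' @param mask non-empty logical 3D array.
#' @return Logical array of the same shape.
#' @export
boundary_inner_hull <- function(mask) {
  stopifnot(is.array(mask), length(dim(mask)) == 3)
  if (!any(mask)) stop("empty mask")
  d <- dim(mask)
  interior <- array(TRUE, d)
  for (ax in 1:3) {
    idx_lo <- lapply(d, seq_len); idx_hi <- idx_lo
    idx_lo[[ax]] <- seq_len(d[ax] - 1); idx_hi[[ax]] <- 2:d[ax]
    # neighbor in +ax direction present?
    nb_hi <- array(FALSE, d)
    nb_hi <- do.call(`[<-`, c(list(nb_hi), idx_lo,
                              list(do.call(`[`, c(list(mask), idx_hi)))))
    nb_lo <- array(FALSE, d)
    nb_lo <- do.call(`[<-`, c(list(nb_lo), idx_hi,
                              list(do.call(`[`, c(list(mask), idx_lo)))))
    interior <- interior & nb_hi & nb_lo   # volume-edge voxels count as hull
  }
  mask & !interior
}
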