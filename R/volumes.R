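#' Voxel volume containers
#'
#' An `intensity_volume` holds a 3D grid of finite, non-negative intensities;
#' a `label_volume` holds a 3D grid of integer cell labels where 0 is
#' background. Both carry the physical voxel spacing in microns, ordered
#' (z, y, x) to match the array dimensions.
#'
#' @param voxels 3D numeric (intensity) or integer (label) array,
#'   dim = c(nz, ny, nx).
#' @param spacing numeric length-3 vector of voxel spacings in microns,
#'   (z, y, x). All entries must be positive.
#' @param channel optional channel name.
#' @return An object of class `intensity_volume` or `label_volume`: a list
#'   with elements `voxels`, `spacing` and `channel`.
#' @examples
#' v <- intensity_volume(array(0, c(4, 4, 4)), spacing = c(0.225, 0.099, 0.099))
#' dim(v$voxels)
#' @export
intensity_volume <- function(voxels, spacing, channel = NULL) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values (z, y, x) in microns")
  if (any(!is.finite(voxels)))
    stop("intensities must be finite")
  structure(list(voxels = voxels, spacing = spacing, channel = channel),
            class = c("intensity_volume", "volume"))
}

#' @rdname intensity_volume
#' @export
label_volume <- function(voxels, spacing, channel = NULL) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values (z, y, x) in microns")
  storage.mode(voxels) <- "integer"
  if (any(voxels < 0, na.rm = TRUE)) stop("labels must be non-negative")
  structure(list(voxels = voxels, spacing = spacing, channel = channel),
            class = c("label_volume", "volume"))
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<%s> %d x %d x %d voxels (z,y,x), spacing %s um",
              class(x)[1], d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = " x ")))
  if (!is.null(x$channel)) cat(", channel:", x$channel)
  cat("\n")
  if (inherits(x, "label_volume")) {
    n <- length(setdiff(unique(as.integer(x$voxels)), 0L))
    cat(" labels:", n, "foreground objects\n")
  }
  invisible(x)
}

# voxel-centre coordinates in microns for linear indices (0-based grid,
# coordinate of voxel i along an axis = (i - 1) * spacing)
voxel_coords_um <- function(idx, dim, spacing) {
  idx0 <- idx - 1L
  z <- idx0 %% dim[1]
  y <- (idx0 %/% dim[1]) %% dim[2]
  x <- idx0 %/% (dim[1] * dim[2])
  cbind(z = z * spacing[1], y = y * spacing[2], x = x * spacing[3])
}
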