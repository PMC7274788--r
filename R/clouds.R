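#' Landmark point clouds
#'
#' A `point_cloud` is an n x 3 matrix of landmark coordinates in microns
#' (columns z, y, x) plus a frame tag recording which reference frame the
#' coordinates live in: `"raw"` (as sampled from the image), `"tfor"`
#' (tissue frame of reference) or `"cfor"` (cell frame of reference /
#' pairwise-distance representation).
#'
#' @param points n x 3 numeric matrix (z, y, x) in microns, n >= 1.
#' @param frame one of "raw", "tfor", "cfor".
#' @param cell_id,sample_id optional identifiers.
#' @return An object of class `point_cloud`.
#' @examples
#' pc <- point_cloud(matrix(rnorm(30), 10, 3))
#' nrow(pc$points)
#' @export
point_cloud <- function(points, frame = "raw", cell_id = NA, sample_id = NA) {
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("points must have 3 columns (z, y, x)")
  if (nrow(points) < 1) stop("point cloud must contain at least one point")
  if (any(!is.finite(points))) stop("coordinates must be finite")
  frame <- match.arg(frame, c("raw", "tfor", "cfor"))
  colnames(points) <- c("z", "y", "x")
  structure(list(points = points, frame = frame,
                 cell_id = cell_id, sample_id = sample_id),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d landmarks, frame '%s'", nrow(x$points), x$frame))
  if (!is.na(x$cell_id)) cat(", cell", x$cell_id)
  if (!is.na(x$sample_id)) cat(", sample", x$sample_id)
  cat("\n")
  invisible(x)
}

# accept a point_cloud, pd_cloud or bare matrix and return the n x 3 matrix
cloud_matrix <- function(cloud) {
  if (inherits(cloud, "point_cloud")) return(cloud$points)
  if (inherits(cloud, "pd_cloud")) return(cloud$rep)
  m <- as.matrix(cloud)
  if (ncol(m) != 3) stop("expected an n x 3 coordinate matrix")
  m
}

cloud_frame <- function(cloud) {
  if (inherits(cloud, "point_cloud")) cloud$frame
  else if (inherits(cloud, "pd_cloud")) "cfor"
  else "raw"
}

#' Save or load a set of point clouds
#'
#' Clouds are stored as a single serialized container (RDS); a flat CSV
#' export (`cell_id`, `sample_id`, `frame`, `z`, `y`, `x`) is available via
#' `export_clouds_csv()`.
#'
#' @param clouds list of [point_cloud()] objects.
#' @param path file path.
#' @return `read_clouds()` returns the list of clouds; the writers return
#'   `path` invisibly.
#' @export
write_clouds <- function(clouds, path) {
  stopifnot(all(vapply(clouds, inherits, logical(1), "point_cloud")))
  saveRDS(clouds, path)
  invisible(path)
}

#' @rdname write_clouds
#' @export
read_clouds <- function(path) readRDS(path)

#' @rdname write_clouds
#' @export
export_clouds_csv <- function(clouds, path) {
  rows <- lapply(clouds, function(cl) {
    data.frame(cell_id = cl$cell_id, sample_id = cl$sample_id,
               frame = cl$frame, cl$points)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
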