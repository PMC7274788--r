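#' Remove channel bleed-through by linear unmixing
#'
#' Models the mixed channel as M = U + a * C, where C is the contaminant
#' channel, and recovers the bleed-through factor `a` by minimizing the
#' Pearson correlation between C and the mean-centered absolute values of
#' the candidate unmixed image M - a * C. Centering and taking absolute
#' values makes over-unmixed regions correlate with C again, penalizing
#' unreasonably large factors. The returned unmixed image is clamped at 0.
#'
#' @param M mixed [intensity_volume()].
#' @param C contaminant [intensity_volume()] (same shape).
#' @param a_range numeric length-2, the scanned interval for `a`.
#' @param a_step grid step of the initial dense scan (refined afterwards by
#'   golden-section search in the bracketing interval).
#' @return List with `U` (unmixed [intensity_volume()]), `a` (factor) and
#'   `loss` (loss at `a`).
#' @examples
#' M <- intensity_volume(array(runif(64), c(4, 4, 4)), c(1, 1, 1))
#' C <- intensity_volume(array(0, c(4, 4, 4)), c(1, 1, 1))
#' unmix_bleedthrough(M, C)$a  # contaminant-free: a = 0
#' @export
unmix_bleedthrough <- function(M, C, a_range = c(0, 2), a_step = 0.02) {
  stopifnot(inherits(M, "intensity_volume"), inherits(C, "intensity_volume"))
  if (!identical(dim(M$voxels), dim(C$voxels)))
    stop("M and C must have the same shape")
  cv <- as.numeric(C$voxels)
  mv <- as.numeric(M$voxels)
  if (sd(cv) == 0) {
    warning("contaminant channel is constant; returning a = 0, U = M")
    return(list(U = M, a = 0, loss = NA_real_))
  }
  loss_fn <- function(a) {
    u <- mv - a * cv
    u <- abs(u - mean(u))
    if (sd(u) == 0) return(1)
    cor(cv, u)
  }
  grid <- seq(a_range[1], a_range[2], by = a_step)
  losses <- vapply(grid, loss_fn, numeric(1))
  i <- which.min(losses)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(loss_fn, c(lo, hi))
  a <- opt$minimum
  if (losses[i] < opt$objective) { a <- grid[i]; opt$objective <- losses[i] }
  u <- mv - a * cv
  u[u < 0] <- 0
  dim(u) <- dim(M$voxels)
  list(U = intensity_volume(u, M$spacing, channel = M$channel), a = a,
       loss = opt$objective)
}

#' Segmentation configuration
#'
#' @param gaussian_sigma Gaussian smoothing sigma in pixels (applied in
#'   pixel space, matching the acquisition-resolution filtering of the
#'   pipeline).
#' @param offsets integer threshold offsets scanned above the histogram
#'   mode (default 0 to 10 in steps of 1).
#' @param min_size minimum connected-component size in voxels; smaller
#'   components are removed as artifacts.
#' @param max_size maximum component size; larger components are treated as
#'   background seeds.
#' @param label_connectivity connectivity for component labeling (26 or 6).
#' @param count_connectivity connectivity for the enclosed-component count
#'   used in threshold selection (6 or 26).
#' @param border_background treat candidate components that touch the
#'   volume border as background seeds regardless of size (default TRUE; a
#'   cell body fully enclosed by membrane cannot touch the stack border).
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(gaussian_sigma = 3, offsets = 0:10,
                                min_size = 1000, max_size = 1e6,
                                label_connectivity = 26,
                                count_connectivity = 6,
                                border_background = TRUE) {
  stopifnot(length(offsets) >= 1, min_size < max_size)
  structure(list(gaussian_sigma = gaussian_sigma, offsets = offsets,
                 min_size = min_size, max_size = max_size,
                 label_connectivity = label_connectivity,
                 count_connectivity = count_connectivity,
                 border_background = border_background),
            class = "segmentation_config")
}

# histogram mode: exact value for integer-valued data, 256-bin midpoint
# otherwise (the pipeline is designed around 8-bit input)
histogram_mode <- function(v) {
  v <- as.numeric(v)
  if (all(v == round(v))) {
    tb <- table(v)
    as.numeric(names(tb)[which.max(tb)])
  } else {
    h <- graphics::hist(v, breaks = 256, plot = FALSE)
    h$mids[which.max(h$counts)]
  }
}

#' Select a membrane threshold by enclosed-component counting
#'
#' Starting from the most frequent intensity value (histogram mode) as the
#' base threshold, scans a range of positive offsets and counts the
#' connected components of the inverted foreground mask — roughly the
#' number of cell bodies fully enclosed by membrane at that threshold. The
#' offset maximizing the count wins; ties break toward the smallest offset.
#'
#' @param volume smoothed [intensity_volume()] (pipeline steps 1-2).
#' @param offsets offsets to scan (default 0:10).
#' @param connectivity connectivity of the component count (default 6).
#' @return List with `threshold`, `base`, `offset` and the per-offset
#'   `counts`.
#' @export
select_threshold <- function(volume, offsets = 0:10, connectivity = 6) {
  stopifnot(inherits(volume, "intensity_volume"))
  v <- volume$voxels
  if (length(v) == 0) stop("empty volume")
  base <- histogram_mode(v)
  counts <- vapply(offsets, function(off) {
    inv <- v <= (base + off)
    max(.cpp_label3d(inv, dim(v), as.integer(connectivity)))
  }, numeric(1))
  i <- which.max(counts)   # first maximum = smallest offset on ties
  list(threshold = base + offsets[i], base = base, offset = offsets[i],
       counts = setNames(counts, offsets))
}

# fill small 3D holes of a binary mask: background components (6-conn)
# not touching the volume border and smaller than max_size are cavities in
# the membrane walls and get filled; cell-sized enclosed bodies are left
# alone (they are what the subsequent labeling step detects)
fill_holes3d <- function(mask, max_size = Inf) {
  d <- dim(mask)
  lab <- .cpp_label3d(!mask, d, 6L)
  border <- unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ],
                     lab[, , 1], lab[, , d[3]]))
  border <- setdiff(border, 0L)
  if (max(lab) == 0) return(mask)
  sizes <- tabulate(lab[lab > 0])
  fill_ids <- setdiff(which(sizes < max_size), border)
  hole <- lab > 0 & (lab %in% fill_ids)
  mask | hole
}

#' Automated 3D single-cell segmentation of a membrane label
#'
#' Eight sequential steps: 3x3x3 median filtering, Gaussian smoothing
#' (sigma = 3 px), automatic thresholding ([select_threshold()]),
#' morphological hole filling of the membrane mask, connected-component
#' labeling of the inverted mask (candidate cell bodies), removal of
#' components smaller than `min_size` voxels and re-assignment of
#' components larger than `max_size` voxels as background seeds, seeded
#' watershed expansion on an additionally Gaussian-smoothed topography
#' (background seeds expand too), and finally zeroing of background labels
#' while keeping only the largest connected foreground object.
#'
#' @param volume single-channel membrane [intensity_volume()].
#' @param cfg a [segmentation_config()].
#' @return A [label_volume()]; labels are consecutive positive integers,
#'   0 = background. Attributes `threshold` and `n_removed` record the
#'   chosen threshold and the number of sub-minimum components removed.
#' @export
segment_cells <- function(volume, cfg = segmentation_config()) {
  stopifnot(inherits(volume, "intensity_volume"))
  d <- dim(volume$voxels)
  v <- .cpp_median3(as.numeric(volume$voxels), d)               # step 1
  s <- cfg$gaussian_sigma
  v <- .cpp_gaussian3d(v, d, rep(s, 3))                         # step 2
  thr <- select_threshold(intensity_volume(v, volume$spacing),
                          offsets = cfg$offsets,
                          connectivity = cfg$count_connectivity) # step 3
  mask <- v > thr$threshold
  dim(mask) <- d
  mask <- fill_holes3d(mask, max_size = cfg$min_size)           # step 4
  seeds <- .cpp_label3d(!mask, d, as.integer(cfg$label_connectivity)) # step 5
  sizes <- tabulate(seeds[seeds > 0])
  border_ids <- integer(0)
  if (isTRUE(cfg$border_background)) {
    border_ids <- setdiff(unique(c(seeds[1, , ], seeds[d[1], , ],
                                   seeds[, 1, ], seeds[, d[2], ],
                                   seeds[, , 1], seeds[, , d[3]])), 0L)
  }
  n_removed <- sum(sizes > 0 & sizes < cfg$min_size)
  keep_fg <- setdiff(which(sizes >= cfg$min_size & sizes <= cfg$max_size),
                     border_ids)
  bg_ids <- union(which(sizes > cfg$max_size), intersect(border_ids,
                  which(sizes >= cfg$min_size)))
  if (length(keep_fg) == 0) {
    warning("no foreground object survives; returning empty labels")
    return(label_volume(array(0L, d), volume$spacing))
  }
  # step 6: relabel — foreground seeds 1..K, background seeds K+1..
  remap <- integer(length(sizes))
  remap[keep_fg] <- seq_along(keep_fg)
  remap[bg_ids] <- length(keep_fg) + seq_along(bg_ids)
  seeds2 <- array(0L, d)
  pos <- seeds > 0
  seeds2[pos] <- remap[seeds[pos]]
  topo <- .cpp_gaussian3d(v, d, rep(s, 3))                      # step 7
  ws <- .cpp_watershed3d(topo, seeds2, d)
  ws[ws > length(keep_fg)] <- 0L                                # step 8
  fg <- ws > 0
  dim(fg) <- d
  comp <- .cpp_label3d(fg, d, 26L)
  if (max(comp) > 0) {
    csz <- tabulate(comp[comp > 0])
    ws[comp != which.max(csz)] <- 0L
  }
  # consecutive labels
  ids <- sort(setdiff(unique(as.integer(ws)), 0L))
  remap2 <- integer(max(c(ids, 0L)))
  remap2[ids] <- seq_along(ids)
  pos <- ws > 0
  ws[pos] <- remap2[ws[pos]]
  dim(ws) <- d
  out <- label_volume(ws, volume$spacing)
  attr(out, "threshold") <- thr$threshold
  attr(out, "n_removed") <- n_removed
  out
}

#' Quality-control summary of a segmentation
#'
#' Reports the cell count and size distribution and flags cells whose
#' volume falls outside plausible bounds. Flagging assists manual review;
#' exclusion remains a user decision.
#'
#' @param labels a [label_volume()].
#' @param min_voxels,max_voxels plausible size bounds in voxels. Defaults
#'   are relative to the median cell size (median / 4 and median * 4).
#' @param n_samples number of samples (embryos/tissues) this segmentation
#'   set stems from, reported as `N` alongside the cell count `n`.
#' @return A list of class `qc_summary` with `n` (cells), `N` (samples),
#'   `sizes` (named voxel counts), `flagged` (label ids) and
#'   `frac_flagged`.
#' @export
qc_summary <- function(labels, min_voxels = NULL, max_voxels = NULL,
                       n_samples = 1) {
  stopifnot(inherits(labels, "label_volume"))
  v <- labels$voxels
  ids <- sort(setdiff(unique(as.integer(v)), 0L))
  sizes <- setNames(tabulate(v[v > 0], nbins = max(c(ids, 0L)))[ids], ids)
  med <- if (length(sizes)) median(sizes) else NA_real_
  if (is.null(min_voxels)) min_voxels <- med / 4
  if (is.null(max_voxels)) max_voxels <- med * 4
  flagged <- ids[sizes < min_voxels | sizes > max_voxels]
  structure(list(n = length(ids), N = n_samples, sizes = sizes,
                 flagged = flagged,
                 frac_flagged = if (length(ids)) length(flagged) / length(ids) else 0,
                 bounds = c(min = min_voxels, max = max_voxels)),
            class = "qc_summary")
}

#' @export
print.qc_summary <- function(x, ...) {
  cat(sprintf("<qc_summary> n = %d cells, N = %d sample(s)\n", x$n, x$N))
  if (x$n) cat(sprintf(" cell size (voxels): median %.0f, range %.0f-%.0f\n",
                       median(x$sizes), min(x$sizes), max(x$sizes)))
  cat(sprintf(" flagged: %d (%.1f%%)\n", length(x$flagged), 100 * x$frac_flagged))
  invisible(x)
}
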