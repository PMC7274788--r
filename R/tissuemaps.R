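#' Tissue consensus map of a per-cell value
#'
#' Pools registered (TFOR) cell centroids across samples and renders the
#' local average of any per-cell scalar over a 2D grid (TFOR axes 1-2 by
#' default). The tissue outline is a validity mask from a Gaussian kernel
#' density estimate of the pooled centroids, thresholded at 10% of the
#' density range; the value field is a point-cloud Gaussian smooth with
#' sigma set to the 0.5th percentile of all pairwise centroid distances.
#'
#' @param centroids n x 2 (or n x 3) matrix of TFOR centroid coordinates;
#'   with 3 columns, `axes` selects the two mapped axes.
#' @param values per-cell scalar values (length n).
#' @param axes the two TFOR axes to map over (default c(1, 2)).
#' @param grid_n grid resolution c(nx1, nx2) (default c(256, 128)).
#' @param sigma smoothing sigma in microns (default: 0.5th percentile of
#'   pairwise centroid distances).
#' @param density_cut mask cutoff as a fraction of the density range
#'   (default 0.10).
#' @return Object of class `consensus_map`: `x1`, `x2` (grid axes),
#'   `values` (grid matrix, NA outside the mask), `mask`, `sigma`,
#'   `centroids`.
#' @export
consensus_map <- function(centroids, values, axes = c(1, 2),
                          grid_n = c(256, 128), sigma = NULL,
                          density_cut = 0.10) {
  cen <- as.matrix(centroids)
  if (ncol(cen) > 2) cen <- cen[, axes, drop = FALSE]
  stopifnot(nrow(cen) == length(values), nrow(cen) >= 2)
  if (all(apply(cen, 2, function(x) diff(range(x)) == 0)))
    stop("all centroids identical")
  pd <- as.numeric(dist(cen))
  if (is.null(sigma)) sigma <- as.numeric(quantile(pd, 0.005))
  if (sigma <= 0) sigma <- min(pd[pd > 0])
  pad <- 3 * sigma
  lims <- c(range(cen[, 1]) + c(-pad, pad), range(cen[, 2]) + c(-pad, pad))
  # guard kde2d's normal-reference bandwidth against degenerate axes
  bw <- pmax(c(MASS::bandwidth.nrd(cen[, 1]), MASS::bandwidth.nrd(cen[, 2])),
             1e-6 * max(diff(lims[1:2]), diff(lims[3:4])))
  kde <- MASS::kde2d(cen[, 1], cen[, 2], h = bw, n = grid_n, lims = lims)
  dmin <- min(kde$z); dmax <- max(kde$z)
  mask <- kde$z >= dmin + density_cut * (dmax - dmin)
  g1 <- kde$x; g2 <- kde$y
  vals <- matrix(NA_real_, length(g1), length(g2))
  inside <- which(mask, arr.ind = TRUE)
  # Gaussian-weighted average of cell values at each masked grid point
  for (r in seq_len(nrow(inside))) {
    p1 <- g1[inside[r, 1]]; p2 <- g2[inside[r, 2]]
    w <- exp(-((cen[, 1] - p1)^2 + (cen[, 2] - p2)^2) / (2 * sigma^2))
    sw <- sum(w)
    vals[inside[r, 1], inside[r, 2]] <-
      if (sw > 0) sum(w * values) / sw else NA_real_
  }
  structure(list(x1 = g1, x2 = g2, values = vals, mask = mask,
                 sigma = sigma, centroids = cen),
            class = "consensus_map")
}

#' @export
plot.consensus_map <- function(x, ...) {
  graphics::image(x$x1, x$x2, x$values, asp = 1, xlab = "TFOR axis 1 (um)",
                  ylab = "TFOR axis 2 (um)", ...)
  invisible(x)
}

#' Correlation bigraph between engineered features and embedded PCs
#'
#' Computes Pearson correlations between every engineered feature and
#' every embedded latent feature; pairs with |r| >= `threshold` become
#' signed, weighted edges of a bipartite graph. Engineered-feature nodes
#' are ordered to reduce edge crossings via [sort_bigraph_nodes()].
#'
#' @param engineered data.frame/matrix of engineered features.
#' @param embedded data.frame/matrix of latent features (matched rows).
#' @param threshold minimum |r| for an edge (default 0.3).
#' @param seed seed for the node-order search.
#' @return Object of class `bigraph`: `edges` (data.frame `engineered`,
#'   `latent`, `r`), `node_order` (engineered node permutation), `loss`,
#'   `correlations` (full r matrix).
#' @export
correlation_bigraph <- function(engineered, embedded, threshold = 0.3,
                                seed = 1) {
  E <- as.matrix(engineered); L <- as.matrix(embedded)
  stopifnot(nrow(E) == nrow(L))
  if (is.null(colnames(E))) colnames(E) <- paste0("E", seq_len(ncol(E)))
  if (is.null(colnames(L))) colnames(L) <- paste0("L", seq_len(ncol(L)))
  zv <- apply(E, 2, sd) == 0
  if (any(zv)) {
    warning("zero-variance engineered feature(s) omitted: ",
            paste(colnames(E)[zv], collapse = ", "))
    E <- E[, !zv, drop = FALSE]
  }
  zvl <- apply(L, 2, sd) == 0
  if (any(zvl)) {
    warning("zero-variance latent feature(s) omitted: ",
            paste(colnames(L)[zvl], collapse = ", "))
    L <- L[, !zvl, drop = FALSE]
  }
  r <- cor(E, L)
  sorted <- sort_bigraph_nodes(abs(r), seed = seed)
  idx <- which(abs(r) >= threshold, arr.ind = TRUE)
  edges <- data.frame(engineered = colnames(E)[idx[, 1]],
                      latent = colnames(L)[idx[, 2]],
                      r = r[idx])
  structure(list(edges = edges, node_order = sorted$order,
                 loss = sorted$loss, correlations = r,
                 threshold = threshold),
            class = "bigraph")
}

bigraph_loss <- function(perm, w) {
  fE <- nrow(w); fL <- ncol(w)
  pos <- (perm - 1) / fE          # engineered node positions, 0-based / fE
  lat <- (seq_len(fL) - 1) / fE   # latent node rank positions
  sum(abs(outer(pos, lat, `-`)) * w)
}

#' Sort bigraph nodes by weighted rank distance
#'
#' Orders the engineered-feature nodes to minimize the sum over all
#' feature pairs of the distance between their normalized rank positions,
#' weighted by the absolute Pearson correlation. Minimization is a random
#' local search: shuffle proposals (transpositions, occasionally full
#' reshuffles) are accepted only when they strictly reduce the loss, and
#' the search stops after `patience` consecutive non-improving proposals.
#'
#' @param correlations fE x fL matrix of absolute correlations.
#' @param patience consecutive non-improving proposals before stopping
#'   (default 2000).
#' @param seed integer seed.
#' @return List with `order` (permutation: `order[i]` is the display
#'   position of engineered feature i), `loss`, `n_proposals`.
#' @export
sort_bigraph_nodes <- function(correlations, patience = 2000, seed = 1) {
  w <- abs(as.matrix(correlations))
  w[!is.finite(w)] <- 0
  fE <- nrow(w)
  if (fE <= 1)
    return(list(order = seq_len(fE), loss = bigraph_loss(seq_len(fE), w),
                n_proposals = 0))
  withr::with_seed(seed, {
    perm <- seq_len(fE)
    best <- bigraph_loss(perm, w)
    stale <- 0; n_prop <- 0
    while (stale < patience) {
      cand <- perm
      u <- runif(1)
      if (u < 0.30) {                      # full reshuffle
        cand <- sample(cand)
      } else if (u < 0.60 && fE >= 3) {    # remove-and-reinsert
        ij <- sample.int(fE, 2)
        val <- cand[ij[1]]
        cand <- append(cand[-ij[1]], val, after = ij[2] - 1)
      } else if (u < 0.75 && fE >= 3) {    # 3-cycle
        ijk <- sample.int(fE, 3)
        cand[ijk] <- cand[c(ijk[2], ijk[3], ijk[1])]
      } else {                             # transposition
        ij <- sample.int(fE, 2)
        cand[ij] <- cand[rev(ij)]
      }
      n_prop <- n_prop + 1
      l <- bigraph_loss(cand, w)
      if (l < best - 1e-12) {
        perm <- cand; best <- l; stale <- 0
      } else stale <- stale + 1
    }
    list(order = perm, loss = best, n_proposals = n_prop)
  })
}

#' Expanded ("ripped") view of a segmentation
#'
#' Shifts segmented cells apart by scaling their centroids' x and y
#' coordinates by a single factor and pasting each cell's voxels —
#' untransformed — at the shifted location in an enlarged canvas. Cells
#' keep their exact shape; only their positions change.
#'
#' @param labels a [label_volume()] with at least one cell.
#' @param factor centroid scaling factor (> 1 separates cells).
#' @return A [label_volume()] on the enlarged canvas.
#' @export
expand_tissue <- function(labels, factor) {
  stopifnot(inherits(labels, "label_volume"), factor >= 1)
  v <- labels$voxels
  d <- dim(v)
  ids <- sort(setdiff(unique(as.integer(v)), 0L))
  if (length(ids) == 0) stop("no cells in label volume")
  out_dim <- c(d[1], ceiling(d[2] * factor) + 2L, ceiling(d[3] * factor) + 2L)
  out <- array(0L, out_dim)
  for (id in ids) {
    idx <- which(v == id)
    sub <- arrayInd(idx, d)
    ctr <- colMeans(sub)
    shift <- c(0, round((factor - 1) * ctr[2]), round((factor - 1) * ctr[3]))
    ns <- sweep(sub, 2, shift, `+`)
    if (any(ns < 1) || any(ns[, 1] > out_dim[1]) || any(ns[, 2] > out_dim[2]) ||
        any(ns[, 3] > out_dim[3]))
      stop("cell ", id, " shifted outside the canvas; raise factor or pad")
    lin <- ns[, 1] + out_dim[1] * ((ns[, 2] - 1) + out_dim[2] * (ns[, 3] - 1))
    if (any(out[lin] != 0))
      stop("overlapping cells after expansion; raise factor")
    out[lin] <- id
  }
  label_volume(out, labels$spacing)
}
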