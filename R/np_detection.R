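# Nanoparticle detection: background-referenced intensity normalization,
# Roberts edge detection of candidate blobs, 3D clustering, and per-cluster
# multilevel Otsu refinement.

#' Normalize a slice to arbitrary intensity units (a.i.u.)
#'
#' Detector settings are constant across a slice-and-view stack, so pixel
#' intensity is proportional to the secondary-electron signal throughout the
#' volume; what varies is the arbitrary raw scale. This maps intensities to
#' background-referenced units: `(I - mu_bg) / sigma_bg`, where `mu_bg` and
#' `sigma_bg` are the median and normal-consistent MAD of the cell-matrix
#' pixels (the cell mask minus candidate particle pixels, found by one
#' robust rejection pass at 3 sigma). The flat matrix maps to 0 and a.i.u.
#' values are invariant under affine rescaling of the raw data.
#'
#' @param image Numeric matrix.
#' @param cell_mask Logical matrix: the segmented cell.
#' @param exclude Optional logical matrix of pixels to exclude from the
#'   background estimate (e.g. known particle candidates).
#' @param bg_erode_px Erode the mask by this radius before estimating the
#'   background (default 0). A segmentation mask that deliberately
#'   overshoots the cell boundary includes a ring of resin whose level
#'   differs from the matrix; eroding by the overshoot restores a pure
#'   matrix sample.
#' @param sigma Optional fixed background sigma, overriding the robust
#'   estimate (used for noiseless synthetic data whose MAD is 0).
#' @return Matrix in a.i.u., with attributes `mu_bg` and `sigma_bg`.
#' @export
normalize_to_background <- function(image, cell_mask, exclude = NULL,
                                    bg_erode_px = 0, sigma = NULL) {
  if (!any(cell_mask)) stop("empty cell mask: no background to reference")
  bg <- cell_mask
  if (bg_erode_px > 0) {
    er <- EBImage::erode(cell_mask * 1,
                         EBImage::makeBrush(2L * as.integer(bg_erode_px) + 1L,
                                            "disc")) > 0
    if (sum(er) >= 64) bg <- er
  }
  if (!is.null(exclude)) bg <- bg & !exclude
  v <- image[bg]
  mu <- stats::median(v)
  s <- robust_sd(v)
  if (s > 0) {  # one rejection pass removes bright particle pixels
    keep <- v < mu + 3 * s
    if (sum(keep) >= 16) {
      mu <- stats::median(v[keep])
      s <- robust_sd(v[keep])
    }
  }
  if (!is.null(sigma)) s <- sigma
  if (s <= 0) stop("degenerate background: sigma_bg = 0 (supply `sigma`)")
  out <- (image - mu) / s
  attr(out, "mu_bg") <- mu
  attr(out, "sigma_bg") <- s
  out
}

#' Detect candidate particle pixels in one slice
#'
#' The rough particle positions are found by Roberts edge detection on the
#' low-pass filtered a.i.u. image: the Roberts gradient magnitude is
#' thresholded at `roberts_k` robust standard deviations above its median
#' within the cell, the resulting edge rings are filled to solid blobs, and
#' pixels outside the cell mask are discarded.
#'
#' @param image_aiu Matrix in a.i.u. (see [normalize_to_background()]).
#' @param cell_mask Logical matrix.
#' @param lowpass_sigma Gaussian sigma (px) of the low-pass filter.
#' @param roberts_k Threshold in robust sigmas of the in-cell gradient.
#' @param min_peak_aiu A filled blob only counts when it encloses signal
#'   above this a.i.u. level (default 3, i.e. about 3 background sigmas):
#'   edges must outline an actual bright object, not a noise ripple.
#' @param min_edge_aiu Edge pixels must sit on intensity above this a.i.u.
#'   level (default 1). Particle edges rise from the matrix (0 a.i.u.)
#'   upwards, whereas the cell outline falls towards the resin; without this
#'   guard the outline - which lies inside the deliberately extended cell
#'   mask - would be filled into one giant false candidate.
#' @return Logical matrix of candidate pixels (possibly all-FALSE).
#' @export
detect_np_candidates <- function(image_aiu, cell_mask, lowpass_sigma = 1.5,
                                 roberts_k = 3, min_peak_aiu = 3,
                                 min_edge_aiu = 1) {
  if (!any(cell_mask)) return(matrix(FALSE, nrow(image_aiu), ncol(image_aiu)))
  sm <- lowpass(image_aiu, lowpass_sigma)
  g <- roberts_gradient(sm)
  gv <- g[cell_mask]
  thr <- stats::median(gv) + roberts_k * robust_sd(gv)
  if (thr <= 0) return(matrix(FALSE, nrow(image_aiu), ncol(image_aiu)))
  edges <- g > thr & sm > min_edge_aiu & cell_mask
  if (!any(edges)) return(edges)
  lab <- EBImage::bwlabel(EBImage::fillHull(EBImage::bwlabel(edges * 1)) > 0)
  keep <- lab > 0 & cell_mask
  if (min_peak_aiu > 0 && any(keep)) {
    ids <- sort(unique(lab[keep]))
    peak <- vapply(ids, function(i) max(sm[lab == i & cell_mask]), numeric(1))
    good <- ids[peak >= min_peak_aiu]
    keep <- keep & (lab %in% good)
    dim(keep) <- dim(lab)
  }
  keep
}

# Roberts cross gradient magnitude; output aligned to the top-left pixel of
# each 2x2 neighborhood, edge rows/cols padded with 0
roberts_gradient <- function(im) {
  d <- dim(im)
  g <- matrix(0, d[1], d[2])
  i <- seq_len(d[1] - 1)
  j <- seq_len(d[2] - 1)
  g1 <- im[i, j, drop = FALSE] - im[i + 1, j + 1, drop = FALSE]
  g2 <- im[i, j + 1, drop = FALSE] - im[i + 1, j, drop = FALSE]
  g[i, j] <- sqrt(g1^2 + g2^2)
  g
}

#' Group candidate pixels into rough 3D clusters
#'
#' 26-connected component labeling across the voxel grid: blobs that touch
#' (also diagonally, also across consecutive slices) form one cluster, so a
#' particle detected in several consecutive slices is one object and
#' agglomerates are kept together for the cluster-level counting formula.
#'
#' @param candidates 3D logical array (row, col, slice) of candidate voxels,
#'   e.g. stacked [detect_np_candidates()] output.
#' @param aiu 3D array of a.i.u. values, same shape; per-voxel intensities
#'   are attached to the clusters.
#' @param min_voxels Discard components smaller than this (default 4).
#' @return List of `np_cluster` objects: `id`, `voxels` (n x 3 integer
#'   matrix: row, col, slice), `aiu` (length-n numeric), `flags`.
#' @export
cluster_candidates_3d <- function(candidates, aiu, min_voxels = 4) {
  stopifnot(identical(dim(candidates), dim(aiu)))
  if (!any(candidates)) return(list())
  lab <- label_components_3d(candidates)
  ids <- seq_len(max(lab))
  out <- list()
  for (i in ids) {
    vox <- voxel_coords(lab == i)
    if (nrow(vox) < min_voxels) next
    out[[length(out) + 1L]] <- new_np_cluster(length(out) + 1L, vox, aiu)
  }
  out
}

new_np_cluster <- function(id, vox, aiu, flags = character(0)) {
  colnames(vox) <- c("row", "col", "slice")
  structure(list(id = id, voxels = vox,
                 aiu = aiu[vox],
                 bbox = apply(vox, 2, range),
                 flags = flags),
            class = "np_cluster")
}

#' @export
print.np_cluster <- function(x, ...) {
  cat(sprintf("NP cluster %d: %d voxels, slices %d-%d, total %.1f a.i.u.\n",
              x$id, nrow(x$voxels), x$bbox[1, 3], x$bbox[2, 3], sum(x$aiu)))
  invisible(x)
}

#' Refine a cluster by local multilevel Otsu thresholding
#'
#' Particle and matrix intensity levels fluctuate with the position of a
#' cluster in the cell, so each cluster is re-thresholded individually: in
#' the cluster bounding box padded by a margin, a 2-threshold (3-class)
#' Otsu determines the local intensity levels. Classes whose mean is
#' consistent with the cell matrix (below `matrix_max_aiu`; the matrix sits
#' at 0 a.i.u. by construction) are background; the refinement threshold is
#' the Otsu boundary above the highest background class, raised if needed
#' to 3 robust sigmas above the local background (so the heavy matrix-noise
#' mode cannot leak into the particle). Voxels above the threshold — the
#' subsurface glow and the exposed particle together — form the refined
#' cluster, restricted to its largest 26-connected component overlapping
#' the rough cluster; the glow belongs to the particle's detected volume,
#' which the escape-depth calibration later decomposes. A box without a
#' class clearly above the matrix leaves the rough cluster unchanged with a
#' `"degenerate"` flag.
#'
#' @param aiu 3D a.i.u. array.
#' @param cluster An `np_cluster` (rough).
#' @param margin_xy,margin_z Bounding-box padding in pixels / slices.
#' @param cell_volume Optional 3D logical array; refined voxels outside it
#'   are dropped.
#' @param matrix_max_aiu Classes with mean at or below this a.i.u. level
#'   count as background (default 2).
#' @return The refined `np_cluster` (per-voxel intensities re-extracted).
#' @export
refine_cluster_otsu <- function(aiu, cluster, margin_xy = 5, margin_z = 3,
                                cell_volume = NULL, matrix_max_aiu = 2) {
  d <- dim(aiu)
  bb <- cluster$bbox
  r0 <- max(1L, bb[1, 1] - margin_xy); r1 <- min(d[1], bb[2, 1] + margin_xy)
  c0 <- max(1L, bb[1, 2] - margin_xy); c1 <- min(d[2], bb[2, 2] + margin_xy)
  s0 <- max(1L, bb[1, 3] - margin_z); s1 <- min(d[3], bb[2, 3] + margin_z)
  box <- aiu[r0:r1, c0:c1, s0:s1, drop = FALSE]
  ot <- otsu_thresholds(as.vector(box), k = 3)
  cls_mean <- c(mean(box[box <= ot$thresholds[1]]),
                mean(box[box > ot$thresholds[1] & box <= ot$thresholds[2]]),
                mean(box[box > ot$thresholds[2]]))
  bg <- which(cls_mean <= matrix_max_aiu | !is.finite(cls_mean))
  if (length(bg) == 0) bg <- 1L
  k_bg <- max(bg)
  if (ot$degenerate || ot$bcv_frac < 0.25 || k_bg >= 3) {
    cluster$flags <- union(cluster$flags, "degenerate")
    return(cluster)
  }
  # a.i.u. units pin the matrix at 0 with unit noise, so a fixed floor of
  # 3 sigmas guards against the noise mode; the Otsu boundary above the
  # background classes adapts to local level fluctuations
  sel <- box > max(ot$thresholds[k_bg], matrix_max_aiu + 1)
  if (!is.null(cell_volume)) {
    sel <- sel & cell_volume[r0:r1, c0:c1, s0:s1, drop = FALSE]
  }
  if (!any(sel)) {
    cluster$flags <- union(cluster$flags, "degenerate")
    return(cluster)
  }
  lab <- label_components_3d(sel)
  # component(s) overlapping the rough cluster; keep the largest
  rough_local <- cbind(cluster$voxels[, 1] - r0 + 1L,
                       cluster$voxels[, 2] - c0 + 1L,
                       cluster$voxels[, 3] - s0 + 1L)
  keep <- rough_local[, 1] >= 1 & rough_local[, 1] <= dim(lab)[1] &
    rough_local[, 2] >= 1 & rough_local[, 2] <= dim(lab)[2] &
    rough_local[, 3] >= 1 & rough_local[, 3] <= dim(lab)[3]
  rl <- rough_local[keep, , drop = FALSE]
  hits <- lab[rl]
  hits <- hits[hits > 0]
  if (length(hits) == 0) {
    cluster$flags <- union(cluster$flags, "degenerate")
    return(cluster)
  }
  target <- as.integer(names(sort(table(hits), decreasing = TRUE))[1])
  vox_local <- voxel_coords(lab == target)
  vox <- cbind(vox_local[, 1] + r0 - 1L, vox_local[, 2] + c0 - 1L,
               vox_local[, 3] + s0 - 1L)
  new_np_cluster(cluster$id, vox, aiu, flags = setdiff(cluster$flags, "degenerate"))
}

#' Detect and refine all NP clusters in a stack
#'
#' Convenience wrapper chaining [detect_np_candidates()] per slice,
#' [cluster_candidates_3d()], and [refine_cluster_otsu()] per cluster.
#' Refinement may split a rough cluster; each refined 26-component with at
#' least `min_voxels` voxels becomes its own cluster, re-numbered
#' consecutively.
#'
#' @param aiu 3D a.i.u. array.
#' @param cell_volume 3D logical array from [segment_cell_stack()].
#' @param lowpass_sigma,roberts_k See [detect_np_candidates()].
#' @param margin_xy,margin_z See [refine_cluster_otsu()].
#' @param min_voxels Minimum cluster size in voxels.
#' @return List of refined `np_cluster` objects.
#' @export
detect_np_clusters <- function(aiu, cell_volume, lowpass_sigma = 1.5,
                               roberts_k = 3, margin_xy = 5, margin_z = 3,
                               min_voxels = 4) {
  d <- dim(aiu)
  cand <- array(FALSE, d)
  for (k in seq_len(d[3])) {
    if (!any(cell_volume[, , k])) next
    cand[, , k] <- detect_np_candidates(aiu[, , k], cell_volume[, , k],
                                        lowpass_sigma, roberts_k)
  }
  rough <- cluster_candidates_3d(cand, aiu, min_voxels = min_voxels)
  refined <- lapply(rough, function(cl) {
    refine_cluster_otsu(aiu, cl, margin_xy, margin_z, cell_volume)
  })
  if (length(refined) == 0) return(list())
  # refinement boxes overlap, and the subsurface glow of one particle may
  # have seeded a second rough cluster: merge everything back through one
  # connected-component pass over the union of refined voxels
  un <- array(FALSE, d)
  for (cl in refined) un[cl$voxels] <- TRUE
  lab <- label_components_3d(un)
  out <- list()
  for (i in seq_len(max(lab))) {
    vox <- voxel_coords(lab == i)
    if (nrow(vox) < min_voxels) next
    out[[length(out) + 1L]] <- new_np_cluster(length(out) + 1L, vox, aiu)
  }
  out
}
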