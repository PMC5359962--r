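# Cell segmentation: trench-anchored lower boundary, thresholding of the
# homogeneous cell matrix, repair of notches carved by bright particles at
# the boundary, boundary extension and smoothing.

#' Locate the cell/substrate interface from the milled trench
#'
#' The ion beam digs a dark trench into the substrate below the cell which
#' moves along with the slicing plane, providing a reliable anchor for the
#' lower boundary of the cell in every slice. For each column, the interface
#' is taken at the strongest downward intensity transition below the image
#' midline (more precisely, the deepest transition of comparable strength,
#' so a bright particle sitting just above the substrate does not hijack
#' the boundary), then median-smoothed across columns.
#'
#' @param image Numeric matrix (one slice).
#' @param search_frac Fraction of the image height above which no boundary
#'   is searched (default 0.45: only the lower ~55% is scanned).
#' @param min_drop Minimum intensity drop, as a fraction of the robust
#'   slice intensity range, for a transition to count (default 0.05). A
#'   slice with no such transition has no trench and raises an error.
#' @return Integer vector, one entry per column: the row index of the first
#'   substrate row below the cell.
#' @export
detect_trench <- function(image, search_frac = 0.45, min_drop = 0.05) {
  d <- dim(image)
  sm <- box_stats(image, 5)$mean  # suppress pixel noise before differencing
  rng <- diff(stats::quantile(sm, c(0.01, 0.99), names = FALSE))
  if (rng <= 1e-9) stop("flat image: no trench transition found")
  lag <- 5L  # span the smoothing window so a 1-row step yields its full height
  r0 <- max(1L, as.integer(floor(d[1] * search_frac)))
  rows <- r0:(d[1] - lag)
  if (length(rows) < 2) stop("image too small for trench search")
  seg <- sm[rows + lag, , drop = FALSE] - sm[rows, , drop = FALSE]  # drop < 0
  strongest <- apply(seg, 2, min)
  # a genuine interface must stand out against both the slice's intensity
  # range and the fluctuation level of the differenced profile itself
  floor_drop <- max(min_drop * rng, 5 * stats::mad(as.vector(seg)))
  if (stats::median(strongest) > -floor_drop) {
    stop("no substrate transition found below the midline")
  }
  # smooth across columns only, keeping the row profile sharp for refinement
  csm <- EBImage::filter2(image, matrix(1 / 5, 1, 5), boundary = "replicate")
  boundary <- integer(d[2])
  for (j in seq_len(d[2])) {
    cand <- which(seg[, j] <= 0.35 * strongest[j] &
                    seg[, j] <= -floor_drop)
    if (length(cand) == 0) cand <- which.min(seg[, j])
    r_star <- rows[max(cand)]
    # the steepest single-row transition inside the drop window is the
    # interface; the window extends slightly above r_star because partial
    # drops on the ramp can push the deepest candidate past the step
    rr <- max(r0, r_star - 2L):min(r_star + lag, d[1] - 1L)
    boundary[j] <- rr[which.min(csm[rr + 1L, j] - csm[rr, j])] + 1L
  }
  if (d[2] >= 9) boundary <- as.integer(round(stats::runmed(boundary, 9)))
  boundary
}

#' Segment the cell cross-section in one slice
#'
#' Steps: (1) 2-class Otsu threshold on the region above the trench,
#' separating resin background from the homogeneous cell matrix; (2) clip
#' below the trench; (3) repair notches: bright particle-level blobs that
#' touch the mask boundary are absorbed by stepwise local growth until the
#' newly added ring is back at the surrounding matrix level; (4) extend the
#' boundary by `extension_px` (the smooth upper cell boundary has no sharp
#' edge, so the mask is deliberately grown to be sure the whole cell is
#' inside); (5) smooth the boundary by convolution with a normalized disc
#' and re-threshold at 0.5. A slice whose resin/matrix contrast is too weak
#' for thresholding (Otsu between-class variance below `contrast_min` of the
#' slice variance) is returned empty with `below_contrast_limit` set.
#'
#' @param image Numeric matrix; should already be noise-filtered (see
#'   [denoise_wiener()]).
#' @param trench Row profile from [detect_trench()] for the same slice.
#' @param extension_px Boundary extension radius in pixels (default 10).
#' @param smooth_radius_px Radius of the smoothing disc (default 5).
#' @param notch_tolerance Relative tolerance for the ring-mean stop rule of
#'   the notch repair (default 0.1).
#' @param max_notch_steps Growth-step bound guaranteeing termination.
#' @param contrast_min Minimum fraction of slice variance the threshold must
#'   explain (default 0.05).
#' @param contrast_sep Minimum separation of the two Otsu class means in
#'   units of the pooled within-class spread (default 4); Otsu applied to
#'   plain noise reaches about 3, a genuine resin/matrix step is well
#'   above.
#' @param min_area_px Minimum mask area in pixels for a slice to count as
#'   segmentable (default 400): a sliver cross-section at the front or rear
#'   of the cell carries too few matrix pixels for reliable background
#'   statistics and is flagged instead.
#' @param threshold Optional fixed threshold overriding Otsu.
#' @return A list of class `cell_mask`: `mask` (logical matrix),
#'   `below_contrast_limit`, `notch_repaired`, `threshold`.
#' @export
segment_cell_slice <- function(image, trench,
                               extension_px = 10,
                               smooth_radius_px = 5,
                               notch_tolerance = 0.1,
                               max_notch_steps = 30,
                               contrast_min = 0.05,
                               contrast_sep = 4,
                               min_area_px = 400,
                               threshold = NULL) {
  d <- dim(image)
  if (length(trench) != d[2]) stop("trench profile does not match the image width")
  above <- outer(seq_len(d[1]), trench, `<`)
  # contrast is judged a guard band above the interface: a slice without a
  # cell must not pass on resin/substrate contrast leaking across a trench
  # boundary that is off by a row or two
  vals <- image[outer(seq_len(d[1]), trench - 5L, `<`)]
  empty <- function() {
    structure(list(mask = matrix(FALSE, d[1], d[2]), below_contrast_limit = TRUE,
                   notch_repaired = FALSE, threshold = NA_real_),
              class = "cell_mask")
  }
  if (length(vals) < 16) return(empty())
  ot <- otsu_thresholds(vals, k = 2)
  if (is.null(threshold)) {
    if (ot$degenerate || ot$bcv_frac < contrast_min) return(empty())
    # bimodality: the between-class variance fraction alone cannot tell a
    # resin/matrix step from plain noise (splitting a Gaussian at its mean
    # already explains ~2/pi of the variance), so additionally require the
    # class means to separate by several within-class spreads
    lo <- vals[vals < ot$thresholds]
    hi <- vals[vals >= ot$thresholds]
    s_w <- sqrt((stats::var(lo) + stats::var(hi)) / 2)
    # s_w of 0 with distinct class means is perfect (noise-free) contrast
    if (!is.finite(s_w) ||
        (mean(hi) - mean(lo)) < contrast_sep * s_w) return(empty())
    threshold <- ot$thresholds
  }
  mask <- image >= threshold & above
  if (!any(mask)) return(empty())
  mask <- largest_component_2d(mask)

  # notch repair: particle-level blobs at the boundary get absorbed
  notch_repaired <- FALSE
  ot3 <- otsu_thresholds(vals, k = 3)
  if (!ot3$degenerate && ot3$thresholds[2] > threshold) {
    bright <- image >= ot3$thresholds[2]
    k3 <- EBImage::makeBrush(3, "box")
    # particle-level blobs within 2 px of the boundary threaten a notch
    boundary_zone <- (EBImage::dilate(mask * 1, EBImage::makeBrush(5, "box")) > 0) &
      !EBImage::erode(mask * 1, EBImage::makeBrush(5, "box"))
    if (any(bright & boundary_zone)) {
      notch_repaired <- TRUE
      matrix_level <- stats::median(image[mask & !bright])
      if (!is.finite(matrix_level)) matrix_level <- stats::median(image[mask])
      for (step in seq_len(max_notch_steps)) {
        ring <- (EBImage::dilate(mask * 1, k3) > 0) & !mask & above
        if (!any(ring)) break
        # stop once the boundary neighborhood is back at the matrix level
        if (abs(mean(image[ring]) - matrix_level) <=
              notch_tolerance * abs(matrix_level) + .Machine$double.eps) break
        # advance into bright pixels and their immediate neighborhood, so a
        # one-pixel dip between boundary and particle does not stall the
        # repair
        grow <- ring & (EBImage::dilate(bright * 1, k3) > 0)
        if (!any(grow)) break
        mask[grow] <- TRUE
        notch_repaired <- TRUE
      }
    }
  }
  pre_extension <- mask
  # judge the cross-section size before the deliberate boundary extension:
  # dilation must not promote a sliver (or a stray glow disc on a cell-free
  # slice) past the minimum area
  if (sum(pre_extension) < min_area_px) return(empty())

  if (extension_px > 0) {
    mask <- EBImage::dilate(mask * 1, EBImage::makeBrush(2L * as.integer(extension_px) + 1L,
                                                         "disc")) > 0
  }
  if (smooth_radius_px > 0) {
    br <- EBImage::makeBrush(2L * as.integer(smooth_radius_px) + 1L, "disc")
    sm <- EBImage::filter2(mask * 1, br / sum(br), boundary = "replicate")
    mask <- sm >= 0.5
  }
  mask <- (mask | pre_extension) & above  # superset of pre-extension mask, clipped at trench
  mask <- largest_component_2d(mask)
  mask <- EBImage::fillHull(mask * 1) > 0
  if (sum(mask) < min_area_px) return(empty())

  structure(list(mask = mask, below_contrast_limit = FALSE,
                 notch_repaired = notch_repaired, threshold = threshold),
            class = "cell_mask")
}

#' Segment the cell across the whole stack
#'
#' Runs [detect_trench()] and [segment_cell_slice()] on every slice (after
#' an optional adaptive noise filter) and assembles the per-slice masks into
#' a 3D cell volume. Slices without a detectable trench or with contrast
#' below the limit are left empty and flagged.
#'
#' @param stack An [image_stack()], already registered and tilt-corrected.
#' @param wiener_window Window of the noise filter applied before
#'   thresholding; 0 disables.
#' @param level_consistency Detector settings are fixed during a
#'   slice-and-view acquisition, so the matrix level inside the mask must
#'   agree across slices; a slice whose masked median deviates from the
#'   stack-wide median by more than this fraction (default 0.25) has locked
#'   onto the wrong material (e.g. resin at a tangent cross-section) and is
#'   flagged instead.
#' @param ... Passed to [segment_cell_slice()].
#' @return A list: `masks` (list of `cell_mask`), `volume` (3D logical
#'   array), `flagged_fraction` (fraction of slices below the contrast
#'   limit).
#' @export
segment_cell_stack <- function(stack, wiener_window = 5,
                               level_consistency = 0.25, ...) {
  n <- length(stack$slices)
  masks <- vector("list", n)
  empty_mask <- function(im) {
    structure(list(mask = matrix(FALSE, nrow(im), ncol(im)),
                   below_contrast_limit = TRUE,
                   notch_repaired = FALSE, threshold = NA_real_),
              class = "cell_mask")
  }
  for (k in seq_len(n)) {
    im <- stack$slices[[k]]
    if (wiener_window >= 3) im <- denoise_wiener(im, wiener_window)
    tr <- tryCatch(detect_trench(im), error = function(e) NULL)
    masks[[k]] <- if (is.null(tr)) empty_mask(im) else
      segment_cell_slice(im, tr, ...)
  }
  if (level_consistency > 0) {
    lev <- vapply(seq_len(n), function(k) {
      m <- masks[[k]]$mask
      if (!any(m)) NA_real_ else stats::median(stack$slices[[k]][m])
    }, numeric(1))
    ref <- stats::median(lev, na.rm = TRUE)
    if (is.finite(ref) && ref != 0) {
      off <- which(is.finite(lev) & abs(lev - ref) > level_consistency * abs(ref))
      for (k in off) masks[[k]] <- empty_mask(stack$slices[[k]])
    }
  }
  volume <- slices_to_array(lapply(masks, `[[`, "mask"))
  flagged <- vapply(masks, `[[`, logical(1), "below_contrast_limit")
  list(masks = masks, volume = volume, flagged_fraction = mean(flagged))
}
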