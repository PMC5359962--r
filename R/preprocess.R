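# Preprocessing: drift registration, tilt correction, denoising.

#' Estimate per-slice drift by cross-correlation
#'
#' The shift between each pair of consecutive slices is the location of the
#' maximum of their 2D cross-correlation (computed by FFT on mean-subtracted
#' images to avoid locking onto the DC component). Shifts are integer pixels;
#' set `subpixel = TRUE` for a parabolic refinement of the correlation peak
#' (rounded shifts are still returned, the refined values are attached as an
#' attribute). The returned trace is the cumulative shift of every slice
#' relative to the first.
#'
#' @param stack An [image_stack()] with at least 2 slices.
#' @param subpixel Refine the correlation peak by parabolic interpolation.
#' @param min_ncc Minimum normalized correlation at the peak for a pair to
#'   count as registered (default 0.2): a pair of featureless slices has no
#'   usable peak, and a random one would corrupt the cumulative trace.
#' @param max_step Largest plausible pairwise shift in pixels (default 10);
#'   a correlation peak beyond it is treated as a degenerate ridge and the
#'   smallest near-maximal shift is taken instead.
#' @return A `drift_trace`: integer matrix with columns `dr`, `dc` (rows,
#'   columns) and one row per slice; first row is (0, 0). A constant or
#'   featureless slice cannot be registered: its pairwise shift is (0, 0)
#'   and its index is recorded in `attr(, "flat_slices")`.
#' @export
estimate_drift <- function(stack, subpixel = FALSE, min_ncc = 0.2,
                           max_step = 10) {
  n <- length(stack$slices)
  if (n < 2) stop("drift estimation needs at least 2 slices")
  pair <- matrix(0, n, 2)
  sub <- matrix(0, n, 2)
  flat <- integer(0)
  for (k in 2:n) {
    a <- stack$slices[[k - 1]]
    b <- stack$slices[[k]]
    if (sd(a) == 0 || sd(b) == 0) {
      flat <- c(flat, k)
      next
    }
    cc <- cross_correlate(a - mean(a), b - mean(b))
    # cc peaks at ~ N * cov at the best alignment; normalize to a correlation
    ncc <- max(cc) / (stats::sd(a) * stats::sd(b) * length(a))
    if (ncc < min_ncc) {
      flat <- c(flat, k)
      next
    }
    d <- dim(cc)
    wrap <- function(v, n) ifelse(v > n / 2, v - n, v)
    pk <- arrayInd(which.max(cc), d)
    if (abs(wrap(pk[1] - 1L, d[1])) > max_step ||
        abs(wrap(pk[2] - 1L, d[2])) > max_step) {
      # an implausibly large jump means the peak is a flat ridge (structure
      # invariant along one axis, e.g. the substrate edge) or noise; among
      # near-maximal entries take the smallest shift instead
      near <- which(cc >= max(cc) - 0.01 * abs(max(cc)))
      pos <- arrayInd(near, d)
      drs <- wrap(pos[, 1] - 1L, d[1])
      dcs <- wrap(pos[, 2] - 1L, d[2])
      best <- which.min(abs(drs) + abs(dcs))
      pk <- pos[best, , drop = TRUE]
    }
    drs <- wrap(pk[1] - 1L, d[1])
    dcs <- wrap(pk[2] - 1L, d[2])
    best <- 1L
    # correlation peak location is the shift of the earlier slice relative
    # to the later one; report the later slice's shift
    dr <- -drs[best]
    dc <- -dcs[best]
    pair[k, ] <- c(dr, dc)
    sub[k, ] <- c(dr, dc)
    if (subpixel) {
      sub[k, ] <- pair[k, ] - parabolic_offset(cc, pk)
    }
  }
  trace <- apply(pair, 2, cumsum)
  if (n == 2) trace <- matrix(trace, 2, 2, byrow = FALSE)
  colnames(trace) <- c("dr", "dc")
  structure(trace, class = "drift_trace", flat_slices = flat,
            subpixel = apply(sub, 2, cumsum))
}

cross_correlate <- function(a, b) {
  fa <- stats::fft(a)
  fb <- stats::fft(b)
  Re(stats::fft(fa * Conj(fb), inverse = TRUE)) / length(a)
}

parabolic_offset <- function(cc, pk) {
  d <- dim(cc)
  off <- numeric(2)
  for (ax in 1:2) {
    i0 <- pk[ax]
    im <- ((i0 - 2) %% d[ax]) + 1L
    ip <- (i0 %% d[ax]) + 1L
    y <- if (ax == 1) c(cc[im, pk[2]], cc[i0, pk[2]], cc[ip, pk[2]])
         else c(cc[pk[1], im], cc[pk[1], i0], cc[pk[1], ip])
    den <- y[1] - 2 * y[2] + y[3]
    if (abs(den) > .Machine$double.eps) off[ax] <- 0.5 * (y[1] - y[3]) / den
  }
  off
}

#' Undo estimated drift
#'
#' Each slice is translated by the negative of its trace entry; pixels that
#' enter the frame are filled with the slice's background median, which avoids
#' spurious edges in the downstream thresholding. Geometry is unchanged.
#'
#' @param stack An [image_stack()].
#' @param trace A `drift_trace` from [estimate_drift()] (or any integer
#'   matrix with one (dr, dc) row per slice).
#' @return The registered [image_stack()].
#' @export
apply_drift_correction <- function(stack, trace) {
  n <- length(stack$slices)
  if (nrow(trace) != n) stop("drift trace length does not match the stack")
  slices <- vector("list", n)
  for (k in seq_len(n)) {
    s <- stack$slices[[k]]
    dr <- as.integer(round(trace[k, 1]))
    dc <- as.integer(round(trace[k, 2]))
    slices[[k]] <- if (dr == 0 && dc == 0) s else
      translate_image(s, -dr, -dc, fill = median(s))
  }
  image_stack(slices, stack$geometry, stack$provenance)
}

#' Correct the tilted-view foreshortening
#'
#' SEM images of the cut face are acquired at an angle to the face normal, so
#' the vertical axis appears compressed by `cos(view_angle)`. This rescales
#' the vertical axis by `1/cos(view_angle)` with linear interpolation and
#' updates `pixel_size_y` so the physical height of every object is
#' preserved; the geometry's `view_angle` is set to 0. With `convention =
#' "sin"` the alternative reading of the acquisition angle (angle measured to
#' the beam rather than the normal) is applied; `"none"` disables the
#' correction.
#'
#' @param stack An [image_stack()].
#' @param convention `"cos"` (default), `"sin"` or `"none"`.
#' @return The corrected [image_stack()] (identity when the angle is 0).
#' @export
correct_view_angle <- function(stack, convention = c("cos", "sin", "none")) {
  convention <- match.arg(convention)
  theta <- stack$geometry$view_angle
  if (theta >= 90) stop("view_angle must be below 90 degrees")
  if (convention == "none" || theta == 0) return(stack)
  f <- switch(convention,
              cos = cos(theta * pi / 180),
              sin = sin(theta * pi / 180))
  if (f <= 0) stop("degenerate view angle")
  d <- dim(stack$slices[[1]])
  new_h <- max(2L, as.integer(round(d[1] / f)))
  # target row i samples source position (i - 0.5) * f + 0.5 (pixel centers)
  src <- (seq_len(new_h) - 0.5) * (d[1] / new_h) + 0.5 - 0.5
  i0 <- pmin(pmax(floor(src), 1L), d[1] - 1L)
  w <- pmin(pmax(src - i0, 0), 1)
  slices <- lapply(stack$slices, function(s) {
    s[i0, , drop = FALSE] * (1 - w) + s[i0 + 1L, , drop = FALSE] * w
  })
  g <- stack$geometry
  geom <- voxel_geometry(g$pixel_size_x, g$pixel_size_y * d[1] / new_h,
                         g$slice_thickness, 0)
  image_stack(slices, geom, stack$provenance)
}

#' Adaptive (local-statistics) noise filter
#'
#' Wiener-style filter driven by local window statistics: pixels in windows
#' whose variance is at the noise level are replaced by the local mean, while
#' high-variance structure (edges, particles) is left intact. The noise power
#' is estimated as the mean of the local variances. Mean intensity is
#' preserved to well within 1%.
#'
#' @param image Numeric matrix.
#' @param window Odd window size in pixels (default 5).
#' @return Filtered matrix of the same size.
#' @export
denoise_wiener <- function(image, window = 5) {
  if (window %% 2 != 1 || window < 3) stop("window must be odd and >= 3")
  if (window > min(dim(image))) stop("window larger than image")
  st <- box_stats(image, window)
  noise <- mean(st$var)
  den <- pmax(st$var, noise)
  gain <- ifelse(den > 0, pmax(st$var - noise, 0) / den, 0)
  st$mean + gain * (image - st$mean)
}

#' Gaussian low-pass filter
#'
#' Smooths with a Gaussian kernel of the stated standard deviation (circular
#' boundary, so total intensity is preserved). Used before edge detection to
#' enhance particle edges over pixel noise. A sigma below 0.3 px is treated
#' as identity.
#'
#' @param image Numeric matrix.
#' @param sigma Gaussian standard deviation in pixels.
#' @return Filtered matrix.
#' @export
lowpass <- function(image, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  if (sigma < 0.3) return(image)
  EBImage::gblur(image, sigma = sigma)
}
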