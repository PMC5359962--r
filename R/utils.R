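# Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Robust standard deviation (MAD, normal-consistent)
#' @noRd
robust_sd <- function(x) stats::mad(x, constant = 1.4826)

#' Integer translation of a matrix with constant fill
#'
#' Content moves by `dr` rows (down if positive) and `dc` columns (right if
#' positive); pixels shifted in from outside get `fill`.
#' @noRd
translate_image <- function(im, dr, dc, fill = 0) {
  d <- dim(im)
  out <- matrix(fill, d[1], d[2])
  sr <- max(1, 1 - dr):min(d[1], d[1] - dr)
  sc <- max(1, 1 - dc):min(d[2], d[2] - dc)
  if (length(sr) < 1 || length(sc) < 1 || sr[1] > sr[length(sr)]) return(out)
  out[sr + dr, sc + dc] <- im[sr, sc, drop = FALSE]
  out
}

#' Local mean and variance over a square window (edge-replicated)
#' @noRd
box_stats <- function(im, window) {
  k <- matrix(1 / window^2, window, window)
  m <- EBImage::filter2(im, k, boundary = "replicate")
  m2 <- EBImage::filter2(im^2, k, boundary = "replicate")
  list(mean = m, var = pmax(m2 - m^2, 0))
}

#' Otsu thresholding with 1 or 2 thresholds (2 or 3 classes)
#'
#' Exhaustive maximization of the between-class variance over a fixed-bin
#' histogram. Returns the thresholds (bin centers), the fraction of the total
#' variance explained between classes, and a degeneracy flag (raised when the
#' sample is essentially unimodal/constant).
#' @noRd
otsu_thresholds <- function(x, k = 2, nbins = 128) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (length(x) < 4 || diff(rng) <= 0) {
    return(list(thresholds = rep(rng[1], k - 1), bcv_frac = 0, degenerate = TRUE))
  }
  br <- seq(rng[1], rng[2], length.out = nbins + 1)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  centers <- (br[-1] + br[-length(br)]) / 2
  p <- h / sum(h)
  w <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[nbins]
  total_var <- sum(p * (centers - mu_t)^2)
  if (total_var <= 0) {
    return(list(thresholds = rep(centers[1], k - 1), bcv_frac = 0, degenerate = TRUE))
  }
  if (k == 2) {
    w1 <- w[-nbins]
    m1 <- mu[-nbins]
    valid <- w1 > 0 & w1 < 1
    bcv <- rep(-Inf, nbins - 1)
    bcv[valid] <- (mu_t * w1[valid] - m1[valid])^2 / (w1[valid] * (1 - w1[valid]))
    best <- max(bcv)
    # well-separated classes give a flat optimum between them: take the
    # plateau middle, not its first bin hugging the lower class
    plateau <- which(bcv >= best * (1 - 1e-9))
    i <- plateau[ceiling(length(plateau) / 2)]
    return(list(thresholds = centers[i], bcv_frac = best / total_var,
                degenerate = !is.finite(best)))
  }
  # k == 3: scan all pairs t1 < t2 using cumulative sums
  best <- -Inf
  opt <- matrix(integer(0), 0, 2)
  for (i in seq_len(nbins - 2)) {
    w1 <- w[i]
    if (w1 <= 0) next
    m1 <- mu[i] / w1
    j <- (i + 1):(nbins - 1)
    w2 <- w[j] - w1
    w3 <- 1 - w[j]
    ok <- w2 > 0 & w3 > 0
    if (!any(ok)) next
    m2 <- (mu[j] - mu[i]) / w2
    m3 <- (mu_t - mu[j]) / w3
    bcv <- w1 * (m1 - mu_t)^2 + w2 * (m2 - mu_t)^2 + w3 * (m3 - mu_t)^2
    bcv[!ok] <- -Inf
    jm <- max(bcv)
    if (jm > best * (1 + 1e-9) || nrow(opt) == 0) {
      best <- jm
      opt <- cbind(i, j[bcv >= jm * (1 - 1e-9)])
    } else if (jm >= best * (1 - 1e-9)) {
      opt <- rbind(opt, cbind(i, j[bcv >= jm * (1 - 1e-9)]))
    }
  }
  if (!is.finite(best)) {
    return(list(thresholds = rep(centers[1], 2), bcv_frac = 0, degenerate = TRUE))
  }
  # plateau middle for both thresholds (see the 2-class case)
  bi <- c(as.integer(round(stats::median(opt[, 1]))),
          as.integer(round(stats::median(opt[, 2]))))
  list(thresholds = centers[bi], bcv_frac = best / total_var, degenerate = FALSE)
}

#' 26-connected component labeling of a 3D logical array
#'
#' Breadth-first flood fill on a zero-padded copy; suitable for the sparse
#' foregrounds produced by NP candidate detection.
#' @noRd
label_components_3d <- function(mask) {
  d <- dim(mask)
  stopifnot(length(d) == 3)
  pd <- d + 2L
  pm <- array(FALSE, pd)
  pm[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  lab <- array(0L, pd)
  off <- as.matrix(expand.grid(dr = -1:1, dc = -1:1, ds = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  loff <- off[, 1] + pd[1] * off[, 2] + pd[1] * pd[2] * off[, 3]
  seeds <- which(pm)
  cur <- 0L
  for (s in seeds) {
    if (lab[s] > 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    frontier <- s
    while (length(frontier) > 0) {
      nb <- unique(as.vector(outer(frontier, loff, `+`)))
      nb <- nb[pm[nb] & lab[nb] == 0L]
      if (length(nb) > 0) lab[nb] <- cur
      frontier <- nb
    }
  }
  lab[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
}

#' Largest connected 2D component of a logical matrix (8-connectivity)
#' @noRd
largest_component_2d <- function(mask) {
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask * 1)
  tab <- tabulate(lab[lab > 0])
  mask & (lab == which.max(tab))
}

#' Voxel coordinates (row, col, slice) of TRUE entries of a 3D array
#' @noRd
voxel_coords <- function(mask) {
  w <- which(mask)
  arrayInd(w, dim(mask))
}

#' Stack a list of equally sized matrices into a 3D array (row, col, slice)
#' @noRd
slices_to_array <- function(slices) {
  d <- dim(slices[[1]])
  array(unlist(slices, use.names = FALSE), dim = c(d[1], d[2], length(slices)))
}

array_to_slices <- function(a) {
  lapply(seq_len(dim(a)[3]), function(k) a[, , k])
}
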