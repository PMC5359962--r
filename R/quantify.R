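# Quantification: per-cluster particle counts via the shading-corrected
# volume formula, whole-cell dose with uncertainty, cluster-size
# distribution, and mass-to-count conversion for ICP-MS cross-checks.

#' Detected volume and projected area of a cluster
#'
#' `V_c` is the accumulated a.i.u. over the cluster voxels (the detected
#' volume, glow included); `A_c` is the area in pixels of the union of the
#' cluster's per-slice footprints, i.e. the projection along the slicing
#' axis onto the cross-section plane. No tilt correction is applied to
#' `A_c`: secondary-electron escape is governed by the shortest path to the
#' cut face, which is normal to the cross-section plane.
#'
#' @param cluster A refined `np_cluster`.
#' @return Named numeric vector `c(V_c, A_c)`.
#' @export
cluster_metrics <- function(cluster) {
  if (nrow(cluster$voxels) == 0) stop("empty cluster")
  c(V_c = sum(cluster$aiu),
    A_c = nrow(unique(cluster$voxels[, 1:2, drop = FALSE])))
}

#' Particle count of a cluster (shading-corrected)
#'
#' The number of particles in a cluster follows from its detected volume
#' after subtracting the glow offset once per projected single-particle
#' footprint: \deqn{n_c = (V_c - V_s' A_c / A_s) / V_{s0}.} Particles lying
#' behind one another along the slicing axis share a footprint and their
#' glow is absorbed by the anterior particle (shading), so the offset scales
#' with the projected area `A_c` rather than with the particle number. The
#' projected particle number `n_p = A_c / A_s` is returned alongside.
#'
#' Uncertainty is first-order propagation over the calibration constants
#' (`V_s'`, `V_s0`, `A_s`); `V_c` and `A_c` are treated as exact.
#'
#' @param V_c Detected cluster volume, a.i.u. (vectorized).
#' @param A_c Projected cluster area, pixels (vectorized).
#' @param cal An `np_calibration`.
#' @return Data frame with `n_p`, `n_c` (clamped at 0) and `n_c_sd`.
#' @export
count_particles <- function(V_c, A_c, cal) {
  stopifnot(inherits(cal, "np_calibration"))
  if (any(!is.finite(V_c)) || any(!is.finite(A_c))) stop("non-finite cluster metrics")
  n_p <- A_c / cal$As_px
  raw <- (V_c - cal$Vs_offset * n_p) / cal$Vs0
  if (any(!is.finite(raw))) stop("non-finite particle count")
  n_c <- pmax(raw, 0)
  sd2 <- (n_p / cal$Vs0)^2 * cal$Vs_offset_sd^2 +
    (cal$Vs_offset * A_c / (cal$As_px^2 * cal$Vs0))^2 * cal$As_sd^2 +
    (raw / cal$Vs0)^2 * cal$Vs0_sd^2
  data.frame(n_p = n_p, n_c = n_c, n_c_sd = sqrt(sd2))
}

#' Cluster-size histogram and cumulative distribution
#'
#' Histogram of per-cluster particle counts with a fixed bin width, plus the
#' particle-weighted cumulative distribution: the CDF value at x is the
#' fraction of all *particles* residing in clusters of size <= x. Also
#' reports the particle-weighted fractions in small clusters (1-5 particles)
#' and large agglomerates (>= 20).
#'
#' @param counts Integer vector of per-cluster particle counts (zeros are
#'   dropped).
#' @param bin_width Histogram bin width in particles (default 10).
#' @return List of class `np_size_distribution`: `histogram` (data frame
#'   `bin_lo`, `bin_hi`, `n_clusters`), `cdf` (data frame `size`,
#'   `frac_particles`), `fraction_1_5`, `fraction_ge_20`, `n_clusters`,
#'   `n_particles`.
#' @export
size_distribution <- function(counts, bin_width = 10) {
  if (bin_width < 1) stop("bin_width must be >= 1")
  counts <- counts[counts > 0]
  if (length(counts) == 0) {
    return(structure(list(histogram = data.frame(bin_lo = integer(0),
                                                 bin_hi = integer(0),
                                                 n_clusters = integer(0)),
                          cdf = NULL, fraction_1_5 = NA_real_,
                          fraction_ge_20 = NA_real_, n_clusters = 0L,
                          n_particles = 0L, bin_width = bin_width,
                          empty = TRUE),
                     class = "np_size_distribution"))
  }
  nb <- ceiling(max(counts) / bin_width)
  lo <- (seq_len(nb) - 1L) * bin_width + 1L
  hi <- seq_len(nb) * bin_width
  bin <- findInterval(counts, c(lo, Inf))
  hist <- data.frame(bin_lo = lo, bin_hi = hi,
                     n_clusters = tabulate(bin, nb))
  sizes <- sort(unique(counts))
  total <- sum(counts)
  cdf <- data.frame(size = sizes,
                    frac_particles = vapply(sizes, function(s)
                      sum(counts[counts <= s]) / total, numeric(1)))
  structure(list(histogram = hist, cdf = cdf,
                 fraction_1_5 = sum(counts[counts <= 5]) / total,
                 fraction_ge_20 = sum(counts[counts >= 20]) / total,
                 n_clusters = length(counts), n_particles = total,
                 bin_width = bin_width, empty = FALSE),
            class = "np_size_distribution")
}

#' Whole-cell absolute dose
#'
#' Sums the per-cluster counts into the total number of particles in the
#' cell. Counts are rounded per cluster to the nearest integer (clusters
#' with `n_c > 0.5` count at least 1); the unrounded total is reported as
#' well. The uncertainty treats the calibration constants as fully
#' correlated across clusters — they all come from the one calibration — by
#' propagating through the total \deqn{N = (\sum V_c - V_s' \sum A_c / A_s)
#' / V_{s0},} which makes the relative uncertainty of `N` at least that of
#' `V_s0`.
#'
#' @param clusters Either a list of refined `np_cluster` objects or a data
#'   frame with columns `V_c` and `A_c`.
#' @param cal An `np_calibration`.
#' @param bin_width Histogram bin width for the size distribution.
#' @return An object of class `dose_report`: `N` (integer total), `N_sd`,
#'   `N_fractional`, `clusters` (per-cluster table), `distribution` (see
#'   [size_distribution()]), `calibration`.
#' @export
total_dose <- function(clusters, cal = NULL, bin_width = 10) {
  if (is.data.frame(clusters)) {
    tab <- clusters
    if (is.null(tab$id)) tab$id <- seq_len(nrow(tab))
    if (is.null(tab$voxel_count)) tab$voxel_count <- NA_integer_
  } else {
    tab <- do.call(rbind, lapply(clusters, function(cl) {
      m <- cluster_metrics(cl)
      data.frame(id = cl$id, voxel_count = nrow(cl$voxels),
                 V_c = m[["V_c"]], A_c = m[["A_c"]])
    }))
    if (is.null(tab)) tab <- data.frame(id = integer(0), voxel_count = integer(0),
                                        V_c = numeric(0), A_c = numeric(0))
  }
  if (nrow(tab) > 0) {
    if (is.null(cal)) stop("a calibration is required when clusters are present")
    cnt <- count_particles(tab$V_c, tab$A_c, cal)
    tab <- cbind(tab, cnt)
    tab$n_int <- ifelse(tab$n_c > 0.5, pmax(1L, as.integer(floor(tab$n_c + 0.5))), 0L)
    # correlated propagation through the totals: the calibration constants
    # are shared by every cluster
    SV <- sum(tab$V_c); SA <- sum(tab$A_c)
    np_tot <- SA / cal$As_px
    raw_tot <- (SV - cal$Vs_offset * np_tot) / cal$Vs0
    N_sd <- sqrt((np_tot / cal$Vs0)^2 * cal$Vs_offset_sd^2 +
                   (cal$Vs_offset * SA / (cal$As_px^2 * cal$Vs0))^2 * cal$As_sd^2 +
                   (raw_tot / cal$Vs0)^2 * cal$Vs0_sd^2)
  } else {
    tab$n_p <- tab$n_c <- tab$n_c_sd <- numeric(0)
    tab$n_int <- integer(0)
    N_sd <- 0
  }
  N <- sum(tab$n_int)
  N_frac <- sum(tab$n_c)
  structure(list(N = N, N_sd = N_sd, N_fractional = N_frac,
                 clusters = tab,
                 distribution = size_distribution(tab$n_int, bin_width),
                 calibration = cal),
            class = "dose_report")
}

#' @export
print.dose_report <- function(x, ...) {
  cat(sprintf("Absolute NP dose: %d +- %.0f particles in %d clusters\n",
              x$N, x$N_sd, nrow(x$clusters)))
  if (!x$distribution$empty) {
    cat(sprintf("  fraction in clusters of 1-5 particles: %.1f%%\n",
                100 * x$distribution$fraction_1_5))
    cat(sprintf("  fraction in clusters of >= 20 particles: %.1f%%\n",
                100 * x$distribution$fraction_ge_20))
  }
  invisible(x)
}

#' @export
summary.dose_report <- function(object, ...) {
  print(object)
  cat(sprintf("  unrounded total: %.2f\n", object$N_fractional))
  if (nrow(object$clusters) > 0) {
    cat("\nLargest clusters:\n")
    o <- order(object$clusters$n_c, decreasing = TRUE)
    print(head(object$clusters[o, c("id", "voxel_count", "V_c", "A_c", "n_p",
                                    "n_c", "n_int")], 10),
          digits = 3, row.names = FALSE)
  }
  invisible(object)
}

#' Plot a dose report: cluster-size histogram with particle-weighted CDF
#'
#' Left axis: number of clusters per size bin; right axis: cumulative
#' fraction of all particles in clusters up to that size.
#'
#' @param x A `dose_report`.
#' @param ... Ignored.
#' @export
plot.dose_report <- function(x, ...) {
  d <- x$distribution
  if (d$empty) {
    plot.new()
    mtext("no clusters detected")
    return(invisible(x))
  }
  op <- par(mar = c(5, 4, 2, 4))
  on.exit(par(op))
  bp <- barplot(d$histogram$n_clusters,
                names.arg = sprintf("%d-%d", d$histogram$bin_lo, d$histogram$bin_hi),
                xlab = "cluster size (particles)", ylab = "clusters",
                col = "grey70", border = NA)
  step <- if (nrow(d$histogram) > 1) diff(bp[1:2]) else 1.2
  mids <- (d$histogram$bin_lo + d$histogram$bin_hi) / 2
  sc <- function(s) bp[1] + (s - mids[1]) / d$bin_width * step
  ymax <- max(d$histogram$n_clusters)
  lines(sc(d$cdf$size), d$cdf$frac_particles * ymax, type = "s", lwd = 2,
        col = "firebrick")
  axis(4, at = seq(0, ymax, length.out = 5),
       labels = sprintf("%.2f", seq(0, 1, length.out = 5)))
  mtext("cumulative particle fraction", side = 4, line = 2.5)
  invisible(x)
}

#' Convert an element mass per cell into a particle count
#'
#' Helper for cross-checking the imaging-based dose against bulk elemental
#' analysis (ICP-MS): divides the measured mass per cell by the mass of one
#' spherical particle, `density * pi d^3 / 6`.
#'
#' @param mass_per_cell_g Mass per cell in grams.
#' @param diameter_nm Particle diameter in nm (default 74).
#' @param density_g_cm3 Bulk density in g/cm^3 (default 10.49, silver).
#' @return Particles per cell (fractional values are reported as-is).
#' @export
icpms_mass_to_count <- function(mass_per_cell_g, diameter_nm = 74,
                                density_g_cm3 = 10.49) {
  if (any(c(mass_per_cell_g, diameter_nm, density_g_cm3) <= 0)) {
    stop("all inputs must be positive")
  }
  particle_mass_g <- density_g_cm3 * sphere_volume_nm3(diameter_nm) * 1e-21
  mass_per_cell_g / particle_mass_g
}

#' Volume of a sphere from its diameter, in nm^3
#' @param diameter_nm Diameter in nm.
#' @return Volume in nm^3.
#' @export
sphere_volume_nm3 <- function(diameter_nm) pi * diameter_nm^3 / 6
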