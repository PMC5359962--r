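# Calibration from isolated single particles: secondary-electron escape
# depth, detected/offset/actual single-particle volumes, projected area.

#' Extract the per-slice intensity profile of a single particle
#'
#' For every slice in and around the cluster, records the maximum a.i.u.
#' within the cluster's projected footprint, extending backwards through the
#' pre-exposure slices (the subsurface glow) down to the noise floor. The
#' profile of a buried sphere rises exponentially as the cut face approaches
#' its surface, saturates at the particle level while the face cuts through
#' it, and drops once it has been milled away — the rising branch carries
#' the escape depth.
#'
#' @param aiu 3D a.i.u. array.
#' @param cluster An `np_cluster` that passed the single-particle screen.
#' @param noise_floor Minimum a.i.u. for a profile point (default 3, i.e.
#'   roughly 3 background sigmas by construction of a.i.u.). For
#'   `stat = "mean"` the floor is rescaled by the footprint size, since
#'   averaging suppresses the noise.
#' @param max_back Maximum number of pre-cluster slices to search.
#' @param stat Per-slice statistic over the footprint: `"max"` (default,
#'   the brightest pixel), `"median"` (median over the central half-radius
#'   of the footprint) or `"mean"`. All decay with the same exponential as
#'   the face approaches the particle; the central median averages pixel
#'   noise away over a fixed pixel set close to the particle axis, making
#'   it the choice for fitting on noisy data, while the max estimates the
#'   exposed-particle level.
#' @return An object of class `single_np_profile`: data frame with `slice`
#'   and `intensity`, plus the footprint and noise floor as attributes.
#' @export
extract_profile <- function(aiu, cluster, noise_floor = 3, max_back = 10,
                            stat = c("max", "median", "mean")) {
  stat <- match.arg(stat)
  d <- dim(aiu)
  foot <- unique(cluster$voxels[, 1:2, drop = FALSE])
  k_in <- range(cluster$voxels[, 3])
  k0 <- max(1L, k_in[1] - max_back)
  ks <- k0:min(d[3], k_in[2] + 2L)
  if (stat == "median") {
    # restrict to the central half-radius: a fixed, well-covered pixel set
    cen <- colMeans(foot)
    rho <- sqrt((foot[, 1] - cen[1])^2 + (foot[, 2] - cen[2])^2)
    core <- foot[rho <= max(stats::median(rho), 1.5), , drop = FALSE]
    if (nrow(core) >= 5) foot <- core
  }
  idx_rc <- foot[, 1] + (foot[, 2] - 1L) * d[1]
  f <- switch(stat, max = max, median = stats::median, mean = mean)
  if (stat != "max") noise_floor <- max(noise_floor / sqrt(nrow(foot)), 0.2)
  prof <- vapply(ks, function(k) {
    f(aiu[idx_rc + (k - 1L) * d[1] * d[2]])
  }, numeric(1))
  keep <- prof > noise_floor
  if (any(keep)) {
    ks <- ks[min(which(keep)):max(which(keep))]
    prof <- prof[min(which(keep)):max(which(keep))]
  }
  if (length(ks) < 3) stop("fewer than 3 usable slices in the particle profile")
  structure(data.frame(slice = ks, intensity = prof),
            class = c("single_np_profile", "data.frame"),
            footprint = foot, noise_floor = noise_floor)
}

#' Fit the secondary-electron escape depth to a particle profile
#'
#' Log-linear least squares on the rising (pre-exposure) branch of the
#' profile: `I_k = I_0 * exp(-z_k / l)` with `z_k = (k_max - k) *
#' slice_thickness`, where `k_max` is the slice attaining the profile
#' maximum (first exposure of the particle surface). Only points strictly
#' before the maximum enter the fit — the maximum itself is clipped at the
#' exposed-particle level and would bias the slope whenever the particle
#' surface falls between two cut faces. At least 2 usable pre-maximum points
#' above the noise floor are required; with the slicing interval and escape
#' depth this package targets, 2-3 glow slices clear the floor.
#'
#' @param profile A `single_np_profile` (or data frame with `slice` and
#'   `intensity`).
#' @param slice_thickness nm per slice.
#' @param noise_floor Minimum a.i.u. for a point to enter the fit.
#' @param monotone_tol Relative tolerance for non-monotonicity of the rising
#'   branch (default 0.25); a branch that dips more than this is rejected.
#' @param plateau_frac First exposure is the first slice reaching this
#'   fraction of the profile maximum (default 0.7, safely above the
#'   one-slice glow attenuation for the slicing regimes this package
#'   targets); the plain argmax would land on whichever exposed slice the
#'   noise pushed highest.
#' @param k_exposure Optionally, the known first-exposure slice index
#'   (e.g. determined from the max-statistic profile when fitting a
#'   footprint-median profile, whose own maximum lags the true exposure).
#' @return Escape depth `l` in nm, with attributes `I0` (fitted intercept,
#'   a.i.u.) and `n_points`.
#' @export
fit_escape_depth <- function(profile, slice_thickness = 40,
                             noise_floor = attr(profile, "noise_floor") %||% 3,
                             monotone_tol = 0.25, plateau_frac = 0.7,
                             k_exposure = NULL) {
  k <- profile$slice
  I <- profile$intensity
  kmax <- if (!is.null(k_exposure)) k_exposure else
    k[min(which(I >= plateau_frac * max(I)))]
  rising <- which(k < kmax & I > noise_floor)
  if (length(rising) < 2) stop("need at least 2 pre-exposure points above the noise floor")
  Ir <- I[rising]
  if (any(diff(Ir) < -monotone_tol * Ir[-length(Ir)])) {
    stop("rising branch is non-monotone beyond tolerance")
  }
  z <- (kmax - k[rising]) * slice_thickness
  # trim leading points that fall off the common exponential: the deepest
  # glow of a particle near the cell surface travels partly through resin
  # and undershoots the matrix decay
  repeat {
    fit <- stats::lm(log(Ir) ~ z)
    if (length(Ir) <= 2) break
    res <- stats::residuals(fit)
    if (abs(res[1]) <= 0.08 || abs(res[1]) < max(abs(res[-1]))) break
    Ir <- Ir[-1]
    z <- z[-1]
  }
  slope <- coef(fit)[["z"]]
  if (!is.finite(slope) || slope >= 0) stop("escape-depth fit did not converge to l > 0")
  l <- -1 / slope
  attr(l, "I0") <- exp(coef(fit)[["(Intercept)"]])
  attr(l, "n_points") <- length(Ir)
  l
}

#' Screen clusters for isolated single particles
#'
#' Replaces the by-hand selection of reference particles with an automated
#' screen: a cluster qualifies as a single when (a) its projected area is
#' within `tolerance` of the expected single-particle footprint, (b) its
#' intensity profile has a single maximal plateau (one rising branch), and
#' (c) the plateau is no longer than one particle diameter of slices —
#' particles stacked along the slicing axis share the footprint of a single
#' but stay bright for twice as long. A manual id list overrides the screen
#' entirely.
#'
#' @param clusters List of refined `np_cluster` objects.
#' @param aiu 3D a.i.u. array.
#' @param A_expected Expected projected area in pixels (e.g. `pi * (d /
#'   2 / pixel_size)^2`).
#' @param tolerance Relative area tolerance (default 0.3).
#' @param diameter_nm,slice_thickness Used for the plateau-length screen.
#' @param noise_floor a.i.u. tolerance defining the maximal plateau.
#' @param manual Optional integer vector of cluster ids: selected as given,
#'   no screening.
#' @return The qualifying subset of `clusters` (possibly empty, in which
#'   case calibration must fall back to a manual list or defaults).
#' @export
select_single_nps <- function(clusters, aiu, A_expected, tolerance = 0.3,
                              diameter_nm = 74, slice_thickness = 40,
                              noise_floor = 3, manual = NULL) {
  if (!is.null(manual)) {
    ids <- vapply(clusters, `[[`, integer(1), "id")
    return(clusters[ids %in% manual])
  }
  max_plateau <- ceiling(diameter_nm / slice_thickness) + 1L
  keep <- vapply(clusters, function(cl) {
    A <- nrow(unique(cl$voxels[, 1:2, drop = FALSE]))
    if (abs(A - A_expected) > tolerance * A_expected) return(FALSE)
    prof <- tryCatch(extract_profile(aiu, cl, noise_floor = noise_floor),
                     error = function(e) NULL)
    if (is.null(prof)) return(FALSE)
    I <- prof$intensity
    top <- I >= max(I) - noise_floor
    runs <- rle(top)
    if (sum(runs$values) != 1) return(FALSE)        # one maximal plateau
    if (max(runs$lengths[runs$values]) > max_plateau) return(FALSE)
    TRUE
  }, logical(1))
  clusters[keep]
}

#' Calibrate single-particle constants from isolated particles
#'
#' For each reference single: the detected volume `V_s` is its accumulated
#' segmented a.i.u.; the offset volume `V_s'` is the part of `V_s`
#' contributed by the subsurface glow, measured per footprint pixel as the
#' accumulated a.i.u. strictly before that pixel's first exposure (the
#' first slice whose intensity reaches within `noise_floor` of the pixel's
#' maximum); the actual volume is `V_s0 = V_s - V_s'`, so `V_s = V_s0 +
#' V_s'` holds exactly. The escape depth `l` comes from
#' [fit_escape_depth()]; the projected area `A_s` is the footprint pixel
#' count. Per-particle values are aggregated as unweighted mean +- sample
#' sd. The closed-form alternative `V_s' = V_s * (1 - exp(-dz/l))` — the
#' glow fraction of a geometric intensity series with decay `exp(-dz/l)` —
#' is reported alongside under `Vs_offset_closed_form`.
#'
#' An a.i.u.-to-volume conversion is attached: dividing `V_s0` by the
#' exposed-particle intensity (the profile maximum) gives an equivalent
#' voxel count, which times the voxel volume estimates the physical particle
#' volume.
#'
#' @param aiu 3D a.i.u. array.
#' @param singles List of `np_cluster` objects (see [select_single_nps()]).
#' @param geometry A [voxel_geometry()].
#' @param noise_floor a.i.u. noise floor (default 3).
#' @param estimator `"empirical"` (default) or `"closed_form"`: which offset
#'   estimate populates `Vs_offset`/`Vs0` (the other is always reported).
#' @return An object of class `np_calibration`; see [np_calibration()] for
#'   the fields.
#' @export
calibrate <- function(aiu, singles, geometry = voxel_geometry(),
                      noise_floor = 3,
                      estimator = c("empirical", "closed_form")) {
  estimator <- match.arg(estimator)
  if (length(singles) < 1) stop("calibration needs at least one single particle")
  d <- dim(aiu)
  rows <- vector("list", length(singles))
  for (i in seq_along(singles)) {
    cl <- singles[[i]]
    Vs <- sum(cl$aiu)
    foot <- unique(cl$voxels[, 1:2, drop = FALSE])
    As <- nrow(foot)
    # per-pixel decomposition of Vs into glow (pre-exposure) and exposed part
    key <- paste(cl$voxels[, 1], cl$voxels[, 2])
    fkey <- paste(foot[, 1], foot[, 2])
    # exposure level: median over footprint pixels of the per-pixel maximum
    # (a plain max over the whole footprint rides on the noise extreme)
    pix_max <- vapply(seq_len(As), function(p) max(cl$aiu[key == fkey[p]]),
                      numeric(1))
    Imax <- stats::median(pix_max)
    Vglow <- 0
    for (p in seq_len(As)) {
      sel <- key == fkey[p]
      ksl <- cl$voxels[sel, 3]
      Ival <- cl$aiu[sel]
      o <- order(ksl)
      ksl <- ksl[o]; Ival <- Ival[o]
      # first exposure of this pixel: first slice at the particle's exposed
      # level; a rim pixel whose chord fell between two cut faces never
      # reaches it and is glow throughout
      hit <- which(Ival >= Imax - noise_floor)
      if (length(hit) == 0) {
        Vglow <- Vglow + sum(Ival)
      } else {
        Vglow <- Vglow + sum(Ival[ksl < ksl[min(hit)]])
      }
    }
    # escape depth from the footprint-median profile (noise-averaged, same
    # exponential decay as the per-pixel model, robust to partial coverage).
    # The first-exposure slice is taken from the max profile: once any pixel
    # is exposed the median mixes glow with exposed levels and its own
    # maximum lags the true exposure.
    lfit <- tryCatch({
      pmx <- extract_profile(aiu, cl, noise_floor = noise_floor, stat = "max")
      kexp <- pmx$slice[min(which(pmx$intensity >= 0.7 * max(pmx$intensity)))]
      pmed <- extract_profile(aiu, cl, noise_floor = noise_floor, stat = "median")
      list(l = as.numeric(fit_escape_depth(pmed, geometry$slice_thickness,
                                           k_exposure = kexp)),
           Imax = Imax)
    }, error = function(e) list(l = NA_real_, Imax = Imax))
    rows[[i]] <- data.frame(id = cl$id, Vs = Vs, Vs_offset_emp = Vglow,
                            As = As, l = lfit$l, Imax = lfit$Imax)
  }
  pp <- do.call(rbind, rows)
  pp$Vs_offset_cf <- pp$Vs * (1 - exp(-geometry$slice_thickness /
                                        ifelse(is.finite(pp$l), pp$l,
                                               mean(pp$l, na.rm = TRUE))))
  off <- if (estimator == "empirical") pp$Vs_offset_emp else pp$Vs_offset_cf
  if (all(!is.finite(off))) stop("all single-particle calibrations failed")
  pp$Vs0 <- pp$Vs - off
  pp$voxels_equiv <- pp$Vs0 / pp$Imax
  pp$volume_nm3 <- pp$voxels_equiv * voxel_volume_nm3(geometry)

  agg <- function(x) {
    x <- x[is.finite(x)]
    c(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else 0)
  }
  l_a <- agg(pp$l); Vs_a <- agg(pp$Vs); off_a <- agg(off)
  Vs0_a <- agg(pp$Vs0); As_a <- agg(pp$As)
  cf_a <- agg(pp$Vs_offset_cf)
  np_calibration(
    l_nm = l_a["mean"], l_sd = l_a["sd"],
    Vs = Vs_a["mean"], Vs_sd = Vs_a["sd"],
    Vs_offset = off_a["mean"], Vs_offset_sd = off_a["sd"],
    As_px = As_a["mean"], As_sd = As_a["sd"],
    n_ref = nrow(pp), estimator = estimator,
    Vs_offset_closed_form = cf_a["mean"],
    volume_nm3 = mean(pp$volume_nm3[is.finite(pp$volume_nm3)]),
    voxels_equiv = mean(pp$voxels_equiv[is.finite(pp$voxels_equiv)]),
    geometry = geometry, per_particle = pp
  )
}

#' Construct a single-particle calibration
#'
#' Builds an `np_calibration` from explicit constants — the route taken when
#' calibrating against published reference values instead of (or before)
#' measuring isolated particles in a stack. `Vs0` is derived as `Vs -
#' Vs_offset`, so the decomposition `Vs = Vs0 + Vs_offset` is exact by
#' construction.
#'
#' @param Vs Detected single-particle volume, a.i.u.
#' @param Vs_offset Offset (glow) volume, a.i.u.
#' @param As_px Projected single-particle area, pixels.
#' @param Vs_sd,Vs_offset_sd,As_sd,l_sd Uncertainties (sd).
#' @param Vs0_sd Uncertainty of the actual volume; by default derived from
#'   `Vs_sd` and `Vs_offset_sd` (or, when per-particle data are available,
#'   the empirical sd), but published constants may state it directly.
#' @param l_nm Escape depth, nm.
#' @param n_ref Number of reference particles behind the constants.
#' @param estimator,Vs_offset_closed_form,volume_nm3,voxels_equiv,geometry,per_particle
#'   Optional metadata filled by [calibrate()].
#' @return An object of class `np_calibration` with fields `l_nm`, `l_sd`,
#'   `Vs`, `Vs_sd`, `Vs_offset`, `Vs_offset_sd`, `Vs0`, `Vs0_sd`, `As_px`,
#'   `As_sd`, `n_ref`, `estimator`.
#' @export
np_calibration <- function(Vs, Vs_offset, As_px,
                           Vs_sd = 0, Vs_offset_sd = 0, As_sd = 0,
                           Vs0_sd = NULL,
                           l_nm = NA_real_, l_sd = 0, n_ref = 1L,
                           estimator = "explicit",
                           Vs_offset_closed_form = NA_real_,
                           volume_nm3 = NA_real_, voxels_equiv = NA_real_,
                           geometry = voxel_geometry(), per_particle = NULL) {
  Vs0 <- Vs - Vs_offset
  if (!all(c(Vs, As_px) > 0) || Vs0 <= 0) {
    stop("calibration constants must be positive and Vs_offset < Vs")
  }
  if (is.null(Vs0_sd)) {
    Vs0_sd <- sqrt(max(Vs_sd^2 - Vs_offset_sd^2, 0))
    # when aggregated from data, prefer the empirical spread of Vs0
    if (!is.null(per_particle)) Vs0_sd <- if (nrow(per_particle) > 1)
      stats::sd(per_particle$Vs0[is.finite(per_particle$Vs0)]) else 0
  }
  structure(list(l_nm = unname(l_nm), l_sd = unname(l_sd),
                 Vs = unname(Vs), Vs_sd = unname(Vs_sd),
                 Vs_offset = unname(Vs_offset), Vs_offset_sd = unname(Vs_offset_sd),
                 Vs0 = unname(Vs0), Vs0_sd = unname(Vs0_sd),
                 As_px = unname(As_px), As_sd = unname(As_sd),
                 n_ref = n_ref, estimator = estimator,
                 Vs_offset_closed_form = unname(Vs_offset_closed_form),
                 volume_nm3 = unname(volume_nm3),
                 voxels_equiv = unname(voxels_equiv),
                 geometry = geometry, per_particle = per_particle),
            class = "np_calibration")
}

#' @export
print.np_calibration <- function(x, ...) {
  cat("Single-particle calibration", sprintf("(n = %d, %s estimator)\n",
                                             x$n_ref, x$estimator))
  cat(sprintf("  escape depth l:    %.3g +- %.2g nm\n", x$l_nm, x$l_sd))
  cat(sprintf("  detected  V_s:     %.4g +- %.2g a.i.u.\n", x$Vs, x$Vs_sd))
  cat(sprintf("  offset    V_s':    %.4g +- %.2g a.i.u.\n", x$Vs_offset, x$Vs_offset_sd))
  cat(sprintf("  actual    V_s0:    %.4g +- %.2g a.i.u.\n", x$Vs0, x$Vs0_sd))
  cat(sprintf("  projected A_s:     %.4g +- %.2g px\n", x$As_px, x$As_sd))
  if (is.finite(x$volume_nm3)) {
    cat(sprintf("  particle volume:   %.4g nm^3 (%.3g voxels)\n",
                x$volume_nm3, x$voxels_equiv))
  }
  invisible(x)
}

#' @export
coef.np_calibration <- function(object, ...) {
  c(l_nm = object$l_nm, Vs = object$Vs, Vs_offset = object$Vs_offset,
    Vs0 = object$Vs0, As_px = object$As_px)
}

#' @export
summary.np_calibration <- function(object, ...) {
  print(object)
  if (!is.null(object$per_particle)) {
    cat("\nPer-particle values:\n")
    print(object$per_particle, digits = 3, row.names = FALSE)
  }
  invisible(object)
}

#' Serialize a calibration to JSON
#' @param cal An `np_calibration`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(cal, path) {
  jsonlite::write_json(list(
    l_nm = cal$l_nm, l_sd = cal$l_sd, Vs = cal$Vs, Vs_sd = cal$Vs_sd,
    Vs_offset = cal$Vs_offset, Vs_offset_sd = cal$Vs_offset_sd,
    Vs0 = cal$Vs0, Vs0_sd = cal$Vs0_sd, As_px = cal$As_px, As_sd = cal$As_sd,
    n_ref = cal$n_ref, estimator = cal$estimator,
    Vs_offset_closed_form = cal$Vs_offset_closed_form,
    volume_nm3 = cal$volume_nm3
  ), path, auto_unbox = TRUE, digits = 10, na = "null")
  invisible(path)
}

#' Read a calibration from JSON
#' @param path File written by [write_calibration()].
#' @return An `np_calibration`.
#' @export
read_calibration <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  np_calibration(Vs = j$Vs, Vs_offset = j$Vs_offset, As_px = j$As_px,
                 Vs_sd = j$Vs_sd %||% 0, Vs_offset_sd = j$Vs_offset_sd %||% 0,
                 As_sd = j$As_sd %||% 0, l_nm = j$l_nm %||% NA_real_,
                 l_sd = j$l_sd %||% 0, n_ref = j$n_ref %||% 1L,
                 estimator = j$estimator %||% "explicit",
                 Vs_offset_closed_form = j$Vs_offset_closed_form %||% NA_real_,
                 volume_nm3 = j$volume_nm3 %||% NA_real_)
}
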