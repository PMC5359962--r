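# Synthetic phantoms: ground-truthed scenes of a cell on a substrate with
# embedded metallic nanoparticles, rendered into FIB/SEM-like stacks with the
# package's imaging model (subsurface exponential glow, anterior occlusion,
# scripted drift, additive noise).

#' Generate a ground-truthed phantom scene
#'
#' Places spherical nanoparticles inside an ellipsoidal cell resting on a
#' substrate plane, grouped into agglomerates of touching spheres. The
#' defaults mirror the acquisition this package targets: 74 nm particles,
#' 6.3 nm pixels, 40 nm slices, an 89 nm secondary-electron escape depth,
#' and a metallic particle about twice as bright as the organic matrix.
#' Placement is deterministic given `seed`.
#'
#' @param agglomerates Either an integer (that many isolated singles) or a
#'   data frame / list describing agglomerates with fields `n` (particles)
#'   and `packing` (one of `"in-plane"`, `"stacked"`, `"random"`); e.g.
#'   `data.frame(n = c(1, 1, 2), packing = c("in-plane", "in-plane",
#'   "stacked"))`. Singles may use any packing label.
#' @param shape Stack shape in voxels: `c(rows, cols, slices)`.
#' @param geometry A [voxel_geometry()]; phantom geometry is the corrected
#'   (post view-angle) raster, the simulated viewing tilt is `view_angle_sim`.
#' @param diameter_nm Nominal particle diameter (nm).
#' @param diameter_sd_nm Per-particle diameter spread (nm), default 0
#'   (monodisperse nominal particles).
#' @param escape_depth_nm Secondary-electron escape depth in the cell matrix.
#' @param levels Named intensities in `[0, 1]`: `resin`, `matrix`, `np`,
#'   `substrate`.
#' @param noise_sd Additive Gaussian noise, same scale as `levels`. Default
#'   is 10% of the matrix level.
#' @param drift `"none"` or `"walk"`: per-slice integer drift as a random
#'   walk with +-1 px steps (probability `drift_p` per axis and step).
#' @param drift_p Step probability of the drift walk.
#' @param view_angle_sim If positive, the rendered stack is foreshortened as
#'   if acquired at this angle (degrees) and carries the matching geometry,
#'   so that [correct_view_angle()] restores it.
#' @param cell_semiaxes_nm Ellipsoid semi-axes `c(x, y, z)` in nm (columns,
#'   rows, slices). Default fills most of the requested shape.
#' @param clearance_nm Minimum gap between distinct agglomerates (between
#'   bounding spheres). Keeps clusters separable in 3D after the subsurface
#'   glow extends them axially.
#' @param seed Integer seed; fixed seed implies a byte-identical phantom and
#'   render.
#' @return An object of class `fib_phantom`: particle table (`x`, `y`, `z`
#'   nm, `d` nm, `cluster`), cell geometry, imaging parameters, drift script
#'   and seed.
#' @export
generate_phantom <- function(agglomerates = 5,
                             shape = c(160, 240, 40),
                             geometry = voxel_geometry(),
                             diameter_nm = 74,
                             diameter_sd_nm = 0,
                             escape_depth_nm = 89,
                             levels = c(resin = 0.2, matrix = 0.5, np = 1.0,
                                        substrate = 0.1),
                             noise_sd = 0.05,
                             drift = c("none", "walk"),
                             drift_p = 0.25,
                             view_angle_sim = 0,
                             cell_semiaxes_nm = NULL,
                             clearance_nm = 150,
                             seed = 1) {
  drift <- match.arg(drift)
  if (is.numeric(agglomerates) && length(agglomerates) == 1) {
    agglomerates <- data.frame(n = rep(1L, agglomerates),
                               packing = rep("random", agglomerates))
  }
  if (is.list(agglomerates) && !is.data.frame(agglomerates)) {
    agglomerates <- data.frame(
      n = vapply(agglomerates, function(a) as.integer(a$n %||% a[[1]]), integer(1)),
      packing = vapply(agglomerates, function(a) as.character(a$packing %||% a[[2]] %||% "random"),
                       character(1)))
  }
  stopifnot(all(agglomerates$n >= 1))
  set.seed(seed)

  px <- geometry$pixel_size_x
  py <- geometry$pixel_size_y
  dz <- geometry$slice_thickness
  width_nm <- shape[2] * px
  height_nm <- shape[1] * py
  depth_nm <- shape[3] * dz
  substrate_y <- 0.82 * height_nm
  if (is.null(cell_semiaxes_nm)) {
    cell_semiaxes_nm <- c(0.40 * width_nm, 0.44 * substrate_y, 0.38 * depth_nm)
  }
  a <- cell_semiaxes_nm[1]; b <- cell_semiaxes_nm[2]; cz <- cell_semiaxes_nm[3]
  # a spread cell sits flat on the substrate: the ellipsoid is clipped by the
  # substrate plane, so its lower boundary coincides with the trench anchor
  center <- c(x = width_nm / 2, y = substrate_y - 0.55 * b, z = depth_nm / 2)

  r_nom <- diameter_nm / 2
  particles <- NULL
  cluster_centers <- matrix(numeric(0), 0, 3)
  cluster_radii <- numeric(0)

  build_offsets <- function(n, packing, d) {
    if (n == 1) return(matrix(0, 1, 3))
    switch(packing,
      "in-plane" = cbind((seq_len(n) - (n + 1) / 2) * d, 0, 0),
      "stacked" = cbind(0, 0, (seq_len(n) - (n + 1) / 2) * d),
      "random" = {
        off <- matrix(0, n, 3)
        for (i in 2:n) {
          placed <- FALSE
          for (try in 1:200) {
            anchor <- off[sample.int(i - 1, 1), ]
            u <- rnorm(3)
            u <- u / sqrt(sum(u^2))
            cand <- anchor + u * d
            dd <- sqrt(rowSums((off[1:(i - 1), , drop = FALSE] -
                                  matrix(cand, i - 1, 3, byrow = TRUE))^2))
            if (all(dd >= d * 0.999)) {
              off[i, ] <- cand
              placed <- TRUE
              break
            }
          }
          if (!placed) stop("could not build a touching agglomerate of size ", n)
        }
        off
      },
      stop("unknown packing: ", packing))
  }

  inside_cell <- function(p, margin) {
    s <- ((p[1] - center["x"]) / max(a - margin, 1))^2 +
      ((p[2] - center["y"]) / max(b - margin, 1))^2 +
      ((p[3] - center["z"]) / max(cz - margin, 1))^2
    s <= 1 && p[2] < substrate_y - margin &&
      p[3] > margin && p[3] < depth_nm - margin   # within the recorded depth
  }

  # place large agglomerates first: they need the most room, and a cell
  # already dotted with singles may have no contiguous space left for them
  for (ci in order(agglomerates$n, decreasing = TRUE)) {
    n <- agglomerates$n[ci]
    packing <- agglomerates$packing[ci]
    d <- if (diameter_sd_nm > 0) max(rnorm(1, diameter_nm, diameter_sd_nm),
                                     0.5 * diameter_nm) else diameter_nm
    off <- build_offsets(n, packing, d)
    rad <- max(sqrt(rowSums(off^2))) + d / 2
    ok <- FALSE
    for (try in 1:4000) {
      u <- runif(3)
      cand <- c(center["x"] + (2 * u[1] - 1) * a,
                center["y"] + (2 * u[2] - 1) * b,
                center["z"] + (2 * u[3] - 1) * cz)
      pts <- off + matrix(cand, n, 3, byrow = TRUE)
      if (!all(apply(pts, 1, inside_cell, margin = d / 2 + 2 * px))) next
      if (nrow(cluster_centers) > 0) {
        dd <- sqrt(rowSums((cluster_centers -
                              matrix(cand, nrow(cluster_centers), 3, byrow = TRUE))^2))
        if (any(dd < cluster_radii + rad + clearance_nm)) next
      }
      ok <- TRUE
      break
    }
    if (!ok) stop("cell too small for the requested particles (agglomerate ", ci, ")")
    cluster_centers <- rbind(cluster_centers, cand)
    cluster_radii <- c(cluster_radii, rad)
    particles <- rbind(particles, data.frame(
      x = pts[, 1], y = pts[, 2], z = pts[, 3], d = d, cluster = ci))
  }
  if (is.null(particles)) {
    particles <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                            d = numeric(0), cluster = integer(0))
  }

  drift_script <- matrix(0L, shape[3], 2)
  if (drift == "walk" && shape[3] > 1) {
    steps <- matrix(sample(c(-1L, 0L, 1L), size = 2L * (shape[3] - 1L),
                           replace = TRUE,
                           prob = c(drift_p / 2, 1 - drift_p, drift_p / 2)),
                    ncol = 2)
    drift_script[2:shape[3], ] <- apply(steps, 2, cumsum)
  }
  colnames(drift_script) <- c("dr", "dc")

  structure(list(
    particles = particles,
    cell = list(center = center, semiaxes = cell_semiaxes_nm,
                substrate_y = substrate_y),
    imaging = list(geometry = geometry, escape_depth = escape_depth_nm,
                   levels = levels, noise_sd = noise_sd,
                   view_angle_sim = view_angle_sim),
    shape = shape, drift_script = drift_script,
    agglomerates = agglomerates, seed = seed
  ), class = "fib_phantom")
}

#' @export
print.fib_phantom <- function(x, ...) {
  cat(sprintf("FIB/SEM phantom: %d particles in %d agglomerates, stack %d x %d x %d\n",
              nrow(x$particles), length(unique(x$particles$cluster)),
              x$shape[1], x$shape[2], x$shape[3]))
  invisible(x)
}

#' Render a phantom into a FIB/SEM-like image stack
#'
#' Implements the imaging model underlying the quantification: slice `k`
#' images the cut face at depth `k * slice_thickness`. The organic matrix,
#' resin and substrate contribute flat base levels; where the face cuts a
#' particle the pixel is at the particle level, and a still-buried particle
#' adds an attenuated contribution `(np - matrix) * exp(-z / l)` on top of
#' the matrix, where `z` is the axial distance from the face to the
#' particle's surface at that pixel. Secondary electrons of a posterior
#' particle are absorbed by any anterior particle above it, so at each pixel
#' only the particle with the shallowest remaining surface is visible
#' (binary occlusion); it glows only once all anterior material at that
#' pixel has been milled away. Scripted drift and additive Gaussian noise
#' are applied last.
#'
#' @param phantom A [generate_phantom()] result.
#' @param noise,drift,shading Logical switches, all on by default (shading
#'   off renders every particle as if alone, for testing the occlusion
#'   model).
#' @return A list: `stack` (an [image_stack()]), `truth` (per-particle table
#'   with first-exposure slice; per-cluster table with particle count and
#'   projected footprint area in px), and `drift_trace` (the script applied).
#' @export
render_stack <- function(phantom, noise = TRUE, drift = TRUE, shading = TRUE) {
  g <- phantom$imaging$geometry
  px <- g$pixel_size_x
  py <- g$pixel_size_y
  dz <- g$slice_thickness
  lv <- phantom$imaging$levels
  l <- phantom$imaging$escape_depth
  shp <- phantom$shape
  nr <- shp[1]; nc <- shp[2]; ns <- shp[3]
  P <- phantom$particles

  # base slice: resin above the substrate plane, substrate below
  sub_row <- ceiling(phantom$cell$substrate_y / py)
  rows_y <- (seq_len(nr) - 0.5) * py
  cols_x <- (seq_len(nc) - 0.5) * px
  base <- matrix(lv[["resin"]], nr, nc)
  base[rows_y >= phantom$cell$substrate_y, ] <- lv[["substrate"]]

  cen <- phantom$cell$center
  ax <- phantom$cell$semiaxes
  glow_cut <- l * log(1e4)  # below 1e-4 of peak the glow is ignored

  slices <- vector("list", ns)
  first_exposure <- rep(NA_integer_, nrow(P))
  for (k in seq_len(ns)) {
    Z <- k * dz
    im <- base
    # cell cross-section (ellipse) at this depth
    dzc <- (Z - cen["z"]) / ax[3]
    if (abs(dzc) < 1) {
      s <- sqrt(1 - dzc^2)
      ex <- outer(((rows_y - cen["y"]) / (ax[2] * s))^2,
                  ((cols_x - cen["x"]) / (ax[1] * s))^2, `+`) <= 1
      ex[rows_y >= phantom$cell$substrate_y, ] <- FALSE
      im[ex] <- lv[["matrix"]]
    }
    if (nrow(P) > 0) {
      val <- matrix(0, nr, nc)
      dep <- matrix(Inf, nr, nc)
      exc <- matrix(0, nr, nc)   # additive excess for the no-shading render
      for (i in seq_len(nrow(P))) {
        r <- P$d[i] / 2
        if (Z > P$z[i] + r) next              # fully milled away
        if (Z < P$z[i] - r - glow_cut) next   # too deep to glow
        ri <- which(abs(rows_y - P$y[i]) <= r)
        ci <- which(abs(cols_x - P$x[i]) <= r)
        if (length(ri) == 0 || length(ci) == 0) next
        rho2 <- outer((rows_y[ri] - P$y[i])^2, (cols_x[ci] - P$x[i])^2, `+`)
        inside <- rho2 <= r^2
        if (!any(inside)) next
        q <- sqrt(pmax(r^2 - rho2, 0))
        zlow <- P$z[i] - q      # upper (anterior) surface depth at each pixel
        zhigh <- P$z[i] + q
        milled <- Z > zhigh
        active <- inside & !milled
        exposed <- active & (Z >= zlow)
        if (any(exposed) && is.na(first_exposure[i])) first_exposure[i] <- k
        sdep <- ifelse(exposed, Z, zlow)
        # glow rides on whatever material is at the cut face (matrix inside
        # the cell, resin/substrate outside): base emission plus the
        # attenuated particle excess
        pb <- im[ri, ci, drop = FALSE]
        v <- ifelse(exposed, lv[["np"]],
                    pb + (lv[["np"]] - pb) * exp(-(zlow - Z) / l))
        if (shading) {
          pv <- val[ri, ci, drop = FALSE]
          pdep <- dep[ri, ci, drop = FALSE]
          upd <- active & (sdep < pdep)
          pv[upd] <- v[upd]
          pdep[upd] <- sdep[upd]
          val[ri, ci] <- pv
          dep[ri, ci] <- pdep
        } else {
          # without occlusion every particle's excess over the local base
          # reaches the detector and the contributions add up
          pe <- exc[ri, ci, drop = FALSE]
          pe[active] <- pe[active] + (v - pb)[active]
          exc[ri, ci] <- pe
        }
      }
      if (shading) {
        vis <- is.finite(dep)
        im[vis] <- pmax(im[vis], val[vis])
      } else {
        im <- im + exc
      }
    }
    slices[[k]] <- im
  }

  trace <- phantom$drift_script
  if (drift && any(trace != 0)) {
    for (k in seq_len(ns)) {
      if (any(trace[k, ] != 0)) {
        slices[[k]] <- translate_image(slices[[k]], trace[k, 1], trace[k, 2],
                                       fill = lv[["resin"]])
      }
    }
  } else {
    trace <- matrix(0L, ns, 2, dimnames = list(NULL, c("dr", "dc")))
  }

  geom_out <- g
  if (phantom$imaging$view_angle_sim > 0) {
    th <- phantom$imaging$view_angle_sim
    f <- cos(th * pi / 180)
    new_h <- max(2L, as.integer(round(nr * f)))
    src <- (seq_len(new_h) - 0.5) * (nr / new_h)
    i0 <- pmin(pmax(floor(src + 0.5 - 0.5), 1L), nr - 1L)
    w <- pmin(pmax(src + 0.5 - 0.5 - i0, 0), 1)
    slices <- lapply(slices, function(s) {
      s[i0, , drop = FALSE] * (1 - w) + s[i0 + 1L, , drop = FALSE] * w
    })
    geom_out <- voxel_geometry(px, py * nr / new_h, dz, th)
  }

  if (noise && phantom$imaging$noise_sd > 0) {
    set.seed(phantom$seed + 104729L)  # decouple noise stream from placement
    d1 <- dim(slices[[1]])
    slices <- lapply(slices, function(s) {
      s + matrix(rnorm(length(s), 0, phantom$imaging$noise_sd), d1[1], d1[2])
    })
  }

  truth_particles <- cbind(P, first_exposure = first_exposure)
  truth_clusters <- NULL
  if (nrow(P) > 0) {
    cl <- sort(unique(P$cluster))
    foot <- vapply(cl, function(ci) {
      sel <- P$cluster == ci
      m <- matrix(FALSE, nr, nc)
      for (i in which(sel)) {
        r <- P$d[i] / 2
        ri <- which(abs(rows_y - P$y[i]) <= r)
        ci2 <- which(abs(cols_x - P$x[i]) <= r)
        rho2 <- outer((rows_y[ri] - P$y[i])^2, (cols_x[ci2] - P$x[i])^2, `+`)
        m[ri, ci2] <- m[ri, ci2] | (rho2 <= r^2)
      }
      sum(m)
    }, numeric(1))
    truth_clusters <- data.frame(
      cluster = cl,
      n_particles = as.integer(table(factor(P$cluster, levels = cl))),
      footprint_px = foot,
      volume_nm3 = vapply(cl, function(ci) sum(pi * P$d[P$cluster == ci]^3 / 6),
                          numeric(1)))
  }

  list(stack = image_stack(slices, geom_out,
                           provenance = sprintf("phantom seed %d", phantom$seed)),
       truth = list(particles = truth_particles, clusters = truth_clusters),
       drift_trace = trace)
}
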