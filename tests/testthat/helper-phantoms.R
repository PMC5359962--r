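# Shared fixtures, all generated in code. Expensive phantoms and pipeline
# runs are cached for the duration of the test session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# the standard mixed phantom: 5 singles, one stacked pair, one in-plane
# pair, one random-touching triple (12 particles, 8 clusters), 10% noise
mixed_phantom <- function() {
  memo("mixed_phantom", generate_phantom(
    agglomerates = data.frame(
      n = c(1, 1, 1, 1, 1, 2, 2, 3),
      packing = c(rep("random", 5), "stacked", "in-plane", "random")),
    shape = c(160, 240, 40), seed = 11))
}

mixed_render <- function() memo("mixed_render", render_stack(mixed_phantom()))

mixed_pipeline <- function() {
  memo("mixed_pipeline", suppressMessages(run_pipeline(
    pipeline_config(report = list(export_meshes = FALSE, histogram = FALSE)),
    stack = mixed_render()$stack)))
}

# noiseless phantom of isolated singles, used for the exact oracles
noiseless_phantom <- function() {
  memo("noiseless_phantom", generate_phantom(
    agglomerates = 6, shape = c(180, 260, 44), noise_sd = 0, seed = 5))
}

noiseless_render <- function() {
  memo("noiseless_render", render_stack(noiseless_phantom(), noise = FALSE,
                                        drift = FALSE))
}

# segmentation + a.i.u. + refined clusters for a rendered stack; noiseless
# stacks need an explicit background sigma (their MAD is 0)
analyse_stack <- function(stack, sigma = NULL, key = NULL) {
  build <- function() {
    seg <- segment_cell_stack(stack, wiener_window = if (is.null(sigma)) 5 else 0)
    a <- stack_array(stack)
    aiu <- array(0, dim(a))
    for (k in seq_len(dim(a)[3])) {
      m <- seg$masks[[k]]$mask
      if (!any(m)) next
      aiu[, , k] <- normalize_to_background(a[, , k], m, bg_erode_px = 15,
                                            sigma = sigma)
    }
    clusters <- detect_np_clusters(aiu, seg$volume)
    list(seg = seg, aiu = aiu, clusters = clusters)
  }
  if (is.null(key)) build() else memo(key, build())
}

mixed_analysis <- function() {
  analyse_stack(mixed_render()$stack, key = "mixed_analysis")
}

noiseless_analysis <- function() {
  analyse_stack(noiseless_render()$stack, sigma = 0.002, key = "noiseless_analysis")
}

# match detected clusters to ground-truth clusters by 3D centroid
match_truth_cluster <- function(cluster, phantom) {
  g <- phantom$imaging$geometry
  cen_row <- mean(cluster$voxels[, 1]) * g$pixel_size_y
  cen_col <- mean(cluster$voxels[, 2]) * g$pixel_size_x
  cen_dep <- mean(cluster$voxels[, 3]) * g$slice_thickness
  d2 <- (phantom$particles$y - cen_row)^2 + (phantom$particles$x - cen_col)^2 +
    (phantom$particles$z - cen_dep)^2
  phantom$particles$cluster[which.min(d2)]
}

# analytic sphere rasterization on the voxel grid (independent of the renderer)
rasterize_sphere <- function(center_nm, diameter_nm, dims, geometry) {
  rows_y <- (seq_len(dims[1]) - 0.5) * geometry$pixel_size_y
  cols_x <- (seq_len(dims[2]) - 0.5) * geometry$pixel_size_x
  dep_z <- (seq_len(dims[3]) - 0.5) * geometry$slice_thickness
  r2 <- (diameter_nm / 2)^2
  out <- array(FALSE, dims)
  for (k in seq_len(dims[3])) {
    dz2 <- (dep_z[k] - center_nm[3])^2
    if (dz2 > r2) next
    out[, , k] <- outer((rows_y - center_nm[2])^2,
                        (cols_x - center_nm[1])^2, `+`) <= r2 - dz2
  }
  out
}
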