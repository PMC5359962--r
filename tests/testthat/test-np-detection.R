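test_that("background normalization maps the matrix to zero sigma units", {
  set.seed(15)
  im <- matrix(rnorm(80 * 80, 100, 10), 80, 80)
  im[40, 40] <- 200
  mask <- matrix(TRUE, 80, 80)
  out <- normalize_to_background(im, mask)
  expect_equal(out[40, 40], 10, tolerance = 0.08 * 10)
  expect_lt(abs(median(out[-(40 + 39 * 80)])), 0.1)
  expect_error(normalize_to_background(im, mask & FALSE), "empty cell mask")
  expect_error(normalize_to_background(matrix(5, 8, 8), matrix(TRUE, 8, 8)),
               "degenerate")
  # explicit sigma rescues the degenerate (noise-free) case: flat -> zeros
  z <- normalize_to_background(matrix(5, 8, 8), matrix(TRUE, 8, 8), sigma = 1)
  expect_true(all(z == 0))
})

test_that("a.i.u. values are invariant under affine rescaling of the raw data", {
  set.seed(16)
  im <- matrix(rnorm(60 * 60, 0.5, 0.05), 60, 60)
  im[20:25, 20:25] <- 1
  mask <- matrix(TRUE, 60, 60)
  a1 <- normalize_to_background(im, mask)
  a2 <- normalize_to_background(2 * im + 5, mask)
  expect_equal(as.vector(a1), as.vector(a2), tolerance = 1e-9)
})

test_that("candidate detection finds bright discs and nothing in flat noise", {
  set.seed(17)
  mask <- matrix(TRUE, 90, 90)
  flat <- matrix(rnorm(90 * 90), 90, 90)
  expect_equal(sum(detect_np_candidates(flat, mask)), 0)

  disc <- outer((1:90 - 45)^2, (1:90 - 45)^2, `+`) <= 36
  im <- flat
  im[disc] <- 8 + rnorm(sum(disc))
  cand <- detect_np_candidates(im, mask)
  # oracle: direct intensity threshold at half maximum, restricted to the disc
  oracle <- im >= max(im[disc]) / 2 & disc
  expect_gte(sum(cand & oracle) / sum(oracle), 0.9)

  two <- matrix(rnorm(90 * 90), 90, 90)
  d1 <- outer((1:90 - 45)^2, (1:90 - 25)^2, `+`) <= 36
  d2 <- outer((1:90 - 45)^2, (1:90 - 65)^2, `+`) <= 36
  two[d1] <- 8 + rnorm(sum(d1)); two[d2] <- 8 + rnorm(sum(d2))
  blobs <- EBImage::bwlabel(detect_np_candidates(two, mask) * 1)
  expect_equal(max(blobs), 2)
})

test_that("3D clustering joins consecutive slices and splits distant ones", {
  d <- c(40, 40, 9)
  aiu <- array(0, d)
  cand <- array(FALSE, d)
  blob <- outer((1:40 - 20)^2, (1:40 - 20)^2, `+`) <= 16
  for (k in 3:5) { cand[, , k] <- blob; aiu[, , k] <- blob * 10 }
  cl <- cluster_candidates_3d(cand, aiu)
  expect_length(cl, 1)
  expect_equal(range(cl[[1]]$voxels[, 3]), c(3, 5))
  expect_true(all(cl[[1]]$aiu > 0))

  cand2 <- array(FALSE, d)
  cand2[, , 3] <- blob
  cand2[, , 7] <- blob          # 3-slice gap: separate clusters
  cl2 <- cluster_candidates_3d(cand2, aiu + 1)
  expect_length(cl2, 2)
  expect_length(cluster_candidates_3d(array(FALSE, d), aiu), 0)
})

test_that("detected cluster count matches the phantom agglomerate count", {
  an <- mixed_analysis()
  truth <- mixed_render()$truth$clusters
  expect_equal(length(an$clusters), nrow(truth))
})

test_that("local multilevel Otsu refinement keeps exactly the particle class", {
  # resin 0, matrix 1, particle 10: three well-separated classes
  d <- c(24, 24, 5)
  aiu <- array(0, d)
  aiu[, 1:12, ] <- 1
  core <- array(FALSE, d)
  core[10:14, 10:14, 2:4] <- TRUE
  aiu[core] <- 10
  rough <- fibcount:::new_np_cluster(1L, which(core, arr.ind = TRUE), aiu)
  ref <- refine_cluster_otsu(aiu, rough, margin_xy = 4, margin_z = 1)
  lin <- ref$voxels[, 1] + (ref$voxels[, 2] - 1) * d[1] +
    (ref$voxels[, 3] - 1) * d[1] * d[2]
  expect_setequal(lin, which(core))
  expect_false("degenerate" %in% ref$flags)
})

test_that("an unimodal box leaves the rough cluster flagged", {
  set.seed(18)
  d <- c(20, 20, 4)
  aiu <- array(rnorm(prod(d)), d)
  vox <- cbind(10:12, 10:12, 2)
  rough <- fibcount:::new_np_cluster(1L, vox, aiu)
  ref <- refine_cluster_otsu(aiu, rough)
  expect_true("degenerate" %in% ref$flags)
  expect_equal(ref$voxels, rough$voxels)
})

test_that("refinement never leaves the padded bounding box", {
  an <- mixed_analysis()
  cand <- array(FALSE, dim(an$aiu))
  for (k in seq_len(dim(an$aiu)[3])) {
    if (!any(an$seg$volume[, , k])) next
    cand[, , k] <- detect_np_candidates(an$aiu[, , k], an$seg$volume[, , k])
  }
  rough <- cluster_candidates_3d(cand, an$aiu)
  ref <- refine_cluster_otsu(an$aiu, rough[[1]], margin_xy = 5, margin_z = 3)
  expect_true(all(ref$voxels[, 1] >= rough[[1]]$bbox[1, 1] - 5 &
                    ref$voxels[, 1] <= rough[[1]]$bbox[2, 1] + 5))
  expect_true(all(ref$voxels[, 3] >= rough[[1]]$bbox[1, 3] - 3 &
                    ref$voxels[, 3] <= rough[[1]]$bbox[2, 3] + 3))
})

test_that("noiseless refined clusters cover the exposed particle voxels", {
  an <- noiseless_analysis()
  raw <- stack_array(noiseless_render()$stack)
  ph <- noiseless_phantom()
  g <- ph$imaging$geometry
  flagged <- vapply(an$seg$masks, `[[`, logical(1), "below_contrast_limit")
  for (cl in an$clusters) {
    truth_id <- match_truth_cluster(cl, ph)
    p <- ph$particles[ph$particles$cluster == truth_id, ]
    exposed <- which(raw >= 0.999, arr.ind = TRUE)
    # restrict to this particle's own projected disc (a neighbor can sit
    # one diameter away)
    r_px <- p$d / 2 / g$pixel_size_x + 1
    keep <- (exposed[, 1] - p$y / g$pixel_size_y)^2 +
      (exposed[, 2] - p$x / g$pixel_size_x)^2 <= r_px^2 &
      !flagged[exposed[, 3]]
    exposed <- exposed[keep, , drop = FALSE]
    got <- paste(cl$voxels[, 1], cl$voxels[, 2], cl$voxels[, 3])
    want <- paste(exposed[, 1], exposed[, 2], exposed[, 3])
    expect_gte(mean(want %in% got), 0.95)
    # refined voxels stay within the particle's projected disc (+1 px)
    rad_px <- p$d / 2 / g$pixel_size_x + 1
    dist <- sqrt((cl$voxels[, 1] - p$y / g$pixel_size_y)^2 +
                   (cl$voxels[, 2] - p$x / g$pixel_size_x)^2)
    expect_gte(mean(dist <= rad_px), 0.95)
  }
})

test_that("cluster detection is invariant to global affine intensity rescaling", {
  r <- mixed_render()
  g <- r$stack$geometry
  scaled <- image_stack(lapply(r$stack$slices, function(s) 1.7 * s + 0.3), g)
  a1 <- analyse_stack(r$stack)
  a2 <- analyse_stack(scaled)
  expect_equal(length(a1$clusters), length(a2$clusters))
  v1 <- lapply(a1$clusters, function(cl) cl$voxels[order(cl$voxels[, 3],
                                                         cl$voxels[, 2],
                                                         cl$voxels[, 1]), ])
  v2 <- lapply(a2$clusters, function(cl) cl$voxels[order(cl$voxels[, 3],
                                                         cl$voxels[, 2],
                                                         cl$voxels[, 1]), ])
  expect_equal(v1, v2)
})
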