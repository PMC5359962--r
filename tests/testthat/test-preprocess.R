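test_that("identical consecutive slices register with zero shift", {
  set.seed(4)
  s <- matrix(runif(64 * 64), 64, 64)
  tr <- estimate_drift(image_stack(list(s, s, s)))
  expect_true(all(tr == 0))
})

test_that("a known translation is recovered exactly", {
  set.seed(5)
  a <- matrix(runif(80 * 80), 80, 80)
  b <- fibcount:::translate_image(a, 3, -2, fill = median(a))
  tr <- estimate_drift(image_stack(list(a, b)))
  expect_equal(unname(tr[2, ]), c(3, -2))
})

test_that("a constant slice cannot be registered and is flagged", {
  set.seed(6)
  a <- matrix(runif(32 * 32), 32, 32)
  flat <- matrix(0.5, 32, 32)
  tr <- estimate_drift(image_stack(list(a, flat, a)))
  expect_equal(unname(tr[2, ]), c(0, 0))
  expect_true(2 %in% attr(tr, "flat_slices"))
  expect_error(estimate_drift(image_stack(list(a))), "at least 2")
})

test_that("scripted drift is recovered from a rendered phantom", {
  ph <- generate_phantom(agglomerates = 4, shape = c(140, 200, 30),
                        drift = "walk", cell_semiaxes_nm = c(500, 320, 1200),
                        seed = 21)
  # noiseless: recovery is exact and the corrected stack matches the
  # drift-free render almost perfectly
  rd <- render_stack(ph, noise = FALSE, drift = TRUE)
  rf <- render_stack(ph, noise = FALSE, drift = FALSE)
  tr <- estimate_drift(rd$stack)
  expect_equal(unclass(tr)[, ], rd$drift_trace[, ], ignore_attr = TRUE)
  corrected <- apply_drift_correction(rd$stack, tr)
  expect_gt(cor(as.vector(stack_array(corrected)),
                as.vector(stack_array(rf$stack))), 0.99)
  # noisy: per-slice (pairwise) shifts stay within 1 pixel of the script
  rn <- render_stack(ph)
  trn <- estimate_drift(rn$stack)
  step_err <- apply(trn, 2, function(x) c(0, diff(x))) -
    apply(rn$drift_trace, 2, function(x) c(0, diff(x)))
  expect_lte(max(abs(step_err)), 1)
})

test_that("drift correction is idempotent", {
  ph <- generate_phantom(agglomerates = 4, shape = c(140, 200, 30),
                        drift = "walk", cell_semiaxes_nm = c(500, 320, 1200),
                        seed = 22)
  r <- render_stack(ph)
  tr <- estimate_drift(r$stack)
  corrected <- apply_drift_correction(r$stack, tr)
  residual <- estimate_drift(corrected)
  expect_true(all(residual == 0))
  # all-zero trace leaves the stack untouched
  zero <- matrix(0L, length(r$stack$slices), 2)
  expect_identical(apply_drift_correction(r$stack, zero)$slices, r$stack$slices)
  expect_error(apply_drift_correction(r$stack, zero[-1, , drop = FALSE]),
               "does not match")
})

test_that("view-angle correction stretches by 1/cos and preserves physics", {
  set.seed(7)
  h <- 50
  st0 <- image_stack(list(matrix(runif(h * 20), h, 20)),
                     voxel_geometry(view_angle = 0))
  expect_identical(correct_view_angle(st0)$slices, st0$slices)

  st60 <- image_stack(list(matrix(runif(h * 20), h, 20)),
                      voxel_geometry(view_angle = 60))
  out <- correct_view_angle(st60)
  expect_equal(nrow(out$slices[[1]]), 2 * h)  # 1/cos(60 deg) = 2
  expect_equal(out$geometry$view_angle, 0)
  # physical height preserved: rows x pixel_size_y is invariant
  expect_equal(2 * h * out$geometry$pixel_size_y, h * st60$geometry$pixel_size_y)

  st52 <- image_stack(list(matrix(runif(h * 20), h, 20)),
                      voxel_geometry(view_angle = 52))
  out52 <- correct_view_angle(st52)
  expect_equal(nrow(out52$slices[[1]]) / h, 1 / cos(52 * pi / 180),
               tolerance = 0.02)  # 1/cos(52 deg) ~ 1.624, up to row rounding
  # the "sin" convention is the selectable alternative
  outsin <- correct_view_angle(st52, convention = "sin")
  expect_equal(nrow(outsin$slices[[1]]) / h, 1 / sin(52 * pi / 180),
               tolerance = 0.02)
  expect_identical(correct_view_angle(st52, convention = "none")$slices,
                   st52$slices)
})

test_that("a foreshortened render is restored by the correction", {
  ph <- generate_phantom(agglomerates = 1, shape = c(120, 120, 24),
                        view_angle_sim = 52, noise_sd = 0, seed = 9)
  r <- render_stack(ph, noise = FALSE, drift = FALSE)
  expect_equal(r$stack$geometry$view_angle, 52)
  expect_lt(nrow(r$stack$slices[[1]]), 120)
  out <- correct_view_angle(r$stack)
  expect_equal(nrow(out$slices[[1]]), 120, tolerance = 0.02)
  expect_equal(out$geometry$pixel_size_y, 6.3, tolerance = 0.02)
})

test_that("the adaptive noise filter smooths noise but keeps the mean", {
  expect_error(denoise_wiener(matrix(0, 10, 10), 4), "odd")
  expect_error(denoise_wiener(matrix(0, 4, 4), 5), "larger than image")
  const <- matrix(0.7, 32, 32)
  expect_equal(denoise_wiener(const, 5), const, ignore_attr = TRUE)
  set.seed(8)
  noisy <- matrix(0.5 + rnorm(64 * 64, 0, 0.05), 64, 64)
  out <- denoise_wiener(noisy, 5)
  expect_lt(sd(out - 0.5), 0.05)           # residual below the input noise
  expect_lt(abs(mean(out) - mean(noisy)) / mean(noisy), 0.01)
})

test_that("wiener filtering preserves particle/background contrast", {
  r <- mixed_render()
  im <- r$stack$slices[[20]]
  out <- denoise_wiener(im, 5)
  # contrast between the particle plateau and the cell matrix, both pixel
  # sets fixed from the raw image so noise extremes cancel
  sel_np <- im > (max(im) + median(im)) / 2
  sel_mx <- im > 0.4 & im < 0.6
  contrast <- function(x) (mean(x[sel_np]) - mean(x[sel_mx])) / mean(x[sel_mx])
  expect_lt(abs(contrast(out) - contrast(im)) / contrast(im), 0.10)
})

test_that("the Gaussian low-pass preserves energy and an impulse maps to a kernel", {
  expect_error(lowpass(matrix(0, 8, 8), 0), "positive")
  im <- matrix(0, 33, 33)
  im[17, 17] <- 1
  k <- lowpass(im, 2)
  expect_equal(sum(k), 1, tolerance = 1e-6)              # energy preserved
  expect_equal(k[17, 17], 1 / (2 * pi * 4), tolerance = 0.01)  # peak of a 2D gaussian
  expect_equal(which.max(k), which.max(im))
  set.seed(9)
  rim <- matrix(runif(40 * 40), 40, 40)
  expect_equal(sum(lowpass(rim, 1.5)), sum(rim), tolerance = 1e-6)
  expect_identical(lowpass(rim, 0.1), rim)  # sigma -> 0 limit: identity
})

test_that("low-pass filtering keeps a bimodal patch Otsu-separable", {
  set.seed(10)
  patch <- matrix(0.5 + rnorm(48 * 48, 0, 0.05), 48, 48)
  disc <- outer((1:48 - 24)^2, (1:48 - 24)^2, `+`) <= 36
  patch[disc] <- 1 + rnorm(sum(disc), 0, 0.05)
  filt <- lowpass(patch, 1.5)
  ot <- fibcount:::otsu_thresholds(as.vector(filt), k = 2)
  expect_false(ot$degenerate)
  expect_gt(ot$thresholds, 0.6)
  expect_lt(ot$thresholds, 0.95)
})
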