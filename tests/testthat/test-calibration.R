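test_that("exact exponential profiles return the decay length exactly", {
  p89 <- data.frame(slice = 1:4,
                    intensity = c(exp(-120 / 89), exp(-80 / 89), exp(-40 / 89), 1))
  expect_equal(as.numeric(fit_escape_depth(p89, 40, noise_floor = 0.01)), 89,
               tolerance = 1e-9)
  p40 <- data.frame(slice = 1:4, intensity = exp(-(3:0)))
  expect_equal(as.numeric(fit_escape_depth(p40, 40, noise_floor = 0.01)), 40,
               tolerance = 1e-9)
  # slice-phase offset scales the intercept, not the slope
  poff <- data.frame(slice = 1:4,
                     intensity = c(exp(-(120 + 17) / 89), exp(-(80 + 17) / 89),
                                   exp(-(40 + 17) / 89), 1))
  expect_equal(as.numeric(fit_escape_depth(poff, 40, noise_floor = 0.001)), 89,
               tolerance = 1e-9)
})

test_that("degenerate profiles are rejected", {
  expect_error(fit_escape_depth(data.frame(slice = 1:2, intensity = c(0.5, 1)),
                                40, noise_floor = 0.01), "at least 2")
  nonmono <- data.frame(slice = 1:5, intensity = c(0.30, 0.6, 0.35, 0.8, 1))
  expect_error(fit_escape_depth(nonmono, 40, noise_floor = 0.01), "non-monotone")
})

test_that("the escape depth estimator is unbiased on noisy profile ensembles", {
  set.seed(101)
  ls <- replicate(16, {
    z <- seq(200, 0, by = -40)   # depth shrinks as slicing proceeds
    I <- exp(-z / 89) * exp(rnorm(length(z), 0, 0.1))   # 10% multiplicative noise
    prof <- data.frame(slice = seq_along(z), intensity = I)
    as.numeric(fit_escape_depth(prof, 40, noise_floor = 0.01))
  })
  expect_gt(mean(ls), 72)
  expect_lt(mean(ls), 106)
})

test_that("profile extraction needs at least 3 usable slices", {
  d <- c(20, 20, 6)
  aiu <- array(0, d)
  aiu[9:11, 9:11, 3] <- 10            # visible in a single slice only
  cl <- fibcount:::new_np_cluster(1L, which(aiu > 0, arr.ind = TRUE), aiu)
  expect_error(extract_profile(aiu, cl), "3 usable")
})

test_that("the single-particle screen keeps isolated spheres only", {
  an <- mixed_analysis()
  ph <- mixed_phantom()
  A_e <- pi * (74 / 2 / 6.3)^2
  singles <- select_single_nps(an$clusters, an$aiu, A_e)
  truth_sizes <- table(ph$particles$cluster)
  got <- vapply(singles, function(cl) match_truth_cluster(cl, ph), numeric(1))
  # exactly the isolated particles, none of the agglomerates
  expect_setequal(got, as.integer(names(truth_sizes)[truth_sizes == 1]))
})

test_that("a manual id list overrides the screen; all-agglomerate input is empty", {
  an <- mixed_analysis()
  ph <- mixed_phantom()
  manual <- select_single_nps(an$clusters, an$aiu, 108, manual = c(3, 7))
  expect_setequal(vapply(manual, `[[`, integer(1), "id"), c(3L, 7L))
  # keep only clusters matching multi-particle truth: the screen rejects all
  agg <- Filter(function(cl) {
    tid <- match_truth_cluster(cl, ph)
    sum(ph$particles$cluster == tid) > 1
  }, an$clusters)
  expect_length(select_single_nps(agg, an$aiu, 108), 0)
})

test_that("explicit calibration constants decompose consistently", {
  cal <- np_calibration(Vs = 160, Vs_offset = 62, As_px = 109,
                        Vs_sd = 42, Vs_offset_sd = 26, As_sd = 16, Vs0_sd = 18)
  expect_equal(cal$Vs0, 98)
  expect_equal(cal$Vs0 + cal$Vs_offset, cal$Vs)
  expect_equal(unname(coef(cal)["As_px"]), 109)
  expect_error(np_calibration(Vs = 100, Vs_offset = 120, As_px = 109),
               "positive")
  # JSON round trip
  f <- withr::local_tempfile(fileext = ".json")
  write_calibration(cal, f)
  rt <- read_calibration(f)
  expect_equal(rt$Vs0, 98)
  expect_equal(rt$As_px, 109)
})

test_that("noiseless singles calibrate to the analytic sphere", {
  an <- noiseless_analysis()
  singles <- select_single_nps(an$clusters, an$aiu, pi * (74 / 2 / 6.3)^2,
                               noise_floor = 0.5)
  expect_gte(length(singles), 4)
  cal <- calibrate(an$aiu, singles, voxel_geometry(), noise_floor = 0.5)
  # decomposition is exact by construction, per particle and aggregated
  pp <- cal$per_particle
  expect_equal(pp$Vs0 + pp$Vs_offset_emp, pp$Vs, tolerance = 1e-12)
  expect_equal(cal$Vs0 + cal$Vs_offset, cal$Vs, tolerance = 1e-9)
  # projected area: equivalent-circle diameter reproduces the generator
  expect_lt(abs(cal$As_px - pi * (37 / 6.3)^2) / (pi * (37 / 6.3)^2), 0.10)
  d_eq <- 2 * sqrt(cal$As_px / pi) * 6.3
  expect_lt(abs(d_eq - 74) / 74, 0.05)
  # corrected volume matches the analytic sphere volume
  expect_lt(abs(cal$volume_nm3 - sphere_volume_nm3(74)) / sphere_volume_nm3(74),
            0.10)
  # closed-form alternative is reported alongside
  expect_true(is.finite(cal$Vs_offset_closed_form))
})

test_that("the escape depth is recovered from a noiseless isolated sphere", {
  ph <- generate_phantom(agglomerates = 1, shape = c(140, 140, 32),
                        cell_semiaxes_nm = c(360, 330, 2000),
                        noise_sd = 0, seed = 7)
  r <- render_stack(ph, noise = FALSE, drift = FALSE)
  an <- analyse_stack(r$stack, sigma = 0.002)
  expect_length(an$clusters, 1)
  cal <- calibrate(an$aiu, an$clusters, voxel_geometry(), noise_floor = 0.5)
  expect_lt(abs(cal$l_nm - 89) / 89, 0.02)
})

test_that("a particle fully exposed in its first slice has no offset volume", {
  d <- c(24, 24, 8)
  aiu <- array(0, d)
  core <- array(FALSE, d)
  core[10:15, 10:15, 1:2] <- TRUE     # bright from slice 1, no glow slices
  aiu[core] <- 10
  cl <- fibcount:::new_np_cluster(1L, which(core, arr.ind = TRUE), aiu)
  cal <- calibrate(aiu, list(cl), voxel_geometry())
  expect_equal(cal$Vs_offset, 0)
  expect_equal(cal$Vs0, cal$Vs)
})
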