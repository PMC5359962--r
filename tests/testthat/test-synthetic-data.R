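test_that("phantom bookkeeping matches the agglomerate specification", {
  spec <- data.frame(n = c(1, 1, 1, 1, 1, 2, 2),
                     packing = c(rep("random", 5), "stacked", "in-plane"))
  ph <- generate_phantom(agglomerates = spec, seed = 2)
  expect_equal(nrow(ph$particles), 9)
  expect_equal(length(unique(ph$particles$cluster)), 7)
  expect_true(all(ph$particles$d == 74))
  # stacked: common (x, y); in-plane: common (y, z)
  stk <- ph$particles[ph$particles$cluster == 6, ]
  expect_equal(sd(stk$x), 0)
  expect_equal(abs(diff(stk$z)), 74)
  inp <- ph$particles[ph$particles$cluster == 7, ]
  expect_equal(sd(inp$z), 0)
  expect_equal(abs(diff(inp$x)), 74)
})

test_that("phantom generation and rendering are deterministic under a seed", {
  spec <- data.frame(n = c(1, 2), packing = c("random", "random"))
  p1 <- generate_phantom(agglomerates = spec, seed = 33)
  p2 <- generate_phantom(agglomerates = spec, seed = 33)
  expect_identical(p1$particles, p2$particles)
  expect_identical(p1$drift_script, p2$drift_script)
  r1 <- render_stack(p1)
  r2 <- render_stack(p2)
  expect_identical(r1$stack$slices, r2$stack$slices)
  p3 <- generate_phantom(agglomerates = spec, seed = 34)
  expect_false(identical(p1$particles, p3$particles))
})

test_that("a zero-particle phantom renders a cell-only stack", {
  ph <- generate_phantom(agglomerates = data.frame(n = integer(0),
                                                  packing = character(0)),
                        shape = c(100, 140, 16), seed = 3)
  expect_equal(nrow(ph$particles), 0)
  r <- render_stack(ph)
  expect_length(r$stack$slices, 16)
  expect_null(r$truth$clusters)
  lv <- ph$imaging$levels
  expect_lte(max(stack_array(render_stack(ph, noise = FALSE)$stack)),
             lv[["matrix"]])
})

test_that("an oversized agglomerate does not fit a small cell", {
  expect_error(generate_phantom(agglomerates = data.frame(n = 40, packing = "in-plane"),
                               shape = c(60, 60, 10), seed = 1),
               "too small")
})

test_that("pre-exposure maxima follow the escape-depth exponential exactly", {
  # the large cell keeps the whole glow path inside the matrix
  ph <- generate_phantom(agglomerates = 1, shape = c(140, 140, 32),
                        cell_semiaxes_nm = c(360, 330, 2000),
                        noise_sd = 0, seed = 7)
  r <- render_stack(ph, noise = FALSE, drift = FALSE)
  a <- stack_array(r$stack)
  lv <- ph$imaging$levels
  k1 <- r$truth$particles$first_exposure
  glow <- apply(a, 3, max)[1:(k1 - 1)] - lv[["matrix"]]
  glow <- tail(glow[glow > 1e-4], 4)   # last pre-exposure slices: glow on matrix
  # consecutive ratios are exp(-slice_thickness / l) to machine precision
  expect_equal(diff(log(glow)),
               rep(40 / ph$imaging$escape_depth, length(glow) - 1),
               tolerance = 1e-9)
})

test_that("an anterior particle shades the posterior one until it is milled", {
  base <- list(shape = c(110, 110, 30), noise_sd = 0, seed = 12)
  pair <- generate_phantom(agglomerates = data.frame(n = 2, packing = "stacked"),
                          shape = base$shape, noise_sd = 0, seed = base$seed)
  r2 <- render_stack(pair, noise = FALSE, drift = FALSE)
  # the same scene with only the anterior particle
  solo <- pair
  solo$particles <- pair$particles[which.min(pair$particles$z), ]
  r1 <- render_stack(solo, noise = FALSE, drift = FALSE)
  # while anterior material remains, the pair renders identically to the
  # anterior alone: the posterior contributes nothing
  z_ant_end <- max(solo$particles$z) + solo$particles$d / 2
  k_hidden <- which((seq_len(base$shape[3]) * 40) < z_ant_end - 40)
  expect_true(length(k_hidden) > 2)
  expect_identical(stack_array(r2$stack)[, , k_hidden],
                   stack_array(r1$stack)[, , k_hidden])
  # and afterwards the posterior shows up
  k_after <- which((seq_len(base$shape[3]) * 40) > z_ant_end)
  expect_gt(max(stack_array(r2$stack)[, , k_after] -
                  stack_array(r1$stack)[, , k_after]), 0.3)
})

test_that("shading only ever reduces rendered intensity", {
  ph <- generate_phantom(agglomerates = data.frame(n = c(3, 2),
                                                  packing = c("random", "stacked")),
                        shape = c(120, 160, 26), noise_sd = 0, seed = 14)
  with_sh <- stack_array(render_stack(ph, noise = FALSE, drift = FALSE,
                                      shading = TRUE)$stack)
  without <- stack_array(render_stack(ph, noise = FALSE, drift = FALSE,
                                      shading = FALSE)$stack)
  expect_true(all(with_sh <= without + 1e-12))
  expect_gt(sum(without - with_sh), 0)
})

test_that("summed particle intensity is stable under depth placement", {
  # same sphere two slices deeper: identical slice phase, so the rendered
  # signal just shifts along the stack (the large cell keeps the glow on
  # the matrix at both depths)
  ph1 <- generate_phantom(agglomerates = 1, shape = c(140, 140, 36),
                         cell_semiaxes_nm = c(360, 330, 2000),
                         noise_sd = 0, seed = 7)
  ph2 <- ph1
  ph2$particles$z <- ph1$particles$z + 2 * 40
  s1 <- stack_array(render_stack(ph1, noise = FALSE, drift = FALSE)$stack)
  s2 <- stack_array(render_stack(ph2, noise = FALSE, drift = FALSE)$stack)
  lv1 <- sum(pmax(s1 - 0.5, 0)[s1 > 0.5001])
  lv2 <- sum(pmax(s2 - 0.5, 0)[s2 > 0.5001])
  expect_lt(abs(lv1 - lv2) / lv1, 0.05)
})
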