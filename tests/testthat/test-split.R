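test_that("centre fraction is the linear projection onto the reference axis", {
  refs <- split_references(p_in = c(0.1, 0.05), p_out = c(0.5, 0.3))
  expect_equal(fraction_in(0.1, 0.05, refs), 1)
  expect_equal(fraction_in(0.5, 0.3, refs), 0)
  expect_equal(fraction_in(0.3, 0.175, refs), 0.5)
  # clamping confines off-axis/outside points
  expect_equal(fraction_in(0.9, 0.6, refs), 0)
  expect_equal(fraction_in(-0.5, -0.3, refs), 1)
  expect_lt(fraction_in(0.9, 0.6, refs, clamp = FALSE), 0)
  # degenerate references are rejected at construction
  expect_error(split_references(c(0.2, 0.2), c(0.2, 0.2)), "degenerate")
})

test_that("two-component SPLIT reconstructs the source image exactly", {
  stk <- simulate_msted(small_sim_config(k = 8, shape = 128L,
                                         n_emitters = 25L, seed = 21))
  ph <- compute_phasor(stk)
  refs <- select_references(ph, cloud_statistics(ph))
  for (src in list("last", 5:8)) {
    sp <- split_two_component(stk, ph, refs, source = src)
    expect_lt(max(abs(sp$F_in + sp$F_out - sp$F_sted)), 1e-9)
    expect_true(all(sp$f_in >= 0 & sp$f_in <= 1))
    expect_equal(sp$f_in + sp$f_out, matrix(1, 128, 128))
  }
  # f_in = 1 everywhere reduces SPLIT to a copy of the source
  ph1 <- ph; ph1$g[] <- refs$p_in[1]; ph1$s[] <- refs$p_in[2]
  sp1 <- split_two_component(stk, ph1, refs)
  v <- ph1$valid
  expect_equal(sp1$F_in[v], sp1$F_sted[v])
  expect_true(all(sp1$F_out[v] == 0))
})

test_that("signal-weighted clamped fraction stays below 20% on nominal stacks", {
  stk <- simulate_msted(small_sim_config(k = 8, s_max = 30, seed = 23))
  ph <- compute_phasor(stk)
  refs <- select_references(ph, cloud_statistics(ph))
  sp <- split_two_component(stk, ph, refs)
  expect_lt(sp$clamped_fraction, 0.20)
  expect_gte(sp$clamped_fraction, 0)
})

test_that("the ramp background phasor matches the DFT and its two-frame limit", {
  expect_equal(background_phasor(2), c(-1, 0))
  for (n in c(4, 8)) {
    b <- (0:(n - 1)) / (n - 1)
    expect_equal(background_phasor(n), unname(phasor_fft_oracle(b, 1)),
                 tolerance = 1e-12)
  }
  # a constant vector, by contrast, sits at the origin
  cst <- theoretical_phasor(0, 8)
  expect_equal(c(cst$g, cst$s), c(0, 0), tolerance = 1e-14)
})

test_that("three-component SPLIT assigns pure dynamics to their components", {
  cfg <- small_sim_config(k = 8, s_max = 40, shape = 64L, n_emitters = 4L,
                          b_max_percent = 20, exc_modulated = TRUE, seed = 2)
  stk <- simulate_msted(cfg)
  n <- stk$protocol$n_frames
  g0 <- protocol_gamma0(stk$protocol)
  ph <- compute_phasor(stk, smooth_radius = 0)
  # overwrite three pixels with exact reference dynamics
  p_in <- unlist(theoretical_phasor(g0, n))
  p_out <- unlist(theoretical_phasor(g0 + 8 / (n - 1), n))
  p_bk <- background_phasor(n)
  ph$g[1, 1] <- p_in[1];  ph$s[1, 1] <- p_in[2]
  ph$g[2, 2] <- p_out[1]; ph$s[2, 2] <- p_out[2]
  ph$g[3, 3] <- p_bk[1];  ph$s[3, 3] <- p_bk[2]
  ph$valid[1:3, 1:3] <- TRUE
  sp <- split_three_component(stk, ph, 8)
  expect_equal(sp$f_in[1, 1], 1, tolerance = 1e-9)
  expect_equal(sp$f_out[2, 2], 1, tolerance = 1e-9)
  expect_equal(sp$f_bkgd[3, 3], 1, tolerance = 1e-9)
  # exact reconstruction and simplex fractions
  v <- sp$valid
  expect_lt(max(abs((sp$F_in + sp$F_out + sp$F_bkgd - sp$F_sted)[v])), 1e-9)
  expect_true(all(sp$f_in >= 0 & sp$f_out >= 0 & sp$f_bkgd >= 0))
  expect_equal((sp$f_in + sp$f_out + sp$f_bkgd)[v],
               rep(1, sum(v)), tolerance = 1e-12)
  # requires a modulated-excitation protocol
  stk2 <- simulate_msted(small_sim_config(shape = 64L, n_emitters = 4L))
  ph2 <- compute_phasor(stk2, smooth_radius = 0)
  expect_error(split_three_component(stk2, ph2, 8), "modulated-excitation")
})

test_that("SPLIT narrows the two-emitter valley and the resolvable separation", {
  seps <- seq(120, 240, by = 20)
  c_src <- c_in <- numeric(length(seps))
  for (i in seq_along(seps)) {
    stk <- two_emitter_stack(seps[i], s_max = 100, noise = FALSE,
                             splat = "bilinear")
    ph <- compute_phasor(stk, smooth_radius = 0, min_counts = 0.5)
    refs <- select_references(ph, cloud_statistics(ph))
    sp <- split_two_component(stk, ph, refs)
    c_src[i] <- valley_contrast(sp$F_sted, seps[i])
    c_in[i] <- valley_contrast(sp$F_in, seps[i])
  }
  # deeper valley at every separation
  expect_true(all(c_in < c_src))
  # strictly smaller minimum resolvable separation (valley < 0.75 x peaks)
  expect_lt(crossing_separation(seps, c_in),
            crossing_separation(seps, c_src))
})

test_that("co-aligned background defeats two-component SPLIT (no contrast gain)", {
  # constant excitation: the ramp background phasor is collinear with the
  # depletion axis, so its photons project onto f_in and the valley stays
  stk <- two_emitter_stack(160, s_max = 40, b_max = 30, seed = 33)
  ph <- compute_phasor(stk)
  refs <- select_references(ph, cloud_statistics(ph))
  sp <- split_two_component(stk, ph, refs)
  c_src <- valley_contrast(sp$F_sted, 160)
  c_in <- valley_contrast(sp$F_in, 160)
  expect_lt((c_src - c_in) / c_src, 0.05)
})
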