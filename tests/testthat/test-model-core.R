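test_that("STED PSF model evaluates the confocal and depleted exponents", {
  # on axis both exponents vanish regardless of depletion
  expect_equal(sted_psf(0, 200, 8), 1)
  expect_equal(sted_psf(0, 350, 0), 1)
  # at the confocal waist: confocal factor exp(-2), depletion exp(-level)
  expect_equal(sted_psf(200, 200, 8), exp(-10))
  expect_equal(sted_psf(200, 200, 0), exp(-2), tolerance = 1e-12)
  # strictly decreasing in radius
  r <- seq(0, 600, by = 10)
  expect_true(all(diff(sted_psf(r, 200, 5)) < 0))
  expect_error(sted_psf(NaN, 200, 1), "finite")
  expect_error(sted_psf(100, 200, -1), ">= 0")
})

test_that("effective waist shrinks as 1/sqrt(1 + k/2)", {
  expect_equal(effective_waist(200, 0), 200)
  expect_equal(effective_waist(200, 8) / 200, 1 / sqrt(5))
  expect_equal(effective_waist(200, 8), 200 / sqrt(5))
  # strictly decreasing in k
  ks <- seq(0, 20, by = 0.5)
  expect_true(all(diff(effective_waist(200, ks)) < 0))
})

test_that("modulated signal follows the ramped-depletion decay", {
  p <- msted_protocol(n_frames = 8, k = 8)
  # centre is undepleted: constant emission across the stack
  expect_equal(modulated_signal(0, 1:8, p, 200), rep(1, 8))
  # r = w_c, last frame: full confocal and depletion exponents
  expect_equal(modulated_signal(200, 8, p, 200), exp(-2) * exp(-8))
  # excitation decay alone scales the centre signal
  pe <- msted_protocol(n_frames = 8, k = 8, tau_exc = 4)
  expect_equal(modulated_signal(0, 5, pe, 200) / modulated_signal(0, 1, pe, 200),
               exp(-1))
  expect_error(modulated_signal(0, 9, p, 200), "out of range")
  # linear ramp gives an exponential decay in j at fixed r
  sig <- modulated_signal(150, 1:8, p, 200)
  rate <- depletion_rate(150, 8, 200, 8)
  expect_equal(sig / sig[1], exp(-rate * (0:7)), tolerance = 1e-12)
})

test_that("theoretical phasor matches the DFT oracle and its limits", {
  # constant signal maps to the origin
  ph <- theoretical_phasor(0, 8)
  expect_equal(c(ph$g, ph$s), c(0, 0), tolerance = 1e-14)
  ph2 <- theoretical_phasor(0, 5)
  expect_equal(c(ph2$g, ph2$s), c(0, 0), tolerance = 1e-14)
  # instantaneous decay: all weight in frame 1
  phi <- theoretical_phasor(Inf, 8)
  expect_equal(c(phi$g, phi$s), c(1, 0))
  # brute-force DFT evaluation at gamma = 1, n = 8, first harmonic
  w <- exp(-(0:7))
  expect_equal(unlist(theoretical_phasor(1, 8, 1)),
               c(g = phasor_fft_oracle(w, 1)[["g"]],
                 s = phasor_fft_oracle(w, 1)[["s"]]),
               tolerance = 1e-12, ignore_attr = TRUE)
  # higher harmonic against the oracle too
  expect_equal(unlist(theoretical_phasor(0.7, 6, 2)),
               phasor_fft_oracle(exp(-0.7 * (0:5)), 2),
               tolerance = 1e-12, ignore_attr = TRUE)
  # modulation grows monotonically with the decay rate, origin -> (1, 0)
  gammas <- seq(0, 6, by = 0.25)
  ph <- theoretical_phasor(gammas, 8)
  M <- sqrt(ph$g^2 + ph$s^2)
  expect_true(all(diff(M) > 0))
  expect_lt(max(M), 1 + 1e-12)
})

test_that("averaged single-emitter render reproduces the hyperbolic depletion curve", {
  # image-mean of the tunable-PSF render of one emitter is the closed form
  # 1 / (1 + (k/2)(j-1)/(n-1)) once normalised to the confocal frame
  cfg <- msted_sim_config(image_shape = c(65L, 65L), k = 8, n_emitters = 0L,
                          field_diameter_um = 2, seed = 1)
  em <- data.frame(x_nm = 0, y_nm = 0, weight = 1)
  ren <- render_noiseless(em, cfg)
  means <- apply(ren$stack, 1, mean)
  jj <- 1:8
  expect_equal(means / means[1], 1 / (1 + 4 * (jj - 1) / 7),
               tolerance = 1e-3)
})

test_that("effective SPLIT PSF sharpens the STED PSF and respects its limits", {
  p <- msted_protocol(n_frames = 8, k = 8)
  # P_out at infinity makes the SPLIT weighting inactive: plain STED waist
  refs_far <- split_references(c(0, 0), c(1e8, 0))
  ep <- effective_split_psf(8, p, refs = refs_far)
  expect_equal(ep$w_over_wc, 1 / sqrt(5), tolerance = 1e-3)
  # defaults: SPLIT can only sharpen
  ed <- effective_split_psf(8, p)
  expect_lt(ed$w_over_wc, 1 / sqrt(5))
  expect_gt(ed$w_over_wc, 0)
  # fitted profile agrees with the tabulated product profile it was fit to
  pred <- stats::predict(ed$fit)
  expect_lt(sqrt(mean((pred - ed$profile)^2)), 0.05 * max(ed$profile))
  # tighter references (larger P_in-P_out separation shrink) sharpen more
  refs_near <- split_references(c(0, 0),
                                unlist(theoretical_phasor(8 / 7 / 2, 8)))
  en <- effective_split_psf(8, p, refs = refs_near)
  expect_lt(en$w_over_wc, ed$w_over_wc)
  expect_error(effective_split_psf(0, p), "positive")
})
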