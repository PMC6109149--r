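make_stack <- function(counts) {
  msted_stack(counts, msted_protocol(n_frames = dim(counts)[1],
                                     k = dim(counts)[1] - 1))
}

test_that("per-pixel phasors match the DFT on canonical count patterns", {
  # constant stack: every pixel at the origin, all valid
  cst <- make_stack(array(5, dim = c(8, 6, 6)))
  ph <- compute_phasor(cst, smooth_radius = 0, min_counts = 1)
  expect_true(all(ph$valid))
  expect_equal(max(abs(ph$g)), 0, tolerance = 1e-12)
  expect_equal(max(abs(ph$s)), 0, tolerance = 1e-12)

  # all counts in frame 1: delta at phase 0 -> (1, 0)
  a <- array(0, dim = c(8, 4, 4)); a[1, , ] <- 20
  ph <- compute_phasor(make_stack(a), smooth_radius = 0, min_counts = 1)
  expect_equal(unique(as.vector(ph$g)), 1)
  expect_equal(unique(as.vector(ph$s)), 0)

  # n = 4, counts only in frame 2 -> (cos(pi/2), sin(pi/2)) = (0, 1)
  a <- array(0, dim = c(4, 3, 3)); a[2, , ] <- 7
  ph <- compute_phasor(make_stack(a), smooth_radius = 0, min_counts = 1)
  expect_equal(as.vector(ph$g), rep(0, 9), tolerance = 1e-12)
  expect_equal(as.vector(ph$s), rep(1, 9), tolerance = 1e-12)
})

test_that("phasor equals the brute-force transform on random stacks, any harmonic", {
  set.seed(42)
  for (n in c(3, 5, 8)) {
    counts <- array(rpois(n * 5 * 4, lambda = 20), dim = c(n, 5, 4))
    for (h in c(1L, n - 1L)) {
      ph <- compute_phasor(make_stack(counts), harmonic = h,
                           smooth_radius = 0, min_counts = 1)
      for (i in 1:5) for (j in 1:4) {
        oracle <- phasor_fft_oracle(counts[, i, j], h)
        expect_equal(c(ph$g[i, j], ph$s[i, j]), oracle,
                     tolerance = 1e-12, ignore_attr = TRUE)
      }
    }
  }
})

test_that("two-frame stacks have identically null s", {
  set.seed(1)
  counts <- array(rpois(2 * 16 * 16, 15), dim = c(2, 16, 16))
  ph <- compute_phasor(make_stack(counts), smooth_radius = 0, min_counts = 1)
  expect_true(all(ph$s == 0))
  expect_true(all(abs(ph$g) <= 1))
})

test_that("dim and empty pixels are masked instead of propagating NaN", {
  a <- array(0, dim = c(4, 3, 3))
  a[, 2, 2] <- c(30, 20, 10, 5)     # one bright pixel
  a[, 1, 1] <- c(2, 1, 0, 0)        # dim pixel below threshold
  ph <- compute_phasor(make_stack(a), smooth_radius = 0, min_counts = 10)
  expect_true(ph$valid[2, 2])
  expect_false(ph$valid[1, 1])
  expect_false(ph$valid[3, 3])      # all-zero pixel
  expect_false(anyNA(ph$g)); expect_false(anyNA(ph$s))
  expect_equal(ph$M[1, 1], 0)
})

test_that("median smoothing of g/s matches a direct median oracle", {
  set.seed(3)
  img <- matrix(rnorm(15 * 11), 15, 11)
  sm <- msted:::median_filter(img, 1L)
  # interior pixel: median over the 3x3 neighbourhood
  for (p in list(c(5, 5), c(2, 9), c(14, 2))) {
    nb <- img[(p[1] - 1):(p[1] + 1), (p[2] - 1):(p[2] + 1)]
    expect_equal(sm[p[1], p[2]], median(as.vector(nb)))
  }
  # edge replication: corner uses clamped indices
  nb <- img[c(1, 1, 2), c(1, 1, 2)]
  expect_equal(sm[1, 1], median(as.vector(nb)))
})

test_that("cloud statistics recover orientation and spreads, with rotation equivariance", {
  set.seed(11)
  npt <- 400
  gr <- 0.4 + rnorm(npt, 0, 0.10)   # elongated along the g-axis
  sr <- rnorm(npt, 0, 0.02)
  ph <- make_phasor_field(matrix(gr, 20, 20), matrix(sr, 20, 20))
  st <- cloud_statistics(ph, weights = "none")
  expect_equal(st$phi0, 0, tolerance = 0.05)
  expect_equal(st$delta_M, 0.10, tolerance = 0.15)
  expect_equal(st$delta_N, 0.02, tolerance = 0.15)
  expect_false(st$degenerate)

  # rotating the cloud by alpha shifts phi0 by alpha, spreads unchanged
  alpha <- 0.5
  g2 <- gr * cos(alpha) - sr * sin(alpha)
  s2 <- gr * sin(alpha) + sr * cos(alpha)
  st2 <- cloud_statistics(make_phasor_field(matrix(g2, 20, 20),
                                            matrix(s2, 20, 20)),
                          weights = "none")
  expect_equal(st2$phi0, st$phi0 + alpha, tolerance = 1e-6)
  expect_equal(st2$delta_M, st$delta_M, tolerance = 1e-9)
  expect_equal(st2$delta_N, st$delta_N, tolerance = 1e-9)

  # isotropic cloud: no preferred direction information
  gi <- 0.3 + rnorm(npt, 0, 0.05); si <- 0.3 + rnorm(npt, 0, 0.05)
  sti <- cloud_statistics(make_phasor_field(matrix(gi, 20, 20),
                                            matrix(si, 20, 20)),
                          weights = "none")
  expect_equal(sti$delta_M / sti$delta_N, 1, tolerance = 0.25)

  # degenerate cloud: zero spreads, flagged
  std <- cloud_statistics(make_phasor_field(matrix(0.5, 4, 4),
                                            matrix(0.2, 4, 4)))
  expect_true(std$degenerate)
  expect_equal(std$delta_M, 0)
})

test_that("M0 rule divides the angular spread by the elongation excess", {
  st <- structure(list(phi0 = 0, delta_M = 0.3, delta_N = 0.1),
                  class = "phasor_cloud_stats")
  expect_equal(estimate_m0(st), 0.25)
  expect_equal(estimate_m0(st, m0 = 0), 0)
  expect_equal(estimate_m0(st, m0 = 2), 0.5)
  st_flat <- structure(list(phi0 = 0, delta_M = 0.1, delta_N = 0.1),
                       class = "phasor_cloud_stats")
  expect_error(estimate_m0(st_flat), "not elongated")
})

test_that("reference placement follows the modulation histogram", {
  set.seed(8)
  stk <- simulate_msted(small_sim_config(k = 8, seed = 3))
  ph <- compute_phasor(stk)
  st <- cloud_statistics(ph)
  refs <- select_references(ph, st)
  # sparse foci: undepleted centres bring the cloud close to the origin
  expect_lt(refs$M_in, 0.15)
  expect_equal(refs$M_out - refs$M_in, refs$M_0)
  expect_equal(sqrt(sum(refs$p_in^2)), refs$M_in, tolerance = 1e-9)
  # median percentile honours the histogram
  refs50 <- select_references(ph, st, percentile = 50)
  expect_equal(refs50$M_in, median(ph$M[ph$valid]))
  # crowded sample: modulated light everywhere opens a gap from the origin
  crowd <- simulate_msted(msted_sim_config(image_shape = c(256L, 256L),
                                           w_c_nm = 400, k = 8,
                                           object_kind = "crowded_foci",
                                           n_emitters = 1200L,
                                           field_diameter_um = 8, seed = 5))
  phc <- compute_phasor(crowd)
  refc <- select_references(phc, cloud_statistics(phc))
  expect_gt(refc$M_in, refs$M_in)
})

test_that("lower SNR widens the angular spread of matched simulations", {
  st30 <- cloud_statistics(compute_phasor(
    simulate_msted(small_sim_config(k = 5, s_max = 30, seed = 17))))
  st10 <- cloud_statistics(compute_phasor(
    simulate_msted(small_sim_config(k = 5, s_max = 10, seed = 17))))
  expect_gt(st10$delta_N, st30$delta_N)
  # and the radial elongation dominates the angular spread when SPLIT works
  expect_gt(st30$delta_M, st30$delta_N)
})
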