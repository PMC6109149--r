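# Shared fixtures: small simulated stacks and two-emitter benchmarks.
# Everything is generated in code under fixed seeds; no stored data.

# compact sparse-foci simulation for unit tests (fast: 256^2 or smaller)
small_sim_config <- function(k = 8, s_max = 30, shape = 256L,
                             n_emitters = 60L, seed = 1L, ...) {
  msted_sim_config(image_shape = c(shape, shape), k = k, s_max = s_max,
                   n_emitters = n_emitters,
                   field_diameter_um = 0.8 * shape * 40 / 1000,
                   seed = seed, ...)
}

# stack with two emitters sep_nm apart on the central row
two_emitter_stack <- function(sep_nm, k = 8, s_max = 100, b_max = 0,
                              exc_modulated = FALSE, seed = 1L,
                              shape = 65L, noise = TRUE,
                              splat = "nearest") {
  cfg <- msted_sim_config(image_shape = c(shape, shape), k = k,
                          s_max = s_max, b_max_percent = b_max,
                          exc_modulated = exc_modulated,
                          n_emitters = 0L, field_diameter_um = 2,
                          splat = splat, seed = seed)
  em <- data.frame(x_nm = c(-sep_nm / 2, sep_nm / 2), y_nm = c(0, 0),
                   weight = c(1, 1))
  set.seed(seed)
  ren <- render_noiseless(em, cfg)
  ren <- add_sted_background(ren, em, cfg)
  if (noise) apply_poisson(ren, truth = list(emitters = em))
  else msted_stack(ren$stack, ren$protocol,
                   truth = list(emitters = em,
                                background = ren$background,
                                noiseless = ren$stack))
}

# valley-to-peak contrast of the central-row profile of a two-emitter image
valley_contrast <- function(img, sep_nm, pixel_size_nm = 40) {
  shape <- nrow(img)
  mid <- (shape + 1) / 2
  prof <- colMeans(img[(mid - 1):(mid + 1), ])
  c1 <- floor(mid - sep_nm / 2 / pixel_size_nm)
  c2 <- ceiling(mid + sep_nm / 2 / pixel_size_nm)
  pk <- c(max(prof[max(1, c1 - 1):(c1 + 1)]),
          max(prof[(c2 - 1):min(shape, c2 + 1)]))
  min(prof[c1:c2]) / mean(pk)
}

# separation at which a contrast-vs-separation curve crosses the threshold,
# by linear interpolation (curves decrease with separation)
crossing_separation <- function(seps, contrasts, threshold = 0.75) {
  above <- contrasts > threshold
  if (!any(above)) return(min(seps))
  if (all(above)) return(Inf)
  i <- max(which(above))
  s0 <- seps[i]; s1 <- seps[i + 1]
  c0 <- contrasts[i]; c1 <- contrasts[i + 1]
  s0 + (s1 - s0) * (c0 - threshold) / (c0 - c1)
}

# build a phasor_field by hand from g/s matrices (for cloud-geometry tests)
make_phasor_field <- function(g, s, total = NULL, valid = NULL,
                              harmonic = 1L) {
  if (is.null(total)) total <- matrix(100, nrow(g), ncol(g))
  if (is.null(valid)) valid <- matrix(TRUE, nrow(g), ncol(g))
  structure(list(g = g, s = s, M = sqrt(g^2 + s^2), phi = atan2(s, g),
                 total = total, valid = valid, harmonic = harmonic),
            class = "phasor_field")
}

# independent per-pixel phasor oracle via the discrete Fourier transform:
# g + i s is the conjugated h-th FFT coefficient over the frame axis
phasor_fft_oracle <- function(counts_vec, h = 1L) {
  z <- Conj(stats::fft(counts_vec))[h + 1] / sum(counts_vec)
  c(g = Re(z), s = Im(z))
}
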