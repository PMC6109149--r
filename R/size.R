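#' Apparent structure size by image correlation spectroscopy
#'
#' Estimates the mean apparent size of spot-like structures from the width
#' of the image's spatial autocorrelation peak. The normalised
#' autocovariance
#' \eqn{G(\xi,\eta) = \langle \delta I(x,y)\, \delta I(x+\xi, y+\eta)
#' \rangle / \langle I \rangle^2}
#' of a field of Gaussian spots of waist `w` is itself Gaussian with a
#' \eqn{1/e^2} correlation radius \eqn{\omega = \sqrt{2} w}, so an
#' isotropic Gaussian plus offset is fitted to the central correlation peak
#' — excluding the zero-lag point, which carries the uncorrelated
#' shot-noise spike — and the apparent size is returned as the FWHM-style
#' quantity \eqn{\Sigma = \sqrt{2 \ln 2}\, w}.
#'
#' @param image Numeric matrix (background-subtracted intensities).
#' @param pixel_size_nm Pixel pitch in nm.
#' @param max_lag_factor Fit radius in units of the initial width guess
#'   (default 3).
#' @return A list with `sigma_nm` (apparent size \eqn{\Sigma}),
#'   `w_spot_nm` (the underlying spot waist), `omega_corr_nm`, and the
#'   `nls` fit.
#' @export
apparent_size_ics <- function(image, pixel_size_nm, max_lag_factor = 3) {
  if (!is.matrix(image)) stop("'image' must be a matrix")
  mu <- mean(image)
  if (!is.finite(mu) || mu <= 0) stop("image mean must be positive")
  H <- nrow(image); W <- ncol(image)
  dI <- image - mu
  Fc <- stats::fft(dI)
  num <- Re(stats::fft(Fc * Conj(Fc), inverse = TRUE)) / (H * W)
  G <- num / (H * W) / mu^2
  # lag grid (wrap-around order)
  ly <- pmin(0:(H - 1), H - (0:(H - 1)))
  lx <- pmin(0:(W - 1), W - (0:(W - 1)))
  rho_px <- sqrt(outer(ly^2, lx^2, "+"))
  # peak amplitude from the four unit lags; must rise above the offset
  unit <- rho_px > 0.5 & rho_px < 1.5
  A0 <- mean(G[unit])
  far <- rho_px > min(H, W) / 4
  offset0 <- stats::median(G[far])
  # the peak must rise above the far-field fluctuations of the correlogram
  if (!is.finite(A0) || A0 - offset0 < 3 * stats::sd(G[far]))
    stop("no correlation peak above the offset: no resolvable structure")
  # initial width: radius where the radial mean of G decays by e^-2
  lim <- (A0 - offset0) * exp(-2) + offset0
  rmax <- floor(min(H, W) / 4)
  radial <- vapply(seq_len(rmax), function(r)
    mean(G[rho_px >= r - 0.5 & rho_px < r + 0.5]), numeric(1))
  below <- which(radial < lim)
  w0_px <- if (length(below)) max(1, below[1]) else rmax / 2
  sel <- rho_px > 0 & rho_px <= max_lag_factor * w0_px
  df <- data.frame(rho = rho_px[sel] * pixel_size_nm, G = G[sel])
  fit <- minpack.lm::nlsLM(
    G ~ A * exp(-2 * rho^2 / omega^2) + c0, data = df,
    start = list(A = A0 - offset0, omega = w0_px * pixel_size_nm,
                 c0 = offset0),
    lower = c(0, pixel_size_nm / 10, -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 300))
  omega <- stats::coef(fit)[["omega"]]
  w_spot <- omega / sqrt(2)
  list(sigma_nm = sqrt(2 * log(2)) * w_spot,
       w_spot_nm = w_spot,
       omega_corr_nm = omega,
       fit = fit)
}

#' FWHM of peaks in a line profile by multi-Gaussian fitting
#'
#' Least-squares fit of a sum of `n_peaks` Gaussians plus a constant
#' offset to a 1-D intensity profile; returns the full width at half
#' maximum \eqn{2\sqrt{2\ln 2}\,\mathrm{sd}} of each peak.
#'
#' @param profile Numeric vector of intensities.
#' @param x Positions in nm (default `pixel_size_nm * (0:(length-1))`).
#' @param n_peaks Number of Gaussian peaks to fit.
#' @param pixel_size_nm Pixel pitch used when `x` is not given.
#' @return A list with `fwhm_nm`, `centers_nm`, `amplitudes`, the fit
#'   object and a logical `overlapping` flag set when fitted peaks are
#'   closer than their mean FWHM.
#' @export
fwhm_profile <- function(profile, n_peaks = 1L, x = NULL,
                         pixel_size_nm = 1) {
  profile <- as.numeric(profile)
  if (is.null(x)) x <- (seq_along(profile) - 1) * pixel_size_nm
  if (length(x) != length(profile)) stop("'x'/'profile' length mismatch")
  if (n_peaks < 1L) stop("'n_peaks' must be >= 1")
  # initial guesses: highest local maxima with mutual separation
  is_max <- which(diff(sign(diff(profile))) < 0) + 1L
  if (!length(is_max)) is_max <- which.max(profile)
  ord <- is_max[order(profile[is_max], decreasing = TRUE)]
  centers <- c()
  min_sep <- (max(x) - min(x)) / (4 * n_peaks)
  for (i in ord) {
    if (!length(centers) || all(abs(x[i] - centers) > min_sep))
      centers <- c(centers, x[i])
    if (length(centers) == n_peaks) break
  }
  if (length(centers) < n_peaks)
    stop("could not locate ", n_peaks, " distinct peaks in the profile")
  amp0 <- stats::approx(x, profile, xout = centers)$y
  sd0 <- rep((max(x) - min(x)) / (8 * n_peaks), n_peaks)
  terms <- paste0("A", seq_len(n_peaks),
                  " * exp(-(x - c", seq_len(n_peaks), ")^2 / (2 * s",
                  seq_len(n_peaks), "^2))")
  form <- stats::as.formula(paste("y ~", paste(terms, collapse = " + "),
                                  "+ b0"))
  start <- c(stats::setNames(as.list(amp0), paste0("A", seq_len(n_peaks))),
             stats::setNames(as.list(centers), paste0("c", seq_len(n_peaks))),
             stats::setNames(as.list(sd0), paste0("s", seq_len(n_peaks))),
             list(b0 = min(profile)))
  lower <- c(rep(0, n_peaks), rep(min(x), n_peaks),
             rep(diff(range(x)) / 1e4, n_peaks), -Inf)
  fit <- minpack.lm::nlsLM(form, data = data.frame(x = x, y = profile),
                           start = start, lower = lower,
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  sds <- abs(cf[paste0("s", seq_len(n_peaks))])
  ctr <- cf[paste0("c", seq_len(n_peaks))]
  fwhm <- 2 * sqrt(2 * log(2)) * sds
  overlapping <- FALSE
  if (n_peaks > 1L) {
    seps <- abs(diff(sort(ctr)))
    overlapping <- any(seps < mean(fwhm))
    if (overlapping)
      warning("fitted peaks closer than their FWHM: likely unresolved")
  }
  list(fwhm_nm = unname(fwhm), centers_nm = unname(ctr),
       amplitudes = unname(cf[paste0("A", seq_len(n_peaks))]),
       overlapping = overlapping, fit = fit)
}

#' Relative effective PSF size of a SPLIT image
#'
#' Size of the effective PSF of a SPLIT image relative to confocal,
#' computed from the fitted saturation factor and the reference phasors
#' used for the decomposition (see [effective_split_psf()]). With SPLIT
#' disabled (`refs = NULL` and `split = FALSE`) this reduces to the
#' analytic ratio \eqn{1/\sqrt{1 + k/2}} of the plain STED PSF.
#'
#' @param k Saturation factor, or a `depletion_fit` from which `k` is
#'   taken.
#' @param protocol An [msted_protocol()].
#' @param refs Optional [split_references()] actually used for SPLIT.
#' @param split If `FALSE`, return the plain STED ratio (no SPLIT
#'   weighting).
#' @param ... Passed to [effective_split_psf()].
#' @return `w / w_c` in `(0, 1]`.
#' @export
relative_psf_size <- function(k, protocol, refs = NULL, split = TRUE, ...) {
  if (inherits(k, "depletion_fit")) k <- k$k
  if (k < 1e-9) return(1)
  if (!split) return(1 / sqrt(1 + k / 2))
  effective_split_psf(k, protocol, refs = refs, ...)$w_over_wc
}

#' Spot-variation regression for true object size
#'
#' Images of the same objects acquired (or SPLIT-processed) with effective
#' PSFs of different size obey
#' \deqn{\Sigma^2 = \sigma^2 + (2\ln 2)\, w_c^2 (w/w_c)^2,}
#' so regressing the squared apparent size on the squared relative PSF
#' size yields the true object size \eqn{\sigma} from the intercept and
#' the confocal waist \eqn{w_c} from the slope — no PSF calibration
#' needed.
#'
#' @param points Data frame with columns `sigma_app_sq` (nm^2) and
#'   `rel_psf_sq` (dimensionless, in `(0, 1]`).
#' @param weights Optional regression weights.
#' @return An object of class `size_regression` with `sigma_nm`,
#'   `w_c_nm`, their standard errors (first-order propagation from the
#'   regression covariance), `intercept`, `slope`, `n_points`, the `lm`
#'   fit and a `point_like` flag (intercept not above zero).
#' @export
fit_size_extrapolation <- function(points, weights = NULL) {
  req <- c("sigma_app_sq", "rel_psf_sq")
  if (!all(req %in% names(points)))
    stop("'points' needs columns sigma_app_sq and rel_psf_sq")
  if (nrow(points) < 3L)
    stop("need at least 3 points spanning distinct rel_psf_sq values")
  if (length(unique(round(points$rel_psf_sq, 10))) < 2L)
    stop("rel_psf_sq values are all identical: regression undetermined")
  fit <- stats::lm(sigma_app_sq ~ rel_psf_sq, data = points,
                   weights = weights)
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  intercept <- cf[[1]]; slope <- cf[[2]]
  c2 <- 2 * log(2)
  if (slope <= 0) stop("non-positive slope: apparent size does not grow ",
                       "with the PSF size")
  w_c <- sqrt(slope / c2)
  se_wc <- se[[2]] / (2 * c2 * w_c)
  sigma <- if (intercept > 0) sqrt(intercept) else 0
  se_sigma <- if (intercept > 0) se[[1]] / (2 * sigma) else NA_real_
  structure(list(sigma_nm = sigma, stderr_sigma = se_sigma,
                 w_c_nm = w_c, stderr_w_c = se_wc,
                 intercept = intercept, stderr_intercept = se[[1]],
                 slope = slope, stderr_slope = se[[2]],
                 n_points = nrow(points),
                 point_like = intercept <= 0,
                 fit = fit),
            class = "size_regression")
}

#' @export
print.size_regression <- function(x, ...) {
  cat("Spot-variation size regression (", x$n_points, " points)\n",
      sep = "")
  if (x$point_like) {
    cat("  object size: point-like within error (intercept <= 0)\n")
  } else {
    cat(sprintf("  object size sigma: %.1f +/- %.1f nm\n",
                x$sigma_nm, x$stderr_sigma))
  }
  cat(sprintf("  confocal waist w_c: %.1f +/- %.1f nm\n",
              x$w_c_nm, x$stderr_w_c))
  invisible(x)
}

#' Spot-variation scan over saturation factors and SPLIT parameters
#'
#' Generates (or analyses) a series of images of the same kind of
#' point-like objects at different effective PSF sizes and collects the
#' `(Sigma^2, (w/w_c)^2)` points for [fit_size_extrapolation()]. For each
#' saturation factor in `ks` a sparse point-emitter stack is simulated,
#' the saturation is re-fitted from its depletion curve, and SPLIT images
#' are produced for every value of the reference-separation constant `m0`;
#' the apparent size of each SPLIT image is measured by
#' [apparent_size_ics()] and paired with the effective PSF size predicted
#' by [relative_psf_size()] from the fitted `k` and the reference phasors
#' actually used.
#'
#' Phasor smoothing is off here by design: median filtering correlates
#' neighbouring pixels and would bias the autocorrelation-based size
#' estimate, whereas unsmoothed shot noise is confined to the zero lag,
#' which the ICS fit excludes.
#'
#' @param ks Saturation factors to scan.
#' @param m0s Values of the `m0` constant, each yielding one SPLIT image
#'   per stack.
#' @param s_max,n_emitters,image_shape,w_c_nm,pixel_size_nm,n_frames
#'   Simulation settings, see [msted_sim_config()].
#' @param seed Base RNG seed; each stack uses `seed + 13 * i` for stack
#'   index `i`.
#' @param min_counts,percentile Analysis settings.
#' @return A data frame of size points with columns `sigma_app_sq`,
#'   `rel_psf_sq`, `k_set`, `k_fit`, `m0`, `sigma_app_nm`.
#' @export
spot_variation_scan <- function(ks = c(2, 4, 6, 8), m0s = c(0.6, 1, 1.6),
                                s_max = 30, n_emitters = 150L,
                                image_shape = c(512L, 512L), w_c_nm = 200,
                                pixel_size_nm = 40, n_frames = 8L,
                                seed = 1L, min_counts = 10, percentile = 1) {
  rows <- list()
  for (i in seq_along(ks)) {
    k <- ks[i]
    cfg <- msted_sim_config(image_shape = image_shape,
                            pixel_size_nm = pixel_size_nm,
                            n_frames = n_frames, w_c_nm = w_c_nm,
                            k = k, s_max = s_max,
                            n_emitters = n_emitters,
                            seed = seed + 13L * i)
    stack <- simulate_msted(cfg)
    kfit <- fit_saturation(average_depletion_curve(stack))
    phasor <- compute_phasor(stack, smooth_radius = 0L,
                             min_counts = min_counts)
    stats <- cloud_statistics(phasor)
    for (m0 in m0s) {
      refs <- select_references(phasor, stats, percentile = percentile,
                                m0 = m0)
      sp <- split_two_component(stack, phasor, refs)
      ics <- apparent_size_ics(sp$F_in, pixel_size_nm)
      wr <- relative_psf_size(kfit$k, stack$protocol, refs = refs)
      rows[[length(rows) + 1L]] <-
        data.frame(sigma_app_sq = ics$sigma_nm^2,
                   rel_psf_sq = wr^2,
                   k_set = k, k_fit = kfit$k, m0 = m0,
                   sigma_app_nm = ics$sigma_nm)
    }
  }
  do.call(rbind, rows)
}
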