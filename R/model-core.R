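#' Closed-form M-STED point-spread-function model
#'
#' Radial fluorescence signal of a STED microscope under the parabolic
#' approximation of the doughnut depletion beam. A molecule at distance `r`
#' from the centre of the PSF emits
#' \deqn{i(r) = \exp(-2 r^2 / w_c^2) \exp(-\zeta r^2 / w_c^2),}
#' normalised to 1 on axis, where `w_c` is the confocal \eqn{1/e^2} waist and
#' \eqn{\zeta} is the relative STED intensity (in saturation units) at
#' \eqn{r = w_c}.
#'
#' @param r Distance from the PSF centre in nm (vectorised, `>= 0`).
#' @param w_c Confocal waist in nm.
#' @param sted_level Relative STED intensity \eqn{I_w/I_{sat}} (`>= 0`).
#' @return Relative intensity in `(0, 1]`.
#' @examples
#' sted_psf(0, 200, 8)              # 1 on axis
#' sted_psf(200, 200, 8)            # exp(-10)
#' @export
sted_psf <- function(r, w_c, sted_level) {
  if (any(!is.finite(r)) || any(r < 0)) stop("'r' must be finite and >= 0")
  if (!is.finite(w_c) || w_c <= 0) stop("'w_c' must be finite and positive")
  if (any(!is.finite(sted_level)) || any(sted_level < 0))
    stop("'sted_level' must be finite and >= 0")
  u <- (r / w_c)^2
  exp(-2 * u) * exp(-sted_level * u)
}

#' Effective waist of the STED PSF
#'
#' Under the parabolic doughnut approximation the effective waist at
#' saturation factor `k` is
#' \deqn{w = w_c / \sqrt{1 + k/2},}
#' so e.g. `k = 8` shrinks the PSF to \eqn{1/\sqrt{5} \approx 0.45} of its
#' confocal size.
#'
#' @param w_c Confocal waist in nm.
#' @param k Saturation factor \eqn{I_{max}/I_{sat}} (`>= 0`, vectorised).
#' @return Effective waist in the units of `w_c`.
#' @examples
#' effective_waist(200, 8) / 200    # 1/sqrt(5)
#' @export
effective_waist <- function(w_c, k) {
  if (!is.finite(w_c) || w_c <= 0) stop("'w_c' must be finite and positive")
  if (any(!is.finite(k)) || any(k < 0)) stop("'k' must be finite and >= 0")
  w_c / sqrt(1 + k / 2)
}

#' Expected modulated signal of a molecule along the stack
#'
#' Expected relative counts, in frame `j` of an M-STED acquisition, from a
#' molecule sitting at distance `r` from the PSF centre:
#' `exc_levels[j] * exp(-2 r^2/w_c^2) * exp(-sted_levels[j] * r^2/w_c^2)`.
#' For the linear STED ramp this is an exponential decay in `j` with
#' per-frame rate \eqn{\gamma(r) = \gamma_0 + k (r^2/w_c^2)/(n-1)}.
#'
#' @param r Distance from the PSF centre in nm.
#' @param j Frame index, `1 <= j <= n` (vectorised).
#' @param protocol An [msted_protocol()].
#' @param w_c Confocal waist in nm.
#' @return Relative expected counts.
#' @export
modulated_signal <- function(r, j, protocol, w_c) {
  stopifnot(inherits(protocol, "msted_protocol"))
  if (any(j < 1L) || any(j > protocol$n_frames) || any(j != round(j)))
    stop("frame index 'j' out of range 1..", protocol$n_frames)
  protocol$exc_levels[j] * sted_psf(r, w_c, protocol$sted_levels[j])
}

#' Per-frame depletion decay rate at distance r
#'
#' \eqn{\gamma(r) = \gamma_0 + k (r^2/w_c^2)/(n-1)} for the linear-ramp
#' protocol: the excitation decay rate plus the STED-induced rate that grows
#' quadratically with the distance from the PSF centre.
#'
#' @param r Distance from the PSF centre in nm (vectorised).
#' @param k Saturation factor.
#' @param w_c Confocal waist in nm.
#' @param n_frames Number of frames in the ramp.
#' @param gamma0 Excitation decay rate per frame (default 0, constant
#'   excitation).
#' @return Per-frame decay rate(s).
#' @export
depletion_rate <- function(r, k, w_c, n_frames, gamma0 = 0) {
  gamma0 + k * (r / w_c)^2 / (n_frames - 1)
}

#' Phasor of a discrete exponential decay
#'
#' First-harmonic (or harmonic `h`) phasor coordinates of the frame-wise
#' signal \eqn{e^{-\gamma (j-1)}}, `j = 1..n`:
#' \deqn{g = \sum_j e^{-\gamma (j-1)} \cos(2\pi h (j-1)/n) /
#'           \sum_j e^{-\gamma (j-1)}}
#' and analogously with the sine for `s`. A constant signal
#' (\eqn{\gamma = 0}) maps to the origin; an infinitely fast decay to
#' `(1, 0)`.
#'
#' @param gamma Per-frame decay rate (`>= 0`, vectorised).
#' @param n_frames Number of frames (`>= 2`).
#' @param harmonic Harmonic index `h`, `1 <= h <= n_frames - 1`.
#' @return A list with numeric components `g` and `s` (same length as
#'   `gamma`).
#' @examples
#' theoretical_phasor(0, 8)    # origin
#' theoretical_phasor(50, 8)   # close to (1, 0)
#' @export
theoretical_phasor <- function(gamma, n_frames, harmonic = 1L) {
  if (any(!is.finite(gamma) & !is.infinite(gamma)) || any(gamma < 0))
    stop("'gamma' must be >= 0")
  n <- as.integer(n_frames)
  if (n < 2L) stop("'n_frames' must be >= 2")
  h <- as.integer(harmonic)
  if (h < 1L || h > n - 1L) stop("'harmonic' must be in 1..n_frames-1")
  jj <- seq_len(n) - 1
  ang <- 2 * pi * h * jj / n
  ca <- phasor_basis(ang)
  g <- s <- numeric(length(gamma))
  for (i in seq_along(gamma)) {
    w <- exp(-gamma[i] * jj)
    if (is.infinite(gamma[i])) w <- c(1, rep(0, n - 1))
    tot <- sum(w)
    g[i] <- sum(w * ca$cos) / tot
    s[i] <- sum(w * ca$sin) / tot
  }
  list(g = g, s = s)
}

#' Phasor of the per-pixel decay family vs distance from the PSF centre
#'
#' Convenience wrapper mapping radius to the theoretical phasor of the decay
#' with rate [depletion_rate()].
#'
#' @inheritParams depletion_rate
#' @param harmonic Harmonic index.
#' @return A list with components `g` and `s`.
#' @keywords internal
phasor_at_radius <- function(r, k, w_c, n_frames, gamma0 = 0, harmonic = 1L) {
  theoretical_phasor(depletion_rate(r, k, w_c, n_frames, gamma0),
                     n_frames, harmonic)
}

#' Effective PSF of a SPLIT image
#'
#' Predicts the radial profile of an emitter in the SPLIT image `F_in` and
#' the effective waist ratio `w/w_c` it implies. A molecule at radius `r`
#' appears in the maximum-power STED frame with intensity
#' `sted_psf(r, w_c, k)` and is weighted by the centre fraction
#' `f_in` evaluated at the theoretical phasor of its decay rate
#' \eqn{\gamma(r)}; the product profile is fitted with a Gaussian
#' \eqn{A \exp(-2 r^2 / w^2)} and the fitted `w/w_c` returned.
#'
#' When `refs` is `NULL`, the periphery reference phasor is placed at the
#' theoretical decay of a molecule at `r = w_c` (rate
#' \eqn{\gamma_0 + k/(n-1)}) and the centre reference at \eqn{\gamma_0};
#' these are the references the SPLIT engine builds from a fitted `k` when
#' no data-driven references are supplied.
#'
#' @param k Saturation factor (`> 0`).
#' @param protocol An [msted_protocol()].
#' @param w_c Confocal waist in nm (enters only through `r/w_c`; default
#'   200).
#' @param refs Optional [split_references()] giving the actual `P_in`,
#'   `P_out` used to build the SPLIT image.
#' @param harmonic Harmonic index used for the phasors.
#' @param r_max_frac Extent of the tabulated radial grid in units of `w_c`.
#' @param n_r Number of radial grid points.
#' @return A list with `w_over_wc` (the fitted ratio), `radii_nm`,
#'   `profile` (the tabulated product profile) and `fit` (the `nls` object).
#' @examples
#' p <- msted_protocol(n_frames = 8, k = 8)
#' effective_split_psf(8, p)$w_over_wc   # < 1/sqrt(5): SPLIT sharpens
#' @export
effective_split_psf <- function(k, protocol, w_c = 200, refs = NULL,
                                harmonic = 1L, r_max_frac = 2, n_r = 401L) {
  stopifnot(inherits(protocol, "msted_protocol"))
  if (!is.finite(k) || k <= 0) stop("'k' must be finite and positive")
  n <- protocol$n_frames
  g0 <- protocol_gamma0(protocol)
  if (is.null(refs)) {
    p_in <- theoretical_phasor(g0, n, harmonic)
    p_out <- theoretical_phasor(g0 + k / (n - 1), n, harmonic)
    refs <- split_references(p_in = c(p_in$g, p_in$s),
                             p_out = c(p_out$g, p_out$s))
  }
  r <- seq(0, r_max_frac * w_c, length.out = n_r)
  ph <- phasor_at_radius(r, k, w_c, n, g0, harmonic)
  f_in <- fraction_in(ph$g, ph$s, refs)
  prof <- sted_psf(r, w_c, k) * f_in
  if (all(prof <= 0) || prof[1] <= 0 ||
      !any(prof < 0.5 * max(prof)))
    stop("degenerate SPLIT profile: cannot fit an effective waist")
  if (any(diff(prof) > 1e-9 + 1e-6 * max(prof)))
    stop("SPLIT profile is not radially decreasing; effective waist undefined")
  df <- data.frame(r = r, p = prof)
  w0 <- effective_waist(w_c, k)
  fit <- minpack.lm::nlsLM(p ~ A * exp(-2 * r^2 / w^2), data = df,
                           start = list(A = prof[1], w = w0),
                           lower = c(0, 1e-3),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  w <- abs(stats::coef(fit)[["w"]])
  list(w_over_wc = w / w_c, radii_nm = r, profile = prof, fit = fit)
}
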