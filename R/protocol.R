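#' Acquisition protocol of an M-STED stack
#'
#' Describes how the depletion (STED) and excitation powers vary across the
#' `n` frames of a modulation-enhanced STED acquisition. Frame `j` carries a
#' relative STED intensity `sted_levels[j]` expressed in units of the
#' saturation intensity (so the level equals \eqn{I_w(j)/I_{sat}} at
#' \eqn{r = w_c}), and a relative excitation level `exc_levels[j]`.
#'
#' The default modulation pattern is the linear ramp used throughout the
#' analysis: frame 1 is confocal (STED off) and frame `n` carries the maximum
#' saturation factor `k`, i.e. `sted_levels[j] = k * (j - 1) / (n - 1)`.
#' Excitation is either constant (the default) or an exponential decay
#' `exp(-(j - 1) / tau_exc)`, the protocol used to displace the
#' centre-of-PSF phasor away from the origin when STED-induced background
#' must be separated.
#'
#' @param n_frames Integer number of frames, at least 2.
#' @param k Maximum saturation factor \eqn{I_{max}/I_{sat}} reached in the
#'   last frame (used only when `sted_levels` is not given).
#' @param sted_levels Optional explicit vector of `n_frames` non-negative
#'   relative STED intensities.
#' @param exc_levels Optional explicit vector of `n_frames` strictly positive
#'   relative excitation intensities.
#' @param tau_exc Excitation decay constant in frame units; `Inf` (default)
#'   means constant excitation. The conventional modulated-excitation choice
#'   is `n_frames / 2`.
#' @param pixel_size_nm Physical pixel pitch in nanometres.
#'
#' @return An object of class `msted_protocol`.
#' @examples
#' p <- msted_protocol(n_frames = 8, k = 8)
#' p$sted_levels
#' @export
msted_protocol <- function(n_frames = 8, k = 8, sted_levels = NULL,
                           exc_levels = NULL, tau_exc = Inf,
                           pixel_size_nm = 40) {
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 2L)
    stop("'n_frames' must be an integer >= 2")
  if (!is.finite(pixel_size_nm) || pixel_size_nm <= 0)
    stop("'pixel_size_nm' must be positive")
  if (is.null(sted_levels)) {
    if (!is.finite(k) || k < 0) stop("'k' must be finite and >= 0")
    sted_levels <- k * (seq_len(n_frames) - 1) / (n_frames - 1)
  }
  if (length(sted_levels) != n_frames)
    stop("length of 'sted_levels' (", length(sted_levels),
         ") must equal 'n_frames' (", n_frames, ")")
  if (any(!is.finite(sted_levels)) || any(sted_levels < 0))
    stop("'sted_levels' must be finite and non-negative")
  if (is.null(exc_levels)) {
    exc_levels <- if (is.finite(tau_exc)) {
      if (tau_exc <= 0) stop("'tau_exc' must be positive")
      exp(-(seq_len(n_frames) - 1) / tau_exc)
    } else {
      rep(1, n_frames)
    }
  }
  if (length(exc_levels) != n_frames)
    stop("length of 'exc_levels' (", length(exc_levels),
         ") must equal 'n_frames' (", n_frames, ")")
  if (any(!is.finite(exc_levels)) || any(exc_levels <= 0))
    stop("'exc_levels' must be finite and strictly positive")
  structure(
    list(n_frames = n_frames,
         sted_levels = as.numeric(sted_levels),
         exc_levels = as.numeric(exc_levels),
         tau_exc = tau_exc,
         pixel_size_nm = pixel_size_nm),
    class = "msted_protocol")
}

#' @export
print.msted_protocol <- function(x, ...) {
  cat("M-STED acquisition protocol\n")
  cat("  frames:         ", x$n_frames, "\n")
  cat("  STED levels:    ", paste(signif(x$sted_levels, 3), collapse = ", "),
      "\n")
  exc <- if (all(x$exc_levels == 1)) "constant"
         else paste0("exponential (tau_exc = ", signif(x$tau_exc, 4), ")")
  cat("  excitation:     ", exc, "\n")
  cat("  pixel size [nm]:", x$pixel_size_nm, "\n")
  invisible(x)
}

#' Maximum saturation factor carried by a protocol
#'
#' For a linear-ramp protocol this is the saturation factor `k` reached in
#' the last frame.
#'
#' @param protocol An [msted_protocol()].
#' @return The largest relative STED level in the protocol.
#' @export
protocol_k <- function(protocol) {
  stopifnot(inherits(protocol, "msted_protocol"))
  max(protocol$sted_levels)
}

#' Excitation decay rate per frame implied by a protocol
#'
#' Returns \eqn{\gamma_0 = 1/\tau_{exc}}, the per-frame decay rate of the
#' excitation modulation (0 for constant excitation).
#'
#' @param protocol An [msted_protocol()].
#' @return Non-negative per-frame rate.
#' @export
protocol_gamma0 <- function(protocol) {
  stopifnot(inherits(protocol, "msted_protocol"))
  if (is.finite(protocol$tau_exc)) 1 / protocol$tau_exc else 0
}
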