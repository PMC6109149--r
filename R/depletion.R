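#' Image-averaged depletion curve
#'
#' Frame-wise mean intensity over (masked) pixels, normalised to frame 1.
#' For point-like objects imaged with the linear STED ramp the curve
#' follows
#' \deqn{\langle F_j \rangle / \langle F_1 \rangle =
#'       1 / (1 + (k/2)(j-1)/(n-1)),}
#' which is what [fit_saturation()] inverts to recover the saturation
#' factor `k`.
#'
#' @param stack An [msted_stack()].
#' @param mask Optional logical `H x W` matrix of pixels to average over;
#'   default all pixels.
#' @return An object of class `depletion_curve`: `ratios` (length `n`,
#'   `ratios[1] == 1`), `means`, `totals` (summed counts per frame, used as
#'   fit weights), `n_frames` and the protocol.
#' @export
average_depletion_curve <- function(stack, mask = NULL) {
  stopifnot(inherits(stack, "msted_stack"))
  n <- stack$protocol$n_frames
  d <- dim(stack$counts)
  if (is.null(mask)) {
    mask <- matrix(TRUE, d[2], d[3])
  } else {
    if (!is.logical(mask) || !all(dim(mask) == d[2:3]))
      stop("'mask' must be a logical H x W matrix matching the stack")
    if (!any(mask)) stop("'mask' selects no pixels")
  }
  mv <- as.vector(mask)
  means <- totals <- numeric(n)
  for (j in seq_len(n)) {
    fj <- as.vector(stack$counts[j, , , drop = TRUE])[mv]
    means[j] <- mean(fj)
    totals[j] <- sum(fj)
  }
  if (means[1] <= 0)
    stop("frame-1 mean is zero: cannot normalise the depletion curve")
  structure(list(ratios = means / means[1], means = means,
                 totals = totals, n_frames = n,
                 protocol = stack$protocol),
            class = "depletion_curve")
}

#' @export
print.depletion_curve <- function(x, ...) {
  cat("Depletion curve over", x$n_frames, "frames:\n ",
      paste(signif(x$ratios, 4), collapse = ", "), "\n")
  invisible(x)
}

# model ratios for the plain and background depletion curves
depletion_model <- function(j, n, k) {
  1 / (1 + (k / 2) * (j - 1) / (n - 1))
}
depletion_model_bg <- function(j, n, k, B, gamma0) {
  exp(-gamma0 * (j - 1)) / (1 + (k / 2) * (j - 1) / (n - 1)) +
    B * (j - 1) / (n - 1)
}

check_depletion_input <- function(curve) {
  stopifnot(inherits(curve, "depletion_curve"))
  lev <- curve$protocol$sted_levels
  if (length(unique(round(lev, 12))) < 2L)
    stop("the stack carries a single STED level: the saturation factor ",
         "cannot be obtained from images at one STED power")
}

#' Fit the saturation factor k from a depletion curve
#'
#' Weighted least-squares fit of the hyperbolic depletion model
#' `1 / (1 + (k/2)(j-1)/(n-1))` to the normalised curve. Weights default
#' to the frame-wise summed counts, the inverse Poisson variance of each
#' frame mean. The fitted `k` directly yields the resolution of the
#' highest-power frame via [effective_waist()].
#'
#' @param curve An [average_depletion_curve()] result.
#' @param weights Optional fit weights (length `n`); default
#'   `curve$totals`.
#' @return An object of class `depletion_fit` with `k`, `stderr_k`,
#'   `B = 0`, `gamma0 = 0`, residual norm and the model name.
#' @export
fit_saturation <- function(curve, weights = NULL) {
  check_depletion_input(curve)
  n <- curve$n_frames
  y <- curve$ratios
  if (any(diff(y) > 0) && mean(diff(y)) > 0)
    stop("intensity increases along the stack: not a depletion series")
  w <- if (is.null(weights)) curve$totals else weights
  if (length(w) != n || any(w < 0)) stop("bad fit weights")
  df <- data.frame(j = seq_len(n), y = y, w = w)
  k0 <- max(0.1, 2 * (1 / max(y[n], 1e-6) - 1))
  fit <- minpack.lm::nlsLM(y ~ 1 / (1 + (k / 2) * (j - 1) / (n - 1)),
                           data = df, weights = w,
                           start = list(k = k0), lower = 0,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  sm <- summary(fit)
  structure(list(k = stats::coef(fit)[["k"]],
                 stderr_k = sm$coefficients["k", "Std. Error"],
                 B = 0, stderr_B = NA_real_, gamma0 = 0,
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 model = "no_background", fit = fit),
            class = "depletion_fit")
}

#' Fit saturation and STED-induced background jointly
#'
#' For stacks acquired with exponentially modulated excitation
#' (`I_exc ~ exp(-(j-1)/tau_exc)`), the depletion curve becomes
#' \deqn{e^{-\gamma_0 (j-1)} / (1 + (k/2)(j-1)/(n-1)) + B (j-1)/(n-1),}
#' where \eqn{\gamma_0 = 1/\tau_{exc}} is known from the protocol and `B`
#' is proportional to the STED-induced background level. Two-parameter
#' `(k, B)` weighted least squares with `gamma0` held fixed (fitting it too
#' would be degenerate with `k` at typical `n`).
#'
#' @param curve An [average_depletion_curve()] result.
#' @param gamma0 Excitation decay rate per frame; default taken from the
#'   curve's protocol.
#' @param weights Optional fit weights; default `curve$totals`.
#' @return A `depletion_fit` with `k`, `B`, their standard errors and
#'   `model = "with_background"`. A `B` pinned at the zero boundary is
#'   reported via the logical `B_at_boundary`.
#' @export
fit_saturation_with_background <- function(curve, gamma0 = NULL,
                                           weights = NULL) {
  check_depletion_input(curve)
  n <- curve$n_frames
  if (is.null(gamma0)) gamma0 <- protocol_gamma0(curve$protocol)
  if (!is.finite(gamma0) || gamma0 < 0) stop("'gamma0' must be >= 0")
  y <- curve$ratios
  w <- if (is.null(weights)) curve$totals else weights
  if (length(w) != n || any(w < 0)) stop("bad fit weights")
  df <- data.frame(j = seq_len(n), y = y, w = w)
  b0 <- max(0, y[n] - exp(-gamma0 * (n - 1)) / (1 + 4))
  fit <- minpack.lm::nlsLM(
    y ~ exp(-gamma0 * (j - 1)) / (1 + (k / 2) * (j - 1) / (n - 1)) +
      B * (j - 1) / (n - 1),
    data = df, weights = w,
    start = list(k = 5, B = b0), lower = c(0, 0),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  sm <- summary(fit)
  structure(list(k = cf[["k"]],
                 stderr_k = sm$coefficients["k", "Std. Error"],
                 B = cf[["B"]],
                 stderr_B = sm$coefficients["B", "Std. Error"],
                 gamma0 = gamma0,
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 model = "with_background",
                 B_at_boundary = cf[["B"]] < 1e-9,
                 fit = fit),
            class = "depletion_fit")
}

#' @export
print.depletion_fit <- function(x, ...) {
  cat("Depletion-curve fit (", x$model, ")\n", sep = "")
  cat(sprintf("  k = %.4g (se %.3g)\n", x$k, x$stderr_k))
  if (x$model == "with_background")
    cat(sprintf("  B = %.4g (se %.3g), gamma0 = %.4g fixed\n",
                x$B, x$stderr_B, x$gamma0))
  cat(sprintf("  residual norm: %.3g\n", x$residual_norm))
  invisible(x)
}
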