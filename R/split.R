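#' Reference phasors for SPLIT unmixing
#'
#' Bundles the phasor positions used to decompose each pixel: `P_in`
#' (centre of the PSF), `P_out` (periphery) and, for the three-component
#' variant, `P_bkgd` (STED-induced background, a linear ramp along the
#' stack).
#'
#' @param p_in,p_out Numeric length-2 vectors `(g, s)`.
#' @param p_bkgd Optional numeric length-2 vector `(g, s)` for the
#'   background component.
#' @return An object of class `split_references`.
#' @export
split_references <- function(p_in, p_out, p_bkgd = NULL) {
  as_pt <- function(p, nm) {
    p <- as.numeric(p)
    if (length(p) != 2L || any(!is.finite(p)))
      stop("'", nm, "' must be a finite (g, s) pair")
    p
  }
  p_in <- as_pt(p_in, "p_in")
  p_out <- as_pt(p_out, "p_out")
  if (sqrt(sum((p_out - p_in)^2)) < 1e-9)
    stop("'p_in' and 'p_out' coincide: SPLIT references are degenerate")
  if (!is.null(p_bkgd)) p_bkgd <- as_pt(p_bkgd, "p_bkgd")
  structure(list(p_in = p_in, p_out = p_out, p_bkgd = p_bkgd),
            class = "split_references")
}

#' @export
print.split_references <- function(x, ...) {
  fmt <- function(p) sprintf("(%.4f, %.4f)", p[1], p[2])
  cat("SPLIT reference phasors\n")
  cat("  P_in:  ", fmt(x$p_in), "\n")
  cat("  P_out: ", fmt(x$p_out), "\n")
  if (!is.null(x$p_bkgd)) cat("  P_bkgd:", fmt(x$p_bkgd), "\n")
  invisible(x)
}

#' Centre-of-PSF fraction of a phasor
#'
#' Scalar projection of the pixel phasor `P` onto the segment from `P_in`
#' to `P_out`:
#' \deqn{f_{in} = (P_{out} - P) \cdot (P_{out} - P_{in}) /
#'       |P_{out} - P_{in}|^2,}
#' equal to 1 at `P_in` and 0 at `P_out`, clamped to `[0, 1]`.
#'
#' @param g,s Phasor coordinates (vectors, matrices or scalars; recycled
#'   together).
#' @param refs A [split_references()].
#' @param clamp Clamp the projection into `[0, 1]` (default `TRUE`).
#' @return Fractions with the shape of `g`.
#' @export
fraction_in <- function(g, s, refs, clamp = TRUE) {
  stopifnot(inherits(refs, "split_references"))
  d <- refs$p_out - refs$p_in
  den <- sum(d^2)
  f <- ((refs$p_out[1] - g) * d[1] + (refs$p_out[2] - s) * d[2]) / den
  if (clamp) f <- clamp01(f)
  f
}

# clamp into [0, 1] preserving dim/names (pmin/pmax would drop them)
clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Pick the STED image to be unmixed
#'
#' The SPLIT fractions multiply a chosen STED image `F'_STED`: by default
#' the last (highest-power, best resolved) frame, optionally the sum of a
#' frame range such as the last half of the stack.
#'
#' @param stack An [msted_stack()].
#' @param source Either `"last"` or an integer vector of frame indices to
#'   sum.
#' @return A numeric `H x W` matrix.
#' @export
split_source_image <- function(stack, source = "last") {
  stopifnot(inherits(stack, "msted_stack"))
  n <- stack$protocol$n_frames
  if (identical(source, "last")) {
    stack$counts[n, , , drop = TRUE]
  } else {
    idx <- as.integer(source)
    if (any(idx < 1L) || any(idx > n)) stop("source frame index out of 1..", n)
    apply(stack$counts[idx, , , drop = FALSE], c(2, 3), sum)
  }
}

#' Two-component SPLIT decomposition
#'
#' Unmixes each pixel of a chosen STED image into centre (`F_in`) and
#' periphery (`F_out`) components using the per-pixel phasor projected onto
#' the `P_in`--`P_out` axis: `F_in = f_in * F'_STED`,
#' `F_out = (1 - f_in) * F'_STED`. `F_in` is the super-resolved SPLIT
#' image.
#'
#' @param stack An [msted_stack()].
#' @param phasor A [compute_phasor()] result for `stack`.
#' @param refs A [split_references()] (e.g. from [select_references()]).
#' @param source Passed to [split_source_image()].
#' @return An object of class `split_result` with matrices `f_in`, `F_in`,
#'   `F_out`, the source image `F_sted`, and `clamped_fraction`: the share
#'   of the unmixed signal (source-image intensity over valid pixels)
#'   sitting in pixels whose raw projection fell outside `[0, 1]` and was
#'   clamped.
#' @export
split_two_component <- function(stack, phasor, refs, source = "last") {
  stopifnot(inherits(stack, "msted_stack"), inherits(phasor, "phasor_field"))
  f_raw <- fraction_in(phasor$g, phasor$s, refs, clamp = FALSE)
  f_in <- clamp01(f_raw)
  f_in[!phasor$valid] <- 0
  fs <- split_source_image(stack, source)
  clamped <- (f_raw < 0 | f_raw > 1) & phasor$valid
  res <- list(mode = "two_component",
              f_in = f_in,
              f_out = 1 - f_in,
              f_bkgd = NULL,
              F_in = f_in * fs,
              F_out = (1 - f_in) * fs,
              F_bkgd = NULL,
              F_sted = fs,
              valid = phasor$valid,
              refs = refs,
              clamped_fraction = sum(fs[clamped]) /
                max(sum(fs[phasor$valid]), .Machine$double.eps))
  class(res) <- "split_result"
  res
}

#' Phasor of the linear-ramp background dynamics
#'
#' STED-induced background grows linearly with the STED power, i.e. as
#' `(j - 1)/(n - 1)` along the stack under the linear ramp. This returns
#' the phasor of that ramp vector; with two frames it sits at `(-1, 0)`.
#'
#' @param n_frames Number of frames (`>= 2`).
#' @param harmonic Harmonic index.
#' @return A numeric length-2 vector `(g, s)`.
#' @export
background_phasor <- function(n_frames, harmonic = 1L) {
  n <- as.integer(n_frames)
  if (n < 2L) stop("'n_frames' must be >= 2")
  h <- as.integer(harmonic)
  jj <- seq_len(n) - 1
  b <- jj / (n - 1)
  ca <- phasor_basis(2 * pi * h * jj / n)
  c(sum(b * ca$cos), sum(b * ca$sin)) / sum(b)
}

#' Three-component SPLIT with STED-induced background removal
#'
#' For stacks acquired with exponentially modulated excitation, each pixel
#' phasor is expressed as a convex combination of three references: the
#' centre-of-PSF decay (rate \eqn{\gamma_0 = 1/\tau_{exc}}), the periphery
#' decay evaluated at `r = w_c` (rate \eqn{\gamma_0 + k/(n-1)}), and the
#' linearly rising background ramp. The per-pixel system
#' \deqn{P = f_{in} P'_{in} + f_{out} P'_{out} + f_{bkgd} P'_{bkgd},
#'       \quad f_{in} + f_{out} + f_{bkgd} = 1}
#' is an exact 3x3 linear solve (two phasor coordinates plus the
#' normalisation), algebraically equivalent to translating the coordinate
#' system so the background phasor sits at the origin. Negative fractions
#' are clamped to zero and the remainder renormalised (or the pixel masked,
#' with `negative = "mask"`).
#'
#' @param stack An [msted_stack()] acquired with modulated excitation.
#' @param phasor A [compute_phasor()] result for `stack`.
#' @param k Saturation factor, typically from
#'   [fit_saturation_with_background()].
#' @param source Passed to [split_source_image()].
#' @param negative Policy for out-of-simplex pixels: `"clamp"` (default)
#'   or `"mask"`.
#' @return A `split_result` with `f_in`, `f_out`, `f_bkgd` maps and the
#'   component images `F_in`, `F_out`, `F_bkgd`.
#' @export
split_three_component <- function(stack, phasor, k, source = "last",
                                  negative = c("clamp", "mask")) {
  stopifnot(inherits(stack, "msted_stack"), inherits(phasor, "phasor_field"))
  negative <- match.arg(negative)
  protocol <- stack$protocol
  g0 <- protocol_gamma0(protocol)
  if (g0 <= 0)
    stop("three-component SPLIT requires a modulated-excitation protocol ",
         "(finite tau_exc)")
  n <- protocol$n_frames
  h <- phasor$harmonic
  p_in <- unlist(theoretical_phasor(g0, n, h))
  p_out <- unlist(theoretical_phasor(g0 + k / (n - 1), n, h))
  p_bk <- background_phasor(n, h)
  A <- rbind(c(p_in[1], p_out[1], p_bk[1]),
             c(p_in[2], p_out[2], p_bk[2]),
             c(1, 1, 1))
  if (abs(det(A)) < 1e-8)
    stop("reference phasors are collinear: components not separable")
  Ai <- solve(A)
  P <- rbind(as.vector(phasor$g), as.vector(phasor$s), 1)
  f <- Ai %*% P                      # 3 x npix raw fractions
  neg_any <- colSums(f < 0) > 0
  if (negative == "clamp") {
    f[f < 0] <- 0
    f <- sweep(f, 2, colSums(f), "/")
    f[, colSums(is.na(f)) > 0] <- c(0, 0, 1)
  } else {
    f[, neg_any] <- NA_real_
  }
  dims <- dim(phasor$g)
  shape <- function(v) matrix(v, dims[1], dims[2])
  f_in <- shape(f[1, ]); f_out <- shape(f[2, ]); f_bk <- shape(f[3, ])
  inval <- !phasor$valid
  f_in[inval] <- 0; f_out[inval] <- 0; f_bk[inval] <- 1
  fs <- split_source_image(stack, source)
  refs <- split_references(p_in, p_out, p_bk)
  clamped <- matrix(neg_any, dims[1], dims[2]) & phasor$valid
  res <- list(mode = "three_component",
              f_in = f_in, f_out = f_out, f_bkgd = f_bk,
              F_in = f_in * fs, F_out = f_out * fs, F_bkgd = f_bk * fs,
              F_sted = fs,
              valid = phasor$valid,
              refs = refs,
              clamped_fraction = sum(fs[clamped]) /
                max(sum(fs[phasor$valid]), .Machine$double.eps))
  class(res) <- "split_result"
  res
}

#' @export
print.split_result <- function(x, ...) {
  cat("SPLIT decomposition (", x$mode, ")\n", sep = "")
  cat("  image size:      ", paste(dim(x$F_sted), collapse = " x "), "\n")
  cat("  valid pixels:    ", sum(x$valid), "\n")
  cat("  clamped fraction:", signif(x$clamped_fraction, 3), "\n")
  invisible(x)
}
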