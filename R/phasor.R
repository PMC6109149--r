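#' Per-pixel phasor of the depletion dynamics
#'
#' Maps each pixel's frame-wise count vector \eqn{F_j(x,y)} to its phasor
#' coordinates at harmonic `h`:
#' \deqn{g = \sum_j F_j \cos(2\pi h (j-1)/n) / \sum_j F_j, \quad
#'       s = \sum_j F_j \sin(2\pi h (j-1)/n) / \sum_j F_j.}
#' Constant pixels map to the origin; pixels whose signal decays along the
#' stack move towards `(1, 0)`, the faster the decay the further out. The
#' modulation image `M = sqrt(g^2 + s^2)` therefore presents minima at the
#' centres of diffraction-limited foci. With `n = 2` frames the `s`
#' coordinate is identically zero.
#'
#' Pixels with fewer than `min_counts` summed counts are flagged invalid
#' (their phasor is noise-dominated) rather than propagated as `NaN`.
#' Optional median smoothing is applied to the `g` and `s` images — never to
#' the raw counts — as is standard phasor practice.
#'
#' @param stack An [msted_stack()].
#' @param harmonic Harmonic index `h`, `1 <= h <= n - 1`.
#' @param smooth_radius Median-filter radius in pixels for the `g`/`s`
#'   images; `1` (default) is a 3x3 window, `0` disables smoothing.
#' @param min_counts Minimum summed counts for a pixel to be considered
#'   valid (default 10).
#' @return An object of class `phasor_field`: matrices `g`, `s`, `M`,
#'   `phi`, `total`, logical `valid`, and the harmonic used.
#' @export
compute_phasor <- function(stack, harmonic = 1L, smooth_radius = 1L,
                           min_counts = 10) {
  stopifnot(inherits(stack, "msted_stack"))
  n <- stack$protocol$n_frames
  h <- as.integer(harmonic)
  if (h < 1L || h > n - 1L) stop("'harmonic' must be in 1..n_frames-1")
  if (min_counts < 0) stop("'min_counts' must be >= 0")
  jj <- seq_len(n) - 1
  ang <- 2 * pi * h * jj / n
  ca <- phasor_basis(ang)
  d <- dim(stack$counts)
  H <- d[2]; W <- d[3]
  total <- matrix(0, H, W); gn <- matrix(0, H, W); sn <- matrix(0, H, W)
  for (j in seq_len(n)) {
    fj <- stack$counts[j, , , drop = TRUE]
    total <- total + fj
    gn <- gn + fj * ca$cos[j]
    sn <- sn + fj * ca$sin[j]
  }
  pos <- total > 0
  g <- matrix(0, H, W); s <- matrix(0, H, W)
  g[pos] <- gn[pos] / total[pos]
  s[pos] <- sn[pos] / total[pos]
  if (smooth_radius >= 1) {
    g <- median_filter(g, smooth_radius)
    s <- median_filter(s, smooth_radius)
  }
  valid <- pos & (total >= min_counts)
  g[!valid] <- 0; s[!valid] <- 0
  structure(list(g = g, s = s,
                 M = sqrt(g^2 + s^2),
                 phi = atan2(s, g),
                 total = total,
                 valid = valid,
                 harmonic = h),
            class = "phasor_field")
}

#' @export
print.phasor_field <- function(x, ...) {
  cat("Phasor field (harmonic ", x$harmonic, "): ",
      nrow(x$g), " x ", ncol(x$g), " pixels, ",
      sum(x$valid), " valid\n", sep = "")
  if (any(x$valid))
    cat("  modulation on valid pixels: median ",
        signif(stats::median(x$M[x$valid]), 3), ", max ",
        signif(max(x$M[x$valid]), 3), "\n", sep = "")
  invisible(x)
}

# cosine/sine basis with exact zeros at multiples of pi/2, so that e.g.
# two-frame phasors have an identically null s coordinate
phasor_basis <- function(ang) {
  cs <- cos(ang); sn <- sin(ang)
  cs[abs(cs) < 1e-12] <- 0
  sn[abs(sn) < 1e-12] <- 0
  list(cos = cs, sin = sn)
}

# 2-D median filter with edge replication. The (2r+1)^2 shifted copies are
# sorted column-wise by a vectorised exchange network, so cost is
# O(m^2) whole-image min/max ops for m window elements.
median_filter <- function(img, radius = 1L) {
  r <- as.integer(radius)
  if (r < 1L) return(img)
  H <- nrow(img); W <- ncol(img)
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  m <- nrow(offs)
  cols <- matrix(0, H * W, m)
  for (i in seq_len(m)) {
    ri <- pmin(pmax(seq_len(H) + offs$dy[i], 1L), H)
    ci <- pmin(pmax(seq_len(W) + offs$dx[i], 1L), W)
    cols[, i] <- as.vector(img[ri, ci])
  }
  for (i in seq_len(m - 1)) {
    for (j in seq_len(m - i)) {
      a <- cols[, j]; b <- cols[, j + 1]
      cols[, j] <- pmin(a, b)
      cols[, j + 1] <- pmax(a, b)
    }
  }
  mid <- (m + 1) / 2
  matrix(cols[, mid], H, W)
}

#' Graphical statistics of the phasor cloud
#'
#' Quantifies the shape of the phasor cloud that calibrates SPLIT: the
#' elongation angle `phi0` of its principal axis through the origin, the
#' spread `delta_M` along that (radial) direction and the spread `delta_N`
#' orthogonal to it. `delta_M` grows with the STED-induced modulation while
#' `delta_N` reflects the noise level, so an elongated cloud
#' (`delta_M >> delta_N`) signals usable encoded spatial information.
#'
#' Spreads are the (by default intensity-weighted) standard deviations of
#' the phasor coordinates after rotating the cloud by `-phi0`.
#'
#' @param phasor A [compute_phasor()] result.
#' @param weights `"intensity"` (default) weights each pixel by its summed
#'   counts; `"none"` weights pixels equally.
#' @return An object of class `phasor_cloud_stats` with `phi0`, `delta_M`,
#'   `delta_N`, the number of pixels used and a `degenerate` flag (all
#'   phasors identical).
#' @export
cloud_statistics <- function(phasor, weights = c("intensity", "none")) {
  stopifnot(inherits(phasor, "phasor_field"))
  weights <- match.arg(weights)
  v <- phasor$valid
  if (sum(v) < 2L) stop("need at least 2 valid pixels for cloud statistics")
  g <- phasor$g[v]; s <- phasor$s[v]
  w <- if (weights == "intensity") phasor$total[v] else rep(1, length(g))
  w <- w / sum(w)
  # principal axis through the origin: second-moment (not centred) tensor
  sgg <- sum(w * g * g); sss <- sum(w * s * s); sgs <- sum(w * g * s)
  phi0 <- 0.5 * atan2(2 * sgs, sgg - sss)
  if (cos(phi0) < 0) phi0 <- phi0 - sign(phi0) * pi  # orientation with g > 0
  gr <- g * cos(phi0) + s * sin(phi0)
  sr <- -g * sin(phi0) + s * cos(phi0)
  wsd <- function(x) {
    mu <- sum(w * x)
    sqrt(max(0, sum(w * (x - mu)^2)))
  }
  dm <- wsd(gr); dn <- wsd(sr)
  structure(list(phi0 = phi0, delta_M = dm, delta_N = dn,
                 n_pixels = sum(v), weights = weights,
                 degenerate = (dm < 1e-12 && dn < 1e-12)),
            class = "phasor_cloud_stats")
}

#' @export
print.phasor_cloud_stats <- function(x, ...) {
  cat("Phasor cloud statistics (", x$n_pixels, " pixels)\n", sep = "")
  cat(sprintf("  phi0:    %.4f rad\n", x$phi0))
  cat(sprintf("  delta_M: %.4f\n", x$delta_M))
  cat(sprintf("  delta_N: %.4f\n", x$delta_N))
  if (x$degenerate) cat("  [degenerate: all phasors identical]\n")
  invisible(x)
}

#' Smallest distinguishable modulation difference
#'
#' The minimum separation in modulation between the centre and periphery
#' reference phasors that the data's signal-to-noise supports:
#' \deqn{M_0 = (m_0/2) \, \Delta_N / |\Delta_M - \Delta_N|.}
#' When the cloud is not elongated (`delta_M` close to `delta_N`) the
#' encoded spatial information is hidden in the noise and SPLIT is refused
#' with an error; the stack remains usable for quantitative saturation
#' analysis only.
#'
#' @param stats A [cloud_statistics()] result.
#' @param m0 User constant scaling the separation (default 1).
#' @param tol Minimum relative excess of `delta_M` over `delta_N` required
#'   to attempt SPLIT (default 0.05).
#' @return The modulation difference `M_0` (a scalar).
#' @examples
#' st <- structure(list(phi0 = 0, delta_M = 0.3, delta_N = 0.1),
#'                 class = "phasor_cloud_stats")
#' estimate_m0(st)   # 0.25
#' @export
estimate_m0 <- function(stats, m0 = 1, tol = 0.05) {
  stopifnot(inherits(stats, "phasor_cloud_stats"))
  if (m0 < 0) stop("'m0' must be >= 0")
  if (!(stats$delta_M > stats$delta_N * (1 + tol)))
    stop("phasor not elongated (delta_M ~ delta_N): encoded spatial ",
         "information is below the noise, SPLIT refused")
  (m0 / 2) * stats$delta_N / abs(stats$delta_M - stats$delta_N)
}

#' Place the SPLIT reference phasors from the modulation histogram
#'
#' Sets the centre reference `P_in` at modulation `M_in` along the cloud's
#' elongation axis, where `M_in` is a low percentile of the modulation
#' histogram over valid pixels (default the 1st percentile, a robust proxy
#' for the minimum modulation observed in the data — in crowded samples the
#' cloud detaches from the origin because even focus centres collect
#' modulated light from neighbouring foci). The periphery reference `P_out`
#' is placed at `M_in + M_0` along the same axis, with `M_0` from
#' [estimate_m0()].
#'
#' @param phasor A [compute_phasor()] result.
#' @param stats A [cloud_statistics()] result for the same field.
#' @param percentile Percentile (0-100) of the modulation histogram used
#'   for `M_in`; default 1.
#' @param m0 User constant passed to [estimate_m0()].
#' @param tol Passed to [estimate_m0()].
#' @return A [split_references()] object with extra fields `M_in`,
#'   `M_out`, `M_0`, `m0` and `phi0`.
#' @export
select_references <- function(phasor, stats, percentile = 1, m0 = 1,
                              tol = 0.05) {
  stopifnot(inherits(phasor, "phasor_field"),
            inherits(stats, "phasor_cloud_stats"))
  if (!any(phasor$valid)) stop("no valid pixels")
  if (percentile < 0 || percentile > 100)
    stop("'percentile' must be in [0, 100]")
  M0 <- estimate_m0(stats, m0 = m0, tol = tol)
  m_in <- as.numeric(stats::quantile(phasor$M[phasor$valid],
                                     probs = percentile / 100))
  m_out <- m_in + M0
  u <- c(cos(stats$phi0), sin(stats$phi0))
  refs <- split_references(p_in = m_in * u, p_out = m_out * u)
  refs$M_in <- m_in
  refs$M_out <- m_out
  refs$M_0 <- M0
  refs$m0 <- m0
  refs$phi0 <- stats$phi0
  refs
}
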