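#' Configuration of a simulated M-STED acquisition
#'
#' Defaults mirror the reference simulation conditions used throughout the
#' package: 512 x 512 frames with 40-nm pixels, a 200-nm confocal waist,
#' an 8-frame linear STED ramp, point-like emitters placed uniformly in a
#' 16-um circle and a peak expectation of 30 counts in the confocal frame,
#' corrupted by Poisson noise.
#'
#' @param image_shape Integer `(H, W)`, default `c(512, 512)`.
#' @param pixel_size_nm Pixel pitch, default 40.
#' @param n_frames Frames in the stack, default 8.
#' @param w_c_nm Confocal waist, default 200.
#' @param k Saturation factor `I_max/I_sat` reached in the last frame.
#' @param s_max Expected counts at the brightest pixel of frame 1, default
#'   30 (use 40 to match the reference background simulations).
#' @param object_kind One of `"sparse_foci"`, `"crowded_foci"`,
#'   `"large_foci"`, `"filaments"`.
#' @param n_emitters Number of emitters (or of filament strands for
#'   `"filaments"`); defaults depend on `object_kind`.
#' @param field_diameter_um Diameter of the circular field holding the
#'   emitters, default 16.
#' @param b_max_percent Peak STED-induced background in the last frame as a
#'   percentage of `s_max`; 0 disables the background.
#' @param exc_modulated If `TRUE`, excitation decays exponentially along
#'   the stack with constant `tau_exc`.
#' @param tau_exc Excitation decay constant in frame units, default
#'   `n_frames / 2`.
#' @param splat Emitter rasterisation: `"nearest"` (default) places each
#'   emitter on its nearest pixel, `"bilinear"` spreads it over the four
#'   neighbouring pixels for sub-pixel positioning.
#' @param seed RNG seed for reproducibility.
#' @return An object of class `msted_sim_config`.
#' @export
msted_sim_config <- function(image_shape = c(512L, 512L), pixel_size_nm = 40,
                             n_frames = 8L, w_c_nm = 200, k = 8, s_max = 30,
                             object_kind = c("sparse_foci", "crowded_foci",
                                             "large_foci", "filaments"),
                             n_emitters = NULL, field_diameter_um = 16,
                             b_max_percent = 0, exc_modulated = FALSE,
                             tau_exc = NULL, splat = c("nearest", "bilinear"),
                             seed = 1L) {
  object_kind <- match.arg(object_kind)
  splat <- match.arg(splat)
  if (s_max <= 0) stop("'s_max' must be positive")
  if (b_max_percent < 0 || b_max_percent > 100)
    stop("'b_max_percent' must be in [0, 100]")
  if (n_frames < 2L) stop("'n_frames' must be >= 2")
  if (object_kind == "crowded_foci" && missing(w_c_nm)) w_c_nm <- 400
  if (is.null(n_emitters))
    n_emitters <- switch(object_kind,
                         sparse_foci = 150L, crowded_foci = 1500L,
                         large_foci = 40L, filaments = 6L)
  if (is.null(tau_exc)) tau_exc <- n_frames / 2
  structure(list(image_shape = as.integer(image_shape),
                 pixel_size_nm = pixel_size_nm,
                 n_frames = as.integer(n_frames),
                 w_c_nm = w_c_nm, k = k, s_max = s_max,
                 object_kind = object_kind,
                 n_emitters = as.integer(n_emitters),
                 field_diameter_um = field_diameter_um,
                 b_max_percent = b_max_percent,
                 exc_modulated = exc_modulated,
                 tau_exc = tau_exc,
                 splat = splat,
                 seed = as.integer(seed)),
            class = "msted_sim_config")
}

sim_protocol <- function(config) {
  msted_protocol(n_frames = config$n_frames, k = config$k,
                 tau_exc = if (config$exc_modulated) config$tau_exc else Inf,
                 pixel_size_nm = config$pixel_size_nm)
}

#' Draw emitter positions for a simulated field
#'
#' Point emitters are placed uniformly inside the circular field centred on
#' the image. For `"large_foci"` each emitter becomes a uniform disc 10
#' pixels across; for `"filaments"` emitters are sampled densely along
#' smooth random curves (random-walk headings with small curvature steps)
#' confined to the field.
#'
#' @param config An [msted_sim_config()].
#' @return A data frame with columns `x_nm`, `y_nm` (position relative to
#'   the image centre) and `weight`.
#' @export
place_emitters <- function(config) {
  stopifnot(inherits(config, "msted_sim_config"))
  radius_nm <- config$field_diameter_um * 1000 / 2
  ne <- config$n_emitters
  if (ne == 0L)
    return(data.frame(x_nm = numeric(0), y_nm = numeric(0),
                      weight = numeric(0)))
  draw_in_circle <- function(m) {
    rr <- radius_nm * sqrt(stats::runif(m))
    th <- stats::runif(m, 0, 2 * pi)
    cbind(rr * cos(th), rr * sin(th))
  }
  if (config$object_kind == "filaments") {
    px <- config$pixel_size_nm
    pts <- list()
    for (f in seq_len(ne)) {
      start <- draw_in_circle(1)
      heading <- stats::runif(1, 0, 2 * pi)
      n_steps <- 600L
      step <- px / 2
      xy <- matrix(NA_real_, n_steps, 2)
      pos <- start[1, ]
      for (i in seq_len(n_steps)) {
        heading <- heading + stats::rnorm(1, 0, 0.06)
        pos <- pos + step * c(cos(heading), sin(heading))
        if (sqrt(sum(pos^2)) > radius_nm) break
        xy[i, ] <- pos
      }
      xy <- xy[stats::complete.cases(xy), , drop = FALSE]
      if (nrow(xy)) pts[[length(pts) + 1L]] <- xy
    }
    xy <- do.call(rbind, pts)
    return(data.frame(x_nm = xy[, 1], y_nm = xy[, 2],
                      weight = rep(1, nrow(xy))))
  }
  xy <- draw_in_circle(ne)
  if (config$object_kind == "large_foci") {
    # replace each point by a disc 10 pixels across
    px <- config$pixel_size_nm
    r_disc <- 5 * px
    offs <- expand.grid(dx = seq(-5, 5) * px, dy = seq(-5, 5) * px)
    offs <- offs[offs$dx^2 + offs$dy^2 <= r_disc^2, ]
    xy <- cbind(rep(xy[, 1], each = nrow(offs)) + offs$dx,
                rep(xy[, 2], each = nrow(offs)) + offs$dy)
  }
  data.frame(x_nm = xy[, 1], y_nm = xy[, 2], weight = rep(1, nrow(xy)))
}

# splat emitters onto the pixel grid; origin at image centre
emitter_map <- function(emitters, config) {
  H <- config$image_shape[1]; W <- config$image_shape[2]
  px <- config$pixel_size_nm
  obj <- matrix(0, H, W)
  if (nrow(emitters) == 0L) return(obj)
  rowf <- emitters$y_nm / px + (H + 1) / 2
  colf <- emitters$x_nm / px + (W + 1) / 2
  if (identical(config$splat, "bilinear")) {
    r0 <- floor(rowf); c0 <- floor(colf)
    fr <- rowf - r0; fc <- colf - c0
    inside <- r0 >= 1 & r0 + 1 <= H & c0 >= 1 & c0 + 1 <= W
    if (any(!inside))
      warning(sum(!inside), " emitter(s) outside the image bounds skipped")
    for (i in which(inside)) {
      w <- emitters$weight[i]
      obj[r0[i], c0[i]] <- obj[r0[i], c0[i]] +
        w * (1 - fr[i]) * (1 - fc[i])
      obj[r0[i] + 1, c0[i]] <- obj[r0[i] + 1, c0[i]] + w * fr[i] * (1 - fc[i])
      obj[r0[i], c0[i] + 1] <- obj[r0[i], c0[i] + 1] + w * (1 - fr[i]) * fc[i]
      obj[r0[i] + 1, c0[i] + 1] <- obj[r0[i] + 1, c0[i] + 1] +
        w * fr[i] * fc[i]
    }
  } else {
    row <- round(rowf); col <- round(colf)
    inside <- row >= 1 & row <= H & col >= 1 & col <= W
    if (any(!inside))
      warning(sum(!inside), " emitter(s) outside the image bounds skipped")
    for (i in which(inside))
      obj[row[i], col[i]] <- obj[row[i], col[i]] + emitters$weight[i]
  }
  obj
}

# circular FFT convolution of an image with a centred radial kernel k(r)
convolve_radial <- function(obj, kernel_fun, config) {
  H <- nrow(obj); W <- ncol(obj)
  px <- config$pixel_size_nm
  # wrapped distance grid so the kernel is centred at (1, 1)
  dy <- pmin(0:(H - 1), H - (0:(H - 1))) * px
  dx <- pmin(0:(W - 1), W - (0:(W - 1))) * px
  r <- sqrt(outer(dy^2, dx^2, "+"))
  ker <- kernel_fun(r)
  Re(stats::fft(stats::fft(obj) * stats::fft(ker), inverse = TRUE)) /
    (H * W)
}

#' Render the noiseless M-STED stack
#'
#' Convolves the emitter map with the tunable STED PSF of each frame
#' (confocal Gaussian times the depletion factor at that frame's STED
#' level), applies the frame's excitation level, and scales globally so the
#' brightest pixel of frame 1 has expectation `s_max`.
#'
#' @param emitters A [place_emitters()] data frame.
#' @param config An [msted_sim_config()].
#' @return A list with `stack` (`n x H x W` real-valued expectations),
#'   `object` (the splatted emitter map) and the protocol.
#' @export
render_noiseless <- function(emitters, config) {
  stopifnot(inherits(config, "msted_sim_config"))
  protocol <- sim_protocol(config)
  obj <- emitter_map(emitters, config)
  H <- config$image_shape[1]; W <- config$image_shape[2]
  out <- array(0, dim = c(config$n_frames, H, W))
  w_c <- config$w_c_nm
  for (j in seq_len(config$n_frames)) {
    lev <- protocol$sted_levels[j]
    img <- convolve_radial(obj, function(r) sted_psf(r, w_c, lev), config)
    img[img < 0] <- 0   # FFT round-off
    out[j, , ] <- protocol$exc_levels[j] * img
  }
  peak1 <- max(out[1, , ])
  if (peak1 > 0) out <- out * (config$s_max / peak1)
  list(stack = out, object = obj, protocol = protocol)
}

#' Add STED-induced background to a noiseless stack
#'
#' Direct excitation by the doughnut-shaped STED beam adds a halo around
#' each emitter whose amplitude grows linearly with the STED power, i.e.
#' with `(j - 1)/(n - 1)` along the ramp, reaching
#' `(b_max_percent/100) * s_max` at the brightest background pixel of the
#' last frame. The halo shape is the vortex doughnut
#' `(r^2/w_c^2) exp(-2 r^2/w_c^2)`, peak-normalised over the rendered
#' field, and is independent of the excitation modulation.
#'
#' @param rendered A [render_noiseless()] result.
#' @param emitters The emitter data frame used for rendering.
#' @param config An [msted_sim_config()].
#' @return `rendered` with the background added to `stack` and the
#'   noiseless background stack attached as `background`.
#' @export
add_sted_background <- function(rendered, emitters, config) {
  n <- config$n_frames
  H <- config$image_shape[1]; W <- config$image_shape[2]
  bg_stack <- array(0, dim = c(n, H, W))
  if (config$b_max_percent > 0) {
    obj <- emitter_map(emitters, config)
    w_c <- config$w_c_nm
    halo <- convolve_radial(obj, function(r)
      (r / w_c)^2 * exp(-2 * (r / w_c)^2), config)
    halo[halo < 0] <- 0
    peak <- max(halo)
    if (peak > 0) halo <- halo / peak
    amp <- (config$b_max_percent / 100) * config$s_max
    for (j in seq_len(n))
      bg_stack[j, , ] <- amp * (j - 1) / (n - 1) * halo
    rendered$stack <- rendered$stack + bg_stack
  }
  rendered$background <- bg_stack
  rendered
}

#' Corrupt a noiseless stack with Poisson noise
#'
#' Independent Poisson draw per pixel and frame; the noiseless expectations
#' are kept as ground truth.
#'
#' @param rendered A [render_noiseless()] (optionally
#'   [add_sted_background()]) result.
#' @param truth Extra ground-truth entries to store alongside.
#' @return An [msted_stack()] whose `truth` holds the noiseless stack.
#' @export
apply_poisson <- function(rendered, truth = list()) {
  lam <- rendered$stack
  counts <- array(stats::rpois(length(lam), lambda = as.vector(lam)),
                  dim = dim(lam))
  msted_stack(counts, rendered$protocol,
              truth = c(list(noiseless = rendered$stack,
                             background = rendered$background,
                             object = rendered$object), truth))
}

#' Simulate a complete M-STED stack
#'
#' Full pipeline: place emitters, render the noiseless tunable-PSF stack,
#' add STED-induced background if requested, and corrupt with Poisson
#' noise. Fully reproducible under `config$seed`.
#'
#' @param config An [msted_sim_config()].
#' @return An [msted_stack()] with ground truth attached
#'   (`truth$emitters`, `truth$noiseless`, `truth$background`,
#'   `truth$object`).
#' @examples
#' cfg <- msted_sim_config(image_shape = c(64, 64), n_emitters = 5,
#'                         field_diameter_um = 2, seed = 7)
#' stk <- simulate_msted(cfg)
#' @export
simulate_msted <- function(config) {
  stopifnot(inherits(config, "msted_sim_config"))
  set.seed(config$seed)
  emitters <- place_emitters(config)
  rendered <- render_noiseless(emitters, config)
  rendered <- add_sted_background(rendered, emitters, config)
  apply_poisson(rendered, truth = list(emitters = emitters))
}
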