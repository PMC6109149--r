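#' Write an M-STED stack as multi-page TIFF plus protocol sidecar
#'
#' One 16-bit page per frame (ascending STED power), ImageJ-compatible,
#' with the acquisition protocol stored in a YAML sidecar so the stack
#' round-trips losslessly through [read_stack()].
#'
#' @param stack An [msted_stack()].
#' @param path Output TIFF path.
#' @param sidecar Path of the YAML protocol sidecar (default
#'   `<path>.yaml`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, sidecar = paste0(path, ".yaml")) {
  stopifnot(inherits(stack, "msted_stack"))
  counts <- stack$counts
  if (max(counts) > 65535)
    stop("counts exceed the 16-bit range")
  pages <- lapply(seq_len(dim(counts)[1]), function(j)
    counts[j, , , drop = TRUE] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  p <- stack$protocol
  yaml::write_yaml(list(n_frames = p$n_frames,
                        sted_levels = p$sted_levels,
                        exc_levels = p$exc_levels,
                        tau_exc = if (is.finite(p$tau_exc)) p$tau_exc else "Inf",
                        pixel_size_nm = p$pixel_size_nm),
                   sidecar, precision = 15L)
  invisible(path)
}

#' Read an M-STED stack from multi-page TIFF
#'
#' @param path TIFF path; page count must equal the protocol's
#'   `n_frames`.
#' @param protocol An [msted_protocol()]; if `NULL`, the YAML sidecar
#'   written by [write_stack()] is read from `sidecar`.
#' @param sidecar Protocol sidecar path (default `<path>.yaml`).
#' @return An [msted_stack()] with integer counts.
#' @export
read_stack <- function(path, protocol = NULL, sidecar = paste0(path, ".yaml")) {
  if (is.null(protocol)) {
    if (!file.exists(sidecar))
      stop("no protocol given and sidecar '", sidecar, "' not found")
    y <- yaml::read_yaml(sidecar)
    tau <- if (identical(y$tau_exc, "Inf")) Inf else as.numeric(y$tau_exc)
    protocol <- msted_protocol(n_frames = y$n_frames,
                               sted_levels = y$sted_levels,
                               exc_levels = y$exc_levels,
                               tau_exc = tau,
                               pixel_size_nm = y$pixel_size_nm)
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != protocol$n_frames)
    stop("TIFF has ", length(pages), " pages but the protocol expects ",
         protocol$n_frames, " frames")
  vals <- unlist(pages)
  if (any(vals != round(vals))) {
    warning("non-integer pixel values rounded to counts")
    pages <- lapply(pages, round)
  }
  counts <- array(0, dim = c(protocol$n_frames, nrow(pages[[1]]),
                             ncol(pages[[1]])))
  for (j in seq_along(pages)) counts[j, , ] <- pages[[j]]
  msted_stack(counts, protocol)
}

write_float_tiff <- function(img, path) {
  tiff::writeTIFF(img, path, bits.per.sample = 32L,
                  reduce = FALSE, compression = "none")
  invisible(path)
}

#' Run the full M-STED analysis pipeline on one stack
#'
#' Phasor computation, depletion-curve fit (plain or with-background model
#' depending on the protocol's excitation modulation), reference-phasor
#' placement and SPLIT decomposition, with all intermediate images, tables
#' and a JSON run report written to `out_dir`. When the phasor cloud is
#' not elongated enough for SPLIT, the pipeline degrades gracefully to
#' quantitative-only output: the fitted `k` (and `B`) are still reported
#' but no SPLIT image is produced.
#'
#' @param stack An [msted_stack()], or a TIFF path readable by
#'   [read_stack()].
#' @param out_dir Output directory (created if missing).
#' @param harmonic,smooth_radius,min_counts Passed to [compute_phasor()].
#' @param m0,percentile Passed to [select_references()].
#' @param source Passed to [split_source_image()].
#' @param mode `"auto"` picks three-component SPLIT for
#'   modulated-excitation protocols, two-component otherwise.
#' @return The run report, invisibly (a list; also written as
#'   `report.json`).
#' @export
run_pipeline <- function(stack, out_dir, harmonic = 1L, smooth_radius = 1L,
                         min_counts = 10, m0 = 1, percentile = 1,
                         source = "last",
                         mode = c("auto", "2comp", "3comp")) {
  mode <- match.arg(mode)
  if (is.character(stack)) stack <- read_stack(stack)
  stopifnot(inherits(stack, "msted_stack"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  protocol <- stack$protocol
  modulated <- protocol_gamma0(protocol) > 0
  if (mode == "auto") mode <- if (modulated) "3comp" else "2comp"

  phasor <- compute_phasor(stack, harmonic = harmonic,
                           smooth_radius = smooth_radius,
                           min_counts = min_counts)
  for (nm in c("g", "s", "M", "phi"))
    write_float_tiff(normalise_unit(phasor[[nm]]),
                     file.path(out_dir, paste0(nm, ".tif")))

  curve <- average_depletion_curve(stack)
  fit <- if (mode == "3comp") fit_saturation_with_background(curve)
         else fit_saturation(curve)
  utils::write.csv(data.frame(frame = seq_len(curve$n_frames),
                              sted_level = protocol$sted_levels,
                              ratio = curve$ratios),
                   file.path(out_dir, "depletion_curve.csv"),
                   row.names = FALSE)

  report <- list(mode = mode, harmonic = harmonic,
                 n_frames = protocol$n_frames,
                 pixel_size_nm = protocol$pixel_size_nm,
                 k = fit$k, stderr_k = fit$stderr_k,
                 B = fit$B, gamma0 = fit$gamma0,
                 split_performed = FALSE)

  split <- NULL
  if (mode == "2comp") {
    stats <- cloud_statistics(phasor)
    report$phi0 <- stats$phi0
    report$delta_M <- stats$delta_M
    report$delta_N <- stats$delta_N
    refs <- tryCatch(select_references(phasor, stats, percentile = percentile,
                                       m0 = m0),
                     error = function(e) e)
    if (inherits(refs, "error")) {
      warning("SPLIT skipped: ", conditionMessage(refs),
              "; writing quantitative output only")
      report$split_skipped_reason <- conditionMessage(refs)
    } else {
      report$M_0 <- refs$M_0
      report$M_in <- refs$M_in
      split <- split_two_component(stack, phasor, refs, source = source)
    }
  } else {
    split <- split_three_component(stack, phasor, fit$k, source = source)
  }
  if (!is.null(split)) {
    report$split_performed <- TRUE
    report$clamped_fraction <- split$clamped_fraction
    for (nm in c("F_in", "F_out", "F_bkgd", "f_in"))
      if (!is.null(split[[nm]]))
        write_float_tiff(normalise_unit(split[[nm]]),
                         file.path(out_dir, paste0(nm, ".tif")))
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}

# scale an image into [0, 1] for float TIFF output
normalise_unit <- function(img) {
  rng <- range(img, finite = TRUE)
  if (diff(rng) <= 0) return(img * 0)
  (img - rng[1]) / diff(rng)
}
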