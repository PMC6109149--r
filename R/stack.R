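#' M-STED image stack
#'
#' Container for an M-STED acquisition: an `n x H x W` array of photon
#' counts (frame-major, ascending STED power) plus the acquisition protocol
#' and, for simulated data, the ground truth.
#'
#' @param counts Numeric `n x H x W` array of non-negative counts.
#' @param protocol An [msted_protocol()] with `n_frames` equal to
#'   `dim(counts)[1]`.
#' @param truth Optional list with ground-truth information (emitter
#'   positions, noiseless stack, noiseless background stack).
#' @return An object of class `msted_stack`.
#' @export
msted_stack <- function(counts, protocol, truth = NULL) {
  stopifnot(inherits(protocol, "msted_protocol"))
  counts <- unclass(counts)
  if (length(dim(counts)) != 3L)
    stop("'counts' must be an n x H x W array")
  if (dim(counts)[1] != protocol$n_frames)
    stop("frame dimension of 'counts' (", dim(counts)[1],
         ") does not match protocol n_frames (", protocol$n_frames, ")")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("'counts' must be finite and non-negative")
  structure(list(counts = counts, protocol = protocol, truth = truth),
            class = "msted_stack")
}

#' @export
print.msted_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat("M-STED stack: ", d[1], " frames of ", d[2], " x ", d[3],
      " pixels\n", sep = "")
  cat("  total counts:", sum(x$counts), "\n")
  cat("  pixel size:  ", x$protocol$pixel_size_nm, "nm\n")
  if (!is.null(x$truth)) cat("  ground truth attached\n")
  invisible(x)
}

#' Extract one frame of a stack as a matrix
#'
#' @param stack An [msted_stack()].
#' @param j Frame index.
#' @return `H x W` numeric matrix.
#' @export
stack_frame <- function(stack, j) {
  stopifnot(inherits(stack, "msted_stack"))
  n <- stack$protocol$n_frames
  if (j < 1 || j > n) stop("frame index out of 1..", n)
  stack$counts[j, , , drop = TRUE]
}
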