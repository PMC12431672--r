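#' Phasor field
#'
#' Per-pixel result of demodulating a phase-stepped stack: DC intensity,
#' modulation depth, phase (principal branch, (-pi, pi]), the equivalent
#' phasor coordinates g = m cos(phase), s = m sin(phase), and a validity
#' mask. Before calibration these are raw instrument quantities; after
#' [calibrate()] the same container holds instrument-corrected values
#' (`calibrated = TRUE`).
#'
#' @param dc,g,s matrices of per-pixel DC and phasor coordinates.
#' @param valid logical matrix.
#' @param acq a [flim_acquisition()].
#' @param calibrated logical flag.
#' @return an object of class `phasor_field` with elements `dc`, `g`,
#'   `s`, `phase`, `modulation`, `valid`.
#' @keywords internal
phasor_field <- function(dc, g, s, valid, acq, calibrated = FALSE) {
  stopifnot(is.matrix(dc), identical(dim(dc), dim(g)),
            identical(dim(dc), dim(s)), identical(dim(dc), dim(valid)))
  structure(
    list(dc = dc, g = g, s = s,
         phase = atan2(s, g), modulation = sqrt(g^2 + s^2),
         valid = valid, acq = acq, calibrated = calibrated),
    class = "phasor_field")
}

#' @export
print.phasor_field <- function(x, ...) {
  cat(sprintf(
    "<phasor_field>%s %d x %d px, %.1f%% valid, %s @ %.4g MHz\n",
    if (x$calibrated) " (calibrated)" else " (raw)",
    nrow(x$dc), ncol(x$dc), 100 * mean(x$valid), x$acq$channel,
    x$acq$frequency / 1e6))
  invisible(x)
}

#' @export
dim.phasor_field <- function(x) dim(x$dc)

#' Demodulate a phase-stepped homodyne stack
#'
#' First-harmonic discrete Fourier projection of the per-pixel phase
#' response. For uniformly spaced phase steps this is exact: a frame set
#' I_k = A [1 + b cos(theta_k - phi)] returns dc = A, modulation = b,
#' phase = phi (the second-harmonic leakage term vanishes for K >= 3
#' uniform steps). Pixels with dc below `dc_min` carry too few counts
#' for a meaningful phase and are flagged invalid rather than raising.
#'
#' @param stack a [phase_stack()].
#' @param dc_min validity threshold on DC counts (default 10; below
#'   this the phase estimate is noise). Set to 0 to keep every pixel
#'   with dc > 0.
#' @return a `phasor_field` with raw (uncalibrated) phase/modulation.
#' @export
demodulate <- function(stack, dc_min = 10) {
  stopifnot(inherits(stack, "phase_stack"), dc_min >= 0)
  theta <- stack$phases
  k <- length(theta)
  if (k < 3L) stop("demodulation needs K >= 3 phase steps")
  d <- dim(stack$frames)
  m <- matrix(stack$frames, nrow = d[1] * d[2], ncol = k)
  dc <- as.vector(m %*% rep(1 / k, k))
  gre <- as.vector(m %*% (2 * cos(theta) / k))
  sim <- as.vector(m %*% (2 * sin(theta) / k))
  valid <- dc > dc_min & dc > 0
  g <- ifelse(valid, gre / dc, NA_real_)
  s <- ifelse(valid, sim / dc, NA_real_)
  shape <- function(v) matrix(v, d[1], d[2])
  phasor_field(shape(dc), shape(g), shape(s), shape(valid), stack$acq)
}

#' Flat-field correction
#'
#' Divides the sample DC intensity by the reference DC intensity to
#' correct for nonuniform illumination across the field of view. Pixels
#' where the reference carries no signal (reference dc <= `epsilon`)
#' are set to the NA sentinel; the sample DC is not gated here, so dim
#' sample regions (e.g. background between cells) remain available to
#' the foreground masking step.
#'
#' @param sample,reference `phasor_field`s of identical shape.
#' @param epsilon reference-DC validity threshold in counts.
#' @return matrix of normalized intensity with NA at invalid pixels.
#' @export
flat_field <- function(sample, reference, epsilon = 10) {
  stopifnot(inherits(sample, "phasor_field"),
            inherits(reference, "phasor_field"))
  if (!identical(dim(sample$dc), dim(reference$dc)))
    stop("sample and reference shapes differ")
  out <- sample$dc / reference$dc
  out[reference$dc <= epsilon] <- NA_real_
  out
}
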