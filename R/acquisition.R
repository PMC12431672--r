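#' Homodyne acquisition configuration
#'
#' Describes one phase-stepped homodyne acquisition: the excitation
#' modulation frequency, the number of uniformly spaced phase steps, the
#' exposure per phase frame, the lifetime of the calibration reference
#' fluorophore, and the spectral channel label. Defaults match a typical
#' widefield autofluorescence protocol: 20 MHz, 25 phases, fluorescein
#' reference (4.0 ns).
#'
#' @param frequency modulation frequency f in Hz (> 0).
#' @param n_phases number of phase steps K (integer >= 3).
#' @param exposure_ms exposure time per phase frame in ms.
#' @param reference_lifetime lifetime of the calibration reference
#'   fluorophore in ns (> 0).
#' @param channel spectral channel label, e.g. "NADH" or "FAD".
#' @return an object of class `flim_acquisition`.
#' @export
flim_acquisition <- function(frequency = 20e6, n_phases = 25L,
                             exposure_ms = 500, reference_lifetime = 4.0,
                             channel = "NADH") {
  stopifnot(is.numeric(frequency), length(frequency) == 1L, frequency > 0,
            is.numeric(n_phases), length(n_phases) == 1L,
            is.numeric(exposure_ms), exposure_ms > 0,
            is.numeric(reference_lifetime), reference_lifetime > 0,
            is.character(channel), length(channel) == 1L)
  n_phases <- as.integer(n_phases)
  if (n_phases < 3L) stop("n_phases must be >= 3 (demodulation is underdetermined below 3)")
  structure(
    list(frequency = frequency, n_phases = n_phases,
         exposure_ms = exposure_ms,
         reference_lifetime = reference_lifetime, channel = channel),
    class = "flim_acquisition")
}

#' @export
print.flim_acquisition <- function(x, ...) {
  cat(sprintf(
    "<flim_acquisition> %s: f = %.4g MHz, K = %d phases, %.0f ms, tau_ref = %.3g ns\n",
    x$channel, x$frequency / 1e6, x$n_phases, x$exposure_ms,
    x$reference_lifetime))
  invisible(x)
}

#' Uniform phase steps for an acquisition
#'
#' theta_k = 2 pi k / K, k = 0 ... K-1. Uniform spacing over a full cycle
#' makes the first-harmonic DFT projection an exact demodulator.
#'
#' @param acq a [flim_acquisition()] or integer K.
#' @return numeric vector of K phase offsets in radians.
#' @export
phase_steps <- function(acq) {
  k <- if (inherits(acq, "flim_acquisition")) acq$n_phases else as.integer(acq)
  stopifnot(k >= 3L)
  2 * pi * (seq_len(k) - 1L) / k
}

#' Instrument response model
#'
#' Lumped model of the detector/illumination chain: a phase delay and a
#' modulation-depth factor applied identically to every pixel, plus
#' optional additive Gaussian read noise. Homodyne gating waveform detail
#' is deliberately abstracted into `mod_factor`: the referencing step
#' cancels the instrument response regardless of waveform shape.
#'
#' @param phase_offset instrument phase delay in radians.
#' @param mod_factor instrument modulation factor, in (0, 1].
#' @param read_noise_sd additive read noise standard deviation in counts
#'   (>= 0; default 0, i.e. pure shot noise).
#' @return an object of class `flim_instrument`.
#' @export
flim_instrument <- function(phase_offset = 0, mod_factor = 1,
                            read_noise_sd = 0) {
  stopifnot(is.numeric(phase_offset), length(phase_offset) == 1L,
            is.finite(phase_offset),
            is.numeric(mod_factor), length(mod_factor) == 1L,
            is.numeric(read_noise_sd), read_noise_sd >= 0)
  if (mod_factor <= 0 || mod_factor > 1)
    stop("mod_factor must lie in (0, 1]")
  structure(
    list(phase_offset = phase_offset, mod_factor = mod_factor,
         read_noise_sd = read_noise_sd),
    class = "flim_instrument")
}

#' @export
print.flim_instrument <- function(x, ...) {
  cat(sprintf(
    "<flim_instrument> phase offset %.4g rad, mod factor %.3g, read noise %.3g\n",
    x$phase_offset, x$mod_factor, x$read_noise_sd))
  invisible(x)
}
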