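#' Expected phasor of the calibration reference
#'
#' Phase and modulation a fluorophore of known lifetime tau_ref should
#' present at modulation frequency f:
#' Phi_ref = atan(omega tau_ref), m_ref = 1/sqrt(1 + (omega tau_ref)^2).
#'
#' @param tau_ref reference lifetime in ns (> 0 allowed to be 0 in the
#'   zero-lifetime limit).
#' @param frequency modulation frequency in Hz.
#' @return list with `phase` (rad) and `modulation`.
#' @examples
#' reference_phasor(4.0, 20e6)  # fluorescein at 20 MHz
#' @export
reference_phasor <- function(tau_ref, frequency) {
  stopifnot(is.numeric(tau_ref), tau_ref >= 0)
  wt <- omega_ns(frequency) * tau_ref
  list(phase = atan(wt), modulation = 1 / sqrt(1 + wt^2))
}

# wrap angles into the principal branch (-pi, pi]
wrap_phase <- function(x) {
  out <- (x + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}

#' Calibrate a raw phasor field against a reference
#'
#' Corrects the instrument frequency response using a reference stack of
#' a spatially uniform fluorophore with known lifetime: per pixel,
#' \deqn{\Phi_{cal} = \Phi_{raw} - \Phi_{raw,ref} + \Phi_{ref,true}}
#' (wrapped into (-pi, pi]) and
#' \deqn{m_{cal} = (m_{raw} / m_{raw,ref}) \cdot m_{ref,true}.}
#' Any instrument phase delay or modulation loss common to both stacks
#' cancels. The reference correction is applied per pixel by default
#' (which also corrects spatially varying instrument response); with
#' `reference_mode = "global"` the medians of the valid reference phase
#' and modulation are used instead.
#'
#' @param sample raw `phasor_field` of the specimen.
#' @param reference raw `phasor_field` of the reference fluorophore.
#' @param reference_mode "pixel" (default) or "global".
#' @param mod_min reference pixels with modulation depth at or below
#'   this are flagged invalid.
#' @return a calibrated `phasor_field`.
#' @export
calibrate <- function(sample, reference,
                      reference_mode = c("pixel", "global"),
                      mod_min = 1e-6) {
  stopifnot(inherits(sample, "phasor_field"),
            inherits(reference, "phasor_field"))
  if (sample$calibrated) stop("sample field is already calibrated")
  if (!identical(dim(sample$dc), dim(reference$dc)))
    stop("sample and reference shapes differ")
  reference_mode <- match.arg(reference_mode)
  acq <- sample$acq
  truth <- reference_phasor(acq$reference_lifetime, acq$frequency)
  if (reference_mode == "pixel") {
    ref_phase <- reference$phase
    ref_mod <- reference$modulation
    ref_valid <- reference$valid & is.finite(ref_mod) & ref_mod > mod_min
  } else {
    ok <- reference$valid & is.finite(reference$modulation) &
      reference$modulation > mod_min
    if (!any(ok)) stop("no valid reference pixels for global calibration")
    ref_phase <- matrix(stats::median(reference$phase[ok]),
                        nrow(sample$dc), ncol(sample$dc))
    ref_mod <- matrix(stats::median(reference$modulation[ok]),
                      nrow(sample$dc), ncol(sample$dc))
    ref_valid <- matrix(TRUE, nrow(sample$dc), ncol(sample$dc))
  }
  valid <- sample$valid & ref_valid
  phase_cal <- wrap_phase(sample$phase - ref_phase + truth$phase)
  mod_cal <- (sample$modulation / ref_mod) * truth$modulation
  phase_cal[!valid] <- NA_real_
  mod_cal[!valid] <- NA_real_
  phasor_field(sample$dc, mod_cal * cos(phase_cal),
               mod_cal * sin(phase_cal), valid, acq, calibrated = TRUE)
}

#' Phase lifetime from calibrated phase
#'
#' tau_phi = tan(Phi)/omega for Phi in [0, pi/2); phases outside that
#' physical domain (e.g. small negative values from noise) return the NA
#' sentinel rather than a clamped value, so masked means stay unbiased.
#'
#' @param phase calibrated phase in radians (vector or matrix).
#' @param frequency modulation frequency in Hz.
#' @return lifetimes in ns with NA where the phase is out of domain.
#' @export
lifetime_from_phase <- function(phase, frequency) {
  w <- omega_ns(frequency)
  ok <- is.finite(phase) & phase >= 0 & phase < pi / 2
  out <- phase
  out[!ok] <- NA_real_
  out[ok] <- tan(phase[ok]) / w
  out
}

#' Modulation lifetime from calibrated modulation depth
#'
#' tau_m = sqrt(1/m^2 - 1)/omega for m in (0, 1]; m > 1 (noise) or
#' m <= 0 returns the NA sentinel.
#'
#' @param modulation calibrated modulation depth (vector or matrix).
#' @param frequency modulation frequency in Hz.
#' @return lifetimes in ns with NA where m is out of domain.
#' @export
lifetime_from_modulation <- function(modulation, frequency) {
  w <- omega_ns(frequency)
  ok <- is.finite(modulation) & modulation > 0 & modulation <= 1
  out <- modulation
  out[!ok] <- NA_real_
  out[ok] <- sqrt(1 / modulation[ok]^2 - 1) / w
  out
}

#' Lifetime image from a calibrated phasor field
#'
#' Converts calibrated phase and modulation into tau_phi and tau_mod
#' maps. Valid pixels carry finite non-negative lifetimes; nonphysical
#' pixels hold the NA sentinel and are excluded from all downstream
#' statistics.
#'
#' @param field calibrated `phasor_field`.
#' @param norm_intensity optional flat-field-normalized intensity matrix
#'   (see [flat_field()]); stored alongside for masking and F-scores.
#' @return an object of class `lifetime_image` with `tau_phi`, `tau_mod`
#'   (ns), `intensity` (raw DC), `norm_intensity`, `valid` and `acq`.
#' @export
lifetime_image <- function(field, norm_intensity = NULL) {
  stopifnot(inherits(field, "phasor_field"))
  if (!field$calibrated)
    stop("lifetime maps require a calibrated phasor field")
  tau_phi <- lifetime_from_phase(field$phase, field$acq$frequency)
  tau_mod <- lifetime_from_modulation(field$modulation,
                                      field$acq$frequency)
  if (!is.null(norm_intensity))
    stopifnot(identical(dim(norm_intensity), dim(field$dc)))
  structure(
    list(tau_phi = tau_phi, tau_mod = tau_mod,
         intensity = field$dc, norm_intensity = norm_intensity,
         valid = field$valid, acq = field$acq),
    class = "lifetime_image")
}

#' @export
print.lifetime_image <- function(x, ...) {
  ok <- is.finite(x$tau_phi)
  cat(sprintf(
    "<lifetime_image> %d x %d px, %s @ %.4g MHz, %.1f%% valid tau_phi\n",
    nrow(x$tau_phi), ncol(x$tau_phi), x$acq$channel,
    x$acq$frequency / 1e6, 100 * mean(ok)))
  if (any(ok))
    cat(sprintf("  tau_phi %.4g +/- %.3g ns, tau_mod %.4g +/- %.3g ns (valid px)\n",
                mean(x$tau_phi[ok]), stats::sd(x$tau_phi[ok]),
                mean(x$tau_mod[is.finite(x$tau_mod)]),
                stats::sd(x$tau_mod[is.finite(x$tau_mod)])))
  invisible(x)
}

#' @export
dim.lifetime_image <- function(x) dim(x$tau_phi)
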