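#' Reconstruct lifetime maps from sample and reference stacks
#'
#' End-to-end single-image reconstruction: demodulate both stacks,
#' calibrate the sample phasor field against the reference, flat-field
#' the intensity, and convert to phase and modulation lifetime maps.
#' This is the per-image core of the analysis; [run_pipeline()] wraps it
#' with file I/O, masking and summaries.
#'
#' @param sample a [phase_stack()] of the specimen.
#' @param reference a [phase_stack()] of the uniform reference
#'   fluorophore acquired with the same settings.
#' @param reference_mode per-"pixel" (default) or "global" reference
#'   correction, see [calibrate()].
#' @param dc_min DC validity threshold in counts, see [demodulate()].
#' @return an object of class `flim_reconstruction`: a list with the
#'   `lifetime` ([lifetime_image()]), the calibrated `phasor`, the raw
#'   `sample_field` and `reference_field`, and `acq`.
#' @examples
#' acq <- flim_acquisition()
#' ref <- reference_stack(acq, photons = 500, dim = c(16, 16), noiseless = TRUE)
#' smp <- simulate_stack(uniform_scene(2.0, 500, c(16, 16)), acq, noiseless = TRUE)
#' rec <- flim_reconstruct(smp, ref)
#' summary(rec)
#' @export
flim_reconstruct <- function(sample, reference,
                             reference_mode = c("pixel", "global"),
                             dc_min = 10) {
  stopifnot(inherits(sample, "phase_stack"),
            inherits(reference, "phase_stack"))
  a <- sample$acq; b <- reference$acq
  if (a$frequency != b$frequency)
    stop(sprintf("modulation frequency mismatch: sample %g Hz, reference %g Hz",
                 a$frequency, b$frequency))
  if (a$n_phases != b$n_phases)
    stop(sprintf("phase count mismatch: sample K=%d, reference K=%d",
                 a$n_phases, b$n_phases))
  if (a$reference_lifetime != b$reference_lifetime)
    stop("reference lifetime mismatch between sample and reference metadata")
  sf <- demodulate(sample, dc_min = dc_min)
  rf <- demodulate(reference, dc_min = dc_min)
  cal <- calibrate(sf, rf, reference_mode = match.arg(reference_mode))
  ni <- flat_field(sf, rf, epsilon = dc_min)
  lt <- lifetime_image(cal, norm_intensity = ni)
  structure(
    list(lifetime = lt, phasor = cal, sample_field = sf,
         reference_field = rf, acq = a),
    class = "flim_reconstruction")
}

#' @export
print.flim_reconstruction <- function(x, ...) {
  cat("<flim_reconstruction>\n")
  print(x$lifetime)
  invisible(x)
}

#' Masked summary of a reconstruction
#'
#' Computes the image-level [summarize_masked()] statistics. With
#' `mask = NULL` an Otsu foreground mask is derived from the normalized
#' intensity (see [otsu_mask()]); pass `mask = "all"` to summarize every
#' valid pixel (e.g. for uniform solution phantoms, whose flat histogram
#' would make Otsu meaningless).
#'
#' @param object a `flim_reconstruction`.
#' @param mask logical matrix, `NULL` (Otsu), or `"all"`.
#' @param ... unused.
#' @return a `masked_summary` (see [summarize_masked()]).
#' @export
summary.flim_reconstruction <- function(object, mask = NULL, ...) {
  lt <- object$lifetime
  if (is.null(mask)) {
    mask <- otsu_mask(lt$norm_intensity)
  } else if (identical(mask, "all")) {
    mask <- matrix(TRUE, nrow(lt$tau_phi), ncol(lt$tau_phi))
  }
  summarize_masked(lt, mask)
}

#' Plot a reconstruction
#'
#' Four-panel display: normalized intensity, tau_phi, tau_mod and the
#' validity mask.
#'
#' @param x a `flim_reconstruction`.
#' @param ... unused.
#' @export
plot.flim_reconstruction <- function(x, ...) {
  lt <- x$lifetime
  old <- graphics::par(mfrow = c(2, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(old))
  panel <- function(m, title) {
    m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
    graphics::image(t(m), axes = FALSE, main = title,
                    col = grDevices::hcl.colors(64, "viridis"),
                    useRaster = TRUE)
  }
  ni <- lt$norm_intensity
  if (is.null(ni)) ni <- lt$intensity
  panel(ni, "normalized intensity")
  panel(lt$tau_phi, sprintf("tau_phi (ns), %s", x$acq$channel))
  panel(lt$tau_mod, sprintf("tau_mod (ns), %s", x$acq$channel))
  panel(lt$valid + 0, "valid mask")
  invisible(x)
}
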