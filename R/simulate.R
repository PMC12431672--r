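#' Phase-stepped homodyne stack
#'
#' Container for K phase-stepped intensity frames plus acquisition
#' metadata. Frames are stored as an `[rows, cols, K]` array; for
#' simulated stacks a `truth` list travels alongside the pixel data
#' (never embedded in it) carrying the generating phase, modulation and
#' lifetime maps.
#'
#' @param frames numeric array `[rows, cols, K]`, finite and >= 0.
#' @param phases phase offsets theta_k in radians, length K.
#' @param acq a [flim_acquisition()].
#' @param instrument optional [flim_instrument()] used to generate the
#'   stack.
#' @param truth optional ground-truth list (simulated stacks only).
#' @param pixel_size pixel pitch in micrometres.
#' @return an object of class `phase_stack`.
#' @export
phase_stack <- function(frames, phases, acq, instrument = NULL,
                        truth = NULL, pixel_size = 1) {
  stopifnot(is.array(frames), length(dim(frames)) == 3L,
            inherits(acq, "flim_acquisition"))
  if (dim(frames)[3] != length(phases))
    stop(sprintf("frame count (%d) does not match phase offsets (%d)",
                 dim(frames)[3], length(phases)))
  if (length(phases) < 3L) stop("a phase stack needs K >= 3 frames")
  if (!all(is.finite(frames)) || any(frames < 0))
    stop("frames must be finite and >= 0")
  structure(
    list(frames = frames, phases = as.numeric(phases), acq = acq,
         instrument = instrument, truth = truth, pixel_size = pixel_size),
    class = "phase_stack")
}

#' @export
print.phase_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<phase_stack> %d x %d px, K = %d frames, %s @ %.4g MHz%s\n",
    d[1], d[2], d[3], x$acq$channel, x$acq$frequency / 1e6,
    if (!is.null(x$truth)) ", with ground truth" else ""))
  invisible(x)
}

#' @export
dim.phase_stack <- function(x) dim(x$frames)

# Separate truth maps for a scene (per-pixel generating phasor and
# lifetimes), evaluated region by region.
scene_truth <- function(scene, acq) {
  ph <- lapply(scene$mixtures, mixture_phasor, frequency = acq$frequency)
  idx <- scene$regions
  take <- function(field) {
    vals <- vapply(ph, `[[`, numeric(1), field)
    matrix(vals[idx], nrow(idx))
  }
  list(phase = take("phase"), modulation = take("modulation"),
       tau_phi = take("tau_phi"), tau_mod = take("tau_mod"),
       dc = scene$intensity * scene$illumination,
       regions = scene$regions)
}

#' Simulate a homodyne phase-stepped acquisition
#'
#' Forward model of a single-frequency homodyne FLIM acquisition. Frame k
#' has per-pixel expectation
#' \deqn{E_k = I \cdot L \cdot [1 + m_{inst} m \cos(\theta_k - \Phi - \phi_{inst})]}
#' where I is the scene intensity, L the illumination field, (Phi, m) the
#' per-pixel mixture phasor and (phi_inst, m_inst) the instrument
#' response. Homodyne detection is modelled as an ideal sinusoidal gain
#' response. Frames are optionally PSF-blurred, then Poisson-sampled
#' (plus Gaussian read noise, truncated at zero) unless `noiseless`.
#'
#' @param scene a [flim_scene()].
#' @param acq a [flim_acquisition()].
#' @param instrument a [flim_instrument()].
#' @param noiseless if TRUE, return expectation frames without sampling.
#' @param seed optional RNG seed; a fixed seed reproduces the stack
#'   bit-exactly.
#' @return a [phase_stack()] with ground truth attached.
#' @export
simulate_stack <- function(scene, acq, instrument = flim_instrument(),
                           noiseless = FALSE, seed = NULL) {
  stopifnot(inherits(scene, "flim_scene"),
            inherits(acq, "flim_acquisition"),
            inherits(instrument, "flim_instrument"))
  theta <- phase_steps(acq)
  truth <- scene_truth(scene, acq)
  base <- truth$dc
  amp <- instrument$mod_factor * truth$modulation
  shift <- truth$phase + instrument$phase_offset
  h <- nrow(base); w <- ncol(base); k <- length(theta)
  frames <- array(0, c(h, w, k))
  for (i in seq_len(k))
    frames[, , i] <- base * (1 + amp * cos(theta[i] - shift))
  if (any(frames < 0))
    stop("negative frame expectation; check modulation factors")
  if (scene$psf_fwhm > 0) {
    sigma_px <- scene$psf_fwhm / (2 * sqrt(2 * log(2))) / scene$pixel_size
    for (i in seq_len(k))
      frames[, , i] <- EBImage::gblur(frames[, , i], sigma = sigma_px,
                                      boundary = "replicate")
    frames[frames < 0] <- 0  # clip tiny negative filter ringing
  }
  if (!noiseless) {
    if (!is.null(seed)) set.seed(seed)
    frames[] <- stats::rpois(length(frames), frames)
    if (instrument$read_noise_sd > 0) {
      frames[] <- frames + stats::rnorm(length(frames),
                                        sd = instrument$read_noise_sd)
      frames[frames < 0] <- 0
    }
  }
  phase_stack(frames, theta, acq, instrument = instrument, truth = truth,
              pixel_size = scene$pixel_size)
}

#' Simulate a reference-fluorophore stack
#'
#' Spatially uniform monoexponential scene at the acquisition's reference
#' lifetime (e.g. fluorescein, 4.0 ns), imaged with the same instrument
#' model and, by default, the same illumination field as the sample so
#' that flat-field correction is meaningful.
#'
#' @param acq a [flim_acquisition()]; `reference_lifetime` is used.
#' @param instrument a [flim_instrument()].
#' @param photons expected photons per pixel per frame.
#' @param dim image dimensions c(rows, cols).
#' @param illumination optional illumination field matrix.
#' @param pixel_size pixel pitch in micrometres.
#' @param noiseless if TRUE, return expectation frames.
#' @param seed optional RNG seed.
#' @return a [phase_stack()].
#' @export
reference_stack <- function(acq, instrument = flim_instrument(),
                            photons = 1000, dim = c(64L, 64L),
                            illumination = NULL, pixel_size = 1,
                            noiseless = FALSE, seed = NULL) {
  scene <- flim_scene(matrix(photons, dim[1], dim[2]),
                      flim_mixture(acq$reference_lifetime, 1, "reference"),
                      illumination = illumination,
                      pixel_size = pixel_size)
  simulate_stack(scene, acq, instrument, noiseless = noiseless,
                 seed = seed)
}
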