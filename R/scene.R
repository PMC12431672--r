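#' Scene phantom for the homodyne simulator
#'
#' Ground-truth description of an imaged field: expected photons per pixel
#' per phase frame, a region map assigning each pixel a fluorophore
#' mixture, a multiplicative illumination (vignetting) field, the pixel
#' pitch, and an optional Gaussian PSF width.
#'
#' @param intensity matrix of expected photons per pixel per frame (>= 0).
#' @param mixtures a [flim_mixture()] or list of mixtures.
#' @param regions integer matrix of the same shape as `intensity` indexing
#'   into `mixtures`; default all 1.
#' @param illumination multiplicative relative-gain matrix (> 0
#'   everywhere); default uniform 1.
#' @param pixel_size pixel pitch in micrometres (> 0).
#' @param psf_fwhm Gaussian PSF full width at half maximum in micrometres
#'   (0 = no blur).
#' @return an object of class `flim_scene`.
#' @export
flim_scene <- function(intensity, mixtures, regions = NULL,
                       illumination = NULL, pixel_size = 1,
                       psf_fwhm = 0) {
  stopifnot(is.matrix(intensity), all(is.finite(intensity)))
  if (any(intensity < 0)) stop("intensity_map must be >= 0 everywhere")
  if (inherits(mixtures, "flim_mixture")) mixtures <- list(mixtures)
  stopifnot(is.list(mixtures), length(mixtures) >= 1L,
            all(vapply(mixtures, inherits, TRUE, "flim_mixture")))
  if (is.null(regions))
    regions <- matrix(1L, nrow(intensity), ncol(intensity))
  stopifnot(is.matrix(regions), identical(dim(regions), dim(intensity)))
  if (any(regions < 1L) || any(regions > length(mixtures)))
    stop("regions must index into mixtures")
  if (is.null(illumination))
    illumination <- matrix(1, nrow(intensity), ncol(intensity))
  stopifnot(is.matrix(illumination),
            identical(dim(illumination), dim(intensity)))
  if (any(illumination <= 0)) stop("illumination_field must be > 0 everywhere")
  stopifnot(is.numeric(pixel_size), pixel_size > 0,
            is.numeric(psf_fwhm), psf_fwhm >= 0)
  structure(
    list(intensity = intensity, mixtures = mixtures,
         regions = matrix(as.integer(regions), nrow(regions)),
         illumination = illumination, pixel_size = pixel_size,
         psf_fwhm = psf_fwhm),
    class = "flim_scene")
}

#' @export
print.flim_scene <- function(x, ...) {
  cat(sprintf(
    "<flim_scene> %d x %d px (%.3g um/px), %d mixture(s), psf_fwhm %.3g um\n",
    nrow(x$intensity), ncol(x$intensity), x$pixel_size,
    length(x$mixtures), x$psf_fwhm))
  invisible(x)
}

#' Spatially uniform scene
#'
#' @param mixture a [flim_mixture()] or a single lifetime in ns.
#' @param photons expected photons per pixel per frame.
#' @param dim image dimensions c(rows, cols).
#' @param pixel_size pixel pitch in micrometres.
#' @return a [flim_scene()].
#' @export
uniform_scene <- function(mixture, photons, dim = c(64L, 64L),
                          pixel_size = 1) {
  if (is.numeric(mixture)) mixture <- flim_mixture(mixture)
  flim_scene(matrix(photons, dim[1], dim[2]), mixture,
             pixel_size = pixel_size)
}

#' Radially symmetric vignetting field
#'
#' Cosine-fourth style illumination falloff used to emulate nonuniform
#' widefield illumination: gain 1 at the optical centre, `edge_gain` at
#' the most distant corner.
#'
#' @param dim image dimensions c(rows, cols).
#' @param edge_gain relative gain at the far corner, in (0, 1].
#' @return matrix of multiplicative gains.
#' @export
vignetting_field <- function(dim, edge_gain = 0.6) {
  stopifnot(edge_gain > 0, edge_gain <= 1)
  r0 <- (dim[1] - 1) / 2; c0 <- (dim[2] - 1) / 2
  rr <- outer((seq_len(dim[1]) - 1 - r0)^2, (seq_len(dim[2]) - 1 - c0)^2, "+")
  rmax <- max(rr)
  if (rmax == 0) return(matrix(1, dim[1], dim[2]))
  1 - (1 - edge_gain) * rr / rmax
}

#' Edge target intensity image
#'
#' Vertical light-dark boundary convolved with a Gaussian PSF of the
#' stated FWHM. The convolution of an ideal step with a Gaussian has the
#' closed form low + (high-low) * Phi((x - x0)/sigma), which is evaluated
#' directly (no numerical convolution), so the generated edge-spread
#' function carries exactly the requested PSF width.
#'
#' @param dim image dimensions c(rows, cols).
#' @param pixel_size pixel pitch in micrometres.
#' @param psf_fwhm Gaussian PSF FWHM in micrometres (0 = ideal step).
#' @param edge_x boundary position in micrometres (default: image centre;
#'   column j sits at x = j * pixel_size, 0-based).
#' @param low,high intensities on the dark and bright sides.
#' @return intensity matrix.
#' @export
edge_target <- function(dim = c(64L, 256L), pixel_size = 0.2,
                        psf_fwhm = 2.0, edge_x = NULL,
                        low = 10, high = 1000) {
  stopifnot(psf_fwhm >= 0, pixel_size > 0, high > low)
  x <- (seq_len(dim[2]) - 1) * pixel_size
  if (is.null(edge_x)) edge_x <- mean(range(x))
  prof <- if (psf_fwhm == 0) {
    ifelse(x >= edge_x, high, low)
  } else {
    sigma <- psf_fwhm / (2 * sqrt(2 * log(2)))
    low + (high - low) * stats::pnorm((x - edge_x) / sigma)
  }
  matrix(prof, dim[1], dim[2], byrow = TRUE)
}

#' Two-population cell scene
#'
#' Elliptical "cells" from two populations with distinct lifetime
#' signatures scattered on a dim background, emulating a monolayer or
#' tissue field of view with two metabolic phenotypes. Cell nuclei are
#' rendered as dimmer concentric ellipses. Overlap policy is
#' deterministic: a later cell overwrites earlier ones.
#'
#' @param dim image dimensions c(rows, cols).
#' @param n_cells integer vector: cells per population (length 2, or a
#'   scalar split evenly).
#' @param mixtures list of two [flim_mixture()]s, one per population.
#' @param photons_per_cell expected photons collected from one cell over
#'   the whole K-frame stack.
#' @param n_phases number of phase frames K (converts the per-stack cell
#'   budget into per-frame pixel intensities).
#' @param radius_px range of cell semi-major axes in pixels.
#' @param axis_ratio range of semi-minor/semi-major ratios.
#' @param nucleus_dim relative intensity of the nucleus (dim structure).
#' @param nucleus_frac nucleus semi-axis as a fraction of the cell's.
#' @param background_fraction background intensity per pixel per frame as
#'   a fraction of the mean cell pixel intensity.
#' @param pixel_size pixel pitch in micrometres.
#' @param seed optional RNG seed for reproducible layouts.
#' @return a [flim_scene()] with extra elements `cells` (data.frame: id,
#'   population, centre, axes, angle, n_pixels) and `labels` (integer
#'   matrix; 0 = background, otherwise cell id).
#' @export
two_population_scene <- function(dim = c(96L, 96L), n_cells = c(6L, 6L),
                                 mixtures, photons_per_cell = 1e4,
                                 n_phases = 25L, radius_px = c(3, 4.5),
                                 axis_ratio = c(0.7, 1),
                                 nucleus_dim = 0.4, nucleus_frac = 0.45,
                                 background_fraction = 0.02,
                                 pixel_size = 1, seed = NULL) {
  stopifnot(is.list(mixtures), length(mixtures) == 2L,
            all(vapply(mixtures, inherits, TRUE, "flim_mixture")))
  if (length(n_cells) == 1L)
    n_cells <- c(ceiling(n_cells / 2), floor(n_cells / 2))
  n_cells <- as.integer(n_cells)
  stopifnot(all(n_cells >= 0L))
  if (!is.null(seed)) set.seed(seed)
  h <- dim[1]; w <- dim[2]
  ntot <- sum(n_cells)
  population <- rep(1:2, n_cells)
  labels <- matrix(0L, h, w)
  regions <- matrix(1L, h, w)
  intensity <- matrix(0, h, w)
  rows <- matrix(seq_len(h) - 1, h, w)
  cols <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
  cells <- NULL
  if (ntot > 0) {
    population <- sample(population)  # interleave populations spatially
    cy <- stats::runif(ntot, radius_px[2], h - 1 - radius_px[2])
    cx <- stats::runif(ntot, radius_px[2], w - 1 - radius_px[2])
    a <- stats::runif(ntot, radius_px[1], radius_px[2])
    b <- a * stats::runif(ntot, axis_ratio[1], axis_ratio[2])
    ang <- stats::runif(ntot, 0, pi)
    npx <- integer(ntot)
    for (i in seq_len(ntot)) {
      u <- (cols - cx[i]) * cos(ang[i]) + (rows - cy[i]) * sin(ang[i])
      v <- -(cols - cx[i]) * sin(ang[i]) + (rows - cy[i]) * cos(ang[i])
      inside <- (u / a[i])^2 + (v / b[i])^2 <= 1
      nucleus <- (u / (a[i] * nucleus_frac))^2 +
                 (v / (b[i] * nucleus_frac))^2 <= 1
      npx[i] <- sum(inside)
      if (npx[i] == 0L) next
      per_px <- photons_per_cell / (npx[i] * n_phases)
      labels[inside] <- i
      regions[inside] <- population[i]
      intensity[inside] <- per_px
      intensity[inside & nucleus] <- per_px * nucleus_dim
    }
    cells <- data.frame(id = seq_len(ntot), population = population,
                        centre_row = cy, centre_col = cx,
                        semi_major = a, semi_minor = b, angle = ang,
                        n_pixels = npx)
  }
  bg <- if (ntot > 0 && any(labels > 0))
    background_fraction * mean(intensity[labels > 0]) else 0
  intensity[labels == 0L] <- bg
  scene <- flim_scene(intensity, mixtures, regions,
                      pixel_size = pixel_size)
  scene$cells <- cells
  scene$labels <- labels
  scene
}
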