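#' Otsu threshold of an intensity image
#'
#' Maximizes the between-class variance over a 256-bin histogram of the
#' finite pixels, spanning [min, max]. Candidate thresholds are the
#' inner bin edges; ties in between-class variance are resolved by the
#' lowest threshold, so the result is deterministic.
#'
#' @param x numeric matrix or vector; NA/NaN pixels are ignored.
#' @param n_bins number of histogram bins (default 256).
#' @return the threshold value (a bin edge).
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  v <- x[is.finite(x)]
  if (length(v) < 2L || diff(range(v)) == 0)
    stop("degenerate histogram: need >= 2 distinct finite values")
  edges <- seq(min(v), max(v), length.out = n_bins + 1L)
  counts <- tabulate(
    pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L), n_bins),
    nbins = n_bins)
  centres <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  w <- cumsum(counts)
  mu <- cumsum(counts * centres)
  n <- w[n_bins]; mu_t <- mu[n_bins] / n
  split <- seq_len(n_bins - 1L)
  w0 <- w[split] / n
  m0 <- ifelse(w[split] > 0, mu[split] / w[split], 0)
  m1 <- ifelse(w[split] < n, (mu[n_bins] - mu[split]) / (n - w[split]), 0)
  bcv <- w0 * (1 - w0) * (m0 - m1)^2
  bcv[w[split] == 0 | w[split] == n] <- -Inf
  edges[which.max(bcv) + 1L]  # which.max takes the first (lowest) maximum
}

#' Otsu foreground mask
#'
#' Pixels strictly above the Otsu threshold of the finite pixels;
#' non-finite pixels are FALSE.
#'
#' @inheritParams otsu_threshold
#' @return logical matrix (or vector) foreground mask.
#' @export
otsu_mask <- function(x, n_bins = 256L) {
  thr <- otsu_threshold(x, n_bins)
  out <- is.finite(x) & x > thr
  out
}

#' Masked image-level lifetime summary
#'
#' Mean and standard deviation of the phase and modulation lifetimes and
#' of the intensity over the masked, valid pixels, plus the photon-economy
#' F-scores. The population SD (divisor n) is used throughout: at the
#' masked pixel counts typical of an image the n vs n-1 distinction is
#' immaterial, but it must be fixed for reproducibility. Intensity
#' statistics use the raw DC counts (F-score inputs must be in photon
#' units for the shot-noise interpretation); the same mask is used for
#' lifetime and intensity statistics.
#'
#' @param lifetimes a [lifetime_image()].
#' @param mask logical matrix; intersected with the image validity and
#'   the per-map finiteness before computing statistics.
#' @return an object of class `masked_summary`: one-row data.frame with
#'   channel, mean/sd of tau_phi, tau_mod and intensity, pixel count and
#'   F-scores (`f_score_phi`, `f_score_mod`; NA when the intensity has
#'   zero variance, e.g. noiseless uniform phantoms).
#' @export
summarize_masked <- function(lifetimes, mask) {
  stopifnot(inherits(lifetimes, "lifetime_image"), is.logical(mask),
            identical(dim(mask), dim(lifetimes$tau_phi)))
  mask <- mask & lifetimes$valid
  if (!any(mask)) stop("empty mask after intersecting with validity")
  sd_pop <- function(v) sqrt(mean((v - mean(v))^2))
  stat <- function(map) {
    v <- map[mask & is.finite(map)]
    if (length(v) == 0L) return(c(NA_real_, NA_real_, 0))
    c(mean(v), sd_pop(v), length(v))
  }
  p <- stat(lifetimes$tau_phi)
  m <- stat(lifetimes$tau_mod)
  i <- stat(lifetimes$intensity)
  fs <- function(tau) {
    if (!is.finite(tau[1]) || tau[1] <= 0 || i[2] == 0 || i[1] <= 0)
      return(NA_real_)
    f_score(tau[1], tau[2], i[1], i[2])
  }
  structure(
    data.frame(channel = lifetimes$acq$channel,
               mean_tau_phi = p[1], sd_tau_phi = p[2],
               mean_tau_mod = m[1], sd_tau_mod = m[2],
               mean_intensity = i[1], sd_intensity = i[2],
               n_pixels = as.integer(sum(mask)),
               f_score_phi = fs(p), f_score_mod = fs(m)),
    class = c("masked_summary", "data.frame"))
}

#' @export
print.masked_summary <- function(x, ...) {
  cat(sprintf("<masked_summary> %s, %d px\n", x$channel, x$n_pixels))
  cat(sprintf("  tau_phi %.4f +/- %.4f ns   tau_mod %.4f +/- %.4f ns\n",
              x$mean_tau_phi, x$sd_tau_phi, x$mean_tau_mod, x$sd_tau_mod))
  cat(sprintf("  intensity %.4g +/- %.4g counts\n",
              x$mean_intensity, x$sd_intensity))
  cat(sprintf("  F-score: phase %.4g, modulation %.4g\n",
              x$f_score_phi, x$f_score_mod))
  invisible(x)
}

#' Photon-economy F-score
#'
#' Figure of merit for lifetime sensitivity:
#' \deqn{F = (\Delta\tau/\tau) / (\Delta I / I)}
#' the relative lifetime spread per relative intensity spread. For a
#' shot-noise-limited acquisition a perfect FLIM system reaches F = 1;
#' lower is more photon-efficient, and real systems sit above 1.
#'
#' @param mean_tau,sd_tau mean and SD of the lifetime (ns).
#' @param mean_intensity,sd_intensity mean and SD of the intensity.
#' @return the dimensionless F-score.
#' @export
f_score <- function(mean_tau, sd_tau, mean_intensity, sd_intensity) {
  stopifnot(is.numeric(mean_tau), is.numeric(sd_tau),
            is.numeric(mean_intensity), is.numeric(sd_intensity))
  if (!(mean_tau > 0) || !(mean_intensity > 0))
    stop("mean lifetime and mean intensity must be > 0")
  if (sd_tau < 0 || sd_intensity < 0) stop("standard deviations must be >= 0")
  if (sd_intensity == 0)
    stop("undefined F (no intensity variation)")
  (sd_tau / mean_tau) / (sd_intensity / mean_intensity)
}
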