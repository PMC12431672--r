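# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the demodulator is checked against a general
# least-squares sinusoid fit, Otsu against a brute-force split search, and
# the mixture phasor against numerical integration of the decay.

# Least-squares fit of I_k = a0 + a1 cos(theta_k) + a2 sin(theta_k) per
# pixel; works for arbitrary (not necessarily uniform) phase steps.
ls_sinusoid_fit <- function(frames, phases) {
  d <- dim(frames)
  m <- matrix(frames, nrow = d[1] * d[2], ncol = d[3])
  X <- cbind(1, cos(phases), sin(phases))
  coef <- t(qr.solve(X, t(m)))  # n_px x 3
  dc <- coef[, 1]
  list(dc = matrix(dc, d[1], d[2]),
       modulation = matrix(sqrt(coef[, 2]^2 + coef[, 3]^2) / dc, d[1], d[2]),
       phase = matrix(atan2(coef[, 3], coef[, 2]), d[1], d[2]))
}

# Brute-force Otsu: for every candidate split of the n_bins histogram,
# recompute both class weights and means directly from the bin counts and
# return the threshold edge with maximal between-class variance (lowest
# split on ties).
brute_otsu <- function(x, n_bins = 256L) {
  v <- x[is.finite(x)]
  edges <- seq(min(v), max(v), length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  centres <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  best <- -Inf; best_split <- NA_integer_
  for (t in seq_len(n_bins - 1L)) {
    n0 <- sum(counts[1:t]); n1 <- sum(counts) - n0
    if (n0 == 0 || n1 == 0) next
    m0 <- sum(counts[1:t] * centres[1:t]) / n0
    m1 <- sum(counts[(t + 1):n_bins] * centres[(t + 1):n_bins]) / n1
    bcv <- (n0 / (n0 + n1)) * (n1 / (n0 + n1)) * (m0 - m1)^2
    if (bcv > best) { best <- bcv; best_split <- t }
  }
  edges[best_split + 1L]
}

# Mixture phasor by numerical integration of the impulse response
# I(t) = sum_i (alpha_i / tau_i) exp(-t / tau_i) at omega = 2 pi f:
# G = Int I cos(wt) / Int I, S = Int I sin(wt) / Int I.
integrate_mixture_phasor <- function(lifetimes, fractions, frequency) {
  w <- 2 * pi * frequency * 1e-9
  decay <- function(t) {
    rowSums(sapply(seq_along(lifetimes), function(i)
      fractions[i] / lifetimes[i] * exp(-t / lifetimes[i])))
  }
  upper <- 60 * max(lifetimes)
  den <- stats::integrate(decay, 0, upper, rel.tol = 1e-12)$value
  g <- stats::integrate(function(t) decay(t) * cos(w * t), 0, upper,
                        rel.tol = 1e-12, subdivisions = 2000L)$value / den
  s <- stats::integrate(function(t) decay(t) * sin(w * t), 0, upper,
                        rel.tol = 1e-12, subdivisions = 2000L)$value / den
  list(g = g, s = s)
}
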