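#' Aggregate image-level summaries into groups
#'
#' Collapses per-image masked summaries to one observation per image per
#' metric and attaches group labels, the unit of inference used
#' downstream (each field of view is one observation; pixel-level
#' inference would be pseudo-replication).
#'
#' @param summaries list of `masked_summary` objects (or a data.frame
#'   with their columns, one row per image).
#' @param groups character or factor vector of group labels, one per
#'   image; NAs or a length mismatch are errors.
#' @param image optional image identifiers (default `image1`, ...).
#' @return data.frame with columns `image`, `group`, `channel`,
#'   `mean_tau_phi`, `mean_tau_mod`.
#' @export
aggregate_images <- function(summaries, groups, image = NULL) {
  if (is.list(summaries) && !is.data.frame(summaries))
    summaries <- do.call(rbind, lapply(summaries, as.data.frame))
  stopifnot(is.data.frame(summaries))
  n <- nrow(summaries)
  if (length(groups) != n)
    stop("every image needs a group label (length mismatch)")
  if (anyNA(groups)) stop("unlabeled image: NA group label")
  if (is.null(image)) image <- paste0("image", seq_len(n))
  data.frame(image = as.character(image),
             group = as.character(groups),
             channel = summaries$channel,
             mean_tau_phi = summaries$mean_tau_phi,
             mean_tau_mod = summaries$mean_tau_mod)
}

# normalize (values, groups) or a named list into a list of numeric vectors
as_group_list <- function(values, groups = NULL) {
  if (is.list(values) && is.null(groups)) {
    gl <- lapply(values, as.numeric)
    if (is.null(names(gl))) names(gl) <- paste0("group", seq_along(gl))
  } else {
    stopifnot(is.numeric(values), length(groups) == length(values))
    gl <- split(as.numeric(values), factor(groups))
  }
  if (length(gl) < 2L) stop("inference needs >= 2 groups")
  if (any(vapply(gl, length, 1L) < 2L))
    stop("every group needs >= 2 observations")
  gl
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA from the between/within sums of
#' squares: F = MSB/MSW with (k-1, N-k) degrees of freedom. Degenerate
#' input with zero variance everywhere (all groups identical constants)
#' reports F = 0, p = 1.
#'
#' @param values numeric vector of observations, or a (named) list of
#'   numeric vectors (one per group).
#' @param groups group labels parallel to `values` (ignored when
#'   `values` is a list).
#' @return list with `f`, `p`, `df_between`, `df_within`, `ms_within`
#'   and per-group `means` and `n`.
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(5, 6, 7)))
#' @export
one_way_anova <- function(values, groups = NULL) {
  gl <- as_group_list(values, groups)
  n <- vapply(gl, length, 1L)
  m <- vapply(gl, mean, 1)
  N <- sum(n); k <- length(gl)
  grand <- sum(n * m) / N
  ssb <- sum(n * (m - grand)^2)
  ssw <- sum(vapply(gl, function(v) sum((v - mean(v))^2), 1))
  dfb <- k - 1L; dfw <- N - k
  msb <- ssb / dfb; msw <- ssw / dfw
  if (ssw == 0 && ssb == 0) {
    f <- 0; p <- 1
  } else if (ssw == 0) {
    f <- Inf; p <- 0
  } else {
    f <- msb / msw
    p <- stats::pf(f, dfb, dfw, lower.tail = FALSE)
  }
  list(f = f, p = p, df_between = dfb, df_within = dfw,
       ms_within = msw, means = m, n = n)
}

#' Tukey-Kramer pairwise comparisons
#'
#' Studentized-range post hoc test for all pairwise group differences,
#' with the Kramer adjustment for unequal group sizes:
#' q_ij = |m_i - m_j| / sqrt((MSW/2)(1/n_i + 1/n_j)), with adjusted
#' p-values from the studentized-range distribution with k means and
#' N - k error degrees of freedom (`stats::ptukey`).
#'
#' @inheritParams one_way_anova
#' @return data.frame with one row per pair: `group1`, `group2`, `diff`
#'   (mean difference, group2 - group1), `se`, `q` and `p_adj`.
#' @export
tukey_kramer <- function(values, groups = NULL) {
  gl <- as_group_list(values, groups)
  n <- vapply(gl, length, 1L)
  m <- vapply(gl, mean, 1)
  k <- length(gl); N <- sum(n)
  msw <- sum(vapply(gl, function(v) sum((v - mean(v))^2), 1)) / (N - k)
  pairs <- utils::combn(k, 2)
  out <- data.frame(
    group1 = names(gl)[pairs[1, ]], group2 = names(gl)[pairs[2, ]],
    diff = m[pairs[2, ]] - m[pairs[1, ]],
    se = sqrt(msw / 2 * (1 / n[pairs[1, ]] + 1 / n[pairs[2, ]])),
    row.names = NULL)
  if (msw == 0) {
    out$q <- ifelse(out$diff == 0, 0, Inf)
    out$p_adj <- ifelse(out$diff == 0, 1, 0)
  } else {
    out$q <- abs(out$diff) / out$se
    out$p_adj <- stats::ptukey(out$q, nmeans = k, df = N - k,
                               lower.tail = FALSE)
  }
  out
}

#' Compare image-level lifetimes across groups
#'
#' One-way ANOVA plus Tukey-Kramer post hoc tests on one image-level
#' metric, the cross-group inference applied to each channel x
#' (phase|modulation) lifetime metric.
#'
#' @param data data.frame from [aggregate_images()] (or with compatible
#'   columns).
#' @param metric column to analyse, e.g. "mean_tau_phi".
#' @param alpha significance level (default 0.05).
#' @return an object of class `group_result`: list with `metric`,
#'   `groups` (named list of image-level values), `anova`, `tukey`,
#'   `alpha` and `significant` (ANOVA p < alpha).
#' @export
group_compare <- function(data, metric = "mean_tau_phi", alpha = 0.05) {
  stopifnot(is.data.frame(data), metric %in% names(data),
            "group" %in% names(data), alpha > 0, alpha < 1)
  gl <- split(data[[metric]], factor(data$group))
  an <- one_way_anova(gl)
  tk <- tukey_kramer(gl)
  structure(
    list(metric = metric, groups = gl, anova = an, tukey = tk,
         alpha = alpha, significant = an$p < alpha),
    class = "group_result")
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf("<group_result> %s, %d groups (n = %s)\n", x$metric,
              length(x$groups),
              paste(vapply(x$groups, length, 1L), collapse = "/")))
  cat(sprintf("  ANOVA: F(%d, %d) = %.4g, p = %.4g %s alpha = %g\n",
              x$anova$df_between, x$anova$df_within, x$anova$f, x$anova$p,
              if (x$significant) "<" else ">=", x$alpha))
  cat("  Tukey-Kramer adjusted p-values:\n")
  for (i in seq_len(nrow(x$tukey)))
    cat(sprintf("    %s vs %s: diff = %+.4g, p = %.4g\n",
                x$tukey$group1[i], x$tukey$group2[i], x$tukey$diff[i],
                x$tukey$p_adj[i]))
  invisible(x)
}
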