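# Rank-based tests and multiple-testing correction shared by all pipeline
# stages. The Wilcoxon signed-rank test is implemented here in full because
# the exact two-sided p-value must be available for tied magnitudes (average
# ranks), which the stock implementation does not provide.

# Exact distribution of the positive-rank sum W+ under random signs, with
# average ranks for ties. Ranks can be half-integers, so everything is scaled
# by 2 and the distribution built by dynamic programming (one convolution per
# rank) instead of enumerating all 2^n sign patterns.
wilcoxon_exact_p <- function(ranks, w_obs) {
  s2 <- as.integer(round(2 * ranks))    # scaled ranks, integers
  total <- sum(s2)
  counts <- numeric(total + 1L)         # counts[k+1] = #patterns with 2*W+ = k
  counts[1L] <- 1
  for (r in s2) {
    shifted <- c(numeric(r), counts[seq_len(total + 1L - r)])
    counts <- counts + shifted
  }
  # two-sided: P(|W| >= |w_obs|) where W = W+ - W- = 2*W+ - sum(ranks)*... in
  # scaled units W_scaled = 2*k - total, |W_obs| scaled likewise.
  w_abs <- abs(round(2 * w_obs))
  k <- seq(0L, total)
  w_scaled <- abs(2L * k - total)
  sum(counts[w_scaled >= w_abs]) / sum(counts)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Differences `x - y` are ranked by absolute magnitude with average ranks for
#' ties; zero differences are dropped (with a message giving the count). The
#' statistic is `W = sum of signed ranks` (equivalently `W+ - W-`); `w_plus`,
#' the positive-rank sum, is also returned. The exact two-sided p-value is the
#' probability, over all 2^n equally likely sign patterns, of a |W| at least
#' as large as observed; it is computed for n <= 25 in `"auto"` mode (by
#' dynamic programming over the rank-sum distribution, valid under ties),
#' otherwise a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param mode `"auto"` (exact when n <= 25), `"exact"`, or `"normal_approx"`.
#' @return list with `statistic` (W), `w_plus`, `p_value`, `n_used` (pairs
#'   after dropping zeros), `n_zero_dropped`, `method`.
#' @export
wilcoxon_signed_rank <- function(x, y, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  if (length(x) != length(y) || length(x) < 1L)
    stop("x and y must be paired vectors of equal, positive length")
  d <- x - y
  if (anyNA(d)) stop("missing values in paired differences")
  zero <- d == 0
  if (all(zero)) stop("degenerate pairing: all differences are zero")
  if (any(zero)) message(sum(zero), " zero difference(s) dropped")
  d <- d[!zero]
  n <- length(d)
  r <- rank(abs(d))                     # average ranks for tied magnitudes
  w_plus <- sum(r[d > 0])
  w <- sum(sign(d) * r)                 # = w_plus - w_minus
  use_exact <- mode == "exact" || (mode == "auto" && n <= 25L)
  if (use_exact) {
    p <- wilcoxon_exact_p(r, w)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (abs(w_plus - mu) - 0.5) / sqrt(sigma2)   # continuity correction
    z <- max(z, 0)
    p <- 2 * stats::pnorm(-z)
    method <- "normal_approx"
  }
  list(statistic = w, w_plus = w_plus, p_value = min(p, 1), n_used = n,
       n_zero_dropped = sum(zero), method = method)
}

#' Kruskal-Wallis rank test across groups
#'
#' H from pooled average ranks with the standard tie correction; p-value from
#' the chi-square distribution on k - 1 degrees of freedom.
#'
#' @param groups list of numeric vectors, each nonempty; >= 2 groups, total
#'   N >= 3.
#' @return list with `statistic` (H), `p_value`, `df`, `n`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of >= 2 groups")
  sizes <- lengths(groups)
  if (any(sizes == 0L)) {
    nm <- names(groups)
    empty <- if (is.null(nm)) which(sizes == 0L) else nm[sizes == 0L]
    stop("empty group(s): ", paste(empty, collapse = ", "))
  }
  if (sum(sizes) < 3L) stop("need at least 3 observations in total")
  kt <- stats::kruskal.test(groups)
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter), n = sum(sizes))
}

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of average ranks; the two-sided p-value uses
#' the t approximation on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors, equal length >= 3, finite.
#' @return list with `statistic` (rho), `p_value`, `n`.
#' @export
spearman <- function(x, y) {
  check_corr_input(x, y)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("zero rank variance: constant input vector")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(statistic = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Pearson correlation
#'
#' Sample correlation with the two-sided t-approximation p-value.
#'
#' @param x,y numeric vectors, equal length >= 3, finite, non-constant.
#' @return list with `statistic` (r), `p_value`, `n`.
#' @export
pearson <- function(x, y) {
  check_corr_input(x, y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: constant input vector")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(statistic = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

check_corr_input <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite values in input")
  invisible(TRUE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment: with p-values sorted ascending,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, returned in the original
#' order.
#'
#' @param p_values numeric vector in \[0, 1\] (NA propagated).
#' @return adjusted vector, same length and order.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}
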