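#' Percentage mean absolute deviation from the subject mean
#'
#' Trial-level variability index of a measure within one condition:
#' for each subject, the mean absolute deviation of the trial values from
#' the subject's trial mean, relative to that mean; the per-subject
#' percentages are then averaged across subjects,
#' \deqn{MAD = \frac{100}{N_{subj}} \sum_{subj} \frac{1}{K_{subj}}
#'   \sum_k \frac{|M_{k,subj} - \mu_{subj}|}{\mu_{subj}}.}
#'
#' @param values Numeric vector of per-trial measure values.
#' @param subjects Vector (same length) of subject identifiers.
#' @return Scalar percentage MAD.
#' @export
mad_percent <- function(values, subjects) {
  if (length(values) != length(subjects))
    stop("values and subjects must have equal length")
  per_subj <- vapply(split(values, subjects), function(v) {
    mu <- mean(v)
    if (mu == 0) stop("zero subject mean; percentage MAD undefined for ",
                      "subject with values ", paste(v, collapse = ", "))
    100 * mean(abs(v - mu)) / abs(mu)
  }, numeric(1))
  mean(per_subj)
}

sawilowsky_label <- function(d) {
  cuts <- c(0.2, 0.5, 0.8, 1.2, 2.0)
  labels <- c("very small", "small", "medium", "large", "very large", "huge")
  labels[findInterval(abs(d), cuts) + 1L]
}

#' Cohen's d effect size with pooled standard deviation
#'
#' \eqn{d = (\mu_1 - \mu_2) / \sigma} with the pooled standard deviation
#' \eqn{\sigma = \sqrt{((n_1 - 1)\sigma_1^2 + (n_2 - 1)\sigma_2^2) /
#' (n_1 + n_2 - 2)}}, plus the Cohen-Sawilowsky qualitative label of |d|
#' (cutpoints 0.2, 0.5, 0.8, 1.2, 2.0 for "small" through "huge").
#'
#' @param group1,group2 Numeric vectors (each of length >= 2).
#' @return List with `d`, `label` and `pooled_sd`.
#' @export
cohens_d <- function(group1, group2) {
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 values")
  sp2 <- ((n1 - 1) * stats::var(group1) + (n2 - 1) * stats::var(group2)) /
    (n1 + n2 - 2)
  if (sp2 <= 0) stop("zero pooled standard deviation")
  d <- (mean(group1) - mean(group2)) / sqrt(sp2)
  list(d = d, label = sawilowsky_label(d), pooled_sd = sqrt(sp2))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration of the permutation distribution of the rank sum
#' (midranks for ties) when the combined sample size is at most 12;
#' otherwise the normal approximation with tie correction and continuity
#' correction. P-values are not corrected for multiple comparisons.
#'
#' @param group1,group2 Numeric vectors (each non-empty).
#' @return List with `statistic` (rank sum of group 1), `p_value`
#'   (two-sided) and `method` ("exact" or "normal").
#' @export
ranksum_test <- function(group1, group2) {
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 1L || n2 < 1L) stop("both groups must be non-empty")
  pooled <- c(group1, group2)
  rk <- rank(pooled)                 # midranks for ties
  w <- sum(rk[seq_len(n1)])
  n <- n1 + n2
  if (n <= 12L) {
    sums <- utils::combn(n, n1, function(ix) sum(rk[ix]))
    eps <- 1e-9
    p <- 2 * min(mean(sums <= w + eps), mean(sums >= w - eps))
    return(list(statistic = w, p_value = min(1, p), method = "exact"))
  }
  mu <- n1 * (n + 1) / 2
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / (n * (n - 1))
  s2 <- n1 * n2 / 12 * (n + 1 - tie_corr)
  if (s2 <= 0) stop("degenerate pooled sample (all values tied)")
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(s2)
  list(statistic = w, p_value = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal")
}
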