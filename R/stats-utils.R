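#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test of observed genotype counts
#' against the HWE expectations p^2, 2pq, q^2 at the estimated allele
#' frequency.
#'
#' @param counts Length-3 nonnegative integer vector: homozygous-major,
#'   heterozygous, homozygous-minor counts.
#' @return List with `chisq`, `df` (1), `p`, and the estimated major-allele
#'   frequency `p_hat`.
#' @export
#' @examples
#' hwe_test(c(25, 50, 25)) # exact HWE proportions: chi-square 0
hwe_test <- function(counts) {
  if (length(counts) != 3 || any(counts < 0)) stop("need 3 counts >= 0")
  n <- sum(counts)
  if (n < 1) stop("all-zero counts")
  p_hat <- (2 * counts[1] + counts[2]) / (2 * n)
  expected <- n * c(p_hat^2, 2 * p_hat * (1 - p_hat), (1 - p_hat)^2)
  ok <- expected > 0
  chisq <- sum((counts[ok] - expected[ok])^2 / expected[ok])
  list(chisq = chisq, df = 1,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       p_hat = p_hat)
}

#' Genotype counts from a genotype column
#'
#' @param genotypes Character vector of unordered allele pairs (e.g. "AG").
#' @param risk_allele The allele whose dose orders the classes.
#' @return Length-3 counts: 2, 1, 0 copies of `risk_allele`.
#' @export
genotype_counts <- function(genotypes, risk_allele) {
  dose <- vapply(strsplit(genotypes, ""), function(a)
    sum(a == risk_allele), 1L)
  c(sum(dose == 2), sum(dose == 1), sum(dose == 0))
}

#' Bonferroni correction
#'
#' @param p A p-value in \[0, 1\].
#' @param m Number of tests (>= 1).
#' @return `min(1, m * p)`.
#' @export
#' @examples
#' bonferroni(0.005, 3)
bonferroni <- function(p, m) {
  if (any(p < 0) || any(p > 1)) stop("p must lie in [0, 1]")
  if (any(m < 1)) stop("m must be at least 1")
  pmin(1, m * p)
}

#' Pearson correlation with two-sided t-transform p
#'
#' @param x,y Numeric vectors of equal length >= 3, both non-constant.
#' @return List with `r`, `p` (two-sided, from
#'   `t = r * sqrt((n - 2) / (1 - r^2))` against t with n - 2 df), `n`.
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need equal-length vectors of length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  ct <- stats::cor.test(x, y, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' One-way repeated-measures ANOVA with partial eta squared
#'
#' Within-subject decomposition of a complete subjects x conditions table:
#' `F = MS_condition / MS_error` with df `(c - 1, (c - 1)(n - 1))` (no
#' sphericity correction), and
#' `partial eta^2 = SS_condition / (SS_condition + SS_error)`.
#'
#' @param data Numeric matrix or data frame, subjects in rows, conditions in
#'   columns, no missing cells.
#' @return An `anova_result` list: `F`, `df`, `p`, `eta_sq_partial`, and the
#'   sums of squares (`ss_condition`, `ss_subject`, `ss_error`, `ss_total`).
#' @export
rm_anova <- function(data) {
  data <- as.matrix(data)
  if (anyNA(data)) stop("missing cells")
  n <- nrow(data); c <- ncol(data)
  if (n < 2 || c < 2) stop("need >= 2 subjects and >= 2 conditions")
  grand <- mean(data)
  ss_total <- sum((data - grand)^2)
  ss_subject <- c * sum((rowMeans(data) - grand)^2)
  ss_condition <- n * sum((colMeans(data) - grand)^2)
  ss_error <- ss_total - ss_subject - ss_condition
  df1 <- c - 1; df2 <- (c - 1) * (n - 1)
  ms_err <- ss_error / df2
  Fv <- if (ms_err > 0) (ss_condition / df1) / ms_err else
    ifelse(ss_condition > 0, Inf, 0)
  structure(list(F = Fv, df = c(df1, df2),
                 p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
                 eta_sq_partial = if (ss_condition + ss_error > 0)
                   ss_condition / (ss_condition + ss_error) else 0,
                 ss_condition = ss_condition, ss_subject = ss_subject,
                 ss_error = ss_error, ss_total = ss_total),
            class = "anova_result")
}

#' Pairwise paired t-tests with Bonferroni correction
#'
#' All condition pairs of a subjects x conditions table, corrected by the
#' number of pairs.
#'
#' @inheritParams rm_anova
#' @return A tibble with `condition_1`, `condition_2`, `t`, `df`, `p`,
#'   `p_corrected` (Bonferroni, m = number of pairs).
#' @export
posthoc_bonferroni <- function(data) {
  data <- as.matrix(data)
  if (anyNA(data)) stop("missing cells")
  if (nrow(data) < 2 || ncol(data) < 2)
    stop("need >= 2 subjects and >= 2 conditions")
  cn <- colnames(data) %||% paste0("cond", seq_len(ncol(data)))
  pairs <- utils::combn(ncol(data), 2)
  m <- ncol(pairs)
  purrr::map_dfr(seq_len(m), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    d <- data[, a] - data[, b]
    if (stats::sd(d) == 0) {
      tv <- 0; p <- 1
    } else {
      tt <- stats::t.test(d)
      tv <- unname(tt$statistic); p <- tt$p.value
    }
    tibble::tibble(condition_1 = cn[a], condition_2 = cn[b], t = tv,
                   df = nrow(data) - 1, p = p,
                   p_corrected = bonferroni(p, m))
  })
}

#' Power of a two-sample t-test (noncentral t)
#'
#' @param n1,n2 Group sizes (>= 2).
#' @param d Cohen's d effect size.
#' @param alpha Two-sided significance level.
#' @return Achieved power.
#' @export
power_t_test2 <- function(n1, n2, d = 0.5, alpha = 0.05) {
  stopifnot(n1 >= 2, n2 >= 2)
  if (alpha <= 0 || alpha >= 1) stop("invalid alpha")
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  tc <- stats::qt(1 - alpha / 2, df)
  stats::pt(tc, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tc, df, ncp = ncp)
}

#' Power of a Pearson correlation test (Fisher z)
#'
#' @param n Sample size (>= 4).
#' @param r Population correlation under the alternative.
#' @param alpha Two-sided significance level.
#' @return Achieved power via the Fisher-z normal approximation.
#' @export
power_correlation <- function(n, r = 0.3, alpha = 0.05) {
  stopifnot(n >= 4)
  if (alpha <= 0 || alpha >= 1) stop("invalid alpha")
  za <- stats::qnorm(1 - alpha / 2)
  mu <- atanh(r) * sqrt(n - 3)
  stats::pnorm(-za + mu) + stats::pnorm(-za - mu)
}

#' Minimum power across the declared test families
#'
#' The sample-size justification of the emulated design: the minimum of the
#' Pearson-correlation power (medium effect r = 0.3, Fisher-z
#' approximation, full sample) and the independent-samples t-test power
#' (medium effect d = 0.5, noncentral t, the two demographic groups).
#'
#' @param n_total Total sample size.
#' @param group_sizes Length-2 group sizes for the t family (default the
#'   male/female split of `n_total`).
#' @param alpha Two-sided significance level.
#' @param r,d Medium-effect conventions (Cohen).
#' @return List with `power_correlation`, `power_t`, and `min_power`.
#' @export
#' @examples
#' min_power(255, c(131, 124))$min_power
min_power <- function(n_total, group_sizes = NULL, alpha = 0.05, r = 0.3,
                      d = 0.5) {
  if (alpha <= 0 || alpha >= 1) stop("invalid alpha")
  if (is.null(group_sizes))
    group_sizes <- c(ceiling(n_total / 2), floor(n_total / 2))
  stopifnot(all(group_sizes >= 2), n_total >= 4)
  pc <- power_correlation(n_total, r = r, alpha = alpha)
  pt2 <- power_t_test2(group_sizes[1], group_sizes[2], d = d, alpha = alpha)
  list(power_correlation = pc, power_t = pt2, min_power = min(pc, pt2))
}
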