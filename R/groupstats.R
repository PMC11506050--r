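#' One-tailed Wilcoxon rank-sum test (Expert > Novice)
#'
#' Thin wrapper over [stats::wilcox.test()]: exact enumeration when both
#' groups have at most 10 observations and no ties are present, otherwise the
#' normal approximation with tie and continuity corrections.
#'
#' @param expert_values,novice_values numeric samples (non-empty).
#' @return list with `statistic` (Mann-Whitney W) and `p_value` for the
#'   alternative "Expert stochastically larger".
#' @export
rank_sum_one_tailed <- function(expert_values, novice_values) {
  rank_sum(expert_values, novice_values, alternative = "greater")
}

rank_sum <- function(x, y, alternative) {
  if (length(x) < 1 || length(y) < 1)
    isa_stop("isa_insufficient_data", "both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 10 && length(y) <= 10 && !ties
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = alternative, exact = exact, correct = TRUE
  ))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Two-tailed rank-sum comparison of group ages
#'
#' @param expert_ages,novice_ages numeric age vectors.
#' @return list with `statistic` and two-sided `p_value`.
#' @export
age_comparison <- function(expert_ages, novice_ages) {
  rank_sum(expert_ages, novice_ages, alternative = "two.sided")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param p_values raw p-values between 0 and 1 (one per frequency band).
#' @return adjusted p-values (monotone, capped at 1).
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    isa_stop("isa_validation", "p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Cohen's d with pooled standard deviation
#'
#' `(mean(expert) - mean(novice)) / s_pooled`, with the pooled SD using
#' (n - 1) denominators.
#'
#' @param expert_values,novice_values numeric samples, each with >= 2 values.
#' @return standardized mean difference.
#' @export
cohens_d <- function(expert_values, novice_values) {
  n1 <- length(expert_values); n2 <- length(novice_values)
  if (n1 < 2 || n2 < 2)
    isa_stop("isa_insufficient_data", "each group needs at least 2 values")
  sp2 <- ((n1 - 1) * stats::var(expert_values) +
          (n2 - 1) * stats::var(novice_values)) / (n1 + n2 - 2)
  if (sp2 <= 0)
    isa_stop("isa_undefined_effect", "pooled standard deviation is zero")
  (mean(expert_values) - mean(novice_values)) / sqrt(sp2)
}

#' Pooled band-level group comparison of PSI
#'
#' Pools (participant x channel) PSI values per group within each band,
#' performs the one-tailed rank-sum test (Expert > Novice), corrects over
#' bands by Benjamini-Hochberg FDR, and reports Cohen's d.
#'
#' @param summaries [summarize_cohort()] output with a `group` column.
#' @return data.frame with columns band, statistic, p_raw, p_fdr, cohens_d,
#'   n_expert, n_novice.
#' @export
band_comparison <- function(summaries) {
  bands <- sort(unique(summaries$band))
  rows <- lapply(bands, function(b) {
    e <- summaries$psi[summaries$band == b & summaries$group == "Expert"]
    n <- summaries$psi[summaries$band == b & summaries$group == "Novice"]
    rs <- rank_sum_one_tailed(e, n)
    data.frame(band = b, statistic = rs$statistic, p_raw = rs$p_value,
               cohens_d = cohens_d(e, n),
               n_expert = length(e), n_novice = length(n))
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- bh_fdr(out$p_raw)
  out[, c("band", "statistic", "p_raw", "p_fdr", "cohens_d",
          "n_expert", "n_novice")]
}

#' Channel-wise group comparison within one band
#'
#' One-tailed rank-sum test (Expert > Novice) and Cohen's d per channel, plus
#' the reverse-direction p-value and the fraction of channels significant in
#' the hypothesized direction.
#'
#' @param summaries [summarize_cohort()] output.
#' @param band band label to analyse.
#' @param alpha per-channel significance level (default 0.05).
#' @return list with `table` (channel, p, p_reverse, cohens_d, significant),
#'   `frac_significant`, `frac_significant_reverse`, `band`.
#' @export
channelwise_comparison <- function(summaries, band, alpha = 0.05) {
  sub <- summaries[summaries$band == band, ]
  if (nrow(sub) == 0)
    isa_stop("isa_config", "band %s not present in summaries", format(band))
  chans <- sort(unique(sub$channel))
  rows <- lapply(chans, function(ch) {
    e <- sub$psi[sub$channel == ch & sub$group == "Expert"]
    n <- sub$psi[sub$channel == ch & sub$group == "Novice"]
    p <- rank_sum_one_tailed(e, n)$p_value
    p_rev <- rank_sum(n, e, alternative = "greater")$p_value
    data.frame(channel = ch, p = p, p_reverse = p_rev,
               cohens_d = cohens_d(e, n), significant = p < alpha)
  })
  tab <- do.call(rbind, rows)
  list(table = tab,
       frac_significant = mean(tab$significant),
       frac_significant_reverse = mean(tab$p_reverse < alpha),
       band = band)
}

#' Demographic participant filter
#'
#' Retains males of any age and females aged at most `max_female_age` (the
#' gender-balance / perimenopause exclusion rule: females older than 38 are
#' removed by default).
#'
#' @param participants data.frame with columns `sex` ("F"/"M") and `age`.
#' @param max_female_age oldest retained female age (default 38).
#' @param n_channels optional channel count used to report pooled sample
#'   sizes.
#' @return the filtered data.frame, with attributes `n_remaining` (named
#'   per-group counts) and, when `n_channels` is given, `pooled_n`
#'   (n_remaining x n_channels).
#' @export
participant_filter <- function(participants, max_female_age = 38,
                               n_channels = NULL) {
  if (is.null(participants$sex) || is.null(participants$age) ||
      any(is.na(participants$sex)) || any(is.na(participants$age)))
    isa_stop("isa_metadata", "participants need complete sex and age metadata")
  keep <- participants$sex == "M" | participants$age <= max_female_age
  out <- participants[keep, , drop = FALSE]
  grp <- if (!is.null(out$group)) out$group else rep("all", nrow(out))
  n_remaining <- table(factor(grp))
  attr(out, "n_remaining") <- c(n_remaining)
  if (!is.null(n_channels)) attr(out, "pooled_n") <- c(n_remaining) * n_channels
  out
}
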