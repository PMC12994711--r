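# Enrichment and group-comparison statistics for the IDR layer.

#' Length-weighted binomial enrichment of sites in IDRs
#'
#' Exact binomial test of whether selected sites fall inside IDRs more
#' often than their length share predicts: successes are the sites inside
#' IDRs (`k_in_idr`), trials the total selected sites (`m_total`), and the
#' success probability the ratio of total IDR length to the total analyzed
#' length. The default alternative is one-sided enrichment (`"greater"`).
#'
#' @param k_in_idr Number of selected sites inside IDRs.
#' @param m_total Total number of selected sites.
#' @param idr_length_total Summed IDR length in residues.
#' @param analyzed_length_total Summed length of all analyzed regions.
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @return Object of class `selscape_enrichment` (see
#'   [tidy.selscape_enrichment()]).
#' @export
binomial_enrichment <- function(k_in_idr, m_total, idr_length_total,
                                analyzed_length_total,
                                alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (k_in_idr < 0 || m_total < 0 || k_in_idr > m_total) {
    stop_domain("need 0 <= k_in_idr <= m_total")
  }
  p0 <- idr_length_total / analyzed_length_total
  if (!is.finite(p0) || p0 <= 0 || p0 >= 1) {
    stop_domain("idr_length_total / analyzed_length_total must lie strictly between 0 and 1")
  }
  if (m_total == 0) stop_domain("no selected sites to test (m_total = 0)")
  ht <- stats::binom.test(k_in_idr, m_total, p = p0, alternative = alternative)
  structure(
    list(
      k = as.integer(k_in_idr), m = as.integer(m_total), p0 = p0,
      estimate = k_in_idr / m_total,
      p_value = ht$p.value,
      alternative = alternative,
      htest = ht
    ),
    class = "selscape_enrichment"
  )
}

#' @export
print.selscape_enrichment <- function(x, ...) {
  cat("<selscape_enrichment>\n")
  cat(sprintf(
    "  %d of %d sites in IDRs (%.3f observed vs %.3f expected); binomial p = %.4g (%s)\n",
    x$k, x$m, x$estimate, x$p0, x$p_value, x$alternative
  ))
  invisible(x)
}

#' Compare an IDR feature between selected and non-selected IDRs
#'
#' Two-sided Wilcoxon rank-sum test (with tie correction) of a feature
#' between IDRs that carry at least one consensus positively selected site
#' and those that carry none. Exact enumeration is used when both groups
#' have at most 20 observations and no ties are present; otherwise the
#' normal approximation with continuity correction.
#'
#' @param selected Numeric feature values of the selected IDRs.
#' @param non_selected Numeric feature values of the non-selected IDRs.
#' @param feature Optional feature name recorded in the output.
#' @return One-row tibble: `feature`, `n_selected`, `n_non_selected`,
#'   `median_selected`, `median_non_selected`, `statistic`, `p_value`.
#' @export
compare_groups <- function(selected, non_selected, feature = NA_character_) {
  selected <- selected[!is.na(selected)]
  non_selected <- non_selected[!is.na(non_selected)]
  if (length(selected) == 0 || length(non_selected) == 0) {
    abort("both groups must be non-empty", class = "selscape_grouping_error")
  }
  has_ties <- anyDuplicated(c(selected, non_selected)) > 0
  use_exact <- !has_ties &&
    max(length(selected), length(non_selected)) <= 20
  wt <- suppressWarnings(stats::wilcox.test(
    selected, non_selected,
    alternative = "two.sided", exact = use_exact, correct = TRUE
  ))
  tibble(
    feature = feature,
    n_selected = length(selected),
    n_non_selected = length(non_selected),
    median_selected = median(selected),
    median_non_selected = median(non_selected),
    statistic = unname(wt$statistic),
    p_value = min(wt$p.value, 1)
  )
}

#' Kendall correlation between selective constraint and an IDR feature
#'
#' Kendall's tau-b (tie-corrected) between the per-IDR fraction of
#' negatively selected sites and a per-IDR feature, with the exact
#' permutation p-value for 8 or fewer (tie-free) pairs and the normal
#' approximation otherwise.
#'
#' @param fraction_negative Numeric vector (per-IDR constraint measure).
#' @param feature Numeric vector, same length.
#' @return One-row tibble: `n`, `tau`, `p_value`.
#' @export
constraint_feature_correlation <- function(fraction_negative, feature) {
  if (length(fraction_negative) != length(feature)) {
    abort("paired vectors must have equal length",
      class = "selscape_schema_error")
  }
  ok <- !is.na(fraction_negative) & !is.na(feature)
  x <- fraction_negative[ok]
  y <- feature[ok]
  if (length(x) < 3) stop_domain("need at least 3 complete pairs")
  has_ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  ct <- suppressWarnings(stats::cor.test(
    x, y,
    method = "kendall",
    exact = !has_ties && length(x) <= 8
  ))
  tibble(n = length(x), tau = unname(ct$estimate), p_value = ct$p.value)
}

#' Pearson correlation between two disorder-fraction annotations
#'
#' Used to compare per-protein disordered fractions from two annotation
#' sources. Returns a missing correlation when either vector has zero
#' variance.
#'
#' @param fractions_a,fractions_b Paired numeric vectors of per-protein
#'   disorder fractions.
#' @return One-row tibble: `n`, `r`, `p_value` (`NA` when undefined).
#' @export
disorder_fraction_correlation <- function(fractions_a, fractions_b) {
  if (length(fractions_a) != length(fractions_b)) {
    abort("paired vectors must have equal length",
      class = "selscape_schema_error")
  }
  ok <- !is.na(fractions_a) & !is.na(fractions_b)
  a <- fractions_a[ok]
  b <- fractions_b[ok]
  if (length(a) < 3) stop_domain("need at least 3 complete pairs")
  if (sd(a) == 0 || sd(b) == 0) {
    warn("zero variance in a disorder-fraction vector; correlation undefined")
    return(tibble(n = length(a), r = NA_real_, p_value = NA_real_))
  }
  ct <- stats::cor.test(a, b, method = "pearson")
  tibble(n = length(a), r = unname(ct$estimate), p_value = ct$p.value)
}
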