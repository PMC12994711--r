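# broom-style tidiers for the package's result objects

#' Tidy the resampled background comparison
#'
#' One row per resampling iteration, with the Wilcoxon p-value and the
#' direction of the candidate-vs-background median difference.
#'
#' @param x A `selscape_resample` object from [pi_background_comparison()].
#' @param ... Unused.
#' @return Tibble with `iteration`, `p_value`, `candidate_median`,
#'   `background_median`, `direction`.
#' @export
tidy.selscape_resample <- function(x, ...) {
  x$iterations
}

#' One-row summary of the resampled background comparison
#'
#' @inheritParams tidy.selscape_resample
#' @return Tibble with `n_candidates`, `n_background`, `iterations`,
#'   `median_p`, `frac_lower` (fraction of iterations with the candidate
#'   median below the background median), `candidate_median` and
#'   `pooled_p` (candidates vs the whole background).
#' @export
glance.selscape_resample <- function(x, ...) {
  tibble(
    n_candidates = x$n_candidates,
    n_background = x$n_background,
    iterations = nrow(x$iterations),
    median_p = median(x$iterations$p_value),
    frac_lower = mean(x$iterations$direction == "lower"),
    candidate_median = x$iterations$candidate_median[1],
    pooled_p = x$pooled_p
  )
}

#' Tidy the IDR enrichment test
#'
#' @param x A `selscape_enrichment` object from [binomial_enrichment()].
#' @param ... Unused.
#' @return One-row tibble with `k`, `m`, `estimate` (observed in-IDR
#'   fraction), `p0` (expected fraction), `p_value`, `alternative`.
#' @export
tidy.selscape_enrichment <- function(x, ...) {
  tibble(
    k = x$k, m = x$m, estimate = x$estimate, p0 = x$p0,
    p_value = x$p_value, alternative = x$alternative
  )
}

#' @rdname tidy.selscape_enrichment
#' @export
glance.selscape_enrichment <- function(x, ...) {
  tidy(x)
}
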