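#' Polarized window of segregating sites
#'
#' Container for the unfolded site-frequency data of one genomic window in
#' one population: the haplotype sample size `n` and one derived-allele
#' count per segregating site (each strictly between 0 and `n`, since
#' monomorphic sites carry no information). All window statistics in the
#' package are functions of this object alone.
#'
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open window coordinates.
#' @param n Haplotype sample size (>= 2).
#' @param derived_counts Integer vector of derived-allele counts, one per
#'   segregating site.
#' @param positions Optional 1-based genomic positions, one per site.
#' @param haplotypes Optional 0/1 matrix (`n` rows, `S` columns).
#' @return An object of class `polarized_window`.
#' @export
polarized_window <- function(chrom, start, end, n, derived_counts,
                             positions = NULL, haplotypes = NULL) {
  if (end <= start) stop_domain("window end must exceed start")
  if (n < 2) stop_domain("n must be >= 2")
  derived_counts <- as.integer(derived_counts)
  if (length(derived_counts) > 0 &&
      (any(derived_counts <= 0L) || any(derived_counts >= n))) {
    stop_domain("derived counts must lie strictly between 0 and n")
  }
  structure(
    list(
      chrom = chrom, start = as.numeric(start), end = as.numeric(end),
      n = as.integer(n),
      derived_counts = derived_counts,
      S = length(derived_counts),
      positions = positions,
      haplotypes = haplotypes
    ),
    class = "polarized_window"
  )
}

#' @export
print.polarized_window <- function(x, ...) {
  cat(sprintf(
    "<polarized_window> %s:%s-%s  n = %d haplotypes, S = %d segregating sites\n",
    x$chrom, format(x$start, scientific = FALSE),
    format(x$end, scientific = FALSE), x$n, x$S
  ))
  invisible(x)
}

window_counts <- function(window) {
  if (inherits(window, "polarized_window")) {
    list(x = window$derived_counts, n = window$n)
  } else if (is.list(window) && all(c("derived_counts", "n") %in% names(window))) {
    list(x = as.integer(window$derived_counts), n = as.integer(window$n))
  } else {
    stop_domain("expected a polarized_window (or list with derived_counts and n)")
  }
}

check_counts <- function(x, n) {
  if (n < 2) stop_domain("n must be >= 2")
  if (length(x) > 0 && (any(x <= 0) || any(x >= n))) {
    stop_domain("derived counts must lie strictly between 0 and n")
  }
  invisible(TRUE)
}

#' Tajima's normalization constants
#'
#' The usual sample-size constants a1, a2, b1, b2, c1, c2, e1, e2 used to
#' normalize the difference between the pairwise and Watterson estimators of
#' theta.
#'
#' @param n Haplotype sample size (>= 2).
#' @return Named list with elements `a1, a2, b1, b2, c1, c2, e1, e2`.
#' @export
tajima_constants <- function(n) {
  if (n < 2) stop_domain("n must be >= 2")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' Nucleotide diversity of a window
#'
#' The average pairwise difference summed over sites:
#' \eqn{\pi = \sum_i 2 x_i (n - x_i) / (n (n - 1))}, equal to the mean
#' Hamming distance over all haplotype pairs. Summed per window, not per bp;
#' see [compute_window_stats()] for per-bp variants.
#'
#' @param window A [polarized_window()].
#' @return Non-negative number.
#' @export
window_pi <- function(window) {
  w <- window_counts(window)
  check_counts(w$x, w$n)
  sum(2 * w$x * (w$n - w$x)) / (w$n * (w$n - 1))
}

#' Watterson's theta
#'
#' \eqn{\theta_W = S / a_1(n)} with \eqn{a_1 = \sum_{i=1}^{n-1} 1/i}.
#'
#' @param S Number of segregating sites.
#' @param n Haplotype sample size (>= 2).
#' @return Non-negative number.
#' @export
theta_watterson <- function(S, n) {
  if (n < 2) stop_domain("n must be >= 2")
  if (S < 0) stop_domain("S must be >= 0")
  S / tajima_constants(n)$a1
}

#' Fay & Wu's theta-H
#'
#' The high-frequency-weighted estimator
#' \eqn{\theta_H = \sum_i 2 x_i^2 / (n (n - 1))}, which up-weights
#' high-frequency derived alleles and therefore reacts strongly to
#' hitch-hiking.
#'
#' @param window A [polarized_window()].
#' @return Non-negative number.
#' @export
theta_fay_wu <- function(window) {
  w <- window_counts(window)
  check_counts(w$x, w$n)
  sum(2 * w$x^2) / (w$n * (w$n - 1))
}

#' Tajima's D of a window
#'
#' \eqn{D = (\pi - \theta_W) / \sqrt{e_1 S + e_2 S (S - 1)}}. Undefined
#' (returned as `NA`) when `S = 0` or when the variance term vanishes
#' (which includes every sample of fewer than 4 haplotypes); an undefined D
#' is propagated as missing, never coerced to 0, so empty windows drop out
#' of downstream ranking.
#'
#' @param window A [polarized_window()].
#' @return A number, or `NA_real_` when undefined.
#' @export
tajimas_d <- function(window) {
  w <- window_counts(window)
  check_counts(w$x, w$n)
  S <- length(w$x)
  if (S == 0) {
    return(NA_real_)
  }
  k <- tajima_constants(w$n)
  denom <- sqrt(k$e1 * S + k$e2 * S * (S - 1))
  if (!is.finite(denom) || denom <= 0) {
    return(NA_real_)
  }
  (window_pi(window) - S / k$a1) / denom
}

#' Fay & Wu's H of a window (unnormalized)
#'
#' \eqn{H = \pi - \theta_H}. Strongly negative values indicate an excess of
#' high-frequency derived alleles, a hallmark of recent positive selection.
#' The unnormalized form is used; the rank-based scan is invariant to any
#' monotone per-population normalization.
#'
#' @param window A [polarized_window()].
#' @return A number, or `NA_real_` when `S = 0`.
#' @export
fay_wu_h <- function(window) {
  w <- window_counts(window)
  check_counts(w$x, w$n)
  if (length(w$x) == 0) {
    return(NA_real_)
  }
  window_pi(window) - theta_fay_wu(window)
}

#' Compute all window statistics for a table of windows
#'
#' Takes a window table (one row per window, with a list-column of derived
#' counts, as produced by [windows_from_vcf()] or [windows_from_simulation()])
#' and appends pi, Watterson's theta, theta-H, Tajima's D and Fay & Wu's H,
#' plus per-bp variants of the three theta-scale statistics.
#'
#' @param windows Tibble with columns `chrom`, `start`, `end`, `n`, and
#'   list-column `derived_counts`.
#' @return The input tibble with columns `S`, `pi`, `theta_w`, `theta_h`,
#'   `tajimas_d`, `fay_wu_h`, `pi_per_bp`, `theta_w_per_bp`,
#'   `theta_h_per_bp` appended.
#' @export
compute_window_stats <- function(windows) {
  assert_columns(windows, c("chrom", "start", "end", "n", "derived_counts"),
    "window table")
  stats <- purrr::pmap(
    list(windows$derived_counts, windows$n, windows$start, windows$end),
    function(x, n, start, end) {
      w <- list(derived_counts = as.integer(x), n = n)
      len <- end - start
      pi <- window_pi(w)
      th <- theta_fay_wu(w)
      tw <- theta_watterson(length(x), n)
      tibble(
        S = length(x), pi = pi, theta_w = tw, theta_h = th,
        tajimas_d = tajimas_d(w), fay_wu_h = fay_wu_h(w),
        pi_per_bp = pi / len, theta_w_per_bp = tw / len,
        theta_h_per_bp = th / len
      )
    }
  )
  dplyr::bind_cols(windows, dplyr::bind_rows(stats))
}

#' Turn simulated windows into a window-statistics table
#'
#' Convenience wrapper: converts a list of [polarized_window()] objects
#' (e.g. from [simulate_chromosome()]) to the tidy window table and computes
#' all statistics.
#'
#' @param windows List of `polarized_window` objects.
#' @return Tibble as returned by [compute_window_stats()].
#' @export
windows_from_simulation <- function(windows) {
  tbl <- purrr::map_dfr(windows, function(w) {
    tibble(
      chrom = w$chrom, start = w$start, end = w$end, n = w$n,
      derived_counts = list(w$derived_counts)
    )
  })
  compute_window_stats(tbl)
}
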