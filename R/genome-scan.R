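#' Configuration for the multi-population outlier scan
#'
#' @param tail_quantile Fraction of the ranked windows counted as the
#'   extreme low tail (default 0.05).
#' @param concurrence_min_populations Minimum number of populations in
#'   which a gene must be extreme, for every statistic, to be a concurrent
#'   hit (default 10).
#' @param resample_iterations Number of background-resampling iterations
#'   for the nucleotide-diversity comparison (default 1000).
#' @param statistics Character vector of statistics to scan; subset of
#'   `c("tajimas_d", "fay_wu_h")`.
#' @param tail_unit Whether the 5% tail is defined over ranked windows
#'   (`"windows"`, default) or over genes' minimum ranks (`"genes"`). The
#'   window-level tail tags a gene as extreme when its best window falls in
#'   the window-level tail; the gene-level alternative takes the lowest
#'   `tail_quantile` fraction of genes instead.
#' @param seed Integer seed for the resampling.
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(tail_quantile = 0.05,
                        concurrence_min_populations = 10L,
                        resample_iterations = 1000L,
                        statistics = c("tajimas_d", "fay_wu_h"),
                        tail_unit = c("windows", "genes"),
                        seed = 1L) {
  if (tail_quantile <= 0 || tail_quantile >= 1) {
    stop_bad_config("tail_quantile must lie strictly between 0 and 1")
  }
  if (concurrence_min_populations < 1) {
    stop_bad_config("concurrence_min_populations must be >= 1")
  }
  if (resample_iterations < 1) {
    stop_bad_config("resample_iterations must be >= 1")
  }
  statistics <- match.arg(statistics, c("tajimas_d", "fay_wu_h"),
    several.ok = TRUE)
  structure(
    list(
      tail_quantile = tail_quantile,
      concurrence_min_populations = as.integer(concurrence_min_populations),
      resample_iterations = as.integer(resample_iterations),
      statistics = statistics,
      tail_unit = match.arg(tail_unit),
      seed = as.integer(seed)
    ),
    class = "scan_config"
  )
}

#' Rank windows by a statistic within each population
#'
#' Ascending ranks: rank 1 is the lowest (most extreme, for the low tail of
#' Tajima's D and Fay & Wu's H) value. Windows with a missing statistic are
#' excluded before ranking and receive `NA`. Ties receive the minimum of
#' the tied rank range.
#'
#' @param stats Window-statistics tibble (see [compute_window_stats()]),
#'   optionally with a `population` column; without one, a single
#'   population is assumed.
#' @param statistic Name of the statistic column to rank.
#' @return The input with columns `rank` and `n_ranked` (count of non-missing
#'   windows in that population) appended.
#' @export
rank_windows <- function(stats, statistic) {
  assert_columns(stats, statistic, "window-statistics table")
  if (!"population" %in% names(stats)) {
    stats <- dplyr::mutate(stats, population = "pop01")
  }
  stats |>
    dplyr::group_by(.data$population) |>
    dplyr::mutate(
      rank = {
        v <- .data[[statistic]]
        r <- rep(NA_integer_, length(v))
        ok <- !is.na(v)
        r[ok] <- rank(v[ok], ties.method = "min")
        as.integer(r)
      },
      n_ranked = sum(!is.na(.data[[statistic]]))
    ) |>
    dplyr::ungroup()
}

#' Assign each gene its minimum window rank
#'
#' A gene's rank for a statistic, in a population, is the minimum rank over
#' all windows overlapping its interval by at least one bp. Genes
#' overlapping no ranked window are reported with a missing rank and are
#' excluded from tail tagging.
#'
#' @param ranked Output of [rank_windows()].
#' @param genes Gene tibble (`chrom`, `start`, `end`, `gene_id`), 0-based
#'   half-open, same chromosome naming as the windows.
#' @param statistic Statistic name recorded in the output.
#' @return Tibble with `gene_id`, `population`, `statistic`, `min_rank`,
#'   `n_ranked`.
#' @export
min_rank_per_gene <- function(ranked, genes, statistic = "statistic") {
  assert_columns(ranked, c("chrom", "start", "end", "population", "rank",
    "n_ranked"), "ranked window table")
  assert_columns(genes, c("chrom", "start", "end", "gene_id"), "gene table")
  if (nrow(genes) == 0) {
    return(tibble(
      gene_id = character(), population = character(),
      statistic = character(), min_rank = integer(), n_ranked = integer()
    ))
  }
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(start = genes$start + 1, end = genes$end)
  )
  purrr::map_dfr(split(ranked, ranked$population), function(win) {
    keep <- !is.na(win$rank)
    nr <- if (nrow(win) > 0) win$n_ranked[1] else 0L
    res <- tibble(
      gene_id = genes$gene_id,
      population = if (nrow(win) > 0) win$population[1] else NA_character_,
      statistic = statistic,
      min_rank = NA_integer_,
      n_ranked = nr
    )
    if (any(keep)) {
      w <- win[keep, ]
      win_gr <- GenomicRanges::GRanges(
        w$chrom, IRanges::IRanges(start = w$start + 1, end = w$end)
      )
      hits <- GenomicRanges::findOverlaps(gene_gr, win_gr)
      if (length(hits) > 0) {
        mr <- tapply(
          w$rank[S4Vectors::subjectHits(hits)],
          S4Vectors::queryHits(hits),
          min
        )
        res$min_rank[as.integer(names(mr))] <- as.integer(mr)
      }
    }
    res
  })
}

#' Tag genes in the extreme low tail
#'
#' Flags each gene whose minimum rank falls within the lowest
#' `tail_quantile` of the ranked windows of its population (inclusive
#' boundary: `min_rank <= ceiling(q * n_ranked)`). With
#' `tail_unit = "genes"` the quantile is taken over the genes' minimum
#' ranks within each population instead.
#'
#' @param gene_ranks Output of [min_rank_per_gene()].
#' @param config A [scan_config()].
#' @return `gene_ranks` with logical column `is_extreme` appended (`FALSE`
#'   for genes with a missing rank).
#' @export
tag_extreme <- function(gene_ranks, config = scan_config()) {
  assert_columns(gene_ranks, c("gene_id", "population", "statistic",
    "min_rank", "n_ranked"), "gene-rank table")
  q <- config$tail_quantile
  if (config$tail_unit == "windows") {
    dplyr::mutate(gene_ranks,
      is_extreme = !is.na(.data$min_rank) &
        .data$min_rank <= ceiling(q * .data$n_ranked)
    )
  } else {
    gene_ranks |>
      dplyr::group_by(.data$population, .data$statistic) |>
      dplyr::mutate(
        is_extreme = {
          ok <- !is.na(.data$min_rank)
          thr <- ceiling(q * sum(ok))
          gr <- rep(NA_integer_, dplyr::n())
          gr[ok] <- rank(.data$min_rank[ok], ties.method = "min")
          !is.na(gr) & gr <= thr
        }
      ) |>
      dplyr::ungroup()
  }
}

#' Count cross-population concurrence and call hits
#'
#' For each gene and statistic, counts the populations in which the gene is
#' tagged extreme; a gene is a concurrent hit iff its count reaches
#' `concurrence_min_populations` for every statistic in
#' `config$statistics`.
#'
#' @param tagged Output of [tag_extreme()], covering every population for
#'   every statistic in `config$statistics` (the population set must be
#'   identical across statistics).
#' @param config A [scan_config()].
#' @return Tibble with `gene_id`, one `count_<statistic>` column per
#'   statistic, and logical `concurrent_hit`.
#' @export
concurrence <- function(tagged, config = scan_config()) {
  assert_columns(tagged, c("gene_id", "population", "statistic",
    "is_extreme"), "tagged gene table")
  stats_present <- sort(unique(tagged$statistic))
  wanted <- sort(config$statistics)
  if (!setequal(stats_present, wanted)) {
    abort(
      sprintf(
        "tagged table covers statistics {%s} but config requests {%s}",
        paste(stats_present, collapse = ", "),
        paste(wanted, collapse = ", ")
      ),
      class = "selscape_consistency_error"
    )
  }
  pops_by_stat <- tapply(tagged$population, tagged$statistic,
    function(p) sort(unique(p)), simplify = FALSE)
  ref_pops <- pops_by_stat[[1]]
  same <- purrr::map_lgl(pops_by_stat, identical, y = ref_pops)
  if (!all(same)) {
    abort("population sets differ across statistics",
      class = "selscape_consistency_error")
  }
  counts <- tagged |>
    dplyr::group_by(.data$gene_id, .data$statistic) |>
    dplyr::summarise(count = sum(.data$is_extreme), .groups = "drop") |>
    tidyr::pivot_wider(
      names_from = "statistic", values_from = "count",
      names_prefix = "count_", values_fill = 0L
    )
  count_cols <- paste0("count_", config$statistics)
  counts$concurrent_hit <- purrr::reduce(
    purrr::map(count_cols, function(cc) {
      counts[[cc]] >= config$concurrence_min_populations
    }),
    `&`
  )
  dplyr::arrange(counts, dplyr::desc(.data$concurrent_hit), .data$gene_id)
}

#' Run the full multi-population concurrence scan
#'
#' Convenience wrapper over [rank_windows()], [min_rank_per_gene()],
#' [tag_extreme()] and [concurrence()] for a long window-statistics table
#' covering all populations.
#'
#' @param stats Window-statistics tibble with a `population` column.
#' @param genes Gene tibble (`chrom`, `start`, `end`, `gene_id`).
#' @param config A [scan_config()].
#' @return List with `gene_ranks` (per population, statistic) and
#'   `concurrence` (per gene).
#' @export
run_scan <- function(stats, genes, config = scan_config()) {
  tagged <- purrr::map_dfr(config$statistics, function(st) {
    stats |>
      rank_windows(st) |>
      min_rank_per_gene(genes, statistic = st) |>
      tag_extreme(config)
  })
  list(gene_ranks = tagged, concurrence = concurrence(tagged, config))
}

#' Resampled background comparison of gene-level nucleotide diversity
#'
#' Compares the per-gene nucleotide diversity of candidate genes against
#' equal-size random subsets of the background genes. A gene's diversity is
#' the median per-bp pi over the windows overlapping it. For each of
#' `config$resample_iterations` iterations a background subset of size
#' equal to the candidate set is drawn without replacement and a two-sided
#' Wilcoxon rank-sum test is recorded, together with the direction of the
#' median difference. No single-number aggregation of the iterations is
#' imposed: the object keeps the full p-value vector and additionally a
#' pooled test of candidates against the entire background.
#'
#' @param stats Window-statistics table for one population (or pooled), with
#'   a `pi_per_bp` column.
#' @param genes Gene tibble; `candidates` must be a subset of its
#'   `gene_id`s.
#' @param candidates Character vector of candidate gene ids.
#' @param config A [scan_config()] (uses `resample_iterations` and `seed`).
#' @return Object of class `selscape_resample`; see [tidy.selscape_resample()]
#'   and [glance.selscape_resample()].
#' @export
pi_background_comparison <- function(stats, genes, candidates,
                                     config = scan_config()) {
  assert_columns(stats, c("chrom", "start", "end", "pi_per_bp"),
    "window-statistics table")
  assert_columns(genes, c("chrom", "start", "end", "gene_id"), "gene table")
  gene_pi <- gene_median_pi(stats, genes)
  gene_pi <- gene_pi[!is.na(gene_pi$median_pi_per_bp), ]
  cand <- gene_pi$median_pi_per_bp[gene_pi$gene_id %in% candidates]
  bg <- gene_pi$median_pi_per_bp[!(gene_pi$gene_id %in% candidates)]
  if (length(cand) == 0) stop_domain("no candidate gene has a defined pi")
  if (length(bg) < length(cand)) {
    abort("background smaller than the candidate set; cannot subsample",
      class = "selscape_sampling_error")
  }
  iters <- with_seed(derive_seed(config$seed, 7L), {
    purrr::map_dfr(seq_len(config$resample_iterations), function(b) {
      sub <- sample(bg, length(cand), replace = FALSE)
      wt <- suppressWarnings(
        stats::wilcox.test(cand, sub, alternative = "two.sided")
      )
      tibble(
        iteration = b,
        p_value = wt$p.value,
        candidate_median = median(cand),
        background_median = median(sub),
        direction = dplyr::case_when(
          median(cand) < median(sub) ~ "lower",
          median(cand) > median(sub) ~ "higher",
          TRUE ~ "equal"
        )
      )
    })
  })
  pooled <- suppressWarnings(
    stats::wilcox.test(cand, bg, alternative = "two.sided")
  )
  structure(
    list(
      iterations = iters,
      pooled_p = pooled$p.value,
      n_candidates = length(cand),
      n_background = length(bg),
      gene_pi = gene_pi,
      candidates = sort(intersect(candidates, gene_pi$gene_id)),
      config = config
    ),
    class = "selscape_resample"
  )
}

# median per-bp pi over the windows overlapping each gene
gene_median_pi <- function(stats, genes) {
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(start = genes$start + 1, end = genes$end)
  )
  win_gr <- GenomicRanges::GRanges(
    stats$chrom, IRanges::IRanges(start = stats$start + 1, end = stats$end)
  )
  hits <- GenomicRanges::findOverlaps(gene_gr, win_gr)
  med <- tapply(
    stats$pi_per_bp[S4Vectors::subjectHits(hits)],
    S4Vectors::queryHits(hits),
    median
  )
  out <- tibble(gene_id = genes$gene_id, median_pi_per_bp = NA_real_)
  out$median_pi_per_bp[as.integer(names(med))] <- as.numeric(med)
  out
}

#' @export
print.selscape_resample <- function(x, ...) {
  g <- glance(x)
  cat("<selscape_resample>\n")
  cat(sprintf("  %d candidate genes vs %d background genes, %d iterations\n",
    x$n_candidates, x$n_background, nrow(x$iterations)))
  cat(sprintf("  median resampled p = %.4g; fraction candidate-lower = %.3f\n",
    g$median_p, g$frac_lower))
  cat(sprintf("  pooled Wilcoxon p (candidates vs all background) = %.4g\n",
    g$pooled_p))
  invisible(x)
}
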