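# Rank/concurrence scan: ranking rules, gene assignment, tail tagging,
# the cross-population AND rule, and the resampled pi comparison.

mk_stats <- function(values, population = "pop01", start = NULL) {
  n <- length(values)
  start <- start %||% seq(0, by = 50000, length.out = n)
  tibble::tibble(
    chrom = "chr1", start = start, end = start + 50000, n = 20,
    S = 10, tajimas_d = values, fay_wu_h = values,
    pi_per_bp = abs(values) + 1e-4, population = population
  )
}

test_that("rank_windows ranks ascending with min ties and skips missing values", {
  r <- rank_windows(mk_stats(c(-2.1, 0.3, -0.5)), "tajimas_d")
  expect_equal(r$rank, c(1L, 3L, 2L))
  expect_equal(r$n_ranked[1], 3L)

  r2 <- rank_windows(mk_stats(c(-1, -1, 0)), "tajimas_d")
  expect_equal(r2$rank, c(1L, 1L, 3L))

  # adding a constant leaves ranks unchanged
  v <- c(0.7, -3, 1.2, 0.1)
  expect_equal(
    rank_windows(mk_stats(v), "tajimas_d")$rank,
    rank_windows(mk_stats(v + 5), "tajimas_d")$rank
  )

  r3 <- rank_windows(mk_stats(c(-1, NA, 0)), "tajimas_d")
  expect_equal(r3$rank, c(1L, NA, 2L))
  expect_equal(r3$n_ranked[1], 2L)

  expect_error(rank_windows(mk_stats(1), "nope"), class = "selscape_schema_error")
})

test_that("a gene's rank is the minimum over overlapping windows", {
  st <- rank_windows(mk_stats(c(0.5, -1, 2, -3, 1)), "tajimas_d")
  # ranks: 3, 2, 5, 1, 4 at starts 0, 50k, 100k, 150k, 200k
  genes <- tibble::tibble(
    chrom = "chr1",
    start = c(60000, 40000, 260000),
    end = c(70000, 160000, 280000),
    gene_id = c("inside_one", "spans_three", "no_window")
  )
  mr <- min_rank_per_gene(st, genes, "tajimas_d")
  expect_equal(mr$min_rank[mr$gene_id == "inside_one"], 2L)
  expect_equal(mr$min_rank[mr$gene_id == "spans_three"], 1L)
  expect_true(is.na(mr$min_rank[mr$gene_id == "no_window"]))

  # empty gene set is an empty table, not an error
  empty <- min_rank_per_gene(st, genes[0, ], "tajimas_d")
  expect_equal(nrow(empty), 0)
})

test_that("extreme tagging uses an inclusive ceiling threshold", {
  gr <- tibble::tibble(
    gene_id = c("a", "b", "c"), population = "pop01",
    statistic = "tajimas_d",
    min_rank = c(50L, 51L, NA), n_ranked = 1000L
  )
  tagged <- tag_extreme(gr, scan_config(tail_quantile = 0.05))
  expect_equal(tagged$is_extreme, c(TRUE, FALSE, FALSE))
  expect_error(scan_config(tail_quantile = 1.0), class = "selscape_config_error")
  expect_error(scan_config(tail_quantile = 0), class = "selscape_config_error")
})

test_that("concurrence applies the AND rule across statistics", {
  mk_tagged <- function(gene, stat, n_extreme, n_pops = 12) {
    tibble::tibble(
      gene_id = gene, population = sprintf("pop%02d", 1:n_pops),
      statistic = stat,
      min_rank = 1L, n_ranked = 100L,
      is_extreme = c(rep(TRUE, n_extreme), rep(FALSE, n_pops - n_extreme))
    )
  }
  tagged <- dplyr::bind_rows(
    mk_tagged("g1", "tajimas_d", 12), mk_tagged("g1", "fay_wu_h", 9),
    mk_tagged("g2", "tajimas_d", 10), mk_tagged("g2", "fay_wu_h", 11)
  )
  cc <- concurrence(tagged, scan_config(concurrence_min_populations = 10))
  expect_equal(cc$concurrent_hit[cc$gene_id == "g1"], FALSE) # 12 and 9
  expect_equal(cc$concurrent_hit[cc$gene_id == "g2"], TRUE) # 10 and 11
  expect_equal(cc$count_tajimas_d[cc$gene_id == "g1"], 12L)

  # raising the threshold never increases the hit count
  hits <- purrr::map_int(8:13, function(k) {
    sum(concurrence(tagged, scan_config(concurrence_min_populations = k))$concurrent_hit)
  })
  expect_true(all(diff(hits) <= 0))

  # single population, threshold 1: hits are genes extreme for all statistics
  t1 <- dplyr::bind_rows(
    mk_tagged("g1", "tajimas_d", 1, 1), mk_tagged("g1", "fay_wu_h", 0, 1)
  )
  c1 <- concurrence(t1, scan_config(concurrence_min_populations = 1))
  expect_false(c1$concurrent_hit[1])

  # differing population sets across statistics is a consistency error
  bad <- dplyr::bind_rows(
    mk_tagged("g1", "tajimas_d", 2, 12),
    mk_tagged("g1", "fay_wu_h", 2, 11)
  )
  expect_error(concurrence(bad, scan_config()),
    class = "selscape_consistency_error")
})

test_that("run_scan recovers a planted low-statistic gene", {
  set.seed(2)
  pops <- sprintf("pop%02d", 1:12)
  stats <- purrr::map_dfr(pops, function(p) {
    v <- rnorm(100)
    v[7] <- -50 # gene region 7 extreme in every population
    mk_stats(v, population = p)
  })
  genes <- make_gene_table(100, region_length_bp = 50000,
    gene_length_bp = 20000)
  res <- run_scan(stats, genes, scan_config(concurrence_min_populations = 10))
  expect_equal(res$concurrence$gene_id[res$concurrence$concurrent_hit],
    "gene0007")
})

test_that("pi comparison separates candidates fully when their pi is lower", {
  # genes one-to-one with windows; candidates have pi 0
  st <- mk_stats(rnorm(40))
  st$pi_per_bp <- c(1e-6 * (1:5), runif(35, 1e-4, 1e-3))
  genes <- make_gene_table(40, region_length_bp = 50000,
    gene_length_bp = 20000)
  cand <- genes$gene_id[1:5]
  res <- pi_background_comparison(st, genes, cand,
    scan_config(resample_iterations = 50, seed = 9))
  g <- glance(res)
  expect_equal(g$frac_lower, 1)
  expect_equal(g$n_candidates, 5L)
  # minimal two-sided exact p for 5 vs 5 distinct values: 2/choose(10,5)
  expect_equal(unique(res$iterations$p_value), 2 / choose(10, 5),
    tolerance = 1e-12)

  # determinism under a fixed seed
  res2 <- pi_background_comparison(st, genes, cand,
    scan_config(resample_iterations = 50, seed = 9))
  expect_identical(res$iterations$p_value, res2$iterations$p_value)

  # background smaller than candidates is a sampling error
  expect_error(
    pi_background_comparison(st, genes[1:8, ], genes$gene_id[1:5],
      scan_config(resample_iterations = 5)),
    class = "selscape_sampling_error"
  )
})

test_that("pi comparison is near-symmetric under the null", {
  set.seed(11)
  st <- mk_stats(rnorm(200))
  st$pi_per_bp <- runif(200, 1e-4, 1e-3)
  genes <- make_gene_table(200, region_length_bp = 50000,
    gene_length_bp = 20000)
  cand <- sample(genes$gene_id, 20)
  res <- pi_background_comparison(st, genes, cand,
    scan_config(resample_iterations = 400, seed = 3))
  g <- glance(res)
  expect_gt(g$frac_lower, 0.2)
  expect_lt(g$frac_lower, 0.8)
  expect_gt(g$median_p, 0.05)
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(nrow(tidy(res)), 400)
})

test_that("gene-level tail unit ranks min-ranks across genes", {
  gr <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:40), population = "pop01",
    statistic = "tajimas_d",
    min_rank = c(1:40), n_ranked = 4000L
  )
  tagged <- tag_extreme(gr, scan_config(tail_quantile = 0.05,
    tail_unit = "genes"))
  # ceiling(0.05 * 40) = 2 genes tagged
  expect_equal(sum(tagged$is_extreme), 2L)
  expect_true(all(tagged$is_extreme[1:2]))
})
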