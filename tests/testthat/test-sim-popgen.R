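# Coalescent simulator: degenerate cases, determinism, Watterson
# calibration, sweep behavior, and the on-disk population outputs.

test_that("theta = 0 yields no segregating sites", {
  cfg <- sim_pop_config(n_haplotypes = 10, theta = 0, n_windows = 3, seed = 1)
  w <- simulate_neutral_window(cfg, 2)
  expect_equal(w$S, 0)
})

test_that("with two haplotypes every segregating site is a singleton", {
  cfg <- sim_pop_config(n_haplotypes = 2, theta = 20, n_windows = 2, seed = 3)
  w <- simulate_neutral_window(cfg, 1)
  expect_gt(w$S, 0)
  expect_true(all(w$derived_counts == 1L))
})

test_that("identical seeds reproduce identical windows and VCF bytes", {
  cfg <- sim_pop_config(n_haplotypes = 12, theta = 8, n_windows = 4,
    window_length_bp = 5000, seed = 99)
  w1 <- simulate_neutral_window(cfg, 1)
  w2 <- simulate_neutral_window(cfg, 1)
  expect_identical(w1$derived_counts, w2$derived_counts)
  expect_identical(w1$positions, w2$positions)
  expect_identical(w1$haplotypes, w2$haplotypes)

  genes <- make_gene_table(2, region_length_bp = 10000, gene_length_bp = 4000)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_populations(list(p = cfg), genes, d1)
  simulate_populations(list(p = cfg), genes, d2)
  expect_identical(
    readLines(file.path(d1, "p.vcf")),
    readLines(file.path(d2, "p.vcf"))
  )
})

test_that("windows have unique sorted positions within bounds", {
  cfg <- sim_pop_config(n_haplotypes = 20, theta = 40, n_windows = 3,
    window_length_bp = 1000, seed = 5)
  for (i in 1:3) {
    w <- simulate_neutral_window(cfg, i)
    expect_false(anyDuplicated(w$positions) > 0)
    expect_true(all(w$positions > (i - 1) * 1000 & w$positions <= i * 1000))
    expect_identical(w$positions, sort(w$positions))
    expect_identical(as.integer(colSums(w$haplotypes)), w$derived_counts)
  }
})

test_that("mean S over replicate windows matches the Watterson expectation", {
  n <- 25
  theta <- 5
  reps <- 600
  cfg <- sim_pop_config(n_haplotypes = n, theta = theta, n_windows = reps,
    window_length_bp = 2000, seed = 17)
  s <- purrr::map_int(simulate_chromosome(cfg), "S")
  a1 <- sum(1 / seq_len(n - 1))
  se <- sd(s) / sqrt(reps)
  expect_lt(abs(mean(s) - theta * a1), 3 * se)
})

test_that("a sweep of strength zero reduces to the neutral model", {
  cfg <- sim_pop_config(n_haplotypes = 15, theta = 10, n_windows = 2,
    sweep_windows = 1L, sweep_strength = 0, sweep_age = 0.05, seed = 31)
  cfg_n <- sim_pop_config(n_haplotypes = 15, theta = 10, n_windows = 2,
    seed = 31)
  expect_identical(
    simulate_sweep_window(cfg, 1)$derived_counts,
    simulate_neutral_window(cfg_n, 1)$derived_counts
  )
})

test_that("strong recent sweeps depress both Tajima's D and Fay & Wu's H", {
  cfg <- sim_pop_config(n_haplotypes = 25, theta = 5, n_windows = 500,
    sweep_windows = 1:500, sweep_age = 0.05, sweep_strength = 1, seed = 41)
  st <- windows_from_simulation(simulate_chromosome(cfg))
  expect_lt(mean(st$tajimas_d, na.rm = TRUE), -0.5)
  expect_lt(mean(st$fay_wu_h, na.rm = TRUE), 0)
})

test_that("increasing sweep strength does not increase mean D or mean H", {
  reps <- 300
  means <- purrr::map_dfr(c(0, 0.5, 1), function(s) {
    cfg <- sim_pop_config(n_haplotypes = 25, theta = 5, n_windows = reps,
      sweep_windows = seq_len(reps), sweep_age = 0.05, sweep_strength = s,
      seed = 55)
    st <- windows_from_simulation(simulate_chromosome(cfg))
    tibble::tibble(
      strength = s,
      d = mean(st$tajimas_d, na.rm = TRUE),
      h = mean(st$fay_wu_h, na.rm = TRUE),
      d_se = sd(st$tajimas_d, na.rm = TRUE) / sqrt(reps),
      h_se = sd(st$fay_wu_h, na.rm = TRUE) / sqrt(reps)
    )
  })
  for (i in 2:3) {
    tol_d <- 2 * sqrt(means$d_se[i]^2 + means$d_se[i - 1]^2)
    tol_h <- 2 * sqrt(means$h_se[i]^2 + means$h_se[i - 1]^2)
    expect_lt(means$d[i], means$d[i - 1] + tol_d)
    expect_lt(means$h[i], means$h[i - 1] + tol_h)
  }
})

test_that("window index validation and sweep/neutral dispatch are enforced", {
  cfg <- sim_pop_config(n_windows = 5, sweep_windows = 2L, seed = 1)
  expect_error(simulate_neutral_window(cfg, 2), class = "selscape_config_error")
  expect_error(simulate_sweep_window(cfg, 1), class = "selscape_config_error")
  expect_error(simulate_neutral_window(cfg, 6), class = "selscape_config_error")
  expect_error(sim_pop_config(n_haplotypes = 1), class = "selscape_config_error")
  expect_error(sim_pop_config(sweep_strength = 1.2), class = "selscape_config_error")
})

test_that("simulate_populations writes VCF, BED and a truthful manifest", {
  genes <- make_gene_table(4, region_length_bp = 10000, gene_length_bp = 4000)
  sweep_units <- units_for_regions(c(2, 4), 10000, 2000)
  mk <- function(seed, sweeps = sweep_units) {
    sim_pop_config(n_haplotypes = 8, theta = 2, n_windows = 20,
      window_length_bp = 2000, sweep_windows = sweeps, seed = seed)
  }
  d <- withr::local_tempdir()
  out <- simulate_populations(list(a = mk(1), b = mk(2)), genes, d)
  expect_true(all(file.exists(out$vcf)))
  expect_true(file.exists(attr(out, "bed")))
  manifest <- jsonlite::read_json(attr(out, "manifest"), simplifyVector = TRUE)
  # the swept gene is listed under every population
  expect_equal(manifest$populations$a$sweep_genes, c("gene0002", "gene0004"))
  expect_equal(manifest$populations$b$sweep_genes, c("gene0002", "gene0004"))

  # no sweeps -> empty sweep set in the manifest
  d2 <- withr::local_tempdir()
  out2 <- simulate_populations(list(a = mk(1, integer())), genes, d2)
  m2 <- jsonlite::read_json(attr(out2, "manifest"), simplifyVector = TRUE)
  expect_length(m2$populations$a$sweep_windows, 0)
  expect_length(m2$populations$a$sweep_genes, 0)

  # BED is 0-based half-open with gene ids
  bed <- read_gene_bed(attr(out, "bed"))
  expect_equal(bed$gene_id, genes$gene_id)
  expect_equal(bed$start, genes$start)
})

test_that("retile_windows agrees with the VCF round trip", {
  cfg <- sim_pop_config(n_haplotypes = 10, theta = 3, n_windows = 30,
    window_length_bp = 2000, seed = 77)
  wins <- simulate_chromosome(cfg)
  direct <- retile_windows(wins, size = 10000, step = 5000, chrom_len = 60000)

  d <- withr::local_tempdir()
  genes <- make_gene_table(1, region_length_bp = 60000, gene_length_bp = 100)
  simulate_populations(list(p = cfg), genes, d)
  via_vcf <- windows_from_vcf(file.path(d, "p.vcf"), size = 10000, step = 5000)
  expect_equal(direct$start, via_vcf$start)
  expect_equal(
    purrr::map(direct$derived_counts, sort),
    purrr::map(via_vcf$derived_counts, sort)
  )
})

test_that("units_for_regions maps gene regions to simulated block indices", {
  expect_equal(units_for_regions(1, 50000, 2000), 1:25)
  expect_equal(units_for_regions(3, 50000, 10000), 11:15)
  expect_error(units_for_regions(1, 50000, 3000), class = "selscape_config_error")
})
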