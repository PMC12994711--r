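# IDR layer: consensus interval calling, sequence descriptors, feature
# summaries, and the enrichment / comparison / correlation statistics.

test_that("consensus IDRs respect the length and species-fraction rules", {
  # 4 species, disordered over reference residues 10..60 in all species
  L <- 80
  msa <- Biostrings::AAStringSet(setNames(
    rep(paste(rep("A", L), collapse = ""), 4),
    c("ref", "sp1", "sp2", "sp3")
  ))
  dis <- tidyr::expand_grid(
    species = c("ref", "sp1", "sp2", "sp3"), residue = seq_len(L)
  ) |>
    dplyr::mutate(disordered = residue >= 10 & residue <= 60, protein = "p1")
  idr <- consensus_idrs(dis, msa, "ref")
  expect_equal(idr$start, 10L)
  expect_equal(idr$end, 60L)
  expect_equal(idr$length, 51L)

  # a 29-residue run is not an IDR
  dis29 <- dplyr::mutate(dis, disordered = residue >= 10 & residue <= 38)
  expect_equal(nrow(consensus_idrs(dis29, msa, "ref")), 0)

  # 2 of 4 species disordered meets the inclusive 50% boundary
  dis_half <- dis |>
    dplyr::mutate(disordered = disordered & species %in% c("ref", "sp1"))
  idr_half <- consensus_idrs(dis_half, msa, "ref")
  expect_equal(idr_half$start, 10L)

  # species order has no effect
  idr_rev <- consensus_idrs(dplyr::arrange(dis, dplyr::desc(species)), msa, "ref")
  expect_equal(idr_rev, idr)
})

test_that("gap columns are excluded from the species vote", {
  # sp2 is all gaps: fractions must be computed among present species only
  msa <- Biostrings::AAStringSet(c(
    ref = "AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA",
    sp1 = "AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA",
    sp2 = "----------------------------------------"
  ))
  dis <- tidyr::expand_grid(species = c("ref", "sp1"), residue = 1:40) |>
    dplyr::mutate(disordered = TRUE)
  idr <- consensus_idrs(dis, msa, "ref", min_len = 30)
  expect_equal(idr$start, 1L)
  expect_equal(idr$end, 40L)
})

test_that("FCR and NCPR count charged residues", {
  expect_equal(fcr_ncpr("KKDD"), list(fcr = 1, ncpr = 0))
  expect_equal(fcr_ncpr("KKKK"), list(fcr = 1, ncpr = 1))
  expect_equal(fcr_ncpr("GGGG"), list(fcr = 0, ncpr = 0))
  expect_equal(fcr_ncpr("KRDEGG"), list(fcr = 4 / 6, ncpr = 0))
  # histidine counts as positive only when asked
  expect_equal(fcr_ncpr("HHHH")$fcr, 0)
  expect_equal(fcr_ncpr("HHHH", feature_config(include_histidine = TRUE))$fcr, 1)
  expect_error(fcr_ncpr(""), class = "selscape_domain_error")
})

test_that("SHD matches hand sums and is reversal-symmetric", {
  # I has the maximum Kyte-Doolittle hydropathy -> lambda = 1; R the minimum -> 0
  expect_equal(shd("II"), 1.0, tolerance = 1e-12)
  expect_equal(shd("IRI"), 1.0, tolerance = 1e-12) # pairs: 1/1, 2/2, 1/1
  set.seed(5)
  for (rep in 1:20) {
    s <- paste(sample(c("A", "R", "N", "D", "K", "I", "G", "P"), 30,
      replace = TRUE), collapse = "")
    rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(shd(s), shd(rev_s), tolerance = 1e-12)
  }
  # beta = 2: hand sum with lambda(I) = 1, lambda(G) = 41/90
  lam_g <- (-0.4 + 4.5) / 9
  expect_equal(
    shd("IGI", feature_config(shd_exponent = 2)),
    ((1 + lam_g) / 1 + (lam_g + 1) / 1 + (1 + 1) / 4) / 3,
    tolerance = 1e-12
  )
  expect_error(shd("I"), class = "selscape_domain_error")
  expect_error(shd("IX"), class = "selscape_config_error")
})

test_that("feature table summarizes across orthologs with n-1 SD", {
  # 10-residue IDR; ref has 2 K (FCR 0.2), sp1 has 4 K (FCR 0.4)
  msa <- Biostrings::AAStringSet(c(
    ref = "KGGKGGGGGG",
    sp1 = "KGKKGGGGKG"
  ))
  idrs <- tibble::tibble(start = 1L, end = 10L)
  ft <- idr_feature_table(idrs, msa, "ref")
  expect_equal(ft$fcr_mean, 0.3, tolerance = 1e-12)
  expect_equal(ft$fcr_sd, sqrt(0.02), tolerance = 1e-6)
  expect_equal(round(ft$fcr_sd, 4), 0.1414)
  expect_equal(ft$n_orthologs, 2L)
  # no external table -> no ensemble columns
  expect_false(any(c("sconf_per_n", "nu") %in% names(ft)))

  # identical orthologs -> all SDs are zero
  msa2 <- Biostrings::AAStringSet(c(ref = "KADGKADGKA", sp1 = "KADGKADGKA",
    sp2 = "KADGKADGKA"))
  ft2 <- idr_feature_table(idrs, msa2, "ref")
  expect_equal(ft2$fcr_sd, 0)
  expect_equal(ft2$ncpr_sd, 0)
  expect_equal(ft2$shd_sd, 0, tolerance = 1e-12)

  # external per-IDR features are joined, never computed
  ext <- tibble::tibble(idr_start = 1L, idr_end = 10L,
    sconf_per_n = -2.5, nu = 0.51)
  ft3 <- idr_feature_table(idrs, msa, "ref", external = ext)
  expect_equal(ft3$sconf_per_n, -2.5)
  expect_equal(ft3$nu, 0.51)
})

test_that("ortholog subsequences shorter than 2 residues are skipped with a warning", {
  msa <- Biostrings::AAStringSet(c(
    ref = "KKKKKKKKKK",
    sp1 = "K---------"
  ))
  idrs <- tibble::tibble(start = 1L, end = 10L)
  expect_warning(ft <- idr_feature_table(idrs, msa, "ref"), "skipped")
  expect_equal(ft$n_orthologs, 1L)
})

test_that("IDRs are flagged selected iff they contain a consensus site", {
  idrs <- tibble::tibble(protein = c("p1", "p1"), start = c(10L, 50L),
    end = c(40L, 90L))
  sites <- tibble::tibble(protein = "p1", residue = c(40L, 95L))
  fl <- flag_selected_idrs(idrs, sites)
  expect_equal(fl$has_positive_site, c(TRUE, FALSE))
})

test_that("binomial enrichment reproduces exact tail probabilities", {
  # k = 9, m = 10, p0 = 0.3: exact upper tail
  en <- binomial_enrichment(9, 10, 30, 100)
  expected <- sum(dbinom(9:10, 10, 0.3))
  expect_equal(en$p_value, expected, tolerance = 1e-12)
  expect_equal(tidy(en)$p0, 0.3)

  # k = 0 with alternative greater has p = 1
  expect_equal(binomial_enrichment(0, 10, 30, 100)$p_value, 1)

  # k = m with p0 near 1: p = p0^m
  en2 <- binomial_enrichment(10, 10, 999, 1000)
  expect_equal(en2$p_value, 0.999^10, tolerance = 1e-12)

  expect_error(binomial_enrichment(5, 10, 100, 100),
    class = "selscape_domain_error")
  expect_error(binomial_enrichment(11, 10, 30, 100),
    class = "selscape_domain_error")
})

test_that("group comparison uses the exact Wilcoxon for small tie-free groups", {
  out <- compare_groups(c(1, 2, 3), c(10, 20, 30), "sconf_per_n")
  expect_equal(out$p_value, 0.1, tolerance = 1e-12) # most extreme of C(6,3)
  expect_equal(out$median_selected, 2)

  # swapping labels leaves the p-value unchanged
  out2 <- compare_groups(c(10, 20, 30), c(1, 2, 3))
  expect_equal(out$p_value, out2$p_value)

  # identical groups: no evidence of a difference
  out3 <- compare_groups(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(out3$p_value, 1)

  expect_error(compare_groups(numeric(), 1:3),
    class = "selscape_grouping_error")
})

test_that("Kendall correlation matches the brute-force tau-b oracle", {
  expect_equal(constraint_feature_correlation(1:10, (1:10)^2)$tau, 1)
  expect_equal(constraint_feature_correlation(1:10, -(1:10))$tau, -1)
  set.seed(12)
  x <- round(runif(50), 2) # rounding induces ties
  y <- round(x + rnorm(50, 0, 0.3), 2)
  got <- constraint_feature_correlation(x, y)
  expect_equal(got$tau, oracle_kendall_tau_b(x, y), tolerance = 1e-12)
  expect_error(constraint_feature_correlation(1:3, 1:4),
    class = "selscape_schema_error")
})

test_that("Pearson correlation matches its definition and handles degeneracy", {
  expect_equal(disorder_fraction_correlation(1:10 / 10, 1:10 / 10)$r, 1)
  expect_equal(disorder_fraction_correlation(1:10 / 10, 1 - 1:10 / 10)$r, -1)
  set.seed(13)
  a <- runif(30)
  b <- 0.3 * a + rnorm(30, 0, 0.1)
  got <- disorder_fraction_correlation(a, b)
  r_def <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(got$r, r_def, tolerance = 1e-12)
  expect_warning(z <- disorder_fraction_correlation(rep(0.5, 5), runif(5)),
    "zero variance")
  expect_true(is.na(z$r))
})
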