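# Window statistics: hand-worked examples, definitional oracles, and the
# VCF/window plumbing.

test_that("pi, theta_W, theta_H and H match hand-worked small cases", {
  w <- polarized_window("chr1", 0, 100, 4, c(1, 2, 3))
  expect_equal(window_pi(w), 0.5 + 2 / 3 + 0.5, tolerance = 1e-12)
  expect_equal(theta_fay_wu(w), 2 * (1 + 4 + 9) / 12, tolerance = 1e-12)
  expect_equal(fay_wu_h(w), window_pi(w) - theta_fay_wu(w), tolerance = 1e-12)
  expect_equal(theta_watterson(3, 4), 3 / (11 / 6), tolerance = 1e-12)
  expect_equal(theta_watterson(0, 7), 0)

  # n = 2: pi = S = theta_W, every site a singleton
  w2 <- polarized_window("chr1", 0, 100, 2, rep(1, 5))
  expect_equal(window_pi(w2), 5)
  expect_equal(theta_watterson(5, 2), 5)

  # all singletons: theta_H = 2S/(n(n-1)), H = S (2/n - 2/(n(n-1))) > 0
  w3 <- polarized_window("chr1", 0, 100, 10, rep(1, 6))
  expect_equal(theta_fay_wu(w3), 2 * 6 / 90, tolerance = 1e-12)
  expect_equal(fay_wu_h(w3), 6 * (2 / 10 - 2 / 90), tolerance = 1e-12)
  expect_gt(fay_wu_h(w3), 0)
})

test_that("empty windows give zero estimators and missing D and H", {
  w <- polarized_window("chr1", 0, 100, 8, integer())
  expect_equal(window_pi(w), 0)
  expect_equal(theta_fay_wu(w), 0)
  expect_true(is.na(tajimas_d(w)))
  expect_true(is.na(fay_wu_h(w)))
})

test_that("D is missing when its variance vanishes (n < 4)", {
  expect_true(is.na(tajimas_d(polarized_window("c", 0, 1, 2, c(1, 1)))))
  expect_true(is.na(tajimas_d(polarized_window("c", 0, 1, 3, c(1, 2)))))
  expect_false(is.na(tajimas_d(polarized_window("c", 0, 1, 4, c(1, 2)))))
})

test_that("derived counts outside (0, n) are rejected", {
  expect_error(polarized_window("c", 0, 1, 4, c(0, 2)), class = "selscape_domain_error")
  expect_error(polarized_window("c", 0, 1, 4, c(1, 4)), class = "selscape_domain_error")
  expect_error(theta_watterson(3, 1), class = "selscape_domain_error")
})

test_that("statistics match brute-force and definitional oracles on random windows", {
  set.seed(421)
  for (rep in 1:100) {
    w <- random_polarized_window()
    x <- w$derived_counts
    n <- w$n
    hap <- counts_to_matrix(x, n)
    expect_equal(window_pi(w), oracle_pi_bruteforce(hap), tolerance = 1e-10)
    expect_equal(theta_fay_wu(w), oracle_theta_h(x, n), tolerance = 1e-10)
    d <- tajimas_d(w)
    d0 <- oracle_tajimas_d(x, n)
    expect_equal(is.na(d), is.na(d0))
    if (!is.na(d)) expect_equal(d, d0, tolerance = 1e-10)
    h <- fay_wu_h(w)
    h0 <- oracle_fay_wu_h(x, n)
    expect_equal(is.na(h), is.na(h0))
    if (!is.na(h)) expect_equal(h, h0, tolerance = 1e-10)
  }
})

test_that("statistics are invariant to site order and scale-free in window length", {
  set.seed(7)
  x <- sample.int(9, 25, replace = TRUE)
  w1 <- polarized_window("c", 0, 50000, 10, x)
  w2 <- polarized_window("c", 0, 50000, 10, sample(x))
  expect_equal(window_pi(w1), window_pi(w2))
  expect_equal(tajimas_d(w1), tajimas_d(w2))
  expect_equal(fay_wu_h(w1), fay_wu_h(w2))

  # per-bp variants scale exactly with 1/length, D and H do not change
  tbl <- tibble::tibble(
    chrom = "c", start = 0, end = c(10000, 50000), n = 10,
    derived_counts = list(x, x)
  )
  st <- compute_window_stats(tbl)
  expect_equal(st$tajimas_d[1], st$tajimas_d[2])
  expect_equal(st$fay_wu_h[1], st$fay_wu_h[2])
  expect_equal(st$pi_per_bp[1], st$pi_per_bp[2] * 5)
})

test_that("tajima constants satisfy their defining identities", {
  for (n in c(2, 4, 10, 25)) {
    k <- tajima_constants(n)
    expect_equal(k$a1, sum(1 / seq_len(n - 1)))
    expect_equal(k$a2, sum(1 / seq_len(n - 1)^2))
    expect_identical(k, tajima_constants(n)) # idempotent
  }
  expect_gt(tajima_constants(4)$e1, 0)
})

test_that("window tiling truncates the final window and keeps short ones", {
  t1 <- tile_windows(100000, 50000, 10000)
  expect_equal(t1$start, seq(0, 50000, by = 10000))
  expect_equal(t1$end[6], 100000)
  expect_equal(nrow(t1), 6)

  t2 <- tile_windows(105000, 50000, 10000)
  expect_equal(nrow(t2), 7)
  expect_equal(t2$end[7], 105000)
  expect_lt(t2$end[7] - t2$start[7], 50000)

  t3 <- tile_windows(40000, 50000, 10000) # chromosome shorter than a window
  expect_equal(nrow(t3), 1)
  expect_equal(t3$end, 40000)
})

test_that("windows_from_vcf polarizes, flips and filters sites", {
  gt <- function(...) paste(c(...), collapse = "\t")
  rows <- c(
    # AA = REF: derived count = ALT count = 3
    gt("chr1", 100, ".", "A", "G", ".", "PASS", "AA=A", "GT", "0|1", "1|1", "0|0"),
    # AA = ALT (lower case, polarity flip): derived = n - 2 = 4
    gt("chr1", 200, ".", "C", "T", ".", "PASS", "AA=t", "GT", "0|1", "0|0", "1|0"),
    # AA matches neither allele: dropped
    gt("chr1", 300, ".", "A", "G", ".", "PASS", "AA=C", "GT", "0|1", "0|0", "0|0"),
    # multi-allelic: dropped
    gt("chr1", 400, ".", "A", "G,T", ".", "PASS", "AA=A", "GT", "0|1", "0|2", "0|0"),
    # no AA: dropped with a warning
    gt("chr1", 500, ".", "A", "G", ".", "PASS", ".", "GT", "0|1", "0|0", "0|0"),
    # monomorphic after polarization (all ALT, AA=ALT): dropped
    gt("chr1", 600, ".", "A", "G", ".", "PASS", "AA=G", "GT", "1|1", "1|1", "1|1")
  )
  path <- write_test_vcf(tempfile(fileext = ".vcf"), rows, 3)
  win <- suppressWarnings(windows_from_vcf(path, size = 50000, step = 10000))
  log <- attr(win, "site_log")
  expect_equal(unname(log["aa_mismatch"]), 1L)
  expect_equal(unname(log["multiallelic"]), 1L)
  expect_equal(unname(log["missing_aa"]), 1L)
  expect_equal(unname(log["monomorphic"]), 1L)
  # all surviving sites are in the first window [0, 50000)
  expect_equal(sort(win$derived_counts[[1]]), c(3L, 4L))
  expect_equal(win$n[1], 6L)
})

test_that("an empty VCF yields all-empty windows over the contig", {
  path <- write_test_vcf(tempfile(fileext = ".vcf"), character(), 3)
  win <- windows_from_vcf(path, size = 50000, step = 10000)
  expect_equal(nrow(win), 6)
  expect_true(all(purrr::map_int(win$derived_counts, length) == 0))
  st <- compute_window_stats(win)
  expect_true(all(st$S == 0))
  expect_true(all(is.na(st$tajimas_d)))
})
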