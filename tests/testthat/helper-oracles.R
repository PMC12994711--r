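`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent oracle implementations used to cross-check the package.
# Everything here is written from the definitions (brute force, set
# algebra, pair enumeration) and never calls the code paths it checks.

# explicit 0/1 haplotype matrix realizing a vector of derived counts
counts_to_matrix <- function(x, n) {
  m <- matrix(0L, nrow = n, ncol = length(x))
  for (j in seq_along(x)) {
    m[sample.int(n, x[j]), j] <- 1L
  }
  m
}

# mean pairwise Hamming distance over all C(n,2) haplotype pairs
oracle_pi_bruteforce <- function(hap) {
  n <- nrow(hap)
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      total <- total + sum(hap[i, ] != hap[j, ])
    }
  }
  total / choose(n, 2)
}

# definitional theta_H
oracle_theta_h <- function(x, n) {
  sum(2 * x^2) / (n * (n - 1))
}

# standalone Tajima's D from the printed constant formulas
oracle_tajimas_d <- function(x, n) {
  S <- length(x)
  if (S == 0) {
    return(NA_real_)
  }
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  pi <- sum(2 * x * (n - x)) / (n * (n - 1))
  denom <- sqrt(e1 * S + e2 * S * (S - 1))
  if (!is.finite(denom) || denom <= 0) {
    return(NA_real_)
  }
  (pi - S / a1) / denom
}

oracle_fay_wu_h <- function(x, n) {
  if (length(x) == 0) {
    return(NA_real_)
  }
  sum(2 * x * (n - x)) / (n * (n - 1)) - oracle_theta_h(x, n)
}

random_polarized_window <- function(n_max = 12, s_max = 40) {
  n <- sample(2:n_max, 1)
  S <- sample(0:s_max, 1)
  x <- if (S > 0) sample.int(n - 1, S, replace = TRUE) else integer()
  polarized_window("chr1", 0, 1000, n, x)
}

# set-algebra consensus oracle: filter per method, count per column
oracle_consensus <- function(calls, min_methods = 2) {
  pass <- (calls$method == "BEB" & calls$score >= 0.90) |
    (calls$method == "FUBAR" & calls$score >= 0.90) |
    (calls$method == "MEME" & calls$score < 0.1) |
    (calls$method == "FEL" & calls$score < 0.1)
  hit <- calls[pass, c("method", "alignment_column")]
  hit <- unique(hit)
  tab <- table(hit$alignment_column)
  sort(as.integer(names(tab)[tab >= min_methods]))
}

random_call_table <- function(n_rows = 30, n_cols = 20) {
  tibble::tibble(
    method = sample(c("BEB", "FUBAR", "MEME", "FEL", "SLAC"), n_rows,
      replace = TRUE),
    alignment_column = sample.int(n_cols, n_rows, replace = TRUE),
    score = round(runif(n_rows), 3),
    direction = "positive"
  ) |>
    dplyr::distinct(method, alignment_column, .keep_all = TRUE)
}

# O(n^2) Kendall tau-b from concordant/discordant pair counts
oracle_kendall_tau_b <- function(x, y) {
  n <- length(x)
  conc <- 0
  disc <- 0
  tx <- 0
  ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i])
      dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) {
        # double tie: counted in neither denominator term
      } else if (dx == 0) {
        tx <- tx + 1
      } else if (dy == 0) {
        ty <- ty + 1
      } else if (dx == dy) {
        conc <- conc + 1
      } else {
        disc <- disc + 1
      }
    }
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# minimal VCF writer for hand-built fixtures
write_test_vcf <- function(path, rows, n_samples, chrom_len = 100000,
                           chrom = "chr1") {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", chrom, chrom_len),
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", sprintf("s%02d", seq_len(n_samples))), collapse = "\t")
  )
  writeLines(c(header, rows), path)
  path
}
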