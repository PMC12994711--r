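# VCF and BED input/output for the population layer. Reading goes through
# vcfR; writing is a plain-text VCF 4.2 emitter for the simulator's
# haplotype matrices (ancestral allele in INFO/AA, phased GT).

#' Write simulated haplotypes as a VCF
#'
#' Serializes a list of [polarized_window()] objects (with haplotype
#' matrices and positions) to a VCF 4.2 file. Haplotypes are paired into
#' phased diploid samples when the sample size is even, otherwise written
#' as haploid samples. The ancestral allele is recorded in the `AA` INFO
#' field; REF is always the ancestral base, so derived counts can be
#' recovered exactly.
#'
#' @param windows List of `polarized_window` objects on one chromosome.
#' @param path Output file path.
#' @param chrom_len Chromosome length for the `##contig` header line.
#' @return Invisibly, `path`.
#' @export
write_population_vcf <- function(windows, path, chrom_len) {
  if (length(windows) == 0) stop_domain("no windows to write")
  n <- windows[[1]]$n
  chrom <- windows[[1]]$chrom
  diploid <- n %% 2 == 0
  sample_names <- if (diploid) {
    sprintf("ind%03d", seq_len(n / 2))
  } else {
    sprintf("hap%03d", seq_len(n))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=selscape",
    sprintf("##contig=<ID=%s,length=%d>", chrom, as.integer(chrom_len)),
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", sample_names
    ), collapse = "\t")
  )
  body <- purrr::map(windows, function(w) {
    if (w$S == 0) {
      return(character())
    }
    if (is.null(w$haplotypes) || is.null(w$positions)) {
      stop_domain("windows must carry haplotypes and positions to be written as VCF")
    }
    gt <- apply(w$haplotypes, 2, function(col) {
      if (diploid) {
        paste(col[seq(1, n, by = 2)], col[seq(2, n, by = 2)], sep = "|")
      } else {
        as.character(col)
      }
    })
    if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
    purrr::map_chr(seq_len(w$S), function(j) {
      paste(c(
        w$chrom, w$positions[j], ".", "A", "G", ".", "PASS", "AA=A", "GT",
        gt[, j]
      ), collapse = "\t")
    })
  })
  writeLines(c(header, unlist(body)), path)
  invisible(path)
}

#' Deterministic sliding-window tiling of a chromosome
#'
#' Windows start at 0, `step`, `2*step`, ... and have length `size`,
#' 0-based half-open. Emission stops with the first window whose nominal
#' end reaches or passes the chromosome end; that window is truncated at
#' the chromosome end rather than dropped, and short trailing windows are
#' still emitted.
#'
#' @param chrom_len Chromosome length in bp.
#' @param size Window size in bp (default 50000).
#' @param step Step between window starts in bp (default 10000).
#' @return Tibble with columns `start`, `end`.
#' @export
tile_windows <- function(chrom_len, size = 50000, step = 10000) {
  if (size < 1 || step < 1) stop_bad_config("size and step must be >= 1")
  starts <- numeric()
  s <- 0
  repeat {
    starts <- c(starts, s)
    if (s + size >= chrom_len) break
    s <- s + step
  }
  tibble(start = starts, end = pmin(starts + size, chrom_len))
}

#' Read a polarized VCF into sliding windows
#'
#' Parses a VCF with an `AA` (ancestral allele) INFO annotation and bins
#' its biallelic SNVs into overlapping sliding windows per chromosome
#' (geometry from [tile_windows()]; chromosome lengths from the `##contig`
#' header). Each site's derived-allele count is the ALT allele count when
#' `AA` equals REF and the flipped count `n - alt_count` when `AA` equals
#' ALT (comparison case-insensitive). Sites are dropped, with a tally kept
#' in the `site_log` attribute, when they are multi-allelic, lack a usable
#' `AA`, have an `AA` matching neither allele, carry missing genotypes, or
#' are monomorphic after polarization.
#'
#' @param vcf_path Path to a VCF 4.2 file.
#' @param size,step Window size and step in bp (defaults 50000 and 10000).
#' @return Window table (tibble with `chrom`, `start`, `end`, `n`,
#'   list-column `derived_counts`), with attribute `site_log` summarizing
#'   dropped sites. Feed to [compute_window_stats()].
#' @export
windows_from_vcf <- function(vcf_path, size = 50000, step = 10000) {
  if (!file.exists(vcf_path)) {
    abort(paste0("VCF not found: ", vcf_path), class = "selscape_file_error")
  }
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  meta <- vcf@meta
  contig <- stringr::str_match(
    meta[grepl("^##contig", meta)],
    "ID=([^,>]+).*?length=([0-9]+)"
  )
  if (nrow(contig) == 0 || anyNA(contig)) {
    abort("VCF header has no ##contig lines with ID and length",
      class = "selscape_format_error")
  }
  chrom_lens <- setNames(as.numeric(contig[, 3]), contig[, 2])

  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  log <- c(
    multiallelic = 0L, missing_aa = 0L, aa_mismatch = 0L,
    missing_gt = 0L, monomorphic = 0L
  )
  n_hap <- NA_integer_
  site_tbl <- NULL
  if (nrow(fix) > 0) {
    gt <- vcfR::extract.gt(vcf)
    aa <- vcfR::extract.info(vcf, "AA")
    keep_multi <- !is.na(fix$ALT) & !stringr::str_detect(fix$ALT, stringr::fixed(","))
    log["multiallelic"] <- sum(!keep_multi)
    has_aa <- !is.na(aa) & nzchar(aa) & aa != "."
    log["missing_aa"] <- sum(keep_multi & !has_aa)
    if (sum(keep_multi & !has_aa) > 0) {
      warn(sprintf("%d site(s) lack an AA annotation and were skipped",
        sum(keep_multi & !has_aa)))
    }
    aa_up <- toupper(aa)
    is_ref <- aa_up == toupper(fix$REF)
    is_alt <- aa_up == toupper(fix$ALT)
    keep <- keep_multi & has_aa & (is_ref | is_alt)
    log["aa_mismatch"] <- sum(keep_multi & has_aa & !(is_ref | is_alt))

    # per-site allele counts from GT (phased or not)
    alleles <- apply(gt, 1, function(row) {
      a <- unlist(strsplit(row, "[|/]"))
      if (any(is.na(a)) || any(a == ".")) {
        return(c(NA_integer_, NA_integer_))
      }
      c(sum(a == "1"), length(a))
    })
    alt_count <- alleles[1, ]
    n_alleles <- alleles[2, ]
    bad_gt <- is.na(alt_count)
    log["missing_gt"] <- sum(keep & bad_gt)
    keep <- keep & !bad_gt
    n_hap <- if (any(!is.na(n_alleles))) {
      as.integer(max(n_alleles, na.rm = TRUE))
    } else {
      NA_integer_
    }
    derived <- ifelse(is_ref, alt_count, n_alleles - alt_count)
    poly <- derived > 0 & derived < n_alleles
    log["monomorphic"] <- sum(keep & !poly)
    keep <- keep & poly
    site_tbl <- tibble(
      chrom = fix$CHROM[keep],
      pos = as.numeric(fix$POS[keep]),
      derived = as.integer(derived[keep])
    )
  }
  if (is.na(n_hap)) {
    # empty or fully filtered VCF: infer sample ploidy is unknowable; use
    # the sample count as a haploid lower bound
    n_hap <- max(2L, ncol(vcf@gt) - 1L)
  }

  windows <- purrr::imap_dfr(chrom_lens, function(len, chrom) {
    w <- tile_windows(len, size = size, step = step)
    w$chrom <- chrom
    w$n <- n_hap
    w$derived_counts <- purrr::map2(w$start, w$end, function(s, e) {
      if (is.null(site_tbl)) {
        return(integer())
      }
      sel <- site_tbl$chrom == chrom & site_tbl$pos - 1 >= s & site_tbl$pos - 1 < e
      as.integer(site_tbl$derived[sel])
    })
    w
  })
  out <- windows[, c("chrom", "start", "end", "n", "derived_counts")]
  attr(out, "site_log") <- log
  out
}

#' Read a BED file of gene intervals
#'
#' Reads a 4-column BED (0-based half-open: chrom, start, end, name) into
#' the gene table used by the scan.
#'
#' @param path Path to a BED file.
#' @return Tibble with `chrom`, `start`, `end`, `gene_id`.
#' @export
read_gene_bed <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("BED not found: ", path), class = "selscape_file_error")
  }
  readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "gene_id"),
    col_types = "ciic",
    progress = FALSE
  )
}
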