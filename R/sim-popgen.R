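#' Configuration for the population-genetic simulator
#'
#' Describes one simulated population: a chromosome made of `n_windows`
#' non-overlapping segments of `window_length_bp` base pairs, each evolving
#' as an independent neutral Kingman coalescent with population-scaled
#' mutation rate `theta` per window (infinite-sites mutations, fully
#' polarized). Windows listed in `sweep_windows` are additionally distorted
#' by a hard selective sweep: at backward time `sweep_age` (coalescent time
#' units) each surviving lineage joins a single star ancestor with
#' probability `sweep_strength` (one lineage always escapes, playing the
#' role of a recombinant/ancestral haplotype), producing the excess of rare
#' and high-frequency derived alleles that depresses Tajima's D and
#' Fay & Wu's H.
#'
#' The simulated window is the unit of genealogical independence -- the
#' scale over which linkage is complete and between which it is absent. It
#' need not equal the (larger) analysis window of the scan: the defaults
#' emulate human-like data with `theta/bp = 0.001` on 2-kb blocks, and
#' [retile_windows()] or [windows_from_vcf()] aggregate blocks into 50-kb
#' analysis windows.
#'
#' @param n_haplotypes Number of sampled haploid sequences (>= 2).
#' @param theta Population-scaled mutation rate per window (> 0).
#' @param n_windows Number of simulated windows.
#' @param window_length_bp Physical window length in base pairs.
#' @param sweep_windows Integer vector of 1-based window indices carrying a
#'   sweep (may be empty).
#' @param sweep_age Time of the sweep, in coalescent units before present.
#' @param sweep_strength Probability, in `[0, 1]`, that a lineage alive at
#'   `sweep_age` is captured by the star merger.
#' @param seed Integer seed; identical seeds reproduce identical output.
#' @return A list of class `sim_pop_config`.
#' @export
#' @examples
#' cfg <- sim_pop_config(n_haplotypes = 10, theta = 5, n_windows = 3, seed = 1)
#' simulate_neutral_window(cfg, 1)
sim_pop_config <- function(n_haplotypes = 30,
                           theta = 2,
                           n_windows = 1500,
                           window_length_bp = 2000,
                           sweep_windows = integer(),
                           sweep_age = 0.05,
                           sweep_strength = 1,
                           seed = 1L) {
  if (n_haplotypes < 2) stop_bad_config("n_haplotypes must be >= 2")
  if (theta < 0) stop_bad_config("theta must be >= 0")
  if (n_windows < 1) stop_bad_config("n_windows must be >= 1")
  if (window_length_bp < 1) stop_bad_config("window_length_bp must be >= 1")
  if (sweep_strength < 0 || sweep_strength > 1) {
    stop_bad_config("sweep_strength must lie in [0, 1]")
  }
  if (sweep_age < 0) stop_bad_config("sweep_age must be >= 0")
  sweep_windows <- as.integer(sweep_windows)
  if (any(sweep_windows < 1 | sweep_windows > n_windows)) {
    stop_bad_config("sweep_windows indices must lie in [1, n_windows]")
  }
  structure(
    list(
      n_haplotypes = as.integer(n_haplotypes),
      theta = theta,
      n_windows = as.integer(n_windows),
      window_length_bp = as.integer(window_length_bp),
      sweep_windows = sweep_windows,
      sweep_age = sweep_age,
      sweep_strength = sweep_strength,
      seed = as.integer(seed)
    ),
    class = "sim_pop_config"
  )
}

# Core genealogy + mutation engine. Runs a Kingman coalescent on `n`
# lineages (pairwise coalescence rate k(k-1)/2 among k lineages), placing
# infinite-sites mutations on branches as a Poisson process of rate theta/2
# per unit branch length. If `sweep_age` is non-NULL, the genealogy is
# interrupted at that backward time and each surviving lineage joins a
# single star ancestor with probability `sweep_strength`; survivors continue
# neutrally. Returns a list of carrier index vectors, one per mutation
# (mutations above the MRCA are fixed and never emitted, so every derived
# count is strictly between 0 and n).
sim_genealogy_mutations <- function(n, theta, sweep_age = NULL,
                                    sweep_strength = 0) {
  lineages <- as.list(seq_len(n))
  carriers <- list()
  t_now <- 0
  sweep_pending <- !is.null(sweep_age) && sweep_strength > 0
  while (length(lineages) > 1) {
    k <- length(lineages)
    if (sweep_pending && t_now >= sweep_age) {
      join <- runif(k) < sweep_strength
      if (all(join)) {
        # one lineage always escapes the sweep (a recombinant/ancestral
        # haplotype); this keeps the merged lineage segregating, so the
        # mutations it accumulates before the final coalescence appear as
        # high-frequency derived alleles -- the signature the sweep model
        # exists to produce. A total merge would instead leave only
        # singletons (and positive H).
        join[sample.int(k, 1)] <- FALSE
      }
      if (sum(join) >= 2) {
        merged <- sort(unlist(lineages[join]))
        lineages <- c(lineages[!join], list(merged))
      }
      sweep_pending <- FALSE
      next
    }
    dt <- rexp(1, rate = k * (k - 1) / 2)
    if (sweep_pending && t_now + dt > sweep_age) {
      dt <- sweep_age - t_now
      n_mut <- rpois(1, theta / 2 * k * dt)
      if (n_mut > 0) {
        hit <- sample.int(k, n_mut, replace = TRUE)
        carriers <- c(carriers, lineages[hit])
      }
      t_now <- sweep_age
      next
    }
    n_mut <- rpois(1, theta / 2 * k * dt)
    if (n_mut > 0) {
      hit <- sample.int(k, n_mut, replace = TRUE)
      carriers <- c(carriers, lineages[hit])
    }
    t_now <- t_now + dt
    pair <- sample.int(k, 2)
    merged <- sort(c(lineages[[pair[1]]], lineages[[pair[2]]]))
    lineages <- c(lineages[-pair], list(merged))
  }
  carriers
}

sim_window_impl <- function(config, window_index, sweep) {
  n <- config$n_haplotypes
  L <- config$window_length_bp
  with_seed(derive_seed(config$seed, window_index), {
    carriers <- sim_genealogy_mutations(
      n, config$theta,
      sweep_age = if (sweep) config$sweep_age else NULL,
      sweep_strength = if (sweep) config$sweep_strength else 0
    )
    s <- length(carriers)
    if (s > L) {
      stop_bad_config("more mutations than base pairs in the window; increase window_length_bp")
    }
    # infinite sites on a finite map: distinct uniform coordinates, sorted;
    # the coordinate draw is independent of the genealogy, so pairing sorted
    # positions with mutations in generation order is an unbiased matching
    positions <- sort(sample.int(L, s))
    hap <- matrix(0L, nrow = n, ncol = s)
    for (j in seq_len(s)) {
      hap[carriers[[j]], j] <- 1L
    }
    polarized_window(
      chrom = "chr1",
      start = (window_index - 1L) * L,
      end = window_index * L,
      n = n,
      derived_counts = as.integer(colSums(hap)),
      positions = positions + (window_index - 1L) * L, # 1-based genomic POS
      haplotypes = hap
    )
  })
}

#' Simulate one neutral window
#'
#' Generates the polarized site-frequency data of a single window under the
#' neutral Kingman coalescent with infinite-sites mutation.
#'
#' @param config A [sim_pop_config()].
#' @param window_index 1-based window index; must not be a sweep window.
#' @return A [polarized_window()] with per-site derived-allele counts,
#'   physical positions, and the underlying 0/1 haplotype matrix.
#' @export
simulate_neutral_window <- function(config, window_index) {
  validate_window_index(config, window_index)
  if (window_index %in% config$sweep_windows) {
    stop_bad_config("window_index is listed in sweep_windows; use simulate_sweep_window()")
  }
  sim_window_impl(config, as.integer(window_index), sweep = FALSE)
}

#' Simulate one sweep-affected window
#'
#' As [simulate_neutral_window()], except that the genealogy is distorted by
#' a star merger at `config$sweep_age`: each lineage alive then joins a
#' single ancestor with probability `config$sweep_strength`. As
#' `sweep_age -> 0` and `sweep_strength -> 1` this yields a star genealogy,
#' an excess of singletons and high-frequency derived alleles, and strongly
#' negative Tajima's D and Fay & Wu's H.
#'
#' @inheritParams simulate_neutral_window
#' @return A [polarized_window()].
#' @export
simulate_sweep_window <- function(config, window_index) {
  validate_window_index(config, window_index)
  if (!(window_index %in% config$sweep_windows)) {
    stop_bad_config("window_index is not in sweep_windows; use simulate_neutral_window()")
  }
  sim_window_impl(config, as.integer(window_index), sweep = TRUE)
}

validate_window_index <- function(config, window_index) {
  if (!inherits(config, "sim_pop_config")) {
    stop_bad_config("config must be created with sim_pop_config()")
  }
  if (length(window_index) != 1 || is.na(window_index) ||
      window_index < 1 || window_index > config$n_windows) {
    stop_bad_config("window_index must be a single index in [1, n_windows]")
  }
  invisible(TRUE)
}

#' Simulate a full chromosome for one population
#'
#' Runs every window of `config` (neutral or sweep as configured) and
#' returns them as a list of [polarized_window()] objects.
#'
#' @param config A [sim_pop_config()].
#' @return List of `polarized_window` objects, one per window, in genomic
#'   order.
#' @export
simulate_chromosome <- function(config) {
  purrr::map(seq_len(config$n_windows), function(i) {
    if (i %in% config$sweep_windows) {
      simulate_sweep_window(config, i)
    } else {
      simulate_neutral_window(config, i)
    }
  })
}

#' Simulate several populations and write their inputs to disk
#'
#' Produces the on-disk inputs the scan consumes: one VCF per population
#' (phased genotypes, ancestral allele in the `AA` INFO field), a BED file
#' of gene intervals (0-based half-open), and a JSON ground-truth manifest
#' recording the sweep windows and the genes they overlap in each
#' population.
#'
#' @param configs Named list of [sim_pop_config()] objects, one per
#'   population. All must share `n_windows` and `window_length_bp`.
#' @param genes Tibble with columns `chrom`, `start`, `end`, `gene_id`
#'   (0-based half-open coordinates on the simulated chromosome). Use
#'   [make_gene_table()] to lay genes out regularly.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a tibble listing the files written (`population`,
#'   `vcf`), with the BED and manifest paths as attributes.
#' @export
simulate_populations <- function(configs, genes, out_dir) {
  if (length(configs) < 1) stop_bad_config("need at least one population config")
  if (is.null(names(configs)) || any(!nzchar(names(configs)))) {
    names(configs) <- sprintf("pop%02d", seq_along(configs))
  }
  assert_columns(genes, c("chrom", "start", "end", "gene_id"), "genes")
  nw <- unique(purrr::map_int(configs, "n_windows"))
  wl <- unique(purrr::map_int(configs, "window_length_bp"))
  if (length(nw) != 1 || length(wl) != 1) {
    stop_bad_config("all population configs must share n_windows and window_length_bp")
  }
  chrom_len <- nw * wl
  if (any(genes$end > chrom_len) || any(genes$start < 0)) {
    stop_bad_config("gene intervals fall outside the simulated chromosome")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  vcf_paths <- purrr::imap_chr(configs, function(cfg, pop) {
    windows <- simulate_chromosome(cfg)
    path <- file.path(out_dir, paste0(pop, ".vcf"))
    write_population_vcf(windows, path, chrom_len = chrom_len)
    path
  })

  bed_path <- file.path(out_dir, "genes.bed")
  readr::write_tsv(
    genes[, c("chrom", "start", "end", "gene_id")],
    bed_path,
    col_names = FALSE
  )

  manifest <- list(
    chrom_length = chrom_len,
    window_length_bp = wl,
    n_windows = nw,
    populations = purrr::imap(configs, function(cfg, pop) {
      sw <- sort(cfg$sweep_windows)
      sweep_genes <- genes_in_windows(genes, sw, wl)
      list(
        n_haplotypes = cfg$n_haplotypes,
        theta = cfg$theta,
        seed = cfg$seed,
        sweep_age = cfg$sweep_age,
        sweep_strength = cfg$sweep_strength,
        sweep_windows = as.integer(sw),
        sweep_genes = sweep_genes
      )
    })
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  out <- tibble(population = names(configs), vcf = unname(vcf_paths))
  attr(out, "bed") <- bed_path
  attr(out, "manifest") <- manifest_path
  invisible(out)
}

# genes whose interval overlaps any of the given 1-based window indices
genes_in_windows <- function(genes, window_indices, window_length_bp) {
  if (length(window_indices) == 0) {
    return(character())
  }
  starts <- (window_indices - 1) * window_length_bp
  ends <- window_indices * window_length_bp
  hit <- purrr::map_lgl(seq_len(nrow(genes)), function(i) {
    any(genes$start[i] < ends & genes$end[i] > starts)
  })
  sort(unique(genes$gene_id[hit]))
}

#' Lay out a regular gene annotation on the simulated chromosome
#'
#' Divides the chromosome into consecutive regions of `region_length_bp`
#' and places one gene of `gene_length_bp` in the middle of each, giving a
#' simple annotation whose sweep status is unambiguous (a swept region
#' contains exactly one gene).
#'
#' @param n_regions Number of gene regions.
#' @param region_length_bp Length of each region in bp (default 50000, one
#'   analysis window).
#' @param gene_length_bp Length of each gene in bp (default 20000).
#' @return Tibble with `chrom`, `start`, `end`, `gene_id`, `region`.
#' @export
make_gene_table <- function(n_regions, region_length_bp = 50000,
                            gene_length_bp = 20000) {
  if (gene_length_bp > region_length_bp) {
    stop_bad_config("gene_length_bp must not exceed region_length_bp")
  }
  idx <- seq_len(n_regions)
  mid <- (idx - 1) * region_length_bp + region_length_bp / 2
  tibble(
    chrom = "chr1",
    start = as.integer(round(mid - gene_length_bp / 2)),
    end = as.integer(round(mid + gene_length_bp / 2)),
    gene_id = sprintf("gene%04d", idx),
    region = idx
  )
}

#' Simulated-window indices covering given gene regions
#'
#' Maps region indices (see [make_gene_table()]) to the indices of the
#' simulated windows (genealogical blocks) they span, e.g. to build the
#' `sweep_windows` entry of a [sim_pop_config()] that sweeps whole gene
#' regions.
#'
#' @param regions Integer vector of 1-based region indices.
#' @param region_length_bp Region length in bp.
#' @param window_length_bp Simulated-window (block) length in bp; must
#'   divide `region_length_bp`.
#' @return Sorted integer vector of simulated-window indices.
#' @export
units_for_regions <- function(regions, region_length_bp = 50000,
                              window_length_bp = 2000) {
  if (region_length_bp %% window_length_bp != 0) {
    stop_bad_config("window_length_bp must divide region_length_bp")
  }
  k <- region_length_bp %/% window_length_bp
  sort(unlist(lapply(as.integer(regions), function(r) {
    ((r - 1L) * k + 1L):(r * k)
  })))
}

#' Re-tile simulated windows into analysis windows
#'
#' Pools the segregating sites of a list of simulated [polarized_window()]
#' blocks (using their genomic positions) and bins them into the sliding
#' analysis windows of [tile_windows()]. This is the in-memory equivalent
#' of writing a VCF and reading it back with [windows_from_vcf()].
#'
#' @param windows List of `polarized_window` objects on one chromosome,
#'   with positions.
#' @param size,step Analysis-window size and step in bp.
#' @param chrom_len Chromosome length; defaults to the largest block end.
#' @return Window table (as [windows_from_vcf()]), ready for
#'   [compute_window_stats()].
#' @export
retile_windows <- function(windows, size = 50000, step = 10000,
                           chrom_len = NULL) {
  if (length(windows) == 0) stop_domain("no windows to retile")
  n <- windows[[1]]$n
  chrom <- windows[[1]]$chrom
  chrom_len <- chrom_len %||% max(purrr::map_dbl(windows, "end"))
  pos <- unlist(purrr::map(windows, "positions"))
  cnt <- unlist(purrr::map(windows, "derived_counts"))
  if (length(pos) != length(cnt)) {
    stop_domain("windows must carry one position per segregating site")
  }
  w <- tile_windows(chrom_len, size = size, step = step)
  w$chrom <- chrom
  w$n <- n
  w$derived_counts <- purrr::map2(w$start, w$end, function(s, e) {
    as.integer(cnt[pos - 1 >= s & pos - 1 < e])
  })
  w[, c("chrom", "start", "end", "n", "derived_counts")]
}
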