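# End-to-end orchestration: synthetic data -> window statistics -> scan;
# ortholog proteins -> consensus sites -> IDR analysis; one JSON report.

#' Default pipeline configuration
#'
#' A nested list describing every stage of the synthetic end-to-end run.
#' Override any entry by passing a partial list (or a YAML file with the
#' same structure) to [run_pipeline()]; unknown keys are rejected. A single
#' global `seed` deterministically derives every stage's RNG stream.
#'
#' @return Nested configuration list.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    populations = list(
      n_populations = 12L,
      n_haplotypes = 30L,
      theta = 2,
      n_units = 1500L,
      unit_length_bp = 2000L,
      sweep_gene_regions = c(10L, 25L, 40L, 55L),
      sweep_age = 0.05,
      sweep_strength = 1
    ),
    genes = list(region_length_bp = 50000L, gene_length_bp = 20000L),
    windows = list(size = 50000L, step = 10000L),
    scan = list(
      tail_quantile = 0.05,
      concurrence_min_populations = 10L,
      resample_iterations = 1000L,
      statistics = c("tajimas_d", "fay_wu_h"),
      tail_unit = "windows"
    ),
    proteome = list(
      n_species = 8L,
      n_proteins = 20L,
      protein_length = 400L,
      idr_fraction = 0.4,
      planted_site_enrichment = 5,
      expected_sites = 100,
      expected_negative_sites = 150,
      method_sensitivity = 0.8,
      method_specificity = 0.995
    ),
    consensus = list(
      beb_min = 0.90, fubar_min = 0.90,
      meme_max_p = 0.1, fel_max_p = 0.1,
      slac_max_p = 0.1, min_methods = 2L
    ),
    idr = list(min_len = 30L, min_species_frac = 0.5)
  )
}

merge_config <- function(base, override, path = character()) {
  if (is.null(override)) {
    return(base)
  }
  unknown <- setdiff(names(override), names(base))
  if (length(unknown) > 0) {
    stop_bad_config(paste0(
      "unknown configuration key(s): ",
      paste(paste(c(path, ""), collapse = "$"), unknown,
        sep = "", collapse = ", ")
    ))
  }
  for (k in names(override)) {
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      base[[k]] <- merge_config(base[[k]], override[[k]], c(path, k))
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the requested stages in dependency order
#' (`simulate -> stats -> scan` on the population side and
#' `sites -> idr` on the protein side), writes every intermediate table
#' under `out_dir`, and assembles a machine-readable JSON report containing
#' the configuration echo, versions, seeds, warning tallies and every
#' computed statistic. With a fixed seed the report and all outputs are
#' byte-identical across runs.
#'
#' @param config Partial configuration list, or path to a YAML file with
#'   the same structure, merged over [default_run_config()].
#' @param out_dir Output directory.
#' @param stages Character subset of
#'   `c("simulate", "stats", "scan", "sites", "idr")` (default: all).
#'   A stage whose inputs were not produced in this run or a previous run
#'   into the same `out_dir` raises a dependency error naming the missing
#'   file.
#' @param seed Optional override of `config$seed`.
#' @return Invisibly, the report list (also written to
#'   `file.path(out_dir, "report.json")`).
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("selscape_run_"),
                         stages = c("simulate", "stats", "scan", "sites", "idr"),
                         seed = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(default_run_config(), config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  report <- list(
    package_version = as.character(utils::packageVersion("selscape")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config = cfg,
    stages_run = stages,
    warnings = list()
  )
  chrom_len <- cfg$populations$n_units * cfg$populations$unit_length_bp
  n_regions <- chrom_len %/% cfg$genes$region_length_bp
  genes <- make_gene_table(
    n_regions,
    region_length_bp = cfg$genes$region_length_bp,
    gene_length_bp = cfg$genes$gene_length_bp
  )
  sweep_units <- units_for_regions(
    cfg$populations$sweep_gene_regions,
    region_length_bp = cfg$genes$region_length_bp,
    window_length_bp = cfg$populations$unit_length_bp
  )
  pop_names <- sprintf("pop%02d", seq_len(cfg$populations$n_populations))
  need <- function(path, stage) {
    if (!file.exists(path)) {
      abort(
        sprintf("stage '%s' needs missing input: %s", stage, path),
        class = "selscape_dependency_error"
      )
    }
    path
  }

  if ("simulate" %in% stages) {
    configs <- setNames(purrr::map(seq_along(pop_names), function(i) {
      sim_pop_config(
        n_haplotypes = cfg$populations$n_haplotypes,
        theta = cfg$populations$theta,
        n_windows = cfg$populations$n_units,
        window_length_bp = cfg$populations$unit_length_bp,
        sweep_windows = sweep_units,
        sweep_age = cfg$populations$sweep_age,
        sweep_strength = cfg$populations$sweep_strength,
        seed = derive_seed(cfg$seed, 100L, i)
      )
    }), pop_names)
    files <- simulate_populations(configs, genes, out_dir)
    report$simulate <- list(
      populations = pop_names,
      sweep_gene_regions = as.integer(cfg$populations$sweep_gene_regions),
      sweep_genes = genes_in_windows(
        genes, sweep_units, cfg$populations$unit_length_bp
      ),
      vcf_files = basename(files$vcf)
    )
  }

  stats_long <- NULL
  if ("stats" %in% stages) {
    per_pop <- purrr::map(pop_names, function(pop) {
      vcf <- need(file.path(out_dir, paste0(pop, ".vcf")), "stats")
      win <- windows_from_vcf(vcf, size = cfg$windows$size,
        step = cfg$windows$step)
      st <- compute_window_stats(win)
      st$population <- pop
      out <- dplyr::select(st, -"derived_counts")
      readr::write_tsv(
        dplyr::mutate(out, dplyr::across(dplyr::where(is.numeric),
          ~ round(.x, 8))),
        file.path(out_dir, paste0(pop, "_window_stats.tsv")),
        na = "NA"
      )
      list(stats = st, log = attr(win, "site_log"))
    })
    stats_long <- purrr::map_dfr(per_pop, "stats")
    report$warnings$skipped_sites <-
      as.list(Reduce(`+`, purrr::map(per_pop, "log")))
    report$stats <- list(
      n_windows_per_population = sum(stats_long$population == pop_names[1]),
      mean_tajimas_d = mean(stats_long$tajimas_d, na.rm = TRUE),
      mean_fay_wu_h = mean(stats_long$fay_wu_h, na.rm = TRUE),
      mean_pi_per_bp = mean(stats_long$pi_per_bp, na.rm = TRUE),
      mean_S = mean(stats_long$S)
    )
  }

  if ("scan" %in% stages) {
    if (is.null(stats_long)) {
      files <- file.path(out_dir, paste0(pop_names, "_window_stats.tsv"))
      purrr::walk(files, need, stage = "scan")
      stats_long <- purrr::map_dfr(seq_along(files), function(i) {
        st <- readr::read_tsv(files[i], show_col_types = FALSE,
          progress = FALSE)
        if (!"population" %in% names(st)) st$population <- pop_names[i]
        st
      })
    }
    scfg <- scan_config(
      tail_quantile = cfg$scan$tail_quantile,
      concurrence_min_populations = cfg$scan$concurrence_min_populations,
      resample_iterations = cfg$scan$resample_iterations,
      statistics = cfg$scan$statistics,
      tail_unit = cfg$scan$tail_unit,
      seed = derive_seed(cfg$seed, 200L)
    )
    scan <- run_scan(stats_long, genes, scfg)
    readr::write_tsv(scan$gene_ranks,
      file.path(out_dir, "gene_ranks.tsv"), na = "NA")
    readr::write_tsv(scan$concurrence,
      file.path(out_dir, "concurrence.tsv"), na = "NA")
    hits <- scan$concurrence$gene_id[scan$concurrence$concurrent_hit]
    report$scan <- list(
      n_genes = nrow(scan$concurrence),
      concurrent_hits = hits,
      n_concurrent_hits = length(hits)
    )
    if (length(hits) > 0 && length(hits) < nrow(genes)) {
      pooled_stats <- dplyr::filter(stats_long,
        .data$population == pop_names[1])
      res <- pi_background_comparison(pooled_stats, genes, hits, scfg)
      g <- glance(res)
      jsonlite::write_json(
        c(as.list(g), list(p_values = res$iterations$p_value)),
        file.path(out_dir, "pi_resampling.json"),
        auto_unbox = TRUE, digits = NA
      )
      report$scan$pi_comparison <- as.list(g)
    }
  }

  proteome <- NULL
  if ("sites" %in% stages) {
    pcfg <- do.call(sim_proteome_config, c(
      cfg$proteome, list(seed = derive_seed(cfg$seed, 300L))
    ))
    proteome <- simulate_ortholog_proteins(pcfg)
    for (pr in names(proteome$msas)) {
      Biostrings::writeXStringSet(proteome$msas[[pr]],
        file.path(out_dir, paste0(pr, "_msa.fasta")))
    }
    readr::write_tsv(proteome$disorder, file.path(out_dir, "disorder.tsv"))
    readr::write_tsv(proteome$calls, file.path(out_dir, "site_calls.tsv"))
    readr::write_tsv(proteome$ensemble, file.path(out_dir, "ensemble.tsv"))
    readr::write_tsv(proteome$truth$sites,
      file.path(out_dir, "truth_sites.tsv"))

    rule <- do.call(consensus_rule, cfg$consensus)
    consensus <- call_consensus_sites(proteome$calls, rule)
    negatives <- negative_sites(proteome$calls, rule, positive = consensus)
    maps <- purrr::imap_dfr(proteome$msas, function(msa, pr) {
      dplyr::mutate(map_column_to_reference(msa, "ref"), protein = pr)
    })
    consensus <- dplyr::left_join(consensus, maps,
      by = c("protein", "alignment_column"))
    negatives <- dplyr::left_join(negatives, maps,
      by = c("protein", "alignment_column"))
    readr::write_tsv(consensus, file.path(out_dir, "consensus_sites.tsv"))
    readr::write_tsv(negatives, file.path(out_dir, "negative_sites.tsv"))
    lengths <- tibble(
      protein = names(proteome$msas),
      length = purrr::map_int(proteome$msas, function(m) {
        sum(strsplit(as.character(m[["ref"]]), "")[[1]] != "-")
      })
    )
    frac <- selected_fraction(consensus, lengths)
    readr::write_tsv(frac, file.path(out_dir, "selected_fraction.tsv"))
    report$sites <- list(
      n_consensus_sites = nrow(consensus),
      n_negative_sites = nrow(negatives),
      mean_selected_fraction = attr(frac, "mean_fraction"),
      max_selected_fraction = max(frac$fraction)
    )
    attr(proteome, "consensus") <- consensus
    attr(proteome, "negatives") <- negatives
    attr(proteome, "lengths") <- lengths
  }

  if ("idr" %in% stages) {
    if (is.null(proteome)) {
      abort("stage 'idr' needs the 'sites' stage in the same run",
        class = "selscape_dependency_error")
    }
    consensus <- attr(proteome, "consensus")
    negatives <- attr(proteome, "negatives")
    lengths <- attr(proteome, "lengths")
    idr_all <- purrr::imap_dfr(proteome$msas, function(msa, pr) {
      d <- dplyr::filter(proteome$disorder, .data$protein == pr)
      idrs <- consensus_idrs(d, msa, "ref",
        min_len = cfg$idr$min_len,
        min_species_frac = cfg$idr$min_species_frac
      )
      if (nrow(idrs) == 0) {
        return(idrs)
      }
      ext <- dplyr::filter(proteome$ensemble, .data$protein == pr)
      feats <- idr_feature_table(idrs, msa, "ref",
        external = dplyr::select(ext, -"protein"))
      flag_selected_idrs(feats, consensus[!is.na(consensus$residue), ])
    })
    idr_all <- fraction_negative_per_idr(
      negatives[!is.na(negatives$residue), ], idr_all, lengths
    )
    readr::write_tsv(
      dplyr::mutate(idr_all, dplyr::across(dplyr::where(is.numeric),
        ~ round(.x, 8))),
      file.path(out_dir, "idr_features.tsv"), na = "NA"
    )

    k <- sum(purrr::map_lgl(seq_len(nrow(consensus)), function(i) {
      r <- consensus$residue[i]
      if (is.na(r)) {
        return(FALSE)
      }
      any(idr_all$protein == consensus$protein[i] &
        idr_all$start <= r & idr_all$end >= r)
    }))
    enr <- binomial_enrichment(
      k_in_idr = k,
      m_total = nrow(consensus),
      idr_length_total = sum(idr_all$length),
      analyzed_length_total = sum(lengths$length)
    )
    report$idr <- list(
      n_idrs = nrow(idr_all),
      idr_fraction = sum(idr_all$length) / sum(lengths$length),
      enrichment = as.list(tidy(enr))
    )

    groups <- purrr::map_dfr(
      c("fcr_sd", "ncpr_sd", "shd_sd", "sconf_per_n", "nu"),
      function(f) {
        if (!f %in% names(idr_all)) {
          return(NULL)
        }
        sel <- idr_all[[f]][idr_all$has_positive_site]
        non <- idr_all[[f]][!idr_all$has_positive_site]
        if (sum(!is.na(sel)) == 0 || sum(!is.na(non)) == 0) {
          return(NULL)
        }
        compare_groups(sel, non, feature = f)
      }
    )
    report$idr$group_comparisons <-
      purrr::map(seq_len(nrow(groups)), function(i) as.list(groups[i, ]))
    report$idr$constraint_correlations <- purrr::map(
      c("sconf_per_n", "nu"),
      function(f) {
        if (!f %in% names(idr_all) || sum(!is.na(idr_all[[f]])) < 3) {
          return(NULL)
        }
        ok <- !is.na(idr_all[[f]])
        ct <- constraint_feature_correlation(
          idr_all$fraction_negative[ok], idr_all[[f]][ok]
        )
        c(list(feature = f), as.list(ct))
      }
    )

    # cross-annotation check: per-protein disorder fraction from the raw
    # reference-species calls vs from the consensus IDR intervals
    raw_frac <- proteome$disorder |>
      dplyr::filter(.data$species == "ref") |>
      dplyr::group_by(.data$protein) |>
      dplyr::summarise(raw = mean(.data$disordered), .groups = "drop")
    idr_frac <- idr_all |>
      dplyr::group_by(.data$protein) |>
      dplyr::summarise(idr_len = sum(.data$length), .groups = "drop") |>
      dplyr::right_join(lengths, by = "protein") |>
      dplyr::mutate(cons = dplyr::coalesce(.data$idr_len, 0L) / .data$length)
    both <- dplyr::inner_join(raw_frac, idr_frac, by = "protein")
    if (nrow(both) >= 3) {
      dc <- disorder_fraction_correlation(both$raw, both$cons)
      report$idr$disorder_fraction_correlation <- as.list(dc)
    }
  }

  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  invisible(report)
}

#' Render a human-readable summary of a pipeline report
#'
#' Formats the per-gene concurrence counts, enrichment p-values and
#' group-comparison medians of a [run_pipeline()] report as aligned text,
#' and returns the concurrence table so it can be re-written as TSV.
#'
#' @param report A report list from [run_pipeline()], or the path to a
#'   `report.json` / run directory.
#' @param out_prefix Optional path prefix; when given, writes
#'   `<out_prefix>_summary.txt` and `<out_prefix>_concurrence.tsv`.
#' @return List with `text` (character vector of lines) and `table`
#'   (concurrence tibble, possibly empty).
#' @export
render_summary <- function(report, out_prefix = NULL) {
  run_dir <- NULL
  if (is.character(report)) {
    path <- report
    if (dir.exists(path)) {
      run_dir <- path
      path <- file.path(path, "report.json")
    } else {
      run_dir <- dirname(path)
    }
    if (!file.exists(path)) {
      abort(paste0("report not found: ", path),
        class = "selscape_format_error")
    }
    report <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.list(report) || is.null(report$seed)) {
    abort("malformed report: expected the JSON written by run_pipeline()",
      class = "selscape_format_error")
  }
  lines <- c(
    sprintf("selscape run summary (seed %s)", report$seed),
    strrep("=", 40)
  )
  tbl <- tibble(gene_id = character(0))
  if (!is.null(run_dir) && file.exists(file.path(run_dir, "concurrence.tsv"))) {
    tbl <- readr::read_tsv(file.path(run_dir, "concurrence.tsv"),
      show_col_types = FALSE, progress = FALSE)
  }
  if (!is.null(report$scan)) {
    n_hits <- report$scan$n_concurrent_hits %||% 0
    if (n_hits == 0) {
      lines <- c(lines, "", "Concurrent hits: none (no gene passed the concurrence rule)")
    } else {
      lines <- c(lines, "", sprintf("Concurrent hits (%d):", n_hits),
        paste(" ", unlist(report$scan$concurrent_hits)))
    }
    if (nrow(tbl) > 0) {
      top <- utils::head(tbl[order(-tbl$concurrent_hit, tbl$gene_id), ], 15)
      lines <- c(lines, "", "Per-gene concurrence counts (top rows):",
        utils::capture.output(print(as.data.frame(top), row.names = FALSE)))
    }
    if (!is.null(report$scan$pi_comparison)) {
      pc <- report$scan$pi_comparison
      lines <- c(lines, "", sprintf(
        "Nucleotide diversity, candidates vs background: median resampled p = %.4g; candidate-lower fraction = %.3f; pooled p = %.4g",
        pc$median_p, pc$frac_lower, pc$pooled_p
      ))
    }
  }
  if (!is.null(report$idr)) {
    en <- report$idr$enrichment
    lines <- c(lines, "", sprintf(
      "IDR enrichment: %d of %d consensus sites in IDRs (expected fraction %.3f); binomial p = %.4g",
      en$k, en$m, en$p0, en$p_value
    ))
    gc <- report$idr$group_comparisons
    if (!is.null(gc) && length(gc) > 0) {
      if (!is.data.frame(gc)) gc <- dplyr::bind_rows(gc)
      lines <- c(lines, "", "Selected vs non-selected IDR features:")
      for (i in seq_len(nrow(gc))) {
        lines <- c(lines, sprintf(
          "  %-12s median %.4f vs %.4f, Wilcoxon p = %.4g",
          gc$feature[i], gc$median_selected[i],
          gc$median_non_selected[i], gc$p_value[i]
        ))
      }
    }
  }
  if (!is.null(out_prefix)) {
    writeLines(lines, paste0(out_prefix, "_summary.txt"))
    readr::write_tsv(tbl, paste0(out_prefix, "_concurrence.tsv"))
  }
  list(text = lines, table = tbl)
}
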