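#' Consensus rule for per-method selection calls
#'
#' Thresholds under which each site-level method counts as a detection:
#' posterior probability at least `beb_min` / `fubar_min` for the Bayesian
#' methods, p-value below `meme_max_p` / `fel_max_p` for the likelihood
#' methods (strict inequality, matching how those cutoffs are stated), and
#' a site is a consensus positive-selection target only when at least
#' `min_methods` methods detect it. SLAC identifies negatively selected
#' sites (p-value at most `slac_max_p`, inclusive) and never contributes to
#' the positive consensus.
#'
#' @param beb_min,fubar_min Posterior-probability cutoffs (default 0.90).
#' @param meme_max_p,fel_max_p P-value cutoffs (default 0.1, strict).
#' @param slac_max_p P-value cutoff for negative sites (default 0.1,
#'   inclusive).
#' @param min_methods Minimum number of concordant methods (default 2).
#' @return A list of class `consensus_rule`.
#' @export
consensus_rule <- function(beb_min = 0.90, fubar_min = 0.90,
                           meme_max_p = 0.1, fel_max_p = 0.1,
                           slac_max_p = 0.1, min_methods = 2L) {
  thr <- c(beb_min, fubar_min, meme_max_p, fel_max_p, slac_max_p)
  if (any(thr <= 0 | thr >= 1)) {
    stop_bad_config("all thresholds must lie strictly between 0 and 1")
  }
  if (min_methods < 1) stop_bad_config("min_methods must be >= 1")
  structure(
    list(
      beb_min = beb_min, fubar_min = fubar_min,
      meme_max_p = meme_max_p, fel_max_p = fel_max_p,
      slac_max_p = slac_max_p, min_methods = as.integer(min_methods)
    ),
    class = "consensus_rule"
  )
}

POSITIVE_METHODS <- c("BEB", "FUBAR", "MEME", "FEL")
ALL_METHODS <- c(POSITIVE_METHODS, "SLAC")

check_calls <- function(calls) {
  assert_columns(calls, c("method", "alignment_column", "score", "direction"),
    "site-call table")
  bad <- setdiff(unique(calls$method), ALL_METHODS)
  if (length(bad) > 0) {
    abort(paste0("unknown method name(s): ", paste(bad, collapse = ", ")),
      class = "selscape_schema_error")
  }
  if (any(calls$score < 0 | calls$score > 1, na.rm = TRUE)) {
    stop_domain("scores must lie in [0, 1]")
  }
  if (any(calls$alignment_column < 1, na.rm = TRUE)) {
    stop_domain("alignment columns are 1-based")
  }
  invisible(calls)
}

method_passes <- function(method, score, rule) {
  dplyr::case_when(
    method == "BEB" ~ score >= rule$beb_min,
    method == "FUBAR" ~ score >= rule$fubar_min,
    method == "MEME" ~ score < rule$meme_max_p,
    method == "FEL" ~ score < rule$fel_max_p,
    TRUE ~ FALSE
  )
}

#' Map alignment columns to reference residue numbers
#'
#' Builds the bijection between the non-gap columns of the reference row of
#' an MSA and 1-based residue numbers on the reference protein. Gap columns
#' map to nothing.
#'
#' @param msa A `Biostrings::AAStringSet` alignment (equal widths).
#' @param reference Name of the reference sequence in `msa`.
#' @return Tibble with columns `alignment_column` and `residue`, one row
#'   per non-gap reference column.
#' @export
map_column_to_reference <- function(msa, reference = "ref") {
  if (!reference %in% names(msa)) {
    abort(paste0("reference sequence '", reference, "' absent from the MSA"),
      class = "selscape_lookup_error")
  }
  chars <- strsplit(as.character(msa[[reference]]), "")[[1]]
  non_gap <- which(chars != "-")
  tibble(
    alignment_column = non_gap,
    residue = seq_along(non_gap)
  )
}

#' Call consensus positively selected sites
#'
#' A column is a consensus positive-selection target iff the number of
#' methods among BEB, FUBAR, MEME, FEL passing their own threshold at that
#' column is at least `rule$min_methods`. SLAC rows are ignored here.
#' Duplicate (method, column) rows are collapsed to the most significant
#' score before counting.
#'
#' @param calls Tibble with columns `method`, `alignment_column`, `score`,
#'   `direction` (an optional `protein` column partitions the calls).
#' @param rule A [consensus_rule()].
#' @return Tibble of consensus columns with `alignment_column`,
#'   `n_methods` (count of passing methods) and `methods`
#'   (comma-separated), plus `protein` when present in the input.
#' @export
call_consensus_sites <- function(calls, rule = consensus_rule()) {
  check_calls(calls)
  grp <- if ("protein" %in% names(calls)) c("protein", "alignment_column") else "alignment_column"
  pos <- calls |>
    dplyr::filter(.data$method %in% POSITIVE_METHODS) |>
    # best score per (method, column): max posterior, min p-value
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "method")))) |>
    dplyr::summarise(
      score = if (.data$method[1] %in% c("BEB", "FUBAR")) max(.data$score) else min(.data$score),
      .groups = "drop"
    ) |>
    dplyr::filter(method_passes(.data$method, .data$score, rule)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      n_methods = dplyr::n_distinct(.data$method),
      methods = paste(sort(unique(.data$method)), collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_methods >= rule$min_methods)
  dplyr::arrange(pos, dplyr::across(dplyr::all_of(grp)))
}

#' Extract negatively selected sites
#'
#' Columns with a SLAC call of direction `"negative"` and p-value at most
#' `rule$slac_max_p` (inclusive boundary). Overlap with the positive
#' consensus set is not forbidden; when `positive` is supplied, overlapping
#' columns are reported with a warning.
#'
#' @inheritParams call_consensus_sites
#' @param positive Optional output of [call_consensus_sites()] used only to
#'   warn on overlap.
#' @return Tibble with `alignment_column` and `score` (plus `protein` when
#'   present).
#' @export
negative_sites <- function(calls, rule = consensus_rule(), positive = NULL) {
  check_calls(calls)
  grp <- if ("protein" %in% names(calls)) c("protein", "alignment_column") else "alignment_column"
  hits <- dplyr::filter(
    calls,
    .data$method == "SLAC",
    .data$direction == "negative",
    .data$score <= rule$slac_max_p
  )
  neg <- if (nrow(hits) == 0) {
    dplyr::bind_cols(hits[grp], tibble(score = numeric()))
  } else {
    hits |>
      dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
      dplyr::summarise(score = min(.data$score), .groups = "drop")
  }
  if (!is.null(positive)) {
    overlap <- dplyr::inner_join(
      neg[grp], positive[grp],
      by = grp
    )
    if (nrow(overlap) > 0) {
      warn(sprintf(
        "%d column(s) are in both the positive and negative site sets",
        nrow(overlap)
      ))
    }
  }
  neg
}

#' Fraction of selected sites per protein
#'
#' For each protein, the number of (mapped) selected sites divided by the
#' protein length; the across-protein mean is attached as attribute
#' `mean_fraction`.
#'
#' @param sites Tibble with a `protein` column and one row per selected
#'   reference residue.
#' @param protein_lengths Tibble with columns `protein` and `length`.
#' @return Tibble with `protein`, `n_sites`, `length`, `fraction`;
#'   attribute `mean_fraction` holds the mean across proteins.
#' @export
selected_fraction <- function(sites, protein_lengths) {
  assert_columns(protein_lengths, c("protein", "length"), "protein lengths")
  if (any(protein_lengths$length <= 0)) {
    stop_domain("protein lengths must be positive")
  }
  counts <- if (nrow(sites) > 0) {
    assert_columns(sites, "protein", "site table")
    dplyr::count(sites, .data$protein, name = "n_sites")
  } else {
    tibble(protein = character(), n_sites = integer())
  }
  out <- protein_lengths |>
    dplyr::left_join(counts, by = "protein") |>
    dplyr::mutate(
      n_sites = dplyr::coalesce(.data$n_sites, 0L),
      fraction = .data$n_sites / .data$length
    ) |>
    dplyr::select("protein", "n_sites", "length", "fraction")
  attr(out, "mean_fraction") <- mean(out$fraction)
  out
}

#' Fraction of negatively selected sites per IDR
#'
#' Counts negative sites falling inside each IDR interval (closed interval:
#' boundary residues count as inside) and divides by the IDR residue
#' length.
#'
#' @param neg_sites Tibble with `protein` and `residue` (reference residue
#'   numbers of negatively selected sites).
#' @param idrs Tibble with `protein`, `start`, `end` (1-based inclusive
#'   residue coordinates) and optionally `length`.
#' @param protein_lengths Optional tibble (`protein`, `length`) used to
#'   range-check the intervals.
#' @return `idrs` with `n_negative` and `fraction_negative` appended.
#' @export
fraction_negative_per_idr <- function(neg_sites, idrs,
                                      protein_lengths = NULL) {
  assert_columns(idrs, c("protein", "start", "end"), "IDR table")
  if (!is.null(protein_lengths)) {
    plen <- dplyr::rename(
      protein_lengths[, c("protein", "length")],
      protein_length = "length"
    )
    chk <- dplyr::inner_join(idrs, plen, by = "protein")
    if (any(chk$end > chk$protein_length) || any(chk$start < 1)) {
      abort("IDR interval outside the protein", class = "selscape_range_error")
    }
  }
  idrs |>
    dplyr::mutate(
      idr_length = .data$end - .data$start + 1,
      n_negative = purrr::pmap_int(
        list(.data$protein, .data$start, .data$end),
        function(pr, s, e) {
          if (nrow(neg_sites) == 0) {
            return(0L)
          }
          sum(neg_sites$protein == pr &
            neg_sites$residue >= s & neg_sites$residue <= e)
        }
      ),
      fraction_negative = .data$n_negative / .data$idr_length
    ) |>
    dplyr::select(-"idr_length")
}
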