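# IDR construction and sequence descriptors: ortholog-consensus interval
# calling, FCR / NCPR / SHD, and the per-IDR, per-ortholog feature table.

# Kyte-Doolittle hydropathy rescaled to [0, 1] (lambda = (KD + 4.5) / 9)
KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

#' Configuration of IDR sequence descriptors
#'
#' @param positive_residues Residues counted as positively charged
#'   (default K, R; add H with `include_histidine`).
#' @param negative_residues Residues counted as negatively charged
#'   (default D, E).
#' @param hydropathy_scale Named vector mapping each of the 20 residues to
#'   a hydropathy lambda in `[0, 1]`; default is the Kyte-Doolittle scale
#'   rescaled to the unit interval.
#' @param shd_exponent Distance-decay exponent beta of the SHD descriptor
#'   (default 1).
#' @param include_histidine Count histidine as positively charged
#'   (default `FALSE`).
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(positive_residues = c("K", "R"),
                           negative_residues = c("D", "E"),
                           hydropathy_scale = NULL,
                           shd_exponent = 1,
                           include_histidine = FALSE) {
  if (is.null(hydropathy_scale)) {
    hydropathy_scale <- (KD_HYDROPATHY + 4.5) / 9
  }
  if (!all(names(KD_HYDROPATHY) %in% names(hydropathy_scale))) {
    stop_bad_config("hydropathy_scale must cover all 20 standard residues")
  }
  if (any(hydropathy_scale < 0 | hydropathy_scale > 1)) {
    stop_bad_config("hydropathy_scale values must lie in [0, 1]")
  }
  if (shd_exponent <= 0) stop_bad_config("shd_exponent must be > 0")
  if (include_histidine) {
    positive_residues <- union(positive_residues, "H")
  }
  structure(
    list(
      positive_residues = positive_residues,
      negative_residues = negative_residues,
      hydropathy_scale = hydropathy_scale,
      shd_exponent = shd_exponent
    ),
    class = "feature_config"
  )
}

seq_to_chars <- function(sequence) {
  if (length(sequence) == 1 && is.character(sequence)) {
    strsplit(sequence, "")[[1]]
  } else {
    as.character(sequence)
  }
}

#' Fraction of charged residues and net charge per residue
#'
#' `FCR = (n+ + n-) / N` and `NCPR = (n+ - n-) / N`, with positive and
#' negative residue sets from `config`.
#'
#' @param sequence Character scalar (or vector of single residues).
#' @param config A [feature_config()].
#' @return Named list with elements `fcr` and `ncpr`.
#' @export
fcr_ncpr <- function(sequence, config = feature_config()) {
  chars <- seq_to_chars(sequence)
  n <- length(chars)
  if (n == 0) stop_domain("sequence is empty")
  npos <- sum(chars %in% config$positive_residues)
  nneg <- sum(chars %in% config$negative_residues)
  list(fcr = (npos + nneg) / n, ncpr = (npos - nneg) / n)
}

#' Sequence hydropathy decoration
#'
#' A patterning descriptor of how hydropathy is distributed along the
#' chain: \eqn{SHD = (1/N) \sum_{i<j} (\lambda_i + \lambda_j) (j-i)^{-\beta}}
#' with per-residue hydropathies \eqn{\lambda} in `[0, 1]` and decay
#' exponent \eqn{\beta} from `config`. Symmetric under sequence reversal.
#'
#' @inheritParams fcr_ncpr
#' @return A number.
#' @export
shd <- function(sequence, config = feature_config()) {
  chars <- seq_to_chars(sequence)
  n <- length(chars)
  if (n < 2) stop_domain("SHD needs at least 2 residues")
  lambda <- config$hydropathy_scale[chars]
  if (anyNA(lambda)) {
    stop_bad_config(paste0(
      "residue(s) missing from the hydropathy scale: ",
      paste(unique(chars[is.na(lambda)]), collapse = ", ")
    ))
  }
  total <- 0
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    total <- total + sum((lambda[i] + lambda[j]) * (j - i)^(-config$shd_exponent))
  }
  total / n
}

# map each species' own residue numbering to MSA columns
species_residue_columns <- function(msa) {
  purrr::imap(as.list(as.character(msa)), function(s, nm) {
    which(strsplit(s, "")[[1]] != "-")
  })
}

#' Call ortholog-consensus IDR intervals
#'
#' Per MSA column, computes the fraction of species (among those with a
#' non-gap residue at that column) whose residue is called disordered;
#' columns with fraction at least `min_species_frac` (inclusive) are
#' consensus-disordered. Maximal runs of consensus-disordered, non-gap
#' reference residues of length at least `min_len` become IDR intervals on
#' the reference protein.
#'
#' @param disorder Tibble of per-species per-residue calls: columns
#'   `species`, `residue` (1-based in that species' ungapped sequence) and
#'   `disordered` (logical). A `protein` column, if present, must be
#'   constant.
#' @param msa `Biostrings::AAStringSet` alignment containing every species
#'   in `disorder`.
#' @param reference Reference sequence name (default `"ref"`).
#' @param min_len Minimum IDR length in residues (default 30).
#' @param min_species_frac Minimum fraction of species calling a column
#'   disordered (default 0.5).
#' @return Tibble with `protein` (if supplied), `start`, `end`, `length`
#'   (1-based inclusive reference residue coordinates).
#' @export
consensus_idrs <- function(disorder, msa, reference = "ref",
                           min_len = 30L, min_species_frac = 0.5) {
  assert_columns(disorder, c("species", "residue", "disordered"),
    "disorder table")
  if (!reference %in% names(msa)) {
    abort(paste0("reference sequence '", reference, "' absent from the MSA"),
      class = "selscape_lookup_error")
  }
  sp_in_data <- unique(disorder$species)
  missing_sp <- setdiff(sp_in_data, names(msa))
  if (length(missing_sp) > 0) {
    abort(paste0("species absent from the MSA: ",
      paste(missing_sp, collapse = ", ")), class = "selscape_lookup_error")
  }
  width <- unique(Biostrings::width(msa))
  if (length(width) != 1) stop_domain("MSA rows must have equal width")
  res_cols <- species_residue_columns(msa)

  called <- integer(width) # species with a call at each column
  dis <- integer(width) # of which disordered
  for (sp in sp_in_data) {
    d <- disorder[disorder$species == sp, ]
    cols_of_res <- res_cols[[sp]]
    bad <- d$residue < 1 | d$residue > length(cols_of_res)
    if (any(bad)) stop_domain("disorder call beyond the species' sequence length")
    cols <- cols_of_res[d$residue]
    called[cols] <- called[cols] + 1L
    dis[cols] <- dis[cols] + as.integer(d$disordered)
  }
  frac <- ifelse(called > 0, dis / called, 0)
  consensus_col <- frac >= min_species_frac

  ref_cols <- res_cols[[reference]]
  ref_dis <- consensus_col[ref_cols] # per reference residue
  runs <- rle(ref_dis)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values & runs$lengths >= min_len
  out <- tibble(
    start = as.integer(starts[keep]),
    end = as.integer(ends[keep])
  )
  out$length <- out$end - out$start + 1L
  if ("protein" %in% names(disorder) && nrow(out) > 0) {
    out <- dplyr::mutate(out, protein = unique(disorder$protein)[1], .before = 1)
  } else if ("protein" %in% names(disorder)) {
    out <- dplyr::mutate(out, protein = character(0), .before = 1)
  }
  out
}

#' Per-IDR, per-ortholog feature table
#'
#' Projects each reference IDR interval through the MSA into every
#' ortholog, extracts the ortholog's (gap-free) subsequence, and computes
#' FCR, NCPR and SHD for each; per-IDR summaries are the mean and the
#' sample (n-1) standard deviation across orthologs. Externally predicted
#' ensemble features (`sconf_per_n`, `nu`) are joined, never computed: the
#' external table may be per-IDR (columns `protein`, `idr_start`,
#' `idr_end`, `sconf_per_n`, `nu`) or per-ortholog (additionally
#' `species`), in which case they are summarized like the sequence
#' features.
#'
#' IDR-ortholog pairs whose projected subsequence has fewer than 2 residues
#' are skipped with a warning.
#'
#' @param idrs IDR tibble (`start`, `end`, optional `protein`), e.g. from
#'   [consensus_idrs()].
#' @param msa `Biostrings::AAStringSet` alignment.
#' @param reference Reference sequence name.
#' @param external Optional ensemble-feature table (see above).
#' @param config A [feature_config()].
#' @return Tibble with one row per IDR: coordinates, `n_orthologs`, then
#'   `<feature>_mean` and `<feature>_sd` for fcr, ncpr, shd (and ensemble
#'   features when per-ortholog). Attribute `per_ortholog` holds the long
#'   per-ortholog table.
#' @export
idr_feature_table <- function(idrs, msa, reference = "ref",
                              external = NULL, config = feature_config()) {
  assert_columns(idrs, c("start", "end"), "IDR table")
  res_cols <- species_residue_columns(msa)
  ref_cols <- res_cols[[reference]]
  if (is.null(ref_cols)) {
    abort(paste0("reference sequence '", reference, "' absent from the MSA"),
      class = "selscape_lookup_error")
  }
  aln <- purrr::map(as.list(as.character(msa)), function(s) strsplit(s, "")[[1]])

  per <- purrr::pmap_dfr(
    list(seq_len(nrow(idrs)), idrs$start, idrs$end),
    function(i, s, e) {
      if (s < 1 || e > length(ref_cols)) {
        abort("IDR interval outside the reference protein",
          class = "selscape_range_error")
      }
      cols <- ref_cols[s]:ref_cols[e]
      purrr::map_dfr(names(msa), function(sp) {
        sub <- aln[[sp]][cols]
        sub <- sub[sub != "-"]
        if (length(sub) < 2) {
          warn(sprintf(
            "IDR %d-%d: ortholog %s subsequence shorter than 2 residues; skipped",
            s, e, sp
          ))
          return(NULL)
        }
        ch <- fcr_ncpr(sub, config)
        tibble(
          idr_index = i, species = sp,
          fcr = ch$fcr, ncpr = ch$ncpr, shd = shd(sub, config)
        )
      })
    }
  )

  feature_cols <- c("fcr", "ncpr", "shd")
  if (!is.null(external) && "species" %in% names(external)) {
    assert_columns(external, c("idr_start", "idr_end", "species",
      "sconf_per_n", "nu"), "ensemble-feature table")
    ext <- dplyr::mutate(external,
      idr_index = match_idr(external, idrs)
    )
    per <- dplyr::left_join(per,
      ext[, c("idr_index", "species", "sconf_per_n", "nu")],
      by = c("idr_index", "species")
    )
    feature_cols <- c(feature_cols, "sconf_per_n", "nu")
  }

  summary <- per |>
    dplyr::group_by(.data$idr_index) |>
    dplyr::summarise(
      n_orthologs = dplyr::n(),
      dplyr::across(
        dplyr::all_of(feature_cols),
        list(mean = ~ mean(.x, na.rm = TRUE), sd = ~ sd(.x, na.rm = TRUE))
      ),
      .groups = "drop"
    )
  out <- dplyr::bind_cols(
    idrs[summary$idr_index, , drop = FALSE],
    dplyr::select(summary, -"idr_index")
  )
  if (!is.null(external) && !"species" %in% names(external)) {
    assert_columns(external, c("idr_start", "idr_end", "sconf_per_n", "nu"),
      "ensemble-feature table")
    join_by <- c("start" = "idr_start", "end" = "idr_end")
    ext <- external
    if ("protein" %in% names(out) && "protein" %in% names(ext)) {
      join_by <- c("protein", join_by)
    }
    out <- dplyr::left_join(
      out, ext[, intersect(names(ext), c("protein", "idr_start", "idr_end",
        "sconf_per_n", "nu"))],
      by = join_by
    )
  }
  attr(out, "per_ortholog") <- per
  out
}

match_idr <- function(external, idrs) {
  key_ext <- paste(external$idr_start, external$idr_end)
  key_idr <- paste(idrs$start, idrs$end)
  match(key_ext, key_idr)
}

#' Flag IDRs containing a consensus positively selected site
#'
#' An IDR is "selected" iff it contains at least one consensus positive
#' site (closed interval on reference residues).
#'
#' @param idrs IDR tibble (`start`, `end`, optional `protein`).
#' @param sites Tibble of consensus sites with `residue` (and `protein`
#'   when IDRs carry one).
#' @return `idrs` with logical column `has_positive_site` appended.
#' @export
flag_selected_idrs <- function(idrs, sites) {
  assert_columns(idrs, c("start", "end"), "IDR table")
  by_protein <- "protein" %in% names(idrs) && "protein" %in% names(sites)
  idrs$has_positive_site <- purrr::pmap_lgl(
    list(seq_len(nrow(idrs)), idrs$start, idrs$end),
    function(i, s, e) {
      if (nrow(sites) == 0) {
        return(FALSE)
      }
      sel <- sites$residue >= s & sites$residue <= e
      if (by_protein) sel <- sel & sites$protein == idrs$protein[i]
      any(sel)
    }
  )
  idrs
}
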