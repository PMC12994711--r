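# Ortholog-proteome generator: reference proteins with disorder-biased
# segments, diverged orthologs aligned in an MSA, planted positively and
# negatively selected sites, per-species disorder calls, noisy per-method
# site-call tables and ensemble-feature tables -- all with ground truth.

# residue pools: disorder-promoting residues dominate inside IDR segments
AA20 <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)
DISORDER_AA <- c("P", "E", "S", "K", "Q", "G", "A", "R", "D", "T")

#' Configuration for the ortholog-proteome simulator
#'
#' Describes a simulated proteome of `n_proteins` reference proteins, each
#' of length `protein_length`, with disorder-biased segments, orthologs in
#' `n_species` species, planted selected sites and noisy per-method call
#' tables.
#'
#' Positively selected sites are planted by a per-residue Bernoulli draw
#' whose probability is `planted_site_enrichment` times higher inside IDR
#' segments than outside; the base rate is chosen so the expected total
#' number of true sites equals `expected_sites`. Each selection method
#' (BEB, FUBAR, MEME, FEL) reports a true site with probability
#' `method_sensitivity` (score drawn on the passing side of that method's
#' threshold) and each non-site with probability `1 - method_specificity`.
#' SLAC analogously reports planted negatively selected sites.
#'
#' @param n_species Number of ortholog species (reference included).
#' @param n_proteins Number of proteins.
#' @param protein_length Residues per reference protein.
#' @param idr_segments Optional list (one element per protein) of tibbles
#'   with columns `start`, `end`, `disorder_bias`; `NULL` lays out
#'   non-overlapping segments covering about `idr_fraction` of each
#'   protein with disorder probability `disorder_bias_default`.
#' @param idr_fraction Target fraction of residues inside IDR segments when
#'   segments are auto-generated (default 0.4). This is the across-proteome
#'   mean; individual proteins vary by `idr_fraction_spread`.
#' @param idr_fraction_spread Half-range of the deterministic per-protein
#'   variation of the IDR fraction around `idr_fraction` (default 0.1,
#'   i.e. fractions span `idr_fraction` +/- 0.1 evenly across proteins
#'   while averaging exactly `idr_fraction`).
#' @param disorder_bias_default Per-residue probability of a disordered
#'   call inside auto-generated segments (default 0.95).
#' @param background_disorder Per-residue probability of a (noise)
#'   disordered call outside segments (default 0.05).
#' @param planted_site_enrichment Enrichment ratio rho >= 0 of the
#'   per-residue selected-site probability inside vs. outside IDRs.
#' @param expected_sites Expected total number of planted positive sites.
#' @param expected_negative_sites Expected total number of planted
#'   negatively selected sites (placed uniformly).
#' @param method_sensitivity Named numeric vector of per-method detection
#'   probabilities (names among BEB, FUBAR, MEME, FEL, SLAC); a single
#'   unnamed value recycles to all methods.
#' @param method_specificity As `method_sensitivity`, for 1 minus the
#'   per-residue false-call probability.
#' @param substitution_rate Per-residue substitution probability between
#'   the reference and each ortholog.
#' @param deletion_rate Per-residue probability that an ortholog carries a
#'   gap at a reference position.
#' @param insertions_per_protein Expected number of single-residue
#'   insertion columns (gap in the reference) per protein.
#' @param seed Integer seed.
#' @return A list of class `sim_proteome_config`.
#' @export
sim_proteome_config <- function(n_species = 8L,
                                n_proteins = 20L,
                                protein_length = 400L,
                                idr_segments = NULL,
                                idr_fraction = 0.4,
                                idr_fraction_spread = 0.1,
                                disorder_bias_default = 0.95,
                                background_disorder = 0.05,
                                planted_site_enrichment = 1,
                                expected_sites = 100,
                                expected_negative_sites = 150,
                                method_sensitivity = 0.8,
                                method_specificity = 0.995,
                                substitution_rate = 0.05,
                                deletion_rate = 0.01,
                                insertions_per_protein = 2,
                                seed = 1L) {
  if (n_species < 2) stop_bad_config("n_species must be >= 2")
  if (n_proteins < 1) stop_bad_config("n_proteins must be >= 1")
  if (protein_length < 40) stop_bad_config("protein_length must be >= 40")
  if (planted_site_enrichment < 0) stop_bad_config("planted_site_enrichment must be >= 0")
  if (idr_fraction <= 0 || idr_fraction >= 1) {
    stop_bad_config("idr_fraction must lie strictly between 0 and 1")
  }
  if (idr_fraction_spread < 0 ||
      idr_fraction - idr_fraction_spread <= 0.05 ||
      idr_fraction + idr_fraction_spread >= 0.95) {
    stop_bad_config("idr_fraction +/- idr_fraction_spread must stay within (0.05, 0.95)")
  }
  methods <- c("BEB", "FUBAR", "MEME", "FEL", "SLAC")
  expand <- function(v, what) {
    if (is.null(names(v)) && length(v) == 1) {
      v <- setNames(rep(v, length(methods)), methods)
    }
    if (!all(methods %in% names(v))) {
      stop_bad_config(paste0(what, " must name all of ", paste(methods, collapse = ", ")))
    }
    if (any(v < 0 | v > 1)) stop_bad_config(paste0(what, " must lie in [0, 1]"))
    v[methods]
  }
  if (!is.null(idr_segments)) {
    if (length(idr_segments) != n_proteins) {
      stop_bad_config("idr_segments must have one element per protein")
    }
    for (seg in idr_segments) {
      assert_columns(seg, c("start", "end", "disorder_bias"), "idr_segments element")
      if (nrow(seg) > 0) {
        seg <- dplyr::arrange(seg, .data$start)
        if (any(seg$start < 1) || any(seg$end > protein_length) ||
            any(seg$end < seg$start)) {
          stop_bad_config("idr_segments must lie within the protein with end >= start")
        }
        if (nrow(seg) > 1 && any(seg$start[-1] <= seg$end[-nrow(seg)])) {
          stop_bad_config("idr_segments must be non-overlapping")
        }
      }
    }
  }
  structure(
    list(
      n_species = as.integer(n_species),
      n_proteins = as.integer(n_proteins),
      protein_length = as.integer(protein_length),
      idr_segments = idr_segments,
      idr_fraction = idr_fraction,
      idr_fraction_spread = idr_fraction_spread,
      disorder_bias_default = disorder_bias_default,
      background_disorder = background_disorder,
      planted_site_enrichment = planted_site_enrichment,
      expected_sites = expected_sites,
      expected_negative_sites = expected_negative_sites,
      method_sensitivity = expand(method_sensitivity, "method_sensitivity"),
      method_specificity = expand(method_specificity, "method_specificity"),
      substitution_rate = substitution_rate,
      deletion_rate = deletion_rate,
      insertions_per_protein = insertions_per_protein,
      seed = as.integer(seed)
    ),
    class = "sim_proteome_config"
  )
}

# two IDR segments per protein; per-protein fractions span
# idr_fraction +/- idr_fraction_spread evenly while averaging idr_fraction
auto_idr_segments <- function(config) {
  L <- config$protein_length
  np <- config$n_proteins
  offs <- if (np == 1) 0 else config$idr_fraction_spread * (2 * (seq_len(np) - 1) / (np - 1) - 1)
  fracs <- config$idr_fraction + offs
  # force the exact target total so proteome-wide IDR fraction is idr_fraction
  totals <- round(fracs * L)
  adj <- round(config$idr_fraction * L * np) - sum(totals)
  totals[seq_len(abs(adj))] <- totals[seq_len(abs(adj))] + sign(adj)
  purrr::map(seq_len(np), function(i) {
    total <- totals[i]
    len1 <- floor(total / 2)
    len2 <- total - len1
    gap <- floor((L - total) / 3)
    tibble(
      start = c(gap + 1L, gap + len1 + gap + 1L),
      end = c(gap + len1, gap + len1 + gap + len2),
      disorder_bias = config$disorder_bias_default
    )
  })
}

draw_passing_score <- function(method) {
  # BEB/FUBAR pass at posterior >= 0.90; MEME/FEL/SLAC pass at p <= 0.1
  if (method %in% c("BEB", "FUBAR")) {
    runif(1, 0.90, 1)
  } else {
    runif(1, 0, 0.1)
  }
}

#' Simulate ortholog protein alignments with planted selected sites
#'
#' Generates, per protein: a protein MSA in which the reference species
#' comes first; per-species per-residue disorder calls consistent with the
#' configured IDR segments plus noise; planted positively selected sites
#' (per-residue probability proportional to `planted_site_enrichment`
#' inside IDR segments and 1 outside) and uniformly placed negatively
#' selected sites; per-method site-call tables in which each true site
#' appears with probability `method_sensitivity` and each non-site with
#' probability `1 - method_specificity`, scores on the correct side of each
#' method's threshold; and a noisy ensemble-feature table (`sconf_per_n`,
#' `nu`) generated as monotone functions of each segment's hydropathy
#' patterning.
#'
#' @param config A [sim_proteome_config()].
#' @return List with elements `msas` (named list of `Biostrings::AAStringSet`
#'   alignments, reference `"ref"` first), `disorder` (tibble: `protein`,
#'   `species`, `residue`, `disordered`), `calls` (tibble: `protein`,
#'   `method`, `alignment_column`, `score`, `direction`), `ensemble`
#'   (tibble: `protein`, `idr_start`, `idr_end`, `sconf_per_n`, `nu`), and
#'   `truth` (list: `sites`, `negative_sites`, `segments` tibbles).
#' @export
simulate_ortholog_proteins <- function(config) {
  if (!inherits(config, "sim_proteome_config")) {
    stop_bad_config("config must be created with sim_proteome_config()")
  }
  segments <- config$idr_segments %||% auto_idr_segments(config)
  species <- c("ref", sprintf("sp%02d", seq_len(config$n_species - 1)))
  methods_pos <- c("BEB", "FUBAR", "MEME", "FEL")

  with_seed(derive_seed(config$seed, 11L), {
    per_protein <- purrr::map(seq_len(config$n_proteins), function(p) {
      L <- config$protein_length
      seg <- segments[[p]]
      in_idr <- rep(FALSE, L)
      for (r in seq_len(nrow(seg))) {
        in_idr[seg$start[r]:seg$end[r]] <- TRUE
      }

      # reference sequence, disorder-biased composition inside segments
      ref_seq <- ifelse(
        in_idr,
        sample(DISORDER_AA, L, replace = TRUE),
        sample(AA20, L, replace = TRUE)
      )

      # ortholog rows: substitutions and deletions relative to the reference
      rows <- list(ref = ref_seq)
      for (sp in species[-1]) {
        s <- ref_seq
        sub <- runif(L) < config$substitution_rate
        s[sub] <- sample(AA20, sum(sub), replace = TRUE)
        del <- runif(L) < config$deletion_rate
        s[del] <- "-"
        rows[[sp]] <- s
      }

      # insertion columns: gap in the reference (and all but one species)
      n_ins <- rpois(1, config$insertions_per_protein)
      aln <- do.call(rbind, rows) # species x columns
      ref_residue_of_col <- seq_len(L)
      if (n_ins > 0 && length(species) > 1) {
        for (k in seq_len(n_ins)) {
          at <- sample.int(ncol(aln) + 1, 1)
          col <- rep("-", length(species))
          col[sample(2:length(species), 1)] <- sample(AA20, 1)
          left <- seq_len(at - 1)
          aln <- cbind(
            aln[, left, drop = FALSE], col,
            aln[, setdiff(seq_len(ncol(aln)), left), drop = FALSE]
          )
          ref_residue_of_col <- append(ref_residue_of_col, NA_integer_,
            after = at - 1)
        }
      }
      colnames(aln) <- NULL
      col_of_ref_residue <- match(seq_len(L), ref_residue_of_col)

      # per-species disorder calls on their own (ungapped) residues
      disorder <- purrr::map_dfr(seq_along(species), function(si) {
        row <- aln[si, ]
        non_gap <- which(row != "-")
        ref_res <- ref_residue_of_col[non_gap]
        p_dis <- ifelse(!is.na(ref_res) & in_idr[pmax(ref_res, 1)],
          config$disorder_bias_default, config$background_disorder)
        # segment-specific bias where provided
        if (nrow(seg) > 0 && !all(seg$disorder_bias == config$disorder_bias_default)) {
          for (r in seq_len(nrow(seg))) {
            inside <- !is.na(ref_res) & ref_res >= seg$start[r] & ref_res <= seg$end[r]
            p_dis[inside] <- seg$disorder_bias[r]
          }
        }
        tibble(
          protein = protein_id(p),
          species = species[si],
          residue = seq_along(non_gap),
          disordered = runif(length(non_gap)) < p_dis
        )
      })

      # planted positive sites: Bernoulli per residue, enriched inside IDRs
      rho <- config$planted_site_enrichment
      w <- ifelse(in_idr, rho, 1)
      base <- config$expected_sites / config$n_proteins / sum(w)
      p_site <- pmin(w * base, 1)
      true_sites <- which(runif(L) < p_site)

      # planted negative sites: uniform, disjoint from positive sites
      p_neg <- config$expected_negative_sites / config$n_proteins / L
      neg_sites <- setdiff(which(runif(L) < p_neg), true_sites)

      # per-method call tables
      calls <- purrr::map_dfr(methods_pos, function(m) {
        sens <- config$method_sensitivity[[m]]
        spec <- config$method_specificity[[m]]
        detected <- true_sites[runif(length(true_sites)) < sens]
        non_sites <- setdiff(seq_len(L), true_sites)
        false_pos <- non_sites[runif(length(non_sites)) < (1 - spec)]
        res <- sort(c(detected, false_pos))
        if (length(res) == 0) {
          return(tibble(
            protein = character(), method = character(),
            alignment_column = integer(), score = numeric(),
            direction = character()
          ))
        }
        tibble(
          protein = protein_id(p),
          method = m,
          alignment_column = col_of_ref_residue[res],
          score = purrr::map_dbl(res, function(i) draw_passing_score(m)),
          direction = "positive"
        )
      })
      slac <- {
        sens <- config$method_sensitivity[["SLAC"]]
        spec <- config$method_specificity[["SLAC"]]
        detected <- neg_sites[runif(length(neg_sites)) < sens]
        others <- setdiff(seq_len(L), neg_sites)
        false_pos <- others[runif(length(others)) < (1 - spec)]
        res <- sort(c(detected, false_pos))
        tibble(
          protein = rep(protein_id(p), length(res)),
          method = rep("SLAC", length(res)),
          alignment_column = col_of_ref_residue[res],
          score = purrr::map_dbl(res, function(i) draw_passing_score("SLAC")),
          direction = rep("negative", length(res))
        )
      }

      # ensemble features per configured segment: noisy monotone functions
      # of the segment's hydropathy patterning (SHD)
      ensemble <- purrr::map_dfr(seq_len(nrow(seg)), function(r) {
        sub_seq <- paste(ref_seq[seg$start[r]:seg$end[r]], collapse = "")
        s <- shd(sub_seq)
        tibble(
          protein = protein_id(p),
          idr_start = seg$start[r],
          idr_end = seg$end[r],
          sconf_per_n = -1.5 - 0.4 * s + stats::rnorm(1, 0, 0.05),
          nu = pmin(pmax(0.45 + 0.05 * s + stats::rnorm(1, 0, 0.02), 0.3), 0.72)
        )
      })

      msa <- Biostrings::AAStringSet(apply(aln, 1, paste, collapse = ""))
      names(msa) <- species
      list(
        msa = msa,
        disorder = disorder,
        calls = dplyr::bind_rows(calls, slac),
        ensemble = ensemble,
        sites = tibble(
          protein = rep(protein_id(p), length(true_sites)),
          residue = true_sites,
          alignment_column = col_of_ref_residue[true_sites],
          in_idr = in_idr[true_sites]
        ),
        negative_sites = tibble(
          protein = rep(protein_id(p), length(neg_sites)),
          residue = neg_sites,
          alignment_column = col_of_ref_residue[neg_sites],
          in_idr = in_idr[neg_sites]
        ),
        segments = dplyr::mutate(seg, protein = protein_id(p), .before = 1)
      )
    })

    list(
      msas = setNames(
        purrr::map(per_protein, "msa"),
        purrr::map_chr(seq_len(config$n_proteins), protein_id)
      ),
      disorder = purrr::map_dfr(per_protein, "disorder"),
      calls = purrr::map_dfr(per_protein, "calls"),
      ensemble = purrr::map_dfr(per_protein, "ensemble"),
      truth = list(
        sites = purrr::map_dfr(per_protein, "sites"),
        negative_sites = purrr::map_dfr(per_protein, "negative_sites"),
        segments = purrr::map_dfr(per_protein, "segments")
      )
    )
  })
}

protein_id <- function(p) sprintf("prot%03d", p)
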