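# Domain-architecture classification of primary-transcript proteins into
# receptor families. Each classifier is a pure function of (protein, hits,
# tm): order-independent, idempotent, and monotone in the E-value thresholds.

has_domain <- function(hits, acc, evalue) {
  any(pfam_base(hits$pfam_acc) == acc & hits$seq_evalue <= evalue)
}

tm_helices <- function(tm) {
  if (is.null(tm)) return(NA_integer_)
  if (is.numeric(tm)) return(as.integer(tm[1]))
  if (is.data.frame(tm)) {
    if (nrow(tm) == 0) return(NA_integer_)
    return(as.integer(tm$n_helices[1]))
  }
  abort("tm must be a count or a one-row TM record")
}

#' Classify a protein as an LRR receptor-like kinase
#'
#' A protein is an LRR-RLK iff it is at least `min_len_rlk` residues long
#' (shorter proteins are unlikely full-length receptor kinases), carries a
#' protein kinase domain (PF00069) at the strict E-value threshold, and at
#' least one LRR domain at the permissive LRR threshold.
#'
#' @param protein one-row protein tibble.
#' @param hits domain-hit tibble for this protein (may be empty).
#' @param thresholds a [rule_thresholds()] object.
#' @return `TRUE` or `FALSE`.
#' @family classifiers
#' @export
classify_lrr_rlk <- function(protein, hits, thresholds = rule_thresholds()) {
  protein$length[1] >= thresholds$min_len_rlk &&
    has_domain(hits, thresholds$kinase_acc, thresholds$kinase_evalue) &&
    any(pfam_base(hits$pfam_acc) %in% thresholds$lrr_accs &
          hits$seq_evalue <= thresholds$lrr_evalue)
}

#' Classify a protein as an LRR receptor-like protein
#'
#' LRR-RLPs carry LRR domains but no kinase domain; they are additionally
#' diagnosed by the C3F juxtamembrane domain (strict E-value and a minimum
#' alignment length) and must have at least one predicted transmembrane
#' helix. A candidate that satisfies the sequence-level rule but has no TM
#' record is an error, because TM evidence is part of the rule.
#'
#' @inheritParams classify_lrr_rlk
#' @param tm transmembrane record for this protein: a helix count or a
#'   one-row tibble with `n_helices`. `NULL`/empty means "no record".
#' @return `TRUE` or `FALSE`.
#' @family classifiers
#' @export
classify_lrr_rlp <- function(protein, hits, tm,
                             thresholds = rule_thresholds()) {
  seq_rule <- protein$length[1] >= thresholds$min_len_other &&
    any(pfam_base(hits$pfam_acc) %in% thresholds$lrr_accs &
          hits$seq_evalue <= thresholds$lrr_evalue) &&
    !has_domain(hits, thresholds$kinase_acc, thresholds$kinase_evalue) &&
    any(pfam_base(hits$pfam_acc) == thresholds$c3f_acc &
          hits$seq_evalue <= thresholds$c3f_evalue &
          (hits$ali_end - hits$ali_start + 1) >= thresholds$c3f_min_ali_len)
  if (!seq_rule) return(FALSE)
  n_tm <- tm_helices(tm)
  if (is.na(n_tm)) {
    abort(sprintf("LRR-RLP candidate '%s' has no transmembrane record",
                  protein$protein_id[1]))
  }
  n_tm >= 1
}

#' Classify a protein as an NB-ARC receptor
#'
#' NB-ARC (NLR) proteins are called from the presence of the NB-ARC
#' nucleotide-binding domain (PF00931) at the strict E-value threshold, on
#' proteins of at least `min_len_other` residues.
#'
#' @inheritParams classify_lrr_rlk
#' @return `TRUE` or `FALSE`.
#' @family classifiers
#' @export
classify_nbarc <- function(protein, hits, thresholds = rule_thresholds()) {
  protein$length[1] >= thresholds$min_len_other &&
    has_domain(hits, thresholds$nbarc_acc, thresholds$nbarc_evalue)
}

#' Classify a protein as a LysM receptor
#'
#' LysM receptors are called from a LysM domain (PF01476) found under a
#' deliberately permissive E-value threshold (maximum-sensitivity search)
#' plus at least one transmembrane helix; candidates are then split into
#' LysM-RLK vs LysM-RLP by presence/absence of a kinase domain at the strict
#' threshold. A missing TM record counts as no transmembrane evidence.
#'
#' @inheritParams classify_lrr_rlp
#' @return `"LysM-RLK"`, `"LysM-RLP"`, or `"none"`.
#' @family classifiers
#' @export
classify_lysm <- function(protein, hits, tm, thresholds = rule_thresholds()) {
  n_tm <- tm_helices(tm)
  if (protein$length[1] < thresholds$min_len_other ||
      !has_domain(hits, thresholds$lysm_acc, thresholds$lysm_evalue) ||
      is.na(n_tm) || n_tm == 0) {
    return("none")
  }
  if (has_domain(hits, thresholds$kinase_acc, thresholds$kinase_evalue)) {
    "LysM-RLK"
  } else {
    "LysM-RLP"
  }
}

#' The five receptor family labels
#' @return character vector.
#' @export
receptor_families <- function() {
  c("LRR-RLK", "LRR-RLP", "LysM-RLK", "LysM-RLP", "NB-ARC")
}

#' Identify the receptor repertoire of a proteome
#'
#' Applies the four family classifiers to every primary-transcript protein
#' and, when a reference panel is supplied, assigns each LRR-RLK to a kinase
#' subgroup. Family rules are independent: a protein satisfying several
#' rules (for example NB-ARC plus kinase plus LRR) is counted in every family
#' it matches; such multi-family proteins are reported separately. LRR-RLK
#' and LRR-RLP calls are disjoint by construction (kinase presence vs
#' absence).
#'
#' @param proteome protein tibble, already primary-transcript-filtered
#'   (see [select_primary_transcripts()]).
#' @param hits domain-hit tibble for the whole proteome.
#' @param tm TM tibble (`protein_id`, `n_helices`); optional when the
#'   proteome can contain no TM-dependent candidates.
#' @param thresholds a [rule_thresholds()] object.
#' @param panel optional `kinase_panel` for subgroup assignment; without it
#'   every LRR-RLK subgroup is `"unclassified"`.
#' @return an object of class `repertoire`: a list with
#'   * `calls` — tibble of (`protein_id`, `family`, `subgroup`),
#'   * `counts` — tibble of (`family`, `count`) over the five families and,
#'     when a panel is given, the 20 `LRR-RLK-<subgroup>` rows,
#'   * `n_searched` — number of searched (primary-transcript) proteins,
#'   * `species_id` — species of the proteome (if unique),
#'   * `multi_family` — protein ids counted in more than one family.
#' @seealso [tidy.repertoire()], [glance.repertoire()]
#' @export
identify_repertoire <- function(proteome, hits, tm = NULL,
                                thresholds = rule_thresholds(),
                                panel = NULL) {
  assert_cols(proteome, c("protein_id", "sequence", "length"))
  assert_cols(hits, c("protein_id", "pfam_acc", "seq_evalue"))
  tm_tbl <- tm %||% tibble::tibble(protein_id = character(),
                                   n_helices = integer())
  hit_split <- split(seq_len(nrow(hits)), hits$protein_id)
  tm_map <- setNames(as.integer(tm_tbl$n_helices), tm_tbl$protein_id)

  calls <- purrr::map(seq_len(nrow(proteome)), function(i) {
    p <- proteome[i, ]
    h <- hits[hit_split[[p$protein_id]] %||% integer(0), , drop = FALSE]
    n_tm <- if (p$protein_id %in% names(tm_map)) tm_map[[p$protein_id]] else NULL
    fams <- character(0)
    if (classify_lrr_rlk(p, h, thresholds)) fams <- c(fams, "LRR-RLK")
    if (classify_lrr_rlp(p, h, n_tm, thresholds)) fams <- c(fams, "LRR-RLP")
    lysm <- classify_lysm(p, h, n_tm, thresholds)
    if (lysm != "none") fams <- c(fams, lysm)
    if (classify_nbarc(p, h, thresholds)) fams <- c(fams, "NB-ARC")
    if (length(fams) == 0) return(NULL)
    sub <- rep(NA_character_, length(fams))
    if ("LRR-RLK" %in% fams) {
      region <- extract_kinase_region(p, h, thresholds)
      sub[fams == "LRR-RLK"] <- if (is.null(panel)) {
        "unclassified"
      } else {
        assign_subgroup(region, panel, thresholds)
      }
    }
    tibble::tibble(protein_id = p$protein_id, family = fams, subgroup = sub)
  })
  calls <- dplyr::bind_rows(calls)
  if (nrow(calls) == 0) {
    calls <- tibble::tibble(protein_id = character(), family = character(),
                            subgroup = character())
  }

  fam_levels <- receptor_families()
  counts <- tibble::tibble(
    family = fam_levels,
    count = purrr::map_int(fam_levels, ~ sum(calls$family == .x))
  )
  if (!is.null(panel)) {
    rlk <- calls[calls$family == "LRR-RLK", , drop = FALSE]
    sub_counts <- tibble::tibble(
      family = paste0("LRR-RLK-", lrr_rlk_subgroups()),
      count = purrr::map_int(lrr_rlk_subgroups(),
                             ~ sum(rlk$subgroup == .x))
    )
    counts <- dplyr::bind_rows(counts, sub_counts)
  }

  multi <- calls |>
    dplyr::count(.data$protein_id) |>
    dplyr::filter(.data$n > 1) |>
    dplyr::pull(.data$protein_id)

  species <- unique(proteome$species_id %||% NA_character_)
  structure(list(
    calls = calls,
    counts = counts,
    n_searched = nrow(proteome),
    species_id = if (length(species) == 1) species else NA_character_,
    multi_family = multi
  ), class = "repertoire")
}

#' @export
print.repertoire <- function(x, ...) {
  cat(sprintf("Receptor repertoire%s: %d call(s) among %d searched proteins\n",
              if (is.na(x$species_id)) "" else paste0(" of ", x$species_id),
              nrow(x$calls), x$n_searched))
  fam <- x$counts[x$counts$family %in% receptor_families(), ]
  for (i in seq_len(nrow(fam))) {
    cat(sprintf("  %-9s %d\n", fam$family[i], fam$count[i]))
  }
  if (length(x$multi_family) > 0) {
    cat(sprintf("  (%d protein(s) matched more than one family)\n",
                length(x$multi_family)))
  }
  invisible(x)
}
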