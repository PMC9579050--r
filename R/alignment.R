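# Kinase-domain extraction and local alignment against the reference
# subgroup panel.

.receptoire_env <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.receptoire_env$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .receptoire_env$BLOSUM62 <- e$BLOSUM62
  }
  .receptoire_env$BLOSUM62
}

#' Smith-Waterman local alignment score
#'
#' Optimal local alignment score of two amino-acid sequences under BLOSUM62
#' with affine gaps (a gap of length L costs `gap_open + L * gap_extend`).
#' The score is floored at 0, the empty local alignment. Symmetric in its
#' arguments.
#'
#' @param query,target non-empty amino-acid strings.
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @param matrix substitution matrix; defaults to BLOSUM62.
#' @return a single non-negative alignment score in bits-like units.
#' @export
local_align_score <- function(query, target, gap_open = 11, gap_extend = 1,
                              matrix = NULL) {
  if (!nzchar(query) || !nzchar(target)) {
    abort("local_align_score requires non-empty sequences")
  }
  matrix <- matrix %||% blosum62()
  s <- suppressWarnings(Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(target),
    type = "local", substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE))
  max(0, s)
}

#' Extract the highest-scoring kinase-domain region
#'
#' Returns the subsequence of `protein` under the envelope coordinates of
#' its best kinase domain hit: maximal per-domain bit score, ties broken by
#' the smallest envelope start.
#'
#' @param protein one-row protein tibble (columns `protein_id`, `sequence`,
#'   `length`).
#' @param hits domain-hit tibble for this protein.
#' @param thresholds a [rule_thresholds()] object.
#' @return the kinase-region amino-acid string.
#' @export
extract_kinase_region <- function(protein, hits, thresholds = rule_thresholds()) {
  assert_cols(protein, c("protein_id", "sequence"))
  k <- hits[pfam_base(hits$pfam_acc) == thresholds$kinase_acc &
              hits$seq_evalue <= thresholds$kinase_evalue, , drop = FALSE]
  if (nrow(k) == 0) {
    abort(sprintf("protein '%s' has no kinase domain hit passing E <= %g",
                  protein$protein_id[1], thresholds$kinase_evalue))
  }
  k <- k[order(-k$bitscore, k$env_start), , drop = FALSE]
  from <- max(1L, k$env_start[1])
  to <- min(nchar(protein$sequence[1]), k$env_end[1])
  substr(protein$sequence[1], from, to)
}

#' Build the reference kinase panel for subgroup assignment
#'
#' Takes labelled reference LRR-RLK sequences (one subgroup label per
#' protein), re-applies the same kinase/LRR filters used for candidate
#' identification, and extracts each survivor's best kinase-domain region.
#' Reference entries failing the filters are dropped (and reported), mirroring
#' how a curated panel is pruned by the thresholds rather than by a fixed
#' list.
#'
#' @param proteins protein tibble with an extra `subgroup` column holding one
#'   of [lrr_rlk_subgroups()].
#' @param hits domain-hit tibble covering the panel proteins.
#' @param thresholds a [rule_thresholds()] object.
#' @return a tibble of class `kinase_panel` with columns `panel_id`,
#'   `subgroup`, `sequence` (the kinase region).
#' @seealso [assign_subgroup()]
#' @export
reference_kinase_panel <- function(proteins, hits,
                                   thresholds = rule_thresholds()) {
  assert_cols(proteins, c("protein_id", "sequence", "length", "subgroup"))
  bad <- setdiff(unique(proteins$subgroup), lrr_rlk_subgroups())
  if (length(bad) > 0) {
    abort(paste0("unknown subgroup label(s): ", paste(bad, collapse = ", ")))
  }
  keep <- purrr::map_lgl(seq_len(nrow(proteins)), function(i) {
    h <- hits[hits$protein_id == proteins$protein_id[i], , drop = FALSE]
    classify_lrr_rlk(proteins[i, ], h, thresholds)
  })
  if (any(!keep)) {
    warn(sprintf("%d reference sequence(s) removed by the kinase/LRR filters: %s",
                 sum(!keep),
                 paste(proteins$protein_id[!keep], collapse = ", ")))
  }
  kept <- proteins[keep, , drop = FALSE]
  if (nrow(kept) == 0) abort("no reference sequence passed the filters")
  region <- purrr::map_chr(seq_len(nrow(kept)), function(i) {
    h <- hits[hits$protein_id == kept$protein_id[i], , drop = FALSE]
    extract_kinase_region(kept[i, ], h, thresholds)
  })
  structure(tibble::tibble(panel_id = kept$protein_id,
                           subgroup = kept$subgroup,
                           sequence = region),
            class = c("kinase_panel", "tbl_df", "tbl", "data.frame"))
}

#' Construct a kinase panel from bare labelled sequences
#'
#' Convenience constructor for panels whose kinase regions are already
#' extracted (synthetic panels, pre-curated references).
#'
#' @param subgroup character vector of subgroup labels.
#' @param sequence kinase-region amino-acid strings, same length.
#' @param panel_id optional ids; defaults to `ref_<subgroup>_<i>`.
#' @return a `kinase_panel` tibble.
#' @export
kinase_panel <- function(subgroup, sequence, panel_id = NULL) {
  stopifnot(length(subgroup) == length(sequence), length(subgroup) > 0,
            all(nzchar(sequence)))
  bad <- setdiff(unique(subgroup), lrr_rlk_subgroups())
  if (length(bad) > 0) {
    abort(paste0("unknown subgroup label(s): ", paste(bad, collapse = ", ")))
  }
  panel_id <- panel_id %||%
    sprintf("ref_%s_%d", subgroup, stats::ave(seq_along(subgroup), subgroup,
                                              FUN = seq_along))
  structure(tibble::tibble(panel_id = panel_id, subgroup = subgroup,
                           sequence = sequence),
            class = c("kinase_panel", "tbl_df", "tbl", "data.frame"))
}

#' Assign an LRR-RLK kinase region to a subgroup
#'
#' Scores the candidate kinase region against every panel entry with
#' [local_align_score()] and returns the subgroup of the best-scoring entry,
#' provided that score reaches the significance floor
#' (`thresholds$subgroup_min_score`); otherwise `"unclassified"`. Ties are
#' broken by panel order, so assignment is deterministic.
#'
#' @param kinase_region candidate kinase-domain amino-acid string.
#' @param panel a `kinase_panel` tibble.
#' @param thresholds a [rule_thresholds()] object (only the subgroup score
#'   floor is used).
#' @return a subgroup label or `"unclassified"`.
#' @export
assign_subgroup <- function(kinase_region, panel,
                            thresholds = rule_thresholds()) {
  if (nrow(panel) == 0) abort("empty reference panel")
  scores <- purrr::map_dbl(panel$sequence, local_align_score,
                           query = kinase_region)
  best <- which.max(scores)  # first maximum = panel-order tie-break
  if (scores[best] < thresholds$subgroup_min_score) return("unclassified")
  panel$subgroup[best]
}
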