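#' Pfam leucine-rich-repeat domain accessions
#'
#' The LRR domain models whose presence (at the LRR E-value threshold)
#' defines an LRR ectodomain. Accessions are matched version-tolerantly.
#'
#' @return character vector of unversioned Pfam accessions.
#' @export
lrr_accessions <- function() {
  c("PF18805", "PF18831", "PF18837", "PF00560", "PF07723", "PF07725",
    "PF12799", "PF13306", "PF13516", "PF13855", "PF14580", "PF01463",
    "PF08263", "PF01462")
}

#' The 20 LRR-RLK subgroup labels
#'
#' Subgroups of the leucine-rich-repeat receptor-like kinases, defined by
#' kinase-domain similarity. Subgroup XII holds the classical
#' pathogen-sensing receptors (FLS2, EFR, Xa21).
#'
#' @return character vector of 20 labels.
#' @export
lrr_rlk_subgroups <- function() {
  c("I", "II", "III", "IV", "V", "VI_1", "VI_2", "VII_1", "VII_2", "VII_3",
    "VIII_1", "VIII_2", "IX", "Xa", "Xb", "XI", "XII", "XIII", "XIV", "XV")
}

#' Classification rule thresholds
#'
#' Bundles every threshold used by the domain-architecture classifiers. All
#' E-value thresholds apply to the full-sequence E-value and are inclusive on
#' the passing side (a hit at exactly the threshold passes); length floors
#' are likewise inclusive. Pfam accessions are compared before the version
#' dot, so hit tables from any Pfam release work.
#'
#' @param kinase_evalue full-sequence E-value threshold for the protein
#'   kinase domain (PF00069).
#' @param lrr_evalue E-value threshold for any LRR domain
#'   (see [lrr_accessions()]).
#' @param nbarc_evalue E-value threshold for the NB-ARC domain (PF00931).
#' @param lysm_evalue permissive E-value threshold for the LysM domain
#'   (PF01476), mirroring a maximum-sensitivity search.
#' @param c3f_evalue E-value threshold for the C3F juxtamembrane domain of
#'   LRR-RLPs.
#' @param c3f_min_ali_len minimum C3F alignment length in residues
#'   (`ali_end - ali_start + 1`).
#' @param min_len_rlk minimum protein length (AA) for LRR-RLK candidates.
#' @param min_len_other minimum protein length (AA) for all other families.
#' @param subgroup_min_score minimum local-alignment bit score for a
#'   subgroup call; below it a candidate is "unclassified". A bit-score
#'   floor is used because E-value calibration is aligner-specific.
#' @param lrr_accs unversioned Pfam accessions accepted as LRR domains.
#' @return a list of class `rule_thresholds`.
#' @export
rule_thresholds <- function(kinase_evalue = 1e-10,
                            lrr_evalue = 1e-2,
                            nbarc_evalue = 1e-10,
                            lysm_evalue = 1000,
                            c3f_evalue = 1e-10,
                            c3f_min_ali_len = 140,
                            min_len_rlk = 250,
                            min_len_other = 150,
                            subgroup_min_score = 50,
                            lrr_accs = lrr_accessions()) {
  stopifnot(kinase_evalue > 0, lrr_evalue > 0, nbarc_evalue > 0,
            lysm_evalue > 0, c3f_evalue > 0, c3f_min_ali_len > 0,
            min_len_rlk > 0, min_len_other > 0, length(lrr_accs) > 0)
  structure(list(
    kinase_acc = "PF00069", kinase_evalue = kinase_evalue,
    lrr_accs = pfam_base(lrr_accs), lrr_evalue = lrr_evalue,
    nbarc_acc = "PF00931", nbarc_evalue = nbarc_evalue,
    lysm_acc = "PF01476", lysm_evalue = lysm_evalue,
    c3f_acc = "C3F", c3f_evalue = c3f_evalue,
    c3f_min_ali_len = c3f_min_ali_len,
    min_len_rlk = min_len_rlk, min_len_other = min_len_other,
    subgroup_min_score = subgroup_min_score
  ), class = "rule_thresholds")
}

#' @export
print.rule_thresholds <- function(x, ...) {
  cat("Receptor classification thresholds\n")
  cat(sprintf("  kinase  %s  E <= %g\n", x$kinase_acc, x$kinase_evalue))
  cat(sprintf("  LRR     %d accessions  E <= %g\n", length(x$lrr_accs),
              x$lrr_evalue))
  cat(sprintf("  NB-ARC  %s  E <= %g\n", x$nbarc_acc, x$nbarc_evalue))
  cat(sprintf("  LysM    %s  E <= %g\n", x$lysm_acc, x$lysm_evalue))
  cat(sprintf("  C3F     %s  E <= %g, alignment >= %d aa\n", x$c3f_acc,
              x$c3f_evalue, x$c3f_min_ali_len))
  cat(sprintf("  length  >= %d AA (LRR-RLK), >= %d AA (others)\n",
              x$min_len_rlk, x$min_len_other))
  cat(sprintf("  subgroup floor  bit score >= %g\n", x$subgroup_min_score))
  invisible(x)
}
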