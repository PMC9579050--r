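#' Run code with a locally fixed RNG seed
#'
#' All stochastic operations in the package funnel through this helper so a
#' `seed` argument makes them reproducible without disturbing the caller's
#' RNG state. A `NULL` seed leaves the global stream untouched.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @noRd
with_seed_or_not <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

#' Strip the version suffix from a Pfam accession
#'
#' Pfam accessions are versioned (`PF00069.26`); rules match on the accession
#' proper so tables produced with any Pfam release are comparable.
#'
#' @param acc character vector of accessions.
#' @return accessions without the `.NN` version suffix.
#' @examples
#' pfam_base(c("PF00069.26", "PF00931", "C3F"))
#' @export
pfam_base <- function(acc) {
  sub("\\.[0-9]+$", "", acc)
}

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
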