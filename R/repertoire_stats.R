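# Percentage normalization of receptor counts and the cross-species Pearson
# correlation analysis.

#' Combine per-species repertoires into a counts table
#'
#' Stacks the counts of several [identify_repertoire()] results into one long
#' counts tibble plus a totals tibble, ready for [compute_percentages()].
#'
#' @param repertoires list of `repertoire` objects (one per species).
#' @param clades optional named character vector mapping species id to clade
#'   label.
#' @return list with `counts` (`species_id`, `family`, `count`) and `totals`
#'   (`species_id`, `n_searched`).
#' @export
repertoire_counts <- function(repertoires, clades = NULL) {
  counts <- purrr::map_dfr(repertoires, function(r) {
    dplyr::mutate(r$counts, species_id = r$species_id, .before = 1)
  })
  totals <- purrr::map_dfr(repertoires, function(r) {
    tibble::tibble(species_id = r$species_id, n_searched = r$n_searched)
  })
  if (!is.null(clades)) {
    counts <- dplyr::mutate(counts,
                            clade = unname(clades[.data$species_id]),
                            .after = "species_id")
  }
  list(counts = counts, totals = totals)
}

#' Normalize receptor counts to percentages of the searched proteome
#'
#' Percentage = identified genes / searched genes x 100, per species and
#' family. The searched-gene denominator is the number of primary-transcript
#' proteins, which makes the percentages invariant under whole-proteome
#' duplication (counts and totals both doubling) — the reason the analysis
#' normalizes at all. Two derived receptor groups are computed as count sums
#' *before* normalization whenever their components are present:
#' `LRR-RLK-excl-XII` (all LRR-RLKs outside subgroup XII) and `LRR-RLP+XII`
#' (LRR-RLPs plus subgroup XII LRR-RLKs).
#'
#' @param counts long counts tibble (`species_id`, `family`, `count`),
#'   optionally with a `clade` column.
#' @param totals per-species searched-gene totals: tibble (`species_id`,
#'   `n_searched`) or a named numeric vector.
#' @return a tibble of class `repertoire_table` with columns `species_id`,
#'   (`clade`,) `family`, `count`, `n_searched`, `percentage`.
#' @seealso [pivot_percentages()], [correlation_suite()]
#' @export
compute_percentages <- function(counts, totals) {
  assert_cols(counts, c("species_id", "family", "count"))
  if (is.numeric(totals)) {
    totals <- tibble::tibble(species_id = names(totals),
                             n_searched = unname(totals))
  }
  assert_cols(totals, c("species_id", "n_searched"))
  zero <- totals$species_id[totals$n_searched <= 0]
  if (length(zero) > 0) {
    abort(paste0("searched-gene total is zero for species: ",
                 paste(zero, collapse = ", ")))
  }
  counts <- add_derived_counts(counts)
  out <- counts |>
    dplyr::inner_join(totals, by = "species_id") |>
    dplyr::mutate(percentage = .data$count / .data$n_searched * 100)
  class(out) <- c("repertoire_table", class(tibble::tibble()))
  out
}

add_derived_counts <- function(counts) {
  fams <- unique(counts$family)
  extra <- list()
  if (all(c("LRR-RLK", "LRR-RLK-XII") %in% fams)) {
    wide <- counts |>
      dplyr::filter(.data$family %in% c("LRR-RLK", "LRR-RLK-XII")) |>
      tidyr::pivot_wider(names_from = "family", values_from = "count")
    extra <- c(extra, list(
      dplyr::mutate(wide, family = "LRR-RLK-excl-XII",
                    count = .data$`LRR-RLK` - .data$`LRR-RLK-XII`) |>
        dplyr::select(-dplyr::all_of(c("LRR-RLK", "LRR-RLK-XII")))
    ))
  }
  if (all(c("LRR-RLP", "LRR-RLK-XII") %in% fams)) {
    wide <- counts |>
      dplyr::filter(.data$family %in% c("LRR-RLP", "LRR-RLK-XII")) |>
      tidyr::pivot_wider(names_from = "family", values_from = "count")
    extra <- c(extra, list(
      dplyr::mutate(wide, family = "LRR-RLP+XII",
                    count = .data$`LRR-RLP` + .data$`LRR-RLK-XII`) |>
        dplyr::select(-dplyr::all_of(c("LRR-RLP", "LRR-RLK-XII")))
    ))
  }
  dplyr::bind_rows(counts, !!!extra)
}

#' Pivot a repertoire table to one percentage column per family
#'
#' @param rt a `repertoire_table` from [compute_percentages()].
#' @return wide tibble: `species_id`, (`clade`,) one numeric column per
#'   family holding percentages.
#' @export
pivot_percentages <- function(rt) {
  assert_cols(rt, c("species_id", "family", "percentage"))
  ids <- intersect(c("species_id", "clade"), names(rt))
  tidyr::pivot_wider(rt, id_cols = dplyr::all_of(ids),
                     names_from = "family", values_from = "percentage")
}

#' Read / write a wide percentage table
#'
#' The CSV schema mirrors the published per-species percentage supplement:
#' a `species_id` column, an optional `clade` column, then one numeric
#' column per receptor family or subgroup.
#'
#' @param path CSV file.
#' @return a wide percentage tibble.
#' @export
read_percentage_table <- function(path) {
  if (!file.exists(path)) abort(paste0("percentage table not found: ", path))
  out <- readr::read_csv(path, show_col_types = FALSE)
  assert_cols(out, "species_id", "percentage table")
  out
}

#' @rdname read_percentage_table
#' @param table wide percentage tibble.
#' @export
write_percentage_table <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

#' Pearson correlation with a two-sided t test
#'
#' Sample product-moment correlation between two percentage vectors, with the
#' two-sided p-value from the t distribution on n - 2 degrees of freedom.
#'
#' @param x,y equal-length numeric vectors, n >= 3, finite.
#' @return one-row tibble: `r`, `p_value`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("x and y must be finite")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("correlation undefined: zero variance in x or y")
  }
  ct <- stats::cor.test(x, y, alternative = "two.sided", method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x))
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, p * k)` with `k` the number of independent tests.
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @param k number of tests; defaults to `length(pvals)`.
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(pvals, k = length(pvals)) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  stats::p.adjust(pvals, method = "bonferroni", n = max(k, length(pvals)))
}

#' Correlate every receptor family against a reference family
#'
#' Runs [pearson_correlation()] of each requested percentage column against
#' the reference column (%NB-ARC by default) over the species passing the
#' clade filter, and applies Bonferroni correction across the executed
#' tests.
#'
#' @param table wide percentage tibble ([pivot_percentages()] output or
#'   [read_percentage_table()]).
#' @param reference reference column name.
#' @param families columns to test; defaults to every numeric column except
#'   the reference.
#' @param clade optional clade filter (requires a `clade` column); species
#'   whose clade label contains this string are kept.
#' @param drop_null drop, per pair, species with a zero (null) percentage in
#'   either member before correlating.
#' @return a tibble of class `correlation_suite`: `family`, `reference`,
#'   `r`, `p_value`, `p_adjusted`, `n`.
#' @export
correlation_suite <- function(table, reference = "NB-ARC", families = NULL,
                              clade = NULL, drop_null = FALSE) {
  assert_cols(table, c("species_id", reference))
  if (!is.null(clade)) {
    assert_cols(table, "clade")
    table <- table[grepl(clade, table$clade, fixed = TRUE), , drop = FALSE]
  }
  numeric_cols <- names(table)[purrr::map_lgl(table, is.numeric)]
  families <- families %||% setdiff(numeric_cols, reference)
  missing <- setdiff(families, names(table))
  if (length(missing) > 0) {
    abort(paste0("families absent from table: ",
                 paste(missing, collapse = ", ")))
  }
  res <- purrr::map_dfr(families, function(f) {
    x <- table[[f]]
    y <- table[[reference]]
    keep <- is.finite(x) & is.finite(y)
    if (drop_null) keep <- keep & x > 0 & y > 0
    if (sum(keep) < 3) {
      abort(sprintf("fewer than 3 species available for %s vs %s", f,
                    reference))
    }
    dplyr::mutate(pearson_correlation(x[keep], y[keep]), family = f,
                  .before = 1)
  })
  res <- res |>
    dplyr::mutate(reference = reference, .after = "family") |>
    dplyr::mutate(p_adjusted = bonferroni_adjust(.data$p_value),
                  .after = "p_value")
  class(res) <- c("correlation_suite", class(tibble::tibble()))
  res
}
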