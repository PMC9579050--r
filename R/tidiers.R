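# broom-style tidy()/glance() methods for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a receptor repertoire
#'
#' @param x a `repertoire` from [identify_repertoire()].
#' @param ... unused.
#' @return the calls tibble (`species_id`, `protein_id`, `family`,
#'   `subgroup`).
#' @method tidy repertoire
#' @export
tidy.repertoire <- function(x, ...) {
  dplyr::mutate(x$calls, species_id = x$species_id, .before = 1)
}

#' One-row summary of a receptor repertoire
#'
#' @param x a `repertoire`.
#' @param ... unused.
#' @return one-row tibble: species, searched total, one count column per
#'   family, number of multi-family proteins.
#' @method glance repertoire
#' @export
glance.repertoire <- function(x, ...) {
  fam <- x$counts[x$counts$family %in% receptor_families(), ]
  wide <- tidyr::pivot_wider(fam, names_from = "family",
                             values_from = "count")
  dplyr::bind_cols(
    tibble::tibble(species_id = x$species_id, n_searched = x$n_searched),
    wide,
    tibble::tibble(n_multi_family = length(x$multi_family))
  )
}

#' Tidy a Mantel or partial Mantel result
#'
#' @param x a `mantel_result`.
#' @param ... unused.
#' @return one-row tibble: `method`, `pair`, `r`, `p_value`, `n_labels`,
#'   `n_perm`, `alternative`.
#' @method tidy mantel_result
#' @export
tidy.mantel_result <- function(x, ...) {
  tibble::tibble(method = x$method, pair = paste(x$pair, collapse = " ~ "),
                 r = x$statistic, p_value = x$p_value,
                 n_labels = x$n_labels, n_perm = x$n_perm,
                 alternative = x$alternative)
}

#' @rdname tidy.mantel_result
#' @method glance mantel_result
#' @export
glance.mantel_result <- tidy.mantel_result

#' Tidy a gene-group proximity test
#'
#' @param x a `cluster_test`.
#' @param ... unused.
#' @return one-row tibble with the observed mean closest distance, null
#'   summary (mean and 2.5/97.5% quantiles), empirical p-value and sizes.
#' @method tidy cluster_test
#' @export
tidy.cluster_test <- function(x, ...) {
  tibble::tibble(
    group_a = x$group_a, n = x$n_a, group_b = x$group_b, m = x$m,
    observed = x$observed, n_excluded = x$n_excluded,
    null_mean = mean(x$null_stats),
    null_q025 = unname(quantile(x$null_stats, 0.025)),
    null_q975 = unname(quantile(x$null_stats, 0.975)),
    n_samples = length(x$null_stats), p_value = x$p_value
  )
}

#' @rdname tidy.cluster_test
#' @method glance cluster_test
#' @export
glance.cluster_test <- tidy.cluster_test
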