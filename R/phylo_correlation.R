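# Phylogeny-aware correlation: distance matrices from percentage vectors,
# Mantel and partial Mantel permutation tests, FDR correction.

#' Distance matrix from a per-species percentage vector
#'
#' `d(i, j) = |x_i - x_j|`: the absolute difference, i.e. the Euclidean
#' metric on the line, so the triangle inequality holds by construction.
#'
#' @param values named numeric vector of percentages (names = species ids),
#'   or unnamed with `labels` supplied.
#' @param labels species labels; defaults to `names(values)`.
#' @param provenance free-text tag recording what the distances are
#'   (receptor family name or "phylogeny").
#' @return a labelled symmetric matrix with zero diagonal and a
#'   `provenance` attribute.
#' @export
percent_to_distance <- function(values, labels = NULL, provenance = NULL) {
  labels <- labels %||% names(values)
  if (is.null(labels)) abort("values must be named or labels supplied")
  if (!all(is.finite(values))) abort("values must be finite")
  if (anyDuplicated(labels) > 0) abort("labels must be unique")
  d <- abs(outer(values, values, "-"))
  dimnames(d) <- list(labels, labels)
  attr(d, "provenance") <- provenance
  d
}

check_dist_matrix <- function(m, what = "distance matrix") {
  if (is.null(dimnames(m)[[1]])) abort(paste0(what, " must be labelled"))
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-12) {
    abort(paste0(what, " must be symmetric"))
  }
  if (any(abs(diag(m)) > 1e-12)) abort(paste0(what, " must have a zero diagonal"))
  invisible(m)
}

#' Restrict a distance matrix to a label subset
#'
#' @param m labelled distance matrix.
#' @param labels labels to keep, in the desired order.
#' @return the restricted, reordered matrix.
#' @export
restrict_labels <- function(m, labels) {
  missing <- setdiff(labels, rownames(m))
  if (length(missing) > 0) {
    abort(paste0("labels absent from matrix: ",
                 paste(missing, collapse = ", ")))
  }
  out <- m[labels, labels, drop = FALSE]
  attr(out, "provenance") <- attr(m, "provenance")
  out
}

align_second <- function(A, B, what = "B") {
  if (!setequal(rownames(A), rownames(B))) {
    abort(sprintf("label mismatch between matrices (%s)", what))
  }
  restrict_labels(B, rownames(A))
}

upper_vec <- function(m) m[upper.tri(m)]

#' Mantel permutation test
#'
#' Mantel r is the Pearson correlation of the upper-triangle entries of the
#' two distance matrices. Significance comes from simultaneously permuting
#' the rows and columns of `B` `n_perm` times; the one-sided (greater)
#' empirical p-value uses the add-one rule `(1 + #\{r* >= r\}) / (n_perm + 1)`,
#' so p is never 0 and never below `1/(n_perm + 1)`.
#'
#' @param A,B labelled distance matrices over the same label set (`B` is
#'   reordered to `A`'s labels if needed).
#' @param n_perm number of permutations.
#' @param seed integer seed for reproducible permutations, or `NULL`.
#' @param alternative `"greater"` (the conventional Mantel alternative) or
#'   `"two.sided"`.
#' @param method correlation flavour on the distance entries: `"pearson"`
#'   (default) or `"spearman"`.
#' @return an object of class `mantel_result`.
#' @seealso [partial_mantel()], [fdr_adjust()]
#' @export
mantel <- function(A, B, n_perm = 10000, seed = NULL,
                   alternative = c("greater", "two.sided"),
                   method = c("pearson", "spearman")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  check_dist_matrix(A, "A"); check_dist_matrix(B, "B")
  B <- align_second(A, B)
  stopifnot(n_perm >= 1)
  n <- nrow(A)
  if (n < 3) abort("need at least 3 labels")
  va <- upper_vec(A)
  if (method == "spearman") {
    r_obs <- stats::cor(va, upper_vec(B), method = "spearman")
    stat <- function(Bp) stats::cor(va, upper_vec(Bp), method = "spearman")
  } else {
    r_obs <- stats::cor(va, upper_vec(B))
    stat <- function(Bp) stats::cor(va, upper_vec(Bp))
  }
  perm_r <- with_seed_or_not(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n)
      stat(B[idx, idx])
    }, numeric(1))
  })
  p <- perm_pvalue(r_obs, perm_r, alternative)
  structure(list(
    method = "mantel", pair = c(attr(A, "provenance") %||% "A",
                                attr(B, "provenance") %||% "B"),
    statistic = r_obs, p_value = p, n_perm = n_perm, n_labels = n,
    alternative = alternative, cor_method = method, seed = seed,
    perm_stats = perm_r
  ), class = "mantel_result")
}

perm_pvalue <- function(obs, perm, alternative) {
  if (alternative == "greater") {
    (1 + sum(perm >= obs)) / (length(perm) + 1)
  } else {
    (1 + sum(abs(perm) >= abs(obs))) / (length(perm) + 1)
  }
}

#' Partial Mantel test
#'
#' First-order partial correlation of `A` and `B` given the controlling
#' matrix `C` (typically patristic distances), computed on the vectorized
#' upper triangles:
#' `r_AB.C = (r_AB - r_AC r_BC) / sqrt((1 - r_AC^2)(1 - r_BC^2))`.
#' The permutation null simultaneously permutes rows/columns of `A` and
#' recomputes the partial statistic; the p-value is one-sided (greater) by
#' default with the same add-one rule as [mantel()].
#'
#' @inheritParams mantel
#' @param C controlling distance matrix over the same labels.
#' @return an object of class `mantel_result`.
#' @export
partial_mantel <- function(A, B, C, n_perm = 10000, seed = NULL,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  check_dist_matrix(A, "A"); check_dist_matrix(B, "B")
  check_dist_matrix(C, "C")
  B <- align_second(A, B); C <- align_second(A, C, "C")
  n <- nrow(A)
  if (n < 4) abort("need at least 4 labels")
  vb <- upper_vec(B); vc <- upper_vec(C)
  r_bc <- stats::cor(vb, vc)
  partial_r <- function(va) {
    r_ab <- stats::cor(va, vb)
    r_ac <- stats::cor(va, vc)
    if (abs(r_ac) >= 1 - 1e-12 || abs(r_bc) >= 1 - 1e-12) {
      abort("degenerate control: a matrix is perfectly correlated with C")
    }
    (r_ab - r_ac * r_bc) / sqrt((1 - r_ac^2) * (1 - r_bc^2))
  }
  r_obs <- partial_r(upper_vec(A))
  perm_r <- with_seed_or_not(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n)
      partial_r(upper_vec(A[idx, idx]))
    }, numeric(1))
  })
  p <- perm_pvalue(r_obs, perm_r, alternative)
  structure(list(
    method = "partial_mantel",
    pair = c(attr(A, "provenance") %||% "A", attr(B, "provenance") %||% "B",
             attr(C, "provenance") %||% "C"),
    statistic = r_obs, p_value = p, n_perm = n_perm, n_labels = n,
    alternative = alternative, cor_method = "pearson", seed = seed,
    perm_stats = perm_r
  ), class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("%s test: %s\n", x$method, paste(x$pair, collapse = " ~ ")))
  cat(sprintf("  r = %.4f, p = %.4g (%s, %d permutations, %d labels)\n",
              x$statistic, x$p_value, x$alternative, x$n_perm, x$n_labels))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjusted p-values, monotone and capped at 1.
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
fdr_adjust <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  stats::p.adjust(pvals, method = "BH")
}

#' Mantel suite over receptor-family pairs and the phylogeny
#'
#' Converts each requested percentage column of a wide percentage table to a
#' distance matrix, runs [mantel()] for every requested family pair, and —
#' when a tree is supplied — [partial_mantel()] for the same pairs
#' controlling for patristic distances plus a plain Mantel of each family
#' against the phylogeny. Species absent from the tree are dropped with a
#' message (tree and table label sets are intersected). FDR correction is
#' applied across each block of tests.
#'
#' @param table wide percentage tibble.
#' @param pairs list of length-2 character vectors (column name pairs), e.g.
#'   `list(c("NB-ARC", "LRR-RLP"))`.
#' @param tree optional [ape::phylo] species tree (labels = species ids).
#' @param n_perm,seed passed to the tests.
#' @return tibble: `test`, `pair`, `r`, `p_value`, `p_fdr`, `n_labels`.
#' @export
mantel_suite <- function(table, pairs, tree = NULL, n_perm = 10000,
                         seed = NULL) {
  assert_cols(table, "species_id")
  fams <- unique(unlist(pairs))
  assert_cols(table, fams)
  labels <- table$species_id
  if (!is.null(tree)) {
    dropped <- setdiff(labels, tree$tip.label)
    if (length(dropped) > 0) {
      message(sprintf("dropping %d species absent from the tree",
                      length(dropped)))
      labels <- intersect(labels, tree$tip.label)
    }
  }
  tab <- table[match(labels, table$species_id), , drop = FALSE]
  dists <- purrr::map(setNames(fams, fams), function(f) {
    percent_to_distance(setNames(tab[[f]], labels), provenance = f)
  })
  phylo_d <- if (!is.null(tree)) patristic_distances(tree, labels)

  run_block <- function(results, test_name) {
    tibble::tibble(
      test = test_name,
      pair = purrr::map_chr(results, ~ paste(.x$pair[1:2], collapse = " ~ ")),
      r = purrr::map_dbl(results, "statistic"),
      p_value = purrr::map_dbl(results, "p_value"),
      n_labels = purrr::map_int(results, "n_labels")
    ) |>
      dplyr::mutate(p_fdr = fdr_adjust(.data$p_value), .after = "p_value")
  }

  out <- list()
  plain <- purrr::map(pairs, function(pr) {
    mantel(dists[[pr[1]]], dists[[pr[2]]], n_perm = n_perm, seed = seed)
  })
  out$pairs <- run_block(plain, "mantel")
  if (!is.null(tree)) {
    partial <- purrr::map(pairs, function(pr) {
      partial_mantel(dists[[pr[1]]], dists[[pr[2]]], phylo_d,
                     n_perm = n_perm, seed = seed)
    })
    out$partial <- run_block(partial, "partial_mantel")
    vs_tree <- purrr::map(fams, function(f) {
      mantel(dists[[f]], phylo_d, n_perm = n_perm, seed = seed)
    })
    out$vs_tree <- run_block(vs_tree, "mantel_vs_phylogeny")
  }
  dplyr::bind_rows(out)
}
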