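# Resampling test for genomic co-clustering: is gene group A closer to gene
# group B than to random gene sets of the same size?

# Gap in bp between two 1-based inclusive intervals; 0 when they overlap or
# abut. Strand-agnostic.
interval_gap <- function(a_start, a_end, b_start, b_end) {
  pmax(0L, pmax(a_start, b_start) - pmin(a_end, b_end) - 1L)
}

#' Distance from one gene to the closest gene of a group
#'
#' Minimum inter-interval gap (bp, 0 for overlap) between gene `a` and any
#' gene of `B` on the same sequence. A gene never measures distance to
#' itself: rows of `B` with `a`'s gene id are skipped. Returns `NA` when no
#' eligible `B` gene shares `a`'s sequence — cross-scaffold distances are
#' undefined rather than given a sentinel value, because any finite sentinel
#' would distort the group mean.
#'
#' @param a one-row locus tibble (see [read_gff_genes()]).
#' @param B locus tibble, non-empty.
#' @return distance in bp, or `NA_real_` if undefined.
#' @export
closest_distance <- function(a, B) {
  if (nrow(B) == 0) abort("B must be non-empty")
  cand <- B[B$seq_id == a$seq_id[1] & B$gene_id != a$gene_id[1], ,
            drop = FALSE]
  if (nrow(cand) == 0) return(NA_real_)
  min(interval_gap(a$start[1], a$end[1], cand$start, cand$end))
}

#' Mean closest distance from group A to group B
#'
#' Arithmetic mean of [closest_distance()] over the genes of `A`; genes with
#' no defined distance (no same-sequence `B` gene) are excluded from the
#' mean, and their number is attached as attribute `n_excluded`.
#'
#' @param A,B locus tibbles.
#' @return mean distance in bp with attributes `n_excluded` and `n_used`.
#' @export
observed_statistic <- function(A, B) {
  d <- closest_distance_all(A, B)
  if (all(is.na(d))) {
    abort("no A gene has a defined distance to any B gene")
  }
  out <- mean(d, na.rm = TRUE)
  attr(out, "n_excluded") <- sum(is.na(d))
  attr(out, "n_used") <- sum(!is.na(d))
  out
}

closest_distance_all <- function(A, B) {
  vapply(seq_len(nrow(A)), function(i) closest_distance(A[i, ], B),
         numeric(1))
}

# |A| x |U| matrix of gaps from each A gene to each universe gene;
# Inf across sequences or to the same gene id.
gap_matrix <- function(A, universe) {
  G <- matrix(Inf, nrow(A), nrow(universe))
  for (s in unique(A$seq_id)) {
    ai <- which(A$seq_id == s)
    ui <- which(universe$seq_id == s)
    if (length(ui) == 0) next
    G[ai, ui] <- outer(seq_along(ai), seq_along(ui), function(i, j) {
      interval_gap(A$start[ai[i]], A$end[ai[i]],
                   universe$start[ui[j]], universe$end[ui[j]])
    })
  }
  same <- outer(A$gene_id, universe$gene_id, "==")
  G[same] <- Inf
  G
}

#' Resampling test for co-clustering of two gene groups
#'
#' Tests whether the genes of group `A` lie closer to the genes of group `B`
#' than expected by chance. The observed statistic is the mean closest
#' distance from `A` to `B` ([observed_statistic()]). The null distribution
#' is built by drawing `n_samples` random sets of `m = nrow(B)` genes from
#' the searched-gene `universe` (without replacement by default — the same
#' list of genes in which group B was searched) and recomputing the
#' statistic against each random set. The one-sided empirical p-value for
#' the "closer than chance" alternative is
#' `(1 + #\{null <= observed\}) / (n_samples + 1)`.
#'
#' @param A,B locus tibbles for the two gene groups.
#' @param universe locus tibble of all searched genes.
#' @param n_samples number of random sets.
#' @param seed integer seed, or `NULL`.
#' @param replace sample the null sets with replacement (sensitivity check).
#' @param group_a,group_b labels carried into the result.
#' @return an object of class `cluster_test`: observed mean distance, null
#'   distribution, empirical p-value, group sizes, exclusion counts.
#' @export
cluster_test <- function(A, B, universe, n_samples = 1000, seed = NULL,
                         replace = FALSE, group_a = "A", group_b = "B") {
  for (df in list(A, B, universe)) {
    assert_cols(df, c("gene_id", "seq_id", "start", "end"), "locus table")
  }
  m <- nrow(B)
  if (m < 1 || nrow(A) < 1) abort("A and B must be non-empty")
  if (!replace && m > nrow(universe)) {
    abort(sprintf("cannot sample %d genes without replacement from a universe of %d",
                  m, nrow(universe)))
  }
  observed <- observed_statistic(A, B)

  G <- gap_matrix(A, universe)
  null_stats <- with_seed_or_not(seed, {
    vapply(seq_len(n_samples), function(i) {
      idx <- sample.int(nrow(universe), m, replace = replace)
      d <- do.call(pmin, c(as.data.frame(G[, idx, drop = FALSE]),
                           list(na.rm = TRUE)))
      d <- d[is.finite(d)]
      if (length(d) == 0) NA_real_ else mean(d)
    }, numeric(1))
  })
  n_bad <- sum(is.na(null_stats))
  if (n_bad > 0) {
    warn(sprintf("%d null sample(s) had no defined distances and were dropped",
                 n_bad))
    null_stats <- null_stats[!is.na(null_stats)]
  }
  p <- (1 + sum(null_stats <= as.numeric(observed))) /
    (length(null_stats) + 1)
  structure(list(
    group_a = group_a, n_a = nrow(A), group_b = group_b, m = m,
    observed = as.numeric(observed),
    n_excluded = attr(observed, "n_excluded"),
    n_used = attr(observed, "n_used"),
    null_stats = null_stats, n_samples = n_samples, p_value = p,
    seed = seed, replace = replace
  ), class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("Gene-group proximity test: %s (n = %d) vs %s (m = %d)\n",
              x$group_a, x$n_a, x$group_b, x$m))
  cat(sprintf("  observed mean closest distance: %.0f bp (%d gene(s) excluded)\n",
              x$observed, x$n_excluded))
  cat(sprintf("  null mean %.0f bp [%.0f, %.0f] over %d samples\n",
              mean(x$null_stats),
              quantile(x$null_stats, 0.025), quantile(x$null_stats, 0.975),
              length(x$null_stats)))
  cat(sprintf("  empirical p (closer than chance) = %.4g\n", x$p_value))
  invisible(x)
}
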