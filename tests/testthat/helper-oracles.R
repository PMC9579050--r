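# Independent oracles and small fixture builders shared across the suite.

# Brute-force Smith-Waterman DP with affine gaps (gap of length L costs
# open + L * ext), independent of the package's alignment backend.
sw_oracle <- function(q, t, open = 11, ext = 1, mat = NULL) {
  if (is.null(mat)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    mat <- e$BLOSUM62
  }
  q <- strsplit(q, "")[[1]]
  t <- strsplit(t, "")[[1]]
  n <- length(q); m <- length(t)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(E[i, j - 1] - ext, H[i, j - 1] - open - ext)
      F[i, j] <- max(F[i - 1, j] - ext, H[i - 1, j] - open - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[q[i - 1], t[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Double-loop product-moment correlation, no cor() call.
pearson_loop <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx <- dx + (x[i] - mx)^2
    dy <- dy + (y[i] - my)^2
  }
  num / sqrt(dx * dy)
}

# All permutations of 1..n (n small).
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1]] <- append(p, n, after = k - 1)
    }
  }
  out
}

# Exact Mantel p over the full permutation group (one-sided, greater),
# with the add-one estimator's population analogue: the identity
# permutation is part of the group, so p = #\{r* >= r\} / n!.
mantel_exhaustive_p <- function(A, B) {
  va <- A[upper.tri(A)]
  r_obs <- cor(va, B[upper.tri(B)])
  perms <- all_perms(nrow(A))
  r_all <- vapply(perms, function(p) {
    Bp <- B[p, p]
    cor(va, Bp[upper.tri(Bp)])
  }, numeric(1))
  mean(r_all >= r_obs - 1e-12)
}

# Exact cluster-test p over all m-subsets of the universe.
cluster_exhaustive_p <- function(A, universe, m, observed) {
  subsets <- utils::combn(nrow(universe), m, simplify = FALSE)
  stats <- vapply(subsets, function(idx) {
    as.numeric(observed_statistic(A, universe[idx, ]))
  }, numeric(1))
  mean(stats <= observed + 1e-9)
}

# --- fixture builders -------------------------------------------------

make_protein <- function(id = "p1", len = 300, gene = id, species = "sp1",
                         seq = NULL) {
  seq <- seq %||% paste(rep("M", len), collapse = "")
  tibble::tibble(protein_id = id, gene_id = gene, species_id = species,
                 sequence = seq, length = nchar(seq))
}

make_hit <- function(id = "p1", acc = "PF00069.26", seq_e = 1e-20,
                     dom_e = seq_e, score = 100, a1 = 10, a2 = 200,
                     e1 = a1, e2 = a2) {
  tibble::tibble(protein_id = id, pfam_acc = acc, seq_evalue = seq_e,
                 dom_evalue = dom_e, bitscore = score,
                 ali_start = as.integer(a1), ali_end = as.integer(a2),
                 env_start = as.integer(e1), env_end = as.integer(e2))
}

make_locus <- function(id, chr = "chr1", start = 1, end = start + 999,
                       strand = "+") {
  tibble::tibble(gene_id = id, seq_id = chr, start = as.integer(start),
                 end = as.integer(end), strand = strand)
}

no_hits <- function() make_hit()[0, ]

`%||%` <- function(x, y) if (is.null(x)) y else x
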