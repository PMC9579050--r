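# Readers and writers for every external format the pipeline touches, plus
# primary-transcript selection. All coordinates are 1-based inclusive (GFF3
# convention) throughout the package.

#' Read an amino-acid FASTA file into a protein table
#'
#' Parses a proteome FASTA into a tibble with one row per record. Header
#' lines may carry `gene=<id>` and `species=<id>` key-value annotations after
#' the sequence identifier; when `gene=` is absent the gene id is inferred by
#' stripping a trailing isoform suffix (`.1`, `.2`, ...) from the protein id
#' if `infer_gene = TRUE`, otherwise each protein is its own gene.
#'
#' @param path path to a FASTA file of amino-acid sequences.
#' @param species_id species identifier applied to records lacking a
#'   `species=` header annotation. Defaults to the file name without
#'   extension.
#' @param infer_gene logical; infer gene ids from `<gene>.<n>` isoform
#'   suffixes when no `gene=` annotation is present.
#' @return a tibble with columns `protein_id`, `gene_id`, `species_id`,
#'   `sequence`, `length`, in file order.
#' @seealso [write_fasta()], [select_primary_transcripts()]
#' @export
read_fasta <- function(path, species_id = NULL, infer_gene = TRUE) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  if (file.size(path) == 0) return(empty_protein_tbl())
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) return(empty_protein_tbl())
  headers <- names(aa)
  if (any(!nzchar(trimws(headers)))) {
    abort(sprintf("FASTA record %d has an empty header",
                  which(!nzchar(trimws(headers)))[1]))
  }
  ids <- sub("\\s.*$", "", headers)
  widths <- Biostrings::width(aa)
  if (any(widths == 0)) {
    abort(sprintf("FASTA record '%s' has an empty sequence",
                  ids[which(widths == 0)[1]]))
  }
  gene <- header_field(headers, "gene")
  if (infer_gene) {
    inferred <- sub("\\.[0-9]+$", "", ids)
  } else {
    inferred <- ids
  }
  gene <- ifelse(is.na(gene), inferred, gene)
  sp <- header_field(headers, "species")
  default_sp <- species_id %||% sub("\\.[^.]*$", "", basename(path))
  sp <- ifelse(is.na(sp), default_sp, sp)
  tibble::tibble(
    protein_id = ids,
    gene_id = gene,
    species_id = sp,
    sequence = unname(as.character(aa)),
    length = as.integer(widths)
  )
}

empty_protein_tbl <- function() {
  tibble::tibble(protein_id = character(), gene_id = character(),
                 species_id = character(), sequence = character(),
                 length = integer())
}

header_field <- function(headers, key) {
  m <- regmatches(headers, regexpr(paste0("\\b", key, "=[^\\s]+"), headers,
                                   perl = TRUE))
  out <- rep(NA_character_, length(headers))
  hit <- grepl(paste0("\\b", key, "="), headers, perl = TRUE)
  out[hit] <- sub(paste0("^", key, "="), "", m)
  out
}

#' Write a protein table to FASTA
#'
#' Inverse of [read_fasta()]: headers carry the protein id plus `gene=` and
#' `species=` annotations so a write/read round trip reproduces the table.
#'
#' @param proteins protein tibble as returned by [read_fasta()].
#' @param path output path.
#' @param width line width for wrapped sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60) {
  assert_cols(proteins, c("protein_id", "gene_id", "species_id", "sequence"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(proteins))) {
    writeLines(sprintf(">%s gene=%s species=%s", proteins$protein_id[i],
                       proteins$gene_id[i], proteins$species_id[i]), con)
    seq <- proteins$sequence[i]
    starts <- seq(1, nchar(seq), by = width)
    writeLines(substring(seq, starts, pmin(starts + width - 1, nchar(seq))),
               con)
  }
  invisible(path)
}

#' Read a domain-hit table
#'
#' Reads per-domain hits either from HMMER3 `--domtblout` output
#' (`hmmer-domtbl`; hmmsearch orientation, i.e. the target is the protein and
#' the query the profile) or from the package's plain `simple-tsv` dialect
#' (tab-separated, header row, columns `protein_id`, `pfam_acc`,
#' `seq_evalue`, `dom_evalue`, `bitscore`, `ali_start`, `ali_end`,
#' `env_start`, `env_end`). Lines starting with `#` are skipped in both
#' dialects. Coordinates are 1-based inclusive.
#'
#' @param path input file.
#' @param dialect `"simple-tsv"` or `"hmmer-domtbl"`.
#' @return a tibble of domain hits, one row per domain.
#' @seealso [write_domain_hits()]
#' @export
read_domain_hits <- function(path, dialect = c("simple-tsv", "hmmer-domtbl")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("domain-hit file not found: ", path))
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (dialect == "simple-tsv" && length(keep) > 0) {
    # first non-comment line is the header
    header <- strsplit(lines[keep[1]], "\t", fixed = TRUE)[[1]]
    if (!identical(header[1:2], c("protein_id", "pfam_acc"))) {
      abort(sprintf("line %d: expected simple-tsv header starting with 'protein_id\\tpfam_acc'",
                    keep[1]))
    }
    keep <- keep[-1]
  }
  if (length(keep) == 0) return(empty_hit_tbl())
  rows <- if (dialect == "simple-tsv") {
    strsplit(lines[keep], "\t", fixed = TRUE)
  } else {
    strsplit(trimws(lines[keep]), "\\s+")
  }
  need <- if (dialect == "simple-tsv") 9L else 22L
  nf <- lengths(rows)
  bad <- if (dialect == "simple-tsv") nf != 9L else nf < 22L
  if (any(bad)) {
    abort(sprintf("line %d: expected %s %d fields, found %d",
                  keep[which(bad)[1]],
                  if (dialect == "simple-tsv") "exactly" else "at least",
                  need, nf[which(bad)[1]]))
  }
  m <- do.call(rbind, lapply(rows, function(r) r[seq_len(need)]))
  if (dialect == "simple-tsv") {
    out <- tibble::tibble(
      protein_id = m[, 1], pfam_acc = m[, 2],
      seq_evalue = as.numeric(m[, 3]), dom_evalue = as.numeric(m[, 4]),
      bitscore = as.numeric(m[, 5]),
      ali_start = as.integer(m[, 6]), ali_end = as.integer(m[, 7]),
      env_start = as.integer(m[, 8]), env_end = as.integer(m[, 9])
    )
  } else {
    # domtblout fields: 1 target, 5 query accession, 7 full-seq E-value,
    # 12/13 c-/i-Evalue, 14 this-domain score, 18-21 ali/env coordinates
    acc <- ifelse(m[, 5] == "-", m[, 4], m[, 5])
    out <- tibble::tibble(
      protein_id = m[, 1], pfam_acc = acc,
      seq_evalue = as.numeric(m[, 7]), dom_evalue = as.numeric(m[, 13]),
      bitscore = as.numeric(m[, 14]),
      ali_start = as.integer(m[, 18]), ali_end = as.integer(m[, 19]),
      env_start = as.integer(m[, 20]), env_end = as.integer(m[, 21])
    )
  }
  bad_coord <- which(out$ali_start > out$ali_end | out$ali_start < 1)
  if (length(bad_coord) > 0) {
    abort(sprintf("line %d: invalid alignment coordinates",
                  keep[bad_coord[1]]))
  }
  out
}

empty_hit_tbl <- function() {
  tibble::tibble(protein_id = character(), pfam_acc = character(),
                 seq_evalue = numeric(), dom_evalue = numeric(),
                 bitscore = numeric(), ali_start = integer(),
                 ali_end = integer(), env_start = integer(),
                 env_end = integer())
}

#' Write a domain-hit table in the simple-tsv dialect
#'
#' @param hits domain-hit tibble as returned by [read_domain_hits()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_domain_hits <- function(hits, path) {
  assert_cols(hits, names(empty_hit_tbl()))
  readr::write_tsv(hits[names(empty_hit_tbl())], path)
  invisible(path)
}

#' Read a transmembrane-segment table
#'
#' Accepts either a two-column TSV (header `protein_id`, `n_helices`) or the
#' one-line-per-protein summary emitted by tmhmm-style predictors, from which
#' the `PredHel=` field is taken.
#'
#' @param path input file.
#' @return a tibble with columns `protein_id`, `n_helices`.
#' @export
read_tm_table <- function(path) {
  if (!file.exists(path)) abort(paste0("TM table not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(protein_id = character(), n_helices = integer()))
  }
  if (any(grepl("PredHel=", lines))) {
    ids <- sub("\\s.*$", "", lines)
    n <- as.integer(sub(".*PredHel=([0-9]+).*", "\\1", lines))
    return(tibble::tibble(protein_id = ids, n_helices = n))
  }
  out <- readr::read_tsv(I(lines), show_col_types = FALSE)
  assert_cols(out, c("protein_id", "n_helices"), "TM table")
  dplyr::mutate(out, n_helices = as.integer(.data$n_helices))
}

#' Write a transmembrane-segment table
#' @param tm tibble with `protein_id`, `n_helices`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tm_table <- function(tm, path) {
  assert_cols(tm, c("protein_id", "n_helices"))
  readr::write_tsv(tm[c("protein_id", "n_helices")], path)
  invisible(path)
}

# Kyte-Doolittle hydropathy values for the 20 standard residues.
kd_scale <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2)

#' Predict transmembrane helices by hydropathy
#'
#' Built-in fallback predictor for when no external transmembrane caller has
#' been run: a sliding Kyte-Doolittle hydropathy window (width 19) is scanned
#' along the sequence and each maximal run of windows with mean hydropathy
#' above the cutoff is counted as one helix. Non-standard residues (X, U, *)
#' contribute 0 to the window mean. This is a coarse stand-in for a dedicated
#' topology predictor and is intended for synthetic or exploratory data.
#'
#' @param proteins protein tibble as returned by [read_fasta()].
#' @param window window width in residues.
#' @param cutoff mean window hydropathy above which a window is helical.
#' @return a tibble with columns `protein_id`, `n_helices`.
#' @export
predict_tm_helices <- function(proteins, window = 19, cutoff = 1.6) {
  assert_cols(proteins, c("protein_id", "sequence"))
  n <- purrr::map_int(proteins$sequence, function(seq) {
    res <- strsplit(seq, "")[[1]]
    h <- unname(kd_scale[res])
    h[is.na(h)] <- 0
    if (length(h) < window) return(0L)
    means <- as.numeric(stats::filter(h, rep(1 / window, window),
                                      sides = 2))
    means <- means[!is.na(means)]
    runs <- rle(means > cutoff)
    sum(runs$values)
  })
  tibble::tibble(protein_id = proteins$protein_id, n_helices = n)
}

#' Read gene loci from a GFF3 file
#'
#' Extracts one locus per feature of the requested type (genes by default),
#' keeping GFF3 1-based inclusive coordinates.
#'
#' @param path GFF3 file.
#' @param feature_type feature type to extract (column 3 of the GFF).
#' @return a tibble with columns `gene_id`, `seq_id`, `start`, `end`,
#'   `strand` (`+`, `-` or `unknown`).
#' @export
read_gff_genes <- function(path, feature_type = "gene") {
  if (!file.exists(path)) abort(paste0("GFF3 file not found: ", path))
  g <- as.data.frame(rtracklayer::readGFF(path))
  g <- g[g$type == feature_type, , drop = FALSE]
  if (nrow(g) == 0) {
    return(tibble::tibble(gene_id = character(), seq_id = character(),
                          start = integer(), end = integer(),
                          strand = character()))
  }
  id <- as.character(g$ID)
  if (anyNA(id)) {
    abort(sprintf("GFF3 %s feature without an ID attribute (seqid %s, start %d)",
                  feature_type, g$seqid[which(is.na(id))[1]],
                  g$start[which(is.na(id))[1]]))
  }
  if (any(g$start > g$end)) {
    abort(sprintf("GFF3 feature '%s' has start > end",
                  id[which(g$start > g$end)[1]]))
  }
  if (any(g$start < 1)) {
    abort(sprintf("GFF3 feature '%s' has start < 1",
                  id[which(g$start < 1)[1]]))
  }
  strand <- as.character(g$strand)
  strand[!strand %in% c("+", "-")] <- "unknown"
  tibble::tibble(gene_id = id, seq_id = as.character(g$seqid),
                 start = as.integer(g$start), end = as.integer(g$end),
                 strand = strand)
}

#' Write gene loci as GFF3
#'
#' @param loci locus tibble as returned by [read_gff_genes()].
#' @param path output path.
#' @param feature_type feature type for column 3.
#' @return `path`, invisibly.
#' @export
write_gff_genes <- function(loci, path, feature_type = "gene") {
  assert_cols(loci, c("gene_id", "seq_id", "start", "end", "strand"))
  strand <- ifelse(loci$strand %in% c("+", "-"), loci$strand, ".")
  lines <- sprintf("%s\t.\t%s\t%d\t%d\t.\t%s\t.\tID=%s", loci$seq_id,
                   feature_type, loci$start, loci$end, strand, loci$gene_id)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read a Newick species tree
#'
#' @param path Newick file; leaf labels are species ids.
#' @return an [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) abort(paste0("Newick file not found: ", path))
  tree <- ape::read.tree(path)
  if (is.null(tree)) abort(paste0("could not parse Newick file: ", path))
  if (anyDuplicated(tree$tip.label) > 0) {
    abort("tree leaf labels are not unique")
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    abort("tree has negative branch lengths")
  }
  tree
}

#' Write a species tree as Newick
#' @param tree an [ape::phylo] tree.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Patristic distance matrix of a species tree
#'
#' Sums branch lengths along the tree path between every pair of requested
#' leaves. The result is symmetric with a zero diagonal, restricted to and
#' ordered by `labels`.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param labels leaf labels to keep, in the desired matrix order. Defaults
#'   to all leaves in tree order.
#' @return a labelled numeric matrix of patristic distances, with attribute
#'   `provenance = "phylogeny"`.
#' @seealso [percent_to_distance()], [mantel()]
#' @export
patristic_distances <- function(tree, labels = NULL) {
  labels <- labels %||% tree$tip.label
  missing <- setdiff(labels, tree$tip.label)
  if (length(missing) > 0) {
    abort(paste0("labels absent from tree: ", paste(missing, collapse = ", ")))
  }
  d <- ape::cophenetic.phylo(tree)[labels, labels, drop = FALSE]
  attr(d, "provenance") <- "phylogeny"
  d
}

#' Keep one primary transcript per gene
#'
#' Reduces a proteome to a single representative protein per gene: the
#' longest isoform, with ties broken by the lexicographically smallest
#' protein id. This is the standard proxy for the curated "primary gene
#' model" when source databases do not flag one. Output rows are sorted by
#' gene id so the result is identical under any permutation of the input.
#'
#' @param proteins protein tibble as returned by [read_fasta()].
#' @return the filtered protein tibble, one row per gene.
#' @export
select_primary_transcripts <- function(proteins) {
  assert_cols(proteins, c("protein_id", "length"))
  if (!"gene_id" %in% names(proteins) || anyNA(proteins$gene_id)) {
    warn("no gene map available; treating each protein as its own gene")
    proteins$gene_id <- dplyr::coalesce(proteins$gene_id %||% NA_character_,
                                        proteins$protein_id)
  }
  proteins |>
    dplyr::arrange(.data$gene_id, dplyr::desc(.data$length),
                   .data$protein_id) |>
    dplyr::distinct(.data$gene_id, .keep_all = TRUE)
}
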