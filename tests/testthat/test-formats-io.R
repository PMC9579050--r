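test_that("FASTA records are parsed with lengths, gene inference and order", {
  path <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">a gene=g1 species=spX", "MK", ">b", "MKL"), path)
  p <- read_fasta(path)
  expect_equal(p$protein_id, c("a", "b"))
  expect_equal(p$length, c(2L, 3L))
  expect_equal(p$gene_id[1], "g1")
  expect_equal(p$species_id[1], "spX")

  # multi-line sequences are concatenated
  chunk <- paste(rep("A", 60), collapse = "")
  writeLines(c(">long", chunk, chunk, chunk), path)
  expect_equal(read_fasta(path)$length, 180L)

  # isoform suffix gives the gene id
  writeLines(c(">g7.2", "MKLV"), path)
  expect_equal(read_fasta(path)$gene_id, "g7")

  # empty file is a vacuous proteome
  writeLines(character(0), path)
  expect_equal(nrow(read_fasta(path)), 0L)

  # empty sequence is a format error naming the record
  writeLines(c(">ok", "MK", ">broken", "", ">next", "ML"), path)
  expect_error(read_fasta(path), "broken")
})

test_that("FASTA write/read round trip preserves every field", {
  p <- tibble::tibble(
    protein_id = c("a1.1", "b2"), gene_id = c("a1", "b2"),
    species_id = "spY",
    sequence = c(strrep("MKLVH", 30), strrep("AC", 40)))
  p$length <- nchar(p$sequence)
  path <- withr::local_tempfile(fileext = ".faa")
  write_fasta(p, path)
  expect_equal(read_fasta(path), p)
})

test_that("simple-tsv domain hits parse, skip comments, and check columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  hdr <- paste(c("protein_id", "pfam_acc", "seq_evalue", "dom_evalue",
                 "bitscore", "ali_start", "ali_end", "env_start",
                 "env_end"), collapse = "\t")
  writeLines(c("# comment", hdr,
               "p1\tPF00931.23\t1e-30\t1e-28\t150\t10\t300\t8\t305",
               "p2\tPF00069.26\t1e-12\t1e-11\t90\t50\t280\t45\t290",
               "p2\tPF13855.7\t1e-4\t1e-4\t30\t5\t20\t5\t20"), path)
  h <- read_domain_hits(path, "simple-tsv")
  expect_equal(nrow(h), 3L)
  expect_equal(h$pfam_acc[1], "PF00931.23")
  expect_equal(h$seq_evalue[1], 1e-30)
  expect_equal(sum(h$protein_id == "p2"), 2L)

  # comment-only file -> empty table
  writeLines(c("# only", "# comments"), path)
  expect_equal(nrow(read_domain_hits(path, "simple-tsv")), 0L)

  # wrong column count -> error with line number
  writeLines(c(hdr, "p1\tPF00069.26\t1e-12"), path)
  expect_error(read_domain_hits(path, "simple-tsv"), "line 2")
})

test_that("HMMER domtblout rows map onto the hit schema", {
  # hmmsearch --domtblout layout: target = protein, query = profile
  row <- paste("prot1 - 900 NB-ARC PF00931.23 280 1.2e-40 140.1 0.1 1 2",
               "3.1e-30 2.2e-28 120.5 0.2 5 270 10 290 8 295 0.95 desc text")
  path <- withr::local_tempfile(fileext = ".domtbl")
  writeLines(c("# comment line", row), path)
  h <- read_domain_hits(path, "hmmer-domtbl")
  expect_equal(h$protein_id, "prot1")
  expect_equal(h$pfam_acc, "PF00931.23")
  expect_equal(h$seq_evalue, 1.2e-40)
  expect_equal(h$dom_evalue, 2.2e-28)
  expect_equal(h$bitscore, 120.5)
  expect_equal(unlist(h[, c("ali_start", "ali_end", "env_start", "env_end")],
                      use.names = FALSE), c(10L, 290L, 8L, 295L))
})

test_that("domain-hit round trip via simple-tsv is lossless", {
  h <- dplyr::bind_rows(make_hit("p1"), make_hit("p2", "PF00931.23", 1e-44))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_domain_hits(h, path)
  expect_equal(read_domain_hits(path, "simple-tsv"), h)
})

test_that("TM tables read from both TSV and tmhmm-style summaries", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tn_helices", "p1\t2", "p2\t0"), path)
  tm <- read_tm_table(path)
  expect_equal(tm$n_helices, c(2L, 0L))

  writeLines(c("p1\tlen=500\tExpAA=44.1\tFirst60=0.1\tPredHel=2\tTopology=i12-34o",
               "p2\tlen=200\tExpAA=0.2\tFirst60=0.0\tPredHel=0\tTopology=o"),
             path)
  expect_equal(read_tm_table(path), tm)

  write_tm_table(tm, path)
  expect_equal(read_tm_table(path), tm)
})

test_that("hydropathy fallback finds hydrophobic stretches only", {
  p <- tibble::tibble(
    protein_id = c("tm1", "sol"),
    sequence = c(paste0(strrep("DENK", 10), strrep("ILVF", 6),
                        strrep("DENK", 10)),
                 strrep("DENKRQST", 10)))
  out <- predict_tm_helices(p)
  expect_equal(out$n_helices, c(1L, 0L))
})

test_that("GFF3 gene extraction respects feature type and validates", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\t.\tgene\t100\t500\t.\t+\t.\tID=g1",
               "chr2\t.\tgene\t10\t90\t.\t-\t.\tID=g2",
               "chr1\t.\tmRNA\t100\t500\t.\t+\t.\tID=g1.1;Parent=g1"),
             path)
  g <- read_gff_genes(path)
  expect_equal(nrow(g), 2L)
  expect_equal(g$start[g$gene_id == "g1"], 100L)
  expect_equal(g$end[g$gene_id == "g1"], 500L)
  expect_equal(sort(unique(g$seq_id)), c("chr1", "chr2"))

  # only mRNA features + gene filter -> empty
  writeLines(c("##gff-version 3",
               "chr1\t.\tmRNA\t100\t500\t.\t+\t.\tID=m1"), path)
  expect_equal(nrow(read_gff_genes(path)), 0L)

  # inverted coordinates are a format error
  writeLines(c("##gff-version 3",
               "chr1\t.\tgene\t500\t100\t.\t+\t.\tID=bad"), path)
  expect_error(read_gff_genes(path), "start > end")
})

test_that("GFF3 write/read round trip preserves loci", {
  loci <- dplyr::bind_rows(make_locus("g1", "chr1", 100, 500),
                           make_locus("g2", "scaf9", 7, 2000, "-"))
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff_genes(loci, path)
  expect_equal(read_gff_genes(path), loci)
})

test_that("patristic distances are path-length sums over the tree", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", path)
  tree <- read_newick(path)
  d <- patristic_distances(tree, c("A", "B", "C"))
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 4)
  expect_equal(d["B", "C"], 4)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 3))

  # restriction to one leaf
  d1 <- patristic_distances(tree, "B")
  expect_equal(dim(d1), c(1L, 1L))
  expect_equal(d1[1, 1], 0)

  # zero-length branches give the zero matrix
  writeLines("((A:0,B:0):0,C:0);", path)
  expect_true(all(patristic_distances(read_newick(path)) == 0))

  expect_error(patristic_distances(tree, c("A", "Z")), "Z")

  # write/read round trip preserves the patristic structure
  out <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, out)
  expect_equal(patristic_distances(read_newick(out), c("A", "B", "C")), d)
})

test_that("patristic matrices from simulated trees satisfy the four-point condition", {
  cfg <- simulation_config(n_species = 8)
  for (s in 1:5) {
    tree <- simulate_tree(cfg, seed = s)
    d <- patristic_distances(tree)
    quads <- utils::combn(rownames(d), 4, simplify = FALSE)
    for (q in quads[seq(1, length(quads), by = 7)]) {
      s1 <- d[q[1], q[2]] + d[q[3], q[4]]
      s2 <- d[q[1], q[3]] + d[q[2], q[4]]
      s3 <- d[q[1], q[4]] + d[q[2], q[3]]
      two_largest <- sort(c(s1, s2, s3), decreasing = TRUE)[1:2]
      expect_equal(two_largest[1], two_largest[2], tolerance = 1e-9)
    }
  }
})

test_that("primary-transcript selection keeps the longest isoform deterministically", {
  p <- dplyr::bind_rows(
    make_protein("g1.1", 300, gene = "g1"),
    make_protein("g1.2", 250, gene = "g1"),
    make_protein("g2.2", 100, gene = "g2"),
    make_protein("g2.1", 100, gene = "g2"),
    make_protein("solo", 80, gene = "solo"))
  out <- select_primary_transcripts(p)
  expect_equal(sort(out$protein_id), c("g1.1", "g2.1", "solo"))

  # idempotent and invariant under input permutation
  expect_equal(select_primary_transcripts(out), out)
  for (s in 1:3) {
    perm <- p[sample(nrow(p)), ]
    expect_equal(select_primary_transcripts(perm), out)
  }

  # unique gene ids pass through unchanged (up to ordering)
  q <- dplyr::bind_rows(make_protein("a", 10, gene = "a"),
                        make_protein("b", 20, gene = "b"))
  expect_equal(select_primary_transcripts(q), q)
})
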