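t0 <- rule_thresholds()

test_that("LRR-RLK rule needs length, kinase and LRR at their thresholds", {
  hits <- dplyr::bind_rows(make_hit("p", "PF00069.26", 1e-15),
                           make_hit("p", "PF13855.7", 1e-5))
  expect_true(classify_lrr_rlk(make_protein("p", 300), hits, t0))
  # too short
  expect_false(classify_lrr_rlk(make_protein("p", 200), hits, t0))
  # LRR above its threshold
  hits2 <- dplyr::bind_rows(make_hit("p", "PF00069.26", 1e-15),
                            make_hit("p", "PF13855.7", 5e-2))
  expect_false(classify_lrr_rlk(make_protein("p", 300), hits2, t0))
  # kinase above its threshold
  hits3 <- dplyr::bind_rows(make_hit("p", "PF00069.26", 1e-9),
                            make_hit("p", "PF13855.7", 1e-5))
  expect_false(classify_lrr_rlk(make_protein("p", 300), hits3, t0))
  # thresholds are inclusive on the passing side
  hits4 <- dplyr::bind_rows(make_hit("p", "PF00069.26", 1e-10),
                            make_hit("p", "PF13855.7", 1e-2))
  expect_true(classify_lrr_rlk(make_protein("p", 250), hits4, t0))
  expect_false(classify_lrr_rlk(make_protein("p", 249), hits4, t0))
})

test_that("LRR-RLP rule needs LRR, C3F (>=140 aa), a TM helix and no kinase", {
  base <- function(c3f_len = 150, c3f_e = 1e-12) {
    dplyr::bind_rows(make_hit("p", "PF13855.7", 1e-4),
                     make_hit("p", "C3F", c3f_e, a1 = 200,
                              a2 = 200 + c3f_len - 1))
  }
  p <- make_protein("p", 400)
  expect_true(classify_lrr_rlp(p, base(), 1, t0))
  # C3F alignment one residue short
  expect_false(classify_lrr_rlp(p, base(c3f_len = 139), 1, t0))
  expect_true(classify_lrr_rlp(p, base(c3f_len = 140), 1, t0))
  # a passing kinase hit vetoes the call
  with_kin <- dplyr::bind_rows(base(), make_hit("p", "PF00069.26", 1e-12))
  expect_false(classify_lrr_rlp(p, with_kin, 1, t0))
  # ... but a sub-threshold kinase hit does not
  weak_kin <- dplyr::bind_rows(base(), make_hit("p", "PF00069.26", 1e-8))
  expect_true(classify_lrr_rlp(p, weak_kin, 1, t0))
  # no TM helix
  expect_false(classify_lrr_rlp(p, base(), 0, t0))
  # candidate without a TM record is an error naming the protein
  expect_error(classify_lrr_rlp(p, base(), NULL, t0), "p")
  # non-candidates do not require TM evidence
  expect_false(classify_lrr_rlp(p, no_hits(), NULL, t0))
})

test_that("NB-ARC rule applies the 150 AA floor and the strict E-value", {
  expect_true(classify_nbarc(make_protein("p", 900),
                             make_hit("p", "PF00931.23", 1e-50), t0))
  expect_false(classify_nbarc(make_protein("p", 140),
                              make_hit("p", "PF00931.23", 1e-50), t0))
  expect_false(classify_nbarc(make_protein("p", 900),
                              make_hit("p", "PF00931.23", 1e-8), t0))
  expect_true(classify_nbarc(make_protein("p", 150),
                             make_hit("p", "PF00931.23", 1e-10), t0))
})

test_that("LysM candidates split into RLK/RLP by kinase presence", {
  lysm <- make_hit("p", "PF01476.21", 5)
  kin <- make_hit("p", "PF00069.26", 1e-20)
  p <- make_protein("p", 300)
  expect_equal(classify_lysm(p, dplyr::bind_rows(lysm, kin), 1, t0),
               "LysM-RLK")
  expect_equal(classify_lysm(p, lysm, 1, t0), "LysM-RLP")
  expect_equal(classify_lysm(p, lysm, 0, t0), "none")
  expect_equal(classify_lysm(make_protein("p", 149), lysm, 1, t0), "none")
  # the permissive threshold really is permissive (and inclusive)
  expect_equal(classify_lysm(p, make_hit("p", "PF01476.21", 1000), 1, t0),
               "LysM-RLP")
  expect_equal(classify_lysm(p, make_hit("p", "PF01476.21", 1001), 1, t0),
               "none")
})

test_that("classification is monotone when thresholds tighten", {
  set.seed(71)
  accs <- c("PF00069.26", "PF00931.23", "PF13855.7", "PF00560.34",
            "PF01476.21", "C3F")
  tight <- rule_thresholds(kinase_evalue = 1e-14, lrr_evalue = 1e-4,
                           nbarc_evalue = 1e-14, lysm_evalue = 1,
                           c3f_evalue = 1e-14)
  for (i in 1:60) {
    len <- sample(100:1000, 1)
    p <- make_protein("p", len)
    h <- dplyr::bind_rows(lapply(seq_len(sample(0:4, 1)), function(j) {
      make_hit("p", sample(accs, 1), 10^runif(1, -30, 2),
               a1 = 1, a2 = min(len, 160))
    }))
    if (nrow(h) == 0) h <- no_hits()
    tm <- sample(0:2, 1)
    expect_false(!classify_lrr_rlk(p, h, t0) && classify_lrr_rlk(p, h, tight))
    expect_false(!classify_nbarc(p, h, t0) && classify_nbarc(p, h, tight))
    ly0 <- classify_lysm(p, h, tm, t0)
    ly1 <- classify_lysm(p, h, tm, tight)
    expect_true(ly1 == "none" || ly0 != "none")
  }
})

test_that("kinase-region extraction picks the top-scoring envelope", {
  seq <- paste(sample(c("A", "C", "D", "E", "F"), 400, TRUE), collapse = "")
  p <- make_protein("p", seq = seq)
  one <- make_hit("p", "PF00069.26", 1e-20, score = 80, e1 = 10, e2 = 260)
  expect_equal(extract_kinase_region(p, one, t0), substr(seq, 10, 260))
  expect_equal(nchar(extract_kinase_region(p, one, t0)), 251L)

  two <- dplyr::bind_rows(
    make_hit("p", "PF00069.26", 1e-20, score = 80, e1 = 10, e2 = 260),
    make_hit("p", "PF00069.26", 1e-20, score = 120, e1 = 100, e2 = 350))
  expect_equal(extract_kinase_region(p, two, t0), substr(seq, 100, 350))

  tie <- dplyr::bind_rows(
    make_hit("p", "PF00069.26", 1e-20, score = 100, e1 = 300, e2 = 390),
    make_hit("p", "PF00069.26", 1e-20, score = 100, e1 = 10, e2 = 100))
  expect_equal(extract_kinase_region(p, tie, t0), substr(seq, 10, 100))

  expect_error(extract_kinase_region(p, no_hits(), t0), "kinase")
})

test_that("local alignment scores match hand sums and the SW floor", {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  B62 <- e$BLOSUM62
  q <- "MKKLLEAGHS"
  diag_sum <- sum(vapply(strsplit(q, "")[[1]], function(r) B62[r, r],
                         numeric(1)))
  expect_equal(local_align_score(q, q), diag_sum)
  # no positive-scoring path -> floor at 0
  expect_equal(local_align_score("AAAA", "PPPP"), 0)
  # exact substring scores like self-alignment
  target <- paste0("DDDDD", q, "EEEEE")
  expect_equal(local_align_score(q, target), diag_sum)
  # symmetry
  expect_equal(local_align_score(q, target), local_align_score(target, q))
  expect_error(local_align_score("", q), "non-empty")
})

test_that("local alignment equals a brute-force DP on short peptides", {
  set.seed(42)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  for (i in 1:20) {
    q <- paste(sample(aa, sample(4:15, 1), TRUE), collapse = "")
    t <- paste(sample(aa, sample(4:15, 1), TRUE), collapse = "")
    expect_equal(local_align_score(q, t), sw_oracle(q, t))
  }
})

test_that("subgroup assignment is best-hit with a score floor", {
  set.seed(9)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  panel <- kinase_panel(
    c("II", "XII", "XI"),
    vapply(1:3, function(i) paste(sample(aa, 60, TRUE), collapse = ""),
           character(1)))
  # identical to a panel entry -> that subgroup
  expect_equal(assign_subgroup(panel$sequence[2], panel, t0), "XII")
  # nothing above the floor -> unclassified
  expect_equal(assign_subgroup("AAAA", panel, t0), "unclassified")
  # equidistant entries of the same subgroup agree on the label
  panel2 <- kinase_panel(c("XII", "XII"), rep(panel$sequence[2], 2))
  expect_equal(assign_subgroup(panel$sequence[2], panel2, t0), "XII")
})

test_that("mutated panel copies are recovered against a brute-force scorer", {
  set.seed(13)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  panel <- kinase_panel(
    c("II", "VIII_1", "XII", "XI", "Xa"),
    vapply(1:5, function(i) paste(sample(aa, 40, TRUE), collapse = ""),
           character(1)))
  for (i in 1:5) {
    src <- sample(nrow(panel), 1)
    cand <- mutate_sequence(panel$sequence[src], 0.20)
    got <- assign_subgroup(cand, panel, t0)
    oracle_scores <- vapply(panel$sequence, sw_oracle, numeric(1), q = cand)
    oracle_label <- if (max(oracle_scores) < t0$subgroup_min_score) {
      "unclassified"
    } else {
      panel$subgroup[which.max(oracle_scores)]
    }
    expect_equal(got, oracle_label)
    expect_equal(got, panel$subgroup[src])
  }
})

test_that("repertoire identification recovers planted truth and handles decoys", {
  cfg <- simulation_config(n_decoys = 100)
  sim <- simulate_proteome(c("LRR-RLK" = 10, "LRR-RLP" = 5, "NB-ARC" = 8),
                           cfg, seed = 21)
  rep <- identify_repertoire(sim$proteins, sim$hits, sim$tm, panel = sim$panel)
  expect_equal(rep$n_searched, 123L)
  counts <- setNames(rep$counts$count, rep$counts$family)
  expect_equal(unname(counts[c("LRR-RLK", "LRR-RLP", "NB-ARC")]),
               c(10L, 5L, 8L))
  expect_equal(unname(counts[c("LysM-RLK", "LysM-RLP")]), c(0L, 0L))

  truth <- sim$truth[!is.na(sim$truth$family), ]
  calls <- tidy(rep)
  expect_setequal(calls$protein_id, truth$protein_id)
  rlk <- calls[calls$family == "LRR-RLK", ]
  expect_equal(rlk$subgroup,
               truth$subgroup[match(rlk$protein_id, truth$protein_id)])

  # decoys only -> all counts zero
  dec <- sim$proteins[sim$proteins$protein_id %in%
                        sim$truth$protein_id[!is.na(sim$truth$decoy_type)], ]
  rep0 <- identify_repertoire(dec, sim$hits, sim$tm, panel = sim$panel)
  expect_true(all(rep0$counts$count == 0))
})

test_that("a protein matching several family rules is counted in each", {
  p <- make_protein("dual", 900)
  h <- dplyr::bind_rows(make_hit("dual", "PF00931.23", 1e-40),
                        make_hit("dual", "PF00069.26", 1e-30, e1 = 300,
                                 e2 = 550),
                        make_hit("dual", "PF13855.7", 1e-5))
  rep <- identify_repertoire(p, h, tibble::tibble(protein_id = "dual",
                                                  n_helices = 1L))
  expect_setequal(rep$calls$family, c("LRR-RLK", "NB-ARC"))
  expect_equal(rep$multi_family, "dual")
  # LRR-RLK and LRR-RLP stay disjoint: the kinase vetoes the RLP call
  expect_false("LRR-RLP" %in% rep$calls$family)
})
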