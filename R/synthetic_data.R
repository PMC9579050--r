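# Synthetic-data generator: per-species receptor counts with a latent shared
# factor, proteomes with planted domain architectures, gene coordinates with
# optional planted clustering, and an ultrametric species tree. Everything
# carries ground truth so every pipeline stage is testable offline.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")

random_aa <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

#' Mutate an amino-acid sequence by point substitutions
#'
#' Replaces a fixed fraction of positions (rounded down) with residues drawn
#' from the 19 alternatives, for building near-copies of reference
#' sequences.
#'
#' @param seq amino-acid string.
#' @param rate fraction of positions to substitute, in `[0, 1]`.
#' @return the mutated string.
#' @export
mutate_sequence <- function(seq, rate) {
  stopifnot(rate >= 0, rate <= 1)
  res <- strsplit(seq, "")[[1]]
  k <- floor(rate * length(res))
  if (k == 0) return(seq)
  pos <- sample(length(res), k)
  res[pos] <- vapply(res[pos],
                     function(r) sample(setdiff(AA20, r), 1), character(1))
  paste(res, collapse = "")
}

#' Simulation configuration
#'
#' Bundles every knob of the generator. Counts follow a Poisson log-linear
#' latent-factor model: each species carries a standard-normal latent factor
#' `z_s` (optionally with phylogenetic signal), and family `f` in species
#' `s` has
#' `N_fs ~ Poisson(T_s * q_f * exp(b_f z_s + sigma_f e_fs - (b_f^2 + sigma_f^2)/2))`
#' with `T_s` the proteome size, `q_f = mean_pct_f / 100` the expected
#' percentage, `b_f` the shared-factor loading and `sigma_f` family-specific
#' idiosyncratic log-normal noise. The exponent correction makes the
#' expected percentage exactly `mean_pct_f` whatever the noise scales, and
#' the shared positive loadings induce a positive correlation between family
#' percentages that [calibrate_loading()] tunes to a target Pearson r in
#' closed form.
#'
#' Defaults emulate the published study conditions: 300 angiosperm species
#' (eudicot/monocot/basal in roughly observed proportions), mean family
#' percentages inside the observed angiosperm ranges, proteome sizes of
#' 20,000-60,000 searched genes, total log-scale variance `log(2)` (so
#' percentage coefficients of variation near 100%, matching the wide
#' observed ranges), and a target percentage correlation of 0.8 for the
#' NB-ARC / LRR-RLP pair.
#'
#' @param n_species number of species (>= 3).
#' @param mean_pct named vector of expected family percentages.
#' @param target_r target Pearson correlation between the percentages of
#'   `calibration_pair`, achieved by the shared loading; ignored if
#'   `loadings` is given.
#' @param calibration_pair the two families whose correlation is calibrated.
#' @param log_var total per-family log-scale variance `b_f^2 + sigma_f^2`
#'   (controls percentage spread).
#' @param loadings optional named vector of shared-factor loadings `b_f`,
#'   overriding calibration.
#' @param base_log_rate optional named vector of baseline log count rates
#'   `a_f`; when given, family rates are `exp(a_f + ...)` independent of
#'   proteome size (mean count `exp(a_f)` when noise-corrected).
#' @param proteome_range integer range of searched-gene totals per species.
#' @param clade_probs named probabilities for clade labels.
#' @param n_decoys decoy (non-receptor) proteins per simulated proteome.
#' @param cluster_fraction fraction of LRR-RLK subgroup-XII genes planted
#'   within `cluster_window` bp of an NB-ARC gene.
#' @param cluster_window planted-cluster window in bp.
#' @param n_chromosomes,chromosome_length simulated genome geometry.
#' @param birth_rate speciation rate of the pure-birth species tree.
#' @param phylo_signal fraction of latent-factor variance attributable to
#'   Brownian motion on the tree, in `[0, 1]` (0 = no signal).
#' @param seed integer seed used by the simulators unless overridden.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_species = 300,
                              mean_pct = c("LRR-RLK" = 1.0,
                                           "LRR-RLP" = 0.25,
                                           "LysM-RLK" = 0.03,
                                           "LysM-RLP" = 0.01,
                                           "NB-ARC" = 0.8),
                              target_r = 0.8,
                              calibration_pair = c("NB-ARC", "LRR-RLP"),
                              log_var = log(2),
                              loadings = NULL,
                              base_log_rate = NULL,
                              proteome_range = c(20000, 60000),
                              clade_probs = c(eudicot = 0.69,
                                              monocot = 0.26,
                                              basal_angiosperm = 0.05),
                              n_decoys = 100,
                              cluster_fraction = 0,
                              cluster_window = 50000,
                              n_chromosomes = 5,
                              chromosome_length = 1e7,
                              birth_rate = 1,
                              phylo_signal = 0,
                              seed = NULL) {
  stopifnot(n_species >= 3, all(mean_pct > 0), log_var >= 0,
            length(proteome_range) == 2,
            proteome_range[1] <= proteome_range[2],
            cluster_fraction >= 0, cluster_fraction <= 1,
            cluster_window > 0, phylo_signal >= 0, phylo_signal <= 1,
            birth_rate > 0)
  fams <- names(mean_pct)
  if (is.null(loadings)) {
    b <- calibrate_loading(target_r,
                           q_f = mean_pct[[calibration_pair[1]]] / 100,
                           q_g = mean_pct[[calibration_pair[2]]] / 100,
                           log_var = log_var,
                           proteome_range = proteome_range)
    loadings <- setNames(rep(b, length(fams)), fams)
  }
  if (is.null(names(loadings))) names(loadings) <- fams
  if (!all(is.finite(loadings)) || any(loadings^2 > log_var + 1e-12)) {
    abort("loadings must be finite with b_f^2 <= log_var")
  }
  sigma <- setNames(sqrt(pmax(0, log_var - loadings[fams]^2)), fams)
  structure(list(
    n_species = n_species, families = fams, mean_pct = mean_pct,
    target_r = target_r, calibration_pair = calibration_pair,
    log_var = log_var, loadings = loadings[fams], sigma = sigma,
    base_log_rate = base_log_rate, proteome_range = proteome_range,
    clade_probs = clade_probs, n_decoys = n_decoys,
    cluster_fraction = cluster_fraction, cluster_window = cluster_window,
    n_chromosomes = n_chromosomes, chromosome_length = chromosome_length,
    birth_rate = birth_rate, phylo_signal = phylo_signal, seed = seed
  ), class = "simulation_config")
}

mean_inv_total <- function(proteome_range) {
  t1 <- proteome_range[1]; t2 <- proteome_range[2]
  if (t1 == t2) return(1 / t1)
  (log(t2) - log(t1)) / (t2 - t1)  # E[1/T] for T ~ Uniform(t1, t2)
}

#' Expected percentage correlation of the count model
#'
#' Closed-form Pearson correlation between the percentages of two families
#' under the Poisson log-linear latent-factor model, accounting for both the
#' log-normal family noise and the Poisson counting noise:
#' `cov = q_f q_g (e^{b_f b_g} - 1)` and
#' `var_f = q_f^2 (e^{v} - 1) + q_f E[1/T]` with `v` the total log-scale
#' variance.
#'
#' @param b_f,b_g shared-factor loadings of the two families.
#' @param q_f,q_g expected percentage fractions (`mean_pct / 100`).
#' @param log_var total log-scale variance.
#' @param proteome_range searched-gene total range.
#' @return the expected Pearson correlation.
#' @export
expected_pct_correlation <- function(b_f, b_g, q_f, q_g, log_var,
                                     proteome_range) {
  einv <- mean_inv_total(proteome_range)
  cov <- q_f * q_g * expm1(b_f * b_g)
  var_f <- q_f^2 * expm1(log_var) + q_f * einv
  var_g <- q_g^2 * expm1(log_var) + q_g * einv
  cov / sqrt(var_f * var_g)
}

#' Calibrate the shared loading for a target correlation
#'
#' Inverts [expected_pct_correlation()] for equal loadings `b_f = b_g = b`:
#' `b^2 = log(1 + r * sqrt((e^v - 1 + E[1/T]/q_f)(e^v - 1 + E[1/T]/q_g)))`.
#'
#' @inheritParams expected_pct_correlation
#' @param target_r desired Pearson correlation, in `(0, 1)`.
#' @return the loading `b`.
#' @export
calibrate_loading <- function(target_r, q_f, q_g, log_var, proteome_range) {
  stopifnot(target_r > 0, target_r < 1)
  einv <- mean_inv_total(proteome_range)
  arg <- target_r * sqrt((expm1(log_var) + einv / q_f) *
                           (expm1(log_var) + einv / q_g))
  b2 <- log1p(arg)
  if (b2 > log_var) {
    abort(sprintf("target_r = %.3f is not attainable with log_var = %.3f; increase log_var",
                  target_r, log_var))
  }
  sqrt(b2)
}

species_ids <- function(n) sprintf("sp%03d", seq_len(n))

#' Simulate per-species receptor counts
#'
#' Draws the latent species factor (standard normal, or a mixture of
#' standardized Brownian motion on `tree` and independent noise when the
#' configuration requests phylogenetic signal), proteome totals, and Poisson
#' counts per family under the model described in [simulation_config()].
#'
#' @param cfg a [simulation_config()].
#' @param tree optional [ape::phylo] tree whose tips are the species (needed
#'   when `cfg$phylo_signal > 0`).
#' @param seed integer seed; defaults to `cfg$seed`.
#' @return list with `counts` (long tibble: `species_id`, `clade`, `family`,
#'   `count`), `totals` (`species_id`, `n_searched`), and `truth` (latent
#'   factors `z`, the rate matrix `lambda`, and the config).
#' @export
simulate_counts <- function(cfg = simulation_config(), tree = NULL,
                            seed = NULL) {
  seed <- seed %||% cfg$seed
  with_seed_or_not(seed, {
    n <- cfg$n_species
    sp <- species_ids(n)
    if (cfg$phylo_signal > 0) {
      if (is.null(tree)) abort("phylo_signal > 0 requires a tree")
      if (!all(sp %in% tree$tip.label)) {
        abort("tree tips must include all simulated species ids")
      }
      bm <- ape::rTraitCont(tree, model = "BM", sigma = 1)[sp]
      bm <- (bm - mean(bm)) / stats::sd(bm)
      z <- sqrt(cfg$phylo_signal) * bm +
        sqrt(1 - cfg$phylo_signal) * rnorm(n)
    } else {
      z <- rnorm(n)
    }
    totals <- sample(seq(cfg$proteome_range[1], cfg$proteome_range[2]), n,
                     replace = TRUE)
    clade <- sample(names(cfg$clade_probs), n, replace = TRUE,
                    prob = cfg$clade_probs)
    fams <- cfg$families
    lambda <- matrix(0, n, length(fams), dimnames = list(sp, fams))
    counts <- matrix(0L, n, length(fams), dimnames = list(sp, fams))
    for (f in fams) {
      b <- cfg$loadings[[f]]; s <- cfg$sigma[[f]]
      base <- if (!is.null(cfg$base_log_rate)) {
        rep(cfg$base_log_rate[[f]], n)
      } else {
        log(totals * cfg$mean_pct[[f]] / 100)
      }
      lam <- exp(base + b * z + s * rnorm(n) - (b^2 + s^2) / 2)
      if (any(lam > 1e9)) {
        abort(sprintf("Poisson rate overflow for family %s; check config", f))
      }
      lambda[, f] <- lam
      counts[, f] <- rpois(n, lam)
    }
    counts_tbl <- tibble::as_tibble(counts) |>
      dplyr::mutate(species_id = sp, clade = clade, .before = 1) |>
      tidyr::pivot_longer(dplyr::all_of(fams), names_to = "family",
                          values_to = "count")
    list(
      counts = counts_tbl,
      totals = tibble::tibble(species_id = sp, n_searched = totals),
      truth = list(z = setNames(z, sp), lambda = lambda, config = cfg)
    )
  })
}

#' Simulate a reference kinase panel
#'
#' One random kinase-region sequence per LRR-RLK subgroup.
#'
#' @param region_length kinase-region length in residues.
#' @param seed integer seed.
#' @return a `kinase_panel` tibble.
#' @export
simulate_panel <- function(region_length = 280, seed = NULL) {
  with_seed_or_not(seed, {
    kinase_panel(lrr_rlk_subgroups(),
                 vapply(lrr_rlk_subgroups(),
                        function(s) random_aa(region_length), character(1)))
  })
}

log_unif <- function(n, lo, hi) exp(runif(n, log(lo), log(hi)))

#' Simulate a proteome with planted receptor architectures
#'
#' Emits, for one species, a protein table, a domain-hit table, a
#' transmembrane table, gene coordinates and a ground-truth table in which
#' exactly `counts[f]` proteins satisfy the rule of family `f` (E-values
#' sampled well inside the thresholds) and `cfg$n_decoys` decoys fail every
#' rule. The first planted protein of each family sits exactly on the rule
#' thresholds (length floors 250/150 AA, E-values at the cutoffs, C3F
#' alignment length 140), and the decoys always include the matching
#' boundary failures (249 AA, C3F alignment 139, E-values just outside), so
#' downstream tests pin which side of each comparison is inclusive. Planted
#' LRR-RLKs embed a mutated copy (10% substitutions) of their subgroup's
#' panel kinase region at the kinase envelope coordinates. Gene coordinates
#' are uniform over the simulated chromosomes except that a fraction
#' `cfg$cluster_fraction` of subgroup-XII genes is re-placed within
#' `cfg$cluster_window` bp of a random NB-ARC gene.
#'
#' @param counts named integer vector of planted receptor counts per family
#'   (names from [receptor_families()]).
#' @param cfg a [simulation_config()].
#' @param species_id species label for the emitted records.
#' @param panel optional `kinase_panel`; simulated if absent.
#' @param subgroups optional character vector assigning a subgroup to each
#'   planted LRR-RLK; sampled uniformly from the 20 labels by default.
#' @param seed integer seed; defaults to `cfg$seed`.
#' @return list of class `simulated_proteome` with elements `proteins`,
#'   `hits`, `tm`, `loci`, `truth`, `panel`.
#' @export
simulate_proteome <- function(counts, cfg = simulation_config(),
                              species_id = "sp001", panel = NULL,
                              subgroups = NULL, seed = NULL) {
  seed <- seed %||% cfg$seed
  fams <- receptor_families()
  counts <- counts[intersect(names(counts), fams)]
  stopifnot(all(counts >= 0))
  with_seed_or_not(seed, {
    panel <- panel %||% simulate_panel()
    rows <- list()
    idx <- 0
    new_id <- function(prefix) {
      idx <<- idx + 1
      sprintf("%s_%s%04d", species_id, prefix, idx)
    }

    plant <- function(family, i, boundary) {
      id <- new_id(switch(family, "LRR-RLK" = "rlk", "LRR-RLP" = "rlp",
                          "LysM-RLK" = "lyk", "LysM-RLP" = "lyp",
                          "NB-ARC" = "nbs"))
      strict_e <- function() log_unif(1, 1e-50, 1e-15)
      lrr_e <- function() log_unif(1, 1e-8, 1e-4)
      hit <- function(acc, seq_e, dom_e, score, a1, a2, e1 = a1, e2 = a2) {
        tibble::tibble(protein_id = id, pfam_acc = acc, seq_evalue = seq_e,
                       dom_evalue = dom_e, bitscore = score,
                       ali_start = as.integer(a1), ali_end = as.integer(a2),
                       env_start = as.integer(e1), env_end = as.integer(e2))
      }
      if (family == "LRR-RLK") {
        sub <- if (is.null(subgroups)) sample(lrr_rlk_subgroups(), 1) else
          subgroups[i]
        ref <- panel$sequence[panel$subgroup == sub][1]
        reg <- mutate_sequence(ref, 0.10)
        # the boundary candidate sits exactly on the 250 AA floor, so its
        # kinase region is truncated to fit
        if (boundary) reg <- substr(reg, 1, 200)
        len <- if (boundary) 250L else sample(600:1200, 1)
        seq <- random_aa(len)
        ks <- if (boundary) 21L else sample(150:(len - nchar(reg) - 10), 1)
        ke <- ks + nchar(reg) - 1L
        substr(seq, ks, ke) <- reg
        kin_e <- if (boundary) 1e-10 else strict_e()
        lrr_acc <- sample(lrr_accessions(), 1)
        lrr_ev <- if (boundary) 1e-2 else lrr_e()
        list(protein = tibble::tibble(protein_id = id, gene_id = id,
                                      species_id = species_id,
                                      sequence = seq, length = nchar(seq)),
             hits = dplyr::bind_rows(
               hit("PF00069.26", kin_e, kin_e, round(runif(1, 120, 400)),
                   ks, ke),
               hit(paste0(lrr_acc, ".7"), lrr_ev, lrr_ev, 30, 5, 20)),
             n_tm = 1L, family = family, subgroup = sub)
      } else if (family == "LRR-RLP") {
        len <- if (boundary) 400L else sample(400:1100, 1)
        ali_len <- if (boundary) 140L else sample(140:200, 1)
        c3f_e <- if (boundary) 1e-10 else strict_e()
        a1 <- len - ali_len - 5L
        lrr_acc <- sample(lrr_accessions(), 1)
        list(protein = tibble::tibble(protein_id = id, gene_id = id,
                                      species_id = species_id,
                                      sequence = random_aa(len),
                                      length = len),
             hits = dplyr::bind_rows(
               hit(paste0(lrr_acc, ".7"), lrr_e(), lrr_e(), 35, 10, 30),
               hit("C3F", c3f_e, c3f_e, 90, a1, a1 + ali_len - 1L)),
             n_tm = sample(1:2, 1), family = family, subgroup = NA_character_)
      } else if (family == "NB-ARC") {
        len <- if (boundary) 150L else sample(600:1400, 1)
        e <- if (boundary) 1e-10 else strict_e()
        a2 <- min(len - 2L, 300L)
        list(protein = tibble::tibble(protein_id = id, gene_id = id,
                                      species_id = species_id,
                                      sequence = random_aa(len),
                                      length = len),
             hits = hit("PF00931.23", e, e, 150, 10, a2),
             n_tm = 0L, family = family, subgroup = NA_character_)
      } else {  # LysM-RLK / LysM-RLP
        len <- if (boundary) 150L else sample(300:700, 1)
        lysm_e <- if (boundary) 1000 else log_unif(1, 1e-10, 1)
        h <- hit("PF01476.21", lysm_e, lysm_e, 25, 5,
                 min(len - 2L, 50L))
        if (family == "LysM-RLK") {
          ke <- min(len - 1L, 140L)
          h <- dplyr::bind_rows(h, hit("PF00069.26", strict_e(), 1e-20,
                                       200, 60, ke))
        }
        list(protein = tibble::tibble(protein_id = id, gene_id = id,
                                      species_id = species_id,
                                      sequence = random_aa(len),
                                      length = len),
             hits = h, n_tm = 1L, family = family, subgroup = NA_character_)
      }
    }

    planted <- list()
    for (f in names(counts)) {
      kf <- counts[[f]]
      if (kf == 0) next
      planted <- c(planted, purrr::map(seq_len(kf), function(i) {
        plant(f, i, boundary = (i == 1))
      }))
    }

    decoys <- simulate_decoys(cfg$n_decoys, new_id, species_id)

    all_parts <- c(planted, decoys)
    proteins <- purrr::map_dfr(all_parts, "protein")
    hits <- purrr::map_dfr(all_parts, "hits")
    tm <- tibble::tibble(protein_id = proteins$protein_id,
                         n_helices = purrr::map_int(all_parts, "n_tm"))
    truth <- tibble::tibble(
      protein_id = proteins$protein_id,
      gene_id = proteins$protein_id,
      species_id = species_id,
      family = purrr::map_chr(all_parts, ~ .x$family %||% NA_character_),
      subgroup = purrr::map_chr(all_parts, ~ .x$subgroup %||% NA_character_),
      decoy_type = purrr::map_chr(all_parts,
                                  ~ .x$decoy_type %||% NA_character_)
    )
    loci <- place_genes(proteins, truth, cfg)
    structure(list(proteins = proteins, hits = hits, tm = tm, loci = loci,
                   truth = truth, panel = panel),
              class = "simulated_proteome")
  })
}

# Decoy proteins, each failing every family rule; always includes the
# boundary failures that pin threshold inclusivity.
simulate_decoys <- function(n_decoys, new_id, species_id) {
  mk <- function(type, len, hits_fun, n_tm = 0L) {
    id <- new_id("dec")
    hit <- function(acc, seq_e, dom_e, score, a1, a2) {
      tibble::tibble(protein_id = id, pfam_acc = acc, seq_evalue = seq_e,
                     dom_evalue = dom_e, bitscore = score,
                     ali_start = as.integer(a1), ali_end = as.integer(a2),
                     env_start = as.integer(a1), env_end = as.integer(a2))
    }
    list(protein = tibble::tibble(protein_id = id, gene_id = id,
                                  species_id = species_id,
                                  sequence = random_aa(len), length = len),
         hits = hits_fun(hit), n_tm = n_tm, family = NA_character_,
         subgroup = NA_character_, decoy_type = type)
  }
  fixed <- list(
    # 249 AA with valid kinase + LRR: fails the 250 AA LRR-RLK floor
    mk("short_rlk_249", 249L, function(hit) dplyr::bind_rows(
      hit("PF00069.26", 1e-30, 1e-30, 200, 20, 240),
      hit("PF13855.7", 1e-5, 1e-5, 30, 5, 18))),
    # C3F alignment of 139 residues: fails the 140-residue floor
    mk("c3f_ali_139", 500L, function(hit) dplyr::bind_rows(
      hit("PF13855.7", 1e-5, 1e-5, 30, 5, 18),
      hit("C3F", 1e-20, 1e-20, 80, 300, 438)), n_tm = 1L),
    # kinase just outside its threshold
    mk("kinase_e_above", 400L, function(hit) dplyr::bind_rows(
      hit("PF00069.26", 2e-10, 2e-10, 60, 50, 300),
      hit("PF13855.7", 1e-5, 1e-5, 30, 5, 18))),
    # LRR just outside its threshold
    mk("lrr_e_above", 400L, function(hit) dplyr::bind_rows(
      hit("PF00069.26", 1e-30, 1e-30, 200, 50, 300),
      hit("PF00560.34", 2e-2, 2e-2, 10, 5, 18))),
    # NB-ARC just outside its threshold
    mk("nbarc_e_above", 900L, function(hit)
      hit("PF00931.23", 1e-8, 1e-8, 40, 10, 300)),
    # NB-ARC hit on a 149 AA fragment
    mk("nbarc_149", 149L, function(hit)
      hit("PF00931.23", 1e-30, 1e-30, 150, 10, 140)),
    # LysM + kinase but no transmembrane helix
    mk("lysm_no_tm", 400L, function(hit) dplyr::bind_rows(
      hit("PF01476.21", 1, 1, 25, 5, 48),
      hit("PF00069.26", 1e-30, 1e-30, 200, 60, 320)), n_tm = 0L)
  )
  extra <- max(0, n_decoys - length(fixed))
  plain <- purrr::map(seq_len(extra), function(i) {
    type <- sample(c("no_domain", "kinase_only", "lrr_only"), 1)
    switch(type,
      no_domain = mk("no_domain", sample(150:900, 1),
                     function(hit) tibble::tibble()),
      kinase_only = mk("kinase_only", sample(300:900, 1), function(hit)
        hit("PF00069.26", log_unif(1, 1e-40, 1e-12),
            1e-20, 150, 50, 280)),
      lrr_only = mk("lrr_only", sample(300:900, 1), function(hit)
        hit(paste0(sample(lrr_accessions(), 1), ".7"),
            log_unif(1, 1e-6, 1e-3), 1e-4, 30, 5, 18))
    )
  })
  c(fixed, plain)
}

# Uniform gene placement, then planted clustering of subgroup-XII genes
# around NB-ARC genes.
place_genes <- function(proteins, truth, cfg) {
  n <- nrow(proteins)
  chr <- sample(sprintf("chr%d", seq_len(cfg$n_chromosomes)), n,
                replace = TRUE)
  span <- pmin(proteins$length * 3L, cfg$chromosome_length %/% 10L)
  start <- purrr::map_int(span, function(s) {
    as.integer(sample.int(cfg$chromosome_length - s, 1))
  })
  loci <- tibble::tibble(gene_id = proteins$protein_id, seq_id = chr,
                         start = start, end = start + span - 1L,
                         strand = sample(c("+", "-"), n, replace = TRUE))
  if (cfg$cluster_fraction > 0) {
    xii <- which(!is.na(truth$subgroup) & truth$subgroup == "XII")
    nbs <- which(!is.na(truth$family) & truth$family == "NB-ARC")
    if (length(xii) > 0 && length(nbs) > 0) {
      k <- ceiling(cfg$cluster_fraction * length(xii))
      move <- xii[seq_len(k)]
      anchor <- sample(nbs, length(move), replace = TRUE)
      for (j in seq_along(move)) {
        i <- move[j]; b <- anchor[j]
        lo <- max(1L, loci$start[b] - as.integer(cfg$cluster_window))
        hi <- min(cfg$chromosome_length - span[i],
                  loci$end[b] + as.integer(cfg$cluster_window))
        if (hi < lo) hi <- lo
        pos <- as.integer(round(runif(1, lo, hi)))
        loci$seq_id[i] <- loci$seq_id[b]
        loci$start[i] <- pos
        loci$end[i] <- pos + span[i] - 1L
      }
    }
  }
  loci
}

#' Simulate an ultrametric species tree
#'
#' Pure-birth (Yule) tree with the configured speciation rate; tips are
#' relabelled to the simulator's species ids.
#'
#' @param cfg a [simulation_config()].
#' @param seed integer seed; defaults to `cfg$seed`.
#' @return an ultrametric [ape::phylo] tree with `cfg$n_species` tips.
#' @export
simulate_tree <- function(cfg = simulation_config(), seed = NULL) {
  seed <- seed %||% cfg$seed
  with_seed_or_not(seed, {
    tree <- ape::rphylo(cfg$n_species, birth = cfg$birth_rate, death = 0)
    tree$tip.label <- species_ids(cfg$n_species)
    tree
  })
}

#' Write a simulated proteome to disk
#'
#' Emits the FASTA, simple-tsv domain hits, TM table, GFF3 and ground-truth
#' CSV for a [simulate_proteome()] result, so the file readers can be
#' round-tripped against known truth.
#'
#' @param sim a `simulated_proteome`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix; defaults to the species id.
#' @return named character vector of the paths written.
#' @export
write_simulation <- function(sim, dir, prefix = NULL) {
  stopifnot(inherits(sim, "simulated_proteome"))
  prefix <- prefix %||% sim$proteins$species_id[1]
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, paste0(prefix, ".faa")),
    hits = file.path(dir, paste0(prefix, ".hits.tsv")),
    tm = file.path(dir, paste0(prefix, ".tm.tsv")),
    gff = file.path(dir, paste0(prefix, ".gff3")),
    truth = file.path(dir, paste0(prefix, ".truth.csv"))
  )
  write_fasta(sim$proteins, paths["fasta"])
  write_domain_hits(sim$hits, paths["hits"])
  write_tm_table(sim$tm, paths["tm"])
  write_gff_genes(sim$loci, paths["gff"])
  readr::write_csv(sim$truth, paths["truth"])
  paths
}
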