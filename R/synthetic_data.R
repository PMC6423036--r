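# Synthetic-data generators with known ground truth for every input class:
# multi-study case/control expression with batch effects and a hidden
# covariate, replicate compound rank profiles with planted set-level shifts,
# regulon/PPI graphs with planted enrichment, and two-trait association loci
# under shared or distinct causal variants. All generators are pure
# functions of (parameters, seed).

#' Simulate multi-study case/control expression with known truth
#'
#' Each study is a genes x samples matrix of Gaussian noise (sd 1) on the
#' log2 scale around gene-level baselines. Differentially expressed genes
#' are shifted in cases by a signed effect, attenuated per study by a random
#' factor in `[0.8, 1]`. Samples carry a two-level batch with additive
#' per-gene offsets (sd `batch_sd`) and a standard-normal hidden covariate
#' whose loading (sd `hidden_sd`) hits a random 30% of genes. A fraction of
#' genes is represented by two probesets (independent noise) to exercise
#' gene-level condensation.
#'
#' @param n_studies number of cohorts.
#' @param n_genes genes per cohort (shared universe).
#' @param n_per_group samples per group per cohort (>= 3).
#' @param frac_de fraction of genes differentially expressed.
#' @param effect_size absolute case-control shift for DE genes (sign is
#'   random per gene, the same in every study).
#' @param batch_sd sd of per-(gene, batch) offsets.
#' @param hidden_sd sd of hidden-covariate loadings.
#' @param seed integer seed.
#' @param dup_frac fraction of genes measured by two probesets.
#' @return list with `studies` (list of [ExpressionStudy]) and `truth`
#'   (class `SimTruth`): `de_genes` (named signed effects), `attenuation`
#'   (per study), `batch_assignment`, `hidden_covariate`, `hidden_loading`.
#' @export
sim_multistudy_expression <- function(n_studies = 5L, n_genes = 2000L,
                                      n_per_group = 25L, frac_de = 0.1,
                                      effect_size = 0.8, batch_sd = 0.5,
                                      hidden_sd = 1, seed = 1L,
                                      dup_frac = 0.2) {
  stopifnot(n_per_group >= 3L, n_genes >= 2L, n_studies >= 1L)
  with_seed(seed, {
    genes <- sprintf("G%04d", seq_len(n_genes))
    n_de <- floor(frac_de * n_genes)
    if (frac_de > 0 && n_de < 1L) {
      warning("frac_de * n_genes < 1; no DE genes generated")
    }
    de_genes <- if (n_de > 0L) sort(sample(genes, n_de)) else character(0)
    de_sign <- sample(c(-1, 1), n_de, replace = TRUE)
    de_effect <- stats::setNames(de_sign * effect_size, de_genes)

    n_load <- floor(0.3 * n_genes)
    load_genes <- sort(sample(genes, n_load))
    loading <- stats::setNames(stats::rnorm(n_load, 0, hidden_sd), load_genes)
    loading_full <- stats::setNames(numeric(n_genes), genes)
    loading_full[load_genes] <- loading

    n_dup <- floor(dup_frac * n_genes)
    dup_genes <- sort(sample(genes, n_dup))
    feature_ids <- c(genes, paste0(dup_genes, "_ps2"))
    feature_gene <- stats::setNames(c(genes, dup_genes), feature_ids)

    baseline <- stats::setNames(stats::rnorm(n_genes, 7, 1), genes)
    effect_full <- stats::setNames(numeric(n_genes), genes)
    effect_full[de_genes] <- de_effect

    attenuation <- stats::runif(n_studies, 0.8, 1)
    n_samp <- 2L * n_per_group
    studies <- vector("list", n_studies)
    batch_assignment <- vector("list", n_studies)
    hidden_covariate <- vector("list", n_studies)
    for (s in seq_len(n_studies)) {
      sid <- sprintf("study%02d", s)
      sample_ids <- sprintf("%s_s%02d", sid, seq_len(n_samp))
      group <- rep(c("case", "control"), each = n_per_group)
      # balanced two-level batch within each group
      batch <- character(n_samp)
      for (g in c("case", "control")) {
        idx <- which(group == g)
        batch[idx] <- sample(rep(c("b1", "b2"), length.out = length(idx)))
      }
      hidden <- stats::rnorm(n_samp)
      batch_off <- matrix(stats::rnorm(n_genes * 2L, 0, batch_sd), ncol = 2L,
                          dimnames = list(genes, c("b1", "b2")))
      signal <- baseline +
        outer(effect_full * attenuation[s], as.numeric(group == "case")) +
        outer(loading_full, hidden) +
        batch_off[, batch]
      vals <- rbind(
        signal + matrix(stats::rnorm(n_genes * n_samp), n_genes),
        signal[dup_genes, , drop = FALSE] +
          matrix(stats::rnorm(n_dup * n_samp), n_dup)
      )
      rownames(vals) <- feature_ids
      colnames(vals) <- sample_ids
      studies[[s]] <- ExpressionStudy(
        study_id = sid, values = vals, group = group,
        factor_covariates = data.frame(batch = batch),
        feature_to_gene = feature_gene
      )
      batch_assignment[[sid]] <- stats::setNames(batch, sample_ids)
      hidden_covariate[[sid]] <- stats::setNames(hidden, sample_ids)
    }
    truth <- structure(
      list(de_genes = de_effect, attenuation = attenuation,
           batch_assignment = batch_assignment,
           hidden_covariate = hidden_covariate,
           hidden_loading = loading_full, genes = genes),
      class = "SimTruth"
    )
    list(studies = studies, truth = truth)
  })
}

#' Simulate replicate compound rank profiles with planted set shifts
#'
#' Every replicate of every compound is a permutation of ranks `1..n_genes`
#' (rank 1 = most up-regulated). For perturbing compounds, the ranks of the
#' assigned target set are pulled toward the chosen extreme by
#' `shift_strength` rank units (replicate noise sd = `shift_strength / 5`),
#' clamped to the valid range, and the whole profile is re-ranked.
#'
#' @param n_compounds number of compounds.
#' @param n_genes size of the gene universe (`G0001...`).
#' @param replicates_per_compound replicates per compound.
#' @param target_sets [GeneSetCollection] of candidate target sets; every
#'   set must be a subset of the gene universe. By default, ten disjoint
#'   sets of 50 genes.
#' @param frac_perturbing fraction of compounds that perturb a target set.
#' @param shift_strength rank-unit pull toward the extreme; default half the
#'   list length.
#' @param seed integer seed.
#' @param active_sets how many of the target sets receive perturbing
#'   compounds. The default 1 plants one coherent compound class acting on
#'   one module (the remaining sets are unperturbed decoys); larger values
#'   scatter the perturbing compounds across sets.
#' @param directions candidate directions for perturbing compounds,
#'   sampled per compound; the default `+1` (up-regulation only) gives a
#'   directionally coherent class, `c(-1, 1)` mixes both ends.
#' @return list with `signatures` (class `CompoundSignatureSet`: per
#'   compound, a list of named rank vectors) and `truth` (`SimTruth`):
#'   `perturbed_compounds` (data.frame compound/target_set/direction) and
#'   `compound_classes` (a [GeneSetCollection] over compound ids containing
#'   the planted classes plus size-matched decoy classes of unperturbed
#'   compounds).
#' @export
sim_compound_profiles <- function(n_compounds = 200L, n_genes = 1000L,
                                  replicates_per_compound = 3L,
                                  target_sets = NULL, frac_perturbing = 0.1,
                                  shift_strength = NULL, seed = 1L,
                                  active_sets = 1L, directions = 1L) {
  genes <- sprintf("G%04d", seq_len(n_genes))
  if (is.null(shift_strength)) shift_strength <- n_genes / 2
  with_seed(seed, {
    if (is.null(target_sets)) {
      set_size <- max(2L, min(50L, floor(n_genes / 20L)))
      idx <- matrix(sample(genes, 10L * set_size), ncol = 10L)
      target_sets <- GeneSetCollection(
        stats::setNames(lapply(seq_len(10L), function(i) idx[, i]),
                        sprintf("TS%02d", seq_len(10L))),
        universe = genes
      )
    }
    if (!all(unlist(target_sets$sets) %in% genes)) {
      stop("every target set must be a subset of the gene universe")
    }
    compounds <- sprintf("C%03d", seq_len(n_compounds))
    n_pert <- floor(frac_perturbing * n_compounds)
    pert <- sort(sample(compounds, n_pert))
    active <- names(target_sets$sets)[seq_len(min(active_sets, length(target_sets$sets)))]
    assigned <- sample(active, n_pert, replace = TRUE)
    direction <- sample(rep(as.integer(directions), length.out = max(n_pert, 1L)),
                        n_pert)
    names(assigned) <- names(direction) <- pert

    n_clamped <- 0L
    signatures <- stats::setNames(vector("list", n_compounds), compounds)
    for (cmp in compounds) {
      reps <- vector("list", replicates_per_compound)
      for (r in seq_len(replicates_per_compound)) {
        base <- sample.int(n_genes)           # ranks in gene order
        score <- as.numeric(base)
        if (cmp %in% pert && shift_strength > 0) {
          members <- genes %in% target_sets$sets[[assigned[[cmp]]]]
          shifted <- score[members] -
            direction[[cmp]] * (shift_strength +
                                  stats::rnorm(sum(members), 0, shift_strength / 5))
          n_clamped <- n_clamped + sum(shifted < 1 | shifted > n_genes)
          score[members] <- pmin(pmax(shifted, 1), n_genes)
        }
        rk <- integer(n_genes)
        rk[order(score, genes, method = "radix")] <- seq_len(n_genes)
        reps[[r]] <- stats::setNames(rk, genes)
      }
      signatures[[cmp]] <- reps
    }
    if (n_clamped > 0L) {
      message(sprintf("dexnet: clamped %d shifted rank(s) to [1, %d]",
                      n_clamped, n_genes))
    }
    classes <- list()
    unpert <- setdiff(compounds, pert)
    decoy_size <- max(2L, if (n_pert > 0L) ceiling(n_pert / max(1L, length(active))) else 5L)
    for (ts in names(target_sets$sets)) {
      members <- names(assigned)[assigned == ts]
      if (length(members) > 0L) classes[[paste0("class_", ts)]] <- members
      if (length(unpert) >= decoy_size) {
        classes[[paste0("decoy_", ts)]] <- sample(unpert, decoy_size)
      }
    }
    truth <- structure(
      list(perturbed_compounds = data.frame(
             compound = pert, target_set = unname(assigned),
             direction = unname(direction), row.names = NULL),
           compound_classes = GeneSetCollection(classes, universe = compounds),
           target_sets = target_sets, genes = genes),
      class = "SimTruth"
    )
    list(signatures = structure(list(compounds = signatures, genes = genes),
                                class = "CompoundSignatureSet"),
         truth = truth)
  })
}

#' @export
print.CompoundSignatureSet <- function(x, ...) {
  cat(sprintf("CompoundSignatureSet: %d compounds x %d genes (%d replicates each)\n",
              length(x$compounds), length(x$genes),
              length(x$compounds[[1L]])))
  invisible(x)
}

#' Simulate TF regulons, kinase substrate sets and a PPI graph
#'
#' Builds per-TF target sets (one to three ChIP-style source sets per TF,
#' named `TF::src<i>`), a kinase-substrate collection over the protein
#' universe, and a TF-partner interaction graph. Enriched TFs draw module
#' genes into their targets at 3.5x the background rate; the planted
#' kinase's substrates over-represent the enriched TFs and their PPI
#' neighbors.
#'
#' @param n_tfs number of transcription factors (`TF001...`).
#' @param n_genes size of the target-gene universe (`G0001...`).
#' @param module character vector of module genes (subset of the universe);
#'   default: 150 random genes.
#' @param enriched_tfs number of TFs with module-enriched targets.
#' @param n_kinases number of kinases (`KINASE001...`).
#' @param enriched_kinase name of the planted kinase.
#' @param seed integer seed.
#' @param regulon_size genes per source set.
#' @param tf_degree mean number of PPI partners per TF.
#' @return list with `regulons` ([GeneSetCollection] over genes),
#'   `kinase_substrates` ([GeneSetCollection] over proteins), `ppi`
#'   ([PPIGraph]), `expressed` (protein universe) and `truth` (`SimTruth`):
#'   `enriched_tfs`, `enriched_kinase`, `module`, `proteins`.
#' @export
sim_regulon_ppi <- function(n_tfs = 100L, n_genes = 2000L, module = NULL,
                            enriched_tfs = 10L, n_kinases = 50L,
                            enriched_kinase = "KINASE001", seed = 1L,
                            regulon_size = 100L, tf_degree = 5) {
  stopifnot(enriched_tfs <= n_tfs)
  with_seed(seed, {
    genes <- sprintf("G%04d", seq_len(n_genes))
    if (is.null(module)) {
      module <- sort(sample(genes, 150L))
    }
    if (length(module) > n_genes || !all(module %in% genes)) {
      stop("module must be a subset of the gene universe")
    }
    tfs <- sprintf("TF%03d", seq_len(n_tfs))
    enr_tfs <- if (enriched_tfs > 0L) sort(sample(tfs, enriched_tfs)) else character(0)
    f_bg <- length(module) / n_genes
    nonmod <- setdiff(genes, module)

    regulons <- list()
    for (tf in tfs) {
      rate <- if (tf %in% enr_tfs) min(3.5 * f_bg, 0.9) else f_bg
      for (src in seq_len(sample(1:3, 1L))) {
        n_mod <- stats::rbinom(1L, regulon_size, rate)
        regulons[[sprintf("%s::src%d", tf, src)]] <-
          c(sample(module, min(n_mod, length(module))),
            sample(nonmod, regulon_size - min(n_mod, length(module))))
      }
    }

    partners <- sprintf("P%04d", seq_len(5L * n_tfs))
    deg <- pmax(1L, stats::rpois(n_tfs, tf_degree))
    edges <- do.call(rbind, lapply(seq_len(n_tfs), function(i) {
      cbind(tfs[i], sample(partners, deg[i]))
    }))
    ppi <- PPIGraph(edges)
    proteins <- c(tfs, partners)

    # substrates of the planted kinase concentrate on the enriched TFs and
    # their interaction partners; other kinases sample proteins uniformly
    enr_neigh <- unique(c(edges[edges[, 1L] %in% enr_tfs, 2L]))
    core <- unique(c(enr_tfs, enr_neigh))
    substrates <- list()
    for (k in seq_len(n_kinases)) {
      kname <- sprintf("KINASE%03d", k)
      substrates[[kname]] <- if (kname == enriched_kinase && length(core) > 0L) {
        unique(c(sample(core, ceiling(0.6 * length(core))),
                 sample(proteins, 10L)))
      } else {
        sample(proteins, 30L)
      }
    }
    if (!enriched_kinase %in% names(substrates)) {
      stop(sprintf("enriched_kinase '%s' is outside KINASE001..KINASE%03d",
                   enriched_kinase, n_kinases))
    }
    truth <- structure(
      list(enriched_tfs = enr_tfs, enriched_kinase = enriched_kinase,
           module = module, proteins = proteins, genes = genes),
      class = "SimTruth"
    )
    list(regulons = GeneSetCollection(regulons, universe = genes),
         kinase_substrates = GeneSetCollection(substrates, universe = proteins),
         ppi = ppi, expressed = proteins, truth = truth)
  })
}

#' Simulate a two-trait association locus
#'
#' Generates per-variant summary statistics for two traits at one locus of
#' independent variants (no LD, so the single-causal-variant assumption of
#' the colocalization model holds exactly). Scenarios: `H0` no association;
#' `H1`/`H2` one causal variant in trait 1/2 only; `H3` distinct causal
#' variants; `H4` one shared causal variant. Standard errors follow
#' `1 / sqrt(2 * maf * (1 - maf) * n)` with maf ~ U(0.05, 0.5); observed
#' betas are the true effects plus N(0, se) noise.
#'
#' @param n_snps number of variants (>= 2 for `H3`).
#' @param scenario one of `"H0"`, `"H1"`, `"H2"`, `"H3"`, `"H4"`.
#' @param n1,n2 sample sizes of the two traits.
#' @param effect causal-variant effect size.
#' @param seed integer seed.
#' @return list with `trait1`, `trait2` (`SummaryStatsTable`) and `truth`
#'   (`SimTruth`): `scenario`, `causal1`, `causal2`.
#' @export
sim_coloc_locus <- function(n_snps = 500L, scenario = "H4", n1 = 5000L,
                            n2 = 5000L, effect = 0.35, seed = 1L) {
  if (!scenario %in% c("H0", "H1", "H2", "H3", "H4")) {
    stop("scenario must be one of H0, H1, H2, H3, H4")
  }
  if (scenario == "H3" && n_snps < 2L) stop("H3 needs at least 2 variants")
  with_seed(seed, {
    ids <- sprintf("rs%05d", seq_len(n_snps))
    maf <- stats::runif(n_snps, 0.05, 0.5)
    causal <- sample(ids, 2L)
    c1 <- c2 <- NA_character_
    b1_true <- b2_true <- numeric(n_snps)
    if (scenario %in% c("H1", "H3", "H4")) {
      c1 <- causal[1L]
      b1_true[ids == c1] <- effect
    }
    if (scenario %in% c("H2", "H3", "H4")) {
      c2 <- if (scenario == "H4") causal[1L] else causal[2L]
      b2_true[ids == c2] <- effect
    }
    make_trait <- function(b_true, n, trait_id) {
      se <- 1 / sqrt(2 * maf * (1 - maf) * n)
      beta <- b_true + stats::rnorm(n_snps, 0, se)
      summary_stats_table(
        data.frame(variant_id = ids, beta = beta, se = se,
                   p = 2 * stats::pnorm(-abs(beta / se)), maf = maf,
                   n = n, case_fraction = NA_real_,
                   stringsAsFactors = FALSE),
        trait_id
      )
    }
    truth <- structure(list(scenario = scenario, causal1 = c1, causal2 = c2),
                       class = "SimTruth")
    list(trait1 = make_trait(b1_true, n1, "trait1"),
         trait2 = make_trait(b2_true, n2, "trait2"),
         truth = truth)
  })
}
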