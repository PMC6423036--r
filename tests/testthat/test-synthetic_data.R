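test_that("expression generator is deterministic and honors the null", {
  a <- sim_multistudy_expression(n_studies = 2, n_genes = 100, n_per_group = 5,
                                 seed = 42)
  b <- sim_multistudy_expression(n_studies = 2, n_genes = 100, n_per_group = 5,
                                 seed = 42)
  expect_identical(a$studies[[1]]$values, b$studies[[1]]$values)
  expect_identical(a$truth$de_genes, b$truth$de_genes)
  d <- sim_multistudy_expression(n_studies = 2, n_genes = 100, n_per_group = 5,
                                 seed = 43)
  expect_false(identical(a$studies[[1]]$values, d$studies[[1]]$values))

  null <- sim_multistudy_expression(n_studies = 2, n_genes = 100,
                                    n_per_group = 5, effect_size = 0, seed = 1)
  expect_true(all(null$truth$de_genes == 0))
  expect_warning(
    sim_multistudy_expression(n_studies = 1, n_genes = 50, n_per_group = 3,
                              frac_de = 0.001, seed = 1),
    "no DE genes"
  )
})

test_that("within-study Hedges' g over true DE genes tracks the planted effect", {
  sim <- sim_multistudy_expression(n_studies = 5, n_genes = 2000,
                                   n_per_group = 25, frac_de = 0.1,
                                   effect_size = 0.8, seed = 1)
  tr <- sim$truth
  # oracle: direct g computation per study, oriented by the planted sign
  g_by_study <- vapply(seq_along(sim$studies), function(s) {
    tab <- study_effect_sizes(sim$studies[[s]])
    g <- stats::setNames(tab$g, tab$gene)[names(tr$de_genes)]
    mean(g * sign(tr$de_genes))
  }, numeric(1))
  expect_equal(mean(g_by_study), 0.8 * mean(tr$attenuation), tolerance = 0.15 / 0.8)
  expect_true(abs(mean(g_by_study) - 0.8 * mean(tr$attenuation)) < 0.15)
})

test_that("compound profiles are valid permutations with planted shifts", {
  sim <- suppressMessages(
    sim_compound_profiles(n_compounds = 10, n_genes = 200,
                          replicates_per_compound = 3, frac_perturbing = 0.2,
                          seed = 9)
  )
  for (reps in sim$signatures$compounds) {
    for (r in reps) expect_setequal(unname(r), seq_len(200))
  }
  # planted up-regulated sets sit in the top half of every replicate
  pert <- sim$truth$perturbed_compounds
  for (i in seq_len(nrow(pert))) {
    gs <- sim$truth$target_sets$sets[[pert$target_set[i]]]
    for (r in sim$signatures$compounds[[pert$compound[i]]]) {
      mr <- mean(r[gs])
      if (pert$direction[i] == 1L) expect_lt(mr, 100) else expect_gt(mr, 100)
    }
  }
  # shift 0 leaves replicates as plain permutations, and seeds reproduce
  a <- sim_compound_profiles(n_compounds = 4, n_genes = 50, shift_strength = 0,
                             frac_perturbing = 0.5, seed = 3)
  b <- sim_compound_profiles(n_compounds = 4, n_genes = 50, shift_strength = 0,
                             frac_perturbing = 0.5, seed = 3)
  expect_identical(a$signatures$compounds, b$signatures$compounds)
})

test_that("regulon generator plants enrichment and reproduces under a seed", {
  a <- sim_regulon_ppi(n_tfs = 20, n_genes = 500, enriched_tfs = 3, seed = 11)
  b <- sim_regulon_ppi(n_tfs = 20, n_genes = 500, enriched_tfs = 3, seed = 11)
  expect_identical(a$regulons$sets, b$regulons$sets)
  expect_identical(a$ppi$edges, b$ppi$edges)
  expect_length(a$truth$enriched_tfs, 3L)
  # enriched TFs carry visibly more module genes than background TFs
  frac_mod <- function(sets, tfs) {
    nm <- names(sets)[sub("::.*$", "", names(sets)) %in% tfs]
    mean(vapply(sets[nm], function(s) mean(s %in% a$truth$module), numeric(1)))
  }
  enr <- frac_mod(a$regulons$sets, a$truth$enriched_tfs)
  bg <- frac_mod(a$regulons$sets, setdiff(sprintf("TF%03d", 1:20), a$truth$enriched_tfs))
  expect_gt(enr, 2 * bg)
  expect_error(sim_regulon_ppi(n_tfs = 5, n_genes = 100, enriched_tfs = 2,
                               module = paste0("X", 1:5), seed = 1),
               "subset")
})

test_that("coloc locus generator matches its scenario", {
  h0 <- sim_coloc_locus(n_snps = 300, scenario = "H0", seed = 2)
  z1 <- abs(h0$trait1$beta / h0$trait1$se)
  expect_lt(max(z1), 6)
  expect_identical(h0$truth$scenario, "H0")

  # shared causal variant carries the top |z| in both traits (strong effect)
  hits <- vapply(1:10, function(s) {
    h4 <- sim_coloc_locus(n_snps = 500, scenario = "H4", effect = 0.35,
                          n1 = 5000, n2 = 5000, seed = s)
    top1 <- h4$trait1$variant_id[which.max(abs(h4$trait1$beta / h4$trait1$se))]
    top2 <- h4$trait2$variant_id[which.max(abs(h4$trait2$beta / h4$trait2$se))]
    top1 == h4$truth$causal1 && top2 == h4$truth$causal2
  }, logical(1))
  expect_gte(mean(hits), 0.8)

  h3 <- sim_coloc_locus(n_snps = 100, scenario = "H3", seed = 5)
  expect_false(h3$truth$causal1 == h3$truth$causal2)

  a <- sim_coloc_locus(n_snps = 50, scenario = "H4", seed = 7)
  b <- sim_coloc_locus(n_snps = 50, scenario = "H4", seed = 7)
  expect_identical(a$trait1$beta, b$trait1$beta)
  expect_error(sim_coloc_locus(scenario = "H9", seed = 1), "scenario")
})

test_that("generated objects survive a write/read round trip", {
  sim <- sim_multistudy_expression(n_studies = 1, n_genes = 50, n_per_group = 4,
                                   seed = 5)
  st <- sim$studies[[1]]
  ep <- withr::local_tempfile(fileext = ".tsv")
  cp <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(st, ep, cp)
  back <- read_expression_table(ep, cp, study_id = st$study_id)
  expect_equal(back$values, st$values, tolerance = 1e-10)
  expect_equal(back$group, st$group)

  l4 <- sim_coloc_locus(n_snps = 20, scenario = "H4", seed = 3)
  sp <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(l4$trait1, sp)
  back2 <- read_summary_stats(sp, "trait1")
  expect_equal(nrow(back2), 20L)
  expect_equal(back2$beta, l4$trait1$beta, tolerance = 1e-10)

  cs <- suppressMessages(sim_compound_profiles(n_compounds = 3, n_genes = 30,
                                               frac_perturbing = 0.4, seed = 2))
  rp <- withr::local_tempfile(fileext = ".tsv")
  mp <- withr::local_tempfile(fileext = ".tsv")
  write_rank_matrix(cs$signatures, rp, mp)
  back3 <- read_rank_matrix(rp, mp)
  expect_equal(back3$compounds[["C001"]][[1]],
               cs$signatures$compounds[["C001"]][[1]])
})
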