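test_that("Hedges' g matches the closed form and condenses by max |g|", {
  vals <- rbind(gA = c(1, 2, 3, 0, 1, 2))
  st <- make_study(vals, c("case", "case", "case", "control", "control", "control"))
  tab <- study_effect_sizes(st)
  expect_equal(tab$g, 0.8, tolerance = 1e-9)           # d=1, J=0.8
  expect_equal(tab$var_g, 6 / 9 + 0.64 / 12, tolerance = 1e-9)

  # identical groups give g = 0
  same <- make_study(rbind(g1 = c(1, 2, 3, 1, 2, 3)),
                     rep(c("case", "control"), each = 3))
  expect_equal(study_effect_sizes(same)$g, 0)

  # two probesets for one gene: keep the one with larger |g|
  set.seed(1)
  m <- matrix(rnorm(40), 4, 10)
  rownames(m) <- c("p1", "p2", "p3", "p4")
  st2 <- make_study(m, rep(c("case", "control"), each = 5),
                    feature_to_gene = c(p1 = "gX", p2 = "gX", p3 = "gY", p4 = "gZ"))
  full <- study_effect_sizes(
    make_study(m, rep(c("case", "control"), each = 5))
  )
  g_by_feat <- stats::setNames(full$g, full$gene)
  cond <- study_effect_sizes(st2)
  expect_equal(nrow(cond), 3L)
  expect_equal(cond$g[cond$gene == "gX"],
               g_by_feat[c("p1", "p2")][which.max(abs(g_by_feat[c("p1", "p2")]))],
               ignore_attr = TRUE)

  # condensation is invariant to probeset row order
  st3 <- make_study(m[c(2, 1, 4, 3), ], rep(c("case", "control"), each = 5),
                    feature_to_gene = c(p1 = "gX", p2 = "gX", p3 = "gY", p4 = "gZ"))
  expect_equal(study_effect_sizes(st3)$g, cond$g)

  # a constant feature is dropped with a message
  m2 <- rbind(gc = rep(1, 10), gn = rnorm(10))
  expect_message(
    out <- study_effect_sizes(make_study(m2, rep(c("case", "control"), each = 5))),
    "zero pooled variance"
  )
  expect_equal(out$gene, "gn")
})

test_that("DerSimonian-Laird combination matches hand values and metafor", {
  t1 <- structure(data.frame(study_id = "s1", gene = "gA", g = 0.8,
                             var_g = 0.72, n_case = 3, n_control = 3),
                  class = c("EffectSizeTable", "data.frame"))
  r1 <- combine_random_effects(list(t1))
  expect_equal(r1$mu_hat, 0.8)
  expect_equal(r1$z_meta, 0.8 / sqrt(0.72), tolerance = 1e-6)  # 0.9428

  t2 <- t1; t2$study_id <- "s2"
  r2 <- combine_random_effects(list(t1, t2))
  expect_equal(r2$Q, 0)
  expect_equal(r2$tau2, 0)
  expect_equal(r2$mu_hat, 0.8)
  expect_equal(r2$z_meta, 0.8 / sqrt(0.36), tolerance = 1e-6)  # 1.3333

  t0a <- t1; t0a$g <- 0
  t0b <- t2; t0b$g <- 0
  r0 <- combine_random_effects(list(t0a, t0b))
  expect_equal(r0$mu_hat, 0)
  expect_equal(r0$p, 1)

  # heterogeneous case against metafor's DL estimator
  skip_if_not_installed("metafor")
  set.seed(7)
  for (i in 1:5) {
    g <- rnorm(6, 0.4, 0.5)
    v <- runif(6, 0.1, 0.6)
    tabs <- lapply(seq_along(g), function(j) {
      structure(data.frame(study_id = paste0("s", j), gene = "gA", g = g[j],
                           var_g = v[j], n_case = 10, n_control = 10),
                class = c("EffectSizeTable", "data.frame"))
    })
    mine <- combine_random_effects(tabs)
    ref <- metafor::rma(yi = g, vi = v, method = "DL")
    expect_equal(mine$mu_hat, as.numeric(ref$beta), tolerance = 1e-8)
    expect_equal(mine$tau2, ref$tau2, tolerance = 1e-8)
    expect_equal(mine$Q, ref$QE, tolerance = 1e-8)
    expect_equal(mine$z_meta, ref$zval, tolerance = 1e-8)
  }
})

test_that("label swap negates effects and tau2=0 reduces to fixed effects", {
  sim <- sim_multistudy_expression(n_studies = 3, n_genes = 80, n_per_group = 6,
                                   seed = 21)
  tabs <- lapply(sim$studies, study_effect_sizes)
  res <- combine_random_effects(tabs)
  flipped <- lapply(sim$studies, function(st) {
    st$group <- ifelse(st$group == "case", "control", "case")
    st
  })
  tabs_f <- lapply(flipped, study_effect_sizes)
  res_f <- combine_random_effects(tabs_f)
  expect_equal(tabs_f[[1]]$g, -tabs[[1]]$g, tolerance = 1e-12)
  expect_equal(res_f$z_meta, -res$z_meta, tolerance = 1e-12)

  # where tau2 = 0 the random-effects mean equals the inverse-variance mean
  zero <- res$tau2 == 0
  G <- vapply(tabs, function(t) stats::setNames(t$g, t$gene)[res$gene], numeric(nrow(res)))
  V <- vapply(tabs, function(t) stats::setNames(t$var_g, t$gene)[res$gene], numeric(nrow(res)))
  mu_fe <- rowSums((G / V))[zero] / rowSums(1 / V)[zero]
  expect_equal(res$mu_hat[zero], unname(mu_fe), tolerance = 1e-12)
})

test_that("per-dataset z signature matches formulas with deterministic ties", {
  vals <- rbind(gB = c(1, 2, 3, 0, 1, 2), gA = c(1, 2, 3, 0, 1, 2))
  st <- make_study(vals, rep(c("case", "control"), each = 3))
  sig <- per_dataset_z(st)
  expect_equal(unname(sig[1]), 0.8 / sqrt(0.72), tolerance = 1e-6)
  expect_equal(names(sig), c("gA", "gB"))   # tie broken by symbol

  same <- make_study(rbind(g1 = c(5, 6, 7, 5, 6, 7), g2 = c(1, 2, 1, 1, 2, 1)),
                     rep(c("case", "control"), each = 3))
  expect_true(all(per_dataset_z(same) == 0))
})

test_that("batch adjustment removes a constant batch offset", {
  set.seed(31)
  n_genes <- 1000
  base <- matrix(rnorm(n_genes * 20), n_genes, 20)
  batch <- rep(c("b1", "b2"), each = 10)
  group <- rep(c("case", "control"), 10)   # no group effect in the data
  c_off <- 1.5
  vals <- base + outer(rep(1, n_genes), ifelse(batch == "b2", c_off, 0))
  rownames(vals) <- paste0("g", 1:n_genes); colnames(vals) <- paste0("s", 1:20)
  st <- ExpressionStudy("b", vals, group,
                        factor_covariates = data.frame(batch = batch))
  adj <- adjust_known_batch(st, "batch")
  diff_after <- rowMeans(adj$values[, batch == "b2"]) -
    rowMeans(adj$values[, batch == "b1"])
  diff_before <- rowMeans(st$values[, batch == "b2"]) -
    rowMeans(st$values[, batch == "b1"])
  expect_lt(abs(mean(diff_after)), 0.05)
  expect_gt(abs(mean(diff_before)), 1)   # the offset was really there
  # the location/scale transform preserves sample ordering per gene within
  # each batch-by-group cell (the group effect itself is protected)
  cell <- batch == "b1" & group == "case"
  o_before <- apply(st$values[1:50, cell], 1, order)
  o_after <- apply(adj$values[1:50, cell], 1, order)
  expect_equal(o_after, o_before)

  # single-level covariate: no-op; level with <2 samples: error
  st1 <- ExpressionStudy("c", vals, group,
                         factor_covariates = data.frame(batch = rep("b1", 20)))
  expect_identical(adjust_known_batch(st1, "batch")$values, st1$values)
  st2 <- ExpressionStudy("d", vals, group,
                         factor_covariates = data.frame(batch = c("solo", batch[-1])))
  expect_error(adjust_known_batch(st2, "batch"), "fewer than 2")
})

test_that("surrogate estimation recovers a planted hidden covariate", {
  sim <- sim_multistudy_expression(n_studies = 1, n_genes = 800,
                                   n_per_group = 15, batch_sd = 0,
                                   hidden_sd = 1.5, seed = 41)
  st <- sim$studies[[1]]
  sv <- estimate_surrogates(st, n_max = 3, n_permutations = 30, seed = 5)
  expect_gte(sv$report$n_surrogates, 1L)
  h <- sim$truth$hidden_covariate[[st$study_id]]
  expect_gt(abs(stats::cor(sv$surrogates[[1]], h)), 0.8)
  # same seed reproduces
  sv2 <- estimate_surrogates(st, n_max = 3, n_permutations = 30, seed = 5)
  expect_identical(sv$surrogates, sv2$surrogates)
  # n_max = 0 returns an empty list
  sv0 <- estimate_surrogates(st, n_max = 0, seed = 5)
  expect_length(sv0$surrogates, 0L)
})

test_that("pure-noise matrices rarely yield surrogates at alpha = 0.05", {
  retained <- vapply(1:20, function(i) {
    set.seed(100 + i)
    m <- matrix(rnorm(200 * 12), 200, 12)
    rownames(m) <- paste0("g", 1:200); colnames(m) <- paste0("s", 1:12)
    st <- ExpressionStudy("n", m, rep(c("case", "control"), each = 6))
    estimate_surrogates(st, n_max = 2, n_permutations = 40, seed = i)$report$n_surrogates
  }, integer(1))
  expect_lte(mean(retained > 0), 0.25)   # ~5% expected; generous margin at 20 runs
})

test_that("wide-effect covariate selection separates signal from noise", {
  sim <- sim_multistudy_expression(n_studies = 1, n_genes = 600,
                                   n_per_group = 12, batch_sd = 0,
                                   hidden_sd = 1.5, seed = 51)
  st <- sim$studies[[1]]
  h <- sim$truth$hidden_covariate[[st$study_id]]
  noise <- withr::with_seed(5, rnorm(length(h)))
  rep <- select_wide_effect_covariates(st, list(hidden = h, noise = noise))
  expect_true("hidden" %in% rep$selected_covariates)
  expect_false("noise" %in% rep$selected_covariates)
  # constant candidates are excluded with a message; empty list is fine
  expect_message(
    select_wide_effect_covariates(st, list(const = rep(1, ncol(st$values)))),
    "constant"
  )
  expect_length(select_wide_effect_covariates(st, list())$selected_covariates, 0L)
})

test_that("robust residualization resists gross outliers and handles edge cases", {
  st <- make_study(matrix(rnorm(30), 3, 10), rep(c("case", "control"), each = 5))
  expect_identical(robust_residualize(st, list()), st)

  # gene exactly collinear with the covariate collapses to its intercept
  x <- seq(-1, 1, length.out = 10)
  m <- rbind(lin = 2 + 3 * x, other = rnorm(10))
  st2 <- make_study(m, rep(c("case", "control"), each = 5))
  adj <- robust_residualize(st2, list(x = x))
  expect_equal(unname(adj$values["lin", ]), rep(2, 10), tolerance = 1e-6)

  # an outlier distorts the OLS slope more than the Huber slope
  set.seed(9)
  y <- 0.5 * x + rnorm(10, 0, 0.1)
  y_out <- y; y_out[10] <- 8
  ols <- stats::lm(y_out ~ x)$coefficients[2]
  rob <- MASS::rlm(y_out ~ x, psi = MASS::psi.huber, k = 1.345)$coefficients[2]
  expect_lt(abs(rob - 0.5), abs(ols - 0.5))
  st3 <- make_study(rbind(g = y_out), rep(c("case", "control"), each = 5))
  adj3 <- robust_residualize(st3, list(x = x))
  # adjusted values = intercept + residual: subtracting the x effect
  expect_false(identical(adj3$values, st3$values))
})

test_that("permutation FDR is reproducible, floored and monotone", {
  sim <- sim_multistudy_expression(n_studies = 3, n_genes = 150, n_per_group = 8,
                                   frac_de = 0.1, effect_size = 1.5, seed = 61)
  tabs <- lapply(sim$studies, study_effect_sizes)
  obs <- combine_random_effects(tabs)
  r1 <- permutation_fdr_meta(sim$studies, obs, n_perm = 50, seed = 3)
  r2 <- permutation_fdr_meta(sim$studies, obs, n_perm = 50, seed = 3)
  expect_identical(r1$fdr, r2$fdr)
  r3 <- permutation_fdr_meta(sim$studies, obs, n_perm = 50, seed = 4)
  expect_false(identical(r1$fdr, r3$fdr))

  # monotone: larger |z| never has larger FDR
  ord <- order(abs(r1$z_meta), decreasing = TRUE)
  expect_true(all(diff(r1$fdr[ord]) >= -1e-12))
  expect_true(all(r1$fdr >= 1 / (50 * nrow(obs))))
  expect_error(permutation_fdr_meta(sim$studies, obs, n_perm = 5, seed = 1),
               "at least 10")
})
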