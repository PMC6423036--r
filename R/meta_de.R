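# Per-study covariate adjustment and effect sizes, probeset condensation,
# cross-study random-effects meta-analysis (DerSimonian-Laird) with
# permutation FDR, and per-study Z signatures.

#' Empirical-Bayes batch adjustment for a known factor covariate
#'
#' Location/scale batch correction (ComBat) that standardizes each gene
#' under a model containing the case/control group plus batch, shrinks
#' per-batch gene-wise means and variances toward batch-wide priors, and
#' returns the data on the original scale with the group effect preserved.
#'
#' @param study an [ExpressionStudy].
#' @param covariate_name name of a factor covariate with >= 2 levels, each
#'   level containing >= 2 samples. A single-level covariate returns the
#'   study unchanged.
#' @return the adjusted [ExpressionStudy].
#' @export
adjust_known_batch <- function(study, covariate_name) {
  stopifnot(inherits(study, "ExpressionStudy"))
  if (is.null(study$factor_covariates) ||
      !covariate_name %in% colnames(study$factor_covariates)) {
    stop(sprintf("factor covariate '%s' not found", covariate_name))
  }
  batch <- factor(study$factor_covariates[[covariate_name]])
  if (nlevels(batch) < 2L) return(study)
  if (any(table(batch) < 2L)) {
    stop(sprintf(
      "batch level(s) with fewer than 2 samples in '%s'; merge or drop them",
      covariate_name
    ))
  }
  mod <- stats::model.matrix(~ factor(study$group))
  adj <- suppressMessages(
    sva::ComBat(dat = study$values, batch = batch, mod = mod)
  )
  out <- study
  out$values <- adj
  out
}

#' Estimate surrogate vectors for hidden covariates
#'
#' Residualizes expression on the case/control label, takes the
#' right-singular vectors of the residual matrix, and retains components
#' whose variance explained exceeds the permutation null (parallel
#' analysis: singular values of row-wise permuted residuals, alpha = 0.05),
#' capped at `n_max`. Retention is sequential: the first non-significant
#' component stops the scan.
#'
#' @param study an [ExpressionStudy] with >= 6 samples.
#' @param n_max maximum number of surrogates.
#' @param n_permutations permutations for the null singular values.
#' @param seed integer seed.
#' @param alpha per-component significance level.
#' @return list with `surrogates` (list of per-sample numeric vectors) and
#'   `report` (class `AdjustmentReport`: per-component observed and null
#'   variance-explained and the retention decision).
#' @export
estimate_surrogates <- function(study, n_max = 5L, n_permutations = 50L,
                                seed = 1L, alpha = 0.05) {
  stopifnot(inherits(study, "ExpressionStudy"))
  if (ncol(study$values) < 6L) stop("need at least 6 samples")
  if (n_max == 0L) {
    report <- structure(list(selected_covariates = character(0),
                             n_surrogates = 0L, statistics = NULL),
                        class = "AdjustmentReport")
    return(list(surrogates = list(), report = report))
  }
  Y <- study$values
  X <- stats::model.matrix(~ factor(study$group))
  P <- X %*% solve(crossprod(X)) %*% t(X)
  R <- Y - Y %*% P                      # residuals on group, per gene
  sv <- svd(R, nu = 0L, nv = n_max)
  ve_obs <- sv$d^2 / sum(sv$d^2)
  n_max <- min(n_max, length(sv$d))

  null_ve <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      Rp <- t(apply(R, 1L, sample))
      Rp <- Rp - Rp %*% P          # same rank structure as the observed residuals
      d <- svd(Rp, nu = 0L, nv = 0L)$d
      (d^2 / sum(d^2))[seq_len(n_max)]
    }, numeric(n_max))
  })
  null_ve <- matrix(null_ve, nrow = n_max)
  thresh <- apply(null_ve, 1L, stats::quantile, probs = 1 - alpha)
  keep <- ve_obs[seq_len(n_max)] > thresh
  n_keep <- as.integer(if (any(!keep)) which(!keep)[1L] - 1L else n_max)

  surrogates <- lapply(seq_len(n_keep), function(k) {
    stats::setNames(sv$v[, k], study$sample_ids)
  })
  names(surrogates) <- if (n_keep > 0L) paste0("sv", seq_len(n_keep)) else character(0)
  report <- structure(
    list(selected_covariates = names(surrogates), n_surrogates = n_keep,
         statistics = data.frame(
           component = seq_len(n_max),
           variance_explained = ve_obs[seq_len(n_max)],
           null_threshold = thresh,
           retained = seq_len(n_max) <= n_keep
         )),
    class = "AdjustmentReport"
  )
  list(surrogates = surrogates, report = report)
}

#' @export
print.AdjustmentReport <- function(x, ...) {
  cat(sprintf("AdjustmentReport: %d covariate(s) selected%s\n",
              length(x$selected_covariates),
              if (length(x$selected_covariates) > 0L) {
                paste0(" (", paste(x$selected_covariates, collapse = ", "), ")")
              } else ""))
  invisible(x)
}

#' Select covariates with widespread effects on expression
#'
#' For each candidate vector, fits a per-gene simple linear model of
#' expression on the candidate and compares the distribution of the model P
#' values against uniform with a one-sample Kolmogorov-Smirnov test. A
#' candidate is selected when the KS P value falls below `ks_alpha`
#' (default 0.01): widespread effects drag the P distribution away from
#' U(0, 1). Constant candidates are excluded with a message.
#'
#' @param study an [ExpressionStudy].
#' @param candidates named list of per-sample numeric vectors.
#' @param ks_alpha selection threshold on the KS-vs-uniform P value.
#' @return an `AdjustmentReport` with per-candidate KS statistics and the
#'   selection decisions; selected vectors are stored in
#'   `$selected_vectors`.
#' @export
select_wide_effect_covariates <- function(study, candidates, ks_alpha = 0.01) {
  stopifnot(inherits(study, "ExpressionStudy"))
  if (length(candidates) == 0L) {
    return(structure(list(selected_covariates = character(0),
                          n_surrogates = 0L, statistics = NULL,
                          selected_vectors = list()),
                     class = "AdjustmentReport"))
  }
  if (is.null(names(candidates))) {
    names(candidates) <- paste0("cand", seq_along(candidates))
  }
  n <- ncol(study$values)
  const <- vapply(candidates, function(x) stats::sd(x) == 0, logical(1L))
  drop_note(sum(const), "constant candidate covariate(s)")
  candidates <- candidates[!const]
  Y <- study$values
  Yc <- Y - rowMeans(Y)
  stats_tab <- do.call(rbind, lapply(names(candidates), function(nm) {
    x <- candidates[[nm]]
    if (length(x) != n || any(!is.finite(x))) {
      stop(sprintf("candidate '%s' must be finite with one value per sample", nm))
    }
    xc <- x - mean(x)
    r <- as.numeric(Yc %*% xc) /
      (sqrt(rowSums(Yc^2)) * sqrt(sum(xc^2)))
    r <- r[is.finite(r)]
    tt <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    ks <- suppressWarnings(stats::ks.test(p, "punif"))
    data.frame(candidate = nm, ks_statistic = unname(ks$statistic),
               ks_p = ks$p.value, selected = ks$p.value < ks_alpha)
  }))
  selected <- stats_tab$candidate[stats_tab$selected]
  structure(list(selected_covariates = selected,
                 n_surrogates = length(selected),
                 statistics = stats_tab,
                 selected_vectors = candidates[selected]),
            class = "AdjustmentReport")
}

#' Residualize expression on selected covariates with a robust fit
#'
#' Per gene, fits expression on the covariates by iteratively reweighted
#' least squares with Huber weights (tuning constant 1.345, at most 50
#' iterations) and replaces the expression values by intercept + residuals.
#' Genes whose robust fit does not converge fall back to ordinary least
#' squares, with a message.
#'
#' @param study an [ExpressionStudy].
#' @param covariates list of per-sample numeric vectors (possibly empty, in
#'   which case the study is returned unchanged).
#' @return the adjusted [ExpressionStudy].
#' @export
robust_residualize <- function(study, covariates) {
  stopifnot(inherits(study, "ExpressionStudy"))
  if (length(covariates) == 0L) return(study)
  X <- do.call(cbind, covariates)
  stopifnot(nrow(X) == ncol(study$values))
  Y <- study$values
  adj <- Y
  n_fallback <- 0L
  for (i in seq_len(nrow(Y))) {
    y <- Y[i, ]
    fit <- tryCatch(
      MASS::rlm(x = cbind(1, X), y = y, psi = MASS::psi.huber, k = 1.345,
                maxit = 50L),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged) {
      n_fallback <- n_fallback + 1L
      fit <- stats::lm.fit(x = cbind(1, X), y = y)
      adj[i, ] <- fit$coefficients[1L] + fit$residuals
    } else {
      adj[i, ] <- fit$coefficients[1L] + fit$residuals
    }
  }
  if (n_fallback > 0L) {
    message(sprintf("dexnet: robust fit fell back to OLS for %d gene(s)",
                    n_fallback))
  }
  out <- study
  out$values <- adj
  out
}

# Shared core: per-feature Hedges' g, then condensation to gene level by
# max |g|. Returns a data.frame(gene, g, var_g) plus counts.
hedges_g_table <- function(study) {
  grp <- study$group
  n1 <- sum(grp == "case")
  n2 <- sum(grp == "control")
  if (n1 < 2L || n2 < 2L) stop("need at least 2 samples per group")
  Y <- study$values
  # standardize each feature to mean 0, sd 1 across all samples (affine, so
  # g is unchanged; matches the meta-analysis convention)
  ntot <- ncol(Y)
  mu <- rowMeans(Y)
  s <- sqrt(pmax(rowSums(Y^2) - ntot * mu^2, 0) / (ntot - 1))
  ok_sd <- s > 0
  Y <- (Y - mu) / ifelse(ok_sd, s, 1)
  Y1 <- Y[, grp == "case", drop = FALSE]
  Y2 <- Y[, grp == "control", drop = FALSE]
  m1 <- rowMeans(Y1)
  m2 <- rowMeans(Y2)
  v1 <- pmax(rowSums(Y1^2) - n1 * m1^2, 0) / (n1 - 1)
  v2 <- pmax(rowSums(Y2^2) - n2 * m2^2, 0) / (n2 - 1)
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  ok <- ok_sd & sp > 0
  drop_note(sum(!ok), "feature(s) with zero pooled variance")
  d <- (m1 - m2) / sp
  J <- 1 - 3 / (4 * (n1 + n2 - 2) - 1)
  g <- J * d
  var_g <- (n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2))
  feat <- study$feature_ids[ok]
  gene <- if (is.null(study$feature_to_gene)) {
    feat
  } else {
    mapped <- study$feature_to_gene[feat]
    ifelse(is.na(mapped), feat, mapped)
  }
  tab <- data.frame(feature = feat, gene = gene, g = g[ok], var_g = var_g[ok],
                    stringsAsFactors = FALSE)
  # condense: per gene keep the feature with max |g| (ties: first feature id)
  ord <- order(-abs(tab$g), tab$feature, method = "radix")
  tab <- tab[ord, , drop = FALSE]
  tab <- tab[!duplicated(tab$gene), , drop = FALSE]
  tab <- tab[order(tab$gene, method = "radix"), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, n_case = n1, n_control = n2)
}

#' Per-study Hedges' g effect sizes with gene-level condensation
#'
#' Standardizes each feature to mean 0 / sd 1 across samples, computes the
#' bias-corrected standardized mean difference between cases and controls
#' (`g = J * d`, `J = 1 - 3 / (4 * (n1 + n2 - 2) - 1)`) with sampling
#' variance `(n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2))`, and condenses
#' probesets to gene level keeping, per gene, the feature with the largest
#' `|g|`. Features with zero pooled variance are dropped with a message.
#'
#' @param study an [ExpressionStudy] with >= 2 samples per group.
#' @return data.frame of class `EffectSizeTable`: study_id, gene, g, var_g,
#'   n_case, n_control.
#' @export
study_effect_sizes <- function(study) {
  stopifnot(inherits(study, "ExpressionStudy"))
  h <- hedges_g_table(study)
  out <- data.frame(study_id = study$study_id, h$table[, c("gene", "g", "var_g")],
                    n_case = h$n_case, n_control = h$n_control,
                    stringsAsFactors = FALSE)
  class(out) <- c("EffectSizeTable", "data.frame")
  out
}

#' DerSimonian-Laird random-effects meta-analysis across studies
#'
#' Per gene: fixed weights `w = 1/var`, heterogeneity
#' `Q = sum(w * (g - g_w)^2)`, moment estimate
#' `tau2 = max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))`,
#' random-effects weights `w* = 1 / (var + tau2)`, combined effect
#' `mu = sum(w* g) / sum(w*)`, `z = mu * sqrt(sum(w*))`, and a two-sided
#' normal P value. Genes are restricted to those present in at least
#' `min_studies` studies (default: all studies).
#'
#' @param tables list of `EffectSizeTable`s (one per study).
#' @param min_studies minimum number of contributing studies per gene;
#'   `NULL` means all studies.
#' @return data.frame of class `MetaResult`: gene, k, mu_hat, tau2, Q,
#'   z_meta, p, fdr (NA until [permutation_fdr_meta()]).
#' @export
combine_random_effects <- function(tables, min_studies = NULL) {
  stopifnot(length(tables) >= 1L)
  if (is.null(min_studies)) min_studies <- length(tables)
  genes <- sort(unique(unlist(lapply(tables, `[[`, "gene"))))
  G <- V <- matrix(NA_real_, nrow = length(genes), ncol = length(tables),
                   dimnames = list(genes, NULL))
  for (j in seq_along(tables)) {
    tab <- tables[[j]]
    G[tab$gene, j] <- tab$g
    V[tab$gene, j] <- tab$var_g
  }
  k <- rowSums(!is.na(G))
  keep <- k >= max(1L, min_studies)
  G <- G[keep, , drop = FALSE]
  V <- V[keep, , drop = FALSE]
  k <- k[keep]
  w <- 1 / V
  sw <- rowSums(w, na.rm = TRUE)
  gw <- rowSums(w * G, na.rm = TRUE) / sw
  Q <- rowSums(w * (G - gw)^2, na.rm = TRUE)
  denom <- sw - rowSums(w^2, na.rm = TRUE) / sw
  tau2 <- pmax(0, (Q - (k - 1)) / denom)
  tau2[k == 1L] <- 0
  ws <- 1 / (V + tau2)
  sws <- rowSums(ws, na.rm = TRUE)
  mu <- rowSums(ws * G, na.rm = TRUE) / sws
  z <- mu * sqrt(sws)
  out <- data.frame(
    gene = rownames(G), k = as.integer(k), mu_hat = mu, tau2 = tau2, Q = Q,
    z_meta = z, p = 2 * stats::pnorm(-abs(z)), fdr = NA_real_,
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("MetaResult", "data.frame")
  out
}

# |meta-Z| vector for one permutation/observation, given studies.
meta_abs_z <- function(studies, min_studies = NULL) {
  tables <- lapply(studies, study_effect_sizes)
  res <- combine_random_effects(tables, min_studies = min_studies)
  stats::setNames(res$z_meta, res$gene)
}

#' Permutation FDR for the meta-analysis Z scores
#'
#' Shuffles the case/control labels independently within each study
#' (preserving the per-study group sizes), recomputes the full effect-size
#' and meta-Z pipeline, and estimates, for each observed `|z|`, the expected
#' number of null genes at or above that threshold divided by the observed
#' count. FDRs are clipped to `[0, 1]`, floored at
#' `1 / (n_perm * n_genes)`, and made monotone non-increasing in `|z|`
#' (q-value style).
#'
#' @param studies the list of (adjusted) [ExpressionStudy] objects the
#'   observed result was computed from.
#' @param observed a `MetaResult` from [combine_random_effects()].
#' @param n_perm number of permutations (>= 10).
#' @param seed integer seed.
#' @param min_studies passed through to the per-permutation meta-analysis.
#' @return `observed` with the `fdr` column filled.
#' @export
permutation_fdr_meta <- function(studies, observed, n_perm = 1000L, seed = 1L,
                                 min_studies = NULL) {
  stopifnot(inherits(observed, "MetaResult"))
  if (n_perm < 10L) stop("n_perm must be at least 10")
  z_obs <- abs(observed$z_meta)
  null_z <- with_seed(seed, {
    unlist(lapply(seq_len(n_perm), function(b) {
      shuffled <- lapply(studies, function(st) {
        st$group <- sample(st$group)
        st
      })
      abs(meta_abs_z(shuffled, min_studies = min_studies))
    }), use.names = FALSE)
  })
  null_sorted <- sort(null_z)
  n_ge_null <- length(null_sorted) -
    findInterval(z_obs, null_sorted, left.open = TRUE)
  exp_null <- n_ge_null / n_perm
  obs_sorted <- sort(z_obs)
  n_ge_obs <- length(obs_sorted) -
    findInterval(z_obs, obs_sorted, left.open = TRUE)
  fdr <- pmin(1, exp_null / pmax(n_ge_obs, 1L))
  fdr <- pmax(fdr, 1 / (n_perm * length(z_obs)))
  # q-value monotonicity: larger |z| never gets a larger FDR
  ord <- order(z_obs)
  fdr[ord] <- cummin(fdr[ord])
  out <- observed
  out$fdr <- fdr
  out
}

#' Per-study Z signature from condensed effect sizes
#'
#' `z = g / sqrt(var_g)` per gene after probeset condensation, returned as
#' a [ranked_signature()] ordered by z descending with ties broken by gene
#' symbol.
#'
#' @param study an [ExpressionStudy].
#' @return a `RankedSignature`.
#' @export
per_dataset_z <- function(study) {
  tab <- study_effect_sizes(study)
  ranked_signature(stats::setNames(tab$g / sqrt(tab$var_g), tab$gene))
}
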