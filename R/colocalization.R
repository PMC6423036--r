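# Bayesian colocalization of two traits' locus summary statistics via
# per-variant approximate Bayes factors and the five-hypothesis posterior.

#' Wakefield log approximate Bayes factor
#'
#' With `V = se^2`, `W = prior_sd^2`, `r = W / (V + W)` and `z = beta / se`:
#' `lABF = 0.5 * log(1 - r) + 0.5 * r * z^2`.
#'
#' @param beta effect estimate(s).
#' @param se standard error(s), > 0.
#' @param prior_sd prior effect standard deviation, > 0.
#' @return log ABF (vectorized).
#' @export
wakefield_labf <- function(beta, se, prior_sd) {
  if (any(!is.finite(beta)) || any(!is.finite(se)) || any(!is.finite(prior_sd))) {
    stop("beta, se and prior_sd must be finite")
  }
  if (any(se <= 0) || any(prior_sd <= 0)) stop("se and prior_sd must be positive")
  V <- se^2
  W <- prior_sd^2
  r <- W / (V + W)
  z <- beta / se
  0.5 * log(1 - r) + 0.5 * r * z^2
}

# Reconstruct beta/se where only (p, maf, n) are available: |z| from the
# two-sided P, se from the variance approximation
# 1 / (2 maf (1 - maf) n), times 1 / (cf (1 - cf)) for case/control traits.
# The sign of beta is unrecoverable from P alone; the ABF only uses z^2.
ensure_beta_se <- function(tab) {
  need <- is.na(tab$beta) | is.na(tab$se)
  if (any(need)) {
    cf <- tab$case_fraction
    denom <- 2 * tab$maf * (1 - tab$maf) * tab$n
    denom <- ifelse(!is.na(cf), denom * cf * (1 - cf), denom)
    se <- 1 / sqrt(denom)
    z <- stats::qnorm(tab$p / 2, lower.tail = FALSE)
    tab$se[need] <- se[need]
    tab$beta[need] <- (z * se)[need]
  }
  tab
}

#' Colocalization posteriors for two traits at one locus
#'
#' Computes per-variant Wakefield log ABFs for each trait over the shared
#' variants and the posterior probabilities of the five hypotheses --
#' no association (PP0), association with trait 1 only (PP1), trait 2 only
#' (PP2), two distinct causal variants (PP3), one shared causal variant
#' (PP4). All hypothesis sums are evaluated in log space; the H3
#' cross-term excludes same-variant pairs and is computed by explicit
#' pairwise log-sum when the locus has at most `pairwise_max` variants,
#' else by the product-minus-diagonal identity with a cancellation guard.
#'
#' When `scale = "z"`, ABFs are computed from the z statistics alone
#' (`V = 1`, `prior_sd` on the z scale), which makes the posteriors
#' invariant to rescaling beta and se by a common constant.
#'
#' @param trait1,trait2 `SummaryStatsTable`s sharing >= 1 variant.
#' @param priors numeric vector `c(p1, p2, p12)` of per-variant prior
#'   probabilities.
#' @param prior_sd1,prior_sd2 prior effect sd per trait (0.15 is the usual
#'   quantitative-trait scale; 0.2 on the log-odds scale for case/control).
#' @param locus_id label for the result.
#' @param scale `"beta"` (default) or `"z"`.
#' @param pairwise_max largest locus size for the exact pairwise H3 sum.
#' @return object of class `ColocResult`: `locus_id`, `pp` (named PP0..PP4,
#'   summing to 1), `n_variants`, `priors`, `labf` (two-column matrix).
#' @export
coloc_posteriors <- function(trait1, trait2,
                             priors = c(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5),
                             prior_sd1 = 0.15, prior_sd2 = 0.15,
                             locus_id = "locus", scale = c("beta", "z"),
                             pairwise_max = 200L) {
  scale <- match.arg(scale)
  t1 <- ensure_beta_se(as.data.frame(trait1))
  t2 <- ensure_beta_se(as.data.frame(trait2))
  shared <- intersect(t1$variant_id, t2$variant_id)
  if (length(shared) == 0L) stop("traits share no variants")
  t1 <- t1[match(shared, t1$variant_id), ]
  t2 <- t2[match(shared, t2$variant_id), ]
  labf <- function(tab, psd) {
    if (scale == "z") {
      wakefield_labf(tab$beta / tab$se, rep(1, nrow(tab)), psd)
    } else {
      wakefield_labf(tab$beta, tab$se, psd)
    }
  }
  l1 <- labf(t1, prior_sd1)
  l2 <- labf(t2, prior_sd2)
  lp <- log(priors)
  s1 <- logsumexp(l1)
  s2 <- logsumexp(l2)
  s12 <- logsumexp(l1 + l2)
  n <- length(shared)
  lh3_cross <- if (n == 1L) {
    -Inf                                  # no distinct pairs
  } else if (n <= pairwise_max) {
    M <- outer(l1, l2, "+")
    logsumexp(M[row(M) != col(M)])
  } else {
    A <- s1 + s2
    d <- s12 - A
    if (d >= 0) -Inf else A + log1p(-exp(d))
  }
  lh <- c(
    PP0 = 0,
    PP1 = lp[[1L]] + s1,
    PP2 = lp[[2L]] + s2,
    PP3 = lp[[1L]] + lp[[2L]] + lh3_cross,
    PP4 = lp[[3L]] + s12
  )
  denom <- logsumexp(lh)
  structure(
    list(locus_id = locus_id, pp = exp(lh - denom), n_variants = n,
         priors = priors,
         labf = cbind(trait1 = l1, trait2 = l2)),
    class = "ColocResult"
  )
}

#' @export
print.ColocResult <- function(x, ...) {
  cat(sprintf("ColocResult '%s' (%d variants): %s\n", x$locus_id,
              x$n_variants,
              paste(sprintf("%s=%.3f", names(x$pp), x$pp), collapse = " ")))
  invisible(x)
}

#' Call colocalized genes per tissue and their intersection
#'
#' A gene is called in a tissue when its PP4 is at or above the threshold
#' (0.75 by convention). The intersection across all tissues is reported
#' separately as the high-confidence set.
#'
#' @param results_by_tissue named list; each element is a named list of
#'   `ColocResult`s keyed by gene.
#' @param threshold PP4 call threshold.
#' @return list with `per_tissue` (named list of called gene vectors) and
#'   `intersection`.
#' @export
call_coloc_genes <- function(results_by_tissue, threshold = 0.75) {
  per_tissue <- lapply(results_by_tissue, function(res) {
    called <- vapply(res, function(r) r$pp[["PP4"]] >= threshold, logical(1L))
    names(res)[called]
  })
  intersection <- if (length(per_tissue) == 0L) {
    character(0)
  } else {
    Reduce(intersect, per_tissue)
  }
  list(per_tissue = per_tissue, intersection = intersection)
}
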