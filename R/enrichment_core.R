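# Shared enrichment statistics: KS-like enrichment of a gene set at either
# end of a ranked signature (with a gene-label permutation null), Fisher's
# exact set-vs-set enrichment, Fisher's combined probability, and
# multiple-testing adjustment.

#' Construct a ranked signature
#'
#' Orders genes by score descending; ties are broken by gene symbol
#' (ascending) so the ordering is deterministic.
#'
#' @param scores named numeric vector of per-gene scores.
#' @return object of class `RankedSignature`: the sorted named score vector.
#' @export
ranked_signature <- function(scores) {
  if (is.null(names(scores)) || anyDuplicated(names(scores))) {
    stop("scores must be named with unique gene symbols")
  }
  if (anyNA(scores)) stop("scores must not contain NA")
  ord <- order(-scores, names(scores), method = "radix")
  structure(scores[ord], class = "RankedSignature")
}

#' @export
print.RankedSignature <- function(x, ...) {
  cat(sprintf("RankedSignature of %d genes (scores %.3g .. %.3g)\n",
              length(x), x[[1L]], x[[length(x)]]))
  invisible(x)
}

# Core KS-like statistic from hit positions in a ranked list of length n.
# v: sorted positions of the t set genes; w: weight of each hit (in v order).
# a = the largest excess of the (weighted) hit fraction over the uniform
# expectation at the hit positions (set concentrated at the top); b likewise
# for the bottom; the score is the larger deviation with its sign.
ks_stat_positions <- function(v, w, n) {
  t <- length(v)
  cw <- cumsum(w)
  W <- cw[t]
  a <- max(cw / W - v / n)
  b <- max(v / n - c(0, cw[-t]) / W)
  if (a > b) a else -b
}

#' KS-like enrichment score of a gene set in a ranked signature
#'
#' Walks the ranked list and measures the maximum signed deviation between
#' the cumulative (weighted) fraction of set genes encountered and the
#' fraction of the list traversed. Positive scores indicate concentration at
#' the top (highest scores); negative, at the bottom. With
#' `weight_exponent = 0` every hit counts equally; with the default 1, hits
#' are weighted by `|score|`.
#'
#' @param signature a [ranked_signature()].
#' @param gene_set character vector of gene symbols.
#' @param weight_exponent exponent applied to `|score|` for hit weights.
#' @return enrichment score in `[-1, 1]`.
#' @export
ks_enrichment <- function(signature, gene_set, weight_exponent = 1) {
  stopifnot(inherits(signature, "RankedSignature"))
  genes <- names(signature)
  v <- which(genes %in% gene_set)
  if (length(v) == 0L) {
    stop(sprintf("gene set has no overlap with the signature (%d genes given)",
                 length(gene_set)))
  }
  w <- if (weight_exponent == 0) {
    rep(1, length(v))
  } else {
    abs(signature[v])^weight_exponent
  }
  if (sum(w) == 0) w <- rep(1, length(v))   # all-zero scores: unweighted
  ks_stat_positions(v, w, length(genes))
}

#' Permutation GSEA over a gene-set collection
#'
#' For each set, the observed KS-like enrichment score is compared against a
#' null obtained by permuting the gene labels of the signature (scores stay
#' fixed; set membership lands on random positions). The two-sided P value
#' uses the +1 correction, so it is never exactly zero. Because a label
#' permutation places a set of size t uniformly at random positions, the
#' null distribution depends only on t; permutations are shared across sets
#' of equal overlap size, which is exactly equivalent and much faster.
#'
#' @param signature a [ranked_signature()].
#' @param sets a [GeneSetCollection].
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @param adjust multiple-testing method across sets.
#' @param weight_exponent passed to [ks_enrichment()].
#' @param min_set_size minimum overlap with the signature; smaller sets are
#'   skipped with a message.
#' @return data.frame: set_name, es, p, adj_p, direction, set_size_in_universe.
#' @export
gsea_test <- function(signature, sets, n_perm = 10000L, seed = 1L,
                      adjust = c("BH", "bonferroni"), weight_exponent = 1,
                      min_set_size = 5L) {
  stopifnot(inherits(signature, "RankedSignature"), inherits(sets, "GeneSetCollection"))
  adjust <- match.arg(adjust)
  genes <- names(signature)
  n <- length(genes)
  overlap <- lapply(sets$sets, function(s) which(genes %in% s))
  sizes <- lengths(overlap)
  skip <- sizes < min_set_size
  drop_note(sum(skip), sprintf("set(s) with overlap below %d", min_set_size))
  keep <- names(sets$sets)[!skip]
  if (length(keep) == 0L) {
    return(data.frame(set_name = character(0), es = numeric(0), p = numeric(0),
                      adj_p = numeric(0), direction = integer(0),
                      set_size_in_universe = integer(0)))
  }
  w_full <- if (weight_exponent == 0) rep(1, n) else abs(signature)^weight_exponent

  es_obs <- vapply(keep, function(nm) {
    v <- overlap[[nm]]
    w <- w_full[v]
    if (sum(w) == 0) w <- rep(1, length(v))
    ks_stat_positions(v, w, n)
  }, numeric(1L))

  p <- with_seed(seed, {
    null_by_size <- new.env(parent = emptyenv())
    vapply(keep, function(nm) {
      t <- sizes[[nm]]
      key <- as.character(t)
      if (is.null(null_by_size[[key]])) {
        null_by_size[[key]] <- vapply(seq_len(n_perm), function(i) {
          v <- sort.int(sample.int(n, t))
          w <- w_full[v]
          if (sum(w) == 0) w <- rep(1, t)
          ks_stat_positions(v, w, n)
        }, numeric(1L))
      }
      nulls <- null_by_size[[key]]
      (1 + sum(abs(nulls) >= abs(es_obs[[nm]]))) / (1 + n_perm)
    }, numeric(1L))
  })

  data.frame(
    set_name = keep,
    es = unname(es_obs),
    p = unname(p),
    adj_p = adjust_pvalues(unname(p), adjust),
    direction = sign(unname(es_obs)),
    set_size_in_universe = unname(sizes[keep]),
    row.names = NULL
  )
}

#' Fisher's exact enrichment between two gene sets
#'
#' Builds the 2x2 table (both, a only, b only, neither) within `universe`
#' and reports the sample odds ratio, the conditional-MLE odds ratio, and
#' the exact hypergeometric P value.
#'
#' @param set_a,set_b character vectors (restricted to `universe`).
#' @param universe character vector, finite and non-empty.
#' @param alternative `"greater"` (enrichment) or `"two-sided"`.
#' @return one-row data.frame: overlap, size_a, size_b, universe_size,
#'   odds_ratio (sample), odds_ratio_cmle, p.
#' @export
fisher_exact_enrichment <- function(set_a, set_b, universe,
                                    alternative = c("greater", "two-sided")) {
  alternative <- match.arg(alternative)
  if (length(universe) == 0L) stop("universe must be non-empty")
  universe <- unique(universe)
  a_set <- intersect(set_a, universe)
  b_set <- intersect(set_b, universe)
  n11 <- length(intersect(a_set, b_set))
  n12 <- length(a_set) - n11
  n21 <- length(b_set) - n11
  n22 <- length(universe) - n11 - n12 - n21
  tab <- matrix(c(n11, n21, n12, n22), nrow = 2L)
  ft <- stats::fisher.test(tab, alternative = sub("two-sided", "two.sided", alternative))
  data.frame(
    overlap = n11, size_a = length(a_set), size_b = length(b_set),
    universe_size = length(universe),
    odds_ratio = (n11 * n22) / (n12 * n21),
    odds_ratio_cmle = unname(ft$estimate),
    p = ft$p.value
  )
}

#' Fisher's combined probability test
#'
#' @param p_values numeric vector of P values in (0, 1]; values above 1 are
#'   clipped to 1 and non-positive values are an error.
#' @return list with `chi2` (= -2 * sum(log p)), `df` (= 2k) and `p`.
#' @export
combine_pvalues_fisher <- function(p_values) {
  if (length(p_values) == 0L) stop("need at least one P value")
  if (any(!is.finite(p_values)) || any(p_values <= 0)) {
    stop("P values must be finite and > 0")
  }
  p_values <- pmin(p_values, 1)
  chi2 <- -2 * sum(log(p_values))
  df <- 2L * length(p_values)
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df = df, lower.tail = FALSE))
}

#' Adjust P values for multiple testing
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @param method `"BH"` (Benjamini-Hochberg step-up FDR) or `"bonferroni"`.
#' @return adjusted values in the input order.
#' @export
adjust_pvalues <- function(p_values, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("P values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = method)
}
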