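# Independent oracles used to check the package's own implementations.

# Exact Fisher P by full hypergeometric enumeration over the table support.
oracle_fisher_p <- function(n11, n12, n21, n22,
                            alternative = c("greater", "two-sided")) {
  alternative <- match.arg(alternative)
  m1 <- n11 + n12          # size of set A
  m2 <- n11 + n21          # size of set B
  N <- n11 + n12 + n21 + n22
  lo <- max(0L, m1 + m2 - N)
  hi <- min(m1, m2)
  supp <- lo:hi
  pr <- stats::dhyper(supp, m2, N - m2, m1)
  if (alternative == "greater") {
    sum(pr[supp >= n11])
  } else {
    sum(pr[pr <= pr[supp == n11] * (1 + 1e-7)])
  }
}

# Conditional-MLE odds ratio by maximizing the noncentral hypergeometric
# likelihood (equivalently solving E_psi[a] = a_obs), independent of
# stats::fisher.test.
oracle_cmle_or <- function(n11, n12, n21, n22) {
  m1 <- n11 + n12
  m2 <- n11 + n21
  N <- n11 + n12 + n21 + n22
  lo <- max(0L, m1 + m2 - N)
  hi <- min(m1, m2)
  if (lo == hi) return(NA_real_)        # degenerate support: OR unidentifiable
  if (n11 == lo) return(0)
  if (n11 == hi) return(Inf)
  supp <- lo:hi
  lw0 <- stats::dhyper(supp, m2, N - m2, m1, log = TRUE)
  mean_a <- function(logpsi) {
    lw <- lw0 + supp * logpsi
    w <- exp(lw - max(lw))
    sum(supp * w) / sum(w) - n11
  }
  exp(stats::uniroot(mean_a, c(-40, 40), tol = 1e-12)$root)
}

# Naive KS-like enrichment score: literal evaluation of the two maxima over
# the hit positions, recomputing cumulative weights by explicit summation.
oracle_ks_es <- function(positions, weights, n) {
  v <- sort(positions)
  t <- length(v)
  w <- weights[order(positions)]
  W <- sum(w)
  a <- -Inf
  b <- -Inf
  for (j in seq_len(t)) {
    cum <- sum(w[seq_len(j)])
    a <- max(a, cum / W - v[j] / n)
    prev <- if (j == 1L) 0 else sum(w[seq_len(j - 1L)])
    b <- max(b, v[j] / n - prev / W)
  }
  if (a > b) a else -b
}

# Small helper: a minimal two-group study from a matrix.
make_study <- function(mat, group, id = "s1", ...) {
  if (is.null(colnames(mat))) colnames(mat) <- paste0("s", seq_len(ncol(mat)))
  if (is.null(rownames(mat))) rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  ExpressionStudy(id, mat, group, ...)
}
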