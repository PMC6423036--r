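# Seed-gene correlation signatures (Pearson r -> Fisher z) and
# cross-context consensus signatures (Stouffer's Z).

#' Correlation signature of a seed gene
#'
#' Pearson correlation between the seed gene's expression and every other
#' gene across samples, transformed to a standard-normal score by Fisher's
#' z: `z = atanh(r) * sqrt(n - 3)`. Correlations are clipped to
#' `+/-(1 - 1e-12)` before `atanh` so that z stays finite. Zero-variance
#' genes are dropped with a message; a zero-variance seed is an error.
#'
#' @param study an [ExpressionStudy] with >= 4 samples. When the study has
#'   a `feature_to_gene` map, features are first condensed to gene level by
#'   maximum variance.
#' @param seed_gene gene symbol present in the study.
#' @return data.frame of class `AssocSignature`: gene, r, z; attributes
#'   `seed_gene` and `n_samples`. Use [as_ranked_signature()] to feed
#'   [gsea_test()].
#' @export
correlation_signature <- function(study, seed_gene) {
  stopifnot(inherits(study, "ExpressionStudy"))
  n <- ncol(study$values)
  if (n < 4L) stop("need at least 4 samples")
  Y <- study$values
  gene_of <- if (is.null(study$feature_to_gene)) {
    stats::setNames(rownames(Y), rownames(Y))
  } else {
    mapped <- study$feature_to_gene[rownames(Y)]
    stats::setNames(ifelse(is.na(mapped), rownames(Y), mapped), rownames(Y))
  }
  # condense to gene level by maximum variance
  v <- apply(Y, 1L, stats::var)
  ord <- order(-v, rownames(Y), method = "radix")
  keep <- ord[!duplicated(gene_of[ord])]
  Y <- Y[keep, , drop = FALSE]
  rownames(Y) <- gene_of[rownames(Y)]
  if (!seed_gene %in% rownames(Y)) {
    stop(sprintf("seed gene '%s' not found", seed_gene))
  }
  x <- Y[seed_gene, ]
  if (stats::sd(x) == 0) stop("seed gene has zero variance")
  others <- setdiff(rownames(Y), seed_gene)
  Y <- Y[others, , drop = FALSE]
  sds <- apply(Y, 1L, stats::sd)
  drop_note(sum(sds == 0), "zero-variance gene(s)")
  Y <- Y[sds > 0, , drop = FALSE]
  xc <- x - mean(x)
  Yc <- Y - rowMeans(Y)
  r <- as.numeric(Yc %*% xc) / (sqrt(rowSums(Yc^2)) * sqrt(sum(xc^2)))
  r <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  out <- data.frame(gene = rownames(Y), r = r,
                    z = atanh(r) * sqrt(n - 3),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "seed_gene") <- seed_gene
  attr(out, "n_samples") <- n
  class(out) <- c("AssocSignature", "data.frame")
  out
}

#' Convert an association signature to a ranked signature
#'
#' @param signature an `AssocSignature`.
#' @return a `RankedSignature` over the z scores.
#' @export
as_ranked_signature <- function(signature) {
  stopifnot(inherits(signature, "AssocSignature"))
  ranked_signature(stats::setNames(signature$z, signature$gene))
}

#' Stouffer consensus of per-gene z scores across contexts
#'
#' Restricts to genes present in every context and combines as
#' `z_combined = sum(z_i) / sqrt(k)`.
#'
#' @param z_tables list of named numeric z vectors (one per context, e.g.
#'   cell line).
#' @return data.frame of class `ConsensusSignature`: gene, z, k.
#' @export
stouffer_consensus <- function(z_tables) {
  stopifnot(length(z_tables) >= 1L)
  genes <- Reduce(intersect, lapply(z_tables, names))
  if (length(genes) == 0L) stop("no genes shared across all contexts")
  k <- length(z_tables)
  zmat <- vapply(z_tables, function(z) z[genes], numeric(length(genes)))
  zmat <- matrix(zmat, nrow = length(genes))
  out <- data.frame(gene = genes, z = rowSums(zmat) / sqrt(k), k = k,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("ConsensusSignature", "data.frame")
  out
}
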