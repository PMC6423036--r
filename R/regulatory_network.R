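# TF-regulon enrichment in a module, TF-PPI network construction with an
# expression filter, and kinase-substrate enrichment in that network.

#' TF target-set enrichment in a module
#'
#' Regulon names follow the `TF::source` convention (multiple ChIP
#' experiments per TF); a name without `::` is treated as a TF with a
#' single unnamed source. Each source set is tested against the module with
#' a one-sided Fisher's exact test in the given universe; per-TF P values
#' are combined with Fisher's method and BH-adjusted across TFs.
#'
#' @param module character vector of module genes.
#' @param regulons [GeneSetCollection] of TF target sets.
#' @param universe character vector of eligible genes.
#' @param fdr_threshold significance cutoff on the BH FDR.
#' @return data.frame of class `TFEnrichmentTable`: tf, n_sets, chi2, df,
#'   p, fdr, significant; per-source P values in attribute `per_set`.
#' @export
tf_target_enrichment <- function(module, regulons, universe,
                                 fdr_threshold = 0.01) {
  stopifnot(inherits(regulons, "GeneSetCollection"))
  nm <- names(regulons$sets)
  tf <- sub("::.*$", "", nm)
  per_set <- vapply(seq_along(nm), function(i) {
    fisher_exact_enrichment(regulons$sets[[i]], module, universe,
                            alternative = "greater")$p
  }, numeric(1L))
  names(per_set) <- nm
  by_tf <- split(per_set, tf)
  combined <- lapply(by_tf, combine_pvalues_fisher)
  out <- data.frame(
    tf = names(by_tf),
    n_sets = lengths(by_tf),
    chi2 = vapply(combined, `[[`, numeric(1L), "chi2"),
    df = vapply(combined, `[[`, numeric(1L), "df"),
    p = vapply(combined, `[[`, numeric(1L), "p"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out$fdr <- adjust_pvalues(out$p, "BH")
  out$significant <- out$fdr < fdr_threshold
  out <- out[order(out$p, out$tf, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "per_set") <- by_tf
  attr(out, "fdr_threshold") <- fdr_threshold
  class(out) <- c("TFEnrichmentTable", "data.frame")
  out
}

#' Build the TF-PPI network around significant TFs
#'
#' Nodes are the significant TFs plus their immediate interaction
#' partners, uniformly trimmed to `expressed_genes` (seed TFs failing the
#' filter are dropped too, and their partners with them unless adjacent to
#' a retained seed). Edges are the interactions induced among retained
#' nodes.
#'
#' @param significant_tfs character vector of seed TFs.
#' @param ppi a [PPIGraph].
#' @param expressed_genes character vector passing the expression filter.
#' @return object of class `TFPPINetwork`: `nodes` (data.frame node /
#'   is_seed), `edges` (two-column character matrix).
#' @export
build_tf_ppi <- function(significant_tfs, ppi, expressed_genes) {
  stopifnot(inherits(ppi, "PPIGraph"))
  seeds <- intersect(unique(significant_tfs), expressed_genes)
  if (length(significant_tfs) == 0L) {
    warning("no significant TFs; returning an empty network")
  }
  if (nrow(ppi$edges) > 0L && length(seeds) > 0L) {
    g <- igraph::graph_from_edgelist(ppi$edges, directed = FALSE)
    present <- intersect(seeds, igraph::V(g)$name)
    neigh <- if (length(present) > 0L) {
      unique(unlist(lapply(igraph::adjacent_vertices(g, present),
                           function(vs) vs$name)))
    } else character(0)
    neigh <- intersect(setdiff(neigh, seeds), expressed_genes)
    nodes <- c(seeds, neigh)
    sub <- igraph::induced_subgraph(g, intersect(nodes, igraph::V(g)$name))
    edges <- igraph::as_edgelist(sub)
  } else {
    nodes <- seeds
    edges <- matrix(character(0), ncol = 2L)
  }
  structure(
    list(nodes = data.frame(node = nodes, is_seed = nodes %in% seeds,
                            stringsAsFactors = FALSE),
         edges = edges),
    class = "TFPPINetwork"
  )
}

#' @export
print.TFPPINetwork <- function(x, ...) {
  cat(sprintf("TFPPINetwork: %d nodes (%d seed TFs), %d edges\n",
              nrow(x$nodes), sum(x$nodes$is_seed), nrow(x$edges)))
  invisible(x)
}

#' Kinase-substrate enrichment in a TF-PPI network
#'
#' Per kinase, a one-sided Fisher's exact test of its substrate set against
#' the network node set within the universe of network-eligible genes; BH
#' FDR and Bonferroni are both reported and the output is sorted by P with
#' a rank index. Kinases with no substrates in the universe are skipped
#' with a message.
#'
#' @param network a `TFPPINetwork`.
#' @param kinase_substrates [GeneSetCollection] of substrate sets.
#' @param universe character vector of network-eligible genes.
#' @return data.frame: kinase, n_substrates, overlap, odds_ratio, p, fdr,
#'   bonferroni, rank.
#' @export
kinase_enrichment <- function(network, kinase_substrates, universe) {
  stopifnot(inherits(network, "TFPPINetwork"),
            inherits(kinase_substrates, "GeneSetCollection"))
  nodes <- network$nodes$node
  rows <- lapply(names(kinase_substrates$sets), function(kin) {
    subs <- intersect(kinase_substrates$sets[[kin]], universe)
    if (length(subs) == 0L) return(NULL)
    fe <- fisher_exact_enrichment(subs, nodes, universe, alternative = "greater")
    data.frame(kinase = kin, n_substrates = length(subs),
               overlap = fe$overlap, odds_ratio = fe$odds_ratio,
               p = fe$p, stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(rows, is.null, logical(1L)))
  drop_note(skipped, "kinase(s) with no substrates in the universe")
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(out)) {
    return(data.frame(kinase = character(0), n_substrates = integer(0),
                      overlap = integer(0), odds_ratio = numeric(0),
                      p = numeric(0), fdr = numeric(0),
                      bonferroni = numeric(0), rank = integer(0)))
  }
  out$fdr <- adjust_pvalues(out$p, "BH")
  out$bonferroni <- adjust_pvalues(out$p, "bonferroni")
  out <- out[order(out$p, out$kinase, method = "radix"), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Overlap between a module and its TF-PPI network
#'
#' Reports the proportion of module genes found in the network together
#' with the Fisher's exact odds ratio and P value of the overlap in the
#' given universe.
#'
#' @param network a `TFPPINetwork`.
#' @param module character vector of module genes.
#' @param universe character vector of eligible genes.
#' @return one-row data.frame: n_module, n_network, overlap, proportion,
#'   odds_ratio, p.
#' @export
network_module_overlap <- function(network, module, universe) {
  stopifnot(inherits(network, "TFPPINetwork"))
  module <- intersect(unique(module), universe)
  fe <- fisher_exact_enrichment(module, network$nodes$node, universe,
                                alternative = "greater")
  data.frame(n_module = length(module), n_network = fe$size_b,
             overlap = fe$overlap,
             proportion = fe$overlap / max(length(module), 1L),
             odds_ratio = fe$odds_ratio, p = fe$p)
}

#' Genes above a detection quantile in a reference study
#'
#' Helper for the expression filter used when trimming TF-PPI networks:
#' a gene passes when its median expression exceeds the given quantile of
#' all expression values in the reference study.
#'
#' @param study an [ExpressionStudy].
#' @param quantile detection quantile in `[0, 1)`.
#' @return character vector of expressed gene symbols.
#' @export
expressed_genes <- function(study, quantile = 0.25) {
  stopifnot(inherits(study, "ExpressionStudy"))
  cutoff <- stats::quantile(study$values, probs = quantile)
  med <- apply(study$values, 1L, stats::median)
  feat <- study$feature_ids[med > cutoff]
  if (is.null(study$feature_to_gene)) return(unique(feat))
  mapped <- study$feature_to_gene[feat]
  unique(ifelse(is.na(mapped), feat, mapped))
}
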