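# Compound-signature aggregation (prototype ranked lists), module
# connectivity scoring with a modified KS statistic and permutation FDR,
# and chemogenomic target-class enrichment over the compound ranking.

#' Spearman's footrule distance between two rank vectors
#'
#' @param list_a,list_b named integer rank vectors over the same gene
#'   universe.
#' @return `sum(|rank_a - rank_b|)`.
#' @export
footrule_distance <- function(list_a, list_b) {
  if (length(list_a) != length(list_b) ||
      !setequal(names(list_a), names(list_b))) {
    stop("rank vectors must share the same gene universe")
  }
  sum(abs(list_a - list_b[names(list_a)]))
}

# Borda merge of two rank vectors: re-rank by mean rank, ties by symbol.
borda_merge <- function(a, b) {
  m <- (a + b[names(a)]) / 2
  rk <- integer(length(m))
  rk[order(m, names(a), method = "radix")] <- seq_along(m)
  stats::setNames(rk, names(a))
}

#' Prototype ranked list from replicate rankings
#'
#' Hierarchically merges replicates: repeatedly find the two lists at the
#' smallest Spearman footrule distance and replace them by their Borda
#' merge (re-rank by mean rank, ties by gene symbol) until one list
#' remains. Tie-breaking on distances uses a canonical key of the rank
#' vectors, so the result is invariant to the input ordering of the
#' replicates.
#'
#' @param replicates list of named rank vectors (>= 1) over a common
#'   universe.
#' @return a named rank vector.
#' @export
prototype_ranked_list <- function(replicates) {
  stopifnot(length(replicates) >= 1L)
  universe <- sort(names(replicates[[1L]]))
  pool <- lapply(replicates, function(r) r[universe])
  keys <- vapply(pool, paste, character(1L), collapse = ",")
  ord <- order(keys, method = "radix")
  pool <- pool[ord]
  keys <- keys[ord]
  while (length(pool) > 1L) {
    best <- NULL
    best_d <- Inf
    for (i in seq_len(length(pool) - 1L)) {
      for (j in seq(i + 1L, length(pool))) {
        d <- sum(abs(pool[[i]] - pool[[j]]))
        if (d < best_d ||
            (d == best_d && paste(keys[i], keys[j]) < paste(keys[best[1L]], keys[best[2L]]))) {
          best_d <- d
          best <- c(i, j)
        }
      }
    }
    merged <- borda_merge(pool[[best[1L]]], pool[[best[2L]]])
    pool <- c(pool[-best], list(merged))
    keys <- c(keys[-best], paste(merged, collapse = ","))
  }
  pool[[1L]]
}

#' Modified KS connectivity score of a gene set in a ranked list
#'
#' With `V(j)` the ascending positions of the `t` set genes in the list of
#' length `n`: `a = max_j (j/t - V(j)/n)`,
#' `b = max_j (V(j)/n - (j-1)/t)`; the score is `a` if `a > b`, else `-b`.
#' Positive scores mean the set concentrates at the up-regulated end
#' (rank 1).
#'
#' @param prl named rank vector (rank 1 = most up-regulated).
#' @param gene_set character vector, a non-empty subset of the universe.
#' @return score in `[-1, 1]`.
#' @export
connectivity_score <- function(prl, gene_set) {
  gene_set <- unique(gene_set)
  if (length(gene_set) == 0L) stop("gene set must be non-empty")
  if (!all(gene_set %in% names(prl))) stop("gene set must be a subset of the universe")
  v <- sort(unname(prl[gene_set]))
  ks_stat_positions(v, rep(1, length(v)), length(prl))
}

#' Compound connectivity scores with permutation FDR
#'
#' For each compound, merges its replicates into a prototype ranked list
#' and scores the gene set with [connectivity_score()]. The null permutes
#' the PRL's gene labels and rescores; since a label permutation places the
#' set at uniform random positions, null scores depend only on (n, t) and
#' a single null sample is shared by all compounds — exactly equivalent to
#' per-compound label permutation. Two-sided P values use the +1
#' correction; FDR is Benjamini-Hochberg across compounds.
#'
#' @param signatures a `CompoundSignatureSet` (see
#'   [sim_compound_profiles()] or [read_rank_matrix()]).
#' @param gene_set character vector of module genes.
#' @param n_perm number of label permutations (>= 10).
#' @param seed integer seed.
#' @return data.frame of class `ConnectivityResult`: compound_id, score,
#'   p, fdr.
#' @export
connectivity_fdr <- function(signatures, gene_set, n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(signatures, "CompoundSignatureSet"))
  if (n_perm < 10L) stop("n_perm must be at least 10")
  gene_set <- intersect(unique(gene_set), signatures$genes)
  if (length(gene_set) == 0L) stop("gene set must overlap the rank universe")
  n <- length(signatures$genes)
  t <- length(gene_set)
  scores <- vapply(signatures$compounds, function(reps) {
    connectivity_score(prototype_ranked_list(reps), gene_set)
  }, numeric(1L))
  nulls <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      ks_stat_positions(sort.int(sample.int(n, t)), rep(1, t), n)
    }, numeric(1L))
  })
  p <- vapply(scores, function(s) {
    (1 + sum(abs(nulls) >= abs(s))) / (1 + n_perm)
  }, numeric(1L))
  out <- data.frame(compound_id = names(scores), score = unname(scores),
                    p = unname(p), fdr = adjust_pvalues(unname(p), "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("ConnectivityResult", "data.frame")
  out
}

#' Target-class enrichment over the compound connectivity ranking
#'
#' Ranks compounds by connectivity score and tests each target class
#' (a gene-set collection over compound ids) for concentration at either
#' end of the ranking with the unweighted KS-like statistic and a
#' compound-label permutation null; BH FDR across classes. Classes with
#' fewer than two scored compounds are skipped with a message.
#'
#' @param results a `ConnectivityResult` from [connectivity_fdr()].
#' @param target_classes [GeneSetCollection] over compound ids.
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @return data.frame as from [gsea_test()].
#' @export
target_class_enrichment <- function(results, target_classes, n_perm = 1000L,
                                    seed = 1L) {
  stopifnot(inherits(results, "ConnectivityResult"))
  sig <- ranked_signature(stats::setNames(results$score, results$compound_id))
  gsea_test(sig, target_classes, n_perm = n_perm, seed = seed,
            adjust = "BH", weight_exponent = 0, min_set_size = 2L)
}

#' Read replicate rank matrices with an experiment-to-compound map
#'
#' The rank matrix is a TSV with genes in the first column and one column
#' of ranks per experiment; the map is a two-column TSV (experiment id,
#' compound id). Every column must be a permutation of `1..n_genes`.
#'
#' @param path rank-matrix TSV.
#' @param map_path experiment-to-compound TSV.
#' @return a `CompoundSignatureSet`.
#' @export
read_rank_matrix <- function(path, map_path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           comment.char = "#", check.names = FALSE)
  genes <- as.character(tab[[1L]])
  ranks <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(ranks) <- "integer"
  rownames(ranks) <- genes
  for (j in seq_len(ncol(ranks))) {
    if (!setequal(ranks[, j], seq_along(genes))) {
      stop(sprintf("column %s is not a permutation of 1..%d",
                   colnames(ranks)[j], length(genes)))
    }
  }
  map <- utils::read.delim(map_path, header = TRUE, sep = "\t",
                           comment.char = "#", check.names = FALSE)
  exp_id <- as.character(map[[1L]])
  cmp_id <- as.character(map[[2L]])
  missing <- setdiff(colnames(ranks), exp_id)
  drop_note(length(missing), "experiment column(s) absent from the map")
  compounds <- lapply(split(exp_id[exp_id %in% colnames(ranks)],
                            cmp_id[exp_id %in% colnames(ranks)]),
                      function(cols) {
                        lapply(cols, function(cc) stats::setNames(ranks[, cc], genes))
                      })
  structure(list(compounds = compounds, genes = genes),
            class = "CompoundSignatureSet")
}

#' Write a compound signature set as a rank matrix plus map
#'
#' Inverse of [read_rank_matrix()].
#'
#' @param signatures a `CompoundSignatureSet`.
#' @param path rank-matrix TSV to write.
#' @param map_path experiment-to-compound TSV to write.
#' @return invisibly, `signatures`.
#' @export
write_rank_matrix <- function(signatures, path, map_path) {
  stopifnot(inherits(signatures, "CompoundSignatureSet"))
  cols <- list()
  map <- list()
  for (cmp in names(signatures$compounds)) {
    reps <- signatures$compounds[[cmp]]
    for (r in seq_along(reps)) {
      eid <- sprintf("%s_rep%d", cmp, r)
      cols[[eid]] <- reps[[r]][signatures$genes]
      map[[eid]] <- cmp
    }
  }
  tab <- data.frame(gene = signatures$genes, cols, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(experiment = names(map), compound = unlist(map)),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(signatures)
}
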