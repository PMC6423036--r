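# Readers/writers for the external formats, plus identifier hygiene.
#
# Conventions: tab-separated UTF-8 tables, '#' comment lines skipped; leading
# non-tabular lines (GCT-style headers) are tolerated by skipping lines that
# contain no tab character. Gene identifiers are case-sensitive strings.

#' Construct an expression study
#'
#' Container for one cohort: a features x samples matrix of log2-scale
#' expression values with case/control labels and optional covariates.
#'
#' @param study_id character scalar identifying the cohort.
#' @param values numeric matrix, rows = features, columns = samples.
#' @param group character/factor of per-sample labels, values in
#'   `c("case", "control")`.
#' @param factor_covariates data.frame of per-sample categorical covariates
#'   (or NULL).
#' @param numeric_covariates data.frame of per-sample numeric covariates
#'   (or NULL).
#' @param feature_to_gene named character vector mapping feature id to gene
#'   symbol, or NULL when feature ids already are gene symbols.
#' @return an object of class `ExpressionStudy`.
#' @export
ExpressionStudy <- function(study_id, values, group,
                            factor_covariates = NULL,
                            numeric_covariates = NULL,
                            feature_to_gene = NULL) {
  stopifnot(is.character(study_id), length(study_id) == 1L)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (anyNA(values) || any(!is.finite(values))) {
    stop("expression values must be finite and complete (no NA cells)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have feature rownames and sample colnames")
  }
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  group <- as.character(group)
  if (length(group) != ncol(values)) {
    stop("group must have one label per sample")
  }
  if (!all(group %in% c("case", "control"))) {
    stop("group labels must be 'case' or 'control'")
  }
  check_cov <- function(cov) {
    if (is.null(cov)) return(NULL)
    cov <- as.data.frame(cov)
    if (nrow(cov) != ncol(values)) stop("covariate rows must match samples")
    rownames(cov) <- colnames(values)
    cov
  }
  structure(
    list(
      study_id = study_id,
      values = values,
      feature_ids = rownames(values),
      sample_ids = colnames(values),
      group = group,
      factor_covariates = check_cov(factor_covariates),
      numeric_covariates = check_cov(numeric_covariates),
      feature_to_gene = feature_to_gene
    ),
    class = "ExpressionStudy"
  )
}

#' @export
print.ExpressionStudy <- function(x, ...) {
  cat(sprintf(
    "ExpressionStudy '%s': %d features x %d samples (%d case / %d control)\n",
    x$study_id, nrow(x$values), ncol(x$values),
    sum(x$group == "case"), sum(x$group == "control")
  ))
  invisible(x)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (members deduplicated).
#' @param universe optional character vector; when given, membership tests
#'   downstream restrict sets to this universe.
#' @return an object of class `GeneSetCollection`.
#' @export
GeneSetCollection <- function(sets, universe = NULL) {
  stopifnot(is.list(sets))
  if (length(sets) > 0L && (is.null(names(sets)) || anyDuplicated(names(sets)))) {
    stop("set names must be unique and non-empty")
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  structure(list(sets = sets, universe = universe), class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf(
    "GeneSetCollection: %d sets%s\n", length(x$sets),
    if (is.null(x$universe)) "" else sprintf(" (universe of %d genes)", length(x$universe))
  ))
  invisible(x)
}

#' Construct an undirected protein-interaction graph
#'
#' Edges are stored as a two-column character matrix with each pair in
#' canonical (sorted) order; self-loops are disallowed.
#'
#' @param edges two-column character matrix or data.frame of gene pairs.
#' @param node_annotations optional named list of per-node flags.
#' @return an object of class `PPIGraph`.
#' @export
PPIGraph <- function(edges, node_annotations = list()) {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2L)
  }
  if (ncol(edges) != 2L) stop("edges must have two columns")
  storage.mode(edges) <- "character"
  if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
  canon <- cbind(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
  canon <- canon[!duplicated(paste(canon[, 1L], canon[, 2L], sep = "\r")), ,
                 drop = FALSE]
  colnames(canon) <- c("a", "b")
  structure(list(edges = canon, node_annotations = node_annotations),
            class = "PPIGraph")
}

#' @export
print.PPIGraph <- function(x, ...) {
  cat(sprintf("PPIGraph: %d edges over %d nodes\n",
              nrow(x$edges), length(unique(c(x$edges)))))
  invisible(x)
}

# Read a tab-separated table tolerating '#' comments and GCT-style leading
# non-tabular lines.
read_tsv_lines <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  # skip leading lines with no tab (GCT version/dimension headers)
  first_tab <- which(grepl("\t", lines, fixed = TRUE))
  if (length(first_tab) > 0L && first_tab[1L] > 1L) {
    lines <- lines[-seq_len(first_tab[1L] - 1L)]
  }
  lines
}

#' Read an expression matrix with its covariate table
#'
#' The expression file is a TSV with a header row of sample ids and feature
#' ids in the first column. The covariate file is a TSV keyed by sample id
#' with a mandatory `group` column (values `case`/`control`); remaining
#' columns become factor or numeric covariates according to their type.
#' Samples present in only one of the two files are dropped with a warning.
#' Duplicated feature-id rows are kept as distinct features (condensation to
#' gene level happens at effect-size time).
#'
#' @param path expression TSV.
#' @param covariate_path covariate TSV.
#' @param study_id cohort identifier; defaults to the expression file name.
#' @param feature_to_gene optional named character vector mapping feature id
#'   to gene symbol.
#' @return an [ExpressionStudy].
#' @export
read_expression_table <- function(path, covariate_path,
                                  study_id = basename(path),
                                  feature_to_gene = NULL) {
  lines <- read_tsv_lines(path)
  if (length(lines) < 2L) stop("expression file needs a header and data rows")
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  sample_ids <- header[-1L]
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  feat <- vapply(rows, `[[`, character(1L), 1L)
  vals <- matrix(NA_real_, nrow = length(rows), ncol = length(sample_ids))
  for (i in seq_along(rows)) {
    cells <- rows[[i]][-1L]
    if (length(cells) != length(sample_ids)) {
      stop(sprintf("row %d has %d values; expected %d",
                   i + 1L, length(cells), length(sample_ids)))
    }
    v <- suppressWarnings(as.numeric(cells))
    if (anyNA(v)) {
      j <- which(is.na(v))[1L]
      stop(sprintf("non-numeric or missing cell at data row %d, column %s",
                   i + 1L, sample_ids[j]))
    }
    vals[i, ] <- v
  }
  # duplicated feature ids stay distinct rows; disambiguate rownames and keep
  # the original id in feature_to_gene when no mapping was supplied
  feature_ids <- feat
  if (anyDuplicated(feature_ids)) {
    uniq <- make.unique(feature_ids, sep = "__dup")
    if (is.null(feature_to_gene)) {
      feature_to_gene <- stats::setNames(feat, uniq)
    }
    feature_ids <- uniq
  }
  rownames(vals) <- feature_ids
  colnames(vals) <- sample_ids

  cov <- utils::read.delim(covariate_path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!"group" %in% colnames(cov)) {
    stop("covariate table must contain a 'group' column")
  }
  rownames(cov) <- as.character(cov[[1L]])
  shared <- intersect(sample_ids, rownames(cov))
  n_drop <- length(sample_ids) - length(shared)
  if (n_drop > 0L) {
    warning(sprintf("%d sample(s) in expression file absent from covariates; dropped",
                    n_drop))
  }
  if (length(shared) == 0L) stop("no samples shared between expression and covariates")
  keep <- sample_ids[sample_ids %in% shared]   # order follows expression file
  vals <- vals[, keep, drop = FALSE]
  cov <- cov[keep, , drop = FALSE]
  group <- as.character(cov$group)
  rest <- cov[, setdiff(colnames(cov), c(colnames(cov)[1L], "group")), drop = FALSE]
  is_num <- vapply(rest, is.numeric, logical(1L))
  ExpressionStudy(
    study_id = study_id, values = vals, group = group,
    factor_covariates = if (any(!is_num)) rest[, !is_num, drop = FALSE] else NULL,
    numeric_covariates = if (any(is_num)) rest[, is_num, drop = FALSE] else NULL,
    feature_to_gene = feature_to_gene
  )
}

#' Write an expression study back to TSV files
#'
#' Inverse of [read_expression_table()]; used for round-trip checks and for
#' exporting simulated cohorts.
#'
#' @param study an [ExpressionStudy].
#' @param path expression TSV to write.
#' @param covariate_path covariate TSV to write.
#' @return invisibly, `study`.
#' @export
write_expression_table <- function(study, path, covariate_path) {
  stopifnot(inherits(study, "ExpressionStudy"))
  tab <- data.frame(feature_id = study$feature_ids,
                    study$values, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cov <- data.frame(sample_id = study$sample_ids, group = study$group,
                    check.names = FALSE)
  if (!is.null(study$factor_covariates)) cov <- cbind(cov, study$factor_covariates)
  if (!is.null(study$numeric_covariates)) cov <- cbind(cov, study$numeric_covariates)
  utils::write.table(cov, covariate_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(study)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, `name TAB description TAB member genes...`;
#' duplicate members within a line are deduplicated.
#'
#' @param path GMT file.
#' @return a [GeneSetCollection].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop(sprintf("GMT line %d has %d field(s); need name, description and members",
                   i, length(fields)))
    }
    sets[[fields[1L]]] <- unique(fields[-c(1L, 2L)])
  }
  GeneSetCollection(sets)
}

#' Write a gene-set collection as GMT
#'
#' @param collection a [GeneSetCollection].
#' @param path output file.
#' @param descriptions optional character vector of per-set descriptions.
#' @return invisibly, `collection`.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  nm <- names(collection$sets)
  desc <- descriptions %||% rep("na", length(nm))
  lines <- vapply(seq_along(nm), function(i) {
    paste(c(nm[i], desc[i], collection$sets[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(collection)
}

#' Read an interaction edge list (TSV or SIF)
#'
#' Two-column TSV of gene pairs, or three-column SIF whose middle column is
#' ignored. Edges are undirected and deduplicated; self-loops are removed
#' with a message.
#'
#' @param path edge-list file.
#' @return a [PPIGraph].
#' @export
read_edge_list <- function(path) {
  lines <- read_tsv_lines(path)
  if (length(lines) == 0L) return(PPIGraph(matrix(character(0), ncol = 2L)))
  parts <- strsplit(lines, "[\t ]+")
  ncols <- lengths(parts)
  if (any(ncols < 2L)) {
    stop(sprintf("edge line %d has fewer than 2 columns", which(ncols < 2L)[1L]))
  }
  a <- vapply(parts, `[[`, character(1L), 1L)
  b <- vapply(parts, function(p) p[[if (length(p) >= 3L) 3L else 2L]], character(1L))
  loops <- a == b
  drop_note(sum(loops), "self-loop edge(s)")
  PPIGraph(cbind(a[!loops], b[!loops]))
}

#' Write a PPI graph as a two-column TSV
#'
#' @param graph a [PPIGraph].
#' @param path output file.
#' @return invisibly, `graph`.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "PPIGraph"))
  utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(graph)
}

#' Read association summary statistics for one trait
#'
#' Expects a TSV with columns for variant id, effect and standard error
#' and/or (p, maf, n); column names are configurable through `column_map`.
#' Rows violating the invariants (duplicate variant, se <= 0, maf outside
#' (0, 0.5], p outside (0, 1], and neither (beta, se) nor (p, maf, n)
#' present) are dropped with a message.
#'
#' @param path summary-statistics TSV.
#' @param trait_id trait label stored with the table.
#' @param column_map named character vector mapping canonical names
#'   (`variant_id`, `beta`, `se`, `p`, `maf`, `n`, `case_fraction`) to the
#'   file's column names; canonical names are used directly when omitted.
#' @return a data.frame of class `SummaryStatsTable` with attribute
#'   `trait_id`.
#' @export
read_summary_stats <- function(path, trait_id, column_map = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE,
                           check.names = FALSE)
  canonical <- c("variant_id", "beta", "se", "p", "maf", "n", "case_fraction")
  map <- stats::setNames(canonical, canonical)
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  present <- map[map %in% colnames(tab)]
  if (!"variant_id" %in% names(present)) {
    stop("configured columns not found in file (no variant id column)")
  }
  out <- data.frame(variant_id = as.character(tab[[present[["variant_id"]]]]),
                    stringsAsFactors = FALSE)
  for (nm in setdiff(canonical, "variant_id")) {
    out[[nm]] <- if (nm %in% names(present)) as.numeric(tab[[present[[nm]]]]) else NA_real_
  }
  summary_stats_table(out, trait_id)
}

#' Validate and construct a summary-statistics table
#'
#' @param tab data.frame with columns `variant_id`, `beta`, `se`, `p`,
#'   `maf`, `n`, `case_fraction` (unavailable fields NA).
#' @param trait_id trait label.
#' @return validated data.frame of class `SummaryStatsTable`.
#' @export
summary_stats_table <- function(tab, trait_id) {
  has_beta_se <- !is.na(tab$beta) & !is.na(tab$se)
  has_pmn <- !is.na(tab$p) & !is.na(tab$maf) & !is.na(tab$n)
  ok <- (has_beta_se | has_pmn) &
    (is.na(tab$se) | tab$se > 0) &
    (is.na(tab$p) | (tab$p > 0 & tab$p <= 1)) &
    (is.na(tab$maf) | (tab$maf > 0 & tab$maf <= 0.5)) &
    (is.na(tab$n) | tab$n > 0) &
    !duplicated(tab$variant_id)
  drop_note(sum(!ok), sprintf("invalid summary-statistic row(s) for trait %s", trait_id))
  out <- tab[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "trait_id") <- trait_id
  class(out) <- c("SummaryStatsTable", "data.frame")
  out
}

#' Write a summary-statistics table as TSV
#'
#' @param tab a `SummaryStatsTable`.
#' @param path output file.
#' @return invisibly, `tab`.
#' @export
write_summary_stats <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tab)
}

#' Map mouse gene symbols to human homologs
#'
#' With an explicit two-column mapping (mouse, human), genes are translated
#' through it: unmapped genes are dropped with a message, and one-to-many
#' rows contribute all their targets. Without a mapping the default rule is
#' symbol uppercasing, the usual convention relating mouse (`Cdk1`) to human
#' (`CDK1`) symbols.
#'
#' @param genes character vector of mouse gene symbols.
#' @param mapping optional two-column data.frame (mouse, human).
#' @return character vector of human symbols (unique).
#' @export
map_homologs <- function(genes, mapping = NULL) {
  genes <- unique(as.character(genes))
  if (is.null(mapping) || nrow(mapping) == 0L) {
    return(unique(toupper(genes)))
  }
  mapping <- as.data.frame(mapping)
  src <- as.character(mapping[[1L]])
  dst <- as.character(mapping[[2L]])
  hit <- src %in% genes
  mapped_src <- unique(src[hit])
  drop_note(length(setdiff(genes, mapped_src)), "unmapped gene(s)")
  multi <- names(which(table(src[hit]) > 1L))
  if (length(multi) > 0L) {
    message(sprintf("dexnet: %d gene(s) map to multiple human symbols; keeping all",
                    length(multi)))
  }
  unique(dst[hit])
}
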