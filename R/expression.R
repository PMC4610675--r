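# Transcript-by-tissue expression tables (ASprofile-style FPKM TSVs) and
# tissue-dominance statistics of the highest-expressed isoform.

#' Construct an expression matrix
#'
#' @param values data.frame/data.table with columns `transcript_id`,
#'   `gene_symbol`, then one numeric column per tissue (FPKM-like,
#'   non-negative)
#' @return object of class `expression_matrix`
#' @export
expression_matrix <- function(values) {
  dt <- data.table::as.data.table(values)
  if (!all(c("transcript_id", "gene_symbol") %in% names(dt)))
    stop("expression table needs 'transcript_id' and 'gene_symbol' columns")
  tissues <- setdiff(names(dt), c("transcript_id", "gene_symbol"))
  if (!length(tissues)) stop("expression table has no tissue columns")
  if (!nrow(dt)) stop("expression table has no rows")
  for (t in tissues) {
    v <- suppressWarnings(as.numeric(dt[[t]]))
    if (anyNA(v)) stop("non-numeric abundance in tissue column '", t, "'")
    if (any(v < 0)) stop("negative abundance in tissue column '", t, "'")
    data.table::set(dt, j = t, value = v)
  }
  if (anyDuplicated(dt$transcript_id))
    stop("duplicate transcript row(s): ",
         paste(head(unique(dt$transcript_id[duplicated(dt$transcript_id)]), 3L),
               collapse = ", "))
  dt[, transcript_id := as.character(transcript_id)]
  dt[, gene_symbol := toupper(as.character(gene_symbol))]
  structure(list(data = dt, tissues = tissues), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d transcripts, %d genes, %d tissues\n",
              nrow(x$data), data.table::uniqueN(x$data$gene_symbol),
              length(x$tissues)))
  invisible(x)
}

#' Read a transcript-by-tissue expression TSV
#'
#' Header line: `transcript_id`, `gene_symbol`, then one column per tissue.
#' Duplicate transcript rows, negative or non-numeric abundances, and
#' header-only files are errors.
#' @param path TSV file path
#' @return an `expression_matrix`
#' @export
read_expression <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (!nrow(dt)) stop("expression table is empty: ", path)
  expression_matrix(dt)
}

#' Write an expression matrix as TSV
#' @param matrix an `expression_matrix`
#' @param path output file
#' @export
write_expression <- function(matrix, path) {
  stopifnot(inherits(matrix, "expression_matrix"))
  data.table::fwrite(matrix$data, path, sep = "\t")
  invisible(path)
}

#' Highest-expressed transcript of a gene
#'
#' The transcript with the maximal summed abundance across tissues (default)
#' or maximal abundance in any single tissue (`mode = "max_any"`). Ties are
#' broken by lexicographic transcript id. A gene whose every transcript is
#' zero everywhere returns `NA` and is excluded from dominance statistics.
#'
#' @param gene_symbol gene symbol
#' @param matrix an `expression_matrix`
#' @param mode `"total"` or `"max_any"`
#' @return transcript id, or `NA_character_` for an all-zero gene
#' @export
highest_expressed_variant <- function(gene_symbol, matrix,
                                      mode = c("total", "max_any")) {
  stopifnot(inherits(matrix, "expression_matrix"))
  mode <- match.arg(mode)
  sym <- toupper(gene_symbol)
  rows <- matrix$data[matrix$data$gene_symbol == sym]
  if (!nrow(rows)) stop("gene not in expression matrix: ", gene_symbol)
  m <- as.matrix(rows[, matrix$tissues, with = FALSE])
  score <- if (mode == "total") rowSums(m) else apply(m, 1L, max)
  if (all(score == 0)) return(NA_character_)
  ids <- rows$transcript_id
  best <- which(score == max(score))
  ids[best][order(ids[best])][1L]
}

#' Tissue dominance of a gene list
#'
#' For each list gene: pick its highest-expressed transcript, then the tissue
#' where that transcript is most abundant (ties broken by lexicographic
#' tissue name, so relabeling or reordering tissues cannot change results).
#' Per-list fractions are computed over scored genes (genes with any nonzero
#' expression); they sum to 1.
#'
#' @param list `gene_list` or character vector of symbols
#' @param matrix an `expression_matrix`
#' @param mode passed to [highest_expressed_variant()]
#' @return object of class `tissue_dominance`: `per_gene` table
#'   (`gene_symbol`, `top_transcript_id`, `top_tissue`) and `fractions`
#'   (named over tissues)
#' @export
tissue_dominance <- function(list, matrix, mode = c("total", "max_any")) {
  stopifnot(inherits(matrix, "expression_matrix"))
  mode <- match.arg(mode)
  syms <- if (inherits(list, "gene_list")) list$symbols else
    toupper(as.character(list))
  syms <- intersect(syms, unique(matrix$data$gene_symbol))
  if (!length(syms)) stop("no list genes in expression matrix")
  dom <- gene_dominant_tissues(matrix, mode)[gene_symbol %in% syms]
  scored <- dom[!is.na(top_tissue)]
  fr <- table(factor(scored$top_tissue, levels = sort(matrix$tissues)))
  fr <- setNames(as.numeric(fr) / nrow(scored), names(fr))
  structure(list(per_gene = dom, fractions = fr, n_scored = nrow(scored)),
            class = "tissue_dominance")
}

#' @export
print.tissue_dominance <- function(x, ...) {
  cat("tissue_dominance over", x$n_scored, "scored genes; top tissues:\n")
  top <- sort(x$fractions, decreasing = TRUE)[1:min(4, length(x$fractions))]
  for (t in names(top)) cat(sprintf("  %-18s %5.1f%%\n", t, 100 * top[[t]]))
  invisible(x)
}

# per-gene (top transcript, top tissue); NA tissue for all-zero genes
gene_dominant_tissues <- function(matrix, mode = "total") {
  dt <- matrix$data
  m <- as.matrix(dt[, matrix$tissues, with = FALSE])
  score <- if (mode == "total") rowSums(m) else apply(m, 1L, max)
  ord <- order(dt$gene_symbol, -score, dt$transcript_id)
  first <- ord[!duplicated(dt$gene_symbol[ord])]
  # argmax tissue with lexicographic tie-break
  tcols <- matrix$tissues[order(matrix$tissues)]
  sub <- m[first, tcols, drop = FALSE]
  top_tissue <- tcols[max.col(sub, ties.method = "first")]
  top_tissue[rowSums(sub) == 0] <- NA_character_
  zero_gene <- score[first] == 0
  data.table::data.table(
    gene_symbol = dt$gene_symbol[first],
    top_transcript_id = ifelse(zero_gene, NA_character_,
                               dt$transcript_id[first]),
    top_tissue = ifelse(zero_gene, NA_character_, top_tissue))
}

#' Normalize a gene's transcript rows across tissues
#'
#' Rescales each transcript row of the gene to sum to 1 across tissues;
#' zero-total rows are dropped with a warning.
#' @inheritParams highest_expressed_variant
#' @return data.table of per-transcript tissue fractions
#' @export
normalize_across_tissues <- function(gene_symbol, matrix) {
  stopifnot(inherits(matrix, "expression_matrix"))
  sym <- toupper(gene_symbol)
  rows <- matrix$data[matrix$data$gene_symbol == sym]
  if (!nrow(rows)) stop("gene not in expression matrix: ", gene_symbol)
  m <- as.matrix(rows[, matrix$tissues, with = FALSE])
  tot <- rowSums(m)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " zero-total transcript row(s) dropped for ",
            gene_symbol)
    m <- m[tot > 0, , drop = FALSE]
    rows <- rows[tot > 0]
    tot <- tot[tot > 0]
  }
  out <- data.table::data.table(transcript_id = rows$transcript_id)
  cbind(out, data.table::as.data.table(m / tot))
}

#' Bootstrap enrichment of tissue dominance for a gene list
#'
#' Statistic: the fraction of list genes whose highest-expressed transcript
#' is most abundant in `tissue` (lung by default). Nulls come from
#' length-matched control lists drawn from `pool`.
#'
#' @inheritParams bootstrap_enrichment
#' @param matrix an `expression_matrix`
#' @param tissue tissue name (must be a matrix column)
#' @return a `bootstrap_result`
#' @export
lung_enrichment <- function(list, pool = NULL, matrix, annotation,
                            tissue = "lung", n_lists = 1000,
                            direction = "greater", tolerance = 0.10,
                            seed = NULL) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (!tissue %in% matrix$tissues)
    stop("tissue '", tissue, "' not in expression matrix")
  bootstrap_enrichment(list, pool, annotation, statistic = "tissue_fraction",
                       n_lists = n_lists, direction = direction,
                       tolerance = tolerance, expression = matrix,
                       stat_args = list(tissue = tissue), seed = seed)
}
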