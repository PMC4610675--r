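#' Mean number of transcripts per locus for a gene list
#'
#' Arithmetic mean of annotated transcript counts over the list symbols found
#' in the annotation. Symbols absent from the annotation are skipped and
#' reported in `attr(, "absent_symbols")`.
#'
#' @param list a `gene_list` or character vector of symbols
#' @param annotation a `genome_annotation`
#' @return mean transcripts per locus (numeric scalar)
#' @export
mean_transcripts_per_locus <- function(list, annotation) {
  syms <- found_symbols(list, annotation)
  out <- mean(annotation$loci[syms, n_transcripts])
  all_syms <- if (inherits(list, "gene_list")) list$symbols else toupper(list)
  attr(out, "absent_symbols") <- setdiff(all_syms, syms)
  out
}

#' Transcript-count histogram of a gene list
#'
#' Proportion of list loci producing 1, 2, 3, 4, 5, and 6-or-more annotated
#' transcripts.
#' @inheritParams mean_transcripts_per_locus
#' @return named numeric vector over bins `"1"..."5","6+"`, summing to 1;
#'   number of scored loci in `attr(, "n")`
#' @export
complexity_histogram <- function(list, annotation) {
  syms <- found_symbols(list, annotation)
  n <- annotation$loci[syms, n_transcripts]
  bin <- ifelse(n >= 6, "6+", as.character(n))
  out <- table(factor(bin, levels = c("1", "2", "3", "4", "5", "6+")))
  out <- as.numeric(out) / length(n)
  names(out) <- c("1", "2", "3", "4", "5", "6+")
  attr(out, "n") <- length(n)
  out
}

#' Remove the k most transcriptionally complex genes from a list
#'
#' Drops the `k` list genes with the largest annotated transcript counts
#' (ties broken by list order), for leave-top-k robustness re-testing.
#' @inheritParams mean_transcripts_per_locus
#' @param k number of genes to drop; must be < length(list)
#' @return a `gene_list`
#' @export
leave_top_k_out <- function(list, annotation, k) {
  stopifnot(inherits(list, "gene_list"))
  if (k >= length(list$symbols))
    stop("k must be smaller than the list size")
  if (k == 0) return(list)
  counts <- annotation$loci[list$symbols, n_transcripts]
  counts[is.na(counts)] <- 0
  drop <- order(-counts)[seq_len(k)]  # stable: ties keep list order
  gene_list(list$symbols[-drop], name = paste0(list$name, "_minus_top", k),
            evidence = list$evidence)
}

#' Keep genes with strictly more positive than negative study evidence
#'
#' Filters a gene list by its per-symbol evidence counts: a symbol survives
#' only if `n_positive > n_negative` (equal counts are removed). Symbols with
#' no evidence record are kept with a warning.
#' @param list a `gene_list` with an `evidence` table
#' @return filtered `gene_list`
#' @export
filter_by_evidence <- function(list) {
  stopifnot(inherits(list, "gene_list"))
  if (is.null(list$evidence)) stop("gene list carries no evidence counts")
  ev <- list$evidence
  idx <- match(list$symbols, ev$symbol)
  no_ev <- is.na(idx)
  if (any(no_ev))
    warning(sum(no_ev), " symbol(s) without evidence records kept: ",
            paste(head(list$symbols[no_ev], 5L), collapse = ", "))
  keep <- no_ev | (ev$n_positive[idx] > ev$n_negative[idx])
  gene_list(list$symbols[keep], name = paste0(list$name, "_evidence"),
            evidence = ev)
}

#' Transcript-level length statistics of a gene list
#'
#' Averages over all transcripts of all list loci found in the annotation:
#' mature mRNA length (sum of exon lengths, bp) and the number of large exons
#' per transcript, where a large exon is strictly longer than 200 bp.
#' @inheritParams mean_transcripts_per_locus
#' @return list with `mean_mrna_length`, `mean_large_exons`, `n_transcripts`
#' @export
transcript_length_stats <- function(list, annotation) {
  syms <- found_symbols(list, annotation)
  tx <- annotation$transcripts[gene_symbol %in% syms]
  list(mean_mrna_length = mean(tx$mature_length),
       mean_large_exons = mean(tx$n_large_exons),
       n_transcripts = nrow(tx))
}

#' Disease-database enrichment of transcriptionally diverse genes
#'
#' Splits the annotation's loci into a high-complexity set (more than
#' `threshold` transcripts, i.e. >= 6 by default) and a 1..`threshold` set,
#' counts disease-database members in the high set, and bootstraps the null by
#' counting members in equally sized random draws from the low-complexity set.
#'
#' @param annotation a `genome_annotation` (the reference pool)
#' @param disease_db `gene_list` of disease-database member symbols
#' @param n_lists number of bootstrap draws
#' @param threshold complexity cut: high set has `n_transcripts > threshold`
#' @param seed RNG seed
#' @return a `bootstrap_result` (statistic: member count)
#' @export
diverse_gene_disease_enrichment <- function(annotation, disease_db,
                                            n_lists = 1000, threshold = 5,
                                            seed = NULL) {
  stopifnot(inherits(annotation, "genome_annotation"),
            inherits(disease_db, "gene_list"))
  lt <- annotation$loci
  high <- lt[n_transcripts > threshold, gene_symbol]
  low <- lt[n_transcripts <= threshold, gene_symbol]
  if (!length(high)) stop("no loci with more than ", threshold, " transcripts")
  if (length(low) < length(high))
    stop("low-complexity set smaller than high-complexity set; cannot resample")
  member <- low %in% disease_db$symbols
  observed <- sum(high %in% disease_db$symbols)
  m <- length(high)
  nulls <- with_seed(seed, {
    vapply(seq_len(n_lists),
           function(i) sum(member[sample.int(length(low), m)]), numeric(1))
  })
  new_bootstrap_result("disease_db_members", observed, nulls,
                       direction = "greater", seed = seed,
                       extra = list(n_high = m, n_low = length(low)))
}
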