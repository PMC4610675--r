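#' Build a genome annotation from an exon table
#'
#' The in-memory model used throughout the package. A locus is the maximal
#' genomic span covering all transcripts that share a gene symbol; a
#' transcript is an ordered set of non-overlapping exon intervals. All
#' coordinates are 0-based half-open (`[start, end)`), the native refFlat
#' convention; GTF input is converted at the boundary.
#'
#' Cleanup rules applied on construction:
#' * exon rows duplicated verbatim are collapsed;
#' * a transcript id annotated with two different structures keeps the first
#'   occurrence (warning);
#' * a gene symbol annotated on two chromosomes keeps the chromosome with the
#'   most transcripts, ties broken by the lexicographically smallest
#'   chromosome name (warning).
#'
#' @param exons data.frame/data.table with columns `gene_symbol`,
#'   `transcript_id`, `chrom`, `strand` (`+`/`-`), `start`, `end`
#'   (0-based half-open).
#' @param source_tag free-text provenance label (e.g. `"refseq"`,
#'   `"synthetic"`).
#' @return A `genome_annotation` object: list with the validated exon table
#'   and derived per-transcript and per-locus tables.
#' @export
genome_annotation <- function(exons, source_tag = "unknown") {
  ex <- data.table::as.data.table(exons)
  need <- c("gene_symbol", "transcript_id", "chrom", "strand", "start", "end")
  miss <- setdiff(need, names(ex))
  if (length(miss))
    stop("exon table lacks column(s): ", paste(miss, collapse = ", "))
  ex <- ex[, need, with = FALSE]
  ex[, `:=`(gene_symbol = as.character(gene_symbol),
            transcript_id = as.character(transcript_id),
            chrom = as.character(chrom), strand = as.character(strand),
            start = as.numeric(start), end = as.numeric(end))]
  if (nrow(ex)) {
    bad <- which(!(ex$start < ex$end))
    if (length(bad))
      stop("rejected exon record(s): start >= end at row(s) ",
           paste(head(bad, 5L), collapse = ", "))
    if (!all(ex$strand %in% c("+", "-")))
      stop("strand must be '+' or '-'")
  }
  ex <- unique(ex)

  # a transcript id must resolve to one (gene, chrom, strand)
  key <- ex[, .(gene_symbol = gene_symbol[1L], chrom = chrom[1L],
                strand = strand[1L]), by = transcript_id]
  merged <- merge(ex, key, by = "transcript_id", suffixes = c("", ".first"))
  clash <- merged$gene_symbol != merged$gene_symbol.first |
    merged$chrom != merged$chrom.first | merged$strand != merged$strand.first
  if (any(clash)) {
    warning("transcript id(s) with conflicting gene/chrom/strand; first wins: ",
            paste(unique(merged$transcript_id[clash]), collapse = ", "))
    ex <- merged[!clash, need, with = FALSE]
  }

  data.table::setorder(ex, transcript_id, start)
  ovl <- ex[, .(bad = .N > 1L && any(start[-1L] < end[-.N])), by = transcript_id]
  if (any(ovl$bad))
    stop("overlapping exons within transcript(s): ",
         paste(ovl$transcript_id[ovl$bad], collapse = ", "))

  # paralog misannotation: one symbol on two chromosomes
  g2c <- unique(ex[, .(gene_symbol, chrom, transcript_id)])
  g2c <- g2c[, .(n_tx = data.table::uniqueN(transcript_id)),
             by = .(gene_symbol, chrom)]
  multi <- g2c[, .N, by = gene_symbol][N > 1L, gene_symbol]
  if (length(multi)) {
    keep <- g2c[gene_symbol %in% multi]
    data.table::setorder(keep, gene_symbol, -n_tx, chrom)
    keep <- keep[, .SD[1L], by = gene_symbol]
    warning("gene symbol(s) on multiple chromosomes; keeping dominant copy: ",
            paste(multi, collapse = ", "))
    drop <- ex$gene_symbol %in% multi &
      !paste(ex$gene_symbol, ex$chrom) %in% paste(keep$gene_symbol, keep$chrom)
    ex <- ex[!drop]
  }

  ann <- structure(list(exons = ex, source_tag = source_tag),
                   class = "genome_annotation")
  if (!nrow(ex)) {  # data.table probes j on the empty subset; avoid warnings
    ann$transcripts <- data.table::data.table(
      transcript_id = character(0), gene_symbol = character(0),
      chrom = character(0), strand = character(0), tx_start = numeric(0),
      tx_end = numeric(0), n_exons = integer(0), mature_length = numeric(0),
      n_large_exons = integer(0))
    ann$loci <- data.table::data.table(
      gene_symbol = character(0), chrom = character(0),
      strand = character(0), span_start = numeric(0), span_end = numeric(0),
      n_transcripts = integer(0), length = numeric(0))
    data.table::setkey(ann$transcripts, transcript_id)
    data.table::setkey(ann$loci, gene_symbol)
    return(ann)
  }
  ann$transcripts <- ex[, .(
    gene_symbol = gene_symbol[1L], chrom = chrom[1L], strand = strand[1L],
    tx_start = min(start), tx_end = max(end), n_exons = .N,
    mature_length = sum(end - start),
    n_large_exons = sum((end - start) > 200)), by = transcript_id]
  ann$loci <- ann$transcripts[, .(
    chrom = chrom[1L], strand = strand[1L],
    span_start = min(tx_start), span_end = max(tx_end),
    n_transcripts = .N), by = gene_symbol]
  ann$loci[, length := span_end - span_start]
  data.table::setkey(ann$transcripts, transcript_id)
  data.table::setkey(ann$loci, gene_symbol)
  ann
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation [%s]: %d loci, %d transcripts, %d exons\n",
              x$source_tag, nrow(x$loci), nrow(x$transcripts), nrow(x$exons)))
  invisible(x)
}

#' Per-locus summary table
#'
#' One row per gene symbol: chromosome, strand, span, span length and
#' transcript count. This is the table the bootstrap engine samples from.
#' @param annotation a `genome_annotation`
#' @return data.table with columns `gene_symbol`, `chrom`, `strand`,
#'   `span_start`, `span_end`, `n_transcripts`, `length`
#' @export
locus_table <- function(annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  data.table::copy(annotation$loci)
}

#' Per-transcript summary table
#' @inheritParams locus_table
#' @return data.table keyed by `transcript_id` with exon count, mature length
#'   (sum of exon lengths) and the count of exons longer than 200 bp.
#' @export
transcript_table <- function(annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  data.table::copy(annotation$transcripts)
}

#' Raw exon table (0-based half-open)
#' @inheritParams locus_table
#' @export
exon_table <- function(annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  data.table::copy(annotation$exons)
}

#' Extract one locus as a structured object
#'
#' @inheritParams locus_table
#' @param gene_symbol gene symbol to extract
#' @return list of class `locus`: symbol, chrom, strand, span, and a named
#'   list of transcripts, each a list of class `transcript_model` carrying its
#'   sorted exon table.
#' @export
get_locus <- function(annotation, gene_symbol) {
  stopifnot(inherits(annotation, "genome_annotation"))
  sym <- gene_symbol  # plain variable: inside DT[] the arg name is a column
  li <- annotation$loci[sym]
  if (is.na(li$chrom)) stop("gene symbol not in annotation: ", sym)
  ex <- annotation$exons[annotation$exons$gene_symbol == sym]
  txs <- lapply(split(ex, by = "transcript_id", sorted = TRUE), function(t) {
    structure(list(transcript_id = t$transcript_id[1L],
                   gene_symbol = gene_symbol,
                   chrom = t$chrom[1L], strand = t$strand[1L],
                   exons = t[order(start), .(start, end)]),
              class = "transcript_model")
  })
  structure(list(gene_symbol = gene_symbol, chrom = li$chrom,
                 strand = li$strand, span_start = li$span_start,
                 span_end = li$span_end, transcripts = txs),
            class = "locus")
}

#' Extract one transcript model
#' @inheritParams locus_table
#' @param transcript_id transcript identifier
#' @export
get_transcript <- function(annotation, transcript_id) {
  stopifnot(inherits(annotation, "genome_annotation"))
  id <- transcript_id
  t <- annotation$exons[annotation$exons$transcript_id == id]
  if (!nrow(t)) stop("transcript id not in annotation: ", transcript_id)
  structure(list(transcript_id = transcript_id,
                 gene_symbol = t$gene_symbol[1L],
                 chrom = t$chrom[1L], strand = t$strand[1L],
                 exons = t[order(start), .(start, end)]),
            class = "transcript_model")
}

#' Genomic span length of a locus
#'
#' The maximum span encompassing all transcripts of the gene, in bp.
#' @param locus a `locus` from [get_locus()]
#' @return span length in bp
#' @export
locus_length <- function(locus) {
  stopifnot(inherits(locus, "locus"))
  locus$span_end - locus$span_start
}

#' Span lengths for every locus
#' @inheritParams locus_table
#' @return named numeric vector, bp per gene symbol
#' @export
locus_lengths <- function(annotation) {
  lt <- locus_table(annotation)
  setNames(lt$length, lt$gene_symbol)
}

#' Filter loci by span length
#'
#' Removes loci whose span exceeds `max_length` (strictly greater — a locus of
#' exactly `max_length` bp is retained) or falls below `min_length`. The
#' default reproduces the convention of dropping loci above one megabase;
#' `min_length` lets the user exclude micro-RNA-scale loci explicitly.
#'
#' @inheritParams locus_table
#' @param max_length maximum span, bp (default 1e6)
#' @param min_length minimum span, bp (default 0)
#' @return filtered `genome_annotation`; removed symbols in
#'   `attr(, "removed_symbols")`
#' @export
filter_loci <- function(annotation, max_length = 1e6, min_length = 0) {
  stopifnot(inherits(annotation, "genome_annotation"))
  lt <- annotation$loci
  bad <- lt[length > max_length | length < min_length, gene_symbol]
  out <- if (length(bad)) {
    genome_annotation(annotation$exons[!gene_symbol %in% bad],
                      annotation$source_tag)
  } else annotation
  attr(out, "removed_symbols") <- bad
  out
}

#' Keep only transcripts whose id matches an accession prefix filter
#'
#' Convenience for annotation sources whose ids carry semantics (e.g. NM_
#' coding vs NR_ non-coding RefSeq accessions). The default model keeps all
#' transcripts; this makes any exclusion an explicit user choice.
#' @inheritParams locus_table
#' @param keep_prefix character vector of allowed id prefixes
#' @export
filter_transcripts_by_prefix <- function(annotation, keep_prefix) {
  stopifnot(inherits(annotation, "genome_annotation"))
  pat <- paste0("^(", paste(keep_prefix, collapse = "|"), ")")
  genome_annotation(annotation$exons[grepl(pat, transcript_id)],
                    annotation$source_tag)
}
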