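#' Read a GTF annotation
#'
#' Parses exon features into a [genome_annotation()]. GTF 1-based closed
#' coordinates are converted to the internal 0-based half-open convention.
#' Genes are grouped by the `gene_name` attribute when present, otherwise
#' `gene_id`. Lines are pre-scanned so malformed records are reported with
#' their line number; the heavy lifting is done by `rtracklayer::import`.
#'
#' @param path GTF file path
#' @param source_tag provenance label stored on the annotation
#' @return a `genome_annotation`
#' @export
read_gtf <- function(path, source_tag = "gtf") {
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  nf <- lengths(regmatches(lines[body], gregexpr("\t", lines[body], fixed = TRUE)))
  bad <- body[nf < 8L]
  if (length(bad))
    stop("malformed GTF line ", bad[1L], ": expected 9 tab-separated fields")
  f45 <- data.table::tstrsplit(lines[body], "\t", fixed = TRUE, keep = 4:5)
  s <- suppressWarnings(as.numeric(f45[[1L]])); e <- suppressWarnings(as.numeric(f45[[2L]]))
  bad <- body[is.na(s) | is.na(e) | s > e]
  if (length(bad))
    stop("rejected GTF record at line ", bad[1L], ": start > end or non-numeric")

  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[as.character(gr$type) == "exon"]
  if (!length(gr)) stop("no exon features in GTF: ", path)
  md <- S4Vectors::mcols(gr)
  gene <- if ("gene_name" %in% names(md) && !all(is.na(md$gene_name)))
    as.character(md$gene_name) else as.character(md$gene_id)
  ex <- data.table::data.table(
    gene_symbol = gene,
    transcript_id = as.character(md$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1,  # to 0-based half-open
    end = as.numeric(GenomicRanges::end(gr)))
  genome_annotation(ex, source_tag)
}

#' Write a genome annotation as GTF
#'
#' Emits one `exon` feature per exon with `gene_id`, `gene_name` and
#' `transcript_id` attributes, converting back to 1-based closed coordinates.
#' Round-trips through [read_gtf()].
#' @param annotation a `genome_annotation`
#' @param path output file
#' @export
write_gtf <- function(annotation, path) {
  stopifnot(inherits(annotation, "genome_annotation"))
  ex <- annotation$exons[order(chrom, start, transcript_id)]
  lines <- sprintf(
    '%s\ttxcomplexity\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_name "%s"; transcript_id "%s";',
    ex$chrom, as.integer(ex$start) + 1L, as.integer(ex$end), ex$strand,
    ex$gene_symbol, ex$gene_symbol, ex$transcript_id)
  writeLines(lines, path)
  invisible(path)
}

#' Read a UCSC refFlat/refGene annotation
#'
#' Tab-separated, no header: geneName, name, chrom, strand, txStart, txEnd,
#' cdsStart, cdsEnd, exonCount, exonStarts, exonEnds (exon lists
#' comma-terminated). Coordinates are already 0-based half-open and are taken
#' verbatim. Rows repeating an already-seen transcript id are dropped so
#' transcript ids are unique; a dropped row with a different structure draws a
#' warning (first record wins).
#'
#' @param path refFlat file path
#' @param source_tag provenance label
#' @return a `genome_annotation`
#' @export
read_refflat <- function(path, source_tag = "refflat") {
  rf <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = "character")
  if (ncol(rf) < 11L)
    stop("refFlat requires 11 tab-separated columns, got ", ncol(rf))
  data.table::setnames(rf, 1:11, c(
    "geneName", "name", "chrom", "strand", "txStart", "txEnd", "cdsStart",
    "cdsEnd", "exonCount", "exonStarts", "exonEnds"))
  recs <- vector("list", nrow(rf))
  seen <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(rf))) {
    starts <- as.numeric(strsplit(rf$exonStarts[i], ",", fixed = TRUE)[[1L]])
    ends <- as.numeric(strsplit(rf$exonEnds[i], ",", fixed = TRUE)[[1L]])
    n <- as.integer(rf$exonCount[i])
    if (length(starts) != n || length(ends) != n)
      stop("rejected refFlat record at row ", i,
           ": exonCount does not match exon list lengths")
    id <- rf$name[i]
    sig <- paste(rf$geneName[i], rf$chrom[i], rf$strand[i],
                 paste(starts, ends, collapse = ";"))
    if (!is.null(prev <- seen[[id]])) {
      if (!identical(prev, sig))
        warning("transcript id ", id, " repeated with different structure; ",
                "first record wins")
      next
    }
    seen[[id]] <- sig
    recs[[i]] <- data.table::data.table(
      gene_symbol = rf$geneName[i], transcript_id = id, chrom = rf$chrom[i],
      strand = rf$strand[i], start = starts, end = ends)
  }
  ex <- data.table::rbindlist(recs)
  if (!nrow(ex)) stop("no records parsed from refFlat: ", path)
  genome_annotation(ex, source_tag)
}

#' Construct a gene list
#'
#' @param symbols character vector of gene symbols (uppercased, trimmed,
#'   deduplicated preserving order)
#' @param name list label
#' @param evidence optional data.frame with columns `symbol`, `n_positive`,
#'   `n_negative` (study-evidence counts used by [filter_by_evidence()])
#' @return object of class `gene_list`
#' @export
gene_list <- function(symbols, name = "gene_list", evidence = NULL) {
  symbols <- toupper(trimws(as.character(symbols)))
  symbols <- symbols[nzchar(symbols)]
  if (!length(symbols)) stop("gene list is empty")
  dup <- duplicated(symbols)
  if (any(dup))
    message(sum(dup), " duplicate symbol(s) collapsed in gene list '", name, "'")
  symbols <- symbols[!dup]
  if (!is.null(evidence)) {
    evidence <- data.table::as.data.table(evidence)
    stopifnot(all(c("symbol", "n_positive", "n_negative") %in% names(evidence)))
    evidence[, symbol := toupper(trimws(symbol))]
    evidence <- evidence[!duplicated(symbol)]
    if (any(evidence$n_positive < 0 | evidence$n_negative < 0))
      stop("evidence counts must be >= 0")
  }
  structure(list(name = name, symbols = symbols, evidence = evidence),
            class = "gene_list")
}

#' @export
print.gene_list <- function(x, ...) {
  cat(sprintf("gene_list '%s': %d symbols%s\n", x$name, length(x$symbols),
              if (is.null(x$evidence)) "" else " (with evidence counts)"))
  invisible(x)
}

#' Load a gene list from a text file
#'
#' One symbol per line; optional second and third tab-separated columns are
#' read as positive/negative study-evidence counts. Symbols are uppercased,
#' trimmed, optionally alias-mapped, then deduplicated.
#'
#' @param path text file path
#' @param alias_map optional named character vector mapping old symbol ->
#'   current symbol (applied after uppercasing)
#' @param name list label (defaults to the file name)
#' @return a `gene_list`
#' @export
load_gene_list <- function(path, alias_map = NULL, name = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (!length(lines)) stop("gene list file is empty: ", path)
  parts <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  syms <- toupper(trimws(parts[[1L]]))
  if (!is.null(alias_map)) {
    names(alias_map) <- toupper(names(alias_map))
    hit <- syms %in% names(alias_map)
    syms[hit] <- toupper(alias_map[syms[hit]])
  }
  evidence <- NULL
  if (length(parts) >= 3L) {
    evidence <- data.table::data.table(
      symbol = syms,
      n_positive = suppressWarnings(as.numeric(parts[[2L]])),
      n_negative = suppressWarnings(as.numeric(parts[[3L]])))
    evidence <- evidence[!is.na(n_positive) & !is.na(n_negative)]
    if (!nrow(evidence)) evidence <- NULL
  }
  gene_list(syms, name = name %||% basename(path), evidence = evidence)
}

#' Write a gene list to a text file
#' @param list a `gene_list`
#' @param path output file
#' @export
write_gene_list <- function(list, path) {
  stopifnot(inherits(list, "gene_list"))
  if (!is.null(list$evidence)) {
    ev <- list$evidence[match(list$symbols, symbol)]
    writeLines(sprintf("%s\t%s\t%s", list$symbols,
                       ifelse(is.na(ev$n_positive), "", ev$n_positive),
                       ifelse(is.na(ev$n_negative), "", ev$n_negative)), path)
  } else writeLines(list$symbols, path)
  invisible(path)
}

#' Symbols of a gene list absent from an annotation
#' @param list a `gene_list`
#' @param annotation a `genome_annotation`
#' @return character vector of missing symbols
#' @export
missing_symbols <- function(list, annotation) {
  stopifnot(inherits(list, "gene_list"),
            inherits(annotation, "genome_annotation"))
  setdiff(list$symbols, annotation$loci$gene_symbol)
}

# symbols of `list` present in annotation; error if none
found_symbols <- function(list, annotation) {
  syms <- if (inherits(list, "gene_list")) list$symbols else
    toupper(as.character(list))
  hit <- intersect(syms, annotation$loci$gene_symbol)
  if (!length(hit)) stop("no gene-list symbols found in annotation")
  hit
}

#' Read a genome FASTA
#'
#' Thin wrapper over `Biostrings::readDNAStringSet` that trims FASTA
#' descriptions to the sequence name, so chromosome lookup by annotation
#' `chrom` works.
#' @param path FASTA file
#' @return a named `DNAStringSet`
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write a genome FASTA
#' @param genome named `DNAStringSet`
#' @param path output file
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}
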