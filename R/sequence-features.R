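# GC-content windows at transcript boundaries and canonical splice motifs.
#
# All windows are centered on a boundary: window/2 nt on each side, extracted
# in transcript (sense-strand) orientation. Region classes follow the
# TSS / Donor / Accept / DonorMid / AcceptMid scheme: the first intron's two
# sides are scored separately from all later ("Mid") junctions.

REGION_CLASSES <- c("TSS", "Donor", "Accept", "DonorMid", "AcceptMid")

CANONICAL_DONOR_MOTIFS <- c("GGTAA", "GGTGA")
CANONICAL_ACCEPTOR_MOTIFS <- c("CAGGT", "TAGGT")

# Boundary positions (0-based, between-base coordinates) of a transcript in
# transcript orientation. Returns per-class genomic positions.
transcript_boundaries <- function(transcript) {
  ex <- transcript$exons
  n <- nrow(ex)
  minus <- transcript$strand == "-"
  # exon index in transcript orientation -> genomic exon index
  gidx <- if (minus) rev(seq_len(n)) else seq_len(n)
  donor_of <- function(i)    # 3' end of tx-exon i
    if (minus) ex$start[gidx[i]] else ex$end[gidx[i]]
  accept_of <- function(i)   # 5' start of tx-exon i
    if (minus) ex$end[gidx[i]] else ex$start[gidx[i]]
  tss <- if (minus) ex$end[n] else ex$start[1L]
  out <- list(TSS = tss, Donor = numeric(0), Accept = numeric(0),
              DonorMid = numeric(0), AcceptMid = numeric(0))
  if (n >= 2L) {
    out$Donor <- donor_of(1L)
    out$Accept <- accept_of(2L)
    if (n >= 3L) {
      out$DonorMid <- vapply(2:(n - 1L), donor_of, numeric(1))
      if (n >= 4L)
        out$AcceptMid <- vapply(3:(n - 1L), accept_of, numeric(1))
    }
  }
  out
}

# Extract the window/2-each-side sequence around a between-base boundary,
# sense-strand oriented. NULL when the window would leave the contig.
extract_window <- function(genome, chrom, pos, strand, window) {
  half <- window %/% 2L
  len <- Biostrings::width(genome[chrom])
  if (pos - half < 0 || pos + half > len) return(NULL)
  s <- Biostrings::subseq(genome[[chrom]], start = pos - half + 1L,
                          width = window)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Boundary windows of one transcript
#'
#' Returns, per region class, the sequences of the windows centered on that
#' transcript's boundaries: TSS (transcript start), Donor (3' boundary of the
#' first exon), Accept (5' boundary of the second exon), DonorMid (3'
#' boundaries of later exons except the last) and AcceptMid (5' boundaries of
#' later exons except the first and last) — all in transcript orientation,
#' i.e. reverse-complemented for minus-strand transcripts. Single-exon
#' transcripts yield only a TSS window. Windows closer than `window/2` to a
#' contig edge are dropped with a warning.
#'
#' @param transcript a `transcript_model` (see [get_transcript()])
#' @param genome named `DNAStringSet` (see [read_genome()])
#' @param window window size in nt (even; default 60)
#' @return named list mapping region class to a character vector of sequences
#' @export
boundary_windows <- function(transcript, genome, window = 60L) {
  stopifnot(inherits(transcript, "transcript_model"),
            window %% 2L == 0L, window > 0L)
  if (!transcript$chrom %in% names(genome))
    stop("chromosome not in genome: ", transcript$chrom)
  b <- transcript_boundaries(transcript)
  dropped <- 0L
  out <- lapply(b, function(pos) {
    seqs <- lapply(pos, function(p)
      extract_window(genome, transcript$chrom, p, transcript$strand, window))
    null <- vapply(seqs, is.null, logical(1))
    dropped <<- dropped + sum(null)
    unlist(seqs[!null]) %||% character(0)
  })
  if (dropped > 0L)
    warning(dropped, " window(s) of ", transcript$transcript_id,
            " dropped at contig edge")
  out
}

#' GC percentage of a sequence
#'
#' `100 * (#G + #C) / (length excluding N)`. N bases are excluded from both
#' numerator and denominator; an all-N window is undefined (`NA`).
#' @param seq character vector of DNA sequences over `A,C,G,T,N`
#' @return numeric vector of percentages
#' @export
gc_percent <- function(seq) {
  if (!length(seq)) return(numeric(0))
  if (any(!nzchar(seq))) stop("empty sequence")
  x <- Biostrings::DNAStringSet(toupper(seq))
  fr <- Biostrings::alphabetFrequency(x)
  gc <- fr[, "G"] + fr[, "C"]
  denom <- rowSums(fr[, c("A", "C", "G", "T"), drop = FALSE])
  ifelse(denom == 0, NA_real_, 100 * gc / denom)
}

# per-window GC observations for the transcripts of a set of loci
collect_windows <- function(annotation, genome, symbols, window) {
  ex <- annotation$exons[gene_symbol %in% symbols]
  res <- vector("list", data.table::uniqueN(ex$transcript_id))
  i <- 0L
  for (t in split(ex, by = "transcript_id")) {
    tm <- structure(list(transcript_id = t$transcript_id[1L],
                         gene_symbol = t$gene_symbol[1L],
                         chrom = t$chrom[1L], strand = t$strand[1L],
                         exons = t[order(start), .(start, end)]),
                    class = "transcript_model")
    w <- suppressWarnings(boundary_windows(tm, genome, window))
    n <- lengths(w)
    if (!sum(n)) next
    i <- i + 1L
    res[[i]] <- data.table::data.table(
      gene_symbol = tm$gene_symbol, transcript_id = tm$transcript_id,
      region = rep(names(w), n), seq = unlist(w, use.names = FALSE))
  }
  data.table::rbindlist(res[seq_len(i)])
}

#' GC profile of a gene list
#'
#' Pools the boundary windows of every transcript of every list locus and
#' reports the mean GC percentage and window count per region class.
#'
#' @param list `gene_list` or character vector of symbols
#' @param annotation a `genome_annotation`
#' @param genome named `DNAStringSet`
#' @param window window size, nt
#' @return object of class `gc_profile`: list with `mean_gc` and `n_windows`,
#'   both named by region class
#' @export
gc_profile <- function(list, annotation, genome, window = 60L) {
  syms <- found_symbols(list, annotation)
  obs <- collect_windows(annotation, genome, syms, window)
  mean_gc <- setNames(rep(NA_real_, length(REGION_CLASSES)), REGION_CLASSES)
  n_windows <- setNames(integer(length(REGION_CLASSES)), REGION_CLASSES)
  if (nrow(obs)) {
    obs[, gc := gc_percent(seq)]
    agg <- obs[!is.na(gc), .(mean_gc = mean(gc), n = .N), by = region]
    mean_gc[agg$region] <- agg$mean_gc
    n_windows[agg$region] <- agg$n
  }
  structure(list(mean_gc = mean_gc, n_windows = n_windows, window = window),
            class = "gc_profile")
}

#' @export
print.gc_profile <- function(x, ...) {
  cat("gc_profile (window", x$window, "nt):\n")
  for (r in REGION_CLASSES)
    cat(sprintf("  %-9s %6.2f%%  (n = %d)\n", r, x$mean_gc[[r]],
                x$n_windows[[r]]))
  invisible(x)
}

#' Donor-acceptor GC gap
#'
#' The signed difference in mean GC percentage between the windows flanking
#' the first intron: `Donor - Accept` (default). The alternative
#' `"tss_accept"` mode reports `TSS - Accept` instead.
#'
#' @param profile a `gc_profile`
#' @param mode `"donor_accept"` (default) or `"tss_accept"`
#' @return signed gap in GC percentage points
#' @export
donor_acceptor_gap <- function(profile, mode = c("donor_accept", "tss_accept")) {
  stopifnot(inherits(profile, "gc_profile"))
  mode <- match.arg(mode)
  a <- if (mode == "donor_accept") profile$mean_gc[["Donor"]]
       else profile$mean_gc[["TSS"]]
  b <- profile$mean_gc[["Accept"]]
  if (is.na(a) || is.na(b))
    stop("profile lacks windows for the requested boundary classes")
  a - b
}

# per-gene (donor GC sum, n, acceptor GC sum, n) for the decomposable
# bootstrap statistic "gc_gap"
per_gene_gc_sums <- function(annotation, genome, window = 60L) {
  obs <- collect_windows(annotation, genome, annotation$loci$gene_symbol,
                         window)
  if (nrow(obs)) obs[, gc := gc_percent(seq) / 100]
  per <- obs[region %in% c("Donor", "Accept") & !is.na(gc),
             .(don_sum = sum(gc[region == "Donor"]),
               don_n = sum(region == "Donor"),
               acc_sum = sum(gc[region == "Accept"]),
               acc_n = sum(region == "Accept")), by = gene_symbol]
  all <- data.table::data.table(gene_symbol = annotation$loci$gene_symbol)
  per <- merge(all, per, by = "gene_symbol", all.x = TRUE)
  for (cn in c("don_sum", "don_n", "acc_sum", "acc_n"))
    per[is.na(get(cn)), (cn) := 0]
  per
}

# windows around every splice junction (donors of tx-exons 1..n-1, acceptors
# of tx-exons 2..n) — unlike the GC region classes, the last exon's acceptor
# is included here; only the transcript's outer ends carry no junction
collect_junction_windows <- function(annotation, genome, symbols, window) {
  ex <- annotation$exons[gene_symbol %in% symbols]
  res <- list()
  for (t in split(ex, by = "transcript_id")) {
    n <- nrow(t)
    if (n < 2L) next
    et <- t[order(start), .(start, end)]
    minus <- t$strand[1L] == "-"
    donors <- if (minus) et$start[-1L] else et$end[-n]
    accepts <- if (minus) et$end[-n] else et$start[-1L]
    pull <- function(pos) vapply(pos, function(p) {
      extract_window(genome, t$chrom[1L], p, t$strand[1L], window) %||%
        NA_character_
    }, character(1))
    res[[length(res) + 1L]] <- data.table::data.table(
      side = rep(c("donor", "acceptor"), c(length(donors), length(accepts))),
      seq = c(pull(donors), pull(accepts)))
  }
  out <- data.table::rbindlist(res)
  if (nrow(out)) out <- out[!is.na(seq)]
  out
}

#' Canonical splice-site fractions of a gene list
#'
#' Scans the 60-nt window around every splice junction of every transcript of
#' the list loci for the strict canonical motifs: donors `GGTAA` / `GGTGA`,
#' acceptors `CAGGT` / `TAGGT`. The 5' region of the first exon and the 3'
#' region of the last exon carry no junction and are excluded. A junction is
#' canonical when its window contains either motif for its side.
#'
#' @inheritParams gc_profile
#' @return list with `donor_pct`, `acceptor_pct` (percent canonical) and the
#'   junction counts `n_donor`, `n_acceptor`
#' @export
canonical_site_fractions <- function(list, annotation, genome, window = 60L) {
  syms <- found_symbols(list, annotation)
  obs <- collect_junction_windows(annotation, genome, syms, window)
  don <- obs[side == "donor", seq]
  acc <- obs[side == "acceptor", seq]
  has_motif <- function(seqs, motifs) {
    if (!length(seqs)) return(logical(0))
    hit <- rep(FALSE, length(seqs))
    for (m in motifs) hit <- hit | grepl(m, seqs, fixed = TRUE)
    hit
  }
  list(donor_pct = 100 * mean(has_motif(don, CANONICAL_DONOR_MOTIFS)),
       acceptor_pct = 100 * mean(has_motif(acc, CANONICAL_ACCEPTOR_MOTIFS)),
       n_donor = length(don), n_acceptor = length(acc))
}
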