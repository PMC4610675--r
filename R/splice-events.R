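# Alternative-splicing event enumeration and classification.
#
# Each transcript is reduced to its chain of *internal* splice sites: an R
# site at every exon end except the last, an L site at every exon start
# except the first (genomic 0-based between-base coordinates). For a
# transcript pair, sites are restricted to the genomic interval where both
# transcripts overlap; each maximal run of sites present in one chain but not
# the other, delimited by sites common to both (or by the overlap boundary),
# is one variation. Classification is by the pattern of differing sites, with
# donor/acceptor roles assigned strand-aware (plus strand: R = donor,
# L = acceptor; minus strand: the reverse):
#
#   one chain empty, other = {L p1, R p2}, p1 < p2 (an exon)  -> skipped_exon
#   one differing donor on each side (common partner site)    -> alt_donor
#   one differing acceptor on each side                       -> alt_acceptor
#   anything else (intron retention, compound runs, termini)  -> other
#
# Events are deduplicated locus-wide by a canonical coordinate signature, so
# a variation shared by several transcript pairs counts once.

EVENT_TYPES <- c("skipped_exon", "alt_donor", "alt_acceptor", "other")

classify_variation <- function(sideA, posA, sideB, posB, strand) {
  donor_side <- if (strand == "+") "R" else "L"
  accept_side <- if (strand == "+") "L" else "R"
  nA <- length(posA); nB <- length(posB)
  if (xor(nA == 0L, nB == 0L)) {
    side <- if (nA) sideA else sideB
    pos <- if (nA) posA else posB
    if (length(pos) == 2L) {
      side <- side[order(pos)]
      if (side[1L] == "L" && side[2L] == "R") return("skipped_exon")
    }
    return("other")
  }
  if (nA == 1L && nB == 1L && sideA == sideB) {
    if (sideA == donor_side) return("alt_donor")
    if (sideA == accept_side) return("alt_acceptor")
  }
  "other"
}

# variations of one transcript pair; plain vectors for speed (this is the
# hot path of locus_event_counts); returns list(event_type, signature,
# terminal) of equal-length vectors, or NULL
pair_variations <- function(exA, exB, strand, include_terminal = TRUE) {
  nA <- nrow(exA); nB <- nrow(exB)
  ovl_lo <- max(exA$start[1L], exB$start[1L])
  ovl_hi <- min(exA$end[nA], exB$end[nB])
  if (ovl_lo >= ovl_hi) return(NULL)
  posA <- c(exA$end[-nA], exA$start[-1L])
  sideA <- rep(c("R", "L"), c(nA - 1L, nA - 1L))
  kp <- posA > ovl_lo & posA < ovl_hi
  posA <- posA[kp]; sideA <- sideA[kp]
  posB <- c(exB$end[-nB], exB$start[-1L])
  sideB <- rep(c("R", "L"), c(nB - 1L, nB - 1L))
  kp <- posB > ovl_lo & posB < ovl_hi
  posB <- posB[kp]; sideB <- sideB[kp]
  kA <- paste0(sideA, posA)
  kB <- paste0(sideB, posB)
  cA <- kA %in% kB
  cB <- kB %in% kA
  if (all(cA) && all(cB)) return(NULL)

  # unified site list in genomic order; every common site cuts a new segment
  pos <- c(posA[!cA], posB[!cB], posA[cA])
  side <- c(sideA[!cA], sideB[!cB], sideA[cA])
  who <- rep(c("A", "B", "C"), c(sum(!cA), sum(!cB), sum(cA)))
  o <- order(pos, side, who)
  pos <- pos[o]; side <- side[o]; who <- who[o]
  is_c <- who == "C"
  seg <- cumsum(is_c) + 1L
  bounds <- c(ovl_lo, pos[is_c], ovl_hi)
  n_seg <- length(bounds) - 1L

  diff_idx <- which(!is_c)
  segs <- unique(seg[diff_idx])
  types <- sigs <- character(length(segs))
  terms <- logical(length(segs))
  n_out <- 0L
  for (k in segs) {
    terminal <- k == 1L || k == n_seg
    if (terminal && !include_terminal) next
    idx <- diff_idx[seg[diff_idx] == k]
    a <- idx[who[idx] == "A"]
    b <- idx[who[idx] == "B"]
    type <- classify_variation(side[a], pos[a], side[b], pos[b], strand)
    ga <- paste(sprintf("%s%.0f", side[a], pos[a]), collapse = ",")
    gb <- paste(sprintf("%s%.0f", side[b], pos[b]), collapse = ",")
    if (gb < ga) { tmp <- ga; ga <- gb; gb <- tmp }
    n_out <- n_out + 1L
    types[n_out] <- type
    terms[n_out] <- terminal
    sigs[n_out] <- sprintf("%.0f..%.0f|%s|%s", bounds[k], bounds[k + 1L],
                           ga, gb)
  }
  if (!n_out) return(NULL)
  list(event_type = types[seq_len(n_out)], signature = sigs[seq_len(n_out)],
       terminal = terms[seq_len(n_out)])
}

#' Enumerate alternative-splicing events of a locus
#'
#' Compares every pair of the locus's transcripts, cuts their internal
#' splice-site chains into variations delimited by shared sites, classifies
#' each variation as `skipped_exon`, `alt_donor`, `alt_acceptor` or `other`,
#' and deduplicates locus-wide by coordinate signature. Variations abutting
#' the boundary of the pair's shared genomic span (rather than a common
#' splice site) are kept and classified by their site pattern when
#' `include_terminal = TRUE` (default), or dropped otherwise.
#'
#' @param locus a `locus` from [get_locus()]
#' @param include_terminal keep variations flanked by the overlap boundary
#' @return data.table with columns `gene_symbol`, `event_type`, `signature`,
#'   `tx1`, `tx2` (one witnessing transcript pair per event); zero rows for a
#'   single-transcript locus
#' @export
enumerate_events <- function(locus, include_terminal = TRUE) {
  stopifnot(inherits(locus, "locus"))
  txs <- locus$transcripts
  empty <- data.table::data.table(
    gene_symbol = character(0), event_type = character(0),
    signature = character(0), tx1 = character(0), tx2 = character(0))
  if (length(txs) < 2L) return(empty)
  events_core(lapply(txs, `[[`, "exons"), names(txs), locus$strand,
              locus$gene_symbol, include_terminal)
}

# pairwise enumeration + locus-wide dedup over a list of exon tables
events_core <- function(exl, ids, strand, gene, include_terminal = TRUE) {
  empty <- data.table::data.table(
    gene_symbol = character(0), event_type = character(0),
    signature = character(0), tx1 = character(0), tx2 = character(0))
  types <- sigs <- t1 <- t2 <- character(0)
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in seq.int(i + 1L, length(ids))) {
      v <- pair_variations(exl[[i]], exl[[j]], strand, include_terminal)
      if (is.null(v)) next
      new <- !v$signature %in% sigs
      if (!any(new)) next
      types <- c(types, v$event_type[new])
      sigs <- c(sigs, v$signature[new])
      t1 <- c(t1, rep(ids[i], sum(new)))
      t2 <- c(t2, rep(ids[j], sum(new)))
    }
  }
  if (!length(sigs)) return(empty)
  data.table::data.table(gene_symbol = gene, event_type = types,
                         signature = sigs, tx1 = t1, tx2 = t2)
}

#' Per-gene splice-event type counts
#'
#' Runs [enumerate_events()] on every multi-transcript locus and tabulates
#' deduplicated event counts per type, plus the total. Used by
#' [event_proportions()] and cached by the bootstrap engine.
#' @param annotation a `genome_annotation`
#' @param include_terminal see [enumerate_events()]
#' @return data.table: `gene_symbol`, one column per event type, `total`
#' @export
locus_event_counts <- function(annotation, include_terminal = TRUE) {
  stopifnot(inherits(annotation, "genome_annotation"))
  lt <- annotation$loci
  counts <- matrix(0L, nrow(lt), length(EVENT_TYPES),
                   dimnames = list(lt$gene_symbol, EVENT_TYPES))
  multi <- lt[n_transcripts >= 2L, gene_symbol]
  ex <- annotation$exons[gene_symbol %in% multi][order(start)]
  for (gdt in split(ex, by = "gene_symbol")) {
    exl <- lapply(split(gdt, by = "transcript_id", sorted = TRUE),
                  function(t) t[, .(start, end)])
    ev <- events_core(exl, names(exl), gdt$strand[1L], gdt$gene_symbol[1L],
                      include_terminal)
    if (nrow(ev)) {
      tb <- table(ev$event_type)
      counts[gdt$gene_symbol[1L], names(tb)] <- as.integer(tb)
    }
  }
  out <- data.table::data.table(gene_symbol = lt$gene_symbol)
  for (t in EVENT_TYPES) out[, (t) := counts[, t]]
  out[, total := skipped_exon + alt_donor + alt_acceptor + other]
  out
}

#' Splice-event type proportions of a gene list
#'
#' Pools the deduplicated events of every list locus and normalizes by the
#' total event count. Loci can be excluded by symbol (the reproducible
#' generalization of dropping a known outlier gene) or by an event-count cap.
#'
#' @param list `gene_list` or character vector
#' @param annotation a `genome_annotation`
#' @param exclude symbols to drop before pooling
#' @param outlier_event_cap drop loci with more than this many events
#' @param include_terminal see [enumerate_events()]
#' @param event_counts optional precomputed [locus_event_counts()] table
#' @return object of class `event_proportions`: `fractions` (named over the
#'   four types, summing to 1) and `total_events`
#' @export
event_proportions <- function(list, annotation, exclude = character(0),
                              outlier_event_cap = NULL,
                              include_terminal = TRUE, event_counts = NULL) {
  syms <- found_symbols(list, annotation)
  counts <- event_counts %||% locus_event_counts(annotation, include_terminal)
  counts <- counts[gene_symbol %in% setdiff(syms, toupper(exclude))]
  if (!is.null(outlier_event_cap))
    counts <- counts[total <= outlier_event_cap]
  tot <- sum(counts$total)
  if (tot == 0)
    stop("no splice events among the list loci; proportions undefined")
  fr <- vapply(EVENT_TYPES, function(t) sum(counts[[t]]) / tot, numeric(1))
  structure(list(fractions = fr, total_events = tot),
            class = "event_proportions")
}

#' @export
print.event_proportions <- function(x, ...) {
  cat("event_proportions over", x$total_events, "events:\n")
  for (t in EVENT_TYPES)
    cat(sprintf("  %-13s %5.1f%%\n", t, 100 * x$fractions[[t]]))
  invisible(x)
}

#' Bootstrap enrichment of one splice-event type's proportion
#'
#' Observed statistic: the named event type's fraction of all pooled events
#' in the list; null: the same fraction over length-matched control lists.
#' Event counts are computed once for the whole pool and reused across
#' control lists.
#'
#' @inheritParams bootstrap_enrichment
#' @param event_type one of `skipped_exon`, `alt_donor`, `alt_acceptor`,
#'   `other`
#' @param exclude,outlier_event_cap,include_terminal see
#'   [event_proportions()]
#' @param events optional precomputed [locus_event_counts()] table
#' @return a `bootstrap_result`
#' @export
proportion_enrichment <- function(list, pool = NULL, annotation, event_type,
                                  n_lists = 1000, direction = "greater",
                                  exclude = character(0),
                                  outlier_event_cap = NULL,
                                  include_terminal = TRUE, events = NULL,
                                  tolerance = 0.10, seed = NULL) {
  stopifnot(event_type %in% EVENT_TYPES)
  events <- events %||% locus_event_counts(annotation, include_terminal)
  bootstrap_enrichment(
    list, pool, annotation, statistic = "event_fraction", n_lists = n_lists,
    direction = direction, tolerance = tolerance, events = events,
    stat_args = list(event_type = event_type, exclude = exclude,
                     outlier_event_cap = outlier_event_cap,
                     include_terminal = include_terminal),
    seed = seed)
}
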