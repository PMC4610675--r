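# Independent brute-force splice-event oracle used to check the classifier.
# Plain vectors and loops, written directly from the event definitions:
# internal splice sites of each transcript, restricted to the pair's shared
# span; consecutive shared sites delimit variations; a variation is
# classified by its differing sites alone. Events are reported as
# "type @ sorted-diff-site-groups" strings for set comparison.

oracle_pair <- function(exA, exB, strand) {
  sites <- function(ex) {
    n <- nrow(ex)
    if (n < 2L) return(character(0))
    c(paste0("R", format(ex$end[-n], scientific = FALSE, trim = TRUE)),
      paste0("L", format(ex$start[-1L], scientific = FALSE, trim = TRUE)))
  }
  pos_of <- function(k) as.numeric(substring(k, 2L))
  side_of <- function(k) substring(k, 1L, 1L)
  lo <- max(exA$start[1L], exB$start[1L])
  hi <- min(exA$end[nrow(exA)], exB$end[nrow(exB)])
  if (lo >= hi) return(character(0))
  sA <- sites(exA); sA <- sA[pos_of(sA) > lo & pos_of(sA) < hi]
  sB <- sites(exB); sB <- sB[pos_of(sB) > lo & pos_of(sB) < hi]
  shared <- intersect(sA, sB)
  cuts <- sort(c(lo, pos_of(shared), hi))
  out <- character(0)
  for (s in seq_len(length(cuts) - 1L)) {
    inseg <- function(v) v[pos_of(v) > cuts[s] & pos_of(v) < cuts[s + 1L]]
    dA <- sort(inseg(setdiff(sA, shared)))
    dB <- sort(inseg(setdiff(sB, shared)))
    if (!length(dA) && !length(dB)) next
    type <- oracle_classify(dA, dB, strand, pos_of, side_of)
    grp <- function(d) paste(d[order(pos_of(d))], collapse = ",")
    key <- paste(sort(c(grp(dA), grp(dB))), collapse = "|")
    out <- c(out, paste0(type, " @ ", key))
  }
  out
}

oracle_classify <- function(dA, dB, strand, pos_of, side_of) {
  donor <- if (strand == "+") "R" else "L"
  accept <- if (strand == "+") "L" else "R"
  if (xor(length(dA) == 0L, length(dB) == 0L)) {
    d <- if (length(dA)) dA else dB
    if (length(d) == 2L) {
      d <- d[order(pos_of(d))]
      # an exon: starts (L) then ends (R)
      if (side_of(d[1L]) == "L" && side_of(d[2L]) == "R")
        return("skipped_exon")
    }
    return("other")
  }
  if (length(dA) == 1L && length(dB) == 1L &&
      side_of(dA) == side_of(dB)) {
    if (side_of(dA) == donor) return("alt_donor")
    if (side_of(dA) == accept) return("alt_acceptor")
  }
  "other"
}

oracle_locus_events <- function(locus) {
  txs <- locus$transcripts
  if (length(txs) < 2L) return(character(0))
  out <- character(0)
  for (i in seq_along(txs)) for (j in seq_along(txs)) {
    if (i >= j) next
    out <- c(out, oracle_pair(as.data.frame(txs[[i]]$exons),
                              as.data.frame(txs[[j]]$exons), locus$strand))
  }
  sort(unique(out))
}

# package events rendered in the oracle's "type @ groups" key format
package_event_keys <- function(ev) {
  if (!nrow(ev)) return(character(0))
  groups <- sub("^[^|]*\\|", "", ev$signature)
  sort(unique(paste0(ev$event_type, " @ ", groups)))
}
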