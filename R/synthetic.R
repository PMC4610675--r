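# Synthetic annotation / genome / expression generator with truth
# bookkeeping. The generator states the world the analysis assumes: a
# majority-single-transcript, heavy-tailed transcripts-per-locus
# distribution; log-normal locus lengths with a rare >1 Mb outlier fraction;
# alternative transcripts built by applying skip / alt-donor / alt-acceptor /
# intron-retention operators to a base transcript; boundary windows with
# region-specific planted GC and canonical motifs planted with a set
# probability; Dirichlet tissue expression with a configurable lung-dominance
# excess for a flagged gene list.

#' The 16 emulated body-map tissue names
#' @export
BODYMAP_TISSUES <- c(
  "adipose", "adrenal", "brain", "breast", "colon", "heart", "kidney",
  "liver", "lung", "lymph_node", "ovary", "prostate", "skeletal_muscle",
  "testes", "thyroid", "white_blood_cells")

#' Parameters of the synthetic data generator
#'
#' Defaults state the reference-set world the analyses assume: 55.7% of loci
#' single-transcript with a 6+ tail of 5% (so ~95% of loci have fewer than
#' five transcripts), log-normal locus lengths with median 20 kb, 1% of loci
#' over one megabase, and a 0.5/0.2/0.2/0.1 splice-operator mix.
#'
#' @param n_loci number of loci
#' @param transcript_count_distribution named probabilities over bins
#'   `"1".."5","6+"` (must sum to 1)
#' @param geom_tail_q geometric parameter expanding the `"6+"` bin
#'   (count = 6 + geometric draw)
#' @param locus_length_meanlog,locus_length_sdlog log-normal locus length
#'   parameters (log-bp)
#' @param outlier_fraction_over_1mb fraction of loci drawn uniformly in
#'   (1.2, 3) Mb
#' @param exon_count_range integer range of exon counts for base transcripts
#' @param event_mix named probabilities over
#'   `skipped_exon, alt_donor, alt_acceptor, other` operators
#' @param p_canonical_motif probability a junction gets its canonical motif
#' @param region_gc named target GC percents per region class
#' @param background_gc background GC percent outside planted windows
#' @param tissues tissue names for expression generation
#' @param dirichlet_concentration Dirichlet concentration of tissue vectors
#' @param lung_dominance_excess multiplier on the probability that a flagged
#'   gene's dominant tissue is lung (1 = no excess)
#' @param topology `"star"` (operators applied to the base transcript) or
#'   `"chain"` (applied to the previously derived transcript, exercising
#'   compound `other` events)
#' @return a `synthetic_params` list
#' @export
synthetic_params <- function(
    n_loci = 500,
    transcript_count_distribution = c(`1` = 0.557, `2` = 0.2, `3` = 0.1,
                                      `4` = 0.05, `5` = 0.043, `6+` = 0.05),
    geom_tail_q = 0.5,
    locus_length_meanlog = log(20000), locus_length_sdlog = 1.0,
    outlier_fraction_over_1mb = 0.01,
    exon_count_range = c(4L, 8L),
    event_mix = c(skipped_exon = 0.5, alt_donor = 0.2, alt_acceptor = 0.2,
                  other = 0.1),
    p_canonical_motif = 0.8,
    region_gc = c(TSS = 62, Donor = 58, Accept = 41, DonorMid = 48,
                  AcceptMid = 44),
    background_gc = 45,
    tissues = BODYMAP_TISSUES,
    dirichlet_concentration = 0.5,
    lung_dominance_excess = 1.0,
    topology = c("star", "chain")) {
  p <- list(n_loci = as.integer(n_loci),
            transcript_count_distribution = transcript_count_distribution,
            geom_tail_q = geom_tail_q,
            locus_length_meanlog = locus_length_meanlog,
            locus_length_sdlog = locus_length_sdlog,
            outlier_fraction_over_1mb = outlier_fraction_over_1mb,
            exon_count_range = as.integer(exon_count_range),
            event_mix = event_mix,
            p_canonical_motif = p_canonical_motif,
            region_gc = region_gc, background_gc = background_gc,
            tissues = tissues,
            dirichlet_concentration = dirichlet_concentration,
            lung_dominance_excess = lung_dominance_excess,
            topology = match.arg(topology))
  stopifnot(p$n_loci >= 1L,
            abs(sum(p$transcript_count_distribution) - 1) < 1e-9,
            abs(sum(p$event_mix) - 1) < 1e-9,
            all(p$event_mix >= 0), p$locus_length_sdlog > 0,
            p$p_canonical_motif >= 0, p$p_canonical_motif <= 1,
            all(names(p$event_mix) == EVENT_TYPES),
            all(REGION_CLASSES %in% names(p$region_gc)))
  structure(p, class = "synthetic_params")
}

MIN_EXON <- 90L
MIN_INTRON <- 250L
LOCUS_MARGIN <- 150L

# chain position of elements: exon j -> 2j-1, intron i -> 2i. Operators whose
# chain positions are closer than 3 can merge their variations into one
# compound run in cross-pairs of alternative transcripts, which would break
# exact truth bookkeeping; targets are picked non-adjacent when possible and
# the locus is flagged exact = FALSE otherwise.
op_chain_pos <- function(op, target) if (op == "skipped_exon")
  2L * target - 1L else 2L * target

serial_sites <- function(side, pos) {
  o <- order(pos)
  paste(sprintf("%s%.0f", side[o], pos[o]), collapse = ",")
}

# apply one operator to an exon table; returns NULL if infeasible, else
# list(exons, target, groups = sorted pair of diff-site serializations)
apply_operator <- function(op, ex, strand) {
  n <- nrow(ex)
  if (op == "skipped_exon") {
    if (n < 3L) return(NULL)
    j <- sample(2:(n - 1L), 1L)
    grp <- sort(c("", serial_sites(c("L", "R"), c(ex$start[j], ex$end[j]))))
    list(exons = ex[-j], target = j, groups = grp)
  } else if (op == "other") {           # intron retention
    if (n < 2L) return(NULL)
    i <- sample(n - 1L, 1L)
    grp <- sort(c("", serial_sites(c("R", "L"), c(ex$end[i], ex$start[i + 1L]))))
    out <- ex[-(i + 1L)]
    out$end[i] <- ex$end[i + 1L]
    list(exons = out, target = i, groups = grp)
  } else {
    if (n < 2L) return(NULL)
    i <- sample(n - 1L, 1L)
    gap <- ex$start[i + 1L] - ex$end[i]
    dmax <- min(60L, gap - (MIN_INTRON - 50L))
    if (dmax < 6L) return(NULL)
    delta <- sample(6:dmax, 1L)
    out <- data.table::copy(ex)
    # donor = tx-5' side of the intron; acceptor = tx-3' side
    mod_right <- (op == "alt_donor") == (strand == "+")
    if (mod_right) {                    # shift exon i's end into the intron
      old <- ex$end[i]; out$end[i] <- old + delta
      grp <- sort(c(sprintf("R%.0f", old), sprintf("R%.0f", old + delta)))
    } else {                            # shift exon i+1's start leftward
      old <- ex$start[i + 1L]; out$start[i + 1L] <- old - delta
      grp <- sort(c(sprintf("L%.0f", old), sprintf("L%.0f", old - delta)))
    }
    list(exons = out, target = i, groups = grp)
  }
}

draw_tx_count <- function(dist, q) {
  bin <- sample(names(dist), 1L, prob = dist)
  if (bin == "6+") 6L + rgeom(1L, q) else as.integer(bin)
}

build_base_exons <- function(L, k) {
  repeat {
    el <- pmin(pmax(round(rlnorm(k, log(150), 0.6)), MIN_EXON), 500L)
    if (k == 1L) {
      el[1L] <- L
      return(data.table::data.table(start = LOCUS_MARGIN,
                                    end = LOCUS_MARGIN + L))
    }
    spare <- L - sum(el) - MIN_INTRON * (k - 1L)
    if (spare >= 0) break
    if (k > 2L) k <- k - 1L else { el <- pmax(el - 50L, MIN_EXON); break }
  }
  k <- length(el)
  spare <- max(0L, L - sum(el) - MIN_INTRON * (k - 1L))
  w <- rexp(k - 1L)
  il <- MIN_INTRON + floor(spare * w / sum(w))
  il[1L] <- il[1L] + (L - sum(el) - sum(il))   # make the span exactly L
  starts <- LOCUS_MARGIN + cumsum(c(0L, head(el, -1L) + il))
  data.table::data.table(start = starts, end = starts + el)
}

#' Generate a synthetic annotation (and optionally genome) with truth records
#'
#' Each locus sits on its own contig. A base transcript is laid out from the
#' locus length and exon-count parameters; alternative transcripts are
#' derived by splice operators drawn from `event_mix` (an operator with no
#' feasible target is resampled; if nothing is feasible the alternative
#' transcript duplicates the base structure under a new id). With
#' `emit_sequence = TRUE`, contig sequences are drawn per-base at the
#' background GC and every non-overlapping boundary window is resampled to
#' its region's target GC (within +/-1 point), with canonical motifs planted
#' at junctions with probability `p_canonical_motif` (and scrubbed
#' otherwise).
#'
#' @param params a [synthetic_params()] object
#' @param seed RNG seed (generation is fully deterministic given the seed)
#' @param emit_sequence generate contig sequences (skip for large
#'   complexity-only corpora)
#' @return list with `annotation` (a `genome_annotation`), `genome` (named
#'   `DNAStringSet`, or `NULL`), and `truth` (per-locus planted values:
#'   transcript counts, events with their differing-site signatures and an
#'   `exact` flag, per-window GC targets and canonical flags)
#' @export
generate_annotation <- function(params, seed = NULL, emit_sequence = TRUE) {
  stopifnot(inherits(params, "synthetic_params"))
  with_seed(seed, {
    n <- params$n_loci
    exon_rows <- vector("list", n)
    seq_list <- if (emit_sequence) vector("list", n) else NULL
    truth_loci <- vector("list", n)
    for (g in seq_len(n)) {
      sym <- sprintf("SYNG%05d", g)
      chrom <- sprintf("chrS%05d", g)
      n_tx <- draw_tx_count(params$transcript_count_distribution,
                            params$geom_tail_q)
      L <- if (runif(1) < params$outlier_fraction_over_1mb)
        round(runif(1, 1.2e6, 3e6))
      else round(pmin(pmax(rlnorm(1, params$locus_length_meanlog,
                                  params$locus_length_sdlog), 3000), 1e6))
      k <- sample(seq.int(params$exon_count_range[1L],
                          params$exon_count_range[2L]), 1L)
      if (n_tx >= 2L) k <- max(k, 4L)
      strand <- sample(c("+", "-"), 1L)
      base <- build_base_exons(L, k)
      tx_exons <- list(base)
      events <- list()
      exact <- TRUE
      used_pos <- integer(0)
      parent <- base
      for (t in seq_len(n_tx - 1L)) {
        applied <- NULL
        for (op_try in 1:5) {          # resample op only if no target exists
          op <- sample(EVENT_TYPES, 1L, prob = params$event_mix)
          for (tgt_try in 1:15) {
            cand <- apply_operator(op, parent, strand)
            if (is.null(cand)) break   # structurally infeasible operator
            pos <- op_chain_pos(op, cand$target)
            clash <- length(used_pos) && any(abs(used_pos - pos) < 3L)
            if (!clash || tgt_try == 15L) {  # accept, flagging inexact truth
              if (clash) exact <- FALSE
              applied <- cand
              used_pos <- c(used_pos, pos)
              break
            }
          }
          if (!is.null(applied)) break
        }
        if (is.null(applied)) {          # nothing feasible: structural copy
          tx_exons[[t + 1L]] <- parent
          next
        }
        tx_exons[[t + 1L]] <- applied$exons
        events[[length(events) + 1L]] <-
          list(type = op, groups = applied$groups)
        if (params$topology == "chain") parent <- applied$exons
      }
      rows <- data.table::rbindlist(lapply(seq_along(tx_exons), function(t)
        data.table::data.table(
          gene_symbol = sym,
          transcript_id = sprintf("%s.T%d", sym, t),
          chrom = chrom, strand = strand,
          start = tx_exons[[t]]$start, end = tx_exons[[t]]$end)))
      exon_rows[[g]] <- rows
      truth_loci[[g]] <- list(gene_symbol = sym, n_transcripts = n_tx,
                              events = events, exact = exact,
                              locus_length = L)
    }
    # sequences drawn in a second pass, so the annotation's structure draws
    # are identical whether or not sequences are emitted
    if (emit_sequence)
      for (g in seq_len(n)) seq_list[[g]] <- synth_contig(exon_rows[[g]],
                                                          params)
    ann <- genome_annotation(data.table::rbindlist(exon_rows),
                             source_tag = "synthetic")
    genome <- NULL
    truth_windows <- NULL
    if (emit_sequence) {
      genome <- Biostrings::DNAStringSet(
        setNames(vapply(seq_list, `[[`, character(1), "seq"),
                 vapply(seq_list, `[[`, character(1), "chrom")))
      truth_windows <- data.table::rbindlist(
        lapply(seq_list, `[[`, "windows"))
    }
    list(annotation = ann, genome = genome,
         truth = list(loci = truth_loci, windows = truth_windows,
                      params = params))
  })
}

# build one contig's sequence with planted windows; rows = exon table of the
# locus (possibly several transcripts)
synth_contig <- function(rows, params) {
  chrom <- rows$chrom[1L]
  strand <- rows$strand[1L]
  len <- max(rows$end) + LOCUS_MARGIN
  bg <- params$background_gc / 100
  base_probs <- c(A = (1 - bg) / 2, C = bg / 2, G = bg / 2, T = (1 - bg) / 2)
  s <- sample(names(base_probs), len, replace = TRUE, prob = base_probs)

  # all boundary windows of all transcripts, genomic order
  wins <- list()
  for (t in split(rows, by = "transcript_id")) {
    tm <- structure(list(transcript_id = t$transcript_id[1L],
                         gene_symbol = t$gene_symbol[1L], chrom = chrom,
                         strand = strand,
                         exons = t[order(start), .(start, end)]),
                    class = "transcript_model")
    b <- transcript_boundaries(tm)
    # the GC region classes exclude the last exon's acceptor, but it is still
    # a junction scanned for canonical motifs: plant it too (AcceptMid GC)
    n_ex <- nrow(tm$exons)
    if (n_ex >= 2L)
      b$AcceptLast <- if (strand == "-") tm$exons$end[1L]
                      else tm$exons$start[n_ex]
    for (cls in names(b)) for (p in b[[cls]])
      wins[[length(wins) + 1L]] <- list(cls = cls, pos = p)
  }
  if (!length(wins))
    return(list(chrom = chrom, seq = paste(s, collapse = ""), windows = NULL))
  wdt <- data.table::data.table(
    cls = vapply(wins, `[[`, character(1), "cls"),
    pos = vapply(wins, function(w) as.numeric(w$pos), numeric(1)))
  wdt <- unique(wdt)[order(pos)]

  planted <- vector("list", nrow(wdt))
  last_end <- -1
  np <- 0L
  for (i in seq_len(nrow(wdt))) {
    b <- wdt$pos[i]
    lo <- b - 30; hi <- b + 30                  # [lo, hi) genomic, 0-based
    if (lo < 0 || hi > len || lo < last_end) next
    side <- switch(wdt$cls[i], Donor = , DonorMid = "donor",
                   Accept = , AcceptMid = , AcceptLast = "acceptor",
                   NA_character_)
    canonical <- !is.na(side) && runif(1) < params$p_canonical_motif
    gc_target <- params$region_gc[[
      if (wdt$cls[i] == "AcceptLast") "AcceptMid" else wdt$cls[i]]]
    s[(lo + 1):hi] <- fill_window(60L, gc_target, side, canonical, strand)
    last_end <- hi
    np <- np + 1L
    planted[[np]] <- data.table::data.table(
      chrom = chrom, region = wdt$cls[i], pos = b, side = side,
      gc_target = gc_target, canonical = canonical)
  }
  list(chrom = chrom, seq = paste(s, collapse = ""),
       windows = data.table::rbindlist(planted[seq_len(np)]))
}

# one 60-nt window (genomic orientation) centered on its boundary (position
# 31 is the first base after the boundary), hitting the GC target exactly
# (+/- rounding), with the side's canonical motif planted or scrubbed
fill_window <- function(w, gc_target, side, canonical, strand) {
  half <- w %/% 2L
  fixed <- rep(NA_character_, w)
  if (!is.na(side) && canonical) {
    motif <- if (side == "donor") sample(CANONICAL_DONOR_MOTIFS, 1L)
             else sample(CANONICAL_ACCEPTOR_MOTIFS, 1L)
    off <- if (side == "donor") -2L else -3L    # plus-strand offsets
    bases <- strsplit(motif, "")[[1L]]
    if (strand == "-") {                        # mirror and complement
      bases <- rev(c(A = "T", C = "G", G = "C", T = "A")[bases])
      off <- -off - 5L
    }
    fixed[(half + off + 1L):(half + off + 5L)] <- bases
  }
  target_gc <- round(w * gc_target / 100)
  free <- which(is.na(fixed))
  need <- min(max(target_gc - sum(fixed %in% c("G", "C"), na.rm = TRUE), 0L),
              length(free))
  motifs <- c(CANONICAL_DONOR_MOTIFS, CANONICAL_ACCEPTOR_MOTIFS)
  for (try in 1:25) {
    out <- fixed
    gc_pos <- if (need) sample(free, need) else integer(0)
    out[gc_pos] <- sample(c("G", "C"), need, replace = TRUE)
    rest <- setdiff(free, gc_pos)
    out[rest] <- sample(c("A", "T"), length(rest), replace = TRUE)
    if (is.na(side) || canonical) return(out)
    sense <- paste(out, collapse = "")
    if (strand == "-")
      sense <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(sense)))
    if (!any(vapply(motifs, grepl, logical(1), x = sense, fixed = TRUE)))
      return(out)
  }
  out   # motif-scrub retry exhausted (vanishingly rare); accept as-is
}

#' Generate a complexity-shifted disease gene list
#'
#' Samples `size` genes without replacement with selection weights
#' `exp(theta * n_transcripts)`, with `theta` solved so the weighted mean
#' transcript count equals the pool mean plus `complexity_shift`. Locus
#' lengths are untouched. `shift = 0` is an unweighted draw (the calibration
#' input).
#'
#' @param annotation a `genome_annotation` (the pool)
#' @param size list size
#' @param complexity_shift target excess in mean transcripts per locus
#' @param seed RNG seed
#' @return a `gene_list`
#' @export
generate_disease_list <- function(annotation, size, complexity_shift = 0,
                                  seed = NULL) {
  stopifnot(inherits(annotation, "genome_annotation"))
  lt <- annotation$loci
  if (size > nrow(lt)) stop("size exceeds the number of loci")
  if (size == nrow(lt)) {
    if (complexity_shift != 0)
      stop("whole-pool list cannot be complexity-shifted")
    return(gene_list(lt$gene_symbol, name = "synthetic_disease"))
  }
  counts <- lt$n_transcripts
  target <- mean(counts) + complexity_shift
  if (target >= max(counts) || target <= min(counts))
    stop("complexity_shift infeasible for this pool")
  # weights exp(theta * count); sampling without replacement attenuates the
  # tilt, so theta is solved against the expected mean of a weighted draw of
  # `size` via the exponential-race (Hajek) approximation: inclusion
  # probability pi_i = 1 - exp(-lambda * w_i) with sum(pi) = size
  w <- if (complexity_shift == 0) rep(1, length(counts)) else {
    race_mean <- function(th) {
      wts <- exp(th * counts - max(th * counts))
      lam <- uniroot(function(l) sum(1 - exp(-l * wts)) - size,
                     c(1e-12, 1e60), tol = 1e-10)$root
      pi <- 1 - exp(-lam * wts)
      sum(pi * counts) / size
    }
    th <- tryCatch(
      uniroot(function(th) race_mean(th) - target, c(-8, 8))$root,
      error = function(e)
        stop("complexity_shift infeasible for this pool and size"))
    exp(th * counts - max(th * counts))
  }
  syms <- with_seed(seed, sample(lt$gene_symbol, size, prob = w))
  gene_list(syms, name = sprintf("synthetic_disease_shift%.2g",
                                 complexity_shift))
}

#' Generate a synthetic transcript-by-tissue expression table
#'
#' Each gene gets a planted dominant tissue (uniform over tissues; for
#' flagged genes the lung probability is multiplied by
#' `lung_dominance_excess`, the rest shared uniformly). One transcript per
#' gene is made the highest-expressed; its tissue vector is a 0.55 one-hot
#' tilt on the dominant tissue plus 0.45 Dirichlet noise, so the planted
#' tissue is always the argmax. Truth (per-gene dominant tissue) is attached
#' as `attr(, "truth")`.
#'
#' @param annotation a `genome_annotation`
#' @param params a [synthetic_params()] (tissues, concentration, excess)
#' @param flagged_list optional `gene_list` receiving the lung excess
#' @param seed RNG seed
#' @return an `expression_matrix`
#' @export
generate_expression <- function(annotation, params = synthetic_params(),
                                flagged_list = NULL, seed = NULL) {
  stopifnot(inherits(annotation, "genome_annotation"))
  tiss <- params$tissues
  Tn <- length(tiss)
  if (!"lung" %in% tiss) stop("tissue set must include 'lung'")
  with_seed(seed, {
    lt <- annotation$loci
    flagged <- lt$gene_symbol %in% (flagged_list$symbols %||% character(0))
    p_lung <- min(1, params$lung_dominance_excess / Tn)
    dom <- character(nrow(lt))
    u <- runif(nrow(lt))
    others <- setdiff(tiss, "lung")
    dom[flagged] <- ifelse(u[flagged] < p_lung, "lung",
                           sample(others, sum(flagged), replace = TRUE))
    dom[!flagged] <- sample(tiss, sum(!flagged), replace = TRUE)

    tx <- annotation$transcripts[order(gene_symbol, transcript_id)]
    gi <- match(tx$gene_symbol, lt$gene_symbol)
    is_top <- !duplicated(tx$gene_symbol)
    top_total <- rlnorm(nrow(lt), log(100), 0.5)
    totals <- ifelse(is_top, top_total[gi],
                     top_total[gi] * runif(nrow(tx), 0.05, 0.7))
    row_dom <- ifelse(is_top, dom[gi],
                      sample(tiss, nrow(tx), replace = TRUE))
    G <- matrix(rgamma(nrow(tx) * Tn, shape = params$dirichlet_concentration),
                nrow(tx), Tn)
    frac <- 0.45 * G / rowSums(G)
    frac[cbind(seq_len(nrow(tx)), match(row_dom, tiss))] <-
      frac[cbind(seq_len(nrow(tx)), match(row_dom, tiss))] + 0.55
    vals <- data.table::as.data.table(round(frac * totals, 4))
    data.table::setnames(vals, tiss)
    out <- expression_matrix(cbind(
      data.table::data.table(transcript_id = tx$transcript_id,
                             gene_symbol = tx$gene_symbol), vals))
    attr(out, "truth") <- data.table::data.table(
      gene_symbol = lt$gene_symbol, dominant_tissue = dom,
      flagged = flagged)
    out
  })
}

#' Generate a synthetic disease-database membership list
#'
#' Bernoulli membership at `base_rate`, with the odds multiplied by
#' `complexity_odds` for loci with more than five transcripts.
#' @param annotation a `genome_annotation`
#' @param base_rate membership probability for 1-5-transcript loci
#' @param complexity_odds odds multiplier for >5-transcript loci
#' @param seed RNG seed
#' @return a `gene_list` of member symbols
#' @export
generate_disease_db <- function(annotation, base_rate = 0.1,
                                complexity_odds = 1, seed = NULL) {
  stopifnot(base_rate >= 0, base_rate <= 1, complexity_odds >= 0)
  lt <- annotation$loci
  odds <- base_rate / (1 - base_rate)
  p_high <- (odds * complexity_odds) / (1 + odds * complexity_odds)
  p <- ifelse(lt$n_transcripts > 5, p_high, base_rate)
  member <- with_seed(seed, runif(nrow(lt)) < p)
  if (!any(member))
    return(structure(list(name = "synthetic_disease_db",
                          symbols = character(0), evidence = NULL),
                     class = "gene_list"))
  gene_list(lt$gene_symbol[member], name = "synthetic_disease_db")
}

#' Write a synthetic bundle to a directory
#'
#' Emits `annotation.gtf`, `genome.fa` (when present), `expression.tsv`
#' (when given), `pool.txt` (all symbols), optional extra gene lists, and
#' `truth.json`.
#' @param bundle result of [generate_annotation()]
#' @param dir output directory (created)
#' @param expression optional `expression_matrix`
#' @param lists optional named list of `gene_list` objects
#' @return `dir`, invisibly
#' @export
write_synthetic_bundle <- function(bundle, dir, expression = NULL,
                                   lists = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gtf(bundle$annotation, file.path(dir, "annotation.gtf"))
  if (!is.null(bundle$genome))
    write_genome(bundle$genome, file.path(dir, "genome.fa"))
  if (!is.null(expression))
    write_expression(expression, file.path(dir, "expression.tsv"))
  writeLines(bundle$annotation$loci$gene_symbol, file.path(dir, "pool.txt"))
  for (nm in names(lists))
    write_gene_list(lists[[nm]], file.path(dir, paste0(nm, ".txt")))
  truth <- bundle$truth
  truth$params <- unclass(truth$params)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
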