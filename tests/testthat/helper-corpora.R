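# Shared synthetic corpora, built once per test run and memoised.

memo <- local({
  cache <- new.env(parent = emptyenv())
  function(key, expr) {
    if (is.null(cache[[key]])) cache[[key]] <- force(expr)
    cache[[key]]
  }
})

# medium complexity pool, no sequences (bootstrap / sampler tests)
pool_medium <- function() memo("pool_medium", {
  generate_annotation(synthetic_params(n_loci = 800), seed = 101,
                      emit_sequence = FALSE)
})

# large reference pool for calibration / power acceptance runs
pool_big <- function() memo("pool_big", {
  generate_annotation(synthetic_params(n_loci = 2000), seed = 808,
                      emit_sequence = FALSE)
})

# small corpus with sequences (GC / motif / expression tests)
seq_small <- function() memo("seq_small", {
  p <- synthetic_params(n_loci = 50, locus_length_meanlog = log(7000),
                        locus_length_sdlog = 0.35,
                        outlier_fraction_over_1mb = 0,
                        exon_count_range = c(4L, 6L))
  generate_annotation(p, seed = 202)
})

# single-transcript multi-exon corpus with sequences (planting recovery)
seq_single_tx <- function(n = 60, seed = 303, p_canonical = 0.8) {
  p <- synthetic_params(
    n_loci = n,
    transcript_count_distribution = c(`1` = 1, `2` = 0, `3` = 0, `4` = 0,
                                      `5` = 0, `6+` = 0),
    locus_length_meanlog = log(6000), locus_length_sdlog = 0.3,
    outlier_fraction_over_1mb = 0, exon_count_range = c(5L, 6L),
    p_canonical_motif = p_canonical)
  generate_annotation(p, seed = seed)
}

# event corpus: <= 3 transcripts, <= 6 exons (classifier-oracle comparisons)
event_corpus <- function(n = 150, seed = 404) {
  p <- synthetic_params(
    n_loci = n,
    transcript_count_distribution = c(`1` = 0.2, `2` = 0.4, `3` = 0.4,
                                      `4` = 0, `5` = 0, `6+` = 0),
    locus_length_meanlog = log(9000), locus_length_sdlog = 0.3,
    outlier_fraction_over_1mb = 0, exon_count_range = c(5L, 6L))
  generate_annotation(p, seed = seed, emit_sequence = FALSE)
}

# mirror a sequence-bearing bundle to the opposite strand: coordinates are
# reflected within each contig and the contig sequence reverse-complemented,
# so every window and event must be invariant
mirror_bundle <- function(ann, genome) {
  widths <- setNames(Biostrings::width(genome), names(genome))
  ex <- exon_table(ann)
  L <- widths[ex$chrom]
  mirrored <- data.table::data.table(
    gene_symbol = ex$gene_symbol, transcript_id = ex$transcript_id,
    chrom = ex$chrom, strand = ifelse(ex$strand == "+", "-", "+"),
    start = L - ex$end, end = L - ex$start)
  list(annotation = genome_annotation(mirrored, "mirrored"),
       genome = Biostrings::reverseComplement(genome))
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")
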