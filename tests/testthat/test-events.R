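# splice-event classification

# helper: locus from a list of exon matrices (start,end rows)
make_locus <- function(tx_list, strand = "+", gene = "G") {
  rows <- data.table::rbindlist(lapply(names(tx_list), function(id) {
    e <- tx_list[[id]]
    data.table::data.table(gene_symbol = gene, transcript_id = id,
                           chrom = "chrE", strand = strand,
                           start = e[, 1], end = e[, 2])
  }))
  get_locus(genome_annotation(rows), gene)
}

exA <- rbind(c(0, 100), c(200, 300), c(400, 500))          # exons A,B,C
exAC <- rbind(c(0, 100), c(400, 500))                      # A,C (B skipped)
exAltD <- rbind(c(0, 120), c(200, 300), c(400, 500))       # exon 1 longer 3'

test_that("textbook cases: skipped exon and alternative donor", {
  ev <- enumerate_events(make_locus(list(T1 = exA, T2 = exAC)))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$event_type, "skipped_exon")

  ev2 <- enumerate_events(make_locus(list(T1 = exA, T2 = exAltD)))
  expect_equal(ev2$event_type, "alt_donor")
  # same structural change on the minus strand is an alternative acceptor
  ev3 <- enumerate_events(make_locus(list(T1 = exA, T2 = exAltD),
                                     strand = "-"))
  expect_equal(ev3$event_type, "alt_acceptor")

  # intron retention falls into 'other'
  exRet <- rbind(c(0, 300), c(400, 500))
  ev4 <- enumerate_events(make_locus(list(T1 = exA, T2 = exRet)))
  expect_equal(ev4$event_type, "other")

  expect_equal(nrow(enumerate_events(make_locus(list(T1 = exA)))), 0L)
})

test_that("three transcripts: dedup equals brute-force pairwise enumeration", {
  # operators on adjacent elements compound in the cross-pair ('other')
  loc <- make_locus(list(T1 = exA, T2 = exAC, T3 = exAltD))
  ev <- enumerate_events(loc)
  expect_setequal(package_event_keys(ev), oracle_locus_events(loc))
  expect_setequal(ev$event_type, c("skipped_exon", "alt_donor", "other"))

  # well-separated operators: the cross-pair reproduces exactly the two
  # planted events, deduplicated locus-wide
  exB4 <- rbind(c(0, 100), c(200, 300), c(400, 500), c(600, 700))
  skipB <- exB4[-2, ]
  altC <- exB4; altC[3, 2] <- 520
  loc2 <- make_locus(list(T1 = exB4, T2 = skipB, T3 = altC))
  ev2 <- enumerate_events(loc2)
  expect_setequal(package_event_keys(ev2), oracle_locus_events(loc2))
  expect_equal(nrow(ev2), 2L)
  expect_setequal(ev2$event_type, c("skipped_exon", "alt_donor"))
})

test_that("duplicate transcripts and input order change nothing", {
  loc <- make_locus(list(T1 = exA, T2 = exAC, T3 = exAltD))
  loc_dup <- make_locus(list(T1 = exA, T2 = exAC, T3 = exAltD, T4 = exA))
  expect_setequal(package_event_keys(enumerate_events(loc_dup)),
                  package_event_keys(enumerate_events(loc)))
  loc_rev <- make_locus(list(T3 = exAltD, T2 = exAC, T1 = exA))
  expect_setequal(package_event_keys(enumerate_events(loc_rev)),
                  package_event_keys(enumerate_events(loc)))
})

test_that("classifier equals the brute-force oracle on a generated corpus", {
  bundle <- event_corpus(n = 120, seed = 19)
  ann <- bundle$annotation
  for (g in locus_table(ann)[n_transcripts >= 2, gene_symbol]) {
    loc <- get_locus(ann, g)
    expect_identical(package_event_keys(enumerate_events(loc)),
                     oracle_locus_events(loc))
  }
})

test_that("strand mirroring preserves event types", {
  bundle <- event_corpus(n = 40, seed = 23)
  ann <- bundle$annotation
  ex <- exon_table(ann)
  shift <- max(ex$end) + 1000
  mirrored <- data.table::copy(ex)[, `:=`(
    strand = ifelse(strand == "+", "-", "+"),
    start = shift - ex$end, end = shift - ex$start)]
  ann2 <- genome_annotation(mirrored)
  for (g in locus_table(ann)[n_transcripts >= 2, gene_symbol]) {
    t1 <- sort(table(enumerate_events(get_locus(ann, g))$event_type))
    t2 <- sort(table(enumerate_events(get_locus(ann2, g))$event_type))
    expect_identical(t1, t2)
  }
})

test_that("event proportions: normalization, exclusions, outlier cap", {
  bundle <- event_corpus(n = 60, seed = 29)
  ann <- bundle$annotation
  counts <- locus_event_counts(ann)
  syms <- locus_table(ann)[n_transcripts >= 2, gene_symbol]
  pr <- event_proportions(syms, ann, event_counts = counts)
  expect_equal(sum(pr$fractions), 1, tolerance = 1e-9)
  expect_equal(pr$total_events, sum(counts[gene_symbol %in% syms, total]))
  # excluding the busiest locus drops its events
  busiest <- counts[which.max(total), gene_symbol]
  pr2 <- event_proportions(syms, ann, exclude = busiest,
                           event_counts = counts)
  expect_equal(pr2$total_events,
               pr$total_events - counts[gene_symbol == busiest, total])
  pr3 <- event_proportions(syms, ann,
                           outlier_event_cap = max(counts$total) - 1,
                           event_counts = counts)
  expect_lt(pr3$total_events, pr$total_events)
  expect_error(event_proportions(
    locus_table(ann)[n_transcripts == 1, gene_symbol][1], ann,
    event_counts = counts), "undefined")
})

test_that("proportion enrichment detects a raised alt-acceptor mix", {
  # pool with the reference mix vs a list generated at a doubled mix
  p_hi <- synthetic_params(
    n_loci = 60,
    transcript_count_distribution = c(`1` = 0, `2` = 0.5, `3` = 0.5,
                                      `4` = 0, `5` = 0, `6+` = 0),
    locus_length_meanlog = log(9000), locus_length_sdlog = 0.3,
    outlier_fraction_over_1mb = 0, exon_count_range = c(5L, 6L),
    event_mix = c(skipped_exon = 0.3, alt_donor = 0.1, alt_acceptor = 0.5,
                  other = 0.1))
  hi <- generate_annotation(p_hi, seed = 61, emit_sequence = FALSE)
  pool <- event_corpus(n = 240, seed = 67)
  hex <- exon_table(hi$annotation)
  hex[, `:=`(gene_symbol = paste0("HI", gene_symbol),
             transcript_id = paste0("HI", transcript_id),
             chrom = paste0("HI", chrom))]
  combined <- genome_annotation(rbind(exon_table(pool$annotation), hex),
                                "combined")
  hi_syms <- unique(hex$gene_symbol)
  r <- proportion_enrichment(hi_syms, NULL, combined, "alt_acceptor",
                             n_lists = 100, seed = 71)
  expect_lte(r$p_value, 0.05)
  # trivial: observed below all nulls with direction = greater -> p = 1
  r2 <- proportion_enrichment(hi_syms, NULL, combined, "skipped_exon",
                              n_lists = 100, seed = 71)
  expect_gt(r2$p_value, 0.5)
})
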