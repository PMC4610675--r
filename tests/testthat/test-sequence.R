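# GC windows, the donor-acceptor gap, canonical motifs

test_that("gc_percent: fixed cases, N handling, reverse-complement identity", {
  expect_equal(gc_percent(c("GGCC", "ATAT", "GATC")), c(100, 0, 50))
  expect_equal(gc_percent("GCNN"), 100)   # N excluded from both sides
  expect_true(is.na(gc_percent("NNNN")))
  expect_error(gc_percent(""), "empty")
  for (i in 1:20) {
    s <- rand_dna(60)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(gc_percent(rc), gc_percent(s))
  }
})

test_that("boundary windows: classes, counts, and planted-string equality", {
  # two-exon transcript: exactly one Donor and one Accept, no Mid windows
  seq <- rand_dna(600)
  genome <- Biostrings::DNAStringSet(c(chrT = seq))
  ex <- data.table::data.table(
    gene_symbol = "G", transcript_id = "t", chrom = "chrT", strand = "+",
    start = c(100, 350), end = c(200, 480))
  ann <- genome_annotation(ex)
  w <- boundary_windows(get_transcript(ann, "t"), genome)
  expect_equal(lengths(w[c("TSS", "Donor", "Accept", "DonorMid", "AcceptMid")]),
               c(TSS = 1L, Donor = 1L, Accept = 1L, DonorMid = 0L,
                 AcceptMid = 0L))
  # windows are literal substrings of the genome on the plus strand
  expect_equal(w$TSS, substr(seq, 71, 130))
  expect_equal(w$Donor, substr(seq, 171, 230))
  expect_equal(w$Accept, substr(seq, 321, 380))
  # single-exon transcript: TSS only
  ex1 <- ex[1][, transcript_id := "t1"]
  w1 <- boundary_windows(get_transcript(genome_annotation(ex1), "t1"), genome)
  expect_equal(sum(lengths(w1)), 1L)
  expect_equal(lengths(w1)[["TSS"]], 1L)
})

test_that("minus-strand windows read 5'->3' (mirror-construction oracle)", {
  bundle <- seq_small()
  mir <- mirror_bundle(bundle$annotation, bundle$genome)
  for (id in sample(transcript_table(bundle$annotation)$transcript_id, 15)) {
    w1 <- boundary_windows(get_transcript(bundle$annotation, id),
                           bundle$genome)
    w2 <- boundary_windows(get_transcript(mir$annotation, id), mir$genome)
    expect_identical(w1, w2)
  }
})

test_that("gc_profile pools windows; duplication invariance; planted recovery", {
  bundle <- seq_single_tx(n = 40, seed = 31)
  ann <- bundle$annotation
  syms <- locus_table(ann)$gene_symbol
  prof <- gc_profile(syms, ann, bundle$genome)
  tgt <- bundle$truth$params$region_gc
  for (r in names(tgt))
    expect_lt(abs(prof$mean_gc[[r]] - tgt[[r]]), 2)
  # Donor and Accept counts = number of multi-exon transcripts
  n_multi <- sum(transcript_table(ann)$n_exons >= 2)
  expect_equal(prof$n_windows[["Donor"]], n_multi)
  expect_equal(prof$n_windows[["Accept"]], n_multi)

  # duplicating a locus's transcript under a new id changes nothing per-mean
  g <- syms[1]
  ex <- exon_table(ann)
  dup <- ex[gene_symbol == g][, transcript_id := paste0(transcript_id, "_dup")]
  ann2 <- genome_annotation(rbind(ex[gene_symbol == g], dup))
  p1 <- gc_profile(g, ann, bundle$genome)
  p2 <- gc_profile(g, ann2, bundle$genome)
  expect_equal(p2$mean_gc, p1$mean_gc)
})

test_that("donor_acceptor_gap: equal means give 0; modes; missing class errors", {
  prof <- structure(list(mean_gc = c(TSS = 60, Donor = 50, Accept = 50,
                                     DonorMid = 48, AcceptMid = 44),
                         n_windows = c(TSS = 5, Donor = 5, Accept = 5,
                                       DonorMid = 5, AcceptMid = 5),
                         window = 60), class = "gc_profile")
  expect_equal(donor_acceptor_gap(prof), 0)
  expect_equal(donor_acceptor_gap(prof, mode = "tss_accept"), 10)
  prof$mean_gc[["Accept"]] <- NA_real_
  expect_error(donor_acceptor_gap(prof), "lacks windows")
})

test_that("canonical fractions: planted probability recovered, all-A window non-canonical", {
  bundle <- seq_single_tx(n = 150, seed = 303, p_canonical = 0.8)
  ann <- bundle$annotation
  f <- canonical_site_fractions(locus_table(ann)$gene_symbol, ann,
                                bundle$genome)
  expect_gte(f$n_donor, 200)
  expect_lt(abs(f$donor_pct / 100 - 0.8), 0.05)
  expect_lt(abs(f$acceptor_pct / 100 - 0.8), 0.05)

  # hand-built: one junction with a planted motif, one with none
  left <- paste(rep("A", 300), collapse = "")
  s <- paste0(left, "GGTAA", paste(rep("A", 295), collapse = ""))
  genome <- Biostrings::DNAStringSet(c(chrM = s))
  ex <- data.table::data.table(
    gene_symbol = "G", transcript_id = "t", chrom = "chrM", strand = "+",
    start = c(200, 400), end = c(302, 500))  # donor at 302: GTAA in intron
  annM <- genome_annotation(ex)
  fM <- canonical_site_fractions("G", annM, genome)
  expect_equal(fM$donor_pct, 100)
  expect_equal(fM$acceptor_pct, 0)
})

test_that("strand mirroring leaves GC profile and canonical fractions unchanged", {
  bundle <- seq_small()
  ann <- bundle$annotation
  mir <- mirror_bundle(ann, bundle$genome)
  syms <- locus_table(ann)$gene_symbol
  p1 <- gc_profile(syms, ann, bundle$genome)
  p2 <- gc_profile(syms, mir$annotation, mir$genome)
  expect_equal(p1$mean_gc, p2$mean_gc, tolerance = 1e-12)
  expect_equal(p1$n_windows, p2$n_windows)
  f1 <- canonical_site_fractions(syms, ann, bundle$genome)
  f2 <- canonical_site_fractions(syms, mir$annotation, mir$genome)
  expect_equal(f1, f2)
})
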