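# length-matched sampling and the bootstrap engine

test_that("length matching: toy candidate choice and the tolerance-0 identity", {
  ex <- data.table::data.table(
    gene_symbol = c("NEAR", "FAR"), transcript_id = c("t1", "t2"),
    chrom = "c", strand = "+", start = 0, end = c(900, 2000))
  ann <- genome_annotation(ex)
  got <- sample_length_matched_list(1000, c("NEAR", "FAR"), ann, seed = 1)
  expect_equal(got$symbols, "NEAR")

  ann2 <- filter_loci(pool_medium()$annotation)
  lt <- locus_table(ann2)
  targets <- lt$length
  perm <- sample_length_matched_list(targets, lt$gene_symbol, ann2,
                                     tolerance = 0, seed = 5)
  # a permutation of the pool: exact lengths, every gene used once
  expect_setequal(perm$symbols, lt$gene_symbol)
  expect_equal(lt[perm$symbols, length], targets)
})

test_that("sampled control lengths are within tolerance of their targets", {
  ann <- filter_loci(pool_medium()$annotation)
  lt <- locus_table(ann)
  for (s in 1:25) {
    tgt_syms <- with_seed(1000 + s, sample(lt$gene_symbol, 40))
    targets <- lt[tgt_syms, length]
    got <- sample_length_matched_list(targets, lt$gene_symbol, ann, seed = s)
    lens <- lt[got$symbols, length]
    expect_true(all(abs(lens - targets) <= 0.10 * targets + 1e-9))
    expect_equal(anyDuplicated(got$symbols), 0L)
  }
})

test_that("unmatchable targets relax with a warning, then error", {
  ex <- data.table::data.table(
    gene_symbol = c("A", "B"), transcript_id = c("t1", "t2"),
    chrom = "c", strand = "+", start = 0, end = c(1000, 1130))
  ann <- genome_annotation(ex)
  # target 1130 vs only candidate 1000: outside 10%, inside 15% -> warn
  expect_warning(got <- sample_length_matched_list(1130, "A", ann, seed = 1),
                 "relaxation")
  expect_equal(got$symbols, "A")
  # beyond every relaxation step: nearest-length fallback, loudly
  expect_warning(
    far <- sample_length_matched_list(5000, c("A", "B"), ann, seed = 1),
    "beyond the relaxation ladder")
  expect_equal(far$symbols, "B")
  # more targets than pool genes is a hard error
  expect_error(
    suppressWarnings(sample_length_matched_list(c(1000, 1100, 1200),
                                                c("A", "B"), ann, seed = 1)),
    "pool smaller")
})

test_that("empirical p-value conventions: floor at 1/N, extremes, direction", {
  ann <- pool_medium()$annotation
  lt <- locus_table(ann)
  # a list made of the most complex genes: observed should beat all nulls
  top <- lt[order(-n_transcripts)][1:30, gene_symbol]
  r <- bootstrap_enrichment(top, NULL, ann, "mean_transcripts",
                            n_lists = 100, match_lengths = FALSE, seed = 3)
  expect_equal(r$p_value, 1 / 100)
  expect_equal(r$n_lists, 100L)
  expect_equal(length(r$null_values), 100L)
  expect_equal(r$null_mean, mean(r$null_values))
  expect_equal(r$null_sd, sd(r$null_values))
  # least complex genes with direction = greater -> p = 1
  bottom <- lt[order(n_transcripts)][1:30, gene_symbol]
  r2 <- bootstrap_enrichment(bottom, NULL, ann, "mean_transcripts",
                             n_lists = 100, match_lengths = FALSE, seed = 3)
  expect_equal(r2$p_value, 1)
  r3 <- bootstrap_enrichment(bottom, NULL, ann, "mean_transcripts",
                             n_lists = 100, match_lengths = FALSE,
                             direction = "less", seed = 3)
  expect_equal(r3$p_value, 1 / 100)
})

test_that("bootstrap is reproducible under a fixed seed and pool order", {
  ann <- filter_loci(pool_medium()$annotation)
  lt <- locus_table(ann)
  syms <- with_seed(9, sample(lt$gene_symbol, 60))
  r1 <- bootstrap_enrichment(syms, NULL, ann, n_lists = 50, seed = 42)
  r2 <- bootstrap_enrichment(syms, NULL, ann, n_lists = 50, seed = 42)
  expect_identical(r1$null_values, r2$null_values)
  expect_identical(r1$p_value, r2$p_value)
  # permuting the pool's symbol order leaves the p-value distribution intact
  r3 <- bootstrap_enrichment(syms, rev(lt$gene_symbol), ann,
                             n_lists = 50, seed = 42)
  expect_identical(sort(r1$null_values), sort(r3$null_values))
})

test_that("registered statistics cover the analysis surface", {
  expect_true(all(c("mean_transcripts", "bin_proportion", "mean_mrna_length",
                    "mean_large_exons", "event_fraction", "gc_gap",
                    "tissue_fraction") %in% list_statistics()))
  ann <- pool_medium()$annotation
  syms <- with_seed(2, sample(locus_table(ann)$gene_symbol, 40))
  r <- bootstrap_enrichment(syms, NULL, ann, "bin_proportion",
                            n_lists = 30, stat_args = list(bin = "1"),
                            seed = 1)
  expect_equal(r$observed,
               as.numeric(complexity_histogram(syms, ann)["1"]))
  r2 <- bootstrap_enrichment(syms, NULL, ann, "mean_mrna_length",
                             n_lists = 30, seed = 1)
  expect_equal(r2$observed, transcript_length_stats(syms, ann)$mean_mrna_length)
})

test_that("disease enrichment of diverse genes: disjoint db and calibration", {
  ann <- pool_medium()$annotation
  db0 <- gene_list("NOT_IN_POOL")
  r <- diverse_gene_disease_enrichment(ann, db0, n_lists = 50, seed = 1)
  expect_equal(r$observed, 0)
  expect_equal(r$p_value, 1)
  # membership independent of complexity -> null-ish p most of the time
  ps <- vapply(1:20, function(i) {
    db <- generate_disease_db(ann, base_rate = 0.1, complexity_odds = 1,
                              seed = 100 + i)
    diverse_gene_disease_enrichment(ann, db, n_lists = 100,
                                    seed = 200 + i)$p_value
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.75)
})
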