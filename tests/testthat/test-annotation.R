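# annotation model and readers

gtf_lines <- function(...) unlist(list(...))

test_that("GTF coordinates convert to 0-based half-open and loci group", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "G"; gene_name "G"; transcript_id "T1";',
    'chr1\tsrc\texon\t301\t400\t.\t+\t.\tgene_id "G"; gene_name "G"; transcript_id "T1";',
    'chr1\tsrc\texon\t101\t400\t.\t+\t.\tgene_id "G"; gene_name "G"; transcript_id "T2";'),
    f)
  ann <- read_gtf(f)
  t1 <- get_transcript(ann, "T1")
  expect_equal(t1$exons$start, c(100, 300))
  expect_equal(t1$exons$end, c(200, 400))
  expect_equal(locus_table(ann)$n_transcripts, 2L)
  expect_equal(locus_table(ann)$length, 300)
})

test_that("malformed GTF lines are rejected with a line number", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "G"; transcript_id "T1";',
    "garbage line without tabs"), f)
  expect_error(read_gtf(f), "line 2")
  writeLines(
    'chr1\tsrc\texon\t500\t400\t.\t+\t.\tgene_id "G"; transcript_id "T1";', f)
  expect_error(read_gtf(f), "line 1")
})

test_that("refFlat parses verbatim coordinates, validates exonCount, dedups", {
  f <- withr::local_tempfile(fileext = ".txt")
  row <- function(gene, id, starts, ends)
    sprintf("%s\t%s\tchr2\t-\t%s\t%s\t0\t0\t%d\t%s\t%s", gene, id,
            min(starts), max(ends), length(starts),
            paste0(paste(starts, collapse = ","), ","),
            paste0(paste(ends, collapse = ","), ","))
  writeLines(c(row("G1", "N1", c(0, 200, 500), c(100, 300, 600)),
               row("G1", "N2", c(0, 500), c(100, 600)),
               row("G1", "N2", c(0, 500), c(100, 600))), f)
  ann <- read_refflat(f)
  expect_equal(nrow(transcript_table(ann)), 2L)
  expect_equal(get_transcript(ann, "N1")$exons$start, c(0, 200, 500))
  expect_equal(locus_table(ann)$n_transcripts, 2L)

  writeLines(row("G1", "N1", c(0, 200), c(100, 300, 600)), f)
  expect_error(read_refflat(f), "exonCount")
})

test_that("GTF and refFlat readers give identical models; GTF round-trips", {
  bundle <- event_corpus(n = 25, seed = 77)
  ann <- bundle$annotation
  gtf <- withr::local_tempfile(fileext = ".gtf")
  rf <- withr::local_tempfile(fileext = ".txt")
  write_gtf(ann, gtf)
  ex <- exon_table(ann)
  rows <- vapply(split(ex, by = "transcript_id"), function(t) {
    t <- t[order(start)]
    sprintf("%s\t%s\t%s\t%s\t%d\t%d\t0\t0\t%d\t%s\t%s",
            t$gene_symbol[1], t$transcript_id[1], t$chrom[1], t$strand[1],
            min(t$start), max(t$end), nrow(t),
            paste0(paste(t$start, collapse = ","), ","),
            paste0(paste(t$end, collapse = ","), ","))
  }, character(1))
  writeLines(rows, rf)

  from_gtf <- read_gtf(gtf)
  from_rf <- read_refflat(rf)
  canon <- function(a) {
    e <- exon_table(a)[order(gene_symbol, transcript_id, start)]
    data.table::setindex(e, NULL)
    as.data.frame(e)
  }
  expect_equal(canon(from_gtf), canon(ann))
  expect_equal(canon(from_rf), canon(from_gtf))

  gtf2 <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(from_gtf, gtf2)
  expect_equal(canon(read_gtf(gtf2)), canon(from_gtf))
})

test_that("locus_length matches brute force over exons on random loci", {
  ann <- pool_medium()$annotation
  lt <- locus_table(ann)
  for (g in sample(lt$gene_symbol, 25)) {
    loc <- get_locus(ann, g)
    ex <- do.call(rbind, lapply(loc$transcripts, `[[`, "exons"))
    expect_equal(locus_length(loc), max(ex$end) - min(ex$start))
    # span length >= mature length of every transcript
    for (tx in loc$transcripts)
      expect_gte(locus_length(loc), sum(tx$exons$end - tx$exons$start))
  }
})

test_that("filter_loci removes strictly above 1 Mb and reports removals", {
  ex <- data.table::data.table(
    gene_symbol = c("A", "B", "C"), transcript_id = c("tA", "tB", "tC"),
    chrom = "chr1", strand = "+", start = c(0, 0, 0),
    end = c(1e6, 1e6 + 1, 500))
  ann <- genome_annotation(ex)
  out <- filter_loci(ann)
  expect_setequal(locus_table(out)$gene_symbol, c("A", "C"))
  expect_equal(attr(out, "removed_symbols"), "B")
  expect_lte(max(locus_table(out)$length), 1e6)
  out2 <- filter_loci(ann, min_length = 600)
  expect_setequal(attr(out2, "removed_symbols"), c("B", "C"))
  empty <- filter_loci(genome_annotation(ex[0]))
  expect_equal(nrow(locus_table(empty)), 0L)
})

test_that("gene-list loading: case, aliases, dedup, evidence, missing report", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("a1bg", "A1BG", " serpina1_old "), f)
  gl <- load_gene_list(f, alias_map = c(SERPINA1_OLD = "SERPINA1"))
  expect_equal(gl$symbols, c("A1BG", "SERPINA1"))
  writeLines(character(0), f)
  expect_error(load_gene_list(f), "empty")

  writeLines(c("g1\t2\t1", "g2\t1\t1", "g3\t0\t2", "g4\t5\t0"), f)
  gl <- load_gene_list(f)
  expect_equal(filter_by_evidence(gl)$symbols, c("G1", "G4"))

  ann <- genome_annotation(data.table::data.table(
    gene_symbol = "G1", transcript_id = "t1", chrom = "c", strand = "+",
    start = 0, end = 10))
  expect_setequal(missing_symbols(gl, ann), c("G2", "G3", "G4"))
})

test_that("paralog misannotation keeps the dominant chromosome copy", {
  ex <- data.table::data.table(
    gene_symbol = "G", transcript_id = c("t1", "t2", "t3"),
    chrom = c("chr1", "chr1", "chr5"), strand = "+",
    start = c(0, 0, 0), end = c(10, 20, 30))
  expect_warning(ann <- genome_annotation(ex), "multiple chromosomes")
  expect_equal(locus_table(ann)$chrom, "chr1")
  expect_equal(locus_table(ann)$n_transcripts, 2L)
})
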