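---
title: "Methods: transcript complexity, splice events, and matched-control bootstraps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcript complexity, splice events, and matched-control bootstraps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question the package addresses

Disease-associated gene lists — from GWAS catalogs and literature curation —
can be asked a structural question: do their loci produce an unusual number
of transcript isoforms, and are those isoforms built by unusual splicing?
`txcomplexity` implements the full chain of analyses needed to answer this
offline: annotation parsing, covariate-matched resampling, GC-content window
profiling at transcript boundaries, canonical splice-motif scanning,
structural classification of alternative-splicing events, and
tissue-dominance statistics for transcript-level expression tables. A
synthetic generator with truth bookkeeping makes every stage testable
without downloading reference data.

# The matched-control bootstrap

The central inferential device is an empirical null built from random gene
lists. GWAS ascertainment favors long loci, and long loci accumulate more
annotated isoforms, so a raw comparison of a disease list against random
genes is confounded by length. The engine therefore pairs each test-list
locus with a random control locus whose genomic span is within ±10% of it,
sampled without replacement from a reference pool that excludes the test
list's own symbols. Repeating this `n_lists` times (1000 by default) gives a
null distribution for any list-level statistic; the empirical p-value is the
fraction of null statistics at least as extreme as the observed one, floored
at `1/n_lists`. A statistic that beats all 1000 controls is reported as
p = 0.001, never 0.

Design choices worth knowing:

* **Per-gene matching, not distribution-level matching.** Pairing each locus
  individually guarantees the control length distribution matches the test
  distribution and is locally verifiable (the test suite brute-force checks
  every sampled control against its target).
* **Statistics are decomposable.** Every registered statistic reduces to a
  per-gene numeric matrix plus a combiner over column sums (e.g. mean
  transcripts = sum of counts / number of genes; the GC gap = two ratios of
  sums). A null list is then just a row subset, so a 1000-list bootstrap
  costs 1000 subset-sums rather than 1000 annotation walks. New statistics
  can be added with `register_statistic()`.
* **Tolerance relaxation.** A target with no ±10% candidate — or whose
  candidates were all consumed by competing targets in a
  without-replacement draw — is widened stepwise (15%, 20%, 30%, 50%) with
  a warning; only then is it an error. The wider ladder matters in the
  upper length tail: with a 2000-locus pool the two or three longest loci
  are sometimes each other's only near-length neighbours, and when two of
  them land in the same test list one of them must reach further down the
  distribution. Matching at the base tolerance is unaffected.
* **Determinism.** All sampling flows through a caller-supplied seed that is
  recorded in every `bootstrap_result`; the pipeline fans per-stage
  sub-seeds out of one root seed so enabling a stage never perturbs
  another's draws.

The locus span ("length") is the maximal genomic interval covering every
exon of every transcript sharing a gene symbol. Loci longer than one
megabase are removed by `filter_loci()` before analysis — the boundary is
strictly greater, so a locus of exactly 1 Mb is retained.

# Splice-event classification

Two transcripts of one locus are compared through their *internal splice
sites*: every exon end except the last (an `R` site) and every exon start
except the first (an `L` site), restricted to the genomic interval where
both transcripts overlap. Sites present in both chains are anchors;
each maximal run of sites present in only one chain, delimited by anchors
(or by the overlap boundary), is one variation. Classification uses only
the differing sites, with donor/acceptor roles assigned strand-aware:

| pattern of differing sites                    | class          |
|-----------------------------------------------|----------------|
| one chain empty, other `{L p1, R p2}`, p1<p2  | `skipped_exon` |
| one differing donor per chain                 | `alt_donor`    |
| one differing acceptor per chain              | `alt_acceptor` |
| anything else                                 | `other`        |

Intron retention (one chain empty, other `{R, L}` — an intron, not an
exon), compound runs, and structural differences at transcript termini all
fall into `other`, consistent with a four-way scheme in which only the three
named internal variations are distinguished. Setting
`include_terminal = FALSE` drops variations flanked by the overlap boundary
instead of a shared site.

Events are deduplicated locus-wide by a canonical coordinate signature, so a
variation witnessed by several transcript pairs counts once; adding an
identical transcript under a new id changes nothing. Proportions are
computed by pooling deduplicated events over the list's loci and dividing by
the total event count. Outlier loci can be excluded by symbol or by a
per-locus event cap — the reproducible generalization of dropping a single
known pathological gene from a control set.

The classifier is checked two ways: against an independently written
brute-force enumerator on hundreds of generated loci, and against the
generator's planted-event records (below).

# GC windows and canonical motifs

Five region classes are profiled: TSS, the first donor site (Donor), the
first acceptor site (Accept), and the pooled later donors/acceptors
(DonorMid/AcceptMid; the last exon's acceptor is excluded from AcceptMid).
Every window is 60 nt centered on its boundary — 30 nt each side — read in
transcript orientation (reverse-complemented on the minus strand). Centering
harmonizes two conflicting descriptions of the window placement (flanked
exonic sequence vs. sequence "surrounding" the site) and makes the TSS and
junction windows structurally identical; the window size is configurable. N
bases are excluded from both numerator and denominator of the GC
percentage; an all-N window is dropped.

The headline statistic is the **donor–acceptor gap**: mean Donor GC minus
mean Accept GC, signed. A `tss_accept` mode is provided because the
source material is internally inconsistent about which pair of boundaries
defines the gap; the default follows the donor–acceptor reading. Control
lists for the GC module are plain same-size draws (`match_lengths = FALSE`),
mirroring the use of non-normalized control lists for this analysis.

Canonical splice sites are called by strict pentamer content: a junction is
canonical if its 60-nt window contains `GGTAA`/`GGTGA` (donor side) or
`CAGGT`/`TAGGT` (acceptor side). Unlike the GC region classes, the motif
scan covers *every* junction including the last exon's acceptor; only the
transcript's outer ends carry no junction.

# The synthetic world

The generator states the data-generating conditions the analyses assume;
its defaults are fixed and are not tuned per test:

* **Transcripts per locus**: 55.7% of loci single-transcript, bins
  2–5 at 20/10/5/4.3%, and a 5% "6+" bin expanded with a geometric tail
  (q = 0.5) — matching the reference-set descriptives that motivate the
  analysis (a majority of single-transcript loci; ~95% below five
  transcripts). Pool mean ≈ 2.1.
* **Locus lengths**: log-normal, median 20 kb, sdlog 1.0 — the right order
  for human genes — with 1% outliers drawn uniformly in 1.2–3 Mb to
  exercise the megabase filter.
* **Alternative transcripts** are derived from a base transcript by splice
  operators drawn from `event_mix` (default 0.5 skip / 0.2 alt-donor /
  0.2 alt-acceptor / 0.1 intron-retention). Operators target non-adjacent
  elements whenever possible: two operators whose affected regions share no
  intact boundary between them merge, in the cross-pair of the two derived
  transcripts, into one compound `other` variation. When spacing is
  infeasible the locus's truth record is flagged `exact = FALSE`, and
  truth-equality checks restrict to exact loci; the classifier-vs-oracle
  comparison runs on all loci regardless.
* **Sequences**: drawn per-base at 45% background GC; every non-overlapping
  boundary window is resampled to its region target (TSS 62, Donor 58,
  Accept 41, DonorMid 48, AcceptMid 44 — a ~17-point donor–acceptor gap)
  to within ±1 point, counting planted motif bases toward the target.
  Junction motifs are planted with probability `p_canonical_motif` and
  actively scrubbed otherwise, so recovery tests are tight. Windows of
  operator-shifted boundaries that overlap an already-planted window are
  left as background; GC/motif recovery corpora therefore use
  single-transcript loci, where every window is planted.
* **Expression**: each gene gets a planted dominant tissue (uniform over 16
  tissues; flagged genes get lung with probability `excess/16`). The
  highest-expressed transcript's tissue vector is a 0.55 one-hot tilt plus
  0.45 Dirichlet noise, so the planted tissue is provably the argmax and
  truth records are exact.

What a green test does **not** establish: the generator's loci are
independent, lengths are independent of transcript counts, splice operators
are applied uniformly, and sequences have no compositional structure beyond
the planted windows. Real annotations violate all of these (length-count
correlation being the most consequential — it is precisely why the
length-matched null exists). The tests establish that the machinery is
correct and calibrated under a known world, not that any biological claim
holds.

# Numerical and policy choices

* Strict inequalities where the counting rules say "more than": the 1 Mb
  filter removes loci *strictly* above the bound; a "large exon" is
  *strictly* longer than 200 bp; the high-complexity set is *more than* 5
  transcripts (≥ 6).
* Evidence filtering keeps genes with strictly more positive than negative
  studies; equal counts are removed; genes without an evidence record are
  kept with a warning.
* "Highest-expressed transcript" is by total abundance across tissues
  (default); a max-in-any-tissue mode is exposed since either reading is
  defensible. Ties break lexicographically (transcript id, tissue name), so
  results are invariant to row and column order. Genes with all-zero
  expression are excluded from dominance denominators.
* Gene symbols are grouped exactly as annotated (after an optional alias
  map); a symbol annotated on two chromosomes keeps the copy with more
  transcripts. Non-coding accessions are kept by default; an
  accession-prefix filter makes exclusion an explicit choice.
* The pipeline config is JSON (`jsonlite` is a hard dependency of the
  analysis reports; no YAML parser is assumed to be available).

# Known limitations

* Per-gene length matching degrades to wider tolerances in sparse length
  tails (logged); distribution-level matching is not implemented as a
  separate mode beyond `match_lengths = FALSE`.
* The event classifier has no notion of event nesting or of AStalavista
  dimension codes; `other` is a heterogeneous bucket.
* No CDS/UTR awareness, no position-weight-matrix splice scoring, no
  multiple-testing correction across statistics (raw bootstrap p-values are
  reported, as is conventional for this design).
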