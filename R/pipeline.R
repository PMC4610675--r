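# End-to-end orchestration: parse -> filter -> complexity bootstrap ->
# GC profile/gap -> canonical fractions -> event proportions -> tissue
# dominance/enrichment, from one declarative JSON config, with per-stage
# seeds fanned out from a single root seed.

#' Read a pipeline run configuration
#'
#' JSON object with fields: `annotation` (GTF path) or `refflat`, optional
#' `genome` (FASTA), `list` (gene-list text), optional `pool` (defaults to
#' every annotated gene), optional `expression` (TSV), optional `disease_db`;
#' `stages`: any of `complexity`, `gc`, `canonical`, `events`, `tissue`,
#' `disease`; plus `n_lists` (default 1000), `tolerance` (0.10), `window`
#' (60), `max_locus_length` (1e6), `seed`, `out_dir`.
#'
#' @param path JSON config file
#' @return validated config list
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_run_config(cfg, dirname(path))
}

validate_run_config <- function(cfg, base = ".") {
  stopifnot(is.list(cfg))
  cfg$n_lists <- cfg$n_lists %||% 1000
  cfg$tolerance <- cfg$tolerance %||% 0.10
  cfg$window <- cfg$window %||% 60
  cfg$max_locus_length <- cfg$max_locus_length %||% 1e6
  cfg$seed <- cfg$seed %||% 1
  cfg$stages <- cfg$stages %||% character(0)
  if (cfg$n_lists < 1) stop("config error: n_lists must be >= 1")
  unknown <- setdiff(cfg$stages, c("complexity", "gc", "canonical", "events",
                                   "tissue", "disease"))
  if (length(unknown))
    stop("config error: unknown stage(s) ", paste(unknown, collapse = ", "))
  for (f in c("annotation", "refflat", "genome", "list", "pool",
              "expression", "disease_db")) {
    if (is.null(cfg[[f]])) next
    if (!file.exists(cfg[[f]])) {
      alt <- file.path(base, cfg[[f]])
      if (!file.exists(alt))
        stop("config error: path for '", f, "' does not exist: ", cfg[[f]])
      cfg[[f]] <- alt
    }
  }
  if (is.null(cfg$annotation) && is.null(cfg$refflat))
    stop("config error: an 'annotation' (GTF) or 'refflat' path is required")
  cfg
}

boot_summary <- function(b) list(
  statistic = b$statistic_name, observed = b$observed,
  null_mean = b$null_mean, null_sd = b$null_sd, p_value = b$p_value,
  direction = b$direction, n_lists = b$n_lists, seed = b$seed)

#' Run the analysis pipeline
#'
#' Executes the configured stages in a fixed order and writes, under
#' `out_dir`: one TSV per stage and a `summary.json` holding every bootstrap
#' result (observed, null mean/sd, empirical p, seed) plus the package
#' version and config. Each stage draws from its own seed derived from the
#' root seed, so enabling one stage never perturbs another stage's results.
#' A stage failure aborts with the stage name; previously written stage
#' outputs are preserved.
#'
#' @param config path to a JSON config, or a config list
#'   (see [read_run_config()])
#' @return the report list, invisibly
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_run_config(config)
         else validate_run_config(config)
  out_dir <- cfg$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  ann <- if (!is.null(cfg$annotation)) read_gtf(cfg$annotation)
         else read_refflat(cfg$refflat)
  ann <- filter_loci(ann, max_length = cfg$max_locus_length,
                     min_length = cfg$min_locus_length %||% 0)
  lst <- if (!is.null(cfg$list)) load_gene_list(cfg$list) else NULL
  pool <- if (!is.null(cfg$pool)) load_gene_list(cfg$pool) else NULL
  genome <- if (!is.null(cfg$genome)) read_genome(cfg$genome) else NULL
  expr <- if (!is.null(cfg$expression)) read_expression(cfg$expression)
          else NULL
  db <- if (!is.null(cfg$disease_db)) load_gene_list(cfg$disease_db)
        else NULL

  report <- list(package_version = as.character(
    utils::packageVersion("txcomplexity")),
    config = cfg[setdiff(names(cfg), "out_dir")],
    removed_loci = attr(ann, "removed_symbols"),
    stages = list())
  tsv <- function(x, name)
    data.table::fwrite(x, file.path(out_dir, paste0(name, ".tsv")),
                       sep = "\t")
  run_stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    report$stages[[name]] <<- res
  }

  if ("complexity" %in% cfg$stages) run_stage("complexity", function() {
    b <- bootstrap_enrichment(lst, pool, ann, "mean_transcripts",
                              n_lists = cfg$n_lists,
                              tolerance = cfg$tolerance,
                              seed = derive_seed(cfg$seed, "complexity"))
    hist <- complexity_histogram(lst, ann)
    tsv(data.table::data.table(bin = names(hist), proportion = hist),
        "complexity_histogram")
    list(mean_transcripts = boot_summary(b),
         histogram = as.list(hist),
         mean_observed = b$observed)
  })
  if ("gc" %in% cfg$stages) run_stage("gc", function() {
    if (is.null(genome)) stop("needs a 'genome' path")
    prof <- gc_profile(lst, ann, genome, window = cfg$window)
    tsv(data.table::data.table(region = REGION_CLASSES,
                               mean_gc = prof$mean_gc[REGION_CLASSES],
                               n_windows = prof$n_windows[REGION_CLASSES]),
        "gc_profile")
    b <- bootstrap_enrichment(lst, pool, ann, "gc_gap",
                              n_lists = cfg$n_lists, direction = "two_sided",
                              match_lengths = FALSE, genome = genome,
                              stat_args = list(window = cfg$window),
                              seed = derive_seed(cfg$seed, "gc"))
    list(profile = as.list(prof$mean_gc),
         donor_acceptor_gap = donor_acceptor_gap(prof),
         gap_bootstrap = boot_summary(b))
  })
  if ("canonical" %in% cfg$stages) run_stage("canonical", function() {
    if (is.null(genome)) stop("needs a 'genome' path")
    canonical_site_fractions(lst, ann, genome, window = cfg$window)
  })
  if ("events" %in% cfg$stages) run_stage("events", function() {
    counts <- locus_event_counts(ann)
    tsv(counts, "event_counts")
    props <- event_proportions(lst, ann, event_counts = counts)
    b <- proportion_enrichment(lst, pool, ann, "alt_acceptor",
                               n_lists = cfg$n_lists, events = counts,
                               tolerance = cfg$tolerance,
                               seed = derive_seed(cfg$seed, "events"))
    list(fractions = as.list(props$fractions),
         total_events = props$total_events,
         alt_acceptor_bootstrap = boot_summary(b))
  })
  if ("tissue" %in% cfg$stages) run_stage("tissue", function() {
    if (is.null(expr)) stop("needs an 'expression' path")
    dom <- tissue_dominance(lst, expr)
    tsv(dom$per_gene, "tissue_dominance")
    b <- lung_enrichment(lst, pool, expr, ann, n_lists = cfg$n_lists,
                         tolerance = cfg$tolerance,
                         seed = derive_seed(cfg$seed, "tissue"))
    list(fractions = as.list(dom$fractions), n_scored = dom$n_scored,
         lung_bootstrap = boot_summary(b))
  })
  if ("disease" %in% cfg$stages) run_stage("disease", function() {
    if (is.null(db)) stop("needs a 'disease_db' path")
    b <- diverse_gene_disease_enrichment(ann, db, n_lists = cfg$n_lists,
                                         seed = derive_seed(cfg$seed,
                                                            "disease"))
    boot_summary(b)
  })

  jsonlite::write_json(report, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(report)
}
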