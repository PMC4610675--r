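# Length-matched bootstrap resampling engine.
#
# Every list-level statistic is registered as a *decomposable* statistic: a
# builder returns one numeric matrix row per gene plus a combiner mapping the
# column sums of any row subset to the scalar statistic. A null list is then a
# row subset, so the 1000-list bootstrap costs 1000 subset-sums rather than
# 1000 re-walks of the annotation.

new_bootstrap_result <- function(statistic_name, observed, null_values,
                                 direction, seed, extra = list()) {
  n <- length(null_values)
  ge <- sum(null_values >= observed) / n
  le <- sum(null_values <= observed) / n
  p <- switch(direction,
              greater = ge, less = le,
              two_sided = min(1, 2 * min(ge, le)),
              stop("unknown direction: ", direction))
  p <- max(p, 1 / n)
  structure(c(list(statistic_name = statistic_name, observed = observed,
                   null_values = null_values, null_mean = mean(null_values),
                   null_sd = sd(null_values), p_value = p,
                   direction = direction, n_lists = n, seed = seed), extra),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "bootstrap_result '%s': observed %.4g vs null %.4g +/- %.4g (N = %d)\n  p = %.4g (direction: %s)\n",
    x$statistic_name, x$observed, x$null_mean, x$null_sd, x$n_lists,
    x$p_value, x$direction))
  invisible(x)
}

# ---- statistic registry -----------------------------------------------------

#' Register a list-level statistic for the bootstrap engine
#'
#' A statistic is decomposable over genes: `builder(annotation, extras, args)`
#' must return `list(genes = <character>, mat = <numeric matrix, one row per
#' gene>, combine = function(colsums) <scalar>)`. The statistic of any gene
#' list is `combine(colSums(mat[list_rows, ]))`.
#'
#' @param name statistic name
#' @param builder builder function (see details)
#' @export
register_statistic <- function(name, builder) {
  stopifnot(is.character(name), is.function(builder))
  if (is.null(.txc_env$stats)) .txc_env$stats <- list()
  .txc_env$stats[[name]] <- builder
  invisible(name)
}

#' Names of registered bootstrap statistics
#' @export
list_statistics <- function() names(.txc_env$stats)

get_statistic <- function(name) {
  b <- .txc_env$stats[[name]]
  if (is.null(b)) stop("unknown statistic '", name, "'; see list_statistics()")
  b
}

ratio_combine <- function(cs) cs[[1L]] / cs[[2L]]

stat_mean_transcripts <- function(annotation, extras, args) {
  lt <- annotation$loci
  list(genes = lt$gene_symbol,
       mat = cbind(num = lt$n_transcripts, den = rep(1, nrow(lt))),
       combine = ratio_combine)
}

stat_bin_proportion <- function(annotation, extras, args) {
  bin <- args$bin %||% "6+"
  lt <- annotation$loci
  ind <- if (identical(bin, "6+")) lt$n_transcripts >= 6
         else lt$n_transcripts == as.integer(bin)
  list(genes = lt$gene_symbol,
       mat = cbind(num = as.numeric(ind), den = rep(1, nrow(lt))),
       combine = ratio_combine)
}

stat_mean_mrna_length <- function(annotation, extras, args) {
  tx <- annotation$transcripts[, .(num = sum(mature_length), den = .N),
                               by = gene_symbol]
  list(genes = tx$gene_symbol, mat = cbind(tx$num, tx$den),
       combine = ratio_combine)
}

stat_mean_large_exons <- function(annotation, extras, args) {
  tx <- annotation$transcripts[, .(num = sum(n_large_exons), den = .N),
                               by = gene_symbol]
  list(genes = tx$gene_symbol, mat = cbind(tx$num, tx$den),
       combine = ratio_combine)
}

stat_event_fraction <- function(annotation, extras, args) {
  type <- args$event_type %||% "alt_acceptor"
  counts <- extras$event_counts %||%
    locus_event_counts(annotation,
                       include_terminal = args$include_terminal %||% TRUE)
  num <- as.numeric(counts[[type]])
  den <- as.numeric(counts$total)
  zero <- counts$gene_symbol %in% toupper(args$exclude %||% character(0))
  if (!is.null(args$outlier_event_cap))
    zero <- zero | counts$total > args$outlier_event_cap
  num[zero] <- 0
  den[zero] <- 0
  list(genes = counts$gene_symbol, mat = cbind(num = num, den = den),
       combine = ratio_combine)
}

stat_gc_gap <- function(annotation, extras, args) {
  if (is.null(extras$genome)) stop("statistic 'gc_gap' needs a genome")
  per <- per_gene_gc_sums(annotation, extras$genome,
                          window = args$window %||% 60)
  list(genes = per$gene_symbol,
       mat = as.matrix(per[, .(don_sum, don_n, acc_sum, acc_n)]),
       combine = function(cs) 100 * (cs[[1L]] / cs[[2L]] - cs[[3L]] / cs[[4L]]))
}

stat_tissue_fraction <- function(annotation, extras, args) {
  if (is.null(extras$expression))
    stop("statistic 'tissue_fraction' needs an expression matrix")
  tissue <- args$tissue %||% "lung"
  dom <- gene_dominant_tissues(extras$expression)
  idx <- match(annotation$loci$gene_symbol, dom$gene_symbol)
  top <- dom$top_tissue[idx]          # NA: absent from matrix or all-zero
  scored <- !is.na(top)
  hit <- scored & !is.na(top) & top == tissue
  hit[is.na(hit)] <- FALSE
  list(genes = annotation$loci$gene_symbol,
       mat = cbind(num = as.numeric(hit), den = as.numeric(scored)),
       combine = ratio_combine)
}

.register_builtin_statistics <- function() {
  register_statistic("mean_transcripts", stat_mean_transcripts)
  register_statistic("bin_proportion", stat_bin_proportion)
  register_statistic("mean_mrna_length", stat_mean_mrna_length)
  register_statistic("mean_large_exons", stat_mean_large_exons)
  register_statistic("event_fraction", stat_event_fraction)
  register_statistic("gc_gap", stat_gc_gap)
  register_statistic("tissue_fraction", stat_tissue_fraction)
}

.onLoad <- function(libname, pkgname) .register_builtin_statistics()

# ---- length-matched sampling ------------------------------------------------

# Precompute, per target length, the index range of candidates (in sorted
# candidate-length order) within the matching tolerance; widen per-target
# through relax steps when a target has no candidate.
build_length_matcher <- function(target_lengths, cand_lengths,
                                 tolerance = 0.10,
                                 relax = c(0.15, 0.20, 0.30, 0.50)) {
  ord <- order(cand_lengths)
  sl <- cand_lengths[ord]
  rng_at <- function(tol) {
    lo <- findInterval(target_lengths * (1 - tol) - 1e-9, sl) + 1L
    hi <- findInterval(target_lengths * (1 + tol) + 1e-9, sl)
    list(lo = lo, hi = hi)
  }
  r <- rng_at(tolerance)
  used_tol <- rep(tolerance, length(target_lengths))
  for (t in relax) {
    empty <- r$hi < r$lo
    if (!any(empty)) break
    wider <- rng_at(t)
    r$lo[empty] <- wider$lo[empty]
    r$hi[empty] <- wider$hi[empty]
    used_tol[empty] <- t
  }
  if (any(r$hi < r$lo)) {
    # beyond every relaxation step (an extreme-tail target whose only
    # near-length peers sit in the test list): fall back to the nearest
    # available length so a control list can always be produced
    bad <- which(r$hi < r$lo)
    warning(length(bad), " target length(s) beyond the relaxation ladder; ",
            "nearest-length candidate(s) used")
    near <- pmin(pmax(findInterval(target_lengths[bad], sl), 1L), length(sl))
    r$lo[bad] <- near
    r$hi[bad] <- near
    used_tol[bad] <- Inf
  }
  if (any(used_tol > tolerance & is.finite(used_tol)))
    warning(sum(used_tol > tolerance),
            " target length(s) needed tolerance relaxation up to ",
            max(used_tol))
  list(ord = ord, lo = r$lo, hi = r$hi, size = r$hi - r$lo + 1L,
       n = length(target_lengths), tolerance = used_tol,
       targets = target_lengths, sl = sl, relax = relax)
}

# Draw one matched list: one candidate per target, without replacement.
# Vectorised rejection of duplicates, exact greedy fallback if it stalls.
sample_matched_idx <- function(m) {
  pos <- m$lo + as.integer(floor(runif(m$n) * m$size))
  for (iter in 1:15) {
    dup <- duplicated(pos)
    if (!any(dup)) return(m$ord[pos])
    w <- which(dup)
    pos[w] <- m$lo[w] + as.integer(floor(runif(length(w)) * m$size[w]))
  }
  # greedy: scarcest targets first, uniform over unused candidates; the
  # greedy order is randomized per attempt, so dead ends are retried
  for (attempt in 1:3) {
    pos <- integer(m$n)
    taken <- logical(length(m$sl))
    ok <- TRUE
    for (i in order(m$size, runif(m$n))) {
      cand <- seq.int(m$lo[i], m$hi[i])
      cand <- cand[!taken[cand]]
      if (!length(cand)) { ok <- FALSE; break }
      pick <- cand[sample.int(length(cand), 1L)]
      pos[i] <- pick
      taken[pick] <- TRUE
    }
    if (ok) return(m$ord[pos])
  }
  # targets whose candidates are all taken by competitors: widen that
  # target's tolerance stepwise (the exhausted-candidate relaxation path);
  # the outcome depends on assignment order, so dead ends are retried too
  for (attempt in 1:25) {
    pos <- integer(m$n)
    taken <- logical(length(m$sl))
    ok <- TRUE
    for (i in order(m$size, runif(m$n))) {
      cand <- seq.int(m$lo[i], m$hi[i])
      cand <- cand[!taken[cand]]
      for (tol in m$relax) {
        if (length(cand)) break
        lo2 <- findInterval(m$targets[i] * (1 - tol) - 1e-9, m$sl) + 1L
        hi2 <- findInterval(m$targets[i] * (1 + tol) + 1e-9, m$sl)
        if (hi2 >= lo2) {
          cand <- seq.int(lo2, hi2)
          cand <- cand[!taken[cand]]
        }
      }
      if (!length(cand)) {            # nearest unused length as last resort
        free <- which(!taken)
        if (!length(free)) { ok <- FALSE; break }
        cand <- free[which.min(abs(m$sl[free] - m$targets[i]))]
      }
      pick <- cand[sample.int(length(cand), 1L)]
      pos[i] <- pick
      taken[pick] <- TRUE
    }
    if (ok) return(m$ord[pos])
  }
  stop("could not assemble a matched list without replacement; ",
       "pool smaller than the number of targets")
}

#' Sample a length-matched control gene list
#'
#' Draws, without replacement, one pool gene per target length such that the
#' i-th sampled gene's locus length lies within `tolerance` (default +/-10%)
#' of `target_lengths[i]`. Targets with no candidate at the base tolerance are
#' widened stepwise through `relax` with a warning; an unmatched target after
#' relaxation is an error.
#'
#' @param target_lengths numeric vector of locus lengths (bp) to match
#' @param pool `gene_list` or character vector of candidate symbols (e.g. a
#'   reference gene set minus the test list)
#' @param annotation a `genome_annotation` providing locus lengths
#' @param tolerance fractional matching tolerance (default 0.10)
#' @param relax widening steps used only for otherwise-unmatchable targets
#' @param seed RNG seed
#' @return a `gene_list` of `length(target_lengths)` symbols
#' @export
sample_length_matched_list <- function(target_lengths, pool, annotation,
                                       tolerance = 0.10,
                                       relax = c(0.15, 0.20, 0.30, 0.50),
                                       seed = NULL) {
  syms <- sort(found_symbols(pool, annotation))
  lens <- annotation$loci[syms, length]
  m <- build_length_matcher(target_lengths, lens, tolerance, relax)
  idx <- with_seed(seed, sample_matched_idx(m))
  gene_list(syms[idx], name = "length_matched_control")
}

# ---- bootstrap --------------------------------------------------------------

#' Bootstrap enrichment of a list statistic against matched control lists
#'
#' Computes a named statistic on the test list, then on `n_lists` random
#' control lists of the same size drawn from `pool` (excluding the test
#' list's own symbols). By default each control gene is length-matched within
#' +/-10% to one test-list locus; `match_lengths = FALSE` gives plain
#' same-size draws (used e.g. for GC-window controls). The empirical p-value
#' is the fraction of null statistics at least as extreme as the observed
#' one, floored at `1/n_lists`.
#'
#' @param list test `gene_list` (or character vector)
#' @param pool candidate control symbols; `NULL` means every annotated gene
#' @param annotation a `genome_annotation`
#' @param statistic registered statistic name (see [list_statistics()])
#' @param n_lists number of control lists (default 1000)
#' @param direction `"greater"`, `"less"` or `"two_sided"`
#' @param tolerance length-matching tolerance
#' @param match_lengths length-match controls (default) or plain draws
#' @param stat_args list of arguments passed to the statistic builder (e.g.
#'   `bin`, `event_type`, `tissue`, `window`)
#' @param genome,expression optional extras required by sequence/expression
#'   statistics
#' @param events optional precomputed per-gene event-count table
#'   (from [locus_event_counts()]) to avoid recomputation
#' @param seed RNG seed, recorded in the result
#' @return a `bootstrap_result`
#' @export
bootstrap_enrichment <- function(list, pool = NULL, annotation,
                                 statistic = "mean_transcripts",
                                 n_lists = 1000, direction = "greater",
                                 tolerance = 0.10, match_lengths = TRUE,
                                 stat_args = list(), genome = NULL,
                                 expression = NULL, events = NULL,
                                 seed = NULL) {
  stopifnot(inherits(annotation, "genome_annotation"), n_lists >= 1)
  list_syms <- found_symbols(list, annotation)
  pool_syms <- if (is.null(pool)) annotation$loci$gene_symbol
               else found_symbols(pool, annotation)
  # canonical ordering: results depend on the pool as a set, not its order
  pool_syms <- sort(setdiff(pool_syms, list_syms))
  if (length(pool_syms) < length(list_syms))
    stop("control pool smaller than the test list")

  extras <- list(genome = genome, expression = expression,
                 event_counts = events)
  st <- get_statistic(statistic)(annotation, extras, stat_args)
  row_of <- match(c(list_syms, pool_syms), st$genes)
  if (anyNA(row_of))
    stop("statistic builder did not cover all pool/list genes")
  mat <- st$mat[row_of, , drop = FALSE]
  list_rows <- seq_along(list_syms)
  pool_rows <- length(list_syms) + seq_along(pool_syms)
  observed <- st$combine(colSums(mat[list_rows, , drop = FALSE]))

  pool_mat <- mat[pool_rows, , drop = FALSE]
  nulls <- with_seed(seed, {
    if (match_lengths) {
      tl <- annotation$loci[list_syms, length]
      pl <- annotation$loci[pool_syms, length]
      m <- build_length_matcher(tl, pl, tolerance)
      vapply(seq_len(n_lists), function(i) {
        st$combine(colSums(pool_mat[sample_matched_idx(m), , drop = FALSE]))
      }, numeric(1))
    } else {
      k <- length(list_syms)
      vapply(seq_len(n_lists), function(i) {
        st$combine(colSums(pool_mat[sample.int(length(pool_syms), k), ,
                                    drop = FALSE]))
      }, numeric(1))
    }
  })
  new_bootstrap_result(statistic, observed, nulls, direction, seed,
                       extra = list(n_list_genes = length(list_syms),
                                    n_pool_genes = length(pool_syms),
                                    stat_args = stat_args))
}
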