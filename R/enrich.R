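#' Random-gene-set null for positive-selection enrichment
#'
#' Draws `reps` random gene sets of size `k` (uniform, without replacement)
#' from the gene universe and records how many drawn genes carry the
#' positively-selected flag in each replicate. Replicates are generated in
#' fixed-size chunks, each chunk seeded deterministically from `seed`, so
#' the stream is reproducible and chunkable.
#'
#' @param universe tibble with columns `gene_id` and logical `psg`.
#' @param k genes drawn per replicate (the focal set size, e.g. 320).
#' @param reps number of replicates (the analysis default is 100000).
#' @param seed integer seed.
#' @param chunk_size replicates per seeded chunk (default 1000).
#' @return integer vector of replicate counts.
#' @export
resample_null <- function(universe, k, reps, seed = 1L, chunk_size = 1000L) {
  universe <- as_tibble(universe)
  n <- nrow(universe)
  if (k > n) abort(sprintf("draw size k = %d exceeds universe size %d", k, n))
  if (reps < 1L) abort("`reps` must be at least 1")
  flag <- as.logical(universe$psg)
  n_chunks <- ceiling(reps / chunk_size)
  counts <- vector("list", n_chunks)
  for (ch in seq_len(n_chunks)) {
    set.seed((as.integer(seed) + ch - 1L) %% .Machine$integer.max)
    m <- min(chunk_size, reps - (ch - 1L) * chunk_size)
    counts[[ch]] <- vapply(
      seq_len(m),
      function(i) sum(flag[sample.int(n, k)]),
      integer(1)
    )
  }
  unlist(counts)
}

#' Empirical tail probabilities from a resampling null
#'
#' Add-one (permutation-inclusive) empirical p-values:
#' `p_upper = (1 + #\{null >= observed\}) / (R + 1)` and the analogous
#' lower tail with `<=`. Never returns 0.
#'
#' @param null_counts integer vector of replicate counts.
#' @param observed observed count.
#' @return named list with `p_upper` and `p_lower`.
#' @export
empirical_tail_p <- function(null_counts, observed) {
  r <- length(null_counts)
  if (r < 1L) abort("need at least one replicate")
  list(
    p_upper = (1 + sum(null_counts >= observed)) / (r + 1),
    p_lower = (1 + sum(null_counts <= observed)) / (r + 1)
  )
}

#' Resampling enrichment test for a focal gene set
#'
#' Is the observed number of positively selected genes in the focal set
#' extreme relative to random gene sets of the same size drawn from the
#' universe? Each tail is tested one-sided at `alpha` (both tails are
#' reported; Bonferroni to alpha/2 if a single two-sided decision is
#' wanted).
#'
#' @param universe tibble with `gene_id` and logical `psg`.
#' @param focal_genes character vector of focal gene ids (must all be in
#'   the universe).
#' @param reps replicates (default 100000).
#' @param seed integer seed.
#' @param alpha per-tail significance level (default 0.05).
#' @param chunk_size see [resample_null()].
#' @return an `enrich_test` object: observed count, null counts, tail
#'   p-values and per-tail significance flags.
#' @export
enrich_test <- function(universe, focal_genes, reps = 1e5, seed = 1L,
                        alpha = 0.05, chunk_size = 1000L) {
  universe <- as_tibble(universe)
  focal_genes <- unique(focal_genes)
  missing_ids <- setdiff(focal_genes, universe$gene_id)
  if (length(missing_ids)) {
    abort(sprintf("focal gene(s) not in universe (first: %s)", missing_ids[1]))
  }
  k <- length(focal_genes)
  observed <- sum(universe$psg[universe$gene_id %in% focal_genes])
  null_counts <- resample_null(universe, k = k, reps = reps, seed = seed,
                               chunk_size = chunk_size)
  p <- empirical_tail_p(null_counts, observed)
  structure(
    list(
      observed = observed,
      k = k,
      n_universe = nrow(universe),
      n_psg = sum(universe$psg),
      reps = length(null_counts),
      seed = seed,
      alpha = alpha,
      null_counts = null_counts,
      p_upper = p$p_upper,
      p_lower = p$p_lower,
      significant_high = p$p_upper <= alpha,
      significant_low = p$p_lower <= alpha
    ),
    class = "enrich_test"
  )
}

#' @export
print.enrich_test <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<enrich_test> %d/%d focal genes positively selected\n",
      "  universe: %d genes (%d PSG); %d replicates\n",
      "  p_upper = %.4g%s, p_lower = %.4g%s (per-tail alpha = %g)\n"
    ),
    x$observed, x$k, x$n_universe, x$n_psg, x$reps,
    x$p_upper, if (x$significant_high) " *" else "",
    x$p_lower, if (x$significant_low) " *" else "",
    x$alpha
  ))
  invisible(x)
}

#' Write an enrichment result to JSON
#'
#' @param x an `enrich_test`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrich_json <- function(x, path) {
  hist <- table(x$null_counts)
  jsonlite::write_json(
    list(
      observed = x$observed, k = x$k, reps = x$reps, seed = x$seed,
      p_upper = x$p_upper, p_lower = x$p_lower,
      significant_high = x$significant_high, significant_low = x$significant_low,
      null_histogram = list(count = as.integer(names(hist)),
                            n = as.integer(hist))
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact conditional test; the two-sided p sums hypergeometric
#' probabilities no larger than that of the observed table. Used for
#' pairwise lineage comparisons of positively-selected gene proportions.
#'
#' @param a,b,c,d non-negative integer cell counts, row-wise
#'   (`a b / c d`).
#' @return two-sided p-value.
#' @export
fisher_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    abort("cell counts must be non-negative integers")
  }
  if (sum(cells) == 0) abort("all-zero table")
  stats::fisher.test(matrix(cells, nrow = 2, byrow = TRUE))$p.value
}
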