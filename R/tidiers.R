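#' Tidy an enrichment test result
#'
#' @param x an `enrich_test`.
#' @param ... unused.
#' @return one-row tibble: observed count, set size, universe size, PSG
#'   count, replicates, tail p-values and per-tail significance flags.
#' @method tidy enrich_test
#' @export
tidy.enrich_test <- function(x, ...) {
  tibble(
    observed = x$observed, k = x$k, n_universe = x$n_universe,
    n_psg = x$n_psg, reps = x$reps,
    p_upper = x$p_upper, p_lower = x$p_lower,
    significant_high = x$significant_high, significant_low = x$significant_low
  )
}

#' @rdname tidy.enrich_test
#' @method glance enrich_test
#' @export
glance.enrich_test <- function(x, ...) {
  tibble(
    observed = x$observed,
    expected = x$k * x$n_psg / x$n_universe,
    p_upper = x$p_upper, p_lower = x$p_lower,
    reps = x$reps, seed = x$seed, alpha = x$alpha
  )
}

#' Tidy a scan result into its gene-level calls
#'
#' @param x a `scan_result`.
#' @param ... unused.
#' @return the gene-level call tibble.
#' @method tidy scan_result
#' @export
tidy.scan_result <- function(x, ...) x$gene_calls

#' @rdname tidy.scan_result
#' @method glance scan_result
#' @export
glance.scan_result <- function(x, ...) {
  per_stat <- x$candidates |>
    distinct(.data$statistic, .data$gene_id) |>
    count(.data$statistic)
  tibble(
    n_candidates = nrow(x$candidates),
    n_genes_called = length(unique(x$gene_calls$gene_id)),
    n_ihs_genes = sum(per_stat$n[per_stat$statistic == "iHS"]),
    n_xpehh_genes = sum(per_stat$n[per_stat$statistic == "xpEHH"]),
    p_upper = if (!is.null(x$enrichment)) x$enrichment$overall$p_upper else NA_real_
  )
}
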