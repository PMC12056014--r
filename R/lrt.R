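#' Likelihood-ratio statistic for nested branch-site models
#'
#' `2 * (lnL_alt - lnL_null)` for the modified Model A against the null
#' with foreground omega fixed at 1. Slightly negative differences (an
#' optimizer at the boundary) are clamped to 0 with a warning.
#'
#' @param lnl_alt,lnl_null finite log-likelihoods of the alternative and
#'   null fits (vectorized).
#' @return non-negative LRT statistic(s).
#' @export
lrt_statistic <- function(lnl_alt, lnl_null) {
  if (any(!is.finite(lnl_alt)) || any(!is.finite(lnl_null))) {
    abort("log-likelihoods must be finite")
  }
  stat <- 2 * (lnl_alt - lnl_null)
  if (any(stat < 0)) {
    warn(sprintf("%d negative LRT statistic(s) clamped to 0", sum(stat < 0)))
    stat <- pmax(stat, 0)
  }
  stat
}

#' Halved chi-square(1) p-value for a boundary LRT
#'
#' Under the null the branch-site LRT follows the mixture
#' (1/2) chi2_0 + (1/2) chi2_1, so the p-value is half the chi-square(1)
#' upper tail: `0.5 * Pr(chi2_1 >= lrt)`.
#'
#' @param lrt non-negative LRT statistic(s).
#' @return p-value(s) in `(0, 0.5]`.
#' @export
halved_chi2_p <- function(lrt) {
  if (any(!is.finite(lrt)) || any(lrt < 0)) abort("`lrt` must be non-negative")
  0.5 * pchisq(lrt, df = 1, lower.tail = FALSE)
}

#' Bonferroni adjustment with an explicit family size
#'
#' `min(1, m * p)`, delegated to [stats::p.adjust()].
#'
#' @param p p-value(s) in `[0, 1]`.
#' @param m family size (number of genes successfully tested on the
#'   branch).
#' @return adjusted p-value(s).
#' @export
bonferroni_adjust <- function(p, m) {
  stop_if_not_prob(p, "p")
  if (m < 1) abort("family size `m` must be at least 1")
  stats::p.adjust(p, method = "bonferroni", n = m)
}

#' Branch-site LRT post-processing for a table of log-likelihood pairs
#'
#' Takes per-gene alternative/null log-likelihoods (e.g. parsed from
#' codeml output) and returns the LRT statistic, the halved-chi-square
#' p-value and the Bonferroni-adjusted p for each gene.
#'
#' @param tbl tibble with columns `gene`, `lnl_alt`, `lnl_null` (extra
#'   columns such as `branch` pass through).
#' @param family_size Bonferroni family size `m`; defaults to the number
#'   of rows.
#' @param alpha significance level applied to the adjusted p (default
#'   0.05).
#' @return `tbl` with `lrt`, `p_half`, `p_bonf`, `significant` added.
#' @export
lrt_table <- function(tbl, family_size = NULL, alpha = 0.05) {
  tbl <- as_tibble(tbl)
  if (!all(c("lnl_alt", "lnl_null") %in% names(tbl))) {
    abort("`tbl` needs columns `lnl_alt` and `lnl_null`")
  }
  m <- family_size %||% nrow(tbl)
  tbl |>
    mutate(
      lrt = lrt_statistic(.data$lnl_alt, .data$lnl_null),
      p_half = halved_chi2_p(.data$lrt),
      p_bonf = bonferroni_adjust(.data$p_half, m),
      significant = .data$p_bonf <= alpha
    )
}

#' Parse lnL values from codeml main output
#'
#' Convenience reader for `mlc` files: extracts the log-likelihood from
#' lines starting with `lnL(ntime:`. Returns the values in file order;
#' pairing alternative/null runs is the caller's responsibility (supply a
#' manual TSV to [lrt_table()] when the layout differs).
#'
#' @param path codeml output file.
#' @return numeric vector of lnL values (possibly empty).
#' @export
read_codeml_lnl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ln <- grep("^lnL\\(ntime:", lines, value = TRUE)
  if (!length(ln)) return(numeric(0))
  as.numeric(stringr::str_match(ln, "\\):\\s*(-?[0-9.]+)")[, 2])
}
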