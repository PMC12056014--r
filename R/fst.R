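#' Weir-Cockerham per-site FST from genotype counts
#'
#' The two-population variance-component estimator theta = a / (a + b + c)
#' of Weir & Cockerham (1984), computed from diploid genotype counts
#' (hom-ref, het, hom-alt) per population: `a` is the among-population
#' component, `b` among-individual-within-population, `c` within-individual.
#' The estimate can be negative; monomorphic sites (a + b + c = 0) give NA.
#'
#' @param counts1,counts2 length-3 numeric vectors or 3-column matrices of
#'   (n_hom_ref, n_het, n_hom_alt) for each population; rows are sites.
#' @return numeric vector of FST estimates (NA where undefined), capped at
#'   the theoretical maximum of 1 so fixed differences return exactly 1.
#' @export
wc_fst_site <- function(counts1, counts2) {
  c1 <- if (is.null(dim(counts1))) matrix(counts1, nrow = 1) else as.matrix(counts1)
  c2 <- if (is.null(dim(counts2))) matrix(counts2, nrow = 1) else as.matrix(counts2)
  if (ncol(c1) != 3L || ncol(c2) != 3L) abort("genotype counts need 3 columns")
  if (any(c1 < 0) || any(c2 < 0)) abort("negative genotype counts")
  n1 <- rowSums(c1)
  n2 <- rowSums(c2)
  if (any(n1 < 1) || any(n2 < 1)) abort("both populations need at least one individual")
  # alt-allele frequency and observed heterozygosity per population
  p1 <- (c1[, 2] + 2 * c1[, 3]) / (2 * n1)
  p2 <- (c2[, 2] + 2 * c2[, 3]) / (2 * n2)
  h1 <- c1[, 2] / n1
  h2 <- c2[, 2] / n2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  out <- pmin(a / denom, 1)
  out[denom == 0] <- NA_real_
  out
}

#' Per-site FST between two populations of a haplotype panel
#'
#' Genotypes are reconstructed from haplotype pairs (columns 2i-1, 2i form
#' individual i). Returns one record per site with the pooled derived-allele
#' frequency used downstream for frequency binning.
#'
#' @param hm a [hap_matrix()] or list of them.
#' @param pop_a,pop_b population labels.
#' @return tibble: `chrom`, `pos`, `fst`, `pooled_freq`.
#' @export
fst_scan <- function(hm, pop_a, pop_b) {
  hms <- if (inherits(hm, "hap_matrix")) list(hm) else hm
  parts <- purrr::map(hms, function(h) {
    g1 <- genotype_counts(h, pop_a)
    g2 <- genotype_counts(h, pop_b)
    cols <- h$hap_pop %in% c(pop_a, pop_b)
    tibble(
      chrom = h$chrom,
      pos = h$positions,
      fst = wc_fst_site(g1, g2),
      pooled_freq = rowMeans(h$alleles[, cols, drop = FALSE])
    )
  })
  bind_rows(parts)
}

genotype_counts <- function(hm, pop) {
  cols <- which(hm$hap_pop == pop)
  if (!length(cols)) abort(sprintf("unknown population: %s", pop))
  if (length(cols) %% 2L != 0L) abort("odd haplotype count; diploids required")
  a1 <- hm$alleles[, cols[seq(1, length(cols), 2)], drop = FALSE]
  a2 <- hm$alleles[, cols[seq(2, length(cols), 2)], drop = FALSE]
  g <- a1 + a2
  cbind(
    rowSums(g == 0L),
    rowSums(g == 1L),
    rowSums(g == 2L)
  )
}

#' Frequency-binned top-quantile FST thresholds
#'
#' Because FST and allele frequency are strongly correlated, thresholds are
#' set within pooled-allele-frequency bins: records are binned into
#' equal-width bins of `bin_width`, undersized bins (fewer than
#' `min_bin_size` non-NA records) are merged into their nearest neighbour,
#' and each bin's threshold is the empirical upper `quantile` under the
#' nearest-rank rule. A record passes if `fst >= ` its bin threshold
#' (inclusive, so ties all pass); NA FST never passes. Negative estimates
#' are kept as-is - they simply never reach the threshold.
#'
#' @param records tibble from [fst_scan()].
#' @param bin_width pooled-frequency bin width (default 0.05).
#' @param quantile upper tail mass defining the threshold (default 0.05).
#' @param min_bin_size minimum non-NA records per retained bin (default 20).
#' @return `records` with `bin_id`, `bin_threshold`, `passes_threshold`
#'   columns added.
#' @export
binned_fst_thresholds <- function(records, bin_width = 0.05, quantile = 0.05,
                                  min_bin_size = 20) {
  if (nrow(records) == 0L) abort("no FST records")
  n_bins <- as.integer(round(1 / bin_width))
  bin <- freq_bin_index(records$pooled_freq, bin_width)
  centers <- (seq_len(n_bins) - 0.5) * bin_width
  records$bin_id <- merge_small_bins(bin, ok = !is.na(records$fst),
                                     centers = centers, min_size = min_bin_size)
  records |>
    group_by(.data$bin_id) |>
    mutate(
      bin_threshold = upper_quantile_nearest_rank(.data$fst, quantile),
      passes_threshold = !is.na(.data$fst) & .data$fst >= .data$bin_threshold
    ) |>
    ungroup()
}
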