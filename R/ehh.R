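#' Extended haplotype homozygosity over an interval
#'
#' The probability that two distinct haplotypes drawn from `carriers` are
#' identical over the sites in `interval`: sum over distinct haplotype
#' strings g of C(k_g, 2), divided by C(n, 2).
#'
#' @param hm a [hap_matrix()].
#' @param carriers integer vector of haplotype column indices (at least 2).
#' @param interval integer vector of site indices defining the string.
#' @return fraction in `[0, 1]`.
#' @export
ehh_step <- function(hm, carriers, interval) {
  stopifnot(inherits(hm, "hap_matrix"))
  n <- length(carriers)
  if (n < 2L) abort("EHH needs at least 2 carrier haplotypes")
  strings <- apply(hm$alleles[interval, carriers, drop = FALSE], 2L, paste, collapse = "")
  k <- table(strings)
  sum(choose(k, 2)) / choose(n, 2)
}

#' EHH decay curve from a core site
#'
#' Walks outward from the core, refining haplotype groups one site at a
#' time, and reports the decay as (distance in bp, EHH) points for one
#' direction. The first point is (0, 1): all carriers share the core
#' allele by construction.
#'
#' @param hm a [hap_matrix()].
#' @param core core site index.
#' @param allele `"ancestral"`, `"derived"`, or `"pooled"` — which carrier
#'   set to follow. `carriers` overrides.
#' @param carriers optional explicit haplotype column indices.
#' @param direction `"left"` or `"right"`.
#' @param cutoff EHH value at which the walk stops (default 0.05).
#' @param max_extension_bp maximum extension from the core (default 1e6).
#' @param max_gap_bp maximum allowed gap between adjacent sites (default 2e5).
#' @return tibble of `distance`, `ehh` points with attributes `status`
#'   (`"ok"`, `"chrom_end"`, `"max_extension"`, `"gap"`) and `truncated`.
#' @export
ehh_curve <- function(hm, core, allele = c("derived", "ancestral", "pooled"),
                      carriers = NULL, direction = c("right", "left"),
                      cutoff = 0.05, max_extension_bp = 1e6,
                      max_gap_bp = 2e5) {
  stopifnot(inherits(hm, "hap_matrix"))
  allele <- match.arg(allele)
  direction <- match.arg(direction)
  if (is.null(carriers)) {
    carriers <- switch(allele,
      derived = which(hm$alleles[core, ] == 1L),
      ancestral = which(hm$alleles[core, ] == 0L),
      pooled = seq_len(n_haps(hm))
    )
  }
  if (length(carriers) < 2L) abort("EHH needs at least 2 carrier haplotypes")
  res <- cpp_ehh_curve(
    hm$alleles, hm$positions, core - 1L, as.integer(carriers) - 1L,
    cutoff, max_extension_bp, max_gap_bp, if (direction == "right") 1L else -1L
  )
  status <- c("ok", "chrom_end", "max_extension", "gap")[res$status + 1L]
  out <- tibble(distance = res$distance, ehh = res$ehh)
  attr(out, "status") <- status
  attr(out, "truncated") <- status != "ok"
  attr(out, "core") <- core
  attr(out, "allele") <- allele
  class(out) <- c("ehh_curve", class(out))
  out
}

#' Integrate an EHH decay curve into an iHH area
#'
#' Trapezoidal area under the (distance, EHH) points, accumulated outward
#' from distance 0 and stopped at the first point with EHH below `cutoff`;
#' the final trapezoid into that point is included. EHH is measured above
#' zero (the raw curve is integrated, not its excess over the cutoff).
#'
#' @param curve tibble with `distance` and `ehh` columns, ordered by
#'   distance (one direction).
#' @param cutoff EHH stopping threshold.
#' @return area in bp x EHH units. If the curve never falls below the
#'   cutoff the area is returned with attribute `truncated = TRUE` (such
#'   sites become NA under the scan truncation policy).
#' @export
integrate_ihh <- function(curve, cutoff = 0.05) {
  d <- curve$distance
  e <- curve$ehh
  if (is.unsorted(d)) abort("curve points must be ordered by distance")
  area <- 0
  truncated <- TRUE
  if (length(d) > 1L) {
    for (i in 2:length(d)) {
      area <- area + 0.5 * (e[i - 1L] + e[i]) * (d[i] - d[i - 1L])
      if (e[i] < cutoff) {
        truncated <- FALSE
        break
      }
    }
  }
  # a curve that already carries a non-ok status from ehh_curve stays truncated
  if (!is.null(attr(curve, "status")) && identical(attr(curve, "status"), "ok")) {
    truncated <- FALSE
  }
  structure(area, truncated = truncated)
}

na_reason_levels <- c("few_carriers", "chrom_end", "max_extension", "gap", "zero_ihh")

code_to_reason <- function(code) {
  ifelse(code == 0L, NA_character_, na_reason_levels[code])
}

#' Unstandardized iHS at one site
#'
#' `ln(iHH_ancestral / iHH_derived)` with both integrals computed by the
#' same decay walk the genome scan uses. Long derived haplotypes (the
#' classic incomplete-sweep signal) give negative values under this sign
#' convention.
#'
#' @inheritParams ehh_curve
#' @param pop population label.
#' @param site core site index.
#' @return the log-ratio, or `NA` (with attribute `na_reason`) when either
#'   allele class has fewer than 2 carriers, an integral is zero, or the
#'   truncation policy fires.
#' @export
ihs_unstandardized <- function(hm, pop, site, cutoff = 0.05,
                               max_extension_bp = 1e6, max_gap_bp = 2e5) {
  stopifnot(inherits(hm, "hap_matrix"))
  sub <- hap_subset(hm, pop = pop)
  res <- cpp_ihs_scan(sub$alleles, sub$positions, cutoff, max_extension_bp,
                      max_gap_bp)
  score <- log(res$ihh_a[site] / res$ihh_d[site])
  attr(score, "na_reason") <- code_to_reason(res$code[site])
  score
}

#' Unstandardized xpEHH at one site
#'
#' `ln(iHH_A / iHH_B)` where each iHH pools all haplotypes of its
#' population and both integrals stop where the pooled two-population EHH
#' first drops below the cutoff. Positive values mean longer haplotypes
#' (less diversity) in population A.
#'
#' @inheritParams ihs_unstandardized
#' @param pop_a,pop_b the ordered population pair (A over B).
#' @return the log-ratio or `NA` with attribute `na_reason`.
#' @export
xpehh_unstandardized <- function(hm, pop_a, pop_b, site, cutoff = 0.05,
                                 max_extension_bp = 1e6, max_gap_bp = 2e5) {
  stopifnot(inherits(hm, "hap_matrix"))
  cols_a <- which(hm$hap_pop == pop_a)
  cols_b <- which(hm$hap_pop == pop_b)
  if (!length(cols_a)) abort(sprintf("unknown population: %s", pop_a))
  if (!length(cols_b)) abort(sprintf("unknown population: %s", pop_b))
  res <- cpp_xpehh_scan(hm$alleles, hm$positions, cols_a - 1L, cols_b - 1L,
                        cutoff, max_extension_bp, max_gap_bp)
  score <- log(res$ihh_a[site] / res$ihh_b[site])
  attr(score, "na_reason") <- code_to_reason(res$code[site])
  score
}

new_score_track <- function(tbl, statistic, pops) {
  tbl <- as_tibble(tbl)
  attr(tbl, "statistic") <- statistic
  attr(tbl, "pops") <- pops
  class(tbl) <- c("score_track", class(tbl))
  tbl
}

#' Genome scan: iHS per site
#'
#' Computes unstandardized iHS for every site of one population and
#' standardizes within derived-allele-frequency bins. Accepts a single
#' [hap_matrix()] or a list of them (multi-chromosome); standardization is
#' genome-wide over everything scanned.
#'
#' @param hm a [hap_matrix()] or list of them.
#' @param pop population label to scan.
#' @param cutoff,max_extension_bp,max_gap_bp EHH walk parameters (tool
#'   defaults 0.05, 1e6 bp, 2e5 bp).
#' @param n_bins number of equal-width derived-frequency bins (default 100).
#' @param min_bin_size bins with fewer non-NA scores are merged into their
#'   nearest neighbour (default 20).
#' @return a `score_track` tibble: `chrom`, `pos`, `freq`, `ihh_a`, `ihh_d`,
#'   `unstd`, `std`, `na_reason`.
#' @export
ihs_scan <- function(hm, pop, cutoff = 0.05, max_extension_bp = 1e6,
                     max_gap_bp = 2e5, n_bins = 100, min_bin_size = 20) {
  hms <- if (inherits(hm, "hap_matrix")) list(hm) else hm
  parts <- purrr::map(hms, function(h) {
    sub <- hap_subset(h, pop = pop)
    res <- cpp_ihs_scan(sub$alleles, sub$positions, cutoff, max_extension_bp,
                        max_gap_bp)
    tibble(
      chrom = h$chrom,
      pos = sub$positions,
      freq = rowMeans(sub$alleles),
      ihh_a = res$ihh_a,
      ihh_d = res$ihh_d,
      unstd = log(res$ihh_a / res$ihh_d),
      na_reason = code_to_reason(res$code)
    )
  })
  tbl <- bind_rows(parts)
  tbl <- standardize_scores(tbl, n_bins = n_bins, mode = "freq_bins",
                            min_bin_size = min_bin_size)
  new_score_track(tbl, "iHS", pop)
}

#' Genome scan: xpEHH per site
#'
#' Computes unstandardized xpEHH for every site between an ordered
#' population pair and standardizes globally (single bin), per tool
#' defaults. `freq` records the pooled derived-allele frequency over both
#' populations.
#'
#' @inheritParams ihs_scan
#' @param pop_a,pop_b the ordered pair; positive scores favour selection in
#'   `pop_a`.
#' @return a `score_track` tibble (`ihh_a`/`ihh_b` are the per-population
#'   integrals).
#' @export
xpehh_scan <- function(hm, pop_a, pop_b, cutoff = 0.05, max_extension_bp = 1e6,
                       max_gap_bp = 2e5) {
  hms <- if (inherits(hm, "hap_matrix")) list(hm) else hm
  parts <- purrr::map(hms, function(h) {
    cols_a <- which(h$hap_pop == pop_a)
    cols_b <- which(h$hap_pop == pop_b)
    if (!length(cols_a)) abort(sprintf("unknown population: %s", pop_a))
    if (!length(cols_b)) abort(sprintf("unknown population: %s", pop_b))
    res <- cpp_xpehh_scan(h$alleles, h$positions, cols_a - 1L, cols_b - 1L,
                          cutoff, max_extension_bp, max_gap_bp)
    tibble(
      chrom = h$chrom,
      pos = h$positions,
      freq = rowMeans(h$alleles[, c(cols_a, cols_b), drop = FALSE]),
      ihh_a = res$ihh_a,
      ihh_b = res$ihh_b,
      unstd = log(res$ihh_a / res$ihh_b),
      na_reason = code_to_reason(res$code)
    )
  })
  tbl <- bind_rows(parts)
  tbl <- standardize_scores(tbl, mode = "global")
  new_score_track(tbl, "xpEHH", c(pop_a, pop_b))
}

#' Standardize raw haplotype scores within frequency bins
#'
#' iHS mode (`"freq_bins"`): sites are binned by derived-allele frequency
#' into `n_bins` equal-width bins, bins with fewer than `min_bin_size`
#' non-NA scores are merged into their nearest neighbour, and each score is
#' replaced by its within-bin z-score (sample SD, n-1 denominator). xpEHH
#' mode (`"global"`): one bin for everything. NA scores stay NA.
#'
#' @param tbl tibble with at least `unstd` and (for `freq_bins`) `freq`.
#' @param n_bins number of equal-width bins on `[0, 1]`.
#' @param mode `"freq_bins"` or `"global"`.
#' @param min_bin_size minimum non-NA scores per retained bin.
#' @return `tbl` with columns `std` and `bin` added.
#' @export
standardize_scores <- function(tbl, n_bins = 100, mode = c("freq_bins", "global"),
                               min_bin_size = 20) {
  mode <- match.arg(mode)
  x <- tbl$unstd
  if (all(is.na(x))) abort("all scores are NA; nothing to standardize")
  if (mode == "global") {
    tbl$bin <- 1L
  } else {
    bw <- 1 / n_bins
    bin <- freq_bin_index(tbl$freq, bw)
    centers <- (seq_len(n_bins) - 0.5) * bw
    tbl$bin <- merge_small_bins(bin, ok = !is.na(x), centers = centers,
                                min_size = min_bin_size)
  }
  tbl |>
    group_by(.data$bin) |>
    mutate(std = {
      v <- .data$unstd
      nn <- sum(!is.na(v))
      if (nn < 2L) rep(NA_real_, length(v))
      else (v - mean(v, na.rm = TRUE)) / sd(v, na.rm = TRUE)
    }) |>
    ungroup()
}
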