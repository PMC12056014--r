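# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: pair enumeration for EHH, a numeric ANOVA for
# Weir-Cockerham FST, exhaustive enumeration for hypergeometric tails and
# Fisher tables, and naive loops for windows and quantiles.

# EHH by brute-force enumeration of all carrier pairs
oracle_ehh <- function(alleles, carriers, interval) {
  n <- length(carriers)
  pairs <- utils::combn(carriers, 2)
  same <- vapply(seq_len(ncol(pairs)), function(j) {
    all(alleles[interval, pairs[1, j]] == alleles[interval, pairs[2, j]])
  }, logical(1))
  sum(same) / choose(n, 2)
}

# Weir-Cockerham theta via numerically computed ANOVA mean squares on
# expanded per-individual genotype data (independent of the a/b/c algebra)
oracle_wc_fst <- function(c1, c2) {
  geno <- function(cc) rep(c(0L, 1L, 2L), cc)
  pops <- list(geno(c1), geno(c2))
  n <- vapply(pops, length, integer(1))
  r <- 2
  N <- sum(n)
  p <- vapply(pops, function(g) mean(g) / 2, numeric(1))
  nc <- (N - sum(n^2) / N) / (r - 1)
  pbar <- sum(n * p) / N
  msg <- sum(vapply(pops, function(g) sum(ifelse(g == 1L, 0.5, 0)), numeric(1))) / N
  msi <- sum(vapply(seq_len(r), function(i) {
    sum(2 * (pops[[i]] / 2 - p[i])^2)
  }, numeric(1))) / sum(n - 1)
  msp <- sum(2 * n * (p - pbar)^2) / (r - 1)
  denom <- msp + (nc - 1) * msi + nc * msg
  if (denom == 0) return(NA_real_)
  (msp - msi) / denom
}

# nearest-rank upper quantile by explicit sort-and-count
oracle_upper_quantile <- function(x, q) {
  x <- sort(x[!is.na(x)], decreasing = TRUE)
  x[max(1L, ceiling(q * length(x)))]
}

# exact null distribution of flagged-gene counts when k genes are drawn
# without replacement from a universe with m flagged among N
oracle_hypergeom_tail <- function(N, m, k, observed) {
  counts <- 0:min(m, k)
  p <- stats::dhyper(counts, m, N - m, k)
  list(
    p_upper = sum(p[counts >= observed]),
    p_lower = sum(p[counts <= observed])
  )
}

# two-sided Fisher p by summing hypergeometric probabilities <= observed's
oracle_fisher_2x2 <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  x <- max(0, k - n):min(k, m)
  p <- stats::dhyper(x, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# naive sliding-window recount of extreme scores
oracle_window_counts <- function(std, window_size, score_cut) {
  half <- (window_size - 1L) %/% 2L
  m <- length(std)
  extreme <- !is.na(std) & abs(std) > score_cut
  vapply((half + 1L):(m - half), function(i) {
    sum(extreme[(i - half):(i + half)])
  }, integer(1))
}

# small literal haplotype panel builder: `haps` is a character vector of
# 0/1 strings, one per haplotype (sites are string positions)
make_hm <- function(haps, positions = NULL, pops = NULL, chrom = "1") {
  mat <- do.call(cbind, lapply(strsplit(haps, ""), as.integer))
  positions <- positions %||% seq_len(nrow(mat)) * 1000
  pops <- pops %||% rep("P1", length(haps))
  hap_matrix(chrom = chrom, positions = positions, alleles = mat, hap_pop = pops)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# a tiny handwritten VCF for reader tests
write_test_vcf <- function(path, lines_body, samples = c("S1", "S2", "S3")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    lines_body
  ), path)
  path
}

fixture_panel <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 1L, sweeps = 2L, focal_enrichment = 0.5) {
    key <- paste(seed, sweeps, focal_enrichment, sep = "_")
    if (is.null(cache[[key]])) {
      cache[[key]] <- simulate_panel(
        sim_config_fixture(seed = seed, sweeps = sweeps,
                           focal_enrichment = focal_enrichment)
      )
    }
    cache[[key]]
  }
})
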