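#' Phased haplotype matrix
#'
#' The central container for one chromosome of phased, biallelic, polarized
#' genotypes: a site-by-haplotype 0/1 matrix (0 = ancestral, 1 = derived)
#' with physical positions, a population label per haplotype, and per-site
#' metadata (ref/alt alleles and how the ancestral allele was determined).
#'
#' @param chrom single chromosome identifier.
#' @param positions integer vector of 1-based base-pair positions, strictly
#'   increasing.
#' @param alleles integer matrix, sites in rows and haplotypes in columns,
#'   values 0 (ancestral) or 1 (derived).
#' @param hap_pop character vector of population labels, one per haplotype
#'   column.
#' @param site_meta optional tibble with one row per site (columns such as
#'   `ref`, `alt`, `aa_source`); a minimal one is built when omitted.
#'
#' @return An object of class `hap_matrix`.
#' @export
hap_matrix <- function(chrom, positions, alleles, hap_pop, site_meta = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  positions <- as.numeric(positions)
  if (length(chrom) != 1L) abort("`chrom` must be a single id")
  if (nrow(alleles) != length(positions)) {
    abort("`positions` length must equal the number of allele rows (sites)")
  }
  if (ncol(alleles) != length(hap_pop)) {
    abort("`hap_pop` length must equal the number of allele columns (haplotypes)")
  }
  if (length(positions) > 1L && any(diff(positions) <= 0)) {
    abort("`positions` must be strictly increasing within a chromosome")
  }
  if (length(alleles) && !all(alleles %in% c(0L, 1L))) {
    abort("alleles must be 0 (ancestral) or 1 (derived); biallelic sites only")
  }
  if (is.null(site_meta)) {
    site_meta <- tibble(
      ref = rep("A", length(positions)),
      alt = rep("T", length(positions)),
      aa_source = rep("annotated", length(positions))
    )
  }
  if (nrow(site_meta) != length(positions)) {
    abort("`site_meta` must have one row per site")
  }
  structure(
    list(
      chrom = as.character(chrom),
      positions = positions,
      alleles = alleles,
      hap_pop = as.character(hap_pop),
      site_meta = as_tibble(site_meta)
    ),
    class = "hap_matrix"
  )
}

#' @export
print.hap_matrix <- function(x, ...) {
  pops <- table(x$hap_pop)
  cat(sprintf(
    "<hap_matrix> chrom %s: %d sites x %d haplotypes (%s)\n",
    x$chrom, n_sites(x), n_haps(x),
    paste(sprintf("%s=%d", names(pops), as.integer(pops)), collapse = ", ")
  ))
  invisible(x)
}

#' @rdname hap_matrix
#' @param x a `hap_matrix`.
#' @export
n_sites <- function(x) length(x$positions)

#' @rdname hap_matrix
#' @export
n_haps <- function(x) ncol(x$alleles)

#' @rdname hap_matrix
#' @export
populations <- function(x) unique(x$hap_pop)

#' Subset a haplotype matrix by population and/or sites
#'
#' @param hm a [hap_matrix()].
#' @param pop optional vector of population labels to keep.
#' @param sites optional integer vector of site indices to keep.
#' @return a `hap_matrix` view.
#' @export
hap_subset <- function(hm, pop = NULL, sites = NULL) {
  stopifnot(inherits(hm, "hap_matrix"))
  cols <- seq_len(n_haps(hm))
  if (!is.null(pop)) {
    missing_pop <- setdiff(pop, hm$hap_pop)
    if (length(missing_pop)) {
      abort(sprintf("unknown population(s): %s", paste(missing_pop, collapse = ", ")))
    }
    cols <- which(hm$hap_pop %in% pop)
  }
  rows <- sites %||% seq_len(n_sites(hm))
  hap_matrix(
    chrom = hm$chrom,
    positions = hm$positions[rows],
    alleles = hm$alleles[rows, cols, drop = FALSE],
    hap_pop = hm$hap_pop[cols],
    site_meta = hm$site_meta[rows, , drop = FALSE]
  )
}

#' Derived-allele frequency at a site
#'
#' Derived-allele count over haplotype count, within one population.
#'
#' @param hm a [hap_matrix()].
#' @param pop population label.
#' @param site site index (1-based row of the matrix).
#' @return a fraction in `[0, 1]`.
#' @export
site_allele_freq <- function(hm, pop, site) {
  stopifnot(inherits(hm, "hap_matrix"))
  if (!pop %in% hm$hap_pop) abort(sprintf("unknown population: %s", pop))
  if (any(site < 1L | site > n_sites(hm))) abort("site index out of range")
  cols <- hm$hap_pop == pop
  unname(rowSums(hm$alleles[site, cols, drop = FALSE]) / sum(cols))
}

#' Per-population derived-allele frequencies for all sites
#'
#' @param hm a [hap_matrix()].
#' @return a tibble with columns `site`, `pos`, one frequency column per
#'   population, and `pooled` (over all haplotypes).
#' @export
allele_freqs <- function(hm) {
  stopifnot(inherits(hm, "hap_matrix"))
  out <- tibble(site = seq_len(n_sites(hm)), pos = hm$positions)
  for (p in populations(hm)) {
    cols <- hm$hap_pop == p
    out[[p]] <- rowMeans(hm$alleles[, cols, drop = FALSE])
  }
  out$pooled <- rowMeans(hm$alleles)
  out
}

#' Sites passing a minor-allele-frequency filter in every listed population
#'
#' A site passes if `min(f, 1 - f) >= maf_min` for its derived-allele
#' frequency `f` in each population named, the conjunctive reading of a
#' "MAF in test populations" filter.
#'
#' @param hm a [hap_matrix()].
#' @param pops population labels that participate in the analysis.
#' @param maf_min minimum minor allele frequency (inclusive).
#' @return integer vector of passing site indices.
#' @export
maf_pass_sites <- function(hm, pops, maf_min = 0.05) {
  stopifnot(inherits(hm, "hap_matrix"))
  keep <- rep(TRUE, n_sites(hm))
  for (p in pops) {
    if (!p %in% hm$hap_pop) abort(sprintf("unknown population: %s", p))
    f <- rowMeans(hm$alleles[, hm$hap_pop == p, drop = FALSE])
    # tolerance keeps count-ratio MAFs exactly at the bound inclusive
    keep <- keep & (pmin(f, 1 - f) >= maf_min - 1e-9)
  }
  which(keep)
}
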