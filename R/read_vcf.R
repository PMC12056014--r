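#' Read phased biallelic SNPs from a VCF into haplotype matrices
#'
#' Parses a VCF with phased diploid genotypes, drops indels and multiallelic
#' records, polarizes alleles to ancestral/derived using the `AA` INFO tag
#' when present (reference allele as fallback, recorded per site), and
#' applies a minor-allele-frequency filter. A site is retained only if its
#' MAF is at least `maf_min` in every population listed in `pops`
#' (conjunctive rule; the bound is inclusive, so MAF exactly 0.05 passes the
#' default filter). Sites with any missing allele in a participating
#' population are dropped.
#'
#' @param path VCF file (plain text or bgzip/gzip).
#' @param pop_map data frame with columns `sample` and `population` covering
#'   every sample retained from the VCF.
#' @param maf_min minimum minor allele frequency, inclusive. Default 0.05.
#' @param pops populations whose MAF gates retention; default all populations
#'   in `pop_map`.
#' @return A [hap_matrix()] when the VCF holds one chromosome, otherwise a
#'   named list of `hap_matrix` objects, one per chromosome.
#' @export
read_phased_vcf <- function(path, pop_map, maf_min = 0.05, pops = NULL) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  pop_map <- as_tibble(pop_map)
  if (!all(c("sample", "population") %in% names(pop_map))) {
    abort("`pop_map` needs columns `sample` and `population`")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  samples <- colnames(gt)
  absent <- setdiff(samples, pop_map$sample)
  if (length(absent)) {
    abort(sprintf(
      "sample(s) absent from pop_map: %s", paste(absent, collapse = ", ")
    ))
  }
  sample_pop <- pop_map$population[match(samples, pop_map$sample)]
  pops <- pops %||% unique(sample_pop)

  chrom <- fix[, "CHROM"]
  pos <- as.numeric(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  aa <- extract_aa(v)

  # biallelic SNPs only: single-base REF and a single single-base ALT
  snp <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")

  unphased <- grep("/", gt, fixed = TRUE)
  if (length(unphased)) {
    bad <- arrayInd(unphased[1], dim(gt))
    abort(sprintf(
      "unphased genotype at %s:%s (sample %s); phased '|' genotypes required",
      chrom[bad[1]], format(pos[bad[1]], scientific = FALSE), samples[bad[2]]
    ))
  }

  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  hap <- matrix(NA_integer_, nrow = nrow(gt), ncol = 2L * ncol(gt))
  hap[, seq(1L, 2L * ncol(gt), by = 2L)] <- suppressWarnings(as.integer(a1))
  hap[, seq(2L, 2L * ncol(gt), by = 2L)] <- suppressWarnings(as.integer(a2))
  hap_pop <- rep(sample_pop, each = 2L)

  # drop sites with missing alleles in any participating population
  part <- hap_pop %in% pops
  complete <- rowSums(is.na(hap[, part, drop = FALSE])) == 0L
  keep <- snp & complete

  # polarize: AA matching ALT flips the site, AA matching REF keeps it,
  # anything else falls back to REF-as-ancestral and is flagged
  aa_up <- toupper(aa)
  flip <- !is.na(aa_up) & aa_up == alt
  annotated <- !is.na(aa_up) & (aa_up == ref | aa_up == alt)
  out <- list()
  for (ch in unique(chrom[keep])) {
    rows <- which(keep & chrom == ch)
    m <- hap[rows, , drop = FALSE]
    fl <- flip[rows]
    m[fl, ] <- 1L - m[fl, ]
    anc <- ifelse(fl, alt[rows], ref[rows])
    der <- ifelse(fl, ref[rows], alt[rows])
    # MAF filter on derived frequency per participating population
    ok <- rep(TRUE, length(rows))
    for (p in pops) {
      cols <- hap_pop == p
      f <- rowMeans(m[, cols, drop = FALSE])
      ok <- ok & (pmin(f, 1 - f) >= maf_min - 1e-9)
    }
    if (!any(ok)) next
    rows2 <- rows[ok]
    o <- order(pos[rows2])
    rows2 <- rows2[o]
    out[[ch]] <- hap_matrix(
      chrom = ch,
      positions = pos[rows2],
      alleles = m[ok, , drop = FALSE][o, , drop = FALSE],
      hap_pop = hap_pop,
      site_meta = tibble(
        ref = ref[rows2],
        alt = alt[rows2],
        ancestral = anc[ok][o],
        derived = der[ok][o],
        aa_source = ifelse(annotated[rows2], "annotated", "ref_fallback")
      )
    )
  }
  if (!length(out)) {
    abort("no sites left after biallelic-SNP, completeness and MAF filtering")
  }
  if (length(out) == 1L) out[[1L]] else out
}

extract_aa <- function(v) {
  info <- v@fix[, "INFO"]
  aa <- rep(NA_character_, length(info))
  has <- grepl("(?:^|;)AA=", info)
  aa[has] <- sub(".*?AA=([^;|]+).*", "\\1", info[has])
  aa
}

#' Write a haplotype matrix (or list of them) to a phased VCF
#'
#' Emits VCF v4.2 with phased diploid genotypes and an `AA` INFO tag giving
#' the ancestral allele for every site. Haplotype columns `2i-1` and `2i`
#' become the two alleles of sample `i`.
#'
#' @param hm a [hap_matrix()] or a named list of them (multi-chromosome).
#' @param path output file path.
#' @param sample_names optional sample names; derived from population labels
#'   when omitted.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(hm, path, sample_names = NULL) {
  hms <- if (inherits(hm, "hap_matrix")) list(hm) else hm
  n_hap <- n_haps(hms[[1]])
  if (n_hap %% 2L != 0L) abort("haplotype count must be even to write diploid VCF")
  n_ind <- n_hap %/% 2L
  hap_pop <- hms[[1]]$hap_pop
  if (is.null(sample_names)) {
    ind_pop <- hap_pop[seq(1L, n_hap, by = 2L)]
    sample_names <- paste0(ind_pop, "_", stats::ave(ind_pop, ind_pop, FUN = seq_along))
  }
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t")
  )
  body <- purrr::map(hms, function(h) {
    sm <- h$site_meta
    anc <- sm$ancestral %||% sm$ref
    gt1 <- h$alleles[, seq(1L, n_hap, by = 2L), drop = FALSE]
    gt2 <- h$alleles[, seq(2L, n_hap, by = 2L), drop = FALSE]
    gt <- matrix(paste0(gt1, "|", gt2), nrow = n_sites(h))
    # allele 0 is ancestral by construction, so REF gets the ancestral base
    # and ALT the derived base regardless of how the site was read
    ref <- anc
    alt <- sm$derived %||% sm$alt
    paste(
      h$chrom, format(h$positions, scientific = FALSE, trim = TRUE), ".",
      ref, alt, ".", "PASS", paste0("AA=", anc), "GT",
      apply(gt, 1L, paste, collapse = "\t"),
      sep = "\t"
    )
  })
  writeLines(c(lines, unlist(body)), path)
  invisible(path)
}

#' Write per-site metadata (positions, alleles, frequencies) to TSV
#'
#' @param hm a [hap_matrix()].
#' @param path output TSV path.
#' @return the tibble written, invisibly.
#' @export
write_site_meta <- function(hm, path) {
  stopifnot(inherits(hm, "hap_matrix"))
  tbl <- tibble(
    chrom = hm$chrom,
    pos = hm$positions,
    ref = hm$site_meta$ref,
    alt = hm$site_meta$alt,
    aa_source = hm$site_meta$aa_source
  )
  for (p in populations(hm)) {
    tbl[[paste0("freq_", p)]] <- rowMeans(hm$alleles[, hm$hap_pop == p, drop = FALSE])
  }
  readr::write_tsv(tbl, path)
  invisible(tbl)
}
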