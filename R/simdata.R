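#' Configuration for the synthetic haplotype generator
#'
#' The generator emulates the statistical structure the scans assume:
#' phased haplotypes for two or more populations diverged by neutral drift
#' (Balding-Nichols allele frequencies around a shared ancestral
#' frequency), linkage that decays with physical distance (a founder-mosaic
#' copying process), an allele-frequency spectrum with sites on both sides
#' of the 5% MAF bound, truthful ancestral-allele annotation, exon
#' annotations with 5'UTR/CDS/3'UTR and non-coding-exon structure, and
#' planted hard sweeps that produce long shared haplotypes around a core
#' SNP.
#'
#' @param seed integer; fully determines all outputs.
#' @param populations named integer vector of diploid sample sizes.
#' @param n_chrom number of chromosomes.
#' @param n_sites segregating sites per chromosome.
#' @param chrom_length_bp chromosome length in bp.
#' @param divergence_F Balding-Nichols drift parameter, one value or one
#'   per population.
#' @param freq_range ancestral-frequency truncation bounds; the density is
#'   proportional to 1/x on this interval (a neutral-like spectrum).
#' @param n_founders founder haplotypes per population for the mosaic.
#' @param recomb_rate founder-switch (crossover) rate per bp per haplotype.
#' @param mut_rate private-mutation rate per bp per haplotype.
#' @param sweeps either an integer (number of sweeps to auto-place in
#'   exons) or a tibble with columns `chrom`, `pos`, `pop`, `freq`,
#'   `strength`.
#' @param sweep_freq,sweep_strength defaults used for auto-placed sweeps:
#'   final derived frequency at the core, and the shared-segment length
#'   parameter in (0, 1] (per-carrier segment length is exponential with
#'   mean `sweep_strength * chrom_length_bp`; at 1 the segment is the whole
#'   chromosome).
#' @param sweep_chroms chromosomes eligible for auto-placed sweeps
#'   (default: all).
#' @param n_genes genes per chromosome (80% protein-coding with
#'   5'UTR/CDS/3'UTR exons, 20% non-coding).
#' @param focal_set_size size of the focal gene set.
#' @param focal_enrichment fraction of sweeps targeted at focal genes; the
#'   remainder are placed uniformly over all genes, so 0 means background
#'   (uniform) placement.
#' @param sweep_margin auto-placed sweep cores stay at least this fraction
#'   of the chromosome length away from either end, so their haplotype
#'   footprint is observable on both sides.
#' @param sweep_min_gap minimum distance between auto-placed cores on the
#'   same chromosome, as a fraction of its length; keeps planted sweeps
#'   from overwriting each other's shared segments.
#' @param sweep_core_freq_range ancestral-frequency range for sweep core
#'   sites (drawn uniformly). Mid-range cores stay above the MAF bound in
#'   the unswept populations, so a planted sweep is analyzable by the
#'   cross-population statistics rather than invisible to them.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       populations = c(P1 = 50L, P2 = 50L),
                       n_chrom = 1L,
                       n_sites = 1500L,
                       chrom_length_bp = 1.5e6,
                       divergence_F = 0.05,
                       freq_range = c(0.05, 0.95),
                       n_founders = 100L,
                       recomb_rate = 3e-6,
                       mut_rate = 3e-5,
                       sweeps = 0L,
                       sweep_freq = 0.85,
                       sweep_strength = 0.05,
                       sweep_chroms = NULL,
                       n_genes = 40L,
                       focal_set_size = 15L,
                       focal_enrichment = 0.5,
                       sweep_margin = 0.1,
                       sweep_min_gap = 0.25,
                       sweep_core_freq_range = c(0.2, 0.4)) {
  if (is.null(names(populations)) || any(!nzchar(names(populations)))) {
    abort("`populations` must be a named vector of diploid sample sizes")
  }
  if (length(divergence_F) == 1L) {
    divergence_F <- setNames(rep(divergence_F, length(populations)), names(populations))
  }
  if (n_sites > chrom_length_bp) abort("more sites than base pairs")
  cfg <- list(
    seed = as.integer(seed), populations = populations, n_chrom = as.integer(n_chrom),
    n_sites = as.integer(n_sites), chrom_length_bp = chrom_length_bp,
    divergence_F = divergence_F, freq_range = freq_range,
    n_founders = as.integer(n_founders), recomb_rate = recomb_rate,
    mut_rate = mut_rate, sweeps = sweeps, sweep_freq = sweep_freq,
    sweep_strength = sweep_strength, sweep_chroms = sweep_chroms,
    n_genes = as.integer(n_genes), focal_set_size = as.integer(focal_set_size),
    focal_enrichment = focal_enrichment, sweep_margin = sweep_margin,
    sweep_min_gap = sweep_min_gap, sweep_core_freq_range = sweep_core_freq_range
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Standard seeded sweep-recovery fixture configuration
#'
#' The panel configuration used throughout the test suite and worked
#' examples: two populations of 50 diploids, five 1.5-Mb chromosomes of
#' 1500 SNPs, and two planted hard sweeps (one per population, derived
#' frequency 0.85) confined to chromosome 1, leaving four neutral
#' chromosomes for false-positive measurement. The sweep footprint is
#' compact (mean shared segment 2% of the chromosome per side) so that at
#' this genome size the top-1% window quota is not saturated by a single
#' sweep's own hitchhikers.
#'
#' @param seed integer seed.
#' @param sweeps number of sweeps to place on chromosome 1.
#' @param focal_enrichment fraction of sweeps targeted at focal genes.
#' @return a [sim_config()].
#' @export
sim_config_fixture <- function(seed = 1L, sweeps = 2L, focal_enrichment = 0.5) {
  sim_config(
    seed = seed, sweeps = sweeps, n_chrom = 5L, sweep_chroms = "1",
    populations = c(P1 = 50L, P2 = 50L), n_founders = 100L, mut_rate = 3e-5,
    sweep_freq = 0.85, sweep_strength = 0.02,
    focal_enrichment = focal_enrichment
  )
}

#' Simulate a multi-population haplotype panel with planted sweeps
#'
#' Runs the whole generator under one seed: gene annotation, focal set,
#' sweep placement, neutral Balding-Nichols/founder-mosaic haplotypes per
#' chromosome, then sweep imposition. Ancestral alleles are always known
#' truthfully (allele 0 is ancestral by construction).
#'
#' @param cfg a [sim_config()].
#' @return a `hap_panel`: list with `haps` (named list of [hap_matrix()]
#'   per chromosome), `annotation`, `focal_genes`, `truth` (tibbles
#'   `sweeps` and `genes`), and `config`.
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  chroms <- as.character(seq_len(cfg$n_chrom))
  annotation <- sim_annotation(chroms, cfg$chrom_length_bp, cfg$n_genes)
  gene_ids <- unique(annotation$gene_id)
  focal_genes <- sort(sample(gene_ids, min(cfg$focal_set_size, length(gene_ids))))
  sweeps <- plan_sweeps(cfg, annotation, focal_genes)
  haps <- list()
  for (ch in chroms) {
    hm <- sim_chromosome(cfg, ch, sweeps[sweeps$chrom == ch, , drop = FALSE])
    haps[[ch]] <- hm
  }
  swept_genes <- gene_hits(sweeps, annotation)
  truth_genes <- tibble(
    gene_id = gene_ids,
    focal = gene_ids %in% focal_genes,
    swept = gene_ids %in% swept_genes
  )
  structure(
    list(
      haps = haps,
      annotation = annotation,
      focal_genes = focal_genes,
      truth = list(sweeps = sweeps, genes = truth_genes),
      config = cfg
    ),
    class = "hap_panel"
  )
}

#' @export
print.hap_panel <- function(x, ...) {
  cat(sprintf(
    "<hap_panel> %d chromosome(s), %d genes, %d focal, %d sweep(s), seed %d\n",
    length(x$haps), nrow(x$truth$genes), length(x$focal_genes),
    nrow(x$truth$sweeps), x$config$seed
  ))
  invisible(x)
}

# Tiled gene models: each gene occupies the middle of its slot; coding
# genes get 5'UTR / three CDS exons / 3'UTR, non-coding genes three plain
# exons. Coordinates 1-based inclusive.
sim_annotation <- function(chroms, len, n_genes) {
  parts <- purrr::map(chroms, function(ch) {
    slot <- len / n_genes
    purrr::map(seq_len(n_genes), function(i) {
      gs <- floor((i - 1) * slot + 0.15 * slot) + 1
      gl <- floor(0.7 * slot)
      coding <- (i %% 5L) != 0L  # every fifth gene is non-coding
      at <- function(f1, f2) c(floor(gs + f1 * gl), floor(gs + f2 * gl))
      gene <- sprintf("G%s_%03d", ch, i)
      if (coding) {
        iv <- rbind(
          c(at(0.00, 0.08), 1),  # FIVE_UTR
          c(at(0.10, 0.25), 2),  # CDS
          c(at(0.40, 0.55), 2),
          c(at(0.70, 0.85), 2),
          c(at(0.90, 1.00), 3)   # THREE_UTR
        )
        cls <- c("FIVE_UTR", "CDS", "THREE_UTR")[iv[, 3]]
      } else {
        iv <- rbind(
          c(at(0.00, 0.20), 4),
          c(at(0.40, 0.60), 4),
          c(at(0.80, 1.00), 4)
        )
        cls <- rep("NONCODING_EXON", 3)
      }
      tibble(
        gene_id = gene, gene_symbol = gene, chrom = ch,
        start = iv[, 1], end = iv[, 2], region_class = cls,
        strand = if (i %% 2L) "+" else "-"
      )
    }) |> bind_rows()
  })
  bind_rows(parts)
}

plan_sweeps <- function(cfg, annotation, focal_genes) {
  if (is.data.frame(cfg$sweeps)) {
    return(as_tibble(cfg$sweeps))
  }
  n_sw <- as.integer(cfg$sweeps)
  if (n_sw == 0L) {
    return(tibble(chrom = character(0), pos = numeric(0), pop = character(0),
                  freq = numeric(0), strength = numeric(0)))
  }
  ann <- annotation
  if (!is.null(cfg$sweep_chroms)) ann <- filter(ann, .data$chrom %in% cfg$sweep_chroms)
  if (nrow(ann) == 0L) abort("no genes on the sweep-eligible chromosomes")
  genes <- unique(ann$gene_id)
  focal_here <- intersect(genes, focal_genes)
  pops <- names(cfg$populations)
  len <- cfg$chrom_length_bp
  margin <- cfg$sweep_margin * len
  min_gap <- cfg$sweep_min_gap * len
  placed <- tibble(chrom = character(0), pos = numeric(0))
  # rejection-sample an exonic core away from chromosome ends and from
  # previously placed cores, so each sweep's footprint is distinct; a
  # targeted draw that cannot be placed in a focal gene falls back to the
  # whole gene pool
  draw_core <- function(pool) {
    for (try in 1:200) {
      g <- sample(pool, 1L)
      iv <- filter(ann, .data$gene_id == g)
      j <- sample.int(nrow(iv), 1L)
      pos <- floor(runif(1, iv$start[j], iv$end[j] + 1))
      ch <- iv$chrom[1]
      if (pos < margin || pos > len - margin) next
      same <- placed$pos[placed$chrom == ch]
      if (length(same) == 0L || min(abs(same - pos)) >= min_gap) {
        return(list(chrom = ch, pos = pos))
      }
    }
    NULL
  }
  rows <- purrr::map(seq_len(n_sw), function(i) {
    targeted <- length(focal_here) > 0 && runif(1) < cfg$focal_enrichment
    core <- if (targeted) draw_core(focal_here) else NULL
    core <- core %||% draw_core(genes)
    if (is.null(core)) abort("could not place sweeps with the configured spacing")
    placed <<- bind_rows(placed, tibble(chrom = core$chrom, pos = core$pos))
    tibble(
      chrom = core$chrom, pos = core$pos,
      pop = pops[(i - 1L) %% length(pops) + 1L],
      freq = cfg$sweep_freq, strength = cfg$sweep_strength
    )
  })
  bind_rows(rows)
}

gene_hits <- function(sweeps, annotation) {
  if (nrow(sweeps) == 0L) return(character(0))
  hits <- purrr::map(seq_len(nrow(sweeps)), function(i) {
    annotation |>
      filter(.data$chrom == sweeps$chrom[i],
             .data$start <= sweeps$pos[i], .data$end >= sweeps$pos[i]) |>
      pull("gene_id")
  })
  unique(unlist(hits))
}

# One chromosome: Balding-Nichols frequencies + founder-mosaic haplotypes,
# then sweep imposition.
sim_chromosome <- function(cfg, chrom, sweeps) {
  len <- cfg$chrom_length_bp
  n <- cfg$n_sites
  sweep_pos <- sweeps$pos
  avail <- setdiff(seq_len(len), sweep_pos)
  positions <- sort(c(sample(avail, n - length(sweep_pos)), sweep_pos))
  lo <- cfg$freq_range[1]
  hi <- cfg$freq_range[2]
  p0 <- lo * (hi / lo)^runif(n)  # density proportional to 1/x on [lo, hi]
  if (nrow(sweeps)) {
    core_idx <- match(sweeps$pos, positions)
    p0[core_idx] <- runif(nrow(sweeps), cfg$sweep_core_freq_range[1],
                          cfg$sweep_core_freq_range[2])
  }
  mats <- list()
  pops <- names(cfg$populations)
  for (p in pops) {
    f <- cfg$divergence_F[[p]]
    pp <- if (f <= 1e-9) p0 else {
      rbeta(n, p0 * (1 - f) / f, (1 - p0) * (1 - f) / f)
    }
    k <- cfg$n_founders
    founders <- matrix(rbinom(n * k, 1L, rep(pp, k)), nrow = n, ncol = k)
    n_hap <- 2L * cfg$populations[[p]]
    mat <- matrix(0L, nrow = n, ncol = n_hap)
    for (h in seq_len(n_hap)) {
      ncx <- rpois(1, cfg$recomb_rate * len)
      bp <- sort(runif(ncx, 1, len))
      seg <- findInterval(positions, bp) + 1L
      fid <- sample.int(k, ncx + 1L, replace = TRUE)
      hap <- founders[cbind(seq_len(n), fid[seg])]
      nm <- rpois(1, cfg$mut_rate * len)
      if (nm > 0) {
        flip <- sample.int(n, min(nm, n))
        hap[flip] <- 1L - hap[flip]
      }
      mat[, h] <- hap
    }
    mats[[p]] <- mat
  }
  alleles <- do.call(cbind, mats)
  hap_pop <- rep(pops, times = 2L * unlist(cfg$populations))
  bases <- c("A", "C", "G", "T")
  anc_base <- sample(bases, n, replace = TRUE)
  der_base <- vapply(anc_base, function(b) sample(setdiff(bases, b), 1L), character(1))
  hm <- hap_matrix(
    chrom = chrom, positions = positions, alleles = alleles, hap_pop = hap_pop,
    site_meta = tibble(ref = anc_base, alt = der_base, ancestral = anc_base,
                       derived = der_base, aa_source = "annotated")
  )
  for (i in seq_len(nrow(sweeps))) {
    hm <- impose_sweep(hm, pop = sweeps$pop[i], core_pos = sweeps$pos[i],
                       freq = sweeps$freq[i], strength = sweeps$strength[i],
                       mut_rate = cfg$mut_rate)
  }
  hm
}

#' Plant a hard sweep at a core SNP
#'
#' Rewrites the derived-allele carriers of the core site (within one
#' population) as copies of a single donor haplotype over a surrounding
#' segment, producing the long shared haplotypes a recent sweep leaves.
#' Each carrier's segment extends left and right by independent
#' exponential lengths with mean `strength * chrom_length`; `strength >= 1`
#' copies the whole chromosome. Private mutations are re-applied inside
#' the copied segment at `mut_rate`. The derived frequency at the core is
#' set to `freq` (carriers drawn at random); haplotypes of other
#' populations are untouched.
#'
#' Uses the current RNG stream (seed it for reproducibility).
#'
#' @param hm a [hap_matrix()].
#' @param pop swept population.
#' @param core_pos core SNP position (must be a panel position).
#' @param freq target derived frequency at the core in `pop`.
#' @param strength shared-segment length parameter in (0, 1].
#' @param mut_rate private-mutation rate per bp per haplotype.
#' @return the modified `hap_matrix`.
#' @export
impose_sweep <- function(hm, pop, core_pos, freq, strength, mut_rate = 1e-5) {
  stopifnot(inherits(hm, "hap_matrix"))
  core <- match(core_pos, hm$positions)
  if (is.na(core)) abort(sprintf("core position %s is not a panel site", core_pos))
  cols <- which(hm$hap_pop == pop)
  if (!length(cols)) abort(sprintf("unknown population: %s", pop))
  n_car <- round(freq * length(cols))
  if (n_car < 2L) abort("target frequency implies fewer than 2 carrier haplotypes")
  carriers <- sample(cols, n_car)
  donor <- hm$alleles[, carriers[1L]]
  len <- max(hm$positions)
  for (h in carriers) {
    if (strength >= 1) {
      lo <- -Inf
      hi <- Inf
    } else {
      lo <- core_pos - rexp(1, rate = 1 / (strength * len))
      hi <- core_pos + rexp(1, rate = 1 / (strength * len))
    }
    w <- which(hm$positions >= lo & hm$positions <= hi)
    hm$alleles[w, h] <- donor[w]
    nm <- rpois(1, mut_rate * (min(hi, len) - max(lo, 1)))
    if (nm > 0 && length(w) > 1L) {
      flip <- sample(setdiff(w, core), min(nm, length(w) - 1L))
      hm$alleles[flip, h] <- 1L - hm$alleles[flip, h]
    }
  }
  hm$alleles[core, cols] <- 0L
  hm$alleles[core, carriers] <- 1L
  hm
}

#' Write a simulated panel to standard files
#'
#' Emits a phased VCF v4.2 (all chromosomes, `AA` INFO tag), a GFF3 exon
#' annotation, a focal gene list TSV, a sample-to-population TSV and the
#' truth tables.
#'
#' @param panel a `hap_panel` from [simulate_panel()].
#' @param dir output directory (created if needed).
#' @return named list of file paths, invisibly.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "hap_panel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    vcf = file.path(dir, "panel.vcf"),
    gff3 = file.path(dir, "annotation.gff3"),
    focal = file.path(dir, "focal_genes.tsv"),
    pop_map = file.path(dir, "pop_map.tsv"),
    truth_sweeps = file.path(dir, "truth_sweeps.tsv"),
    truth_genes = file.path(dir, "truth_genes.tsv")
  )
  write_phased_vcf(panel$haps, paths$vcf)
  write_gff3(panel$annotation, paths$gff3)
  readr::write_tsv(tibble(gene_id = panel$focal_genes), paths$focal,
                   col_names = FALSE)
  hm1 <- panel$haps[[1]]
  n_hap <- n_haps(hm1)
  ind_pop <- hm1$hap_pop[seq(1L, n_hap, by = 2L)]
  readr::write_tsv(
    tibble(sample = paste0(ind_pop, "_", stats::ave(ind_pop, ind_pop, FUN = seq_along)),
           population = ind_pop),
    paths$pop_map, col_names = FALSE
  )
  readr::write_tsv(panel$truth$sweeps, paths$truth_sweeps)
  readr::write_tsv(panel$truth$genes, paths$truth_genes)
  invisible(paths)
}

write_gff3 <- function(annotation, path) {
  type <- dplyr::case_match(
    annotation$region_class,
    "FIVE_UTR" ~ "five_prime_UTR",
    "THREE_UTR" ~ "three_prime_UTR",
    "CDS" ~ "CDS",
    "NONCODING_EXON" ~ "exon"
  )
  biotype <- ifelse(annotation$region_class == "NONCODING_EXON",
                    "noncoding", "protein_coding")
  lines <- paste(
    annotation$chrom, "haploscan", type,
    annotation$start, annotation$end, ".", annotation$strand, ".",
    sprintf("ID=%s.%d;gene_id=%s;gene_name=%s;biotype=%s",
            annotation$gene_id, seq_len(nrow(annotation)),
            annotation$gene_id, annotation$gene_symbol, biotype),
    sep = "\t"
  )
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
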