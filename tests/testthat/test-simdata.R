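test_that("the generator is fully deterministic under a seed", {
  cfg <- sim_config(seed = 21, sweeps = 1L, n_sites = 400)
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1$haps[[1]]$alleles, p2$haps[[1]]$alleles)
  expect_identical(p1$truth, p2$truth)
  f1 <- tempfile(fileext = ".vcf")
  f2 <- tempfile(fileext = ".vcf")
  write_phased_vcf(p1$haps, f1)
  write_phased_vcf(p2$haps, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("Balding-Nichols drift is mean-preserving around the ancestral frequency", {
  # frequency model isolated: no private mutations
  cfg <- sim_config(seed = 22, n_sites = 2000, divergence_F = 0.15,
                    mut_rate = 0, populations = c(P1 = 60L, P2 = 60L))
  panel <- simulate_panel(cfg)
  hm <- panel$haps[[1]]
  f1 <- rowMeans(hm$alleles[, hm$hap_pop == "P1", drop = FALSE])
  f2 <- rowMeans(hm$alleles[, hm$hap_pop == "P2", drop = FALSE])
  # both populations drift around the same ancestral frequency, so the
  # per-site difference has mean zero
  d <- f1 - f2
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)))
  # and the overall mean matches the 1/x spectrum mean (hi-lo)/log(hi/lo)
  lo <- cfg$freq_range[1]; hi <- cfg$freq_range[2]
  expected <- (hi - lo) / log(hi / lo)
  for (f in list(f1, f2)) {
    expect_lt(abs(mean(f) - expected), 3 * sd(f) / sqrt(length(f)))
  }
})

test_that("the F -> 0 limit removes population differentiation", {
  cfg <- sim_config(seed = 23, divergence_F = 0, n_sites = 800, mut_rate = 0)
  panel <- simulate_panel(cfg)
  fst <- fst_scan(panel$haps[[1]], "P1", "P2")$fst
  expect_lt(abs(mean(fst, na.rm = TRUE)), 0.01)
})

test_that("a strength-1 sweep makes carriers identical and EHH stays at 1", {
  cfg <- sim_config(seed = 24, n_sites = 600, mut_rate = 0)
  panel <- simulate_panel(cfg)
  hm <- panel$haps[[1]]
  core <- 300
  hm2 <- impose_sweep(hm, "P1", core_pos = hm$positions[core], freq = 0.8,
                      strength = 1, mut_rate = 0)
  carriers <- which(hm2$alleles[core, ] == 1L & hm2$hap_pop == "P1")
  expect_equal(length(carriers), round(0.8 * sum(hm2$hap_pop == "P1")))
  ref <- hm2$alleles[, carriers[1]]
  for (h in carriers[-1]) {
    same <- hm2$alleles[, h] == ref
    same[core] <- TRUE
    expect_true(all(same))
  }
  expect_equal(ehh_step(hm2, carriers, 1:n_sites(hm2)), 1)
  # derived frequency at the core hits the target; other population untouched
  expect_equal(mean(hm2$alleles[core, hm2$hap_pop == "P1"]), 0.8)
  expect_equal(hm2$alleles[, hm2$hap_pop == "P2"],
               hm$alleles[, hm$hap_pop == "P2"])
  expect_error(impose_sweep(hm, "P1", hm$positions[10], freq = 0.005,
                            strength = 0.5),
               "fewer than 2")
})

test_that("a vanishing sweep strength leaves the panel essentially neutral", {
  cfg <- sim_config(seed = 25, n_sites = 600)
  panel <- simulate_panel(cfg)
  hm <- panel$haps[[1]]
  core <- 300
  hm2 <- impose_sweep(hm, "P1", hm$positions[core], freq = 0.5,
                      strength = 1e-9, mut_rate = 0)
  # only the core row may change
  changed <- which(rowSums(hm2$alleles != hm$alleles) > 0)
  expect_true(all(changed %in% core))
})

test_that("planted sweep cores carry extreme standardized iHS", {
  hits <- vapply(1:8, function(seed) {
    panel <- fixture_panel(seed = seed)
    sw <- panel$truth$sweeps
    tr1 <- ihs_scan(panel$haps, "P1")
    tr2 <- ihs_scan(panel$haps, "P2")
    z <- c(tr1$std[tr1$pos %in% sw$pos[sw$pop == "P1"] & tr1$chrom == "1"],
           tr2$std[tr2$pos %in% sw$pos[sw$pop == "P2"] & tr2$chrom == "1"])
    mean(abs(z) > 2, na.rm = TRUE)
  }, numeric(1))
  expect_gte(mean(hits), 0.8)
})

test_that("the simulated MAF spectrum straddles the 5% filter bound", {
  panel <- fixture_panel()
  hm <- panel$haps[[2]]
  for (p in populations(hm)) {
    f <- rowMeans(hm$alleles[, hm$hap_pop == p, drop = FALSE])
    maf <- pmin(f, 1 - f)
    expect_gt(sum(maf < 0.05), 10)
    expect_gt(sum(maf >= 0.05), 100)
  }
})

test_that("written outputs are consistent with the truth tables and round-trip", {
  panel <- fixture_panel()
  dir <- tempfile()
  paths <- write_panel(panel, dir)
  expect_true(all(file.exists(unlist(paths))))
  # every sweep core position appears in the VCF
  vcf_lines <- readLines(paths$vcf)
  body <- vcf_lines[!startsWith(vcf_lines, "#")]
  pos_by_chrom <- split(
    as.numeric(vapply(strsplit(body, "\t"), `[`, character(1), 2)),
    vapply(strsplit(body, "\t"), `[`, character(1), 1)
  )
  sw <- panel$truth$sweeps
  for (i in seq_len(nrow(sw))) {
    expect_true(sw$pos[i] %in% pos_by_chrom[[sw$chrom[i]]])
  }
  # truth gene flags agree with sweep-in-exon geometry
  ann <- read_gene_annotation(paths$gff3, format = "gff3")
  swept <- unique(unlist(lapply(seq_len(nrow(sw)), function(i) {
    ann$gene_id[ann$chrom == sw$chrom[i] & ann$start <= sw$pos[i] &
                  ann$end >= sw$pos[i]]
  })))
  truth <- panel$truth$genes
  expect_setequal(truth$gene_id[truth$swept], swept)
  # focal list round-trips
  expect_equal(read_focal_genes(paths$focal, universe = truth$gene_id),
               panel$focal_genes)
})

test_that("uniform sweep placement hits focal genes at the background rate", {
  # focal_enrichment 0 places sweeps uniformly over genes; across seeds the
  # focal-hit count behaves like Binomial(n, focal share)
  hits <- 0L
  total <- 0L
  for (seed in 1:15) {
    panel <- simulate_panel(sim_config_fixture(seed = seed, sweeps = 2L,
                                               focal_enrichment = 0))
    tg <- panel$truth$genes
    hits <- hits + sum(tg$focal & tg$swept)
    total <- total + nrow(panel$truth$sweeps)
  }
  share <- 15 / 200  # focal genes / all genes
  ci <- qbinom(c(0.0005, 0.9995), total, share)
  expect_gte(hits, ci[1])
  expect_lte(hits, ci[2])
})
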