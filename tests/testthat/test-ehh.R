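test_that("ehh_step matches hand-enumerated pair counts", {
  # 4 carriers, one extension site with alleles {0,0,0,1}:
  # identical pairs C(3,2) = 3 of C(4,2) = 6
  hm <- make_hm(c("10", "10", "10", "11"))
  expect_equal(ehh_step(hm, 1:4, 1:2), 0.5)
  # two-site extensions {00, 00, 01, 11}: one identical pair of six
  hm2 <- make_hm(c("100", "100", "101", "111"))
  expect_equal(ehh_step(hm2, 1:4, 1:3), 1 / 6)
  # interval = core only: all carriers share the core allele
  expect_equal(ehh_step(hm2, 1:4, 1), 1)
  expect_error(ehh_step(hm2, 1, 1), "at least 2")
})

test_that("ehh_step equals the pair-enumeration oracle on random small panels", {
  set.seed(101)
  for (rep in 1:150) {
    n_hap <- sample(3:8, 1)
    n_site <- sample(2:10, 1)
    mat <- matrix(rbinom(n_hap * n_site, 1, runif(1, 0.2, 0.8)), nrow = n_site)
    hm <- hap_matrix("1", seq_len(n_site) * 500, mat, rep("P1", n_hap))
    carriers <- sample(n_hap, sample(2:n_hap, 1))
    interval <- sort(sample(n_site, sample(1:n_site, 1)))
    expect_equal(ehh_step(hm, carriers, interval),
                 oracle_ehh(mat, carriers, interval))
  }
})

test_that("EHH is non-increasing as the interval extends", {
  set.seed(102)
  for (rep in 1:20) {
    mat <- matrix(rbinom(80, 1, 0.5), nrow = 10)
    hm <- hap_matrix("1", 1:10 * 1000, mat, rep("P1", 8))
    vals <- vapply(1:10, function(j) ehh_step(hm, 1:8, 1:j), numeric(1))
    expect_true(all(diff(vals) <= 1e-12))
  }
})

test_that("iHH integration follows the trapezoid-to-cutoff contract", {
  expect_equal(as.numeric(integrate_ihh(
    tibble::tibble(distance = c(0, 10000), ehh = c(1, 1)), cutoff = 0.05
  )), 10000)
  # 750 over the first leg, 270 into the below-cutoff point, then stop
  curve <- tibble::tibble(distance = c(0, 1000, 2000, 3000),
                          ehh = c(1, 0.5, 0.04, 0.04))
  expect_equal(as.numeric(integrate_ihh(curve, cutoff = 0.05)), 1020)
  expect_equal(as.numeric(integrate_ihh(
    tibble::tibble(distance = 0, ehh = 1), cutoff = 0.05
  )), 0)
})

test_that("decay curves start at (0,1), are non-increasing, and agree with ehh_step", {
  panel <- fixture_panel()
  hm <- hap_subset(panel$haps[[2]], pop = "P1")
  core <- 700
  cv <- ehh_curve(hm, core, allele = "derived", cutoff = 0.05)
  expect_equal(cv$distance[1], 0)
  expect_equal(cv$ehh[1], 1)
  expect_true(all(diff(cv$ehh) <= 1e-12))
  # each curve point equals a direct pair-count over the same interval
  carriers <- which(hm$alleles[core, ] == 1L)
  for (i in 2:min(5, nrow(cv))) {
    j <- core + which(hm$positions[(core + 1):n_sites(hm)] - hm$positions[core] == cv$distance[i])
    expect_equal(cv$ehh[i], ehh_step(hm, carriers, core:j))
  }
})

test_that("iHS sign convention: long derived haplotypes give negative scores", {
  # ancestral carriers (cols 1-4) diverge immediately on both sides of the
  # core (row 5); derived carriers (cols 5-8) stay identical for two sites
  # before diverging, so iHH_D > iHH_A and ln(iHH_A / iHH_D) < 0
  distinct2 <- rbind(c(0, 0, 1, 1), c(0, 1, 0, 1))  # splits 4 haps fully
  zeros <- matrix(0L, 2, 4)
  anc <- rbind(distinct2[2:1, ], distinct2, c(0, 0, 0, 0), distinct2, distinct2[2:1, ])
  der <- rbind(distinct2[2:1, ], zeros, c(1, 1, 1, 1), zeros, distinct2[2:1, ])
  mat <- cbind(anc, der)
  storage.mode(mat) <- "integer"
  hm <- hap_matrix("1", seq_len(nrow(mat)) * 1000, mat, rep("P1", 8))
  score <- ihs_unstandardized(hm, "P1", 5, cutoff = 0.05)
  expect_true(is.finite(score) && score < 0)
})

test_that("symmetric panels give iHS of exactly zero", {
  # ancestral and derived carrier blocks with identical haplotype structure
  distinct2 <- rbind(c(0, 0, 1, 1), c(0, 1, 0, 1))
  blk <- rbind(distinct2[2:1, ], c(0, 0, 0, 0), distinct2)
  mat <- cbind(blk, blk)
  mat[3, ] <- c(rep(0, 4), rep(1, 4))  # the core
  storage.mode(mat) <- "integer"
  hm <- hap_matrix("1", seq_len(nrow(mat)) * 1000, mat, rep("P1", 8))
  score <- ihs_unstandardized(hm, "P1", 3, cutoff = 0.05)
  expect_equal(as.numeric(score), 0)
})

test_that("site-level iHS equals a from-first-principles enumeration on a toy panel", {
  # 8 haplotypes x 9 sites; carriers of each core allele thin out to all-
  # distinct within the panel so both decay curves hit zero before the ends
  split4a <- c(0, 0, 1, 1)
  split4b <- c(0, 1, 0, 1)
  anc <- rbind(0, split4a, split4b, split4b, 0, split4b, split4a, 0, 0)
  der <- rbind(0, split4a, split4b, 0, 1, 0, split4b, split4a, 0)
  mat <- cbind(anc, der)
  storage.mode(mat) <- "integer"
  hm <- hap_matrix("1", 1:9 * 1000, mat, rep("P1", 8))
  core <- 5
  score <- ihs_unstandardized(hm, "P1", core, cutoff = 0.05)
  # oracle: enumerate EHH at each extension, trapezoid by hand
  ihh_oracle <- function(carriers) {
    area <- 0
    for (dir in c(-1, 1)) {
      prev_e <- 1; prev_d <- 0
      j <- core + dir
      while (j >= 1 && j <= 9) {
        iv <- if (dir < 0) j:core else core:j
        e <- oracle_ehh(mat, carriers, iv)
        d <- abs(hm$positions[j] - hm$positions[core])
        area <- area + 0.5 * (prev_e + e) * (d - prev_d)
        if (e < 0.05) break
        prev_e <- e; prev_d <- d; j <- j + dir
      }
    }
    area
  }
  anc <- which(mat[core, ] == 0L)
  der <- which(mat[core, ] == 1L)
  expect_equal(as.numeric(score), log(ihh_oracle(anc) / ihh_oracle(der)))
})

test_that("iHS is antisymmetric under swapping the core's allele labels", {
  panel <- fixture_panel()
  hm <- panel$haps[[3]]
  set.seed(7)
  sites <- sample(200:1300, 6)
  for (s in sites) {
    a <- ihs_unstandardized(hm, "P1", s)
    flipped <- hm
    flipped$alleles[s, ] <- 1L - flipped$alleles[s, ]
    b <- ihs_unstandardized(flipped, "P1", s)
    if (is.na(a)) expect_true(is.na(b)) else expect_equal(as.numeric(a), -as.numeric(b))
  }
})

test_that("xpEHH is exactly antisymmetric in the population order and zero for identical panels", {
  panel <- fixture_panel()
  hm <- panel$haps[[1]]
  ab <- xpehh_scan(hm, "P1", "P2")
  ba <- xpehh_scan(hm, "P2", "P1")
  expect_equal(ab$unstd, -ba$unstd)
  expect_equal(ab$std, -ba$std)
  # identical haplotype panels in both populations -> all zeros
  sub <- hap_subset(hm, pop = "P1", sites = 400:520)
  twin <- hap_matrix(sub$chrom, sub$positions,
                     cbind(sub$alleles, sub$alleles),
                     rep(c("A", "B"), each = n_haps(sub)))
  tr <- xpehh_scan(twin, "A", "B")
  expect_true(all(is.na(tr$unstd) | tr$unstd == 0))
  expect_true(any(!is.na(tr$unstd)))
})

test_that("a homogeneous population scores positive xpEHH against a diverse one", {
  # population A shares one haplotype across a 40-site central block (and is
  # diverse outside it, so the pooled EHH can still decay to the cutoff);
  # population B is diverse everywhere
  set.seed(55)
  n_site <- 220
  div <- matrix(rbinom(n_site * 40, 1, 0.5), nrow = n_site)
  mono <- matrix(rbinom(n_site * 40, 1, 0.5), nrow = n_site)
  block <- 91:130
  mono[block, ] <- rbinom(length(block), 1, 0.5)
  core <- 110
  mono[core, ] <- 1L  # shared derived core in the homogeneous block
  hm <- hap_matrix("1", seq_len(n_site) * 1000, cbind(mono, div),
                   rep(c("A", "B"), each = 40))
  sc <- xpehh_unstandardized(hm, "A", "B", core)
  expect_true(is.finite(sc) && sc > 0)
})

test_that("standardization yields mean 0 / sample SD 1 within every retained bin", {
  # literal one-bin example
  tbl <- tibble::tibble(unstd = c(1, 2, 3), freq = c(0.5, 0.5, 0.5))
  out <- standardize_scores(tbl, n_bins = 10, min_bin_size = 1)
  expect_equal(out$std, c(-1, 0, 1))

  panel <- fixture_panel()
  tr <- ihs_scan(panel$haps, "P1")
  stats <- tr |>
    dplyr::filter(!is.na(.data$std)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(m = mean(std), s = sd(std), n = dplyr::n())
  expect_true(all(abs(stats$m) < 1e-9))
  expect_true(all(abs(stats$s - 1) < 1e-9))
  expect_true(all(stats$n >= 20))
  # NA propagates
  expect_equal(is.na(tr$std), is.na(tr$unstd))
  expect_error(standardize_scores(tibble::tibble(unstd = c(NA_real_, NA_real_),
                                                 freq = c(0.1, 0.2))),
               "all scores")
})

test_that("standardization preserves within-bin rank order", {
  panel <- fixture_panel()
  tr <- ihs_scan(panel$haps, "P2")
  by_bin <- split(tr[!is.na(tr$unstd), ], tr$bin[!is.na(tr$unstd)])
  for (b in by_bin) {
    expect_equal(order(b$unstd), order(b$std))
  }
})
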