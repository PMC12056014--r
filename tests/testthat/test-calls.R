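mk_track <- function(std, chrom = "1", pos = NULL, statistic = "iHS", pops = "P1") {
  tbl <- tibble::tibble(chrom = chrom, pos = pos %||% seq_along(std) * 1000,
                        std = std)
  attr(tbl, "statistic") <- statistic
  attr(tbl, "pops") <- pops
  class(tbl) <- c("score_track", class(tbl))
  tbl
}

test_that("window counts match the worked example and the brute-force recount", {
  tr <- mk_track(c(2.5, 1.0, 2.1, 0.0, 3.0))
  win <- window_extreme_counts(tr, window_size = 3, score_cut = 2)
  expect_equal(win$n_extreme, c(2L, 1L, 2L))          # ends excluded
  expect_equal(win$pos, c(2000, 3000, 4000))

  set.seed(41)
  std <- ifelse(runif(500) < 0.1, NA, rnorm(500, sd = 1.5))
  tr2 <- mk_track(std)
  win2 <- window_extreme_counts(tr2, window_size = 51, score_cut = 2)
  expect_equal(win2$n_extreme, oracle_window_counts(std, 51, 2))
})

test_that("all-NA tracks count zero and saturated tracks count the window size", {
  win <- window_extreme_counts(mk_track(rep(NA_real_, 200)), 51, 2)
  expect_true(all(win$n_extreme == 0L))
  win2 <- window_extreme_counts(mk_track(rep(5, 200)), 51, 2)
  expect_true(all(win2$n_extreme == 51L))
  expect_warning(window_extreme_counts(mk_track(rep(1, 10)), 51, 2),
                 "no windows")
})

test_that("the top-window threshold reproduces nearest-rank behaviour", {
  # ten clustered high-count windows among 1000: they are exactly the top 1%
  win <- tibble::tibble(chrom = "1", pos = 1:1000, center_site = 1:1000,
                        n_extreme = c(rep(0L, 990), rep(40L, 10)))
  cut <- top_window_cut(win, top_frac = 0.01)
  expect_equal(as.integer(cut), 40L)
  expect_equal(sum(attr(cut, "qualifies")), 10L)
  # uniform counts: brute-force the smallest qualifying threshold
  set.seed(42)
  win2 <- tibble::tibble(chrom = "1", pos = 1:3000, center_site = 1:3000,
                         n_extreme = sample(0:50, 3000, replace = TRUE))
  cut2 <- top_window_cut(win2, top_frac = 0.01)
  brute <- sort(win2$n_extreme, decreasing = TRUE)[ceiling(0.01 * nrow(win2))]
  while (mean(win2$n_extreme >= brute) > 0.01) brute <- brute + 1L
  expect_equal(as.integer(cut2), brute)
  # and the qualifying fraction never exceeds the nominal one
  expect_lte(mean(attr(cut2, "qualifies")), 0.01)
  # degenerate all-equal counts: documented tie behaviour, all qualify
  win3 <- tibble::tibble(chrom = "1", pos = 1:200, center_site = 1:200,
                         n_extreme = 7L)
  expect_warning(cut3 <- top_window_cut(win3), "same extreme count")
  expect_true(all(attr(cut3, "qualifies")))
  expect_error(top_window_cut(win3[1, ]), "at least 100")
})

test_that("candidate calls require the three-way conjunction", {
  # one extreme block (sites 61..121); probes sit at its centre, where the
  # centered 51-SNP window is saturated and certainly qualifies
  std <- c(rep(0, 60), rep(2.5, 61), rep(0, 380))
  std[90] <- 1.9
  tr <- mk_track(std)
  win <- window_extreme_counts(tr, window_size = 51, score_cut = 2)
  fst_pass <- tibble::tibble(chrom = "1", pos = tr$pos,
                             passes_threshold = tr$pos != 91000)
  cand <- call_candidates(tr, win, fst_pass, score_cut = 2, top_frac = 0.1)
  # site 90 (|score| 1.9) sits inside qualifying windows but fails the
  # site-level cut; site 91 passes score+window but fails the FST gate
  expect_true(89000 %in% cand$pos)
  expect_false(90000 %in% cand$pos)
  expect_false(91000 %in% cand$pos)
  expect_true(92000 %in% cand$pos)
  # a window outside the qualifying set blocks an extreme isolated site:
  # the block's flanks fail the window rule even with perfect FST
  expect_false(61000 %in% cand$pos)
  # alignment error when an FST record is missing
  expect_error(call_candidates(tr, win, fst_pass[-10, ], score_cut = 2,
                               top_frac = 0.1),
               "no aligned FST record")
})

test_that("raising the score cut never adds candidates", {
  panel <- fixture_panel()
  tr <- ihs_scan(panel$haps, "P1")
  win <- window_extreme_counts(tr)
  fst_pass <- tibble::tibble(chrom = tr$chrom, pos = tr$pos,
                             passes_threshold = TRUE)
  lower <- call_candidates(tr, win, fst_pass, score_cut = 2)
  higher <- call_candidates(tr, win, fst_pass, score_cut = 2.5)
  expect_true(all(paste(higher$chrom, higher$pos) %in% paste(lower$chrom, lower$pos)))
})

test_that("exon mapping keeps only exonic candidates with CDS-first precedence", {
  ann <- tibble::tibble(
    gene_id = c("G", "G", "H"),
    gene_symbol = c("G", "G", "H"),
    chrom = "1",
    start = c(100, 100, 900),
    end = c(200, 150, 950),
    region_class = c("THREE_UTR", "CDS", "NONCODING_EXON"),
    strand = "+"
  )
  cand <- tibble::tibble(chrom = "1", pos = c(120, 180, 500, 920),
                         statistic = "iHS", pops = "P1", score = 3,
                         n_extreme = 40L, fst_pass = TRUE)
  mapped <- map_and_classify(cand, ann)
  expect_equal(mapped$pos, c(120, 180, 920))  # intergenic 500 dropped
  expect_equal(mapped$region_class[mapped$pos == 120], "CDS")     # precedence
  expect_equal(mapped$region_class[mapped$pos == 180], "THREE_UTR")
  expect_equal(mapped$gene_id[mapped$pos == 920], "H")
})

test_that("eQTL flags are strict at 0.9 and validate their input", {
  expect_true(eqtl_flag(0.95))
  expect_false(eqtl_flag(0.9))
  expect_false(eqtl_flag(0))
  expect_equal(eqtl_flag(c(0.91, 0.89)), c(TRUE, FALSE))
  expect_error(eqtl_flag(1.2), "\\[0, 1\\]")
})

test_that("eQTL m-values join onto candidates with strict-threshold flags", {
  mv <- readr::read_tsv(
    system.file("extdata", "synthetic_eqtl_mvalues.tsv", package = "haploscan"),
    show_col_types = FALSE
  )
  cand <- tibble::tibble(chrom = c("1", "2"), pos = c(120345, 88012),
                         gene_id = c("GA", "GB"))
  out <- add_eqtl_mvalues(cand, mv)
  expect_equal(nrow(out), 5L)  # one row per (candidate, tissue) record
  cortex <- out[out$pos == 120345 & out$tissue == "cortex", ]
  expect_true(cortex$eqtl_effect)
  blood <- out[out$pos == 120345 & out$tissue == "whole_blood", ]
  expect_false(blood$eqtl_effect)  # m exactly 0.9: the threshold is strict
})

test_that("region proportions cover all classes, sum to one, and match a recount", {
  cand <- tibble::tibble(region_class = c("CDS", "CDS", "THREE_UTR",
                                          "NONCODING_EXON"))
  props <- region_proportions(cand)
  expect_equal(sum(props$proportion), 1)
  expect_equal(props$proportion[props$region_class == "CDS"], 0.5)
  expect_equal(props$proportion[props$region_class == "FIVE_UTR"], 0)
  set.seed(43)
  cand2 <- tibble::tibble(
    region_class = sample(c("CDS", "FIVE_UTR", "THREE_UTR", "NONCODING_EXON"),
                          200, replace = TRUE)
  )
  props2 <- region_proportions(cand2)
  for (cl in props2$region_class) {
    expect_equal(props2$proportion[props2$region_class == cl],
                 sum(cand2$region_class == cl) / 200)
  }
  expect_error(region_proportions(cand2[0, ]), "no candidates")
})
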