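#' Count extreme scores in sliding SNP windows
#'
#' Slides a `window_size`-SNP window (odd, default 51) along each
#' chromosome of a score track and counts the sites with
#' `|standardized score| > score_cut` inside the window centered on each
#' site. Clustering of extreme scores is the hallmark of a sweep, so these
#' counts feed the top-window rule. Windows truncated at chromosome ends
#' are excluded (a center needs `(window_size - 1) / 2` flanking sites on
#' both sides); NA scores count as non-extreme.
#'
#' @param track a score track tibble (`chrom`, `pos`, `std`).
#' @param window_size odd window width in SNPs (default 51).
#' @param score_cut site-level |score| threshold (default 2).
#' @return tibble: `chrom`, `pos`, `center_site` (row index within the
#'   track), `n_extreme`.
#' @export
window_extreme_counts <- function(track, window_size = 51, score_cut = 2) {
  if (window_size %% 2L != 1L) abort("`window_size` must be odd")
  half <- (window_size - 1L) %/% 2L
  track <- mutate(track, .row = row_number())
  parts <- track |>
    group_by(.data$chrom) |>
    dplyr::group_map(function(g, key) {
      m <- nrow(g)
      if (m < window_size) {
        warn(sprintf("chromosome %s has %d scored sites (< window size %d); no windows",
                     key$chrom, m, window_size))
        return(NULL)
      }
      extreme <- as.integer(!is.na(g$std) & abs(g$std) > score_cut)
      counts <- as.integer(stats::filter(extreme, rep(1L, window_size), sides = 2))
      centers <- (half + 1L):(m - half)
      tibble(
        chrom = key$chrom,
        pos = g$pos[centers],
        center_site = g$.row[centers],
        n_extreme = counts[centers]
      )
    })
  out <- bind_rows(parts)
  if (nrow(out) == 0L) {
    out <- tibble(chrom = character(0), pos = numeric(0),
                  center_site = integer(0), n_extreme = integer(0))
  }
  out
}

#' Genome-wide top-fraction window count threshold
#'
#' Sort-and-count rule: the threshold starts at the count of the
#' `ceiling(top_frac * n)`-th largest window and is raised until at most a
#' `top_frac` fraction of windows reach it (ties at the boundary would
#' otherwise let more than the nominal fraction qualify). Windows qualify
#' iff their count reaches the threshold. Degenerate all-equal counts are
#' treated as all qualifying at that common count (with a warning), the
#' documented tie behaviour.
#'
#' @param windows tibble from [window_extreme_counts()] (>= 100 windows).
#' @param top_frac fraction of windows allowed to qualify (default 0.01).
#' @return integer threshold with attribute `qualifies`: logical vector
#'   aligned with `windows`.
#' @export
top_window_cut <- function(windows, top_frac = 0.01) {
  n <- nrow(windows)
  if (n < 100L) abort(sprintf("need at least 100 windows, got %d", n))
  counts <- windows$n_extreme
  if (length(unique(counts)) == 1L) {
    warn("all windows have the same extreme count; treating all as qualifying")
    cut <- counts[1L]
  } else {
    m <- max(1L, as.integer(ceiling(top_frac * n)))
    cut <- sort(counts, decreasing = TRUE)[m]
    while (mean(counts >= cut) > top_frac) cut <- cut + 1L
  }
  structure(as.integer(cut), qualifies = counts >= cut)
}

#' Composite candidate-variant calls
#'
#' A site is called a candidate iff all three conditions hold: its
#' `|standardized score| > score_cut`, the window centered on it qualifies
#' under the genome-wide top-fraction rule, and its FST passes the
#' frequency-binned threshold.
#'
#' @param track score track (`chrom`, `pos`, `std`).
#' @param windows output of [window_extreme_counts()].
#' @param fst either the flagged record table from
#'   [binned_fst_thresholds()] or any tibble with `chrom`, `pos`,
#'   `passes_threshold` (e.g. a precomputed multi-pair gate).
#' @param score_cut site-level |score| threshold (default 2).
#' @param top_frac window-qualification fraction (default 0.01).
#' @param allow_missing_fst if `FALSE` (default) a track site missing from
#'   `fst` is an alignment error; if `TRUE` missing sites simply fail the
#'   gate.
#' @return tibble of candidates: `chrom`, `pos`, `statistic`, `pops`,
#'   `score`, `n_extreme`, `fst_pass`.
#' @export
call_candidates <- function(track, windows, fst, score_cut = 2,
                            top_frac = 0.01, allow_missing_fst = FALSE) {
  cut <- top_window_cut(windows, top_frac = top_frac)
  qual <- windows |>
    mutate(qualifies = attr(cut, "qualifies")) |>
    select("chrom", "pos", "n_extreme", "qualifies")
  fst_cols <- fst |>
    select("chrom", "pos", fst_pass = "passes_threshold")
  joined <- track |>
    left_join(qual, by = c("chrom", "pos")) |>
    left_join(fst_cols, by = c("chrom", "pos"))
  if (!allow_missing_fst && anyNA(joined$fst_pass)) {
    bad <- joined[which(is.na(joined$fst_pass))[1L], ]
    abort(sprintf("site %s:%s has no aligned FST record",
                  bad$chrom, format(bad$pos, scientific = FALSE)))
  }
  joined |>
    filter(
      !is.na(.data$std), abs(.data$std) > score_cut,
      !is.na(.data$qualifies), .data$qualifies,
      !is.na(.data$fst_pass), .data$fst_pass
    ) |>
    mutate(
      statistic = attr(track, "statistic") %||% NA_character_,
      pops = paste(attr(track, "pops") %||% NA_character_, collapse = "/"),
      score = .data$std
    ) |>
    select("chrom", "pos", "statistic", "pops", "score", "n_extreme", "fst_pass")
}

#' Map candidates to exons and classify their region
#'
#' Keeps only candidates falling inside at least one exon interval and
#' resolves the region class by the precedence CDS > 5' UTR > 3' UTR >
#' non-coding exon when transcripts disagree. Candidates overlapping exons
#' of several genes yield one row per gene.
#'
#' @param candidates tibble with `chrom`, `pos` (from [call_candidates()]).
#' @param annotation tibble from [read_gene_annotation()].
#' @return `candidates` with `gene_id`, `gene_symbol`, `region_class` added
#'   (intergenic candidates dropped).
#' @export
map_and_classify <- function(candidates, annotation) {
  if (nrow(candidates) == 0L) {
    return(mutate(candidates, gene_id = character(0), gene_symbol = character(0),
                  region_class = character(0)))
  }
  cand_gr <- GenomicRanges::GRanges(
    candidates$chrom, IRanges::IRanges(candidates$pos, candidates$pos)
  )
  ann_gr <- GenomicRanges::GRanges(
    annotation$chrom, IRanges::IRanges(annotation$start, annotation$end)
  )
  hits <- GenomicRanges::findOverlaps(cand_gr, ann_gr, ignore.strand = TRUE)
  if (!length(hits)) {
    return(candidates[0, ] |>
             mutate(gene_id = character(0), gene_symbol = character(0),
                    region_class = character(0)))
  }
  prec <- stats::setNames(seq_along(region_classes()), region_classes())
  hit_tbl <- tibble(
    cand = S4Vectors::queryHits(hits),
    gene_id = annotation$gene_id[S4Vectors::subjectHits(hits)],
    gene_symbol = annotation$gene_symbol[S4Vectors::subjectHits(hits)],
    region_class = annotation$region_class[S4Vectors::subjectHits(hits)]
  ) |>
    group_by(.data$cand, .data$gene_id, .data$gene_symbol) |>
    summarise(
      region_class = region_classes()[min(prec[.data$region_class])],
      .groups = "drop"
    )
  candidates |>
    mutate(cand = row_number()) |>
    inner_join(hit_tbl, by = "cand") |>
    select(-"cand")
}

#' eQTL effect flag from an m-value
#'
#' Declares an eQTL effect in a tissue when the posterior probability
#' (m-value) strictly exceeds 0.9; exactly 0.9 is not an effect.
#'
#' @param m numeric m-value(s) in `[0, 1]`.
#' @return logical vector.
#' @export
eqtl_flag <- function(m) {
  stop_if_not_prob(m, "m-value")
  m > 0.9
}

#' Attach eQTL m-values to classified candidates
#'
#' @param candidates classified candidates (`chrom`, `pos`).
#' @param mvalues tibble with `chrom`, `pos`, `tissue`, `m`.
#' @return candidates with `tissue`, `m` and `eqtl_effect` columns (left
#'   join; candidates without records keep NA).
#' @export
add_eqtl_mvalues <- function(candidates, mvalues) {
  mvalues |>
    mutate(chrom = as.character(.data$chrom),
           eqtl_effect = eqtl_flag(.data$m)) |>
    left_join(x = mutate(candidates, chrom = as.character(.data$chrom)),
              by = c("chrom", "pos"))
}

#' Proportion of candidates per exonic region class
#'
#' @param candidates classified candidates with `region_class`.
#' @return tibble of `region_class`, `n`, `proportion` over all four
#'   classes (zeros included); proportions sum to 1.
#' @export
region_proportions <- function(candidates) {
  if (nrow(candidates) == 0L) abort("no candidates to summarise")
  tibble(region_class = region_classes()) |>
    left_join(count(candidates, .data$region_class), by = "region_class") |>
    mutate(
      n = tidyr::replace_na(.data$n, 0L),
      proportion = .data$n / sum(.data$n)
    )
}
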