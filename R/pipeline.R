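#' Scan thresholds and parameters
#'
#' All pipeline thresholds in one place, defaulting to the analysis values:
#' site score cut 2, 51-SNP windows, top 1% windows, top 5% binned FST,
#' MAF 0.05, per-tail alpha 0.05, 100000 resampling replicates.
#'
#' @param maf_min minimum minor allele frequency per participating
#'   population.
#' @param score_cut site-level |standardized score| threshold.
#' @param window_size SNP window width (odd).
#' @param top_frac fraction of windows that may qualify.
#' @param fst_quantile upper tail mass for the binned FST threshold.
#' @param fst_bin_width pooled-frequency bin width for FST thresholds.
#' @param cutoff,max_extension_bp,max_gap_bp EHH walk parameters.
#' @param n_bins,min_bin_size iHS standardization bins.
#' @param alpha per-tail significance level for enrichment.
#' @param reps resampling replicates for enrichment.
#' @return a named list of parameters.
#' @export
scan_params <- function(maf_min = 0.05, score_cut = 2, window_size = 51,
                        top_frac = 0.01, fst_quantile = 0.05,
                        fst_bin_width = 0.05, cutoff = 0.05,
                        max_extension_bp = 1e6, max_gap_bp = 2e5,
                        n_bins = 100, min_bin_size = 20, alpha = 0.05,
                        reps = 1e5) {
  as.list(environment())
}

#' Run the full selection scan on a haplotype panel
#'
#' Executes the pipeline end to end: per-population iHS scans and
#' all-ordered-pair xpEHH scans (each on the sites passing the MAF filter
#' in the participating populations), per-pair frequency-binned FST
#' thresholds, 51-SNP extreme-score windows with the genome-wide top-1%
#' rule, the three-way composite candidate call, exon mapping and gene
#' summarisation, and (when a focal set is given) the random-gene-set
#' enrichment test per population and for the union call set.
#'
#' The FST gate follows the statistic: an xpEHH candidate must pass the
#' binned threshold of its own pair; an iHS candidate must pass it in at
#' least one pair involving the target population.
#'
#' @param panel a `hap_panel` from [simulate_panel()], or a named list of
#'   [hap_matrix()] objects (e.g. from [read_phased_vcf()]).
#' @param annotation exon annotation tibble; taken from the panel when
#'   omitted.
#' @param focal_genes optional focal gene ids; taken from the panel when
#'   omitted (use `character(0)` to skip enrichment).
#' @param pops populations to scan (default: all).
#' @param params a [scan_params()] list.
#' @param seed integer seed for the enrichment resampling.
#' @return a `scan_result` list: `tracks`, `fst`, `windows`, `candidates`,
#'   `gene_calls`, `enrichment`, `manifest`.
#' @export
run_scan <- function(panel, annotation = NULL, focal_genes = NULL,
                     pops = NULL, params = scan_params(), seed = 1L) {
  if (inherits(panel, "hap_panel")) {
    haps <- panel$haps
    annotation <- annotation %||% panel$annotation
    focal_genes <- focal_genes %||% panel$focal_genes
  } else {
    haps <- if (inherits(panel, "hap_matrix")) {
      setNames(list(panel), panel$chrom)
    } else {
      panel
    }
  }
  if (is.null(annotation)) abort("an exon annotation is required")
  all_pops <- populations(haps[[1]])
  pops <- pops %||% all_pops
  pairs <- expand.grid(a = pops, b = all_pops, stringsAsFactors = FALSE) |>
    filter(.data$a != .data$b)

  # per-pair FST with binned thresholds, on sites passing MAF in both pops
  fst_tabs <- list()
  for (i in seq_len(nrow(pairs))) {
    key <- paste(pairs$a[i], pairs$b[i], sep = "/")
    rev_key <- paste(pairs$b[i], pairs$a[i], sep = "/")
    if (!is.null(fst_tabs[[rev_key]])) {
      fst_tabs[[key]] <- fst_tabs[[rev_key]]
      next
    }
    sub <- purrr::map(haps, function(h) {
      hap_subset(h, sites = maf_pass_sites(h, c(pairs$a[i], pairs$b[i]),
                                           params$maf_min))
    })
    fst_tabs[[key]] <- binned_fst_thresholds(
      fst_scan(sub, pairs$a[i], pairs$b[i]),
      bin_width = params$fst_bin_width, quantile = params$fst_quantile
    )
  }

  tracks <- list()
  windows <- list()
  candidates <- list()

  # iHS per population: FST gate = pass in >= 1 pair involving the target
  for (p in pops) {
    sub <- purrr::map(haps, function(h) {
      hap_subset(h, sites = maf_pass_sites(h, p, params$maf_min))
    })
    tr <- ihs_scan(sub, p, cutoff = params$cutoff,
                   max_extension_bp = params$max_extension_bp,
                   max_gap_bp = params$max_gap_bp, n_bins = params$n_bins,
                   min_bin_size = params$min_bin_size)
    win <- window_extreme_counts(tr, window_size = params$window_size,
                                 score_cut = params$score_cut)
    gate <- multi_pair_gate(tr, fst_tabs, p, all_pops)
    cand <- call_candidates(tr, win, gate, score_cut = params$score_cut,
                            top_frac = params$top_frac)
    key <- paste0("iHS:", p)
    tracks[[key]] <- tr
    windows[[key]] <- win
    candidates[[key]] <- mutate(cand, target_pop = p)
  }

  # xpEHH per ordered pair: FST gate = the pair's own thresholded records.
  # xpEHH(B,A) = -xpEHH(A,B) exactly, so each unordered pair is scanned once.
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$a[i]
    b <- pairs$b[i]
    rev_key <- paste0("xpEHH:", b, "/", a)
    if (!is.null(tracks[[rev_key]])) {
      tr <- reverse_xpehh_track(tracks[[rev_key]])
    } else {
      sub <- purrr::map(haps, function(h) {
        hap_subset(h, sites = maf_pass_sites(h, c(a, b), params$maf_min))
      })
      tr <- xpehh_scan(sub, a, b, cutoff = params$cutoff,
                       max_extension_bp = params$max_extension_bp,
                       max_gap_bp = params$max_gap_bp)
    }
    win <- window_extreme_counts(tr, window_size = params$window_size,
                                 score_cut = params$score_cut)
    cand <- call_candidates(tr, win, fst_tabs[[paste(a, b, sep = "/")]],
                            score_cut = params$score_cut,
                            top_frac = params$top_frac)
    key <- paste0("xpEHH:", a, "/", b)
    tracks[[key]] <- tr
    windows[[key]] <- win
    candidates[[key]] <- mutate(cand, target_pop = a)
  }

  cand_all <- bind_rows(candidates)
  classified <- map_and_classify(cand_all, annotation)
  gene_calls <- classified |>
    group_by(.data$gene_id, .data$gene_symbol, .data$target_pop, .data$statistic) |>
    summarise(n_variants = n(), top_score = max(abs(.data$score)), .groups = "drop")

  enrichment <- NULL
  if (is.null(focal_genes) || length(focal_genes) == 0L) {
    message("no focal gene set supplied; enrichment stage skipped")
  } else {
    universe_ids <- unique(annotation$gene_id)
    psg_union <- universe_ids %in% gene_calls$gene_id
    enrichment <- list(
      overall = enrich_test(
        tibble(gene_id = universe_ids, psg = psg_union),
        focal_genes, reps = params$reps, seed = seed, alpha = params$alpha
      ),
      per_pop = purrr::map(setNames(pops, pops), function(p) {
        called <- gene_calls$gene_id[gene_calls$target_pop == p]
        enrich_test(
          tibble(gene_id = universe_ids, psg = universe_ids %in% called),
          focal_genes, reps = params$reps, seed = seed, alpha = params$alpha
        )
      })
    )
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("haploscan")),
    seed = seed,
    params = params,
    pops = pops,
    chromosomes = names(haps),
    n_sites = vapply(haps, n_sites, integer(1)),
    statistics = names(tracks),
    timestamp = format(Sys.time(), tz = "UTC")
  )

  structure(
    list(tracks = tracks, fst = fst_tabs, windows = windows,
         candidates = classified, gene_calls = gene_calls,
         enrichment = enrichment, manifest = manifest),
    class = "scan_result"
  )
}

reverse_xpehh_track <- function(tr) {
  out <- tr |>
    mutate(unstd = -.data$unstd, std = -.data$std) |>
    rename(ihh_a = "ihh_b", ihh_b = "ihh_a")
  new_score_track(out, "xpEHH", rev(attr(tr, "pops")))
}

# site passes if it passes the binned FST threshold in >= 1 pair between
# the target population and any other analyzed population; sites absent
# from a pair's record set (MAF fail there) do not pass through that pair
multi_pair_gate <- function(track, fst_tabs, target, all_pops) {
  gate <- track |>
    select("chrom", "pos") |>
    mutate(passes_threshold = FALSE)
  for (q in setdiff(all_pops, target)) {
    tab <- fst_tabs[[paste(target, q, sep = "/")]]
    if (is.null(tab)) next
    hit <- gate |>
      left_join(select(tab, "chrom", "pos", pq = "passes_threshold"),
                by = c("chrom", "pos"))
    gate$passes_threshold <- gate$passes_threshold |
      (!is.na(hit$pq) & hit$pq)
  }
  gate
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf(
    "<scan_result> %d statistic track(s); %d candidate variant rows; %d gene calls\n",
    length(x$tracks), nrow(x$candidates),
    length(unique(x$gene_calls$gene_id))
  ))
  if (!is.null(x$enrichment)) {
    cat("  overall enrichment: "); print(x$enrichment$overall)
  }
  invisible(x)
}

#' Write scan outputs to a directory
#'
#' Candidates TSV, gene-level TSV, per-statistic score TSVs, FST TSVs and
#' a JSON run manifest.
#'
#' @param x a `scan_result`.
#' @param dir output directory.
#' @return named list of paths, invisibly.
#' @export
write_scan_result <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    candidates = file.path(dir, "candidates.tsv"),
    gene_calls = file.path(dir, "gene_calls.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  readr::write_tsv(x$candidates, paths$candidates)
  readr::write_tsv(x$gene_calls, paths$gene_calls)
  for (key in names(x$tracks)) {
    fn <- file.path(dir, paste0("scores_", gsub("[:/]", "_", key), ".tsv"))
    readr::write_tsv(as_tibble(x$tracks[[key]]), fn)
    paths[[paste0("scores_", key)]] <- fn
  }
  for (key in names(x$fst)) {
    fn <- file.path(dir, paste0("fst_", gsub("[:/]", "_", key), ".tsv"))
    readr::write_tsv(x$fst[[key]], fn)
    paths[[paste0("fst_", key)]] <- fn
  }
  jsonlite::write_json(x$manifest, paths$manifest, auto_unbox = TRUE)
  if (!is.null(x$enrichment)) {
    paths$enrichment <- file.path(dir, "enrichment.json")
    write_enrich_json(x$enrichment$overall, paths$enrichment)
  }
  invisible(paths)
}
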