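#' Read exon-level gene annotation from GFF3 or BED
#'
#' Produces the tidy interval table the candidate-classification step
#' consumes: one row per (gene, interval) with a region class among
#' `FIVE_UTR`, `THREE_UTR`, `CDS` and `NONCODING_EXON`. Coordinates are
#' 1-based inclusive internally; BED's 0-based half-open intervals are
#' converted on read (a BED line `chr1 99 200` becomes `[100, 200]`).
#'
#' GFF3: `five_prime_UTR`, `three_prime_UTR` and `CDS` features map to the
#' corresponding classes; `exon` features whose attributes carry
#' `biotype=noncoding` (or that belong to genes with no CDS feature) map to
#' `NONCODING_EXON`. The `gene_id` attribute (falling back to `Parent`/`ID`)
#' identifies the gene; intervals are pooled over transcripts of a gene and
#' deduplicated.
#'
#' BED: the name field must be `<gene>_<class>` with class one of `CDS`,
#' `FIVE_UTR`, `THREE_UTR`, `NONCODING_EXON` (case-insensitive; `5UTR`/`3UTR`
#' accepted).
#'
#' @param path annotation file.
#' @param format `"gff3"` or `"bed"`; guessed from the extension by default.
#' @return tibble with columns `gene_id`, `gene_symbol`, `chrom`, `start`,
#'   `end`, `region_class`, `strand`.
#' @export
read_gene_annotation <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3"),
    error = function(e) abort(sprintf("failed to parse %s as %s: %s", path, format, conditionMessage(e)))
  )
  if (format == "bed") {
    nm <- gr$name
    if (is.null(nm) || anyNA(nm)) abort("BED needs a name field of the form <gene>_<class>")
    cls <- toupper(sub("^.*_(CDS|FIVE_UTR|THREE_UTR|NONCODING_EXON|5UTR|3UTR)$", "\\1",
                       nm, ignore.case = TRUE))
    gene <- sub("_(CDS|FIVE_UTR|THREE_UTR|NONCODING_EXON|5UTR|3UTR)$", "",
                nm, ignore.case = TRUE)
    cls[cls == "5UTR"] <- "FIVE_UTR"
    cls[cls == "3UTR"] <- "THREE_UTR"
    bad <- !cls %in% region_classes()
    if (any(bad)) {
      abort(sprintf("BED name without a region class suffix: %s", nm[bad][1]))
    }
    out <- tibble(
      gene_id = gene,
      gene_symbol = gene,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      region_class = cls,
      strand = as.character(GenomicRanges::strand(gr))
    )
  } else {
    md <- S4Vectors::mcols(gr)
    type <- as.character(md$type)
    keep <- type %in% c("five_prime_UTR", "three_prime_UTR", "CDS", "exon")
    gr <- gr[keep]
    md <- S4Vectors::mcols(gr)
    type <- as.character(md$type)
    gene <- as.character(md$gene_id %||% rep(NA_character_, length(gr)))
    if (anyNA(gene)) {
      parent <- if (!is.null(md$Parent)) as.character(S4Vectors::unstrsplit(md$Parent, ",")) else NA_character_
      gene <- ifelse(is.na(gene), sub("^(transcript|gene):", "", parent), gene)
    }
    if (anyNA(gene)) abort("GFF3 features need a gene_id (or Parent) attribute")
    biotype <- as.character(md$biotype %||% rep(NA_character_, length(gr)))
    cls <- dplyr::case_when(
      type == "five_prime_UTR" ~ "FIVE_UTR",
      type == "three_prime_UTR" ~ "THREE_UTR",
      type == "CDS" ~ "CDS",
      TRUE ~ NA_character_
    )
    # exons of non-coding genes (by biotype, or genes lacking any CDS)
    coding_genes <- unique(gene[type == "CDS"])
    cls[type == "exon" & (biotype %in% "noncoding" | !gene %in% coding_genes)] <- "NONCODING_EXON"
    symbol <- as.character(md$gene_name %||% md$Name %||% gene)
    out <- tibble(
      gene_id = gene,
      gene_symbol = ifelse(is.na(symbol), gene, symbol),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      region_class = cls,
      strand = as.character(GenomicRanges::strand(gr))
    ) |>
      filter(!is.na(.data$region_class))
  }
  if (any(out$end < out$start)) abort("interval with end < start")
  distinct(out)
}

region_classes <- function() c("CDS", "FIVE_UTR", "THREE_UTR", "NONCODING_EXON")

#' Read a focal gene list
#'
#' One gene id per line (or first TSV column, header optional via
#' `col_names`).
#'
#' @param path TSV/one-column file of gene ids.
#' @param universe optional gene universe the set must be contained in.
#' @param col_names passed to [readr::read_tsv()].
#' @return character vector of unique gene ids.
#' @export
read_focal_genes <- function(path, universe = NULL, col_names = FALSE) {
  tbl <- readr::read_tsv(path, col_names = col_names, show_col_types = FALSE)
  ids <- unique(as.character(tbl[[1]]))
  if (!is.null(universe)) {
    missing_ids <- setdiff(ids, universe)
    if (length(missing_ids)) {
      abort(sprintf(
        "%d focal gene(s) absent from the gene universe (first: %s)",
        length(missing_ids), missing_ids[1]
      ))
    }
  }
  ids
}
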