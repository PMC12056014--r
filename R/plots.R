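#' Plot a standardized score track
#'
#' Manhattan-style view of |standardized score| along each chromosome with
#' the site-level threshold drawn.
#'
#' @param object a `score_track` from [ihs_scan()] or [xpehh_scan()].
#' @param score_cut threshold line (default 2).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot score_track
#' @export
autoplot.score_track <- function(object, score_cut = 2, ...) {
  stat <- attr(object, "statistic") %||% "score"
  pops <- paste(attr(object, "pops"), collapse = "/")
  ggplot2::ggplot(
    filter(as_tibble(object), !is.na(.data$std)),
    ggplot2::aes(x = .data$pos / 1e6, y = abs(.data$std))
  ) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = score_cut, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = sprintf("|%s| (%s)", stat, pops)) +
    ggplot2::theme_minimal()
}

#' Plot an EHH decay curve
#'
#' @param object an `ehh_curve` from [ehh_curve()].
#' @param cutoff EHH cutoff line (default 0.05).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot ehh_curve
#' @export
autoplot.ehh_curve <- function(object, cutoff = 0.05, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$distance / 1e3, y = .data$ehh)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "distance from core (kb)", y = "EHH",
                  subtitle = sprintf("core allele: %s", attr(object, "allele"))) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot an enrichment null distribution with the observed count
#'
#' @param object an `enrich_test`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot enrich_test
#' @export
autoplot.enrich_test <- function(object, ...) {
  ggplot2::ggplot(tibble(count = object$null_counts),
                  ggplot2::aes(x = .data$count)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick") +
    ggplot2::labs(
      x = "positively selected genes per random set",
      y = "replicates",
      subtitle = sprintf("observed = %d, p_upper = %.4g",
                         object$observed, object$p_upper)
    ) +
    ggplot2::theme_minimal()
}

#' Bar plot of candidate-variant region proportions
#'
#' @param candidates classified candidates (with `region_class`).
#' @return a ggplot of the per-class proportions.
#' @export
plot_region_proportions <- function(candidates) {
  props <- region_proportions(candidates)
  ggplot2::ggplot(props, ggplot2::aes(x = .data$region_class,
                                      y = .data$proportion)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "proportion of candidate variants") +
    ggplot2::theme_minimal()
}
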