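# ggplot2 views of the result objects.

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_abline
#'   facet_wrap labs theme_minimal scale_fill_manual
NULL

category_fills <- c(IDENTICAL = "#4daf4a", ALTERNATIVE = "#377eb8",
                    UNMAPPED = "#e41a1c")

#' Plot a run comparison
#'
#' @param object a `run_comparison` tibble.
#' @param type `"categories"` (category percentages with junction overlay),
#'   `"moe"` (per-category MOE histograms of two-exon junction reads) or
#'   `"exon_span"` (category mix by exon span).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot run_comparison
#' @export
autoplot.run_comparison <- function(object,
                                    type = c("categories", "moe",
                                             "exon_span"), ...) {
  type <- match.arg(type)
  s <- summarize_comparison(object)
  if (type == "categories") {
    ggplot(s$categories, aes(x = .data$category, y = .data$pct,
                             fill = .data$category)) +
      geom_col() +
      scale_fill_manual(values = category_fills, guide = "none") +
      labs(x = NULL, y = "% of guided-run-mapped reads") +
      theme_minimal()
  } else if (type == "moe") {
    ggplot(s$moe, aes(x = .data$moe, y = .data$n)) +
      geom_col() +
      facet_wrap(~category, scales = "free_y", ncol = 1) +
      labs(x = "MOE = min(overlap left exon, overlap right exon)",
           y = "junction reads") +
      theme_minimal()
  } else {
    ggplot(s$exon_span |> filter(.data$span != "1"),
           aes(x = .data$span, y = .data$pct_within_span,
               fill = .data$category)) +
      geom_col(position = "stack") +
      scale_fill_manual(values = category_fills) +
      labs(x = "exons spanned", y = "% of junction reads") +
      theme_minimal()
  }
}

#' Plot per-gene count impact
#'
#' @param object a `gene_impact` tibble.
#' @param ... unused.
#' @return a ggplot of guided vs annotation-free counts per gene.
#' @method autoplot gene_impact
#' @export
autoplot.gene_impact <- function(object, ...) {
  ggplot(object, aes(x = .data$count_a, y = .data$count_b)) +
    geom_point(alpha = 0.7) +
    geom_abline(slope = 1, intercept = 0, linetype = 2) +
    labs(x = "reads per gene, guided run",
         y = "reads per gene, annotation-free run") +
    theme_minimal()
}

#' Plot fold-change concordance between runs
#'
#' @param object an `fc_concordance` tibble.
#' @param ... unused.
#' @return a ggplot of run-A vs run-B log2 fold changes, coloured by the
#'   discordance flag (`|delta| > 2` blue, `> 3.3` red).
#' @method autoplot fc_concordance
#' @export
autoplot.fc_concordance <- function(object, ...) {
  ggplot(object, aes(x = .data$log2fc_a, y = .data$log2fc_b,
                     colour = .data$flag)) +
    geom_point(alpha = 0.8) +
    geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(none = "grey40",
                                            blue = "#377eb8",
                                            red = "#e41a1c")) +
    labs(x = "log2 fold change, guided run",
         y = "log2 fold change, annotation-free run", colour = NULL) +
    theme_minimal()
}

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot
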