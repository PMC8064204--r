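#' Plot stratified conditional Q-Q curves
#'
#' One curve per conditional-trait stratum; the dashed diagonal is the
#' uniform-null expectation. Leftward/upward deflection of stricter strata
#' indicates cross-trait enrichment.
#'
#' @param qq A `cfdr_qq` tibble from [conditional_qq()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_conditional_qq <- function(qq, ...) {
  ggplot2::ggplot(qq, ggplot2::aes(x = .data$nominal, y = .data$empirical,
                                   colour = .data$stratum)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(nominal ~ -log[10](p)),
                  y = expression(empirical ~ -log[10](q)),
                  colour = "conditional stratum") +
    ggplot2::theme_minimal()
}

#' @rdname plot_conditional_qq
#' @param object A `cfdr_qq` tibble.
#' @method autoplot cfdr_qq
#' @export
autoplot.cfdr_qq <- function(object, ...) plot_conditional_qq(object, ...)

#' Plot fold-enrichment curves
#'
#' Fold enrichment of each conditional stratum relative to the full panel
#' against the nominal (inflation-corrected) significance of the principal
#' trait; the dashed line at 1 is the no-enrichment null.
#'
#' @param fe A `cfdr_enrichment` tibble from [fold_enrichment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_fold_enrichment <- function(fe, ...) {
  ggplot2::ggplot(fe, ggplot2::aes(x = .data$neglog10_p, y = .data$fold_enrichment,
                                   colour = .data$stratum)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(nominal ~ -log[10](p)), y = "fold enrichment",
                  colour = "conditional stratum") +
    ggplot2::theme_minimal()
}

#' @rdname plot_fold_enrichment
#' @param object A `cfdr_enrichment` tibble.
#' @method autoplot cfdr_enrichment
#' @export
autoplot.cfdr_enrichment <- function(object, ...) plot_fold_enrichment(object, ...)

#' Conditional / conjunction Manhattan plot
#'
#' SNPs on a cumulative genome axis against `-log10` of the conditional (or
#' conjunction) FDR, with the significance reference line (1.301 for
#' alpha = 0.05).
#'
#' @param md A `cfdr_manhattan` tibble from [manhattan_data()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(md, ...) {
  chroms <- unique(md$chrom)
  shade <- (match(md$chrom, chroms) %% 2) == 0
  ggplot2::ggplot(md, ggplot2::aes(x = .data$pos_cum, y = .data$neglog10)) +
    ggplot2::geom_point(ggplot2::aes(colour = shade), size = 0.6, show.legend = FALSE) +
    ggplot2::geom_point(data = md[md$significant, , drop = FALSE],
                        colour = "#d95f02", size = 1.1) +
    ggplot2::geom_hline(yintercept = attr(md, "ref_line"), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_colour_manual(values = c("grey60", "grey30")) +
    ggplot2::labs(x = "genomic position", y = expression(-log[10](FDR))) +
    ggplot2::theme_minimal()
}

#' @rdname plot_manhattan
#' @param object A `cfdr_manhattan` tibble.
#' @method autoplot cfdr_manhattan
#' @export
autoplot.cfdr_manhattan <- function(object, ...) plot_manhattan(object, ...)
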