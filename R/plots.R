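#' Manhattan-style plot of association results
#'
#' @param object a `breedmap_assoc` tibble from [allelic_chisq()].
#' @param p_line significance threshold drawn as a horizontal line.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.breedmap_assoc <- function(object, p_line = 1e-4, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pos / 1e6,
                                       y = -log10(.data$p))) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(p_line), linetype = "dashed",
                        colour = "red") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](P)),
                  title = "Allelic association") +
    ggplot2::theme_minimal()
}

#' Case-only versus control-only burden per gene
#'
#' Scatter of per-gene case-only against control-only variant counts
#' (constrained elements only), with the identity line; genes above the
#' line carry more case-only variation.
#'
#' @param object a `gene_burden` tibble from [gene_burden()].
#' @param top number of top-ranked genes to label.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.gene_burden <- function(object, top = 4, ...) {
  lab <- dplyr::slice_min(object, .data$rank, n = top)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$control_only_constrained,
                                       y = .data$case_only_constrained)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$gene),
                       vjust = -0.6, size = 3) +
    ggplot2::labs(x = "control-only variants (constrained)",
                  y = "case-only variants (constrained)",
                  title = "Gene burden of group-specific variants") +
    ggplot2::theme_minimal()
}

#' Normalized frequency difference against overall allele frequency
#'
#' @param object a `freq_contrast` result from [frequency_contrast()].
#' @param ... unused.
#' @return A ggplot object with the per-variant points and the linear fit.
#' @export
autoplot.freq_contrast <- function(object, ...) {
  d <- dplyr::filter(object$variants, !.data$excluded)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$af_all, y = .data$norm_diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "steelblue") +
    ggplot2::labs(x = "allele frequency, all dogs",
                  y = "(AF risk - AF control) / (AF risk + AF control)",
                  title = "Breed-group frequency contrast") +
    ggplot2::theme_minimal()
}

#' Window variability scores with selected RRV windows highlighted
#'
#' @param object an `rrv_scan` result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.rrv_scan <- function(object, ...) {
  ggplot2::ggplot(object$windows,
                  ggplot2::aes(x = .data$start / 1e6, y = .data$score,
                               colour = .data$selected)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "window start (Mb)",
                  y = if (object$mode == "relative") {
                    "heterozygosity ratio (target / reference)"
                  } else "mean expected heterozygosity",
                  title = "Reduced-variability scan") +
    ggplot2::theme_minimal()
}

#' Two-channel intensity cloud for one SNP
#'
#' @param intensities intensity tibble (`sample`, `chip`, `snp`, `a`, `b`).
#' @param snp SNP id to plot.
#' @param calls optional `call_set`; points are coloured by called
#'   genotype.
#' @return A ggplot object.
#' @export
plot_snp_intensities <- function(intensities, snp, calls = NULL) {
  d <- dplyr::filter(intensities, .data$snp == !!snp)
  if (!is.null(calls)) {
    d <- d %>% mutate(genotype = factor(calls$gt[cbind(
      match(.data$sample, rownames(calls$gt)),
      match(.data$snp, colnames(calls$gt)))], exclude = NULL))
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$a, y = .data$b))
  p <- if (!is.null(calls)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$genotype), alpha = 0.8)
  } else p + ggplot2::geom_point(alpha = 0.8)
  p + ggplot2::labs(x = "channel A", y = "channel B", title = snp) +
    ggplot2::theme_minimal()
}
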