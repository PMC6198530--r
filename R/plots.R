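# ggplot2 displays for scan, enrichment and GWAS results.

#' @exportS3Method ggplot2::autoplot
autoplot.slope_scan <- function(object, ...) {
  d <- object |>
    dplyr::filter(.data$converged) |>
    dplyr::arrange(.data$lrt_slope) |>
    dplyr::mutate(pp = stats::ppoints(dplyr::n()),
                  expected = qchisq(pmax(2 * .data$pp - 1, 0), df = 1))
  ggplot2::ggplot(d, ggplot2::aes(.data$expected, .data$lrt_slope)) +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(
      x = expression("expected quantile of " * 0.5 * chi[0]^2 + 0.5 * chi[1]^2),
      y = "observed slope LRT statistic",
      title = "Random-slope test statistics against the mixture null")
}

#' @exportS3Method ggplot2::autoplot
autoplot.enrich_result <- function(object, ...) {
  d <- dplyr::mutate(object,
                     class = factor(.data$class,
                                    levels = object$class[order(object$fold)]))
  p_col <- if ("p_perm" %in% names(d)) "p_perm" else "p"
  d$significant <- d[[p_col]] < 0.05
  ggplot2::ggplot(d, ggplot2::aes(.data$fold, .data$class,
                                  fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::labs(x = "fold enrichment (observed / expected)", y = NULL,
                  fill = "p < 0.05",
                  title = "Annotation class enrichment")
}

#' Manhattan plot of slope GWAS results
#'
#' @param assoc A `slope_assoc` tibble (possibly several probes).
#' @param p_threshold Genome-wide line to draw (default 5e-8).
#' @return A ggplot object.
#' @export
plot_manhattan <- function(assoc, p_threshold = 5e-8) {
  .assert(all(c("chrom", "pos", "p") %in% names(assoc)),
          "assoc needs chrom, pos, p")
  d <- assoc |>
    dplyr::arrange(.data$chrom, .data$pos) |>
    dplyr::mutate(x = dplyr::row_number(),
                  chrom_f = factor(.data$chrom))
  ggplot2::ggplot(d, ggplot2::aes(.data$x, -log10(.data$p),
                                  colour = .data$chrom_f)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(p_threshold), linetype = 2,
                        colour = "red") +
    ggplot2::labs(x = "SNP (ordered by chromosome, position)",
                  y = expression(-log[10](p)),
                  title = "GWAS of SNP dosage on predicted random slope")
}
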