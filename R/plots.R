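# ggplot2 views of the main result types.

#' @rdname resilience_scores
#' @method autoplot resilience_result
#' @export
autoplot.resilience_result <- function(object, ...) {
  sm <- object$animals |>
    dplyr::summarise(ad_mean = mean(.data$value),
                     ntg_mean = .data$ntg_mean[1], .by = "strain")
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$ntg_mean, y = .data$ad_mean)) +
    ggplot2::geom_abline(intercept = object$fit$intercept,
                         slope = object$fit$slope, colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Ntg strain mean CFM (% freezing)",
      y = "AD strain mean CFM (% freezing)",
      title = sprintf("Strain-mean baseline fit (R² = %.2f)",
                      object$fit$r.squared)
    ) +
    ggplot2::theme_minimal()
}

#' Manhattan-style view of a pQTL scan
#'
#' @param records Output of [qtl_scan()].
#' @param fdr Reference threshold drawn as the weakest significant record.
#' @return A ggplot.
#' @export
plot_qtl_scan <- function(records, fdr = 0.05) {
  d <- records |>
    dplyr::arrange(.data$chr, .data$bp) |>
    dplyr::mutate(pos = dplyr::row_number() / dplyr::n(),
                  odd = .data$chr %% 2 == 1)
  thr <- suppressWarnings(max(d$p[d$q < fdr]))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = -log10(.data$p),
                                       colour = .data$odd)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c("grey55", "grey20")) +
    ggplot2::labs(x = "genome position (markers, concatenated chromosomes)",
                  y = expression(-log[10](p)), title = "pQTL scan") +
    ggplot2::theme_minimal()
  if (is.finite(thr)) {
    p <- p + ggplot2::geom_hline(yintercept = -log10(thr),
                                 linetype = "dashed", colour = "firebrick")
  }
  p
}

#' @rdname module_pca
#' @method autoplot module_pca
#' @export
autoplot.module_pca <- function(object, ...) {
  d <- tibble::tibble(component = seq_along(object$variance_fractions),
                      fraction = object$variance_fractions)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$component),
                                  y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "principal component", y = "variance fraction",
                  title = sprintf("Module PCA (PC1 = %.0f%%)",
                                  100 * object$variance_fractions[1])) +
    ggplot2::theme_minimal()
}

#' @rdname mediate
#' @method autoplot mediation_result
#' @export
autoplot.mediation_result <- function(object, ...) {
  d <- tibble::tibble(indirect = object$bootstrap)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$indirect)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$indirect, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = c(object$ci$lower, object$ci$upper),
                        linetype = "dashed") +
    ggplot2::labs(x = "bootstrap indirect effect (a·b)", y = "replicates",
                  title = sprintf("Indirect effect %.3f, %d%% CI [%.3f, %.3f]",
                                  object$indirect, round(100 * object$ci$level),
                                  object$ci$lower, object$ci$upper)) +
    ggplot2::theme_minimal()
}
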