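#' Plot rarefied indices before vs after
#'
#' Boxplots of the per-iteration across-locus mean rarefied richness and
#' M-ratio for the two periods.
#'
#' @param object a [hierarchical_rarefy()] result.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.rarefaction_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$iterations, c("richness", "m_ratio"),
    names_to = "index"
  )
  long$period <- factor(long$period, levels = c("before", "after"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$period, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::facet_wrap(ggplot2::vars(.data$index), scales = "free_y") +
    ggplot2::labs(
      title = sprintf("Hierarchically rarefied indices at %s", object$design$site),
      x = NULL, y = "across-locus mean"
    )
}

#' Plot the joint posterior of the endpoint effective sizes
#'
#' Hex-binned joint posterior of `(N_before, N_after)` on log axes with the
#' `N_before = N_after` diagonal; mass below the diagonal indicates a
#' decline.
#'
#' @param object an `ne_posterior`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.ne_posterior <- function(object, ...) {
  draws <- tibble::as_tibble(as.data.frame(posterior_draws(object)))
  ggplot2::ggplot(draws, ggplot2::aes(x = .data$n_before, y = .data$n_after)) +
    ggplot2::geom_hex(bins = 40) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      title = if (is.null(object$site)) "Posterior of endpoint Ne" else {
        sprintf("Posterior of endpoint Ne at %s", object$site)
      },
      x = "N_before", y = "N_after"
    )
}

#' Plot per-locus heterozygosity excess
#'
#' Standardized differences `DH = (He - mean Heq) / sd Heq` per locus and
#' sample; positive values are the bottleneck signature.
#'
#' @param object a [heterozygosity_excess_test()] result.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.heq_test <- function(object, ...) {
  d <- object$loci
  d$sample <- paste(d$site, d$year, sep = " ")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$locus, y = .data$DH)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$sample)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5)) +
    ggplot2::labs(x = NULL, y = "standardized difference DH")
}
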