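# ggplot2 displays for fitted objects and summaries.

#' Plot genotype x treatment trait means
#'
#' Bar chart of cell means with +/- 1 SD error bars, faceted by trait.
#'
#' @param cell_summary Output of [summarize_trial()].
#' @param traits Optional subset of traits to show.
#' @return A ggplot object.
#' @export
plot_trait_means <- function(cell_summary, traits = NULL) {
  d <- cell_summary
  if (!is.null(traits)) d <- dplyr::filter(d, .data$trait %in% traits)
  d$treatment <- factor(d$treatment, levels = treatment_levels())
  ggplot2::ggplot(d, ggplot2::aes(x = .data$genotype, y = .data$mean,
                                  fill = .data$treatment)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$trait), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "cell mean", fill = "treatment") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a fitted NUE analysis
#'
#' `type = "sfsi"` shows the per-genotype susceptibility index by trait
#' with the SFSI = 1 susceptibility threshold; `type = "anr"` and
#' `type = "pe"` show apparent recovery and physiological efficiency
#' per nutrient, with bootstrap error bars when available.
#'
#' @param object A `yam_nue` object.
#' @param type One of `"sfsi"`, `"anr"`, `"pe"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.yam_nue <- function(object, type = c("sfsi", "anr", "pe"), ...) {
  type <- match.arg(type)
  d <- tidy(object)
  if (type == "sfsi") {
    d <- dplyr::filter(d, .data$measure %in% object$traits)
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$genotype, y = .data$sfsi,
                                         fill = .data$class)) +
      ggplot2::geom_col(width = 0.7) +
      ggplot2::geom_hline(yintercept = 1, linetype = 2) +
      ggplot2::facet_wrap(ggplot2::vars(.data$measure)) +
      ggplot2::labs(x = NULL, y = "soil fertility susceptibility index",
                    fill = NULL)
    if ("sfsi_se" %in% names(d)) {
      p <- p + ggplot2::geom_errorbar(
        ggplot2::aes(ymin = .data$sfsi - .data$sfsi_se,
                     ymax = .data$sfsi + .data$sfsi_se), width = 0.25)
    }
  } else {
    ycol <- if (type == "anr") "anr_pct" else "pe_g_per_g"
    secol <- if (type == "anr") "anr_se" else "pe_se"
    ylab <- if (type == "anr") "apparent recovery efficiency (%)"
            else "physiological efficiency (g/g)"
    d <- dplyr::filter(d, !.data$measure %in% object$traits)
    d$nutrient <- sub("^uptake_([NPK])_g$", "\\1", d$measure)
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$genotype,
                                         y = .data[[ycol]])) +
      ggplot2::geom_col(width = 0.7, fill = "grey40") +
      ggplot2::facet_wrap(ggplot2::vars(.data$nutrient), scales = "free_y") +
      ggplot2::labs(x = NULL, y = ylab)
    if (secol %in% names(d)) {
      p <- p + ggplot2::geom_errorbar(
        ggplot2::aes(ymin = .data[[ycol]] - .data[[secol]],
                     ymax = .data[[ycol]] + .data[[secol]]), width = 0.25)
    }
  }
  p + ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a parameter-recovery experiment
#'
#' Estimated vs true index values across replicates, per statistic.
#'
#' @param object A `yam_recovery` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.yam_recovery <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$truth, y = .data$mean_estimate)) +
    ggplot2::geom_abline(linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_estimate - .data$rmse,
                   ymax = .data$mean_estimate + .data$rmse), width = 0
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$statistic), scales = "free") +
    ggplot2::labs(x = "configured truth", y = "mean estimate (+/- RMSE)") +
    ggplot2::theme_bw()
}
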