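#' Plot the learned motifs as a probability heatmap
#'
#' One tile per motif-study pair, shaded by the differential probability
#' `q[k, d]` (white = 0, black = 1), with the implied gene count `pi * G`
#' annotated per motif row.
#'
#' @param object A `cormotif_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cormotif_fit <- function(object, ...) {
  tab <- tidy(object)
  tab$motif <- factor(tab$motif, levels = rev(seq_len(object$model$K)))
  tab$study <- factor(tab$study, levels = object$study_ids)
  lab <- tab[!duplicated(tab$motif), ]
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$study, y = .data$motif,
                                    fill = .data$q)) +
    ggplot2::geom_tile(colour = "grey40") +
    ggplot2::geom_text(
      data = lab,
      ggplot2::aes(label = sprintf("%.0f genes", .data$genes)),
      x = length(object$study_ids) + 0.7, hjust = 0, size = 3
    ) +
    ggplot2::scale_fill_gradient(low = "white", high = "black",
                                 limits = c(0, 1), name = "Pr(diff)") +
    ggplot2::coord_cartesian(clip = "off") +
    ggplot2::labs(x = "study", y = "motif") +
    ggplot2::theme_minimal() +
    ggplot2::theme(plot.margin = ggplot2::margin(5, 70, 5, 5))
}

#' Plot BIC against the motif number
#'
#' @param object A `cormotif_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cormotif_scan <- function(object, ...) {
  tab <- tidy(object)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$K, y = .data$bic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$best), size = 2,
                        show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c("FALSE" = "black", "TRUE" = "red")) +
    ggplot2::labs(x = "number of motifs K", y = "BIC") +
    ggplot2::theme_minimal()
}

#' Plot true-positive curves for several methods
#'
#' @param curves Named list of TP vectors (each from [tp_curve()]), or a
#'   tibble with columns `method`, `rank`, `tp`.
#' @param r_max Optional largest rank shown.
#' @return A ggplot object.
#' @export
plot_tp_curves <- function(curves, r_max = NULL) {
  if (!is.data.frame(curves)) {
    curves <- do.call(rbind, lapply(names(curves), function(nm) {
      tibble::tibble(method = nm, rank = seq_along(curves[[nm]]),
                     tp = as.numeric(curves[[nm]]))
    }))
  }
  if (!is.null(r_max)) curves <- curves[curves$rank <= r_max, ]
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$rank, y = .data$tp,
                                       colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "rank cutoff r", y = "true positives in top r",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
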