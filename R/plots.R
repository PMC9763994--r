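#' Accuracy plane of candidate designs
#'
#' Type I error versus power for every threshold combination, with the
#' optimal-efficiency design (if flagged) highlighted.
#'
#' @param oc An [estimate_oc()] table, optionally after
#'   [select_optimal_efficiency()].
#' @return A ggplot object.
#' @export
plot_accuracy <- function(oc) {
  p <- ggplot2::ggplot(oc, ggplot2::aes(.data$type1, .data$power)) +
    ggplot2::geom_point(colour = "grey40") +
    ggplot2::labs(x = "Type I error", y = "Power",
                  title = sprintf("Accuracy (%s design)", oc$design[1])) +
    ggplot2::theme_minimal()
  if ("optimal" %in% names(oc))
    p <- p + ggplot2::geom_point(data = oc[oc$optimal, ], shape = 18,
                                 size = 4, colour = "darkorange")
  p
}

#' Efficiency plane of candidate designs
#'
#' Average total sample size under the null versus under the alternative.
#' Good designs sit toward the lower right: few patients when the
#' treatment is inactive, many (full information) when it works.
#'
#' @inheritParams plot_accuracy
#' @return A ggplot object.
#' @export
plot_efficiency <- function(oc) {
  p <- ggplot2::ggplot(oc, ggplot2::aes(.data$avg_n_null, .data$avg_n_alt)) +
    ggplot2::geom_point(colour = "grey40") +
    ggplot2::labs(x = "Average N under the null",
                  y = "Average N under the alternative",
                  title = sprintf("Efficiency (%s design)", oc$design[1])) +
    ggplot2::theme_minimal()
  if ("optimal" %in% names(oc))
    p <- p + ggplot2::geom_point(data = oc[oc$optimal, ], shape = 18,
                                 size = 4, colour = "darkorange")
  p
}
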