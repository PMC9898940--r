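#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_abline
#'   geom_col labs coord_equal facet_wrap
#' @export
ggplot2::autoplot

#' Plot a confidence-based calibration curve
#'
#' Empirical coverage fraction against nominal confidence level; the
#' diagonal is perfect calibration.
#'
#' @param object A [confidence_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot confidence_curve
#' @export
autoplot.confidence_curve <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$level, y = .data$fraction)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey50") +
    geom_line() +
    coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    labs(x = "Confidence level", y = "Empirical fraction",
         title = sprintf("ECE = %.4f", object$ece))
}

#' Plot an error-based calibration curve
#'
#' Parity plot of per-bin RMSE against per-bin root mean uncertainty (RMU);
#' the diagonal is perfect calibration.
#'
#' @param object An [error_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot error_curve
#' @export
autoplot.error_curve <- function(object, ...) {
  lim <- range(c(object$curve$rmse, object$curve$rmu, 0))
  ggplot(object$curve, aes(x = .data$rmu, y = .data$rmse)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey50") +
    geom_point() +
    geom_line() +
    coord_equal(xlim = lim, ylim = lim) +
    labs(x = "RMU (binned)", y = "RMSE (binned)",
         title = sprintf("ENCE = %.4f", object$ence))
}

#' Plot the atomic uncertainty attribution of one molecule
#'
#' Bar chart of per-atom aleatoric and epistemic variance components from
#' an atom-mode ensemble prediction.
#'
#' @param atoms A per-atom tibble from [decompose_atomic_uncertainty()] or
#'   one element of the `atoms` list-column of [ensemble_predict()].
#' @return A ggplot.
#' @export
plot_atomic_uncertainty <- function(atoms) {
  long <- atoms |>
    dplyr::mutate(label = paste0(.data$element, .data$atom_index)) |>
    tidyr::pivot_longer(c("sigma2_ale_atom", "sigma2_epi_atom"),
                        names_to = "component", values_to = "variance") |>
    dplyr::mutate(component = ifelse(.data$component == "sigma2_ale_atom",
                                     "aleatoric", "epistemic"))
  ggplot(long, aes(x = stats::reorder(.data$label, .data$atom_index),
                   y = .data$variance)) +
    geom_col() +
    facet_wrap(~component, scales = "free_y") +
    labs(x = "Atom", y = "Variance")
}
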