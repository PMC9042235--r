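#' Plot a conservation call
#'
#' Per-column identity fractions with the conservation threshold line;
#' conserved columns are highlighted.
#'
#' @param object A `conservation_call` from [call_conservation()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.conservation_call <- function(object, ...) {
  thr <- attr(object, "threshold")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$column,
                                       y = .data$identity_fraction,
                                       fill = .data$conserved)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "#2c7fb8")) +
    ggplot2::labs(x = "alignment column", y = "identity fraction",
                  fill = paste0(">= ", format(thr))) +
    ggplot2::theme_minimal()
}

#' Plot a contact map
#'
#' Residue-pair probabilities as tiles. Works on hybrid-indexed maps
#' (`i`, `j`) and on chain-indexed maps (`res_a`, `res_b`).
#'
#' @param object A `contact_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.contact_map <- function(object, ...) {
  if (all(c("i", "j") %in% names(object))) {
    df <- tibble::tibble(x = object$i, y = object$j, p = object$probability)
  } else {
    df <- tibble::tibble(x = object$res_a, y = object$res_b,
                         p = object$probability)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$p)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "residue i", y = "residue j", fill = "p(contact)") +
    ggplot2::theme_minimal()
}

#' Plot a ratio time course with its fitted trend line
#'
#' @param object A `trend_fit` from [fit_trend()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trend_fit <- function(object, ...) {
  co <- stats::coef(object$fit)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time,
                                            y = .data$ratio)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = co[1], slope = co[2],
                         colour = "#d95f02") +
    ggplot2::labs(x = "time (min)", y = "ratio") +
    ggplot2::theme_minimal()
}

#' Plot an assembly ensemble summary
#'
#' Cross-link violations and total score per ensemble member; the selected
#' model is highlighted.
#'
#' @param object An `assembly_result` from [build_ensemble()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.assembly_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$model),
                                   y = .data$crosslink_violations,
                                   fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "#2c7fb8"), guide = "none") +
    ggplot2::labs(x = "ensemble model", y = "cross-link violations") +
    ggplot2::theme_minimal()
}

#' Plot an annealing score trace
#'
#' @param model A model returned by [anneal()] (carrying a `"trace"`
#'   attribute).
#' @return A ggplot of score per cycle.
#' @export
plot_score_trace <- function(model) {
  tr <- attr(model, "trace")
  if (is.null(tr)) stop("model has no annealing trace", call. = FALSE)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$cycle, y = .data$score)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "cycle", y = "score after minimization") +
    ggplot2::theme_minimal()
}
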