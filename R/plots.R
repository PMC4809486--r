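#' Plot RMSE against the selection ratio
#'
#' Line chart of estimation precision (RMSE) versus the selection ratio,
#' one line per correction method, faceted by estimator. Accepts either an
#' accuracy tibble ([accuracy_summary()]) or a full `rr_condition` run via
#' [autoplot()].
#'
#' @param accuracy An accuracy tibble with columns `sr`, `rmse`, `method`,
#'   `estimator`.
#' @param estimators Which estimators to show (default all present).
#' @return A ggplot object.
#' @export
plot_rmse_by_sr <- function(accuracy, estimators = unique(accuracy$estimator)) {
  d <- dplyr::filter(accuracy, .data$estimator %in% estimators,
                     !is.na(.data$rmse))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sr, y = .data$rmse,
                                  colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~estimator, scales = "free_y") +
    ggplot2::scale_x_continuous(breaks = sort(unique(d$sr))) +
    ggplot2::labs(x = "Selection ratio", y = "RMSE", colour = "Method") +
    ggplot2::theme_minimal()
}

#' @rdname plot_rmse_by_sr
#' @param object An `rr_condition` object.
#' @param ... Passed on to [plot_rmse_by_sr()].
#' @method autoplot rr_condition
#' @export
autoplot.rr_condition <- function(object, ...) {
  plot_rmse_by_sr(object$accuracy, ...)
}
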