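#' Plot posterior densities of the choice-model population parameters
#'
#' One panel per male-strain SD and cross-context correlation, with the
#' posterior mode and 95% HDCI marked. SD posteriors are typically
#' right-skewed, which is why the package summarizes with modes and
#' highest-density intervals rather than means and quantiles.
#'
#' @param object A `choice_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.choice_fit <- function(object, ...) {
  pars <- object$parameters[grepl("^(sigma|R)\\[", object$parameters)]
  long <- object$draws |>
    dplyr::select(dplyr::all_of(pars)) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "parameter",
                        values_to = "value")
  summ <- tidy(object, check_rhat = FALSE)
  summ <- summ[summ$parameter %in% pars, ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::geom_vline(data = summ,
                        ggplot2::aes(xintercept = .data$mode),
                        linetype = 2) +
    ggplot2::geom_errorbarh(
      data = summ,
      ggplot2::aes(xmin = .data$.lower, xmax = .data$.upper, y = 0),
      height = 0, inherit.aes = FALSE) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = NULL, y = "posterior density")
}

#' Plot marginal means of the cross contrast
#'
#' Point-and-interval display of the within- versus between-strain
#' estimated marginal means (+/- 1 SE): inbreeding depression appears as a
#' lower within-strain mean.
#'
#' @param object A `cross_lmm`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cross_lmm <- function(object, ...) {
  ggplot2::ggplot(object$emm,
                  ggplot2::aes(x = .data$level, y = .data$emmean)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$emmean - .data$se,
                                        ymax = .data$emmean + .data$se),
                           width = 0.1) +
    ggplot2::labs(x = "cross", y = paste("marginal mean", object$response))
}

#' Plot aligned landmark configurations
#'
#' Scatter of all aligned landmarks with the mean shape overlaid — a quick
#' check that the Procrustes fit removed position, orientation and size.
#'
#' @param object A `shape_space`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.shape_space <- function(object, ...) {
  k <- object$k
  n <- nrow(object$aligned)
  long <- tibble::tibble(
    wing_id = rep(object$info$wing_id, each = k),
    landmark = rep(seq_len(k), n),
    x = as.vector(t(object$aligned[, seq(1, 2 * k, 2), drop = FALSE])),
    y = as.vector(t(object$aligned[, seq(2, 2 * k, 2), drop = FALSE])))
  mean_df <- tibble::tibble(landmark = seq_len(k),
                            x = object$mean_shape[, 1],
                            y = object$mean_shape[, 2])
  ggplot2::ggplot(long, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.5) +
    ggplot2::geom_point(data = mean_df, color = "red", size = 2) +
    ggplot2::geom_text(data = mean_df,
                       ggplot2::aes(label = .data$landmark),
                       nudge_y = 0.02, color = "red", size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL)
}
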