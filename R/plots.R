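#' Plot a simulated A-Ci curve
#'
#' Net assimilation against intercellular CO2, coloured by the limiting
#' process, from one or more curves produced by [simulate_aci()]. Supply a
#' `label` column (e.g. the sigma value per curve) to compare arrangements
#' on one panel.
#'
#' @param curve A curve tibble from [simulate_aci()], optionally with a
#'   `label` column distinguishing multiple curves.
#' @return A ggplot object.
#' @export
plot_aci <- function(curve) {
  aes_line <- if ("label" %in% names(curve)) {
    ggplot2::aes(x = .data$ci_ubar, y = .data$a_umol,
                 colour = factor(.data$label), group = factor(.data$label))
  } else {
    ggplot2::aes(x = .data$ci_ubar, y = .data$a_umol)
  }
  ggplot2::ggplot(curve, aes_line) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$limitation), size = 1.6) +
    ggplot2::labs(x = expression(C[i] ~ "(" * mu * "bar)"),
                  y = expression(A ~ "(" * mu * "mol" ~ m^-2 ~ s^-1 * ")"),
                  colour = "curve", shape = "limitation") +
    ggplot2::theme_minimal()
}

#' Plot apparent mesophyll conductance along Ci
#'
#' The signature diagnostic of the two-resistance model: `gm_app` declines
#' towards the compensation point whenever `omega*(1-sigma) > 0`, while the
#' classical model predicts a horizontal line at `gm_dif`.
#'
#' @inheritParams plot_aci
#' @param gm_dif Optional intrinsic conductance to draw as a reference line.
#' @return A ggplot object.
#' @export
plot_gm_profile <- function(curve, gm_dif = NULL) {
  aes_line <- if ("label" %in% names(curve)) {
    ggplot2::aes(x = .data$ci_ubar, y = .data$gm_app,
                 colour = factor(.data$label), group = factor(.data$label))
  } else {
    ggplot2::aes(x = .data$ci_ubar, y = .data$gm_app)
  }
  p <- ggplot2::ggplot(tidyr::drop_na(curve, "gm_app"), aes_line) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(C[i] ~ "(" * mu * "bar)"),
                  y = expression(g[m * ",app"] ~
                                   "(mol" ~ m^-2 ~ s^-1 ~ bar^-1 * ")"),
                  colour = "curve") +
    ggplot2::theme_minimal()
  if (!is.null(gm_dif)) {
    p <- p + ggplot2::geom_hline(yintercept = gm_dif, linetype = "dashed")
  }
  p
}

#' Diagnostic plot for a multi-O2 conductance fit
#'
#' Observed versus fitted net assimilation, one colour per O2 level, with
#' the 1:1 line.
#'
#' @param object A `"gm_fit"` object from [fit_gm_multi_o2()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gm_fit
#' @export
autoplot.gm_fit <- function(object, ...) {
  d <- mutate(object$data, fitted = object$fitted)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fitted, y = .data$a_umol,
                                  colour = factor(.data$o_mbar))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "fitted A", y = "observed A",
                  colour = expression(O[2] ~ "(mbar)")) +
    ggplot2::theme_minimal()
}
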