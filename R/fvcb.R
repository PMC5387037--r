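#' Gross Rubisco carboxylation rate
#'
#' Evaluates the FvCB hyperbola \eqn{V_c = x_1 C_c / (C_c + x_2)} for the
#' given limitation state. Saturates at `x1` as `Cc` grows; half-saturates
#' at `Cc = x2`.
#'
#' @param Cc Chloroplast CO2 partial pressure, ubar (vectorised, > 0).
#' @param s A [limitation_params()] state.
#' @return Carboxylation flux, umol m^-2 s^-1.
#' @export
carboxylation <- function(Cc, s) {
  check_cc(Cc)
  s$x1 * Cc / (Cc + s$x2)
}

#' Photorespiratory CO2 release
#'
#' \eqn{F = V_c \Gamma^*/C_c = x_1 \Gamma^*/(C_c + x_2)}: the mitochondrial
#' CO2 release driven by Rubisco oxygenation, proportional to carboxylation
#' through the ratio \eqn{\Gamma^*/C_c}.
#'
#' @inheritParams carboxylation
#' @param gstar \eqn{\Gamma^*}, ubar.
#' @return Photorespiratory flux, umol m^-2 s^-1 (zero when `gstar` is 0).
#' @export
photorespiratory_release <- function(Cc, s, gstar) {
  check_cc(Cc)
  s$x1 * gstar / (Cc + s$x2)
}

#' Net CO2 assimilation at known chloroplast CO2
#'
#' \eqn{A = V_c - F - R_d = (C_c - \Gamma^*) x_1/(C_c + x_2) - R_d}. Equals
#' `-Rd` at `Cc = Gamma*` and approaches `x1 - Rd` at saturating `Cc`.
#'
#' @inheritParams photorespiratory_release
#' @param Rd Day respiration, umol m^-2 s^-1.
#' @return Net assimilation flux, umol m^-2 s^-1.
#' @examples
#' p <- photo_params(80, 125, 1, 291, 194, 3.1)
#' s <- limitation_params(p, "rubisco")
#' net_assimilation(300, s, p$gamma_star, p$Rd)
#' @export
net_assimilation <- function(Cc, s, gstar, Rd) {
  check_cc(Cc)
  (Cc - gstar) * s$x1 / (Cc + s$x2) - Rd
}

#' Co-limited net assimilation
#'
#' Net assimilation as the minimum of the Rubisco-limited and
#' electron-transport-limited rates evaluated at the same chloroplast CO2.
#' Ties are labelled `"rubisco"` for deterministic reporting.
#'
#' @param Cc Chloroplast CO2 partial pressure, ubar (vectorised, > 0).
#' @param p A [photo_params()] object.
#' @return A tibble with one row per `Cc`: columns `cc_ubar`, `a_umol` and
#'   `limitation`.
#' @examples
#' p <- photo_params(80, 125, 1, 291, 194, 3.1)
#' colimited_assimilation(c(100, 300, 500), p)
#' @export
colimited_assimilation <- function(Cc, p) {
  stopifnot(inherits(p, "photo_params"))
  check_cc(Cc)
  sc <- limitation_params(p, "rubisco")
  sj <- limitation_params(p, "electron_transport")
  ac <- net_assimilation(Cc, sc, p$gamma_star, p$Rd)
  aj <- net_assimilation(Cc, sj, p$gamma_star, p$Rd)
  tibble(
    cc_ubar = Cc,
    a_umol = pmin(ac, aj),
    limitation = if_else(ac <= aj, "rubisco", "electron_transport")
  )
}

# shared domain guard: chloroplast CO2 must be strictly positive
check_cc <- function(Cc) {
  if (any(!is.finite(Cc)) || any(Cc <= 0)) {
    abort("`Cc` must be strictly positive.", class = "mesoflux_domain_error")
  }
  invisible(Cc)
}
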