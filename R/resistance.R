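# Vectorised positive root of the coupled drawdown balance
#   Cc = Ci - A*r - omega(1-sigma)(F+Rd)*r
# with A, F the FvCB hyperbolae. Writing beta = 1 - omega(1-sigma) and
# clearing (Cc + x2) gives Cc^2 + b*Cc + c = 0 with
#   b = x2 - Ci + r*x1 - r*beta*Rd
#   c = -(Ci*x2 + r*beta*x1*gstar + r*beta*Rd*x2)
# c < 0 for valid inputs, so the roots straddle zero and the positive root
# is the physical one.
solve_cc_quad <- function(Ci, x1, x2, gstar, Rd, r, beta) {
  b <- x2 - Ci + r * x1 - r * beta * Rd
  cc0 <- -(Ci * x2 + r * beta * x1 * gstar + r * beta * Rd * x2)
  disc <- b^2 - 4 * cc0
  if (any(disc < 0) || any(cc0 >= 0)) {
    abort(paste0("No positive root for the chloroplast-CO2 balance ",
                 "(discriminant or sign guard failed); check parameters."),
          class = "mesoflux_numerical_error")
  }
  (-b + sqrt(disc)) / 2
}

#' Solve chloroplast CO2 for one limitation state
#'
#' Solves the drawdown balance
#' \eqn{C_c = C_i - A\,r_{m,dif} - \omega(1-\sigma)(F+R_d)\,r_{m,dif}}
#' self-consistently with the FvCB rate equations for the given limitation
#' state. The balance reduces to a quadratic in `Cc`; the unique positive
#' root is returned. The arrangement parameters enter only through the
#' composite `omega * (1 - sigma)`.
#'
#' @param Ci Intercellular CO2 partial pressure, ubar (vectorised, > 0).
#' @param p A [photo_params()] object.
#' @param r A [resistance_params()] object.
#' @param s A [limitation_params()] state.
#' @return Chloroplast CO2 partial pressure(s), ubar.
#' @examples
#' p <- photo_params(80, 125, 1, 291, 194, 3.1)
#' r <- resistance_params(0.4, omega = 0.5, sigma = 1)
#' solve_cc(100, p, r, limitation_params(p, "rubisco"))
#' @export
solve_cc <- function(Ci, p, r, s) {
  stopifnot(inherits(p, "photo_params"), inherits(r, "resistance_params"),
            inherits(s, "limitation_state"))
  if (any(!is.finite(Ci)) || any(Ci <= 0)) {
    abort("`Ci` must be strictly positive.", class = "mesoflux_domain_error")
  }
  beta <- 1 - effective_sensitivity(r$omega, r$sigma)
  solve_cc_quad(Ci, s$x1, s$x2, p$gamma_star, p$Rd, r$rm_dif, beta)
}

#' Apparent mesophyll conductance from fluxes
#'
#' Closed form for the apparent conductance
#' \eqn{g_{m,app} = g_{m,dif} / [1 + \omega(1-\sigma)(F+R_d)/A]}, which
#' equals the drawdown ratio `A/(Ci - Cc)` of the corresponding operating
#' point. At `sigma = 1` or `omega = 0` it reduces to `gm_dif` regardless of
#' the flux ratio.
#'
#' @param A Net assimilation, umol m^-2 s^-1 (vectorised, non-zero).
#' @param F Photorespiratory release, umol m^-2 s^-1.
#' @param Rd Day respiration, umol m^-2 s^-1.
#' @param r A [resistance_params()] object.
#' @return Apparent mesophyll conductance, mol m^-2 s^-1 bar^-1.
#' @export
gm_app <- function(A, F, Rd, r) {
  stopifnot(inherits(r, "resistance_params"))
  if (any(A == 0)) {
    abort("`A` must be non-zero: gm_app is undefined at the compensation point.",
          class = "mesoflux_domain_error")
  }
  r$gm_dif / (1 + effective_sensitivity(r$omega, r$sigma) * (F + Rd) / A)
}

#' Solved leaf operating points along Ci
#'
#' For each intercellular CO2 value, solves the coupled biochemistry +
#' diffusion model under both limitation states, applies the FvCB minimum
#' rule to pick the operating state, and reports the full solved state.
#' `gm_app` is reported only where `A > 0` (it is undefined at and below the
#' compensation point).
#'
#' @param Ci Intercellular CO2 partial pressure(s), ubar.
#' @param p A [photo_params()] object.
#' @param r A [resistance_params()] object.
#' @return A tibble with one row per `Ci`: `ci_ubar`, `cc_ubar`,
#'   `cm_outer_ubar` (outer-cytosol CO2, `Ci - A*rwp`), `a_umol`, `vc_umol`,
#'   `f_umol`, `limitation`, `gm_app`.
#' @examples
#' p <- photo_params(80, 125, 1, 291, 194, 3.1)
#' r <- resistance_params(0.4, omega = 0.5, sigma = 0.5)
#' operating_point(c(100, 250, 400), p, r)
#' @export
operating_point <- function(Ci, p, r) {
  stopifnot(inherits(p, "photo_params"), inherits(r, "resistance_params"))
  sc <- limitation_params(p, "rubisco")
  sj <- limitation_params(p, "electron_transport")
  cc_c <- solve_cc(Ci, p, r, sc)
  cc_j <- solve_cc(Ci, p, r, sj)
  a_c <- net_assimilation(cc_c, sc, p$gamma_star, p$Rd)
  a_j <- net_assimilation(cc_j, sj, p$gamma_star, p$Rd)
  rub <- a_c <= a_j
  cc <- if_else(rub, cc_c, cc_j)
  a <- pmin(a_c, a_j)
  x1 <- if_else(rub, sc$x1, sj$x1)
  x2 <- if_else(rub, sc$x2, sj$x2)
  vc <- x1 * cc / (cc + x2)
  f <- x1 * p$gamma_star / (cc + x2)
  tibble(
    ci_ubar = Ci,
    cc_ubar = cc,
    cm_outer_ubar = Ci - a * r$rwp,
    a_umol = a,
    vc_umol = vc,
    f_umol = f,
    limitation = if_else(rub, "rubisco", "electron_transport"),
    gm_app = if_else(a > 0, r$gm_dif /
                       (1 + effective_sensitivity(r$omega, r$sigma) *
                          (f + p$Rd) / a),
                     NA_real_)
  )
}

#' Simulate an A-Ci curve
#'
#' Convenience wrapper around [operating_point()] for a strictly increasing
#' Ci grid, the standard way gas-exchange response curves are recorded.
#'
#' @param p A [photo_params()] object.
#' @param r A [resistance_params()] object.
#' @param ci Strictly increasing vector of Ci values, ubar.
#' @return A tibble as in [operating_point()], ordered along `ci`.
#' @examples
#' p <- photo_params(80, 125, 1, 291, 194, 3.1)
#' r <- resistance_params(0.4, omega = 0.5, sigma = 0.5)
#' head(simulate_aci(p, r, seq(50, 400, by = 50)))
#' @export
simulate_aci <- function(p, r, ci) {
  if (any(diff(ci) <= 0)) {
    abort("`ci` must be strictly increasing.", class = "mesoflux_domain_error")
  }
  operating_point(ci, p, r)
}

#' CO2 compensation points of the coupled model
#'
#' At the compensation point `A = 0`, so `F + Rd = Vc` and the chloroplast
#' compensation point has the closed form
#' \eqn{C_{c,\Gamma} = (\Gamma^* x_1 + R_d x_2)/(x_1 - R_d)}. The
#' intercellular compensation point then follows from the drawdown balance:
#' \eqn{C_{i,\Gamma} = C_{c,\Gamma} + \omega(1-\sigma) V_c r_{m,dif}}. The
#' two coincide when `omega*(1-sigma) = 0` (classical model).
#'
#' Each limitation state has its own compensation pair; under the minimum
#' rule the model-wide ("overall") compensation point is the larger of the
#' two state-specific `Ci_Gamma` values, since the lower branch is the last
#' to reach zero as Ci falls. `kind = "overall"` returns that binding pair,
#' so the solved operating point there has `A = 0` to solver tolerance.
#'
#' @param p A [photo_params()] object.
#' @param r A [resistance_params()] object.
#' @param kind `"rubisco"` (default), `"electron_transport"`, or
#'   `"overall"` for the binding compensation point of the full model.
#' @return A one-row tibble: `ci_gamma_ubar`, `cc_gamma_ubar`.
#' @examples
#' p <- photo_params(80, 125, 1, 291, 194, 3.1)
#' co2_compensation(p, resistance_params(0.4, 0.5, sigma = 0))
#' @export
co2_compensation <- function(p, r,
                             kind = c("rubisco", "electron_transport",
                                      "overall")) {
  stopifnot(inherits(p, "photo_params"), inherits(r, "resistance_params"))
  kind <- match.arg(kind)
  if (kind == "overall") {
    both <- lapply(c("rubisco", "electron_transport"), function(k)
      co2_compensation(p, r, k))
    pick <- which.max(c(both[[1]]$ci_gamma_ubar, both[[2]]$ci_gamma_ubar))
    return(both[[pick]])
  }
  s <- limitation_params(p, kind)
  if (s$x1 <= p$Rd) {
    abort("No compensation point: x1 <= Rd (respiration exceeds capacity).",
          class = "mesoflux_domain_error")
  }
  cc_g <- (p$gamma_star * s$x1 + p$Rd * s$x2) / (s$x1 - p$Rd)
  vc <- s$x1 * cc_g / (cc_g + s$x2)
  ci_g <- cc_g + effective_sensitivity(r$omega, r$sigma) * vc * r$rm_dif
  tibble(ci_gamma_ubar = ci_g, cc_gamma_ubar = cc_g)
}
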