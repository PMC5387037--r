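#' Mesophyll conductance from the CO2 drawdown
#'
#' The classical definition \eqn{g_m = A/(C_i - C_c)}. Applied to operating
#' points of the two-resistance model this yields the *apparent*
#' conductance, which coincides with the intrinsic `gm_dif` only when
#' `omega*(1-sigma) = 0`.
#'
#' @param A Net assimilation, umol m^-2 s^-1 (vectorised).
#' @param Ci,Cc Intercellular and chloroplast CO2 partial pressures, ubar.
#' @return Conductance, mol m^-2 s^-1 bar^-1.
#' @export
gm_from_drawdown <- function(A, Ci, Cc) {
  if (any(Ci == Cc)) {
    abort("`Ci` equals `Cc`: drawdown conductance is undefined.",
          class = "mesoflux_domain_error")
  }
  A / (Ci - Cc)
}

#' Chloroplast CO2 by the variable-J inversion
#'
#' Inverts the (NADPH-limited) electron-transport-limited FvCB equation for
#' `Cc` given measured `A` and fluorescence-derived `J`:
#' \deqn{C_c = \Gamma^* \frac{J + 8(A + R_d)}{J - 4(A + R_d)}}
#' Substituting the result back into the Aj equation recovers `A` exactly.
#' The inversion is only meaningful where electron transport actually limits
#' assimilation; applied in the Rubisco-limited region it underestimates
#' `Cc` and hence the conductances derived from it.
#'
#' @param A Net assimilation, umol m^-2 s^-1 (vectorised).
#' @param J Linear electron transport rate, umol m^-2 s^-1.
#' @param Rd Day respiration, umol m^-2 s^-1.
#' @param gstar \eqn{\Gamma^*}, ubar.
#' @return Chloroplast CO2 partial pressure, ubar.
#' @examples
#' variable_j_cc(A = 20, J = 125, Rd = 1, gstar = 34)
#' @export
variable_j_cc <- function(A, J, Rd, gstar) {
  if (any(J <= 4 * (A + Rd))) {
    abort("Infeasible fluxes: need J > 4*(A + Rd) for the variable-J inversion.",
          class = "mesoflux_domain_error")
  }
  gstar * (J + 8 * (A + Rd)) / (J - 4 * (A + Rd))
}

#' Back-calculate intrinsic mesophyll conductance from one record
#'
#' Inverts the drawdown balance for `gm_dif` given an estimate of `Cc` and
#' the arrangement parameters. The photorespiratory flux is inferred from
#' the same `Cc` under test, \eqn{\hat F = (A + R_d)\Gamma^*/(C_c -
#' \Gamma^*)}, since the estimation pathway has no access to the true `F`:
#' \deqn{\hat g_{m,dif} = \frac{A + \omega(1-\sigma)(\hat F + R_d)}
#'   {C_i - C_c}}
#' With the model-true `Cc` this recovers the configured `gm_dif` exactly;
#' with a variable-J `Cc` it does so only in the Aj-limited region.
#'
#' @param A Net assimilation, umol m^-2 s^-1 (vectorised).
#' @param Ci Intercellular CO2, ubar.
#' @param Cc Chloroplast CO2 estimate, ubar; must exceed `gstar`.
#' @param Rd Day respiration, umol m^-2 s^-1.
#' @param omega,sigma Arrangement parameters, each in `[0, 1]`.
#' @param gstar \eqn{\Gamma^*}, ubar.
#' @return Intrinsic conductance estimate, mol m^-2 s^-1 bar^-1.
#' @export
backcalc_gm_dif <- function(A, Ci, Cc, Rd, omega, sigma, gstar) {
  if (any(Cc <= gstar)) {
    abort("`Cc` must exceed Gamma* (inferred photorespiration would be negative).",
          class = "mesoflux_domain_error")
  }
  fhat <- (A + Rd) * gstar / (Cc - gstar)
  num <- A + effective_sensitivity(omega, sigma) * (fhat + Rd)
  if (any(num == 0)) {
    abort("Zero net flux through the mesophyll: gm_dif is undefined.",
          class = "mesoflux_domain_error")
  }
  num / (Ci - Cc)
}

#' Variable-J conductance estimates for a gas-exchange table
#'
#' Applies the variable-J method row-wise to a table of gas-exchange
#' records: estimates `Cc` by [variable_j_cc()], the apparent conductance by
#' [gm_from_drawdown()], and (when `omega`/`sigma` are given) the intrinsic
#' conductance by [backcalc_gm_dif()]. Rows where the inversion is
#' infeasible (`J <= 4(A+Rd)`) or `Cc <= Gamma*` are returned as `NA` with a
#' warning rather than dropped, so the output aligns with the input.
#'
#' @param data A data frame with columns `ci_ubar`, `a_umol`, `j_umol` and
#'   (optionally) `rd_umol`, `o_mbar`.
#' @param gstar \eqn{\Gamma^*}, ubar. Required unless `Sco` is given.
#' @param Sco Optional Rubisco specificity; with per-row `o_mbar` this
#'   computes a per-row `gstar`.
#' @param rd_default Day respiration fallback for tables without `rd_umol`.
#' @param omega,sigma Optional arrangement parameters for the intrinsic
#'   back-calculation column.
#' @return The input tibble with added columns `cc_varj_ubar`,
#'   `gm_app_varj` and (if requested) `gm_dif_varj`.
#' @export
variable_j_gm <- function(data, gstar = NULL, Sco = NULL, rd_default = NULL,
                          omega = NULL, sigma = NULL) {
  data <- as_tibble(data)
  need <- c("ci_ubar", "a_umol", "j_umol")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort(paste0("Missing column(s): ", paste(miss, collapse = ", ")),
          class = "mesoflux_validation_error")
  }
  rd <- if ("rd_umol" %in% names(data)) data$rd_umol else {
    if (is.null(rd_default)) {
      abort("No `rd_umol` column and no `rd_default` supplied.",
            class = "mesoflux_validation_error")
    }
    rep(rd_default, nrow(data))
  }
  gs <- if (!is.null(gstar)) {
    rep_len(gstar, nrow(data))
  } else {
    if (is.null(Sco) || !("o_mbar" %in% names(data))) {
      abort("Supply `gstar`, or `Sco` with an `o_mbar` column.",
            class = "mesoflux_validation_error")
    }
    gamma_star(Sco, data$o_mbar)
  }
  feasible <- data$j_umol > 4 * (data$a_umol + rd)
  if (!all(feasible)) {
    warn(sprintf("%d record(s) infeasible for variable-J (J <= 4(A+Rd)); NA returned.",
                 sum(!feasible)))
  }
  cc <- rep(NA_real_, nrow(data))
  cc[feasible] <- variable_j_cc(data$a_umol[feasible], data$j_umol[feasible],
                                rd[feasible], gs[feasible])
  out <- mutate(data,
                cc_varj_ubar = cc,
                gm_app_varj = .data$a_umol / (.data$ci_ubar - cc))
  if (!is.null(omega) && !is.null(sigma)) {
    ok <- feasible & !is.na(cc) & cc > gs
    gmd <- rep(NA_real_, nrow(data))
    if (any(ok)) {
      gmd[ok] <- backcalc_gm_dif(data$a_umol[ok], data$ci_ubar[ok], cc[ok],
                                 rd[ok], omega, sigma, gs[ok])
    }
    out$gm_dif_varj <- gmd
  }
  out
}

# forward net assimilation for the fitter: vectorised over records with
# per-row O (hence per-row gstar and Rubisco x2) and per-row J; arrangement
# enters only through omega_eff = omega*(1-sigma).
forward_a_multi <- function(ci, o, j, p, gm_dif, omega_eff) {
  gs <- gamma_star(p$Sco, o)
  r <- 1 / gm_dif
  beta <- 1 - omega_eff
  x2c <- p$KmC * (1 + o / p$KmO)
  cc_c <- solve_cc_quad(ci, p$Vcmax, x2c, gs, p$Rd, r, beta)
  cc_j <- solve_cc_quad(ci, j / 4, 2 * gs, gs, p$Rd, r, beta)
  a_c <- (cc_c - gs) * p$Vcmax / (cc_c + x2c)
  a_j <- (cc_j - gs) * (j / 4) / (cc_j + 2 * gs)
  pmin(a_c - p$Rd, a_j - p$Rd)
}

#' Fit intrinsic mesophyll conductance from multi-O2 gas exchange
#'
#' Estimates the intrinsic diffusional mesophyll conductance `gm_dif` and
#' the effective arrangement sensitivity `omega_eff = omega*(1-sigma)` by
#' bounded nonlinear least squares on observed net assimilation across at
#' least two O2 levels. A single O2 level cannot separate the two
#' parameters, because the sensitivity acts through the photorespiratory
#' flux ratio, which O2 modulates.
#'
#' The sum of squared A residuals is minimised with `L-BFGS-B` from every
#' point of a fixed 5 x 5 start grid (`gm_dif` in \{0.05, 0.15, 0.4, 1, 3\},
#' `omega_eff` in \{0, 0.25, 0.5, 0.75, 1\}); the best converged start is
#' reported, making the fit deterministic.
#'
#' @param data A data frame with columns `ci_ubar`, `a_umol`, `o_mbar` and
#'   optionally `j_umol`, `rd_umol` (falling back to `p$J`, `p$Rd`).
#' @param p A [photo_params()] object carrying the known biochemistry
#'   (`Vcmax`, `KmC`, `KmO`, `Sco`, and defaults for `J`, `Rd`).
#' @param gm_bounds Box bounds for `gm_dif`, mol m^-2 s^-1 bar^-1.
#' @return An object of class `"gm_fit"` with components `coefficients`
#'   (`gm_dif`, `omega_eff`), `fitted`, `residuals`, `rss`, `residual_norm`,
#'   `converged`, `n_obs`, `o2_levels`, `data` and the winning `optim`
#'   result. Supports [tidy()], [glance()] and [ggplot2::autoplot()].
#' @examples
#' p <- photo_params(80, 125, 1, 291, 194, 3.1)
#' r <- resistance_params(0.4, omega = 0.5, sigma = 0.5)
#' d <- generate_gas_exchange(p, r, ci = seq(100, 400, 50),
#'                            o2_levels = c(20, 210))
#' fit_gm_multi_o2(d, p)
#' @export
fit_gm_multi_o2 <- function(data, p, gm_bounds = c(1e-3, 10)) {
  stopifnot(inherits(p, "photo_params"))
  data <- as_tibble(data)
  need <- c("ci_ubar", "a_umol", "o_mbar")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort(paste0("Missing column(s): ", paste(miss, collapse = ", ")),
          class = "mesoflux_validation_error")
  }
  o2 <- sort(unique(data$o_mbar))
  if (length(o2) < 2) {
    abort("Need records at >= 2 distinct O2 levels to identify (gm_dif, omega_eff).",
          class = "mesoflux_validation_error")
  }
  if (nrow(data) < 6) {
    abort("Need >= 6 records for the two-parameter fit.",
          class = "mesoflux_validation_error")
  }
  j <- if ("j_umol" %in% names(data)) data$j_umol else rep(p$J, nrow(data))
  ci <- data$ci_ubar
  o <- data$o_mbar
  a_obs <- data$a_umol

  obj <- function(par) {
    a_mod <- forward_a_multi(ci, o, j, p, gm_dif = par[1], omega_eff = par[2])
    sum((a_obs - a_mod)^2)
  }
  starts <- expand.grid(gm_dif = c(0.05, 0.15, 0.4, 1, 3),
                        omega_eff = c(0, 0.25, 0.5, 0.75, 1))
  lower <- c(gm_bounds[1], 0)
  upper <- c(gm_bounds[2], 1)
  fits <- purrr::pmap(starts, function(gm_dif, omega_eff) {
    tryCatch(
      optim(c(gm_dif, omega_eff), obj, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = 500, factr = 1e4)),
      error = function(e) list(value = Inf, convergence = 99L, par = c(NA, NA))
    )
  })
  vals <- map_dbl(fits, "value")
  best <- fits[[which.min(vals)]]
  # L-BFGS-B aborts its line search (code 52) when it lands exactly on a
  # zero-residual minimum; polish with a bounded Nelder-Mead pass and take
  # the convergence flag from that.
  obj_box <- function(par) {
    if (par[1] < lower[1] || par[1] > upper[1] ||
        par[2] < lower[2] || par[2] > upper[2]) return(Inf)
    obj(par)
  }
  polish <- optim(best$par, obj_box, method = "Nelder-Mead",
                  control = list(maxit = 1000, reltol = 1e-12))
  if (polish$value <= best$value) {
    best <- polish
  } else {
    best$convergence <- polish$convergence
  }
  est <- c(gm_dif = unname(best$par[1]), omega_eff = unname(best$par[2]))
  fitted <- forward_a_multi(ci, o, j, p, est["gm_dif"], est["omega_eff"])
  res <- a_obs - fitted
  structure(list(
    coefficients = est,
    fitted = fitted,
    residuals = res,
    rss = sum(res^2),
    residual_norm = sqrt(sum(res^2)),
    converged = is.finite(best$value) && best$convergence == 0L,
    n_obs = nrow(data),
    o2_levels = o2,
    data = data,
    optim = best
  ), class = "gm_fit")
}

#' @export
print.gm_fit <- function(x, ...) {
  cat("<gm_fit> multi-O2 mesophyll conductance fit\n")
  cat(sprintf("  gm_dif    = %.4f mol m-2 s-1 bar-1\n",
              x$coefficients["gm_dif"]))
  cat(sprintf("  omega_eff = %.4f  (omega * (1 - sigma))\n",
              x$coefficients["omega_eff"]))
  cat(sprintf("  %d records at O2 = {%s} mbar; residual norm %.4g; %s\n",
              x$n_obs, paste(x$o2_levels, collapse = ", "),
              x$residual_norm,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
coef.gm_fit <- function(object, ...) object$coefficients

#' Tidy a multi-O2 conductance fit
#'
#' @param x A `"gm_fit"` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`.
#' @method tidy gm_fit
#' @export
tidy.gm_fit <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients))
}

#' One-row summary of a multi-O2 conductance fit
#'
#' @param x A `"gm_fit"` object.
#' @param ... Unused.
#' @return A one-row tibble: `rss`, `residual_norm`, `n_obs`,
#'   `n_o2_levels`, `converged`.
#' @method glance gm_fit
#' @export
glance.gm_fit <- function(x, ...) {
  tibble(rss = x$rss,
         residual_norm = x$residual_norm,
         n_obs = x$n_obs,
         n_o2_levels = length(x$o2_levels),
         converged = x$converged)
}
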