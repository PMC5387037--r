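#' CO2 compensation point in the absence of day respiration
#'
#' `gamma_star()` returns \eqn{\Gamma^* = 0.5\,O / S_{c/o}}, the chloroplast
#' CO2 partial pressure at which photorespiratory CO2 release exactly offsets
#' Rubisco carboxylation. The factor 0.5 reflects the release of half a CO2
#' per oxygenation.
#'
#' @param Sco Rubisco relative CO2/O2 specificity, mbar ubar^-1. Must be
#'   strictly positive.
#' @param O Oxygen partial pressure, mbar. Must be non-negative.
#'
#' @return \eqn{\Gamma^*} in ubar (mbar divided by mbar ubar^-1).
#'
#' @examples
#' gamma_star(Sco = 3.1, O = 210) # ~33.9 ubar at ambient O2
#' @export
gamma_star <- function(Sco, O) {
  if (any(!is.finite(Sco)) || any(Sco <= 0)) {
    abort("`Sco` must be strictly positive.", class = "mesoflux_domain_error")
  }
  if (any(!is.finite(O)) || any(O < 0)) {
    abort("`O` must be non-negative.", class = "mesoflux_domain_error")
  }
  0.5 * O / Sco
}

#' FvCB biochemical parameter set
#'
#' Bundles the Rubisco and electron-transport parameters of the FvCB C3
#' photosynthesis model on a chloroplast-CO2 basis. \eqn{\Gamma^*} is derived
#' from `Sco` and `O` via [gamma_star()] and stored alongside the inputs.
#'
#' Unit convention used throughout the package: CO2 partial pressures
#' (Cc, Ci, Gamma*, KmC) in ubar; O2 partial pressures (O, KmO) in mbar;
#' fluxes in umol m^-2 s^-1; resistances in bar m^2 s mol^-1, so that
#' resistance times flux gives ubar directly.
#'
#' @param Vcmax Maximum Rubisco carboxylation rate, umol m^-2 s^-1.
#' @param J Linear electron transport rate, umol m^-2 s^-1.
#' @param Rd Day respiration (mitochondrial CO2 release in the light other
#'   than photorespiration), umol m^-2 s^-1. Must be below `Vcmax`.
#' @param KmC Rubisco Michaelis constant for CO2, ubar.
#' @param KmO Rubisco Michaelis constant for O2, mbar.
#' @param Sco Rubisco relative specificity, mbar ubar^-1.
#' @param O Oxygen partial pressure, mbar. Defaults to ambient (210 mbar).
#'
#' @return An object of class `"photo_params"`: a named list with the inputs
#'   plus the derived `gamma_star` (ubar).
#'
#' @examples
#' p <- photo_params(Vcmax = 80, J = 125, Rd = 1,
#'                   KmC = 291, KmO = 194, Sco = 3.1)
#' p$gamma_star
#' @export
photo_params <- function(Vcmax, J, Rd, KmC, KmO, Sco, O = 210) {
  fields <- list(Vcmax = Vcmax, J = J, Rd = Rd, KmC = KmC, KmO = KmO,
                 Sco = Sco, O = O)
  bad <- names(fields)[!vapply(fields, function(v)
    is.numeric(v) && length(v) == 1L && is.finite(v), logical(1))]
  if (length(bad)) {
    abort(paste0("Non-finite or non-scalar parameter(s): ",
                 paste(bad, collapse = ", ")),
          class = "mesoflux_validation_error")
  }
  pos <- c("Vcmax", "J", "Rd", "KmC", "KmO", "Sco")
  neg <- pos[vapply(fields[pos], function(v) v <= 0, logical(1))]
  if (O < 0) neg <- c(neg, "O")
  if (length(neg)) {
    abort(paste0("Parameter(s) out of range (must be > 0; O >= 0): ",
                 paste(neg, collapse = ", ")),
          class = "mesoflux_validation_error")
  }
  if (Rd >= Vcmax) {
    abort("`Rd` must be smaller than `Vcmax`.",
          class = "mesoflux_validation_error")
  }
  gs <- gamma_star(Sco, O)
  if (gs >= KmC * (1 + O / KmO)) {
    abort("Derived Gamma* must be below KmC*(1 + O/KmO).",
          class = "mesoflux_validation_error")
  }
  structure(c(fields, list(gamma_star = gs)), class = "photo_params")
}

#' @export
print.photo_params <- function(x, ...) {
  cat("<photo_params>\n")
  cat(sprintf("  Vcmax = %g, J = %g, Rd = %g umol m-2 s-1\n",
              x$Vcmax, x$J, x$Rd))
  cat(sprintf("  KmC = %g ubar, KmO = %g mbar, Sco = %g mbar/ubar\n",
              x$KmC, x$KmO, x$Sco))
  cat(sprintf("  O = %g mbar  =>  Gamma* = %.3f ubar\n", x$O, x$gamma_star))
  invisible(x)
}

#' Limitation-specific FvCB kinetic coefficients
#'
#' The FvCB rate equations share one hyperbolic form
#' \eqn{V_c = x_1 C_c / (C_c + x_2)}, with `(x1, x2)` depending on the
#' limiting process: `(Vcmax, KmC(1 + O/KmO))` under Rubisco limitation and
#' `(J/4, 2 Gamma*)` under (NADPH-limited) electron-transport limitation.
#'
#' @param p A [photo_params()] object.
#' @param kind `"rubisco"` or `"electron_transport"`.
#'
#' @return An object of class `"limitation_state"`: list with `kind`, `x1`
#'   (umol m^-2 s^-1) and `x2` (ubar).
#'
#' @examples
#' p <- photo_params(80, 125, 1, 291, 194, 3.1)
#' limitation_params(p, "rubisco")$x2      # KmC * (1 + O/KmO)
#' limitation_params(p, "electron_transport")$x1  # J / 4
#' @export
limitation_params <- function(p, kind = c("rubisco", "electron_transport")) {
  stopifnot(inherits(p, "photo_params"))
  kind <- match.arg(kind)
  if (kind == "rubisco") {
    st <- list(kind = kind, x1 = p$Vcmax, x2 = p$KmC * (1 + p$O / p$KmO))
  } else {
    st <- list(kind = kind, x1 = p$J / 4, x2 = 2 * p$gamma_star)
  }
  structure(st, class = "limitation_state")
}

#' Mesophyll diffusion resistance network
#'
#' Describes the physical CO2 diffusion path from the substomatal cavity to
#' the Rubisco carboxylation sites as two lumped resistances in series:
#' cell wall + plasmalemma (plus most cytosol), `r_wp`, and chloroplast
#' envelope + stroma (plus residual cytosol), `r_ch`, with
#' `r_m,dif = r_wp + r_ch = 1/gm_dif` and `omega = r_ch / r_m,dif`.
#'
#' The organelle-arrangement parameter `sigma` is the fraction of
#' mitochondria-released (photo)respired CO2 that must additionally cross
#' `r_ch` to escape the leaf: `sigma = 1` corresponds to mitochondria behind
#' a continuous chloroplast layer (the classical single-resistance picture),
#' `sigma = 0` to mitochondria in the outer cytosol (the two-resistance
#' model of Tholen and co-workers). For discontinuous chloroplast coverage
#' `sigma = k * lambda`, where `lambda` is the inner-cytosol mitochondria
#' fraction and `k` a chloroplast-gap diffusion factor; supplying `lambda`
#' (and optionally `k`) instead of `sigma` performs this reduction.
#'
#' @param gm_dif Intrinsic (diffusional) mesophyll conductance,
#'   mol m^-2 s^-1 bar^-1.
#' @param omega Fraction of `r_m,dif` contributed by the chloroplast
#'   component, in `[0, 1]`.
#' @param sigma Fraction of (photo)respired CO2 experiencing `r_ch` on
#'   escape, in `[0, 1]`. Give either `sigma` or `lambda`.
#' @param lambda Optional fraction of mitochondria in the inner cytosol,
#'   in `[0, 1]`; used as `sigma = k * lambda` when `sigma` is missing.
#' @param k Optional chloroplast-gap factor (default 1 when `lambda` is
#'   given); must keep `k * lambda` within `[0, 1]`.
#' @param rsc Stomatal plus boundary-layer resistance, bar m^2 s mol^-1.
#'   Defaults to `1/gm_dif`.
#'
#' @return An object of class `"resistance_params"`: list with `gm_dif`,
#'   `omega`, `sigma`, `rm_dif`, `rwp`, `rch`, `rsc` (and `lambda`, `k`
#'   when supplied).
#'
#' @examples
#' resistance_params(gm_dif = 0.4, omega = 0.5, sigma = 0.5)
#' resistance_params(gm_dif = 0.4, omega = 0.65, lambda = 0.8) # sigma = 0.8
#' @export
resistance_params <- function(gm_dif, omega, sigma = NULL, lambda = NULL,
                              k = NULL, rsc = NULL) {
  if (!is.numeric(gm_dif) || length(gm_dif) != 1L || !is.finite(gm_dif) ||
      gm_dif <= 0) {
    abort("`gm_dif` must be a positive scalar.",
          class = "mesoflux_validation_error")
  }
  if (!is.numeric(omega) || length(omega) != 1L || omega < 0 || omega > 1) {
    abort("`omega` must lie in [0, 1].", class = "mesoflux_validation_error")
  }
  if (is.null(sigma)) {
    if (is.null(lambda)) {
      abort("Supply `sigma`, or `lambda` (with optional `k`).",
            class = "mesoflux_validation_error")
    }
    if (lambda < 0 || lambda > 1) {
      abort("`lambda` must lie in [0, 1].",
            class = "mesoflux_validation_error")
    }
    k <- k %||% 1
    if (k < 0) abort("`k` must be non-negative.",
                     class = "mesoflux_validation_error")
    sigma <- k * lambda
    if (sigma > 1) {
      abort("`k * lambda` must not exceed 1 (so k <= 1/lambda).",
            class = "mesoflux_validation_error")
    }
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0 || sigma > 1) {
    abort("`sigma` must lie in [0, 1].", class = "mesoflux_validation_error")
  }
  rm_dif <- 1 / gm_dif
  rsc <- rsc %||% rm_dif
  if (rsc <= 0) abort("`rsc` must be positive.",
                      class = "mesoflux_validation_error")
  structure(list(gm_dif = gm_dif, omega = omega, sigma = sigma,
                 lambda = lambda, k = k,
                 rm_dif = rm_dif, rwp = (1 - omega) * rm_dif,
                 rch = omega * rm_dif, rsc = rsc),
            class = "resistance_params")
}

#' @export
print.resistance_params <- function(x, ...) {
  cat("<resistance_params>\n")
  cat(sprintf("  gm_dif = %g mol m-2 s-1 bar-1 (rm_dif = %g)\n",
              x$gm_dif, x$rm_dif))
  cat(sprintf("  omega = %g  =>  rwp = %g, rch = %g bar m2 s mol-1\n",
              x$omega, x$rwp, x$rch))
  cat(sprintf("  sigma = %g (effective sensitivity omega*(1-sigma) = %g)\n",
              x$sigma, x$omega * (1 - x$sigma)))
  cat(sprintf("  rsc = %g bar m2 s mol-1\n", x$rsc))
  invisible(x)
}

#' Effective chloroplast-resistance sensitivity
#'
#' The apparent mesophyll conductance depends on organelle arrangement only
#' through the composite \eqn{\omega(1-\sigma)}: zero recovers the classical
#' constant-gm model, `omega` itself recovers the outer-mitochondria
#' two-resistance model.
#'
#' @param omega,sigma Dimensionless, each in `[0, 1]`.
#' @return `omega * (1 - sigma)`, in `[0, 1]`.
#' @examples
#' effective_sensitivity(0.65, 0.8) # 0.13
#' @export
effective_sensitivity <- function(omega, sigma) {
  if (any(omega < 0 | omega > 1) || any(sigma < 0 | sigma > 1)) {
    abort("`omega` and `sigma` must lie in [0, 1].",
          class = "mesoflux_domain_error")
  }
  omega * (1 - sigma)
}

#' Convert a fitted effective sensitivity to sigma given anatomical omega
#'
#' Gas exchange alone identifies only the composite `omega_eff =
#' omega * (1 - sigma)`. When `omega` is available from anatomical
#' measurements, `sigma` follows as `1 - omega_eff / omega`.
#'
#' @param omega_eff Fitted effective sensitivity, in `[0, 1]`.
#' @param omega Anatomically measured chloroplast resistance fraction,
#'   in `(0, 1]`.
#' @return `sigma` in `[0, 1]`; a warning is issued (and the value clipped)
#'   if the pair is inconsistent (`omega_eff > omega`).
#' @examples
#' sigma_from_omega(omega_eff = 0.13, omega = 0.65) # 0.8
#' @export
sigma_from_omega <- function(omega_eff, omega) {
  if (any(omega <= 0 | omega > 1)) {
    abort("`omega` must lie in (0, 1].", class = "mesoflux_domain_error")
  }
  if (any(omega_eff < 0 | omega_eff > 1)) {
    abort("`omega_eff` must lie in [0, 1].", class = "mesoflux_domain_error")
  }
  sigma <- 1 - omega_eff / omega
  if (any(sigma < 0)) {
    warn("`omega_eff` exceeds `omega`; sigma clipped to 0.")
    sigma <- pmax(sigma, 0)
  }
  sigma
}
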