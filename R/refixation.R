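#' Carboxylation resistance
#'
#' Converts the carboxylation flux into the resistance framework:
#' \eqn{r_{cx} = (C_c + x_2)/x_1}, the marginal "resistance" Rubisco
#' presents to CO2 arriving at the stroma. Grows without bound as
#' carboxylation saturates.
#'
#' @param Cc Chloroplast CO2 partial pressure, ubar (vectorised, > 0).
#' @param s A [limitation_params()] state.
#' @return Resistance, bar m^2 s mol^-1.
#' @examples
#' p <- photo_params(80, 125, 1, 291, 194, 3.1)
#' rcx(34, limitation_params(p, "rubisco")) # (34 + 606)/80 = 8
#' @export
rcx <- function(Cc, s) {
  check_cc(Cc)
  (Cc + s$x2) / s$x1
}

#' Refixed fraction of (photo)respired CO2, general arrangement
#'
#' Fraction of mitochondria-released CO2 refixed by Rubisco rather than
#' escaping through the stomata, for an arbitrary organelle arrangement
#' parameter `sigma`. The inner fraction `sigma` refixes through `r_cx`
#' alone and escapes through `r_ch + r_wp + r_sc`; the outer fraction
#' `1 - sigma` refixes through `r_ch + r_cx` and escapes through
#' `r_wp + r_sc`:
#' \deqn{f_{refix} = \frac{\sigma/r_{cx} + (1-\sigma)/(r_{ch}+r_{cx})}
#'   {\sigma/r_{cx} + (1-\sigma)/(r_{ch}+r_{cx}) +
#'    \sigma/(r_{ch}+r_{wp}+r_{sc}) + (1-\sigma)/(r_{wp}+r_{sc})}}
#' The flux-to-pressure conversion factor cancels in the ratio.
#'
#' @param rwp Cell wall + plasmalemma resistance, bar m^2 s mol^-1.
#' @param rch Chloroplast resistance, bar m^2 s mol^-1.
#' @param rsc Stomatal (+ boundary layer) resistance, bar m^2 s mol^-1.
#' @param rcx Carboxylation resistance (see [rcx()]), bar m^2 s mol^-1.
#' @param sigma Inner-path fraction, in `[0, 1]` (vectorised).
#' @return Refixed fraction, dimensionless, in `(0, 1)`.
#' @examples
#' frefix_general(1.25, 1.25, 2.5, 8, sigma = c(0, 0.5, 1))
#' @export
frefix_general <- function(rwp, rch, rsc, rcx, sigma) {
  if (any(c(rwp, rch, rsc, rcx) <= 0)) {
    abort("All resistances must be positive.", class = "mesoflux_domain_error")
  }
  if (any(sigma < 0 | sigma > 1)) {
    abort("`sigma` must lie in [0, 1].", class = "mesoflux_domain_error")
  }
  refix <- sigma / rcx + (1 - sigma) / (rch + rcx)
  escape <- sigma / (rch + rwp + rsc) + (1 - sigma) / (rwp + rsc)
  refix / (refix + escape)
}

#' Refixed fraction, outer-mitochondria arrangement
#'
#' Continuous chloroplast layer with all mitochondria in the outer cytosol
#' (`sigma = 0`): escaping CO2 crosses only `r_wp + r_sc`, refixed CO2
#' crosses `r_ch + r_cx`, so
#' `f_refix = (rsc + rwp) / (rsc + rwp + rch + rcx)`.
#'
#' @inheritParams frefix_general
#' @return Refixed fraction, dimensionless.
#' @export
frefix_case1 <- function(rwp, rch, rsc, rcx) {
  if (any(c(rwp, rch, rsc, rcx) <= 0)) {
    abort("All resistances must be positive.", class = "mesoflux_domain_error")
  }
  (rsc + rwp) / (rsc + rwp + rch + rcx)
}

#' Refixed fraction, inner-mitochondria arrangement
#'
#' Continuous chloroplast layer with all mitochondria closely behind it
#' (`sigma = 1`): escaping CO2 must additionally cross `r_ch`, so
#' `f_refix = (rsc + rwp + rch) / (rsc + rwp + rch + rcx)` — always higher
#' than the outer arrangement of [frefix_case1()].
#'
#' @inheritParams frefix_general
#' @return Refixed fraction, dimensionless.
#' @export
frefix_case2 <- function(rwp, rch, rsc, rcx) {
  if (any(c(rwp, rch, rsc, rcx) <= 0)) {
    abort("All resistances must be positive.", class = "mesoflux_domain_error")
  }
  (rsc + rwp + rch) / (rsc + rwp + rch + rcx)
}

#' Refixed fraction, mixed inner/outer mitochondria
#'
#' Continuous chloroplast layer with a fraction `lambda` of mitochondria in
#' the inner cytosol; identical to [frefix_general()] with `sigma = lambda`,
#' and interpolates the two pure arrangements continuously.
#'
#' @inheritParams frefix_general
#' @param lambda Inner-mitochondria fraction, in `[0, 1]`.
#' @return Refixed fraction, dimensionless.
#' @export
frefix_case3 <- function(lambda, rwp, rch, rsc, rcx) {
  frefix_general(rwp, rch, rsc, rcx, sigma = lambda)
}

#' Refixation table across organelle arrangements
#'
#' Evaluates the refixed fraction for a set of arrangement parameters under
#' one biochemical + resistance parameterisation. By default the
#' carboxylation resistance is evaluated at `Cc = Gamma*` with the
#' Rubisco-limited kinetics — the reference point at which refixation
#' exactly balances release.
#'
#' @param p A [photo_params()] object.
#' @param r A [resistance_params()] object (its own `sigma` is not used;
#'   `sigma` below is the scan variable).
#' @param sigma Arrangement fractions to tabulate.
#' @param cc Evaluation Cc for [rcx()], ubar; defaults to `p$gamma_star`.
#' @param kind Limitation state used for `rcx`, default `"rubisco"`.
#' @return A tibble: `sigma`, `rcx`, `f_refix`.
#' @examples
#' p <- photo_params(80, 125, 1, 291, 194, 3.1)
#' r <- resistance_params(0.4, omega = 0.5, sigma = 0.5)
#' refix_table(p, r, sigma = c(1, 0.5, 0))
#' @export
refix_table <- function(p, r, sigma = c(1, 0.5, 0), cc = NULL,
                        kind = "rubisco") {
  stopifnot(inherits(p, "photo_params"), inherits(r, "resistance_params"))
  s <- limitation_params(p, kind)
  cc <- cc %||% p$gamma_star
  rx <- rcx(cc, s)
  tibble(
    sigma = sigma,
    rcx = rx,
    f_refix = frefix_general(r$rwp, r$rch, r$rsc, rx, sigma)
  )
}
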