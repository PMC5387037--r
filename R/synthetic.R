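#' Generate synthetic gas-exchange records from the forward model
#'
#' Simulates what a gas-exchange system would record for a leaf that
#' behaves exactly like the coupled biochemistry + resistance model:
#' for every combination of `ci` and O2 level the full model is solved and
#' independent Gaussian noise (sd `noise_sd`) is added to net assimilation
#' only — Ci, J and O are treated as error-free. The model-true chloroplast
#' CO2 is attached so estimation routines can be validated against truth.
#'
#' @param p A [photo_params()] object (its `O` is overridden per level).
#' @param r A [resistance_params()] object.
#' @param ci Vector of intercellular CO2 values, ubar.
#' @param o2_levels O2 partial pressures to cross with `ci`, mbar.
#' @param noise_sd Gaussian noise standard deviation on `a_umol`,
#'   umol m^-2 s^-1 (0 = noise-free).
#' @param seed Optional integer; when given, the RNG state is scoped to
#'   this call (via [withr::with_seed()]) so identical seeds give identical
#'   tables without disturbing the session RNG.
#' @return A tibble with columns `ci_ubar`, `o_mbar`, `a_umol`, `j_umol`,
#'   `rd_umol`, `true_cc_ubar`, `true_a_umol`, `noise_sd`.
#' @examples
#' p <- photo_params(80, 125, 1, 291, 194, 3.1)
#' r <- resistance_params(0.4, omega = 0.5, sigma = 0.5)
#' generate_gas_exchange(p, r, ci = c(100, 200), o2_levels = c(20, 210),
#'                       noise_sd = 0.2, seed = 7)
#' @export
generate_gas_exchange <- function(p, r, ci, o2_levels = p$O,
                                  noise_sd = 0, seed = NULL) {
  stopifnot(inherits(p, "photo_params"), inherits(r, "resistance_params"))
  if (noise_sd < 0) {
    abort("`noise_sd` must be non-negative.",
          class = "mesoflux_validation_error")
  }
  base <- purrr::map(o2_levels, function(o) {
    po <- photo_params(p$Vcmax, p$J, p$Rd, p$KmC, p$KmO, p$Sco, O = o)
    op <- operating_point(ci, po, r)
    tibble(ci_ubar = op$ci_ubar, o_mbar = o,
           true_a_umol = op$a_umol, true_cc_ubar = op$cc_ubar)
  })
  out <- bind_rows(base)
  draw <- function() rnorm(nrow(out), mean = 0, sd = noise_sd)
  eps <- if (noise_sd == 0) {
    rep(0, nrow(out))
  } else if (is.null(seed)) {
    draw()
  } else {
    withr::with_seed(seed, draw())
  }
  mutate(out,
         a_umol = .data$true_a_umol + eps,
         j_umol = p$J,
         rd_umol = p$Rd,
         noise_sd = noise_sd) |>
    select("ci_ubar", "o_mbar", "a_umol", "j_umol", "rd_umol",
           "true_cc_ubar", "true_a_umol", "noise_sd")
}
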