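# Shared fixtures: the simulation parameter set used throughout
# (Vcmax = 80, J = 125, Rd = 1 umol m-2 s-1; KmC = 291 ubar, KmO = 194 mbar,
# Sco = 3.1 mbar/ubar, ambient O2) and a matching resistance network.
fix_photo <- function(O = 210) {
  photo_params(Vcmax = 80, J = 125, Rd = 1, KmC = 291, KmO = 194,
               Sco = 3.1, O = O)
}

fix_resist <- function(omega = 0.5, sigma = 0.5, gm_dif = 0.4, ...) {
  resistance_params(gm_dif = gm_dif, omega = omega, sigma = sigma, ...)
}

# Independent oracle for the chloroplast-CO2 solution: root-bracketing on
# the drawdown balance written out directly, no quadratic algebra shared
# with the implementation.
oracle_cc <- function(Ci, p, r, s) {
  resid <- function(cc) {
    vc <- s$x1 * cc / (cc + s$x2)
    f <- s$x1 * p$gamma_star / (cc + s$x2)
    a <- vc - f - p$Rd
    cc - (Ci - r$rm_dif * (a + r$omega * (1 - r$sigma) * (f + p$Rd)))
  }
  uniroot(resid, c(1e-12, Ci + 5000), tol = 1e-12)$root
}

# Independent implementation of the outer-mitochondria two-resistance model
# (Cc = Ci - A(rwp + rch) - (F + Rd) rch), solved by root bracketing.
tholen_cc <- function(Ci, p, rwp, rch, s) {
  resid <- function(cc) {
    vc <- s$x1 * cc / (cc + s$x2)
    f <- s$x1 * p$gamma_star / (cc + s$x2)
    a <- vc - f - p$Rd
    cc - (Ci - a * (rwp + rch) - (f + p$Rd) * rch)
  }
  uniroot(resid, c(1e-12, Ci + 5000), tol = 1e-12)$root
}

# Random-but-reproducible parameter draws for property tests.
draw_cases <- function(n, seed) {
  withr::with_seed(seed, {
    tibble::tibble(
      Ci = runif(n, 20, 1500),
      gm_dif = runif(n, 0.05, 2),
      omega = runif(n),
      sigma = runif(n),
      Vcmax = runif(n, 20, 150),
      J = runif(n, 60, 300),
      Rd = runif(n, 0.2, 3),
      KmC = runif(n, 150, 500),
      KmO = runif(n, 100, 400),
      Sco = runif(n, 2, 4),
      O = runif(n, 10, 400),
      kind = sample(c("rubisco", "electron_transport"), n, replace = TRUE)
    )
  })
}
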