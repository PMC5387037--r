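test_that("resistance_params decomposes rm_dif and reduces k*lambda to sigma", {
  r <- fix_resist(omega = 0.5, sigma = 0.5)
  expect_equal(r$rm_dif, 2.5)
  expect_equal(r$rwp, 1.25)
  expect_equal(r$rch, 1.25)
  expect_equal(r$rsc, 2.5) # defaults to rm_dif
  r2 <- resistance_params(0.4, omega = 0.65, lambda = 0.8)
  expect_equal(r2$sigma, 0.8) # k defaults to 1
  r3 <- resistance_params(0.4, omega = 0.65, lambda = 0.4, k = 1.5)
  expect_equal(r3$sigma, 0.6)
  expect_error(resistance_params(0.4, omega = 1.2, sigma = 0.5),
               class = "mesoflux_validation_error")
  expect_error(resistance_params(0.4, omega = 0.5, lambda = 0.8, k = 2),
               class = "mesoflux_validation_error") # k*lambda > 1
  expect_error(resistance_params(-0.4, omega = 0.5, sigma = 0.5),
               class = "mesoflux_validation_error")
})

test_that("effective sensitivity is omega*(1-sigma)", {
  expect_equal(effective_sensitivity(0.65, 0.8), 0.13)
  expect_equal(effective_sensitivity(0.7, 1), 0)
  expect_equal(effective_sensitivity(0.5, 0), 0.5)
  expect_error(effective_sensitivity(1.1, 0.5),
               class = "mesoflux_domain_error")
  expect_error(effective_sensitivity(0.5, -0.1),
               class = "mesoflux_domain_error")
})

test_that("quadratic Cc solution matches the bracketing oracle on 200 draws", {
  cases <- draw_cases(200, seed = 421)
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    p <- photo_params(cs$Vcmax, cs$J, cs$Rd, cs$KmC, cs$KmO, cs$Sco, O = cs$O)
    r <- resistance_params(cs$gm_dif, cs$omega, sigma = cs$sigma)
    s <- limitation_params(p, cs$kind)
    cc <- solve_cc(cs$Ci, p, r, s)
    expect_lt(abs(cc - oracle_cc(cs$Ci, p, r, s)), 1e-6)
    # residual of the drawdown balance at the returned root
    vc <- carboxylation(cc, s)
    f <- photorespiratory_release(cc, s, p$gamma_star)
    a <- vc - f - p$Rd
    resid <- cc - (cs$Ci - r$rm_dif * (a + r$omega * (1 - r$sigma) *
                                         (f + p$Rd)))
    expect_lt(abs(resid), 1e-6)
  }
})

test_that("Cc solution hits frozen spot values and limiting behaviour", {
  p <- fix_photo()
  s <- limitation_params(p, "rubisco")
  # bracketing-oracle value, sigma = 1, omega = 0.5
  expect_equal(solve_cc(100, p, fix_resist(sigma = 1), s), 87.13182,
               tolerance = 1e-6)
  # vanishing mesophyll resistance: no drawdown
  r0 <- resistance_params(1e9, omega = 0.5, sigma = 0.5)
  expect_equal(solve_cc(100, p, r0, s), 100, tolerance = 1e-4)
  # the arrangement enters only through omega*(1-sigma)
  expect_equal(
    solve_cc(100, p, resistance_params(0.4, omega = 0, sigma = 0.3), s),
    solve_cc(100, p, resistance_params(0.4, omega = 0.5, sigma = 1), s),
    tolerance = 1e-12)
  expect_equal(
    solve_cc(150, p, resistance_params(0.4, omega = 0.6, sigma = 0.5), s),
    solve_cc(150, p, resistance_params(0.4, omega = 0.3, sigma = 0), s),
    tolerance = 1e-12)
  expect_error(solve_cc(-5, p, fix_resist(), s),
               class = "mesoflux_domain_error")
})

test_that("sigma = 1 and omega = 0 recover the classical constant-gm model", {
  p <- fix_photo()
  ci <- seq(60, 500, by = 20)
  for (r in list(fix_resist(omega = 0.5, sigma = 1),
                 fix_resist(omega = 0, sigma = 0.3))) {
    op <- operating_point(ci, p, r)
    pos <- op$a_umol > 0
    expect_equal(op$gm_app[pos], rep(r$gm_dif, sum(pos)), tolerance = 1e-12)
    # drawdown identity: gm from Ci - Cc equals gm_dif exactly
    expect_equal(gm_from_drawdown(op$a_umol[pos], op$ci_ubar[pos],
                                  op$cc_ubar[pos]),
                 rep(r$gm_dif, sum(pos)), tolerance = 1e-9)
  }
})

test_that("sigma = 0 reproduces the independent outer-mitochondria model", {
  p <- fix_photo()
  r <- fix_resist(omega = 0.5, sigma = 0)
  ci <- c(60, 100, 200, 350, 500)
  for (kind in c("rubisco", "electron_transport")) {
    s <- limitation_params(p, kind)
    cc_pkg <- solve_cc(ci, p, r, s)
    cc_ref <- vapply(ci, tholen_cc, numeric(1), p = p,
                     rwp = r$rwp, rch = r$rch, s = s)
    expect_equal(cc_pkg, cc_ref, tolerance = 1e-8)
  }
})

test_that("solved drawdown ratio equals the closed-form gm_app identity", {
  p <- fix_photo()
  r <- fix_resist(omega = 0.7, sigma = 0.3)
  op <- operating_point(seq(60, 600, by = 15), p, r)
  pos <- op$a_umol > 0
  lhs <- op$a_umol[pos] / (op$ci_ubar[pos] - op$cc_ubar[pos])
  rhs <- gm_app(op$a_umol[pos], op$f_umol[pos], p$Rd, r)
  expect_equal(lhs, rhs, tolerance = 1e-9)
  expect_equal(op$gm_app[pos], rhs, tolerance = 1e-9)
  expect_error(gm_app(0, 2, 1, r), class = "mesoflux_domain_error")
})

test_that("gm_app rises with Ci between compensation and the limitation crossover", {
  p <- fix_photo()
  r <- fix_resist(omega = 0.5, sigma = 0.5) # omega*(1-sigma) = 0.25 > 0
  comp <- co2_compensation(p, r)
  ci <- seq(comp$ci_gamma_ubar + 0.5, 320, length.out = 120)
  op <- operating_point(ci, p, r)
  rub <- op$limitation == "rubisco" & op$a_umol > 0
  expect_gt(sum(rub), 50)
  expect_true(all(diff(op$gm_app[rub]) > 0))
})

test_that("A responds to arrangement as expected: up with sigma, down with omega", {
  p <- fix_photo()
  ci_low <- seq(60, 200, by = 10)
  a_by_sigma <- sapply(c(0, 0.5, 1), function(sg)
    operating_point(ci_low, p, fix_resist(omega = 0.5, sigma = sg))$a_umol)
  expect_true(all(a_by_sigma[, 2] > a_by_sigma[, 1]))
  expect_true(all(a_by_sigma[, 3] > a_by_sigma[, 2]))
  a_by_omega <- sapply(c(0, 0.5, 0.9), function(w)
    operating_point(ci_low, p, fix_resist(omega = w, sigma = 0.5))$a_umol)
  expect_true(all(a_by_omega[, 2] < a_by_omega[, 1]))
  expect_true(all(a_by_omega[, 3] < a_by_omega[, 2]))
  # refixation matters less at high Ci: curves converge
  a_hi <- sapply(c(0, 1), function(sg)
    operating_point(1200, p, fix_resist(omega = 0.5, sigma = sg))$a_umol)
  expect_lt(abs(diff(a_hi)), 0.05)
})

test_that("outer-cytosol CO2 lies between chloroplast and intercellular CO2", {
  p <- fix_photo()
  op <- operating_point(seq(80, 500, by = 30), p,
                        fix_resist(omega = 0.5, sigma = 0.5))
  pos <- op$a_umol > 0
  expect_true(all(op$cm_outer_ubar[pos] < op$ci_ubar[pos]))
  expect_true(all(op$cm_outer_ubar[pos] > op$cc_ubar[pos]))
  expect_equal(op$cm_outer_ubar, op$ci_ubar - op$a_umol * 1.25,
               tolerance = 1e-12)
})

test_that("compensation points close the model: A vanishes at Ci_Gamma", {
  p <- fix_photo()
  s <- limitation_params(p, "rubisco")
  r0 <- fix_resist(omega = 0.5, sigma = 0)
  comp <- co2_compensation(p, r0)
  expect_equal(comp$cc_gamma_ubar,
               (p$gamma_star * s$x1 + p$Rd * s$x2) / (s$x1 - p$Rd),
               tolerance = 1e-12) # 41.9706 ubar
  expect_equal(comp$cc_gamma_ubar, 41.9706, tolerance = 1e-4)
  # under the minimum rule the binding compensation point closes the model
  comp_all <- co2_compensation(p, r0, kind = "overall")
  op <- operating_point(comp_all$ci_gamma_ubar, p, r0)
  expect_lt(abs(op$a_umol), 1e-6)
  expect_gte(comp_all$ci_gamma_ubar, comp$ci_gamma_ubar)
  # zero sensitivity: intercellular and chloroplast compensation coincide
  comp1 <- co2_compensation(p, fix_resist(sigma = 1))
  expect_equal(comp1$ci_gamma_ubar, comp1$cc_gamma_ubar)
  # the refixation-poor arrangement needs more CO2 to break even
  expect_gt(comp$ci_gamma_ubar, comp1$ci_gamma_ubar)
  expect_error(
    co2_compensation(photo_params(80, 125, 35, 291, 194, 3.1),
                     r0, kind = "electron_transport"),
    class = "mesoflux_domain_error") # x1 = J/4 = 31.25 < Rd
})

test_that("simulated A-Ci curves are monotone and demand increasing grids", {
  p <- fix_photo()
  cur <- simulate_aci(p, fix_resist(), seq(50, 600, by = 25))
  expect_true(all(diff(cur$a_umol) > 0))
  expect_error(simulate_aci(p, fix_resist(), c(100, 100, 200)),
               class = "mesoflux_domain_error")
})
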