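test_that("tracer rates convert protocol constants to umol/kg/min", {
  pr <- infusion_protocol()
  r <- tracer_rates(pr)
  # independent unit-conversion oracle: mg/h -> umol/min -> per kg
  I6 <- (2.5 * 0.5) / 186.18 * 1000 / 60 / 0.022
  Igal <- (6 * 0.5) / 181.16 * 1000 / 60 / 0.022
  expect_equal(r$I6, I6, tolerance = 1e-12)
  expect_equal(r$Igal, Igal, tolerance = 1e-12)
  expect_equal(r$I6, 5.09, tolerance = 0.01)
})

test_that("dilution, turnover, clearance and m3m6 follow their definitions", {
  expect_equal(compute_dilution(0.033, 1.0), 0.033)
  expect_equal(compute_dilution(0.0495, 0.99), 0.05)
  expect_equal(compute_dilution(0.99, 0.99), 1)
  expect_error(compute_dilution(0), "dilution")

  tv <- compute_turnover(2.0, 0.05)
  expect_equal(tv$turnover, 40)
  expect_equal(tv$endogenous, 38)
  expect_equal(compute_turnover(2, 1)$turnover, 2)
  expect_error(compute_turnover(2, 0), "dilution")

  expect_equal(compute_clearance(40, 8), 5)
  expect_equal(compute_clearance(0, 8), 0)
  expect_error(compute_clearance(40, 0), "positive")

  expect_equal(m3m6_ratio(c(0, 0, 0, 0.01, 0, 0, 0.04)), 0.25)
  expect_equal(m3m6_ratio(0, m6 = 0.04), 0)
  expect_error(m3m6_ratio(0.01, m6 = 1e-9), "noise floor")
})

test_that("exchange fractions are enrichment ratios with a noise floor", {
  ex <- compute_exchange(0.0071, 0.033, 0.05, 0.26)
  expect_equal(ex$c_glc, 0.0071 / 0.033)
  expect_equal(ex$c_glc, 0.215, tolerance = 0.01)
  expect_equal(ex$c_udpglc, 0.05 / 0.26)
  expect_error(compute_exchange(0.007, 1e-6, 0.05, 0.26), "noise floor")
})

test_that("the G6P-balance closure reproduces the worked example exactly", {
  fx <- solve_fluxes(list(d_glc = 0.0625, d_udpglc = 1 / 31,
                          c_glc = 0.25, c_udpglc = 0.3,
                          f_glc = 0.5, f_udpglc = 0.5),
                     rates = list(I6 = 2.5, Igal = 1))
  expect_equal(fx$Ra, 40)
  expect_equal(fx$Ru, 31)
  expect_equal(fx$EGP, 37.5)
  expect_equal(fx$G6Pase, 50)
  expect_equal(fx$GS, 30)
  expect_equal(fx$GCK, 20)
  expect_equal(fx$GNG_G6P, 40)
  expect_equal(fx$GP, 20)
  expect_equal(fx$glucose_balance, 30)
  expect_equal(fx$glycogen_balance, 10)
})

test_that("closure boundaries behave: no exchange, full partition, errors", {
  rates <- list(I6 = 2.5, Igal = 1)
  base <- list(d_glc = 0.0625, d_udpglc = 1 / 31, c_udpglc = 0.3,
               f_glc = 0.5)
  fx0 <- solve_fluxes(c(base, c_glc = 0, f_udpglc = 0), rates = rates)
  expect_equal(fx0$GCK, 0)
  expect_equal(fx0$GNG_G6P, 0)
  expect_equal(fx0$GP, fx0$G6Pase + fx0$GS)
  fx1 <- solve_fluxes(c(base, c_glc = 0.4, f_udpglc = 0.6), rates = rates)
  expect_equal(fx1$GP, 0)
  expect_error(solve_fluxes(c(base, c_glc = 0.5, f_udpglc = 0.6),
                            rates = rates), "infeasible")
  expect_error(solve_fluxes(c(base, c_glc = 1.0, f_udpglc = 0),
                            rates = rates), "c_glc")
})

test_that("every solved flux set closes the G6P balance", {
  set.seed(42)
  for (i in 1:200) {
    fx <- solve_fluxes(random_feasible_params(),
                       rates = list(I6 = runif(1, 0.5, 10),
                                    Igal = runif(1, 0.5, 20)))
    expect_lt(abs(fx$GCK + fx$GP + fx$GNG_G6P - (fx$G6Pase + fx$GS)),
              1e-9)
    expect_true(all(unlist(fx[c("Ra", "Ru", "EGP", "G6Pase", "GS", "GCK",
                                "GNG_G6P", "GP")]) >= 0))
    expect_gte(fx$Ra, fx$EGP)  # total appearance includes the tracer
  }
})

test_that("fluxes respond monotonically to their parameters", {
  rates <- list(I6 = 2.5, Igal = 1)
  base <- list(d_udpglc = 0.1, c_glc = 0.2, c_udpglc = 0.2,
               f_glc = 0.5, f_udpglc = 0.5)
  Ra <- vapply(c(0.02, 0.04, 0.08), function(d) {
    solve_fluxes(utils::modifyList(base, list(d_glc = d)),
                 rates = rates)$Ra
  }, numeric(1))
  expect_true(all(diff(Ra) < 0))          # Ra decreases in d_glc
  GS <- vapply(c(0.4, 0.2, 0.1), function(d) {
    solve_fluxes(utils::modifyList(base, list(d_glc = 0.05, d_udpglc = d)),
                 rates = rates)$GS
  }, numeric(1))
  expect_true(all(diff(GS) > 0))          # GS increases in 1/d_udpglc
  GCK <- vapply(c(0.1, 0.2, 0.3), function(cg) {
    fx <- solve_fluxes(utils::modifyList(base, list(d_glc = 0.05,
                                                    c_glc = cg)),
                       rates = rates)
    fx$GCK / (fx$G6Pase + fx$GS)
  }, numeric(1))
  expect_true(all(diff(GCK) > 0))         # GCK share increases in c_glc
})

test_that("custom closures can be registered and selected", {
  register_closure("test_null", function(params, rates) {
    list(Ra = rates$I6 / params$d_glc, Ru = rates$Igal / params$d_udpglc,
         EGP = 0, G6Pase = 1, GS = 1, GCK = 1, GNG_G6P = 1, GP = 0,
         GNG_blood = 0, glucose_balance = 0, glycogen_balance = 0)
  })
  fx <- solve_fluxes(list(d_glc = 0.5, d_udpglc = 0.5, c_glc = 0.1,
                          c_udpglc = 0.1, f_glc = 0.1, f_udpglc = 0.1),
                     rates = list(I6 = 1, Igal = 1), closure = "test_null")
  expect_equal(fx$Ra, 2)
  expect_error(get_closure("no_such_closure"), "unknown closure")
})
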