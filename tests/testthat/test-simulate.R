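truth_worked <- function(...) {
  synthetic_truth(GCK = 20, G6Pase = 50, GS = 30, GNG_G6P = 40,
                  protocol = protocol_with_rates(2.5, 1), ...)
}

test_that("steady-state inversion reproduces the worked example parameters", {
  ss <- steady_state_enrichments(truth_worked())
  expect_equal(ss$params$d_glc, 0.0625, tolerance = 1e-12)
  expect_equal(ss$params$d_udpglc, 1 / 31, tolerance = 1e-12)
  expect_equal(ss$params$c_glc, 0.25, tolerance = 1e-12)
  expect_equal(ss$params$f_udpglc, 0.5, tolerance = 1e-12)
})

test_that("inversion boundaries: no uptake, no gluconeogenesis", {
  t0 <- synthetic_truth(GCK = 0, G6Pase = 50, GS = 30, GNG_G6P = 40)
  expect_equal(steady_state_enrichments(t0)$params$c_glc, 0)
  t1 <- synthetic_truth(GCK = 20, G6Pase = 50, GS = 30, GNG_G6P = 0)
  ss1 <- steady_state_enrichments(t1)
  expect_equal(ss1$params$f_udpglc, 0)
  expect_equal(ss1$pools$udp_glucose$carbon_only[3], 0)  # no m+2 excess
})

test_that("infeasible truths are rejected before simulation", {
  expect_error(synthetic_truth(GCK = 100, G6Pase = 10, GS = 10,
                               GNG_G6P = 0), "infeasible")
  expect_error(synthetic_truth(GCK = 1, G6Pase = 10, GS = 10,
                               GNG_G6P = 1, GP = 5), "identity")
})

test_that("enrichment reaches its plateau when t >> tau", {
  tr <- truth_worked(tau_glc = 1, tau_udpglc = 1, noise_cv = 0)
  dat <- simulate_experiment(tr, times_blood = 60, times_urine = numeric(0))
  ss <- attr(dat, "targets")
  M <- channel_matrices()$carbon_only
  target <- ss$pools$blood_glucose$carbon_only
  target[1] <- 1 - sum(target)
  got <- as.numeric(M %*% target)
  row <- as.numeric(dat[dat$channel == "carbon_only",
                        paste0("m", 0:6)])
  expect_lt(max(abs(row - got)), 1e-9)
})

test_that("simulated deuterium enrichment equals the injected 2H fraction", {
  # construct channels with known 2H 0.12 and 13C m+1 contamination 0.03
  carb <- c(1 - 0.03, 0.03, rep(0, 5)); carb[1] <- 1 - sum(carb[-1])
  comb <- carb; comb[2] <- comb[2] + 0.12; comb[1] <- 1 - sum(comb[-1])
  Ms <- channel_matrices()
  oc <- correct_natural_abundance(as.numeric(Ms$carbon_only %*% carb),
                                  Ms$carbon_only)
  ob <- correct_natural_abundance(as.numeric(Ms$combined %*% comb),
                                  Ms$combined)
  expect_equal(deuterium_enrichment(ob, oc), 0.12, tolerance = 1e-9)
})

test_that("simulation is schema-valid and seed-deterministic", {
  tr <- truth_worked(noise_cv = 0.05)
  set.seed(7); d1 <- simulate_experiment(tr)
  set.seed(7); d2 <- simulate_experiment(tr)
  expect_identical(d1, d2)
  set.seed(8); d3 <- simulate_experiment(tr)
  expect_false(identical(d1$m1, d3$m1))
  # accepted unchanged by the real-data entry point
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(d1, f)
  expect_silent(dat <- read_mid_table(f))
  expect_equal(nrow(dat), nrow(d1))
})

test_that("noise-free end-to-end pipeline recovers the truth fluxes", {
  tr <- truth_worked(tau_glc = 1, tau_udpglc = 1, noise_cv = 0)
  dat <- simulate_experiment(tr)
  af <- animal_fluxes(sample_parameters(correct_mid_table(dat)),
                      protocol = tr$protocol)
  truthfx <- tr$fluxes
  for (nm in names(truthfx)) {
    expect_lt(abs(af[[nm]] - truthfx[[nm]]) / truthfx[[nm]], 1e-6)
  }
  # reported-only parameters match the inversion targets
  ss <- steady_state_enrichments(tr)
  expect_equal(af$c_udpglc, ss$params$c_udpglc, tolerance = 1e-6)
  expect_equal(af$f_glc, ss$params$f_glc, tolerance = 1e-6)
  expect_equal(af$m3m6_glc, tr$recycling, tolerance = 1e-6)
})

test_that("cohort simulation jitters animals and keeps the truth ledger", {
  truths <- list(A = truth_worked(), B = truth_worked())
  d0 <- simulate_cohort(3, truths, between_animal_cv = 0, seed = 5)
  led0 <- attr(d0, "truth_ledger")
  expect_equal(nrow(led0), 6)
  expect_true(all(led0$GCK == 20))  # CV = 0: identical animals
  d1 <- simulate_cohort(3, truths, between_animal_cv = 0.1, seed = 5)
  led1 <- attr(d1, "truth_ledger")
  expect_gt(stats::sd(led1$GCK), 0)
  # balance identity holds for every jittered animal
  expect_lt(max(abs(led1$GCK + led1$GP + led1$GNG_G6P -
                      (led1$G6Pase + led1$GS))), 1e-9)
})

test_that("large noisy cohorts recover the group mean flux", {
  tr <- truth_worked(tau_glc = 5, tau_udpglc = 5, noise_cv = 0.02)
  dat <- simulate_cohort(20, list(grp = tr), between_animal_cv = 0.05,
                         seed = 99)
  af <- suppressWarnings(
    animal_fluxes(sample_parameters(correct_mid_table(dat)),
                  protocol = tr$protocol))
  expect_gte(nrow(af), 18)
  sem <- stats::sd(af$GCK) / sqrt(nrow(af))
  expect_lt(abs(mean(af$GCK) - 20), max(3 * sem, 1.5))
})
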