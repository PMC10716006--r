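test_that("normalize_mid divides by the sum, preserves order, is idempotent", {
  expect_equal(normalize_mid(c(2, 2, 0, 0, 0, 0, 0)),
               c(0.5, 0.5, 0, 0, 0, 0, 0))
  expect_equal(normalize_mid(c(1, 0, 0, 0, 0, 0, 0)),
               c(1, 0, 0, 0, 0, 0, 0))
  set.seed(11)
  for (i in 1:20) {
    x <- runif(7, 0.01, 5)
    n <- normalize_mid(x)
    expect_equal(sum(n), 1, tolerance = 1e-12)
    expect_equal(n, x / sum(x))                 # direct-division oracle
    expect_equal(normalize_mid(n), n)           # idempotent
  }
})

test_that("normalize_mid rejects invalid measurements", {
  expect_error(normalize_mid(rep(0, 7)), "zero")
  expect_error(normalize_mid(c(1, -0.1, rep(0, 5))), "negative")
  expect_error(normalize_mid(numeric(0)))
})

test_that("correction matrix reduces to identity with no heavy isotopes", {
  ab0 <- list(C = 1, H = 1, N = 1, O = 1)
  M <- build_correction_matrix(glucose_pentaacetate(), K = 6,
                               abundances = ab0)
  expect_equal(unclass(M), diag(7), ignore_attr = TRUE)
})

test_that("one-carbon fragment at abundance a gives the n=1 binomial matrix", {
  a <- 0.0107
  f <- fragment_formula(C = 1, n_labelable = 1)
  M <- build_correction_matrix(f, K = 1)
  expect_equal(unclass(M), matrix(c(1 - a, a, 0, 1), 2, 2),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("column 0 equals the brute-force elemental envelope", {
  for (formula in list(glucose_pentaacetate(),
                       glucose_aldonitrile_pentaacetate())) {
    M <- build_correction_matrix(formula, K = 6)
    counts <- as.list(stats::setNames(as.integer(formula), names(formula)))
    oracle <- oracle_envelope(counts, natural_abundances(), K = 6)
    expect_equal(M[, 1], oracle, tolerance = 1e-10)
  }
})

test_that("correction matrices are lower-triangular with valid columns", {
  M <- build_correction_matrix(glucose_pentaacetate(), K = 6)
  expect_true(all(M[upper.tri(M)] == 0))
  expect_true(all(diag(M) > 0))
  expect_true(all(colSums(M) <= 1 + 1e-12))
  # inverse applied to column 0 yields the unit vector
  e0 <- solve(unclass(M), M[, 1])
  expect_equal(e0, c(1, rep(0, 6)), tolerance = 1e-10)
})

test_that("natural-abundance correction round-trips noise-free spectra", {
  M <- build_correction_matrix(glucose_pentaacetate(), K = 6)
  x <- c(0.9, 0, 0, 0.06, 0, 0, 0.04)
  obs <- as.numeric(M %*% x)
  expect_equal(as.numeric(correct_natural_abundance(obs, M)), x,
               tolerance = 1e-10)
  # unlabeled envelope maps back to the unit vector
  expect_equal(as.numeric(correct_natural_abundance(M[, 1], M)),
               c(1, rep(0, 6)), tolerance = 1e-10)
  # identity matrix leaves the (normalized) observation unchanged
  y <- normalize_mid(runif(7))
  expect_equal(as.numeric(correct_natural_abundance(y, diag(7))), y,
               tolerance = 1e-12)
  set.seed(23)
  for (i in 1:50) {
    x <- random_label_mid()
    got <- correct_natural_abundance(as.numeric(M %*% x), M)
    expect_lt(max(abs(as.numeric(got) - x)), 1e-10)
  }
})

test_that("correction records residual diagnostics on distorted input", {
  M <- build_correction_matrix(glucose_pentaacetate(), K = 6)
  y <- as.numeric(M %*% c(0.8, 0.1, 0, 0, 0, 0, 0.1))
  y[2] <- y[2] * 3  # gross distortion
  got <- correct_natural_abundance(normalize_mid(y), M,
                                   residual_tol = 0.01)
  expect_true(attr(got, "fit_warning"))
  expect_gt(attr(got, "residual_norm"), 0.01)
  expect_true(all(as.numeric(got) >= 0))
})

test_that("excess_mid subtracts the baseline and reports clipping", {
  b <- c(1, rep(0, 6))
  expect_equal(as.numeric(excess_mid(b, b)), rep(0, 7))
  x <- c(0.95, rep(0, 5), 0.05)
  expect_equal(excess_mid(x)[7], 0.05)
  set.seed(31)
  for (i in 1:20) {
    a <- normalize_mid(runif(7)); b2 <- normalize_mid(runif(7))
    got <- excess_mid(a, b2)
    expect_equal(as.numeric(got), pmax(a - b2, 0))
    expect_equal(attr(got, "clipped"), sum(pmax(b2 - a, 0)[-1]))
  }
  expect_error(excess_mid(1:7 / 28, 1:6 / 21), "length")
})

test_that("deuterium enrichment is the channel m+1 excess difference", {
  comb <- c(0.70, 0.30, rep(0, 5))
  carb <- c(0.95, 0.05, rep(0, 5))
  expect_equal(deuterium_enrichment(comb, carb), 0.25)
  expect_equal(deuterium_enrichment(carb, carb), 0)
  # floored at zero when the carbon channel is higher
  expect_equal(deuterium_enrichment(carb, comb), 0)
  m1 <- mid(comb, "blood_glucose", "combined")
  m2 <- mid(carb, "udp_glucose", "carbon_only")
  expect_error(deuterium_enrichment(m1, m2), "mismatch")
})
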