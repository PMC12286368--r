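test_that("distribution specs validate their parameters", {
  expect_s3_class(dist_spec("C_As", "lognormal", meanlog = 0, sdlog = 1),
                  "dist_spec")
  expect_error(dist_spec("C_As", "lognormal", meanlog = 0), "sdlog")
  expect_error(dist_spec("x", "triangular", lower = 2, mode = 1, upper = 3),
               "invalid parameters")
  expect_error(dist_spec("x", "uniform", min = 2, max = 1),
               "invalid parameters")
  expect_error(dist_spec("x", "normal", mean = 0, sd = -1),
               "invalid parameters")
})

test_that("maximum-likelihood fitting recovers lognormal parameters", {
  set.seed(200)
  draws <- rlnorm(10000, meanlog = 0, sdlog = 1)
  spec <- fit_distribution(draws, "lognormal", "C_As")
  expect_equal(spec$parameters$meanlog, 0, tolerance = 0.05)
  expect_equal(spec$parameters$sdlog, 1, tolerance = 0.05)

  const <- fit_distribution(rep(2.5, 10), "point")
  expect_equal(const$parameters$value, 2.5)
  expect_error(fit_distribution(c(0, 1, 2, 3, 4), "lognormal"), "positive")
  expect_error(fit_distribution(c(1, 2), "normal"), ">= 5")
})

test_that("fitting a record table respects the censoring policy", {
  rec <- rbind(
    make_records(bakery_id = sprintf("N-%02d", 1:6),
                 value = c(1.0, 1.2, 0.9, 1.1, 1.05, 0.95)),
    make_records(bakery_id = "N-07", value = NA, censored = TRUE, lod = 0.02))
  spec <- fit_distribution(rec, "lognormal", element = "As")
  expect_equal(spec$variable, "C_As")
  # exclude policy: the censored cell does not enter the fit
  direct <- fit_distribution(c(1.0, 1.2, 0.9, 1.1, 1.05, 0.95),
                             "lognormal", "C_As")
  expect_equal(spec$parameters, direct$parameters)
})

test_that("all-point-mass simulation reproduces the deterministic risk exactly", {
  p <- default_exposure_params()$adult
  dists <- list(dist_spec("C_As", "point", value = 1.0),
                dist_spec("C_Cd", "point", value = 0.01),
                dist_spec("C_Zn", "point", value = 4))
  mc <- simulate_risk(dists, p, n = 101, seed = 7)
  det_hi <- ADULT_FACTOR * (1.0 / 0.003 + 0.01 / 0.001 + 4 / 0.3)
  det_tcr <- ADULT_FACTOR * (1.0 * 1.5 + 0.01 * 0.38)
  expect_equal(unique(mc$hi), det_hi, tolerance = 0)
  expect_equal(unique(mc$tcr), det_tcr, tolerance = 0)
  expect_equal(length(mc$hi), 101)
})

test_that("simulation is bit-identical under a repeated seed", {
  p <- default_exposure_params()$child
  dists <- list(dist_spec("C_As", "lognormal", meanlog = 0, sdlog = 0.4),
                dist_spec("BW", "normal", mean = 20, sd = 3))
  a <- simulate_risk(dists, p, n = 500, seed = 11)
  b <- simulate_risk(dists, p, n = 500, seed = 11)
  expect_identical(a, b)
  c <- simulate_risk(dists, p, n = 500, seed = 12)
  expect_false(identical(a$hi, c$hi))
})

test_that("missing concentration specs are reported by name", {
  p <- default_exposure_params()$adult
  expect_error(simulate_risk(list(dist_spec("BW", "point", value = 70)), p),
               "C_<element>")
  expect_error(simulate_risk(list(dist_spec("C_Xx", "point", value = 1)), p),
               "Xx")
})

test_that("simulated HI dispersion matches the closed-form lognormal value", {
  # one stochastic input: As concentration, mean 1, cv 0.3; the rest fixed
  s <- sqrt(log(1 + 0.3^2))
  dists <- list(dist_spec("C_As", "lognormal", meanlog = -s^2 / 2, sdlog = s),
                dist_spec("C_Zn", "point", value = 4))
  p <- default_exposure_params()$adult
  mc <- simulate_risk(dists, p, n = 20000, seed = 21)
  expected_sd <- ADULT_FACTOR / 0.003 * 0.3  # sd(C_As) = cv * mean = 0.3
  expect_equal(sd(mc$hi), expected_sd, tolerance = 0.03)
  expect_equal(mean(mc$hi),
               ADULT_FACTOR * (1 / 0.003 + 4 / 0.3), tolerance = 0.01)
})

test_that("percentiles follow the fixed interpolation convention", {
  expect_equal(percentile(c(1, 2, 3, 4, 5), 0.5), 3)
  expect_equal(percentile(rep(2.5, 100), 0.37), 2.5)
  set.seed(202)
  z <- rnorm(100000)
  expect_equal(percentile(z, 0.95), qnorm(0.95), tolerance = 0.02)
  qs <- percentile(z, c(0.05, 0.25, 0.5, 0.75, 0.95))
  expect_true(all(diff(qs) >= 0))
  expect_error(percentile(numeric(0), 0.5), "no draws")
  expect_error(percentile(z, 1), "strictly")
})

test_that("cumulative curves are monotone with endpoints 0 and 1", {
  set.seed(203)
  x <- rlnorm(400)
  cc <- cumulative_curve(x)
  expect_equal(cc$prob[1], 0)
  expect_equal(cc$prob[nrow(cc)], 1)
  expect_true(all(diff(cc$prob) >= 0))
  expect_true(all(diff(cc$value) >= 0))

  pm <- cumulative_curve(rep(3, 10))
  expect_equal(unique(pm$value), 3)

  # mixture identity: the curve of pooled half-weight samples is the curve
  # of their concatenation
  y <- rlnorm(400, 0.5)
  pooled <- cumulative_curve(c(x, y))
  ecdf_mix <- function(t) (mean(x <= t) + mean(y <= t)) / 2
  at <- quantile(c(x, y), c(0.1, 0.35, 0.6, 0.9))
  for (t in at) {
    expect_equal(pooled$prob[max(which(pooled$value <= t))], ecdf_mix(t),
                 tolerance = 1e-12)
  }
})

test_that("the simulate method covers both cohorts and feeds sensitivity", {
  fit <- risk_assessment(small_study(seed = 8))
  mc <- simulate(fit, nsim = 400, seed = 31)
  expect_named(mc, c("adult", "child"))
  expect_equal(mc$adult$n, 400)
  expect_equal(ncol(mc$adult$inputs), 5 + 10)  # exposure vars + elements
  # same seed, same draws
  mc2 <- simulate(fit, nsim = 400, seed = 31)
  expect_identical(mc$child$hi, mc2$child$hi)
  # overriding one variable changes only the draws that depend on it
  mc3 <- simulate(fit, nsim = 400, seed = 31,
                  dists = list(dist_spec("C_As", "point", value = 1)))
  expect_equal(unique(mc3$adult$inputs[, "C_As"]), 1)
})
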