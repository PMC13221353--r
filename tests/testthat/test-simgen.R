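test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(n = 100, p = 1), "p")
  expect_error(sim_config(n = 100, prop_treated = 1.2), "prop_treated")
  expect_error(sim_config(n = 100, missing_rate = 0), "missing_rate")
  expect_error(sim_config(n = 100, p = 3, corr = "user",
                          corr_matrix = matrix(1, 3, 3)),
               "positive definite")
  bad <- diag(3); bad[1, 2] <- 0.5  # asymmetric
  expect_error(sim_config(n = 100, p = 3, corr = "user", corr_matrix = bad),
               "symmetric")
})

test_that("calibration hits the treated proportion, pseudo-R2, R2 and missing-rate targets", {
  cfg <- sim_config(n = 1000, p = 10, mechanism = "MAR", missing_rate = 0.3)
  set.seed(11)
  params <- calibrate_coefficients(cfg)
  expect_lt(abs(params$achieved$pseudo_r2 - 0.2), 0.01)
  expect_lt(abs(params$achieved$prop_treated - 0.2), 0.01)
  expect_lt(abs(params$achieved$r2 - 0.2), 0.01)
  expect_true(all(abs(params$achieved$missing_rate[-1] - 0.3) < 0.01))

  # independent check on a fresh large sample (different stream than the
  # internal calibration sample)
  big <- sim_config(n = 5e4, p = 10, mechanism = "MAR", missing_rate = 0.3)
  d <- impose_missingness(generate_dataset(big, params, seed = 99))
  expect_lt(abs(mean(d$Z) - 0.2), 0.012)
  expect_lt(abs(mean(d$S[, -1]) - 0.3), 0.012)
  r2 <- summary(stats::lm(d$Y ~ d$X_complete + d$Z))$r.squared
  expect_lt(abs(r2 - 0.2), 0.015)
})

test_that("missing-rate calibration covers the focused and diffuse MNAR mechanisms", {
  for (mech in c("FD_MNAR", "FI_MNAR", "DF_MNAR", "DF_MNAR_INT1",
                 "DF_MNAR_INT2")) {
    cfg <- sim_config(n = 2e4, p = 6, mechanism = mech, missing_rate = 0.5)
    set.seed(7)
    params <- calibrate_coefficients(cfg)
    expect_true(all(abs(params$achieved$missing_rate[-1] - 0.5) < 0.01),
                label = mech)
    d <- impose_missingness(generate_dataset(cfg, params, seed = 3))
    expect_true(all(abs(colMeans(d$S)[-1] - 0.5) < 0.03), label = mech)
    expect_true(all(d$S[, 1] == 0), label = mech)
  }
})

test_that("intercept-only missingness model has the closed-form logit solution", {
  cfg <- sim_config(n = 100, p = 4, mechanism = "MAR", missing_rate = 0.3,
                    calib_n = 2e4)
  set.seed(5)
  params <- calibrate_coefficients(cfg)
  params$gamma <- 0  # zero slope: intercept must be exactly logit(rate)
  g0 <- calibrate_missing_intercept("MAR", 0.3, params, cfg)
  expect_equal(unname(g0[-1]), rep(qlogis(0.3), 3), tolerance = 1e-6)
})

test_that("outcome R2 calibration agrees with a brute-force Monte Carlo oracle", {
  cfg <- sim_config(n = 100, p = 2, corr = "identity", mechanism = "MAR",
                    missing_rate = 0.3)
  set.seed(21)
  params <- calibrate_coefficients(cfg)
  # oracle: simulate the outcome model from scratch at large n and measure
  # the R2 of the regression of Y on (X, Z)
  set.seed(22)
  big <- sim_config(n = 2e5, p = 2, corr = "identity", mechanism = "MAR",
                    missing_rate = 0.3)
  d <- generate_dataset(big, params)
  r2 <- summary(stats::lm(d$Y ~ d$X_complete + d$Z))$r.squared
  expect_lt(abs(r2 - 0.2), 0.01)
})

test_that("generated data recover the population treatment effect and binary margins", {
  cfg <- sim_config(n = 5e4, p = 10, mechanism = "MAR", calib_n = 2e4)
  set.seed(31)
  params <- calibrate_coefficients(cfg)
  d <- generate_dataset(cfg, params)
  fit <- stats::lm(d$Y ~ d$X_complete + d$Z)
  expect_lt(abs(unname(stats::coef(fit)["d$Z"]) - 0.5), 0.02)
  binary_cols <- which(sim_column_types(10) == "binary")
  expect_true(all(abs(colMeans(d$X_complete[, binary_cols]) - 0.5) < 0.02))
  expect_true(all(d$X_complete[, binary_cols] %in% c(0, 1)))
})

test_that("the no-selection limit reduces treatment to a Bernoulli draw at the target rate", {
  cfg <- sim_config(n = 5e4, p = 4, pseudo_r2 = 0, mechanism = "MAR",
                    calib_n = 2e4)
  set.seed(41)
  params <- calibrate_coefficients(cfg)
  expect_equal(unname(params$beta), rep(0, 4))
  expect_equal(plogis(params$beta0), 0.2, tolerance = 1e-6)
  d <- generate_dataset(cfg, params)
  expect_lt(abs(mean(d$Z) - 0.2), 0.01)
})

test_that("MAR missingness depends on the fully observed confounder only", {
  cfg <- sim_config(n = 2e4, p = 6, mechanism = "MAR", missing_rate = 0.3,
                    calib_n = 2e4)
  set.seed(51)
  params <- calibrate_coefficients(cfg)
  d <- impose_missingness(generate_dataset(cfg, params))
  fit <- stats::glm(d$S[, 4] ~ d$X_complete, family = stats::binomial())
  zs <- summary(fit)$coefficients[-1, "z value"]
  expect_gt(abs(zs[1]), 8)          # X1 drives missingness
  expect_true(all(abs(zs[-1]) < 4)) # other confounders do not
})

test_that("focused-direct MNAR shifts the withheld values away from the observed ones", {
  cfg <- sim_config(n = 2e4, p = 6, mechanism = "FD_MNAR",
                    missing_rate = 0.3, calib_n = 2e4)
  set.seed(61)
  params <- calibrate_coefficients(cfg)
  d <- impose_missingness(generate_dataset(cfg, params))
  k <- 2  # continuous target column
  withheld <- d$X_complete[d$S[, k] == 1, k]
  observed <- d$X_complete[d$S[, k] == 0, k]
  # gamma_1 > 0: larger values are more likely withheld; oracle by direct
  # simulation of the truncation direction
  expect_gt(mean(withheld), mean(observed))
  # and the dependence survives conditioning on X1 (unlike MAR)
  fit <- stats::glm(d$S[, k] ~ d$X_complete[, 1] + d$X_complete[, k],
                    family = stats::binomial())
  expect_gt(summary(fit)$coefficients[3, "z value"], 8)
})

test_that("the missing-rate-to-zero limit leaves the data complete", {
  cfg <- quick_config(n = 500, mechanism = "MAR")
  set.seed(71)
  params <- calibrate_coefficients(cfg)
  params$gamma0[] <- -40
  d <- impose_missingness(generate_dataset(cfg, params))
  expect_true(all(d$S == 0))
  expect_identical(d$X_observed, d$X_complete)
})

test_that("identical configuration and seed reproduce the dataset bitwise", {
  d1 <- quick_dataset(seed = 123)
  d2 <- quick_dataset(seed = 123)
  expect_identical(d1$X_observed, d2$X_observed)
  expect_identical(d1$Z, d2$Z)
  expect_identical(d1$Y, d2$Y)
  expect_identical(d1$S, d2$S)
})

test_that("indicator convention converters are involutions", {
  S <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  expect_identical(response_to_missing(missing_to_response(S)), S)
})
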