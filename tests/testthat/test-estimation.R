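test_that("with unit weights the estimate and SE reduce to the two-sample formulas", {
  set.seed(3)
  Y <- rnorm(200); Z <- rep(c(1, 0), each = 100)
  eff <- weighted_effect(Y, Z, rep(1, 200))
  expect_equal(eff$estimate, mean(Y[Z == 1]) - mean(Y[Z == 0]))
  s2 <- function(v) mean((v - mean(v))^2) / length(v)
  expect_equal(eff$se, sqrt(s2(Y[Z == 1]) + s2(Y[Z == 0])), tolerance = 0.01)
  expect_equal(unname(eff$n_effective), c(100, 100))
})

test_that("the hand linearization equals the HC0 sandwich of the weighted regression", {
  set.seed(5)
  n <- 150
  Y <- rnorm(n); Z <- rbinom(n, 1, 0.4); w <- rexp(n) + 0.1
  eff <- weighted_effect(Y, Z, w)
  fit <- lm(Y ~ Z, weights = w)
  expect_equal(eff$estimate, unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(eff$se, sqrt(sandwich::vcovHC(fit, type = "HC0")[2, 2]),
               tolerance = 1e-8)
})

test_that("the linearized SE tracks a weighted bootstrap on a fixed fixture", {
  set.seed(7)
  n <- 500
  X <- rnorm(n)
  Z <- rbinom(n, 1, plogis(X - 1))
  Y <- X + 0.5 * Z + rnorm(n)
  e <- estimate_propensity(cbind(x = X), Z, "lr")
  w <- ipw_weights(e, Z, "ATE")
  eff <- weighted_effect(Y, Z, w)
  boots <- replicate(2000, {
    idx <- sample.int(n, replace = TRUE)
    weighted_effect(Y[idx], Z[idx], as.numeric(w)[idx])$estimate
  })
  expect_equal(eff$se, sd(boots), tolerance = 0.1 * sd(boots))
})

test_that("the Hajek estimator is invariant to rescaling the weights", {
  set.seed(11)
  Y <- rnorm(80); Z <- rbinom(80, 1, 0.5); w <- rexp(80) + 0.2
  a <- weighted_effect(Y, Z, w)
  b <- weighted_effect(Y, Z, 7.3 * w)
  expect_equal(a$estimate, b$estimate)
  expect_equal(a$se, b$se)
})

test_that("Rubin pooling matches its closed form and is order invariant", {
  p <- rubin_pool(c(0.4, 0.6), c(0.1, 0.1))
  expect_equal(p$estimate, 0.5)
  expect_equal(p$W, 0.01)
  expect_equal(p$B, 0.02)
  expect_equal(p$T, 0.01 + 1.5 * 0.02)
  expect_equal(p$se, 0.2)
  # identical copies: no between-imputation variance
  p2 <- rubin_pool(rep(0.3, 5), rep(0.12, 5))
  expect_equal(p2$B, 0)
  expect_equal(p2$se, 0.12)
  # order invariance
  set.seed(13)
  est <- rnorm(10); ses <- rexp(10)
  perm <- sample.int(10)
  pa <- rubin_pool(est, ses); pb <- rubin_pool(est[perm], ses[perm])
  expect_equal(pa$T, pb$T)
  expect_equal(pa$estimate, pb$estimate)
  expect_error(rubin_pool(0.5, 0.1), "at least two")
})

test_that("balance table equals the direct formula on a hand dataset", {
  X <- cbind(x = c(1, 2, 3, 4))
  Z <- c(1, 1, 0, 0)
  w <- c(1, 1, 1, 1)
  bal <- balance_table(X, Z, w)
  want <- abs(1.5 - 3.5) / sqrt((var(c(1, 2)) + var(c(3, 4))) / 2)
  expect_equal(bal$std_diff, want)
  # identical arms balance exactly; zero-variance columns are flagged
  X2 <- cbind(a = rep(1, 4), b = c(5, 6, 5, 6))
  bal2 <- balance_table(X2, Z = c(1, 0, 1, 0), w = rep(1, 4))
  expect_equal(bal2$std_diff, c(0, 0))
  expect_true(bal2$zero_variance[1])
  expect_equal(attr(bal2, "threshold"), 0.05)
})

test_that("multiple-imputation balance averages moments before forming the ratio", {
  set.seed(17)
  Z <- rep(c(1, 0), each = 20)
  w <- rep(1, 40)
  sets <- list(cbind(x = rnorm(40)), cbind(x = rnorm(40)))
  bal <- balance_table(NULL, Z, w, imputation_sets = sets)
  d_m <- mean(sapply(sets, function(Xs)
    mean(Xs[Z == 1, 1]) - mean(Xs[Z == 0, 1])))
  s_m <- sqrt((mean(sapply(sets, function(Xs) sd(Xs[Z == 1, 1])))^2 +
               mean(sapply(sets, function(Xs) sd(Xs[Z == 0, 1])))^2) / 2)
  expect_equal(bal$std_diff, abs(d_m) / s_m)
})

test_that("the weighted Poisson effect matches the closed-form log rate ratio", {
  Y <- c(2, 4, 6, 1, 2, 3)
  Z <- c(1, 1, 1, 0, 0, 0)
  eff <- poisson_att(Y, Z, rep(1, 6))
  expect_equal(eff$estimate, log(mean(Y[Z == 1]) / mean(Y[Z == 0])),
               tolerance = 1e-8)
  # identical arms: zero effect
  eff0 <- poisson_att(c(2, 3, 2, 3), c(1, 1, 0, 0), rep(1, 4))
  expect_equal(eff0$estimate, 0, tolerance = 1e-10)
  expect_error(poisson_att(c(-1, 2), c(1, 0), c(1, 1)), "non-negative")
  # ATT-form weights are accepted
  e <- c(0.4, 0.6, 0.3, 0.2)
  z <- c(1, 1, 0, 0)
  w <- ipw_weights(e, z, "ATT")
  effw <- poisson_att(c(2, 4, 1, 2), z, w)
  expect_gt(effw$se, 0)
})

test_that("the linearized SE is calibrated against the empirical SD over replications", {
  cfg <- sim_config(n = 500, p = 6, mechanism = "MAR", calib_n = 2e4)
  set.seed(19)
  params <- calibrate_coefficients(cfg)   # fixed across replications
  reps <- t(replicate(500, {
    d <- generate_dataset(cfg, params)
    e <- estimate_propensity(d$X_complete, d$Z, "lr")
    eff <- weighted_effect(d$Y, d$Z, ipw_weights(e, d$Z, "ATE"))
    c(eff$estimate, eff$se)
  }))
  ratio <- mean(reps[, 2]) / sd(reps[, 1])
  expect_gt(ratio, 0.9)
  expect_lt(ratio, 1.1)
})

test_that("common-support summaries expose the per-arm propensity range", {
  e <- c(0.1, 0.2, 0.3, 0.6, 0.7, 0.8)
  Z <- c(0, 0, 0, 1, 1, 1)
  cs <- common_support(e, Z)
  expect_equal(cs["treated", "min"], 0.6)
  expect_equal(cs["control", "max"], 0.3)
})
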