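test_that("strawman fills continuous cells with medians and binary cells with modes", {
  X <- cbind(a = c(1, 2, 100, NA), b = c(0, 0, 1, NA))
  out <- strawman_initialize(X)
  expect_equal(unname(out$X_imputed[4, "a"]), 2)    # median of {1, 2, 100}
  expect_equal(unname(out$X_imputed[4, "b"]), 0)    # mode of {0, 0, 1}
  expect_equal(out$S[4, ], c(a = 1L, b = 1L))
  # observed cells untouched; complete input is returned unchanged
  complete <- cbind(a = 1:3, b = c(0, 1, 0))
  expect_equal(strawman_initialize(complete)$X_imputed, complete,
               ignore_attr = TRUE)
  expect_error(strawman_initialize(cbind(a = c(NA, NA), b = c(1, 2))),
               "no observed values")
})

test_that("proximity-weighted update reproduces the donor-rule arithmetic", {
  # donors 1 and 3 with proximities 0.2 / 0.6 -> weights 0.25 / 0.75
  X <- cbind(x = c(1, 0, 3))
  S <- cbind(x = c(0L, 1L, 0L))
  M <- matrix(0, 3, 3)
  M[2, 1] <- M[1, 2] <- 0.2
  M[2, 3] <- M[3, 2] <- 0.6
  out <- proximity_weighted_update(X, S, M, column_types = "continuous")
  expect_equal(unname(out$X_imputed[2, 1]), 0.25 * 1 + 0.75 * 3)

  # binary vote: equal proximity support, marginal proportions 0.8 / 0.2
  Xb <- cbind(b = c(0, 0, 0, 0, 1, 1))
  Sb <- cbind(b = c(0L, 0L, 0L, 0L, 0L, 1L))
  Mb <- matrix(0, 6, 6)
  Mb[6, 1] <- Mb[1, 6] <- 0.5   # one donor holding 0
  Mb[6, 5] <- Mb[5, 6] <- 0.5   # one donor holding 1
  outb <- proximity_weighted_update(Xb, Sb, Mb, column_types = "binary")
  expect_equal(unname(outb$X_imputed[6, 1]), 0)  # 0.8 * 0.5 > 0.2 * 0.5
})

test_that("update equals the literal per-cell loop on random fixtures", {
  for (s in 1:4) {
    set.seed(s)
    n <- 20
    X <- cbind(matrix(rnorm(n * 3), n, 3), rbinom(n, 1, 0.4))
    colnames(X) <- paste0("v", 1:4)
    S <- matrix(rbinom(n * 4, 1, 0.25), n, 4)
    S[1, ] <- 0L  # keep at least one fully observed row
    types <- c(rep("continuous", 3), "binary")
    M <- matrix(runif(n * n), n, n)
    M <- (M + t(M)) / 2
    diag(M) <- 0
    Xc <- strawman_initialize(ifelse(S == 1, NA, X), S, types)$X_imputed
    got <- proximity_weighted_update(Xc, S, M, types)$X_imputed
    want <- brute_force_update(Xc, S, M, types)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("zero-proximity rows fall back to uniform donor means", {
  X <- cbind(x = c(1, 2, 3, 10))
  S <- cbind(x = c(0L, 0L, 0L, 1L))
  M <- matrix(0, 4, 4)       # row 4 has no proximity mass anywhere
  M[1, 2] <- M[2, 1] <- 1
  Xc <- strawman_initialize(ifelse(S == 1, NA, X), S, "continuous")$X_imputed
  out <- proximity_weighted_update(Xc, S, M, "continuous")
  expect_equal(unname(out$X_imputed[4, 1]), mean(c(1, 2, 3)))
  expect_equal(attr(out, "zero_proximity_rows"), 4L)
})

test_that("every imputer preserves observed cells exactly", {
  d <- quick_dataset(seed = 3, n = 120, p = 6)
  ctl <- impute_control(n_trees = 30, max_iter = 2, m = 3, seed = 5)
  obs <- d$S == 0
  res <- list(
    dfpi = suppressWarnings(dfpi_impute(d$X_observed, d$S, d$Z, d$Y, ctl)),
    pi_i = suppressWarnings(pi_i_impute(d$X_observed, d$S, d$Z, d$Y, ctl)),
    pi_u = suppressWarnings(pi_u_impute(d$X_observed, d$S, ctl)),
    straw = strawman_initialize(d$X_observed, d$S))
  for (nm in names(res)) {
    expect_identical(res[[nm]]$X_imputed[obs], d$X_complete[obs], label = nm)
    expect_false(anyNA(res[[nm]]$X_imputed), label = nm)
    bin <- which(sim_column_types(6) == "binary")
    expect_true(all(res[[nm]]$X_imputed[, bin] %in% c(0, 1)), label = nm)
  }
  mi <- mice_pmm_impute(d$X_observed, d$S, d$Z, d$Y, ctl)
  for (Xi in mi$imputations)
    expect_identical(Xi[obs], d$X_complete[obs])
})

test_that("proximity imputers return the input unchanged when nothing is missing", {
  set.seed(5)
  X <- cbind(a = rnorm(40), b = rnorm(40), c = rbinom(40, 1, 0.5))
  Z <- rbinom(40, 1, 0.4); Y <- rnorm(40)
  ctl <- impute_control(n_trees = 10, seed = 1)
  for (f in list(function() dfpi_impute(X, NULL, Z, Y, ctl),
                 function() pi_i_impute(X, NULL, Z, Y, ctl),
                 function() pi_u_impute(X, NULL, ctl))) {
    out <- f()
    expect_equal(out$X_imputed, X, ignore_attr = TRUE)
    expect_identical(out$iterations, 0L)
  }
})

test_that("dfpi records a trace and stops at the iteration cap when unconverged", {
  d <- quick_dataset(seed = 7, n = 100, p = 4, missing_rate = 0.4)
  ctl <- impute_control(n_trees = 20, max_iter = 3, seed = 9)
  expect_warning(out <- dfpi_impute(d$X_observed, d$S, d$Z, d$Y, ctl),
                 "maximum iterations")
  expect_length(out$trace, 3)
  expect_false(out$converged)
  expect_identical(out$iterations, 3L)
})

test_that("unsupervised proximity imputation ignores treatment and outcome by construction", {
  d <- quick_dataset(seed = 11, n = 80, p = 4)
  ctl <- impute_control(n_trees = 20, max_iter = 2, seed = 13)
  a <- suppressWarnings(pi_u_impute(d$X_observed, d$S, ctl))
  b <- suppressWarnings(pi_u_impute(d$X_observed, d$S, ctl))
  expect_identical(a$X_imputed, b$X_imputed)  # no Y/Z in the signature
})

test_that("dfpi beats strawman median imputation on a smooth fixture under light MCAR", {
  fx <- smooth_fixture(n = 150, seed = 17)
  set.seed(19)
  S <- matrix(rbinom(150 * 4, 1, 0.1), 150, 4)
  S[, 1] <- 0L
  X_obs <- ifelse(S == 1, NA, fx$X)
  ctl <- impute_control(n_trees = 60, max_iter = 4, seed = 21)
  dfpi <- suppressWarnings(dfpi_impute(X_obs, S, fx$Z, fx$Y, ctl))
  straw <- strawman_initialize(X_obs, S)
  cont <- S[, 2:3] == 1
  rmse <- function(imp) sqrt(mean((imp$X_imputed[, 2:3][cont] -
                                     fx$X[, 2:3][cont])^2))
  expect_lte(rmse(dfpi), rmse(straw))
})

test_that("chained-equation PMM returns m donor-matched completions", {
  d <- quick_dataset(seed = 23, n = 150, p = 6)
  ctl <- impute_control(m = 10, seed = 25)
  mi <- mice_pmm_impute(d$X_observed, d$S, d$Z, d$Y, ctl)
  expect_length(mi$imputations, 10)
  # PMM property: every imputed value is an observed value of its column
  for (j in seq_len(ncol(d$S))) {
    obs_vals <- d$X_observed[d$S[, j] == 0, j]
    for (Xi in mi$imputations)
      expect_true(all(Xi[d$S[, j] == 1, j] %in% obs_vals))
  }
  # chains genuinely differ
  expect_false(identical(mi$imputations[[1]], mi$imputations[[2]]))
  expect_error(mice_pmm_impute(d$X_observed, d$S, d$Z, d$Y,
                               impute_control(m = 1)), "m >= 2")
})

test_that("complete data passes through multiple imputation unchanged", {
  set.seed(27)
  X <- cbind(a = rnorm(30), b = rnorm(30))
  mi <- mice_pmm_impute(X, NULL, rbinom(30, 1, 0.5), rnorm(30),
                        impute_control(m = 3, seed = 29))
  for (Xi in mi$imputations) expect_equal(Xi, X, ignore_attr = TRUE)
})

test_that("the out-of-bag proximity variant runs the same contract", {
  d <- quick_dataset(seed = 31, n = 80, p = 4, missing_rate = 0.3)
  ctl <- impute_control(n_trees = 40, max_iter = 2, seed = 33,
                        oob_proximity = TRUE)
  out <- suppressWarnings(dfpi_impute(d$X_observed, d$S, d$Z, d$Y, ctl))
  obs <- d$S == 0
  expect_identical(out$X_imputed[obs], d$X_complete[obs])
  expect_false(anyNA(out$X_imputed))
  outu <- suppressWarnings(pi_u_impute(d$X_observed, d$S, ctl))
  expect_identical(outu$X_imputed[obs], d$X_complete[obs])
})
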