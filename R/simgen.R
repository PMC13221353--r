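#' Simulation configuration for the MNAR propensity-score study
#'
#' Describes one data-generating condition: multivariate-normal confounders
#' (half dichotomized to binary), a logistic treatment-assignment model
#' calibrated to a target treated proportion and McKelvey--Zavoina pseudo-R2,
#' a linear outcome model calibrated to a target R2, and one of six
#' missingness mechanisms imposed on confounders 2..p at a calibrated
#' marginal rate.
#'
#' @param n Sample size (>= 50 recommended; >= 2 required).
#' @param p Number of confounders (>= 2). Columns `1..ceiling(p/2)` are
#'   continuous, the remainder are dichotomized at 0 to \{0, 1\}. Column 1 is
#'   always fully observed.
#' @param delta Population treatment effect on the outcome.
#' @param prop_treated Target marginal treated proportion, in (0, 1).
#' @param pseudo_r2 Target McKelvey--Zavoina pseudo-R2 of the treatment
#'   model, `var(X beta) / (var(X beta) + pi^2/3)`.
#' @param r2 Target population R2 of the linear outcome model (signal
#'   `X pi + delta Z` against unit residual variance).
#' @param missing_rate Target marginal missingness proportion per incomplete
#'   column, in (0, 1).
#' @param mechanism One of `"MAR"`, `"FD_MNAR"` (focused-direct: the missing
#'   value itself), `"FI_MNAR"` (focused-indirect: an unobserved auxiliary),
#'   `"DF_MNAR"` (diffuse: all confounders), `"DF_MNAR_INT1"` (observed x
#'   target interaction), `"DF_MNAR_INT2"` (observed x auxiliary
#'   interaction).
#' @param corr Correlation structure of the latent multivariate normal:
#'   `"exchangeable"` (default, with off-diagonal `rho`), `"identity"`, or
#'   `"user"` with `corr_matrix` supplied.
#' @param rho Exchangeable correlation (ignored otherwise).
#' @param corr_matrix Optional user correlation matrix (symmetric positive
#'   definite, unit diagonal).
#' @param deterministic_threshold If `TRUE`, treatment is the literal
#'   deterministic threshold `Z = 1\{beta0 + X beta > 0\}`; the default adds a
#'   latent logistic(0,1) error, i.e. `Z ~ Bernoulli(plogis(beta0 + X beta))`,
#'   which preserves overlap.
#' @param calib_n Size of the internal Monte Carlo calibration sample.
#' @param calib_seed Fixed internal seed for the calibration sample, so that
#'   calibration is deterministic given the configuration.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n, p = 10, delta = 0.5, prop_treated = 0.2,
                       pseudo_r2 = 0.2, r2 = 0.2, missing_rate = 0.3,
                       mechanism = c("MAR", "FD_MNAR", "FI_MNAR", "DF_MNAR",
                                     "DF_MNAR_INT1", "DF_MNAR_INT2"),
                       corr = c("exchangeable", "identity", "user"),
                       rho = 0.2, corr_matrix = NULL,
                       deterministic_threshold = FALSE,
                       calib_n = 1e5, calib_seed = 760541L) {
  mechanism <- match.arg(mechanism)
  corr <- match.arg(corr)
  if (n < 2) stop("'n' must be at least 2")
  if (p < 2) stop("'p' must be at least 2")
  if (!(prop_treated > 0 && prop_treated < 1))
    stop("'prop_treated' must lie in (0, 1)")
  if (!(missing_rate > 0 && missing_rate < 1))
    stop("'missing_rate' must lie in (0, 1)")
  if (!(pseudo_r2 >= 0 && pseudo_r2 < 1)) stop("'pseudo_r2' must lie in [0, 1)")
  if (!(r2 >= 0 && r2 < 1)) stop("'r2' must lie in [0, 1)")
  if (corr == "user") {
    if (is.null(corr_matrix)) stop("corr = 'user' requires 'corr_matrix'")
    corr_matrix <- as.matrix(corr_matrix)
    if (nrow(corr_matrix) != p || ncol(corr_matrix) != p)
      stop("'corr_matrix' must be p x p")
    if (max(abs(corr_matrix - t(corr_matrix))) > 1e-8)
      stop("'corr_matrix' must be symmetric")
    if (max(abs(diag(corr_matrix) - 1)) > 1e-8)
      stop("'corr_matrix' must have unit diagonal")
    ev <- eigen(corr_matrix, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10)
      stop("'corr_matrix' must be positive definite")
  }
  structure(list(n = as.integer(n), p = as.integer(p), delta = delta,
                 prop_treated = prop_treated, pseudo_r2 = pseudo_r2, r2 = r2,
                 missing_rate = missing_rate, mechanism = mechanism,
                 corr = corr, rho = rho, corr_matrix = corr_matrix,
                 deterministic_threshold = deterministic_threshold,
                 calib_n = as.integer(calib_n),
                 calib_seed = as.integer(calib_seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  n = %d, p = %d (continuous 1..%d, binary %d..%d)\n",
              x$n, x$p, n_continuous(x$p), n_continuous(x$p) + 1L, x$p))
  cat(sprintf("  delta = %g, treated = %g, pseudo-R2 = %g, R2 = %g\n",
              x$delta, x$prop_treated, x$pseudo_r2, x$r2))
  cat(sprintf("  mechanism = %s at rate %g, correlation = %s%s\n",
              x$mechanism, x$missing_rate, x$corr,
              if (x$corr == "exchangeable") sprintf("(%g)", x$rho) else ""))
  invisible(x)
}

# index of last continuous column; binary columns are n_continuous(p)+1 .. p
n_continuous <- function(p) as.integer(ceiling(p / 2))

#' Column types implied by a configuration
#' @param p Number of confounders.
#' @return Character vector `"continuous"`/`"binary"` of length `p`.
#' @export
sim_column_types <- function(p) {
  ifelse(seq_len(p) <= n_continuous(p), "continuous", "binary")
}

# Draw the latent standardized-normal design and dichotomize half of it.
# Exchangeable correlation uses the exact one-factor representation.
draw_covariates <- function(n, config) {
  p <- config$p
  if (config$corr == "identity") {
    X <- matrix(stats::rnorm(n * p), n, p)
  } else if (config$corr == "exchangeable") {
    rho <- config$rho
    if (rho < 0) stop("exchangeable correlation requires rho >= 0")
    f <- stats::rnorm(n)
    X <- sqrt(rho) * f + sqrt(1 - rho) * matrix(stats::rnorm(n * p), n, p)
  } else {
    L <- chol(config$corr_matrix)
    X <- matrix(stats::rnorm(n * p), n, p) %*% L
  }
  cb <- n_continuous(p)
  if (cb < p) {
    idx <- (cb + 1L):p
    X[, idx] <- (X[, idx] > 0) + 0
  }
  colnames(X) <- paste0("x", seq_len(p))
  X
}

# Calibration sample is deterministic given the configuration: drawn under a
# fixed internal seed without disturbing the caller's RNG stream. Because it
# is deterministic it can be cached (keyed by the distribution-relevant
# fields), which matters when thousands of replications share one condition.
.calibration_cache <- new.env(parent = emptyenv())

calibration_sample <- function(config) {
  key <- paste(config$p, config$corr, config$rho, config$calib_n,
               config$calib_seed,
               if (is.null(config$corr_matrix)) ""
               else paste(signif(config$corr_matrix, 8), collapse = ","),
               sep = "|")
  hit <- get0(key, envir = .calibration_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  state <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
  })
  set.seed(config$calib_seed)
  X <- draw_covariates(config$calib_n, config)
  aux <- matrix(stats::rnorm(config$calib_n * config$p), config$calib_n,
                config$p)
  out <- list(X = X, aux = aux)
  if (length(ls(.calibration_cache)) >= 8)
    rm(list = ls(.calibration_cache)[1], envir = .calibration_cache)
  assign(key, out, envir = .calibration_cache)
  out
}

#' Calibrate treatment- and outcome-model coefficients
#'
#' Draws treatment slopes from U(-0.4, 0.4) and outcome slopes from
#' U(0.1, 0.8), then rescales each vector by a single multiplicative constant
#' so that, on a fixed 1e5-draw calibration sample, the McKelvey--Zavoina
#' pseudo-R2 of the treatment model and the population R2 of the outcome
#' model hit their targets. The treatment intercept is root-found so the
#' marginal treated proportion matches its target, and the missingness slopes
#' are drawn from U(0.1, 0.5). Missingness intercepts are calibrated by
#' [calibrate_missing_intercept()].
#'
#' @param config A [sim_config()].
#' @return An object of class `model_params` with elements `beta0`, `beta`,
#'   `pi0`, `pi`, `gamma`, `gamma0` (per-column missingness intercepts) and
#'   `achieved` (realized calibration values on the calibration sample).
#' @export
calibrate_coefficients <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$p
  cal <- calibration_sample(config)
  X <- cal$X

  # treatment model: rescale to the target latent-variable pseudo-R2
  beta_raw <- stats::runif(p, -0.4, 0.4)
  eta_raw <- drop(X %*% beta_raw)
  v_raw <- stats::var(eta_raw)
  target_var <- config$pseudo_r2 / (1 - config$pseudo_r2) * pi^2 / 3
  scale_b <- if (v_raw > 0 && target_var > 0) sqrt(target_var / v_raw) else 0
  beta <- beta_raw * scale_b
  eta <- eta_raw * scale_b
  beta0 <- calibrate_beta0(eta, config)

  # achieved values on the calibration sample
  v_eta <- stats::var(eta)
  achieved_pr2 <- v_eta / (v_eta + pi^2 / 3)
  if (config$deterministic_threshold) {
    z_cal <- as.numeric(beta0 + eta > 0)
    achieved_prop <- mean(z_cal)
  } else {
    pz <- stats::plogis(beta0 + eta)
    achieved_prop <- mean(pz)
    z_cal <- stats::rbinom(length(pz), 1L, pz)
  }

  # outcome model: closed-form rescaling of pi to the target R2 given the
  # calibrated treatment model (signal = c * X pi_raw + delta * Z, noise 1)
  pi_raw <- stats::runif(p, 0.1, 0.8)
  s <- drop(X %*% pi_raw)
  d <- config$delta * z_cal
  a <- stats::var(s)
  b <- stats::cov(s, d)
  v <- stats::var(d)
  tau <- config$r2 / (1 - config$r2)
  if (tau <= v) {
    scale_p <- 0
    warning("treatment effect alone exceeds the target outcome R2; ",
            "outcome slopes set to zero")
  } else {
    scale_p <- (-b + sqrt(b^2 + a * (tau - v))) / a
  }
  pi_vec <- pi_raw * scale_p
  sig <- s * scale_p + d
  achieved_r2 <- stats::var(sig) / (stats::var(sig) + 1)

  # missingness slopes for the configured mechanism
  n_slopes <- switch(config$mechanism,
                     MAR = 1L, FD_MNAR = 1L, FI_MNAR = 1L,
                     DF_MNAR = p, DF_MNAR_INT1 = 3L, DF_MNAR_INT2 = 3L)
  gamma <- stats::runif(n_slopes, 0.1, 0.5)

  params <- structure(list(beta0 = beta0, beta = beta, pi0 = 0, pi = pi_vec,
                           gamma = gamma, gamma0 = NULL,
                           achieved = list(prop_treated = achieved_prop,
                                           pseudo_r2 = achieved_pr2,
                                           r2 = achieved_r2,
                                           missing_rate = NULL)),
                      class = "model_params")
  params$gamma0 <- calibrate_missing_intercept(config$mechanism,
                                               config$missing_rate,
                                               params, config)
  params$achieved$missing_rate <-
    attr(params$gamma0, "achieved_rate")
  attr(params$gamma0, "achieved_rate") <- NULL
  params
}

#' @export
print.model_params <- function(x, ...) {
  cat("Calibrated model parameters\n")
  cat(sprintf("  beta0 = %.4f; |beta| in [%.3f, %.3f]\n", x$beta0,
              min(abs(x$beta)), max(abs(x$beta))))
  cat(sprintf("  achieved: treated %.4f, pseudo-R2 %.4f, R2 %.4f\n",
              x$achieved$prop_treated, x$achieved$pseudo_r2, x$achieved$r2))
  if (!is.null(x$achieved$missing_rate))
    cat(sprintf("  achieved missing rate: mean %.4f\n",
                mean(x$achieved$missing_rate, na.rm = TRUE)))
  invisible(x)
}

calibrate_beta0 <- function(eta, config) {
  target <- config$prop_treated
  if (config$deterministic_threshold)
    return(-stats::quantile(eta, 1 - target, names = FALSE))
  f <- function(b0) mean(stats::plogis(b0 + eta)) - target
  stats::uniroot(f, c(-30, 30), tol = 1e-8)$root
}

# Linear predictors of the missingness models for target columns 2..p
# (excluding the intercept). Returns an n x (p-1) matrix, one column per
# target confounder.
missingness_linear_predictor <- function(X, aux, gamma, mechanism) {
  p <- ncol(X)
  targets <- 2:p
  eta <- switch(mechanism,
    MAR = matrix(gamma[1] * X[, 1], nrow(X), p - 1L),
    FD_MNAR = sweep(X[, targets, drop = FALSE], 2, gamma[1], `*`),
    FI_MNAR = gamma[1] * aux[, targets, drop = FALSE],
    DF_MNAR = matrix(drop(X %*% gamma), nrow(X), p - 1L),
    DF_MNAR_INT1 = {
      xk <- X[, targets, drop = FALSE]
      gamma[1] * X[, 1] + gamma[2] * xk + gamma[3] * (X[, 1] * xk)
    },
    DF_MNAR_INT2 = {
      ak <- aux[, targets, drop = FALSE]
      gamma[1] * X[, 1] + gamma[2] * ak + gamma[3] * (X[, 1] * ak)
    },
    stop("unknown mechanism: ", mechanism))
  eta <- as.matrix(eta)
  colnames(eta) <- paste0("x", targets)
  eta
}

# Target columns whose missingness linear predictor shares one distribution,
# so a single intercept root serves the whole group. Valid for exchangeable /
# identity correlation, where (X1, Xk) has the same joint law for every
# continuous k and for every binary k.
intercept_groups <- function(config) {
  p <- config$p
  targets <- 2:p
  types <- sim_column_types(p)[targets]
  shared <- config$corr %in% c("exchangeable", "identity")
  by_type <- config$mechanism %in% c("FD_MNAR", "DF_MNAR_INT1")
  if (!shared) {
    split(targets, targets)                     # one group per column
  } else if (by_type) {
    split(targets, types)                       # continuous vs binary target
  } else {
    list(all = targets)                         # identical across columns
  }
}

#' Calibrate the missingness-model intercept(s)
#'
#' Root-finds, on the fixed calibration sample, the intercept `gamma0` of
#' each column's missingness model so that the marginal probability of a
#' missing cell equals `missing_rate`. Column 1 is always fully observed.
#'
#' @param mechanism Missingness mechanism (see [sim_config()]).
#' @param missing_rate Target marginal missing proportion per column.
#' @param params A `model_params` object carrying the slopes `gamma`.
#' @param config The [sim_config()].
#' @return Numeric vector of length `p`: `NA` for column 1, the calibrated
#'   intercept for columns 2..p, with the achieved per-column rates attached
#'   as attribute `achieved_rate`.
#' @export
calibrate_missing_intercept <- function(mechanism, missing_rate, params,
                                        config) {
  cal <- calibration_sample(config)
  eta <- missingness_linear_predictor(cal$X, cal$aux, params$gamma, mechanism)
  p <- config$p
  gamma0 <- rep(NA_real_, p)
  achieved <- rep(NA_real_, p)
  for (group in intercept_groups(config)) {
    k <- group[1]
    ek <- eta[, k - 1L]
    f <- function(g0) mean(stats::plogis(g0 + ek)) - missing_rate
    lo <- stats::qlogis(missing_rate) - max(abs(ek)) - 1
    hi <- stats::qlogis(missing_rate) + max(abs(ek)) + 1
    if (f(lo) > 0 || f(hi) < 0) stop("missingness intercept root not bracketed")
    root <- stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
    gamma0[group] <- root
    for (kk in group) achieved[kk] <- mean(stats::plogis(root + eta[, kk - 1L]))
  }
  names(gamma0) <- paste0("x", seq_len(p))
  attr(gamma0, "achieved_rate") <- achieved
  gamma0
}

#' Generate the complete part of a simulated dataset
#'
#' Draws confounders from the configured multivariate standardized normal
#' (half dichotomized at 0), treatment from the logistic model
#' `logit P(Z = 1) = beta0 + X beta` (or the deterministic threshold if
#' configured), and the outcome `Y = pi0 + X pi + delta Z + e`, `e ~ N(0,1)`.
#'
#' @param config A [sim_config()].
#' @param params Calibrated [calibrate_coefficients()] output.
#' @param seed Optional integer seed (otherwise the current RNG stream is
#'   used).
#' @return An object of class `sim_data` with elements `X_complete`, `Z`,
#'   `Y`, `config`, `params` (and, after [impose_missingness()], `S` and
#'   `X_observed`).
#' @export
generate_dataset <- function(config, params, seed = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(params, "model_params"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n
  X <- draw_covariates(n, config)
  eta <- params$beta0 + drop(X %*% params$beta)
  Z <- if (config$deterministic_threshold) as.numeric(eta > 0)
       else stats::rbinom(n, 1L, stats::plogis(eta))
  Y <- params$pi0 + drop(X %*% params$pi) + config$delta * Z + stats::rnorm(n)
  structure(list(X_complete = X, Z = Z, Y = Y, S = NULL, X_observed = NULL,
                 config = config, params = params),
            class = "sim_data")
}

#' @export
print.sim_data <- function(x, ...) {
  cat(sprintf("Simulated dataset: n = %d, p = %d, treated = %.3f\n",
              nrow(x$X_complete), ncol(x$X_complete), mean(x$Z)))
  if (!is.null(x$S))
    cat(sprintf("  mechanism %s, observed missing rate %.3f (columns 2..p)\n",
                x$config$mechanism, mean(x$S[, -1])))
  else cat("  no missingness imposed yet\n")
  invisible(x)
}

#' Impose missingness on a simulated dataset
#'
#' For each target column k in 2..p, computes the mechanism-specific latent
#' score `gamma0_k + eta_k + e`, `e ~ logistic(0, 1)`, and withholds the cell
#' (S = 1) where the score exceeds 0. The focused-indirect and
#' interaction-2 mechanisms draw one unobserved N(0,1) auxiliary variable per
#' target column; auxiliaries are never exposed downstream. Column 1 is never
#' missing.
#'
#' @param dataset A `sim_data` object with complete covariates.
#' @param mechanism,missing_rate,params Optional overrides; defaults come
#'   from the dataset's own config/params.
#' @param seed Optional integer seed.
#' @return The dataset with `S` (1 = missing) and `X_observed` (NA where
#'   withheld) filled in.
#' @export
impose_missingness <- function(dataset, mechanism = NULL, missing_rate = NULL,
                               params = NULL, seed = NULL) {
  stopifnot(inherits(dataset, "sim_data"))
  if (!is.null(seed)) set.seed(seed)
  config <- dataset$config
  mechanism <- mechanism %||% config$mechanism
  params <- params %||% dataset$params
  if (!is.null(missing_rate) || mechanism != config$mechanism) {
    config$mechanism <- mechanism
    config$missing_rate <- missing_rate %||% config$missing_rate
    params$gamma0 <- calibrate_missing_intercept(mechanism,
                                                 config$missing_rate, params,
                                                 config)
  }
  X <- dataset$X_complete
  n <- nrow(X); p <- ncol(X)
  aux <- matrix(stats::rnorm(n * p), n, p)
  eta <- missingness_linear_predictor(X, aux, params$gamma, mechanism)
  prob <- stats::plogis(sweep(eta, 2, params$gamma0[-1], `+`))
  S <- matrix(0L, n, p, dimnames = dimnames(X))
  S[, -1] <- (matrix(stats::runif(n * (p - 1L)), n, p - 1L) < prob) + 0L
  X_obs <- X
  X_obs[S == 1L] <- NA_real_
  dataset$S <- S
  dataset$X_observed <- X_obs
  dataset$config <- config
  dataset$params <- params
  dataset
}

#' Simulate one complete study dataset
#'
#' Convenience wrapper: calibrate coefficients, generate the complete data
#' and impose the configured missingness, all under the current RNG stream
#' (or `seed`).
#'
#' @inheritParams generate_dataset
#' @param params Optional pre-calibrated parameters (calibrated afresh when
#'   `NULL`).
#' @return A `sim_data` object with missingness imposed.
#' @export
simulate_mnar_dataset <- function(config, params = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(params)) params <- calibrate_coefficients(config)
  impose_missingness(generate_dataset(config, params))
}

#' Convert between missing-indicator conventions
#'
#' Internally `S = 1` marks a missing cell; some of the missing-data
#' literature codes `R = 1` as observed. These helpers convert between the
#' two.
#' @param S,R Binary indicator matrix.
#' @return The complementary indicator matrix.
#' @export
missing_to_response <- function(S) 1L - S

#' @rdname missing_to_response
#' @export
response_to_missing <- function(R) 1L - R

`%||%` <- function(a, b) if (is.null(a)) b else a
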