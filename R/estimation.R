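#' Weighted treatment-effect estimate with linearized standard error
#'
#' The effect is the Hajek (weight-normalized) difference of weighted outcome
#' means between the treated and control arms. Its standard error comes from
#' Taylor-series linearization of the two weighted ratio means under the
#' with-replacement design approximation: the influence contribution of unit
#' i in arm t is `w_i (Y_i - mu_t) / sum(arm weights)`, and the variance is
#' the sum of squared contributions over both arms. Propensity-estimation
#' uncertainty is not propagated, matching standard survey-weighted
#' practice.
#'
#' @param Y Numeric outcome vector.
#' @param Z Binary treatment vector.
#' @param w Positive weights (e.g. [ipw_weights()]).
#' @param estimand Optional tag carried through (taken from `w` if present).
#' @return An object of class `effect_estimate`: `estimate`, `se`,
#'   `estimand`, and `n_effective` (Kish effective sizes per arm).
#' @export
weighted_effect <- function(Y, Z, w, estimand = NULL) {
  w <- as.numeric(w)
  if (any(w <= 0)) stop("weights must be positive")
  if (anyNA(Y) || anyNA(Z) || anyNA(w)) stop("Y, Z, w must be complete")
  estimand <- estimand %||% attr(w, "estimand") %||% "ATE"
  t1 <- Z == 1
  if (!any(t1) || all(t1)) stop("both arms must be non-empty")
  sw1 <- sum(w[t1]); sw0 <- sum(w[!t1])
  mu1 <- sum(w[t1] * Y[t1]) / sw1
  mu0 <- sum(w[!t1] * Y[!t1]) / sw0
  u <- numeric(length(Y))
  u[t1] <- w[t1] * (Y[t1] - mu1) / sw1
  u[!t1] <- -w[!t1] * (Y[!t1] - mu0) / sw0
  se <- sqrt(sum(u^2))
  n_eff <- c(treated = sw1^2 / sum(w[t1]^2),
             control = sw0^2 / sum(w[!t1]^2))
  structure(list(estimate = mu1 - mu0, se = se, estimand = estimand,
                 n_effective = n_eff),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%s estimate: %.4f (SE %.4f); effective n = %.1f / %.1f\n",
              x$estimand, x$estimate, x$se, x$n_effective[1],
              x$n_effective[2]))
  invisible(x)
}

#' Pool multiply imputed estimates by Rubin's rules
#'
#' Pooled point estimate is the mean; total variance is the within-imputation
#' variance plus the between-imputation variance inflated by `1 + 1/m`.
#'
#' @param estimates Numeric vector of per-imputation estimates (length m
#'   >= 2).
#' @param ses Matching vector of per-imputation standard errors.
#' @return An object of class `pooled_estimate`: `estimate`, `se`, `W`
#'   (within), `B` (between), `T` (total variance), `m`.
#' @export
rubin_pool <- function(estimates, ses) {
  m <- length(estimates)
  if (m < 2) stop("Rubin pooling requires at least two imputations")
  if (length(ses) != m) stop("'estimates' and 'ses' must have equal length")
  W <- mean(ses^2)
  B <- stats::var(estimates)
  Tv <- W + (1 + 1 / m) * B
  structure(list(estimate = mean(estimates), se = sqrt(Tv), W = W, B = B,
                 T = Tv, m = m),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("Pooled estimate (m = %d): %.4f (SE %.4f; W %.5f, B %.5f)\n",
              x$m, x$estimate, x$se, x$W, x$B))
  invisible(x)
}

#' Weighted covariate balance table
#'
#' Per covariate, the absolute weighted mean difference between arms divided
#' by the pooled unweighted standard deviation,
#' `sqrt((sd_1^2 + sd_0^2)/2)`. With multiply imputed data the weighted
#' means/proportions and the unweighted standard deviations are first
#' averaged across the imputed sets and the ratio formed afterwards.
#' Covariates with standardized difference below `threshold` count as
#' balanced (What Works Clearinghouse baseline-equivalence rule).
#'
#' @param X Complete covariate matrix (ignored when `imputation_sets` is
#'   given).
#' @param Z Binary treatment vector.
#' @param w Weights.
#' @param threshold Balance threshold (default 0.05).
#' @param imputation_sets Optional list of complete covariate matrices (one
#'   per imputation).
#' @return An object of class `balance_table`: data frame of standardized
#'   differences plus summary attributes `max`, `mean`, `n_exceeding`,
#'   `threshold`.
#' @export
balance_table <- function(X, Z, w, threshold = 0.05,
                          imputation_sets = NULL) {
  sets <- imputation_sets %||% list(named_matrix(X))
  sets <- lapply(sets, named_matrix)
  w <- as.numeric(w)
  t1 <- Z == 1
  stats_one <- function(Xs) {
    wm1 <- apply(Xs[t1, , drop = FALSE], 2, stats::weighted.mean, w = w[t1])
    wm0 <- apply(Xs[!t1, , drop = FALSE], 2, stats::weighted.mean, w = w[!t1])
    s1 <- apply(Xs[t1, , drop = FALSE], 2, stats::sd)
    s0 <- apply(Xs[!t1, , drop = FALSE], 2, stats::sd)
    list(diff = wm1 - wm0, s1 = s1, s0 = s0)
  }
  per_set <- lapply(sets, stats_one)
  p <- ncol(sets[[1]])
  collect <- function(field)
    rowMeans(matrix(unlist(lapply(per_set, `[[`, field)), nrow = p))
  diff <- collect("diff")
  s1 <- collect("s1")
  s0 <- collect("s0")
  pooled_sd <- sqrt((s1^2 + s0^2) / 2)
  zero_var <- pooled_sd == 0
  std <- ifelse(zero_var, 0, abs(diff) / ifelse(zero_var, 1, pooled_sd))
  tab <- data.frame(covariate = colnames(sets[[1]]),
                    std_diff = std, zero_variance = zero_var,
                    row.names = NULL)
  structure(tab, class = c("balance_table", "data.frame"),
            max = max(std), mean = mean(std),
            n_exceeding = sum(std >= threshold), threshold = threshold)
}

#' @export
print.balance_table <- function(x, ...) {
  cat(sprintf("Covariate balance: mean |d| = %.3f, max = %.3f, %d of %d >= %g\n",
              attr(x, "mean"), attr(x, "max"), attr(x, "n_exceeding"),
              nrow(x), attr(x, "threshold")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Weighted Poisson treatment-effect estimate (ATT pipelines)
#'
#' Fits the weighted Poisson regression `log E[Y] = g0 + g1 Z` and returns
#' the treatment coefficient `g1` with its linearized (robust sandwich)
#' standard error. With unit weights, `g1` is the log ratio of arm means.
#'
#' @param Y Non-negative outcome vector.
#' @param Z Binary treatment vector.
#' @param w Positive weights.
#' @return An `effect_estimate` whose `estimate` is the log rate ratio.
#' @export
poisson_att <- function(Y, Z, w) {
  if (any(Y < 0)) stop("'Y' must be non-negative")
  if (all(Y == 0)) stop("'Y' is identically zero")
  w <- as.numeric(w)
  dat <- data.frame(y = Y, z = Z, w = w)
  fit <- stats::glm(y ~ z, family = stats::quasipoisson(), data = dat,
                    weights = w)
  vc <- sandwich::vcovHC(fit, type = "HC0")
  n_eff <- c(treated = sum(w[Z == 1])^2 / sum(w[Z == 1]^2),
             control = sum(w[Z == 0])^2 / sum(w[Z == 0]^2))
  structure(list(estimate = unname(stats::coef(fit)["z"]),
                 se = sqrt(vc["z", "z"]), estimand = "ATT (log ratio)",
                 n_effective = n_eff),
            class = "effect_estimate")
}

#' Common-support summary
#'
#' Numeric overlap diagnostics of the propensity distributions per arm
#' (min/max/quartiles), in place of the usual overlaid histograms so the
#' diagnostic is testable and scriptable.
#'
#' @param e Propensity scores.
#' @param Z Binary treatment vector.
#' @return Matrix of summary quantiles, rows = arms.
#' @export
common_support <- function(e, Z) {
  qs <- function(v) stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1),
                                    names = FALSE)
  out <- rbind(treated = qs(e[Z == 1]), control = qs(e[Z == 0]))
  colnames(out) <- c("min", "q25", "median", "q75", "max")
  out
}
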