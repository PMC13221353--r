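#' Missingness-pattern approaches for propensity score analysis
#'
#' Fits one of the seven missingness-pattern-aware treatment-effect
#' estimators (or plain PSA on complete data) end to end: pre-imputation or
#' pattern pooling, propensity-score estimation, inverse-probability
#' weighting, and the weighted effect estimate with linearized standard
#' error (Rubin-pooled across imputations for the MIMP methods).
#'
#' Method recipes (imputation / PS model / indicators in PS model /
#' pooling):
#' \describe{
#'   \item{`mp_lr`, `mp_rf`}{no imputation; pattern-pooled group-specific
#'     logistic or forest PS (mean-filled cells), no indicator columns.}
#'   \item{`mimp_lr`, `mimp_rf`}{chained-equations PMM multiple imputation;
#'     logistic or forest PS with missing indicators; Rubin's-rule pooling.}
#'   \item{`pi_i`, `pi_u`, `dfpi`}{proximity pre-imputation (supervised,
#'     unsupervised, dual-forest); logistic PS with missing indicators.}
#'   \item{`psa`}{no imputation (complete data assumed); logistic PS.}
#' }
#'
#' @param x Confounder matrix or data frame (`NA` marks missing cells), or a
#'   formula `z ~ x1 + x2 + ...` with `data`.
#' @param ... Passed on between methods.
#' @return An object of class `mpa`.
#' @export
mpa <- function(x, ...) UseMethod("mpa")

#' @rdname mpa
#' @param data Data frame holding the formula variables.
#' @param outcome Outcome vector, or (formula interface) the name of the
#'   outcome column in `data`.
#' @export
mpa.formula <- function(x, data, outcome, ...) {
  mf <- stats::model.frame(x, data = data, na.action = stats::na.pass)
  Z <- stats::model.response(mf)
  X <- mf[, -1, drop = FALSE]
  Y <- if (is.character(outcome)) data[[outcome]] else outcome
  if (is.null(Y)) stop("outcome column not found")
  res <- mpa.default(X, Z, Y, ...)
  res$call <- match.call()
  res
}

#' @rdname mpa
#' @param z Binary treatment vector.
#' @param y Numeric outcome vector.
#' @param method One of `"dfpi"`, `"pi_i"`, `"pi_u"`, `"mp_lr"`, `"mp_rf"`,
#'   `"mimp_lr"`, `"mimp_rf"`, `"psa"` (case/dash insensitive).
#' @param estimand `"ATE"` or `"ATT"`.
#' @param control An [impute_control()].
#' @param ps_indicators Override the recipe's default for including missing
#'   indicators in the PS model.
#' @param min_size Pattern-pooling threshold for the MP methods.
#' @param column_types Optional `"continuous"`/`"binary"` vector.
#' @export
mpa.default <- function(x, z, y, method = "dfpi",
                        estimand = c("ATE", "ATT"),
                        control = impute_control(), ps_indicators = NULL,
                        min_size = 100, column_types = NULL,
                        mp_restrict = c("mean_fill", "observed_columns"),
                        ...) {
  mp_restrict <- match.arg(mp_restrict)
  estimand <- match.arg(estimand)
  method <- normalize_method(method)
  recipe <- mpa_recipes()[[method]]
  X <- named_matrix(x)
  S <- as_indicator(X)
  if (anyNA(z) || anyNA(y)) stop("treatment and outcome must be complete")
  if (!all(z %in% c(0, 1))) stop("treatment must be binary 0/1")
  if (is.null(column_types)) column_types <- infer_column_types(X)
  indicators <- ps_indicators %||% recipe$indicators

  imputed <- NULL
  mi <- NULL
  e <- w <- eff <- NULL
  per_imputation <- NULL

  if (recipe$impute == "mice") {
    mi <- mice_pmm_impute(X, S, z, y, control, column_types)
    ests <- ses <- numeric(length(mi$imputations))
    e_list <- w_list <- vector("list", length(mi$imputations))
    for (i in seq_along(mi$imputations)) {
      ei <- estimate_propensity(mi$imputations[[i]], z, model = recipe$ps,
                                indicators = if (indicators) S else NULL,
                                n_trees = control$n_trees,
                                seed = control$seed,
                                num_threads = control$num_threads)
      wi <- ipw_weights(ei, z, estimand)
      effi <- weighted_effect(y, z, wi)
      ests[i] <- effi$estimate; ses[i] <- effi$se
      e_list[[i]] <- ei; w_list[[i]] <- wi
    }
    pooled <- rubin_pool(ests, ses)
    eff <- list(estimate = pooled$estimate, se = pooled$se)
    per_imputation <- list(estimates = ests, ses = ses, pooled = pooled)
    e <- e_list[[1]]; w <- w_list[[1]]
  } else if (recipe$impute == "mp") {
    e <- mp_propensity(X, S, z, model = recipe$ps, min_size = min_size,
                       restrict = mp_restrict,
                       n_trees = control$n_trees, seed = control$seed,
                       num_threads = control$num_threads)
    if (anyNA(e))
      stop("missingness-pattern propensity model failed in ",
           length(attr(e, "failed_groups")), " pooled group(s)")
    w <- ipw_weights(e, z, estimand)
    eff <- weighted_effect(y, z, w)
  } else {
    imputed <- switch(recipe$impute,
      none = {
        if (anyNA(X)) stop("method 'psa' requires complete confounders")
        completed_data(X, S, "none")
      },
      dfpi = dfpi_impute(X, S, z, y, control, column_types),
      pi_i = pi_i_impute(X, S, z, y, control, column_types),
      pi_u = pi_u_impute(X, S, control, column_types))
    e <- estimate_propensity(imputed$X_imputed, z, model = recipe$ps,
                             indicators = if (indicators) S else NULL,
                             n_trees = control$n_trees, seed = control$seed,
                             num_threads = control$num_threads)
    w <- ipw_weights(e, z, estimand)
    eff <- weighted_effect(y, z, w)
  }

  structure(list(estimate = eff$estimate, se = eff$se, method = method,
                 estimand = estimand, propensity = e, weights = w,
                 imputed = imputed, mi = mi,
                 per_imputation = per_imputation,
                 X_observed = X, S = S, Z = z, Y = y,
                 column_types = column_types, control = control,
                 call = match.call()),
            class = "mpa")
}

normalize_method <- function(method) {
  m <- gsub("-", "_", tolower(method))
  valid <- names(mpa_recipes())
  if (!m %in% valid)
    stop("unknown method '", method, "'; valid methods: ",
         paste(valid, collapse = ", "))
  m
}

#' Available method recipes
#'
#' @return Named list of recipes (imputation engine, PS model, indicator
#'   default) for the methods understood by [mpa()].
#' @export
mpa_recipes <- function() {
  list(
    mp_lr   = list(impute = "mp",   ps = "lr", indicators = FALSE),
    mp_rf   = list(impute = "mp",   ps = "rf", indicators = FALSE),
    mimp_lr = list(impute = "mice", ps = "lr", indicators = TRUE),
    mimp_rf = list(impute = "mice", ps = "rf", indicators = TRUE),
    pi_i    = list(impute = "pi_i", ps = "lr", indicators = TRUE),
    pi_u    = list(impute = "pi_u", ps = "lr", indicators = TRUE),
    dfpi    = list(impute = "dfpi", ps = "lr", indicators = TRUE),
    psa     = list(impute = "none", ps = "lr", indicators = FALSE)
  )
}

#' @export
print.mpa <- function(x, ...) {
  cat(sprintf("Missingness-pattern PSA fit: method %s, estimand %s\n",
              toupper(gsub("_", "-", x$method)), x$estimand))
  cat(sprintf("  %s = %.4f (SE %.4f)\n", x$estimand, x$estimate, x$se))
  invisible(x)
}

#' @export
coef.mpa <- function(object, ...) {
  stats::setNames(object$estimate, object$estimand)
}

#' @export
vcov.mpa <- function(object, ...) {
  matrix(object$se^2, 1, 1,
         dimnames = list(object$estimand, object$estimand))
}

#' @export
weights.mpa <- function(object, ...) object$weights

#' @export
confint.mpa <- function(object, parm, level = 0.95, ...) {
  a <- (1 - level) / 2
  q <- stats::qnorm(c(a, 1 - a))
  out <- matrix(object$estimate + q * object$se, 1, 2,
                dimnames = list(object$estimand,
                                sprintf("%.1f %%", 100 * c(a, 1 - a))))
  out
}

#' @export
summary.mpa <- function(object, balance_threshold = 0.05, ...) {
  sets <- if (!is.null(object$mi)) object$mi$imputations
          else list(object$imputed$X_imputed %||% object$X_observed)
  bal <- balance_table(sets[[1]], object$Z, object$weights,
                       threshold = balance_threshold,
                       imputation_sets = if (length(sets) > 1) sets else NULL)
  structure(list(fit = object, balance = bal,
                 support = common_support(object$propensity, object$Z),
                 z_value = object$estimate / object$se,
                 p_value = 2 * stats::pnorm(-abs(object$estimate / object$se))),
            class = "summary.mpa")
}

#' @export
print.summary.mpa <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  z = %.3f, p = %.4f\n", x$z_value, x$p_value))
  cat("\nCommon support (propensity quantiles):\n")
  print(round(x$support, 4))
  cat("\n")
  print(x$balance)
  invisible(x)
}

#' @export
plot.mpa <- function(x, breaks = 20, ...) {
  e <- as.numeric(x$propensity)
  h1 <- graphics::hist(e[x$Z == 1], breaks = breaks, plot = FALSE)
  h0 <- graphics::hist(e[x$Z == 0], breaks = breaks, plot = FALSE)
  ylim <- c(0, max(h1$density, h0$density))
  graphics::plot(h0, freq = FALSE, col = grDevices::adjustcolor("grey40", 0.5),
                 border = NA, xlim = range(e), ylim = ylim,
                 main = sprintf("Propensity overlap (%s)",
                                toupper(gsub("_", "-", x$method))),
                 xlab = "propensity score")
  graphics::plot(h1, freq = FALSE, col = grDevices::adjustcolor("firebrick", 0.5),
                 border = NA, add = TRUE)
  graphics::legend("topright", legend = c("control", "treated"),
                   fill = grDevices::adjustcolor(c("grey40", "firebrick"), 0.5),
                   bty = "n")
  invisible(x)
}
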