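#' Estimate propensity scores
#'
#' Logistic-regression or random-forest propensity scores on a complete
#' confounder matrix, optionally augmented with missing-indicator columns.
#' Random-forest scores are the out-of-bag treated-class proportions (in-bag
#' probabilities overfit) and are clipped away from 0/1; logistic scores are
#' returned unclipped unless requested. Perfect separation in the logistic
#' fit triggers a penalized (ridge) refit with a warning.
#'
#' @param X_complete Complete numeric confounder matrix.
#' @param Z Binary treatment vector.
#' @param model `"lr"` (maximum-likelihood logistic regression) or `"rf"`
#'   (classification forest).
#' @param indicators Optional missing-indicator matrix appended to the
#'   predictors; constant columns are dropped.
#' @param n_trees,mtry,seed,num_threads Forest settings (`model = "rf"`).
#' @param clip Two-sided clipping bounds for the scores. Default: `c(0.005,
#'   0.995)` for forests, none for logistic regression.
#' @return An object of class `propensity`: numeric score vector with
#'   attributes `model` and `n_clipped`.
#' @export
estimate_propensity <- function(X_complete, Z, model = c("lr", "rf"),
                                indicators = NULL, n_trees = 500,
                                mtry = NULL, clip = NULL, seed = NULL,
                                num_threads = 1) {
  model <- match.arg(model)
  X <- named_matrix(X_complete)
  if (anyNA(X)) stop("'X_complete' contains missing cells")
  if (length(unique(Z)) < 2) stop("constant treatment indicator")
  if (!is.null(indicators)) {
    Si <- as.matrix(indicators) + 0
    colnames(Si) <- paste0("s", seq_len(ncol(Si)))
    keep <- apply(Si, 2, function(col) length(unique(col)) > 1)
    X <- cbind(X, Si[, keep, drop = FALSE])
  }
  if (model == "lr") {
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, X), Z, family = stats::binomial()))
    e <- fit$fitted.values
    # extreme fitted values (quasi-separation) are kept as-is — they are the
    # maximum-likelihood scores and their instability is a property of the
    # method under study; only an outright IRLS failure triggers the
    # penalized rescue
    if (!fit$converged || anyNA(e)) {
      warning("logistic propensity model did not converge; ",
              "penalized (ridge) refit applied")
      rf <- glmnet::glmnet(X, Z, family = "binomial", alpha = 0,
                           lambda = 1e-3)
      e <- drop(stats::predict(rf, newx = X, type = "response"))
    }
    if (is.null(clip)) clip <- c(0, 1)
  } else {
    forest <- fit_supervised_forest(X, Z, task = "classification",
                                    n_trees = n_trees, mtry = mtry,
                                    seed = seed, num_threads = num_threads)
    prob <- oob_predictions(forest)
    e <- prob[, colnames(prob) == "1", drop = TRUE]
    if (anyNA(e)) e[is.na(e)] <- mean(Z)  # rows never out of bag
    if (is.null(clip)) clip <- c(0.005, 0.995)
  }
  n_clipped <- sum(e < clip[1] | e > clip[2])
  e <- pmin(pmax(e, clip[1]), clip[2])
  structure(e, class = "propensity", model = model, n_clipped = n_clipped)
}

#' @export
print.propensity <- function(x, ...) {
  cat(sprintf("Propensity scores (%s): n = %d, range [%.4f, %.4f], %d clipped\n",
              attr(x, "model"), length(x), min(x), max(x),
              attr(x, "n_clipped")))
  invisible(x)
}

#' Missingness-pattern propensity scores
#'
#' Stratified propensity estimation: the data are split into pooled
#' missingness-pattern groups; within each group a separate propensity model
#' is fit and scored. Missing cells are filled beforehand with the overall
#' observed column means (default) or, alternatively, each group's model is
#' restricted to the columns fully observed within its patterns.
#'
#' @param X_observed Confounder matrix with `NA` at missing cells.
#' @param S Optional missing-indicator matrix.
#' @param Z Binary treatment vector.
#' @param model `"lr"` or `"rf"`.
#' @param pooling Optional [pool_patterns()] result; computed from `S` with
#'   `min_size` when omitted.
#' @param min_size Pooling threshold (default 100).
#' @param restrict `"mean_fill"` (default) fits every group on all columns
#'   after mean-filling; `"observed_columns"` drops, per group, any column
#'   missing for any group member.
#' @param ... Passed to [estimate_propensity()] (forest settings, clipping).
#' @return A `propensity` vector; rows in groups whose model could not be
#'   fit (e.g. single-class treatment) are `NA` and the failed group ids are
#'   recorded in attribute `failed_groups`.
#' @export
mp_propensity <- function(X_observed, S = NULL, Z, model = c("lr", "rf"),
                          pooling = NULL, min_size = 100,
                          restrict = c("mean_fill", "observed_columns"),
                          ...) {
  model <- match.arg(model)
  restrict <- match.arg(restrict)
  X <- named_matrix(X_observed)
  S <- as_indicator(X, S)
  X[S == 1L] <- NA_real_
  if (is.null(pooling)) pooling <- pool_patterns(extract_patterns(S), min_size)
  # mean-fill from the overall observed column means
  fill <- colMeans(X, na.rm = TRUE)
  X_fill <- X
  for (j in seq_len(ncol(X))) X_fill[is.na(X_fill[, j]), j] <- fill[j]
  e <- rep(NA_real_, nrow(X))
  failed <- integer(0)
  for (g in seq_along(pooling$group_counts)) {
    rows <- which(pooling$row_group == g)
    if (length(unique(Z[rows])) < 2) {
      failed <- c(failed, g)
      next
    }
    Xg <- if (restrict == "mean_fill") {
      X_fill[rows, , drop = FALSE]
    } else {
      keep <- colSums(S[rows, , drop = FALSE]) == 0
      if (!any(keep)) {
        failed <- c(failed, g)
        next
      }
      X_fill[rows, keep, drop = FALSE]
    }
    eg <- tryCatch(estimate_propensity(Xg, Z[rows], model = model, ...),
                   error = function(err) NULL)
    if (is.null(eg)) {
      failed <- c(failed, g)
      next
    }
    e[rows] <- eg
  }
  if (length(failed) > 0)
    warning("propensity model failed in pooled group(s) ",
            paste(failed, collapse = ", "), "; affected rows scored NA")
  structure(e, class = "propensity", model = paste0("mp_", model),
            n_clipped = NA_integer_, failed_groups = failed)
}

#' Inverse-probability-of-treatment weights
#'
#' ATE weights `Z/e + (1-Z)/(1-e)`; ATT weights `Z + (1-Z) e/(1-e)` (treated
#' units have weight 1).
#'
#' @param e Propensity scores in (0, 1).
#' @param Z Binary treatment vector.
#' @param estimand `"ATE"` or `"ATT"`.
#' @return An `ipw_weights` vector with attribute `estimand`.
#' @export
ipw_weights <- function(e, Z, estimand = c("ATE", "ATT")) {
  estimand <- match.arg(estimand)
  e <- as.numeric(e)
  if (anyNA(e)) stop("propensity scores contain NA")
  if (any(e <= 0 | e >= 1))
    stop("propensity scores must lie strictly in (0, 1); clip first")
  w <- if (estimand == "ATE") Z / e + (1 - Z) / (1 - e)
       else Z + (1 - Z) * e / (1 - e)
  structure(w, class = "ipw_weights", estimand = estimand)
}

#' Truncate weights at percentiles
#'
#' Optional symmetric percentile truncation of extreme weights (off by
#' default in the simulation pipelines).
#'
#' @param w Weight vector.
#' @param percentile Upper percentile at which to cap (e.g. 0.99); the lower
#'   cap is `1 - percentile`.
#' @return The truncated weights.
#' @export
truncate_weights <- function(w, percentile = 0.99) {
  qs <- stats::quantile(w, c(1 - percentile, percentile), names = FALSE)
  structure(pmin(pmax(as.numeric(w), qs[1]), qs[2]),
            class = class(w), estimand = attr(w, "estimand"))
}
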