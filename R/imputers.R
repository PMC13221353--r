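#' Control parameters for the imputation engines
#'
#' @param n_trees Trees per random forest (default 500).
#' @param max_iter Maximum proximity-imputation iterations (default 10).
#' @param tol Convergence threshold on the relative change of the imputed
#'   continuous cells (default 1e-5); categorical cells must additionally
#'   stop changing.
#' @param m Number of multiply imputed datasets for MICE (default 10).
#' @param pmm_donors Candidate donors for predictive mean matching
#'   (default 5).
#' @param mice_iter Chained-equation sweeps per MICE chain (default 5).
#' @param mtry,min_node_size Forest hyperparameters (ranger defaults when
#'   `NULL`).
#' @param outcome_forest_includes_z Add the treatment indicator to the DFPI
#'   outcome forest's predictors (default `FALSE`: the outcome forest sees
#'   `[X | S]` only).
#' @param oob_proximity Use out-of-bag-only proximities (default `FALSE`:
#'   unconditional count over all trees).
#' @param seed Optional integer seed.
#' @param num_threads Threads for ranger.
#' @return A list of class `impute_control`.
#' @export
impute_control <- function(n_trees = 500, max_iter = 10, tol = 1e-5, m = 10,
                           pmm_donors = 5, mice_iter = 5, mtry = NULL,
                           min_node_size = NULL,
                           outcome_forest_includes_z = FALSE,
                           oob_proximity = FALSE, seed = NULL,
                           num_threads = 1) {
  if (tol <= 0) stop("'tol' must be positive")
  if (max_iter < 1) stop("'max_iter' must be >= 1")
  structure(list(n_trees = n_trees, max_iter = max_iter, tol = tol, m = m,
                 pmm_donors = pmm_donors, mice_iter = mice_iter, mtry = mtry,
                 min_node_size = min_node_size,
                 outcome_forest_includes_z = outcome_forest_includes_z,
                 oob_proximity = oob_proximity, seed = seed,
                 num_threads = num_threads),
            class = "impute_control")
}

#' Infer continuous/binary column types from observed values
#'
#' A column whose observed values are all 0/1 is treated as binary.
#' @param X Numeric matrix (may contain `NA`).
#' @return Character vector `"continuous"`/`"binary"` per column.
#' @export
infer_column_types <- function(X) {
  apply(X, 2, function(col) {
    obs <- col[!is.na(col)]
    if (length(obs) > 0 && all(obs %in% c(0, 1))) "binary" else "continuous"
  })
}

as_indicator <- function(X, S = NULL) {
  if (is.null(S)) S <- (is.na(X)) + 0L
  S <- as.matrix(S) + 0L
  dimnames(S) <- dimnames(X)
  S
}

# ensure stable column names before matrices become forest features
named_matrix <- function(X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  X
}

completed_data <- function(X, S, method, trace = numeric(0), iterations = 0L,
                           converged = TRUE) {
  structure(list(X_imputed = X, S = S, method = method, trace = trace,
                 iterations = iterations, converged = converged),
            class = "completed_data")
}

#' @export
print.completed_data <- function(x, ...) {
  cat(sprintf("Completed dataset (%s): %d x %d, %d cells imputed",
              x$method, nrow(x$X_imputed), ncol(x$X_imputed), sum(x$S)))
  if (x$iterations > 0)
    cat(sprintf(", %d iteration%s%s", x$iterations,
                if (x$iterations == 1) "" else "s",
                if (x$converged) " (converged)" else " (max_iter reached)"))
  cat("\n")
  invisible(x)
}

#' Strawman initialization
#'
#' Replaces each missing continuous cell with the column median of the
#' observed values and each missing categorical cell with the observed mode.
#' This provides the stable starting values required before any forest can
#' be fit.
#'
#' @param X_observed Numeric matrix with `NA` at missing cells.
#' @param S Optional missing-indicator matrix (1 = missing); derived from
#'   the `NA` pattern when omitted.
#' @param column_types Optional `"continuous"`/`"binary"` vector; inferred
#'   when omitted.
#' @return A `completed_data` object.
#' @export
strawman_initialize <- function(X_observed, S = NULL, column_types = NULL) {
  X <- named_matrix(X_observed)
  S <- as_indicator(X, S)
  X[S == 1L] <- NA_real_
  if (is.null(column_types)) column_types <- infer_column_types(X)
  for (j in seq_len(ncol(X))) {
    obs <- X[S[, j] == 0L, j]
    if (length(obs) == 0)
      stop("column ", colnames(X)[j] %||% j, " has no observed values")
    fill <- if (column_types[j] == "binary") {
      tab <- table(obs)
      as.numeric(names(tab)[which.max(tab)])
    } else stats::median(obs)
    X[S[, j] == 1L, j] <- fill
  }
  completed_data(X, S, "strawman")
}

#' Proximity-weighted imputation update
#'
#' One pass of the proximity-weighted donor rule: each originally missing
#' continuous cell becomes the proximity-weighted mean of all donors'
#' current values, with weights `w(i,i') = M(i,i') / sum_k M(i,k)`;
#' each missing categorical cell receives the category maximizing the
#' product of its observed marginal proportion and its proximity-weighted
#' support, ties resolved toward the lowest category. Observed cells are
#' never altered. Rows with all-zero proximity fall back to uniform weights
#' over donors observed in that column (logged as attribute
#' `zero_proximity_rows`).
#'
#' @param X_current Complete numeric matrix (current iterate).
#' @param S Missing-indicator matrix (1 = originally missing).
#' @param M Proximity matrix with zero diagonal.
#' @param column_types Optional per-column types; inferred from `X_current`
#'   outside the missing cells when omitted.
#' @return A `completed_data` with the updated matrix.
#' @export
proximity_weighted_update <- function(X_current, S, M, column_types = NULL) {
  X <- as.matrix(X_current)
  S <- as_indicator(X, S)
  if (anyNA(X)) stop("'X_current' must be complete (use strawman first)")
  if (any(diag(M) != 0)) stop("'M' must have a zeroed diagonal")
  n <- nrow(X)
  if (is.null(column_types)) {
    masked <- X
    masked[S == 1L] <- NA_real_
    column_types <- infer_column_types(masked)
  }
  rs <- rowSums(M)
  zero_rows <- which(rs == 0 & rowSums(S) > 0)
  binary <- column_types == "binary"
  # observed marginal category-1 proportion per binary column
  p1 <- vapply(seq_len(ncol(X)), function(j) {
    if (!binary[j]) return(0)
    mean(X[S[, j] == 0L, j] == 1)
  }, numeric(1))
  Sint <- S; storage.mode(Sint) <- "integer"
  out <- .prox_update_cpp(M, X, Sint, binary, p1)
  dimnames(out) <- dimnames(X)
  # fallback: uniform weights over donors observed in the column
  for (i in zero_rows) {
    for (j in which(S[i, ] == 1L)) {
      donors <- which(S[, j] == 0L)
      donors <- setdiff(donors, i)
      vals <- X[donors, j]
      out[i, j] <- if (column_types[j] == "binary") {
        tab <- table(vals)
        as.numeric(names(tab)[which.max(tab)])
      } else mean(vals)
    }
  }
  res <- completed_data(out, S, "proximity_update")
  attr(res, "zero_proximity_rows") <- zero_rows
  res
}

# relative-change convergence metric over originally missing cells:
# continuous cells by relative absolute change, categorical by change count
relative_change <- function(X_new, X_old, S, column_types) {
  cont <- column_types == "continuous"
  miss_cont <- S == 1L & matrix(cont, nrow(S), ncol(S), byrow = TRUE)
  miss_cat <- S == 1L & !miss_cont
  num <- sum(abs(X_new[miss_cont] - X_old[miss_cont]))
  den <- sum(abs(X_new[miss_cont]))
  rel <- if (den > 0) num / den else 0
  list(rel = rel, cat_changes = sum(X_new[miss_cat] != X_old[miss_cat]))
}

# shared iteration engine for DFPI / PI-I / PI-U: `proximity_fn(X_iter)`
# returns the zero-diagonal proximity matrix for the current iterate
iterate_proximity_imputation <- function(X_observed, S, column_types, control,
                                         proximity_fn, method) {
  init <- strawman_initialize(X_observed, S, column_types)
  X_iter <- init$X_imputed
  S <- init$S
  if (sum(S) == 0)
    return(completed_data(X_iter, S, method, iterations = 0L))
  trace <- numeric(0)
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(control$max_iter)) {
    M <- proximity_fn(X_iter, it)
    upd <- proximity_weighted_update(X_iter, S, M, column_types)
    chg <- relative_change(upd$X_imputed, X_iter, S, column_types)
    trace <- c(trace, chg$rel)
    X_iter <- upd$X_imputed
    iterations <- it
    if (chg$rel < control$tol && chg$cat_changes == 0L) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning(method, ": maximum iterations reached without convergence ",
            sprintf("(last relative change %.2e)", trace[length(trace)]))
  completed_data(X_iter, S, method, trace = trace, iterations = iterations,
                 converged = converged)
}

forest_seed <- function(control, it, offset) {
  if (is.null(control$seed)) NULL else control$seed + 1000L * it + offset
}


# zero-diagonal single-forest proximity, honoring the OOB-only option
single_proximity <- function(model, feats, control) {
  if (control$oob_proximity) {
    M <- unclass(proximity_from_leaves(model, feats, oob_only = TRUE))
    diag(M) <- 0
    M
  } else {
    proximity_from_nodes(leaf_matrix(model, feats), source = model$source,
                         zero_diagonal = TRUE)
  }
}

#' Dual-forest proximity imputation (DFPI)
#'
#' Iterative pre-imputation for propensity score analysis with MNAR
#' confounders. At each iteration the current complete matrix is augmented
#' with the missing indicators, `X* = [X | S]`; a classification forest
#' predicting treatment and a regression forest predicting the outcome are
#' fit on `X*`; their co-leaf proximity matrices are averaged into the
#' confounder-signified proximity matrix (diagonal zeroed); and every
#' originally missing cell is refreshed by the proximity-weighted donor
#' rule. Iteration stops when the relative change of the imputed cells falls
#' below `control$tol` (categorical cells unchanged) or at
#' `control$max_iter`.
#'
#' @param X_observed Confounder matrix with `NA` at missing cells.
#' @param S Optional missing-indicator matrix (1 = missing).
#' @param Z Binary treatment vector (no missing values).
#' @param Y Numeric outcome vector (no missing values).
#' @param control An [impute_control()].
#' @param column_types Optional per-column types.
#' @return A `completed_data` with the final imputed matrix, the per-
#'   iteration relative-change trace and convergence status.
#' @export
dfpi_impute <- function(X_observed, S = NULL, Z, Y,
                        control = impute_control(), column_types = NULL) {
  X <- named_matrix(X_observed)
  S <- as_indicator(X, S)
  if (anyNA(Z) || anyNA(Y)) stop("Z and Y must be fully observed")
  if (length(unique(Z)) < 2) stop("constant treatment indicator")
  if (is.null(column_types)) column_types <- infer_column_types(X)
  Sdf <- S
  colnames(Sdf) <- paste0("s", seq_len(ncol(S)))
  proximity_fn <- function(X_iter, it) {
    feats <- cbind(X_iter, Sdf)
    f_t <- fit_supervised_forest(feats, Z, task = "classification",
                                 n_trees = control$n_trees,
                                 mtry = control$mtry,
                                 min_node_size = control$min_node_size,
                                 seed = forest_seed(control, it, 1L),
                                 num_threads = control$num_threads,
                                 keep_inbag = control$oob_proximity)
    feats_y <- if (control$outcome_forest_includes_z) cbind(feats, z = Z)
               else feats
    f_y <- fit_supervised_forest(feats_y, Y, task = "regression",
                                 n_trees = control$n_trees,
                                 mtry = control$mtry,
                                 min_node_size = control$min_node_size,
                                 seed = forest_seed(control, it, 2L),
                                 num_threads = control$num_threads,
                                 keep_inbag = control$oob_proximity)
    if (control$oob_proximity) {
      combine_proximities(proximity_from_leaves(f_t, feats, oob_only = TRUE),
                          proximity_from_leaves(f_y, feats_y,
                                                oob_only = TRUE))
    } else {
      dual_proximity(leaf_matrix(f_t, feats), leaf_matrix(f_y, feats_y))
    }
  }
  iterate_proximity_imputation(X, S, column_types, control, proximity_fn,
                               "dfpi")
}

#' Proximity imputation with missing indicators, supervised (PI-I)
#'
#' A single supervised regression forest predicts the outcome from
#' `[X | S | Z]`; its proximity matrix (diagonal zeroed) drives the same
#' iterative proximity-weighted update as DFPI.
#'
#' @inheritParams dfpi_impute
#' @return A `completed_data`.
#' @export
pi_i_impute <- function(X_observed, S = NULL, Z, Y,
                        control = impute_control(), column_types = NULL) {
  X <- named_matrix(X_observed)
  S <- as_indicator(X, S)
  if (anyNA(Z) || anyNA(Y)) stop("Z and Y must be fully observed")
  if (is.null(column_types)) column_types <- infer_column_types(X)
  Sdf <- S
  colnames(Sdf) <- paste0("s", seq_len(ncol(S)))
  proximity_fn <- function(X_iter, it) {
    feats <- cbind(X_iter, Sdf, z = Z)
    f <- fit_supervised_forest(feats, Y, task = "regression",
                               n_trees = control$n_trees, mtry = control$mtry,
                               min_node_size = control$min_node_size,
                               seed = forest_seed(control, it, 3L),
                               num_threads = control$num_threads,
                               keep_inbag = control$oob_proximity)
    single_proximity(f, feats, control)
  }
  iterate_proximity_imputation(X, S, column_types, control, proximity_fn,
                               "pi_i")
}

#' Proximity imputation with missing indicators, unsupervised (PI-U)
#'
#' An unsupervised (synthetic-class) forest on `[X | S]` supplies the
#' proximity matrix; neither treatment nor outcome is used. The iterative
#' update contract matches DFPI.
#'
#' @inheritParams dfpi_impute
#' @return A `completed_data`.
#' @export
pi_u_impute <- function(X_observed, S = NULL, control = impute_control(),
                        column_types = NULL) {
  X <- named_matrix(X_observed)
  S <- as_indicator(X, S)
  if (is.null(column_types)) column_types <- infer_column_types(X)
  Sdf <- S
  colnames(Sdf) <- paste0("s", seq_len(ncol(S)))
  proximity_fn <- function(X_iter, it) {
    feats <- cbind(X_iter, Sdf)
    f <- fit_unsupervised_forest(feats, n_trees = control$n_trees,
                                 mtry = control$mtry,
                                 min_node_size = control$min_node_size,
                                 seed = forest_seed(control, it, 4L),
                                 num_threads = control$num_threads,
                                 keep_inbag = control$oob_proximity)
    single_proximity(f, NULL, control)
  }
  iterate_proximity_imputation(X, S, column_types, control, proximity_fn,
                               "pi_u")
}

#' Multiple imputation by chained equations with predictive mean matching
#'
#' Chained-equations multiple imputation: each incomplete confounder is
#' imputed in turn by predictive mean matching (PMM). The univariate model
#' for column j conditions on all other confounders, the treatment indicator
#' and the outcome; regression coefficients are drawn from their Bayesian
#' posterior (normal-inverse-chi-squared), predictions for missing rows are
#' matched to the `pmm_donors` closest observed-row predictions, and one
#' donor's observed value is sampled. Donor matching makes every imputed
#' value an observed value of its column, so binary columns stay binary.
#' `m` independent chains are run; observed cells are identical across all
#' copies. A near-singular design triggers a logged ridge fallback.
#'
#' @inheritParams dfpi_impute
#' @return An object of class `mi_set`: list with `imputations` (list of
#'   `m` complete matrices), `S` and `method`.
#' @export
mice_pmm_impute <- function(X_observed, S = NULL, Z, Y,
                            control = impute_control(),
                            column_types = NULL) {
  X <- named_matrix(X_observed)
  S <- as_indicator(X, S)
  if (control$m < 2) stop("multiple imputation requires m >= 2")
  if (anyNA(Z) || anyNA(Y)) stop("Z and Y must be fully observed")
  if (!is.null(control$seed)) set.seed(control$seed)
  n <- nrow(X); p <- ncol(X)
  incomplete <- which(colSums(S) > 0)
  imputations <- vector("list", control$m)
  for (chain in seq_len(control$m)) {
    Xc <- X
    # random hot-deck start: sample observed values of the same column
    for (j in incomplete) {
      obs <- X[S[, j] == 0L, j]
      nm <- sum(S[, j])
      Xc[S[, j] == 1L, j] <- sample(obs, nm, replace = TRUE)
    }
    if (length(incomplete) > 0) {
      for (sweep in seq_len(control$mice_iter)) {
        for (j in incomplete) {
          D <- cbind(1, Xc[, -j, drop = FALSE], z = Z, y = Y)
          Xc[S[, j] == 1L, j] <- pmm_draw(
            y_obs = X[S[, j] == 0L, j],
            D_obs = D[S[, j] == 0L, , drop = FALSE],
            D_mis = D[S[, j] == 1L, , drop = FALSE],
            donors = control$pmm_donors)
        }
      }
    }
    imputations[[chain]] <- Xc
  }
  structure(list(imputations = imputations, S = S, method = "mice_pmm"),
            class = "mi_set")
}

#' @export
print.mi_set <- function(x, ...) {
  cat(sprintf("Multiple-imputation set (%s): m = %d copies, %d x %d, %d cells imputed\n",
              x$method, length(x$imputations), nrow(x$S), ncol(x$S),
              sum(x$S)))
  invisible(x)
}

# One PMM univariate draw (type-1 matching): posterior-draw predictions for
# missing rows matched against least-squares predictions for observed rows.
pmm_draw <- function(y_obs, D_obs, D_mis, donors = 5) {
  q <- ncol(D_obs)
  n_obs <- length(y_obs)
  xtx <- crossprod(D_obs)
  ridge <- 1e-5 * mean(diag(xtx))
  inv <- tryCatch(solve(xtx), error = function(e) NULL)
  if (is.null(inv) || !all(is.finite(inv))) {
    inv <- solve(xtx + diag(ridge, q))
    message("pmm: near-singular design, ridge fallback applied")
  }
  beta_hat <- inv %*% crossprod(D_obs, y_obs)
  resid <- y_obs - drop(D_obs %*% beta_hat)
  df <- max(n_obs - q, 1)
  sigma2 <- sum(resid^2) / stats::rchisq(1, df)
  cholv <- tryCatch(chol(inv), error = function(e) chol(inv + diag(ridge, q)))
  beta_star <- beta_hat + sqrt(sigma2) * t(cholv) %*% stats::rnorm(q)
  yhat_obs <- drop(D_obs %*% beta_hat)
  yhat_mis <- drop(D_mis %*% beta_star)
  k <- min(donors, n_obs)
  vapply(yhat_mis, function(v) {
    idx <- order(abs(yhat_obs - v))[seq_len(k)]
    y_obs[sample(idx, 1L)]
  }, numeric(1))
}
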