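#' Summarize replication-level estimates into the study metrics
#'
#' Relative bias of the effect, relative bias of the standard error against
#' the empirical standard deviation, and mean squared error:
#' `RB = mean((d_r - delta) / delta)`,
#' `RB_SE = mean((SE_r - SD(d)) / SD(d))` with `SD(d)` the empirical SD of
#' the estimates across replications, `MSE = mean((d_r - delta)^2)`.
#'
#' @param estimates Per-replication effect estimates.
#' @param ses Matching per-replication standard errors.
#' @param delta True effect (non-zero).
#' @return List with `RB`, `RB_SE` (`NA` when fewer than two replications),
#'   `MSE`, `mean_est`, `emp_sd`, `mean_se`, `R`.
#' @export
summarize_metrics <- function(estimates, ses, delta) {
  if (delta == 0) stop("relative bias is undefined for delta = 0")
  keep <- is.finite(estimates) & is.finite(ses)
  estimates <- estimates[keep]; ses <- ses[keep]
  R <- length(estimates)
  if (R == 0) stop("no successful replications")
  emp_sd <- if (R >= 2) stats::sd(estimates) else NA_real_
  list(RB = mean((estimates - delta) / delta),
       RB_SE = if (R >= 2 && isTRUE(emp_sd > 0))
         mean((ses - emp_sd) / emp_sd) else NA_real_,
       MSE = mean((estimates - delta)^2),
       mean_est = mean(estimates), emp_sd = emp_sd, mean_se = mean(ses),
       R = R)
}

#' Run one Monte Carlo condition
#'
#' For each replication: redraw and calibrate the population coefficients
#' (unless `fix_coefficients`), generate a dataset, impose the configured
#' missingness, and run each requested method's impute / propensity / weight
#' / estimate chain. Failed replications (e.g. a pooled pattern group
#' containing a single treatment class) are counted per method and excluded
#' from the summaries.
#'
#' @param config A [sim_config()] describing the condition.
#' @param methods Character vector of [mpa()] methods.
#' @param R Number of replications.
#' @param seed Master seed; per-replication seeds derive from it.
#' @param control An [impute_control()] shared by all methods.
#' @param estimand `"ATE"` (default) or `"ATT"`.
#' @param fix_coefficients Calibrate the population coefficients once and
#'   reuse them in every replication (default `FALSE`: redrawn each
#'   replication).
#' @param min_size Pattern-pooling threshold for MP methods.
#' @return An object of class `condition_summary`: a data frame with one row
#'   per method (RB, RB_SE, MSE, empirical SD, mean SE, replications used,
#'   failures) carrying the per-replication estimates as attributes.
#' @export
run_condition <- function(config, methods = c("dfpi"), R = 100,
                          seed = 1, control = impute_control(),
                          estimand = "ATE", fix_coefficients = FALSE,
                          min_size = 100,
                          mp_restrict = c("mean_fill", "observed_columns")) {
  mp_restrict <- match.arg(mp_restrict)
  methods <- vapply(methods, normalize_method, character(1))
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, R)
  params0 <- if (fix_coefficients) calibrate_coefficients(config) else NULL
  est <- se <- matrix(NA_real_, R, length(methods),
                      dimnames = list(NULL, methods))
  failures <- stats::setNames(integer(length(methods)), methods)
  messages <- character(0)
  for (r in seq_len(R)) {
    set.seed(rep_seeds[r])
    params <- params0 %||% calibrate_coefficients(config)
    dataset <- impose_missingness(generate_dataset(config, params))
    for (m in methods) {
      x_in <- if (m == "psa") dataset$X_complete else dataset$X_observed
      fit <- tryCatch(
        suppressWarnings(mpa.default(x_in, dataset$Z, dataset$Y, method = m,
                                     estimand = estimand, control = control,
                                     min_size = min_size,
                                     mp_restrict = mp_restrict)),
        error = function(err) err)
      if (inherits(fit, "error")) {
        failures[m] <- failures[m] + 1L
        messages <- c(messages, sprintf("rep %d, %s: %s", r, m,
                                        conditionMessage(fit)))
      } else {
        est[r, m] <- fit$estimate
        se[r, m] <- fit$se
      }
    }
  }
  rows <- lapply(methods, function(m) {
    s <- summarize_metrics(est[, m], se[, m], config$delta)
    data.frame(method = m, R_used = s$R, failures = failures[m],
               mean_est = s$mean_est, emp_sd = s$emp_sd,
               mean_se = s$mean_se, RB = s$RB, RB_SE = s$RB_SE,
               MSE = s$MSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("condition_summary", "data.frame"),
            config = config, seed = seed, estimates = est, ses = se,
            failure_messages = messages)
}

#' @export
print.condition_summary <- function(x, digits = 4, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Condition: n = %d, p = %d, %s at %g%% missing, delta = %g\n",
              cfg$n, cfg$p, cfg$mechanism, 100 * cfg$missing_rate,
              cfg$delta))
  print.data.frame(x, digits = digits, ...)
  invisible(x)
}

#' Factorial effect sizes over simulation design cells
#'
#' Fixed-effects factorial ANOVA on cell-level summaries of a fully crossed
#' simulation design. For every modeled effect the generalized eta-squared
#' is `SS_effect / SS_total` (where the total includes the residual) and the
#' proportion of effect variance is `SS_effect / sum(SS_modeled)`,
#' excluding the residual. This cell-mean decomposition approximates the
#' replication-level mixed design: the residual term here is the
#' highest-order cell variation not captured by the modeled effects, so the
#' eta-squared values are approximate by construction.
#'
#' @param cells Data frame of cell-level outcomes (one row per design cell).
#' @param response Name of the outcome column.
#' @param factors Character vector of factor columns; the design must be
#'   fully crossed in them.
#' @param interactions Optional character vector of interaction terms (e.g.
#'   `"rate:method"`) added to the main effects.
#' @return An object of class `effect_size_table`: data frame with the sum
#'   of squares, generalized eta-squared and PEV per modeled effect.
#' @export
anova_effect_sizes <- function(cells, response, factors,
                               interactions = NULL) {
  cells <- as.data.frame(cells)
  missing_cols <- setdiff(c(response, factors), names(cells))
  if (length(missing_cols) > 0)
    stop("columns not found: ", paste(missing_cols, collapse = ", "))
  for (f in factors) cells[[f]] <- factor(cells[[f]])
  grid <- table(cells[factors])
  if (any(grid == 0)) {
    empty <- which(grid == 0, arr.ind = TRUE)
    lab <- apply(empty, 1, function(idx)
      paste(mapply(function(f, i) paste0(f, "=", dimnames(grid)[[f]][i]),
                   factors, idx), collapse = ", "))
    stop("design is not fully crossed; empty cells: ",
         paste(utils::head(lab, 5), collapse = "; "))
  }
  if (length(unique(as.vector(grid))) > 1)
    stop("design is unbalanced across cells")
  terms <- c(factors, interactions)
  fml <- stats::as.formula(paste(response, "~", paste(terms, collapse = " + ")))
  fit <- stats::aov(fml, data = cells)
  ss <- summary(fit)[[1]][["Sum Sq"]]
  labels <- trimws(rownames(summary(fit)[[1]]))
  resid_idx <- labels == "Residuals"
  ss_resid <- if (any(resid_idx)) ss[resid_idx] else 0
  ss_model <- ss[!resid_idx]
  labels <- labels[!resid_idx]
  total <- sum(ss_model) + ss_resid
  if (sum(ss_model) == 0) {
    warning("outcome constant across cells: effect sizes undefined")
    pev <- rep(NA_real_, length(ss_model))
  } else {
    pev <- ss_model / sum(ss_model)
  }
  out <- data.frame(effect = labels, sum_sq = ss_model,
                    eta2G = if (total > 0) ss_model / total else NA_real_,
                    PEV = pev, row.names = NULL)
  structure(out, class = c("effect_size_table", "data.frame"),
            ss_residual = ss_resid)
}

#' @export
print.effect_size_table <- function(x, digits = 4, ...) {
  cat("Factorial effect sizes (cell-level approximation)\n")
  print.data.frame(x, digits = digits, ...)
  invisible(x)
}

#' Run a crossed set of conditions
#'
#' Convenience driver looping [run_condition()] over mechanisms, missing
#' rates, sample sizes and confounder counts, returning a long-format table
#' of metrics per condition and method.
#'
#' @param base_config A [sim_config()] template (its `n`, `p`, `mechanism`,
#'   `missing_rate` are overridden per condition).
#' @param mechanisms,rates,ns,ps Vectors of levels to cross.
#' @param methods,R,seed,control,estimand,min_size As in [run_condition()].
#' @return Data frame with one row per condition x method, carrying the
#'   metric columns of `condition_summary`.
#' @export
run_study <- function(base_config, mechanisms = base_config$mechanism,
                      rates = base_config$missing_rate, ns = base_config$n,
                      ps = base_config$p, methods = "dfpi", R = 100,
                      seed = 1, control = impute_control(),
                      estimand = "ATE", min_size = 100) {
  grid <- expand.grid(mechanism = mechanisms, rate = rates, n = ns, p = ps,
                      stringsAsFactors = FALSE)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- sim_config(n = grid$n[i], p = grid$p[i], delta = base_config$delta,
                      prop_treated = base_config$prop_treated,
                      pseudo_r2 = base_config$pseudo_r2, r2 = base_config$r2,
                      missing_rate = grid$rate[i],
                      mechanism = grid$mechanism[i], corr = base_config$corr,
                      rho = base_config$rho,
                      corr_matrix = base_config$corr_matrix,
                      calib_n = base_config$calib_n)
    cs <- run_condition(cfg, methods = methods, R = R, seed = seed + i,
                        control = control, estimand = estimand,
                        min_size = min_size)
    out[[i]] <- cbind(grid[rep(i, nrow(cs)), , drop = FALSE],
                      as.data.frame(cs), row.names = NULL)
  }
  do.call(rbind, out)
}
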