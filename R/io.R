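#' Read an observational dataset from CSV
#'
#' Expects one column per confounder plus a binary treatment column and a
#' numeric outcome column; empty fields are parsed as missing. Column types
#' (continuous/binary) are inferred from the observed values unless
#' declared.
#'
#' @param path CSV file path.
#' @param covariates Optional character vector naming the confounder
#'   columns; by default every column other than `treatment` and `outcome`.
#' @param treatment,outcome Column names (defaults `"z"`, `"y"`).
#' @param column_types Optional declared types per covariate
#'   (`"continuous"`/`"binary"`).
#' @return List with `X_observed`, `S` (1 = missing), `Z`, `Y`,
#'   `column_types`.
#' @export
load_dataset <- function(path, covariates = NULL, treatment = "z",
                         outcome = "y", column_types = NULL) {
  df <- utils::read.csv(path, na.strings = c("", "NA"))
  if (!treatment %in% names(df))
    stop("treatment column '", treatment, "' not found")
  if (!outcome %in% names(df))
    stop("outcome column '", outcome, "' not found")
  covariates <- covariates %||% setdiff(names(df), c(treatment, outcome))
  Z <- df[[treatment]]
  if (anyNA(Z) || !all(Z %in% c(0, 1)))
    stop("treatment column must be binary 0/1 with no missing values")
  Y <- df[[outcome]]
  if (anyNA(Y)) stop("outcome column must have no missing values")
  X <- as.matrix(df[covariates])
  if (!is.numeric(X)) stop("covariate columns must be numeric")
  if (is.null(column_types)) {
    column_types <- infer_column_types(X)
  } else {
    column_types <- rep_len(column_types, ncol(X))
    for (j in which(column_types == "binary")) {
      bad <- which(!is.na(X[, j]) & !X[, j] %in% c(0, 1))
      if (length(bad) > 0)
        stop(sprintf("column '%s' declared binary but row %d holds %g",
                     covariates[j], bad[1], X[bad[1], j]))
    }
  }
  list(X_observed = X, S = as_indicator(X), Z = as.numeric(Z),
       Y = as.numeric(Y), column_types = column_types)
}

#' Write an observational dataset to CSV
#'
#' Inverse of [load_dataset()]: missing cells become empty fields, so a
#' write/read round trip is lossless up to floating-point formatting.
#'
#' @param dataset List with `X_observed` (or `X_complete`), `Z`, `Y`.
#' @param path Output CSV path.
#' @param complete Write the complete (pre-missingness) covariates instead.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, complete = FALSE) {
  X <- if (complete) dataset$X_complete else dataset$X_observed
  if (is.null(X)) stop("dataset holds no covariate table of that kind")
  df <- as.data.frame(X)
  df$z <- dataset$Z
  df$y <- dataset$Y
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Run manifest
#'
#' Records everything needed to replay a run: package version, master seed,
#' per-stage seeds, calibration constants and warnings.
#'
#' @param seed Master seed.
#' @param config Optional [sim_config()] echoed into the manifest.
#' @param achieved Optional calibration values.
#' @param stages Optional named list of per-stage seeds.
#' @param warnings Character vector of warnings encountered.
#' @return List of class `run_manifest`.
#' @export
run_manifest <- function(seed, config = NULL, achieved = NULL,
                         stages = list(), warnings = character(0)) {
  cfg <- NULL
  if (!is.null(config)) {
    cfg <- unclass(config)
    cfg$corr_matrix <- NULL
  }
  structure(list(tool = "dfpi",
                 version = as.character(utils::packageVersion("dfpi")),
                 timestamp = format(Sys.time(), tz = "UTC"),
                 seed = seed, stage_seeds = stages, config = cfg,
                 achieved = achieved, warnings = warnings),
            class = "run_manifest")
}

#' Write a manifest as JSON
#' @param manifest A [run_manifest()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Run a declarative configuration file
#'
#' Executes a YAML configuration describing either a `simulate` run (keys:
#' `n`, `p`, `rate`, `mechanism`, `reps`, `seed`, `out`) or a `study` run
#' (additionally `mechanisms`, `rates`, `methods`, `trees`). Outputs are
#' CSV files plus a JSON manifest sufficient to replay the run.
#'
#' @param config_path Path to the YAML configuration.
#' @return The [run_manifest()] of the run, invisibly.
#' @export
run_from_config <- function(config_path) {
  cfg <- yaml::read_yaml(config_path)
  command <- cfg$command %||% stop("config must name a 'command'")
  if (!command %in% c("simulate", "study"))
    stop("unknown command '", command, "'; valid commands: simulate, study")
  seed <- as.integer(cfg$seed %||% 1L)
  out_dir <- cfg$out %||% paste0(command, "_out")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  base <- sim_config(n = cfg$n %||% 500, p = cfg$p %||% 10,
                     missing_rate = cfg$rate %||% 0.3,
                     mechanism = cfg$mechanism %||% "MAR")
  if (command == "simulate") {
    reps <- as.integer(cfg$reps %||% 1L)
    set.seed(seed)
    rep_seeds <- sample.int(.Machine$integer.max - 1L, reps)
    achieved <- NULL
    for (r in seq_len(reps)) {
      d <- simulate_mnar_dataset(base, seed = rep_seeds[r])
      write_dataset(d, file.path(out_dir, sprintf("rep_%03d.csv", r)))
      write_dataset(d, file.path(out_dir,
                                 sprintf("rep_%03d_complete.csv", r)),
                    complete = TRUE)
      achieved <- d$params$achieved
    }
    man <- run_manifest(seed, config = base, achieved = achieved,
                        stages = list(replication = rep_seeds))
  } else {
    tab <- run_study(base,
                     mechanisms = cfg$mechanisms %||% base$mechanism,
                     rates = cfg$rates %||% base$missing_rate,
                     methods = cfg$methods %||% "dfpi",
                     R = as.integer(cfg$reps %||% 50L), seed = seed,
                     control = impute_control(
                       n_trees = as.integer(cfg$trees %||% 500L)))
    utils::write.csv(tab, file.path(out_dir, "study_results.csv"),
                     row.names = FALSE)
    man <- run_manifest(seed, config = base)
  }
  write_manifest(man, file.path(out_dir, "manifest.json"))
  invisible(man)
}
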