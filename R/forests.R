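#' Fit a supervised random forest with retrievable terminal nodes
#'
#' Thin adapter over \pkg{ranger} exposing, for any input row, its terminal
#' node id in every tree (the basis of proximity computation) and the
#' out-of-bag predictions. Splitting uses Gini impurity for classification
#' and variance reduction for regression; `mtry` defaults to
#' `floor(sqrt(q))` for `q` predictors.
#'
#' @param features Complete numeric matrix or data frame (no missing cells).
#' @param response Response vector (`task = "classification"` coerces it to a
#'   factor).
#' @param task `"classification"` or `"regression"`.
#' @param n_trees Number of trees.
#' @param mtry Features tried per split; default `floor(sqrt(ncol(features)))`.
#' @param min_node_size Minimal node size (ranger defaults: 1 classification,
#'   5 regression).
#' @param seed Integer seed for the forest.
#' @param num_threads Threads used by ranger (default 1, deterministic and
#'   suited to single-CPU batch runs).
#' @param keep_inbag Keep per-tree in-bag counts (needed only for the
#'   out-of-bag proximity variant).
#' @return An object of class `forest_model`.
#' @export
fit_supervised_forest <- function(features, response,
                                  task = c("classification", "regression"),
                                  n_trees = 500, mtry = NULL,
                                  min_node_size = NULL, seed = NULL,
                                  num_threads = 1, keep_inbag = FALSE) {
  task <- match.arg(task)
  features <- feature_matrix(features)
  if (ncol(features) == 0) stop("'features' has no columns")
  if (anyNA(features))
    stop("'features' contains missing cells; complete them before fitting")
  if (length(unique(response)) < 2)
    stop("constant response: forest cannot be fit")
  if (n_trees < 1) stop("'n_trees' must be >= 1")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(features))))
  y <- if (task == "classification") factor(response) else as.numeric(response)
  fit <- ranger::ranger(x = features, y = y,
                        num.trees = n_trees, mtry = mtry,
                        min.node.size = min_node_size,
                        probability = task == "classification",
                        keep.inbag = keep_inbag,
                        seed = seed, num.threads = num_threads)
  structure(list(fit = fit, task = task, n_trees = as.integer(n_trees),
                 mtry = as.integer(mtry), feature_names = colnames(features),
                 num_threads = num_threads, source = "supervised"),
            class = "forest_model")
}

#' Fit an unsupervised random forest (synthetic-class construction)
#'
#' Implements Breiman's unsupervised-forest device: a shadow dataset of the
#' same size is formed by independently permuting each column (destroying the
#' joint dependence while keeping the marginals) and a classification forest
#' is trained to separate real from shadow rows. Terminal-node assignments
#' are reported for the real rows only, so proximities reflect the latent
#' joint structure of the features.
#'
#' @inheritParams fit_supervised_forest
#' @return A `forest_model` whose proximity queries refer to the real rows.
#' @export
fit_unsupervised_forest <- function(features, n_trees = 500, mtry = NULL,
                                    min_node_size = NULL, seed = NULL,
                                    num_threads = 1, keep_inbag = FALSE) {
  features <- feature_matrix(features)
  if (ncol(features) == 0) stop("'features' has no columns")
  if (anyNA(features)) stop("'features' contains missing cells")
  if (!is.null(seed)) set.seed(seed)
  shadow <- apply(features, 2, function(col) col[sample.int(length(col))])
  both <- rbind(features, shadow)
  y <- factor(rep(c("real", "shadow"), each = nrow(features)))
  model <- fit_supervised_forest(both, y, task = "classification",
                                 n_trees = n_trees, mtry = mtry,
                                 min_node_size = min_node_size, seed = seed,
                                 num_threads = num_threads,
                                 keep_inbag = keep_inbag)
  model$source <- "unsupervised"
  model$real_features <- features
  model
}

#' @export
print.forest_model <- function(x, ...) {
  cat(sprintf("%s forest (%s): %d trees, mtry %d\n",
              x$source, x$task, x$n_trees, x$mtry))
  invisible(x)
}

#' Terminal-node assignments
#'
#' @param model A `forest_model`.
#' @param features Rows to drop down the trees (defaults to the real training
#'   rows of an unsupervised forest).
#' @return Integer matrix, rows = observations, columns = trees; entries are
#'   per-tree terminal node ids.
#' @export
leaf_matrix <- function(model, features = NULL) {
  stopifnot(inherits(model, "forest_model"))
  if (is.null(features)) {
    if (is.null(model$real_features))
      stop("'features' must be supplied for a supervised forest")
    features <- model$real_features
  }
  features <- feature_matrix(features)
  if (!identical(colnames(features), model$feature_names))
    stop("feature schema does not match the fitted forest")
  pred <- stats::predict(model$fit, data = features, type = "terminalNodes",
                         num.threads = model$num_threads)
  pred$predictions
}

# numeric feature matrix from matrix or all-numeric data frame input
feature_matrix <- function(features) {
  if (is.matrix(features)) return(named_matrix(features))
  features <- as.data.frame(features)
  if (!all(vapply(features, is.numeric, logical(1))))
    stop("features must be numeric")
  named_matrix(as.matrix(features))
}

#' Proximity matrix from terminal-node assignments
#'
#' The proximity of two observations is the proportion of trees in which
#' they share a terminal node. Computed by grouping equal leaf ids through a
#' sparse indicator cross-product rather than a per-pair double loop; the
#' result is identical to the naive count.
#'
#' @param nodes Integer matrix of terminal node ids (rows = observations,
#'   columns = trees), e.g. from [leaf_matrix()].
#' @param source Optional tag recorded on the result.
#' @param zero_diagonal Zero the diagonal (for imputation use); default
#'   `FALSE` keeps the unit diagonal.
#' @return A symmetric `proximity_matrix` with entries in \[0, 1\] and unit
#'   diagonal (unless zeroed).
#' @export
proximity_from_nodes <- function(nodes, source = "forest",
                                 zero_diagonal = FALSE) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "integer"
  n <- nrow(nodes); B <- ncol(nodes)
  if (B < 1) stop("need at least one tree")
  P <- .prox_counts_cpp(nodes, zero_diagonal) / B
  dimnames(P) <- NULL
  structure(P, class = c("proximity_matrix", "matrix"),
            source = source, n_trees = B)
}

#' Dual-forest proximity matrix
#'
#' Confounder-signified proximity: the element-wise average of the
#' treatment- and outcome-forest co-leaf proportions with zeroed diagonal,
#' computed in one fused pass. Equal to
#' `combine_proximities(proximity_from_nodes(nodes_t),
#' proximity_from_nodes(nodes_y))`.
#'
#' @param nodes_t,nodes_y Terminal-node matrices of the treatment and
#'   outcome forests (same rows).
#' @return A `proximity_matrix` with source `"combined"`.
#' @export
dual_proximity <- function(nodes_t, nodes_y) {
  nodes_t <- as.matrix(nodes_t); storage.mode(nodes_t) <- "integer"
  nodes_y <- as.matrix(nodes_y); storage.mode(nodes_y) <- "integer"
  P <- .prox_dual_cpp(nodes_t, nodes_y)
  structure(P, class = c("proximity_matrix", "matrix"), source = "combined",
            n_trees = NA_integer_)
}

#' Proximity matrix of a fitted forest
#'
#' @inheritParams leaf_matrix
#' @param oob_only If `TRUE`, count only trees where both rows are out of
#'   bag (off by default; the unconditional count over all trees is the
#'   standard choice for imputation).
#' @return A `proximity_matrix`.
#' @export
proximity_from_leaves <- function(model, features = NULL, oob_only = FALSE) {
  nodes <- leaf_matrix(model, features)
  if (!oob_only)
    return(proximity_from_nodes(nodes, source = model$source))
  if (is.null(model$fit$inbag.counts))
    stop("out-of-bag proximity requires the forest to keep in-bag counts ",
         "(refit with keep_inbag = TRUE)")
  inbag <- simplify2array(model$fit$inbag.counts)
  # unsupervised forests train on [real; shadow]; real rows come first
  inbag <- inbag[seq_len(nrow(nodes)), , drop = FALSE]
  oob <- inbag == 0
  n <- nrow(nodes); B <- ncol(nodes)
  num <- matrix(0, n, n); den <- matrix(0, n, n)
  for (b in seq_len(B)) {
    ob <- oob[, b]
    den <- den + tcrossprod(ob + 0)
    same <- outer(nodes[, b], nodes[, b], `==`) & outer(ob, ob, `&`)
    num <- num + same
  }
  P <- ifelse(den > 0, num / den, 0)
  diag(P) <- 1
  structure(P, class = c("proximity_matrix", "matrix"),
            source = paste0(model$source, "_oob"), n_trees = B)
}

#' Out-of-bag predictions of a fitted forest
#'
#' @param model A `forest_model`.
#' @return OOB predicted values (regression) or class-probability matrix
#'   (classification).
#' @export
oob_predictions <- function(model) {
  stopifnot(inherits(model, "forest_model"))
  model$fit$predictions
}

#' Combine treatment- and outcome-forest proximities
#'
#' Element-wise average of the two proximity matrices; by convention the
#' diagonal is zeroed so each observation is imputed only from other
#' observations.
#'
#' @param m_t,m_y Proximity matrices of equal dimension.
#' @param zero_diagonal Zero the diagonal (default `TRUE`).
#' @return The combined `proximity_matrix` (source `"combined"`).
#' @export
combine_proximities <- function(m_t, m_y, zero_diagonal = TRUE) {
  if (!all(dim(m_t) == dim(m_y)))
    stop("proximity matrices must have equal dimensions")
  M <- .prox_average_cpp(m_t, m_y)
  if (!zero_diagonal) diag(M) <- (diag(m_t) + diag(m_y)) / 2
  structure(M, class = c("proximity_matrix", "matrix"), source = "combined",
            n_trees = NA_integer_)
}

#' @export
print.proximity_matrix <- function(x, ...) {
  cat(sprintf("Proximity matrix: %d x %d (%s), mean off-diagonal %.4f\n",
              nrow(x), ncol(x), attr(x, "source"),
              mean(x[row(x) != col(x)])))
  invisible(x)
}
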