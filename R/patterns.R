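#' Enumerate missingness patterns
#'
#' A missingness pattern is the distinct row of the missing-indicator matrix
#' shared by a subgroup of observations.
#'
#' @param S Binary missing-indicator matrix (1 = missing).
#' @return An object of class `pattern_table`: `patterns` (unique indicator
#'   matrix, one row per pattern, ordered by member count descending),
#'   `counts`, and `row_pattern` (pattern index of every input row).
#' @export
extract_patterns <- function(S) {
  S <- as.matrix(S) + 0L
  if (!all(S %in% c(0L, 1L))) stop("'S' must be binary")
  key <- apply(S, 1, paste, collapse = "")
  # deterministic ordering: count descending, then lexicographic key
  tab <- table(key)
  ord <- order(-as.integer(tab), names(tab))
  keys <- names(tab)[ord]
  counts <- as.integer(tab)[ord]
  patterns <- t(vapply(strsplit(keys, ""),
                       function(ch) as.integer(ch), integer(ncol(S))))
  if (ncol(S) == 1L) patterns <- matrix(patterns, ncol = 1L)
  colnames(patterns) <- colnames(S)
  structure(list(patterns = patterns, counts = counts,
                 row_pattern = match(key, keys), n = nrow(S)),
            class = "pattern_table")
}

#' @export
print.pattern_table <- function(x, ...) {
  cat(sprintf("Missingness patterns: %d distinct over %d rows (largest %d)\n",
              length(x$counts), x$n, max(x$counts)))
  invisible(x)
}

#' Pool small missingness patterns (Qu--Lipkovich rule)
#'
#' Patterns with at least `min_size` members stand as their own pooled
#' groups. The remaining small patterns are pooled by Euclidean distance
#' between their indicator vectors. Two variants of the rule are provided:
#'
#' * `method = "chain"` (default): small patterns accumulate with each
#'   other. The largest unassigned small pattern opens a cell; the closest
#'   unassigned small pattern (ties: larger count, then lexicographic
#'   pattern order) is merged repeatedly until the cell reaches `min_size`;
#'   then the next cell opens. A final cell left short of `min_size` is
#'   merged into the closest existing group (ties toward the largest). This
#'   reproduces the accumulate-until-100 behaviour that yields several
#'   moderate-sized propensity strata even at low missingness.
#' * `method = "seed"`: every small pattern merges directly into the
#'   closest group seeded by a large pattern; with no seed, all rows form a
#'   single group.
#'
#' @param patterns A [extract_patterns()] table.
#' @param min_size Minimum observations per pooled group (default 100).
#' @param method Pooling variant, `"chain"` (default) or `"seed"`.
#' @return An object of class `pattern_pooling`: `group` (pooled-group id per
#'   pattern), `group_counts`, `min_size`, and `row_group` (group id per
#'   original data row).
#' @export
pool_patterns <- function(patterns, min_size = 100,
                          method = c("chain", "seed")) {
  stopifnot(inherits(patterns, "pattern_table"))
  method <- match.arg(method)
  if (min_size < 1) stop("'min_size' must be >= 1")
  counts <- patterns$counts
  P <- patterns$patterns
  k <- length(counts)
  keys <- apply(P, 1, paste, collapse = "")
  seeds <- which(counts >= min_size)
  small <- setdiff(seq_len(k), seeds)
  group <- integer(k)
  group[seeds] <- seq_along(seeds)
  n_groups <- length(seeds)
  group_rep <- seeds                    # representative pattern per group

  pick_closest <- function(from, candidates) {
    d2 <- colSums((t(P[candidates, , drop = FALSE]) - P[from, ])^2)
    best <- candidates[d2 == min(d2)]
    if (length(best) > 1) {
      best <- best[counts[best] == max(counts[best])]
      if (length(best) > 1) best <- best[order(keys[best])]
    }
    best[1]
  }

  if (method == "seed") {
    if (length(seeds) == 0) {
      group[] <- 1L
      n_groups <- 1L
    } else {
      for (s in small[order(counts[small], keys[small])])
        group[s] <- group[pick_closest(s, seeds)]
    }
  } else {
    # chain: small patterns accumulate with each other, largest first
    unassigned <- small[order(-counts[small], keys[small])]
    last_cell <- NULL
    while (length(unassigned) > 0) {
      s0 <- unassigned[1]
      unassigned <- unassigned[-1]
      cell <- s0
      cnt <- counts[s0]
      while (cnt < min_size && length(unassigned) > 0) {
        nxt <- pick_closest(s0, unassigned)
        unassigned <- setdiff(unassigned, nxt)
        cell <- c(cell, nxt)
        cnt <- cnt + counts[nxt]
      }
      n_groups <- n_groups + 1L
      group[cell] <- n_groups
      group_rep <- c(group_rep, s0)
      if (cnt < min_size) last_cell <- list(id = n_groups, seed = s0)
    }
    # a leftover cell short of the minimum joins the closest other group
    if (!is.null(last_cell) && n_groups > 1L) {
      others <- group_rep[-last_cell$id]
      target <- group[pick_closest(last_cell$seed, others)]
      group[group == last_cell$id] <- target
      remap <- match(group, sort(unique(group)))
      group <- remap
      n_groups <- max(group)
    }
  }
  group_counts <- vapply(seq_len(n_groups),
                         function(g) sum(counts[group == g]), integer(1))
  structure(list(group = group, group_counts = group_counts,
                 min_size = min_size, method = method,
                 row_group = group[patterns$row_pattern]),
            class = "pattern_pooling")
}

#' @export
print.pattern_pooling <- function(x, ...) {
  cat(sprintf("Pattern pooling (min %d): %d group%s with sizes %s\n",
              x$min_size, length(x$group_counts),
              if (length(x$group_counts) == 1) "" else "s",
              paste(x$group_counts, collapse = ", ")))
  invisible(x)
}

#' Pooling report
#'
#' Diagnostic table pairing each distinct missingness pattern with its count
#' and pooled-group id; written as CSV by the command-line tool.
#'
#' @param patterns A `pattern_table`.
#' @param pooling The matching `pattern_pooling`.
#' @return A data frame with the pattern string, member count and group id.
#' @export
pooling_report <- function(patterns, pooling) {
  data.frame(pattern = apply(patterns$patterns, 1, paste, collapse = ""),
             count = patterns$counts, group = pooling$group)
}
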