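# Small fixtures shared across the suite. Everything is generated in code;
# calibration samples are reduced (calib_n) where a test only needs the
# machinery, not the +-0.01 calibration guarantee.

quick_config <- function(n = 200, p = 6, missing_rate = 0.3,
                         mechanism = "MAR", calib_n = 2e4, ...) {
  sim_config(n = n, p = p, missing_rate = missing_rate,
             mechanism = mechanism, calib_n = calib_n, ...)
}

quick_dataset <- function(seed = 1, ...) {
  simulate_mnar_dataset(quick_config(...), seed = seed)
}

# a smooth low-noise fixture where X columns are strongly related, so
# proximity imputation has signal to exploit
smooth_fixture <- function(n = 120, seed = 2) {
  set.seed(seed)
  u <- rnorm(n)
  X <- cbind(x1 = u + rnorm(n, sd = 0.3),
             x2 = u + rnorm(n, sd = 0.3),
             x3 = -u + rnorm(n, sd = 0.3),
             x4 = (u > 0) + 0)
  Z <- rbinom(n, 1, plogis(u))
  Y <- u + 0.5 * Z + rnorm(n, sd = 0.3)
  list(X = X, Z = Z, Y = Y, u = u)
}

# reference R implementation of the proximity-weighted donor rule, written
# as the literal per-cell loop
brute_force_update <- function(X, S, M, column_types) {
  out <- X
  n <- nrow(X)
  for (i in seq_len(n)) {
    rs <- sum(M[i, -i])
    for (j in seq_len(ncol(X))) {
      if (S[i, j] != 1) next
      if (rs == 0) next  # fallback handled by the implementation
      w <- M[i, ] / rs
      w[i] <- 0
      if (column_types[j] == "continuous") {
        out[i, j] <- sum(w * X[, j])
      } else {
        p1 <- mean(X[S[, j] == 0, j] == 1)
        s1 <- sum(w * (X[, j] == 1))
        s0 <- sum(w * (X[, j] == 0))
        out[i, j] <- if (p1 * s1 > (1 - p1) * s0) 1 else 0
      }
    }
  }
  out
}

# naive per-pair proximity count
brute_force_proximity <- function(nodes) {
  n <- nrow(nodes)
  P <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      P[i, j] <- mean(nodes[i, ] == nodes[j, ])
  P
}
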