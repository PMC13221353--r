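test_that("optimized proximity equals the naive per-pair count exactly", {
  for (s in 1:5) {
    set.seed(s)
    n <- sample(10:60, 1)
    B <- sample(1:10, 1)
    nodes <- matrix(sample.int(7, n * B, replace = TRUE), n, B)
    P <- proximity_from_nodes(nodes)
    expect_equal(unclass(P), brute_force_proximity(nodes),
                 ignore_attr = TRUE)
    expect_true(all(P >= 0 & P <= 1))
    expect_equal(unname(diag(P)), rep(1, n))
    expect_identical(unclass(P), t(unclass(P)))
  }
})

test_that("proximity hand example: two trees over three observations", {
  nodes <- cbind(c(1L, 1L, 2L), c(1L, 2L, 2L))
  P <- proximity_from_nodes(nodes)
  expect_equal(P[1, 2], 0.5)
  expect_equal(P[1, 3], 0)
  expect_equal(P[2, 3], 0.5)
})

test_that("a single tree with one shared leaf yields the all-ones matrix", {
  P <- proximity_from_nodes(matrix(1L, 5, 1))
  expect_equal(unclass(P), matrix(1, 5, 5), ignore_attr = TRUE)
})

test_that("fused dual-forest proximity equals composing the two matrices", {
  set.seed(9)
  nt <- matrix(sample.int(5, 40 * 6, TRUE), 40, 6)
  ny <- matrix(sample.int(3, 40 * 4, TRUE), 40, 4)
  fused <- dual_proximity(nt, ny)
  composed <- combine_proximities(proximity_from_nodes(nt),
                                  proximity_from_nodes(ny))
  expect_equal(unclass(fused), unclass(composed), ignore_attr = TRUE)
  expect_equal(unname(diag(fused)), rep(0, 40))
  # equal inputs: combined matrix equals either input off the diagonal
  same <- combine_proximities(proximity_from_nodes(nt),
                              proximity_from_nodes(nt))
  off <- row(same) != col(same)
  expect_equal(unclass(same)[off], unclass(proximity_from_nodes(nt))[off])
})

test_that("permuting rows permutes the proximity matrix accordingly", {
  set.seed(13)
  nodes <- matrix(sample.int(4, 30 * 5, TRUE), 30, 5)
  perm <- sample.int(30)
  P <- unclass(proximity_from_nodes(nodes))
  Pp <- unclass(proximity_from_nodes(nodes[perm, ]))
  expect_equal(Pp, P[perm, perm], ignore_attr = TRUE)
})

test_that("supervised forest uses the square-root mtry default and is deterministic", {
  set.seed(17)
  X <- matrix(rnorm(100 * 20), 100, 20)
  y <- rnorm(100)
  f1 <- fit_supervised_forest(X, y, task = "regression", n_trees = 20,
                              seed = 5)
  expect_equal(f1$mtry, 4L)  # floor(sqrt(20))
  f2 <- fit_supervised_forest(X, y, task = "regression", n_trees = 20,
                              seed = 5)
  expect_identical(leaf_matrix(f1, X), leaf_matrix(f2, X))
  expect_error(fit_supervised_forest(X, rep(1, 100), task = "regression"),
               "constant")
  Xna <- X; Xna[1, 1] <- NA
  expect_error(fit_supervised_forest(Xna, y, task = "regression"),
               "missing")
})

test_that("a separable binary response gives a small out-of-bag error", {
  set.seed(19)
  n <- 200
  cl <- rep(0:1, each = n / 2)
  X <- matrix(rnorm(n * 4), n, 4) + 4 * cl
  f <- fit_supervised_forest(X, cl, task = "classification", n_trees = 100,
                             seed = 3)
  prob <- oob_predictions(f)
  oob_class <- as.integer(prob[, "1"] > 0.5)
  expect_lt(mean(oob_class != cl), 0.1)
})

test_that("schema mismatches are rejected at proximity time", {
  set.seed(23)
  X <- matrix(rnorm(50 * 3), 50, 3, dimnames = list(NULL, c("a", "b", "c")))
  f <- fit_supervised_forest(X, rnorm(50), task = "regression", n_trees = 5)
  X2 <- X
  colnames(X2) <- c("a", "b", "d")
  expect_error(leaf_matrix(f, X2), "schema")
})

test_that("unsupervised forest separates well-separated clusters by proximity", {
  set.seed(29)
  n <- 60
  cl <- rep(0:1, each = n / 2)
  X <- matrix(rnorm(n * 4, sd = 0.4), n, 4) + 5 * cl
  f <- fit_unsupervised_forest(X, n_trees = 100, seed = 7)
  P <- unclass(proximity_from_leaves(f))
  within <- P[cl %o% rep(1, n) == rep(1, n) %o% cl & row(P) != col(P)]
  between <- P[cl %o% rep(1, n) != rep(1, n) %o% cl]
  expect_gt(mean(within), mean(between))
})

test_that("identical rows always share a leaf in the unsupervised forest", {
  X <- matrix(c(1.5, 2.5, 1.5, 2.5), 2, 2, byrow = TRUE)  # two equal rows
  f <- fit_unsupervised_forest(X, n_trees = 20, seed = 11)
  P <- proximity_from_leaves(f)
  expect_equal(P[1, 2], 1)
})

test_that("constant features collapse every observation into one leaf", {
  X <- matrix(1, 30, 3)
  f <- fit_supervised_forest(X, rnorm(30), task = "regression", n_trees = 1,
                             seed = 2)
  P <- proximity_from_leaves(f, X)
  expect_equal(unclass(P), matrix(1, 30, 30), ignore_attr = TRUE)
})

test_that("i.i.d. noise features give roughly exchangeable proximities", {
  # the most-proximate pair should wander across independent forests rather
  # than one pair dominating systematically
  set.seed(31)
  X <- matrix(rnorm(40 * 5), 40, 5)
  top_pair <- replicate(5, {
    f <- fit_unsupervised_forest(X, n_trees = 60,
                                 seed = sample.int(1e6, 1))
    P <- unclass(proximity_from_leaves(f))
    diag(P) <- -1
    which.max(P)
  })
  expect_gt(length(unique(top_pair)), 1)
})
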