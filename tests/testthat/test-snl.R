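test_that("affinities are cosine weights split by label agreement", {
  V <- cbind(c(1, 0, 1), c(1, 0, 1), c(0, 1, 0), c(1, 1, 1))
  y <- c("high", "high", "low", "low")
  aff <- build_affinities(V, y)
  expect_equal(aff$A_plus[1, 2], 1.0)        # identical same-label sessions
  expect_equal(aff$A_minus[1, 3], 0.0)       # orthogonal different-label pair
  expect_equal(diag(aff$A_plus), rep(0, 4))
  expect_true(all(aff$A_plus[y[row(aff$A_plus)] != y[col(aff$A_plus)]] == 0))
  expect_error(build_affinities(cbind(V, 0), c(y, "low")), "zero-norm")

  set.seed(51)
  V6 <- matrix(runif(10 * 6, 0.1, 1), 10, 6)
  y6 <- rep(c("high", "low"), 3)
  aff6 <- build_affinities(V6, y6)
  # D equals independently recomputed row sums of A+
  nv <- sweep(V6, 2, sqrt(colSums(V6^2)), "/")
  manual <- sapply(1:6, function(i) sum(sapply(1:6, function(j)
    if (i != j && y6[i] == y6[j]) sum(nv[, i] * nv[, j]) else 0)))
  expect_equal(aff6$D, manual)
})

test_that("snl_fit solves the generalized eigenproblem with unit metric norm", {
  # 4 sessions over the 3-vertex dual of a 3-region clique: vertex 1 tracks
  # the labels, vertices 2-3 are constant
  dual <- to_edge_dual(3L)
  V <- rbind(c(1, 1, 0.05, 0.05), 0.5, 0.5)
  y <- c("high", "high", "low", "low")
  C <- dual_laplacian(dual)
  fit <- snl_fit(V, y, C, lam = 0)
  expect_equal(which.max(abs(fit$u)), 1L)
  expect_gt(fit$u[which.max(abs(fit$u))], 0)  # sign convention

  # constraint u'(VDV' + eps I)u = 1
  aff <- build_affinities(V, y)
  K <- V %*% diag(aff$D) %*% t(V) + fit$eps * diag(3)
  expect_equal(drop(crossprod(fit$u, K %*% fit$u)), 1, tolerance = 1e-8)

  # independent dense oracle: non-symmetric eigen of K^{-1} S
  Lp <- diag(rowSums(aff$A_plus)) - aff$A_plus
  Lm <- diag(rowSums(aff$A_minus)) - aff$A_minus
  S <- V %*% (Lm - Lp) %*% t(V)
  eo <- eigen(solve(K, S))
  u_or <- Re(eo$vectors[, which.max(Re(eo$values))])
  u_or <- u_or / sqrt(drop(crossprod(u_or, K %*% u_or)))
  expect_equal(abs(fit$u), abs(u_or), tolerance = 1e-6)
  expect_equal(fit$objective, max(Re(eo$values)), tolerance = 1e-8)
})

test_that("the SNL solution is the global optimum over feasible vectors", {
  set.seed(52)
  for (trial in 1:3) {
    dual <- to_edge_dual(5L)
    ne <- nrow(dual$pairs)
    V <- matrix(runif(ne * 8, 0.1, 0.9), ne, 8)
    y <- rep(c("high", "low"), each = 4)
    C <- dual_laplacian(dual)
    lam <- c(0, 0.1, 1)[trial]
    fit <- snl_fit(V, y, C, lam = lam)
    aff <- build_affinities(V, y)
    Lp <- diag(rowSums(aff$A_plus)) - aff$A_plus
    Lm <- diag(rowSums(aff$A_minus)) - aff$A_minus
    S <- V %*% (Lm - Lp) %*% t(V) - lam * C
    K <- V %*% diag(aff$D) %*% t(V) + fit$eps * diag(ne)
    obj <- function(u) drop(crossprod(u, S %*% u))
    best_random <- max(replicate(200, {
      u <- rnorm(ne)
      u <- u / sqrt(drop(crossprod(u, K %*% u)))
      obj(u)
    }))
    expect_gte(obj(fit$u) + 1e-10, best_random)
  }
})

test_that("selection is scale invariant and obeys the tie-break rule", {
  dual <- to_edge_dual(6L)
  V <- small_V()
  dual8 <- to_edge_dual(8L)
  y <- small_study()$labels
  C <- dual_laplacian(dual8)
  s1 <- select_edges(snl_fit(V, y, C, lam = 0.1), 4, dual8)$vertices
  s2 <- select_edges(snl_fit(7.3 * V, y, C, lam = 0.1), 4, dual8)$vertices
  expect_equal(s1, s2)

  expect_equal(select_edges(c(0.9, 0.1, 0.05), 1, to_edge_dual(3L))$vertices, 1L)
  # exact tie at rank k: canonically smaller vertex retained
  expect_equal(select_edges(c(0.5, -0.5, 0.1), 1, to_edge_dual(3L))$vertices, 1L)

  set.seed(53)
  u <- rnorm(nrow(dual$pairs))
  sel <- select_edges(u, 5, dual)
  expect_identical(sel$components, igraph_edge_components(sel$vertices, dual))
})

test_that("a planted separating edge pair is recovered across seeds", {
  dual <- to_edge_dual(6L)
  ne <- nrow(dual$pairs)
  planted <- c(1L, 2L)  # edges (0,1) and (0,2): dual-linked via region 0
  hits <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    y <- rep(c("high", "low"), each = 6)
    V <- matrix(runif(ne * 12, 0.2, 0.8), ne, 12)
    V[planted, y == "high"] <- 0.85 + rnorm(2 * 6, sd = 0.03)
    V[planted, y == "low"] <- 0.15 + abs(rnorm(2 * 6, sd = 0.03))
    fit <- snl_fit(V, y, dual_laplacian(dual), lam = 0.05)
    sel <- select_edges(fit, 2, dual)$vertices
    if (all(planted %in% sel)) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("increasing the topology penalty never increases the Laplacian quadratic form", {
  V <- small_V()
  y <- small_study()$labels
  C <- dual_laplacian(to_edge_dual(8L))
  qf <- vapply(c(0, 0.01, 0.1, 1, 10), function(lam) {
    u <- snl_fit(V, y, C, lam = lam)$u
    drop(crossprod(u, C %*% u))
  }, numeric(1))
  expect_true(all(diff(qf) <= 1e-8))
})

test_that("hyperparameter tuning prefers the smallest sufficient model", {
  dual <- to_edge_dual(5L)
  ne <- nrow(dual$pairs)
  set.seed(54)
  y <- rep(c("high", "low"), each = 6)
  V <- matrix(runif(ne * 12, 0.3, 0.7), ne, 12)
  V[1, ] <- ifelse(y == "high", 0.9, 0.1) + rnorm(12, sd = 0.01)
  tuned <- tune_snl(V, y, dual, lam_grid = 0.1, k_grid = c(1L, 3L, 5L),
                    inner_folds = 3L, seed = 3)
  expect_equal(tuned$k, 1L)  # separable by one feature; ties go to smaller k
  expect_equal(tuned$accuracy, 1.0)

  one <- tune_snl(V, y, dual, lam_grid = 0.5, k_grid = 2L,
                  inner_folds = 2L, seed = 3)
  expect_equal(one$lam, 0.5)
  expect_equal(one$k, 2L)
})
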