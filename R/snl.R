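#' Affinity matrices over session coherence vectors
#'
#' Each session's edge coherence values form a vector; cosine similarity
#' between session vectors weighs the same-label meta-network `A+` and the
#' different-label meta-network `A-`. Diagonals are zero, and `D` is the
#' diagonal of row sums of `A+`.
#'
#' @param V numeric matrix, |E| rows (dual vertices) x m columns (sessions).
#' @param labels binary session labels (`"high"`/`"low"`).
#' @return list with `A_plus`, `A_minus` (m x m) and `D` (length-m row-sum
#'   vector of `A_plus`).
#' @export
build_affinities <- function(V, labels) {
  V <- as.matrix(V)
  y <- .as_label_factor(labels)
  if (length(y) != ncol(V)) stop("labels must have one entry per column of V")
  S <- .cosine_similarity(V)
  same <- outer(y, y, "==")
  A_plus <- S * same
  A_minus <- S * !same
  diag(A_plus) <- 0
  diag(A_minus) <- 0
  list(A_plus = A_plus, A_minus = A_minus, D = rowSums(A_plus))
}

#' Sub-network learning: discriminative projection over dual vertex values
#'
#' Learns the 1-dimensional projection `u` over edge-dual vertex values that
#' pulls same-label sessions together and pushes different-label sessions
#' apart, regularized by the dual-graph Laplacian so that large coefficients
#' concentrate on topologically coherent (connected) edge sets.
#'
#' With `L+`/`L-` the Laplacians of the same/different-label affinity
#' meta-networks, the solution is the top generalized eigenvector of
#' \deqn{(V L^- V' - V L^+ V' - \lambda C)\, u = \mu (V D V' + \epsilon I)\, u,}
#' the Lagrangian form of the constrained objective in which the topology
#' penalty `u'Cu <= t` appears as a ridge-type penalty with weight `lambda`.
#' The metric `V D V'` is rank-deficient whenever m < |E|, so a small ridge
#' `epsilon I` (relative to its trace) makes it positive definite. The
#' returned `u` satisfies `u' (V D V' + eps I) u = 1` and its sign is fixed
#' so the largest-magnitude entry is positive, making the solution fully
#' deterministic.
#'
#' @param V numeric matrix, |E| x m session vertex-value matrix.
#' @param labels binary session labels.
#' @param laplacian dual-graph combinatorial Laplacian (|E| x |E|), see
#'   [dual_laplacian()].
#' @param lam nonnegative topology-penalty weight.
#' @param ridge_eps relative ridge; the absolute ridge is
#'   `ridge_eps * trace(V D V') / |E|`.
#' @return an object of class `snl` with elements `u`, `objective` (the top
#'   generalized eigenvalue), `lam`, `eps`, `n_vertices`, `n_sessions`.
#' @seealso [select_edges()], [tune_snl()]
#' @export
snl_fit <- function(V, labels, laplacian, lam = 0, ridge_eps = 1e-8) {
  V <- as.matrix(V)
  ne <- nrow(V); m <- ncol(V)
  if (m < 4L) stop("need at least 4 sessions")
  y <- .as_label_factor(labels)
  if (nlevels(droplevels(y)) != 2L) stop("both classes must be represented")
  if (!all(dim(laplacian) == ne)) stop("laplacian dimension must match nrow(V)")
  if (lam < 0) stop("lam must be nonnegative")
  aff <- build_affinities(V, y)
  Lp <- diag(rowSums(aff$A_plus)) - aff$A_plus
  Lm <- diag(rowSums(aff$A_minus)) - aff$A_minus
  S <- V %*% (Lm - Lp) %*% t(V) - lam * laplacian
  K <- V %*% (aff$D * t(V))
  eps <- ridge_eps * sum(diag(K)) / ne
  if (!is.finite(eps) || eps <= 0) eps <- ridge_eps
  diag(K) <- diag(K) + eps
  R <- tryCatch(chol((K + t(K)) / 2), error = function(e)
    stop("projection metric not positive definite (conditioning failure): ",
         conditionMessage(e)))
  # Whiten: B = R^{-T} S R^{-1}; top eigenvector y1; u = R^{-1} y1.
  Z <- backsolve(R, S, transpose = TRUE)
  B <- backsolve(R, t(Z), transpose = TRUE)
  B <- (B + t(B)) / 2
  ev <- eigen(B, symmetric = TRUE)
  u <- backsolve(R, ev$vectors[, 1L])
  u <- u / sqrt(drop(crossprod(u, K %*% u)))   # exact unit metric norm
  if (u[which.max(abs(u))] < 0) u <- -u
  structure(list(u = as.numeric(u), objective = ev$values[1L],
                 lam = lam, eps = eps, n_vertices = ne, n_sessions = m),
            class = "snl")
}

#' @export
print.snl <- function(x, ...) {
  cat(sprintf(paste0("Sub-network learning fit: %d dual vertices, %d sessions\n",
                     "  lambda = %g, objective = %.4g\n"),
              x$n_vertices, x$n_sessions, x$lam, x$objective))
  invisible(x)
}

#' @export
coef.snl <- function(object, ...) object$u

#' @export
predict.snl <- function(object, newdata, ...) {
  V <- as.matrix(newdata)
  if (nrow(V) != object$n_vertices)
    stop("newdata must have one row per dual vertex")
  drop(crossprod(V, object$u))
}

#' @export
plot.snl <- function(x, ...) {
  graphics::plot(abs(x$u), type = "h", xlab = "dual vertex (canonical order)",
                 ylab = "|u|", main = "Projection coefficient magnitudes", ...)
  invisible(x)
}

#' Select the top-ranked edges of an SNL fit
#'
#' Takes the `k` dual vertices of largest absolute projection coefficient
#' (exact ties broken toward the canonically smaller vertex) and partitions
#' them into link-connected components.
#'
#' @param u numeric coefficient vector (or an `snl` fit).
#' @param k number of edges to retain.
#' @param dual the `edge_dual` the coefficients are indexed by.
#' @return list with `vertices` (sorted selected ids) and `components`
#'   (from [dual_connected_components()]).
#' @export
select_edges <- function(u, k, dual) {
  if (inherits(u, "snl")) u <- u$u
  ne <- length(u)
  if (!.is_count(k) || k > ne) stop("k must be an integer in 1..|E|")
  ord <- order(-abs(u), seq_len(ne))
  sel <- sort(ord[seq_len(k)])
  list(vertices = sel, components = dual_connected_components(sel, dual))
}

#' Tune the SNL penalty and edge count by inner cross-validation
#'
#' Grid search over (lambda, k): for each inner fold, fit SNL on the inner
#' training sessions at each lambda, select the top-k edges, train a linear
#' margin classifier on those coherence features and score the held-in
#' validation sessions. The grid point with the highest mean inner accuracy
#' wins; ties go to the smaller k, then the smaller lambda.
#'
#' @param V |E| x m vertex-value matrix of the (outer) training sessions.
#' @param labels their binary labels.
#' @param dual the `edge_dual`.
#' @param laplacian dual Laplacian (recomputed from `dual` when missing).
#' @param lam_grid,k_grid candidate penalty weights and edge counts.
#' @param inner_folds number of inner folds (each class must have at least
#'   this many sessions).
#' @param ridge_eps relative ridge for [snl_fit()].
#' @param seed RNG seed for the inner fold split.
#' @return list with `lam`, `k`, `accuracy` (mean inner CV accuracy) and the
#'   full `grid` of accuracies.
#' @export
tune_snl <- function(V, labels, dual, laplacian = NULL,
                     lam_grid = c(0.01, 0.1, 1), k_grid = c(2L, 4L, 8L),
                     inner_folds = 3L, ridge_eps = 1e-8, seed = 1L) {
  V <- as.matrix(V)
  y <- .as_label_factor(labels)
  if (is.null(laplacian)) laplacian <- dual_laplacian(dual)
  k_grid <- sort(unique(pmin(as.integer(k_grid), nrow(V))))
  lam_grid <- sort(unique(as.numeric(lam_grid)))
  fold <- .stratified_folds(y, inner_folds, seed)
  acc <- array(0, dim = c(length(lam_grid), length(k_grid), inner_folds))
  for (f in seq_len(inner_folds)) {
    tr <- fold != f
    if (nlevels(droplevels(y[tr])) != 2L || nlevels(droplevels(y[!tr])) != 2L)
      stop("stratification error: a class is absent from an inner fold")
    for (li in seq_along(lam_grid)) {
      fit <- snl_fit(V[, tr, drop = FALSE], y[tr], laplacian,
                     lam = lam_grid[li], ridge_eps = ridge_eps)
      for (ki in seq_along(k_grid)) {
        sel <- select_edges(fit, k_grid[ki], dual)$vertices
        acc[li, ki, f] <- .svm_accuracy(
          t(V[sel, tr, drop = FALSE]), droplevels(y[tr]),
          t(V[sel, !tr, drop = FALSE]), y[!tr], kernel = "linear")
      }
    }
  }
  mean_acc <- apply(acc, c(1L, 2L), mean)
  # ties: smaller k first, then smaller lam
  best <- c(Inf, Inf, -Inf)  # k, lam, acc
  for (ki in seq_along(k_grid)) for (li in seq_along(lam_grid)) {
    a <- mean_acc[li, ki]
    if (a > best[3] + 1e-12) best <- c(k_grid[ki], lam_grid[li], a)
  }
  list(lam = best[2], k = as.integer(best[1]), accuracy = best[3],
       grid = list(lam_grid = lam_grid, k_grid = k_grid, accuracy = mean_acc))
}
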