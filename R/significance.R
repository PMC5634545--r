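#' Uniform sampling of connected dual subgraphs
#'
#' Draws connected vertex sets of a fixed size uniformly at random from the
#' edge-dual graph, the null model against which candidate subgraphs are
#' scored. The sampler is a Metropolis chain on the space of connected
#' k-sets: a step removes a vertex whose deletion keeps the remainder
#' connected, adds a uniform random neighbor of the remainder, and accepts
#' with ratio `R(S)/R(S')` where `R` counts removable vertices — the
#' correction that makes the stationary distribution exactly uniform (the
#' neighbor-count factors cancel because both moves share the same
#' remainder). Size-1 sets are drawn directly.
#'
#' @param dual a connected `edge_dual`.
#' @param size subgraph size in edges (1..|E|).
#' @param n_samples number of draws.
#' @param seed RNG seed.
#' @param burn_in,thin chain burn-in and thinning in steps (defaults scale
#'   with `size`).
#' @return list of sorted integer vertex-id vectors, one per draw.
#' @export
sample_connected_subgraphs <- function(dual, size, n_samples = 1L, seed = 1L,
                                       burn_in = 100L * size,
                                       thin = 5L * size) {
  stopifnot(inherits(dual, "edge_dual"))
  ne <- nrow(dual$pairs)
  if (!.is_count(size) || size > ne)
    stop("size must be an integer in 1..|E|")
  if (!.dual_is_connected(seq_len(ne), dual))
    stop("dual graph is not connected")
  adj <- dual$adjacency
  if (size == 1L) {
    return(.with_seed(seed, lapply(sample.int(ne, n_samples, replace = TRUE),
                                   identity)))
  }
  connected_without <- function(vs, drop_pos) {
    rest <- vs[-drop_pos]
    seen <- rest[1L]
    queue <- rest[1L]
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      nb <- intersect(adj[[u]], rest)
      new <- setdiff(nb, seen)
      seen <- c(seen, new)
      queue <- c(queue, new)
    }
    length(seen) == length(rest)
  }
  removable <- function(vs) {
    which(vapply(seq_along(vs), function(p) connected_without(vs, p), logical(1)))
  }
  .with_seed(seed, {
    # start from a random connected growth
    S <- .sample1(seq_len(ne))
    while (length(S) < size) {
      nb <- setdiff(unique(unlist(adj[S], use.names = FALSE)), S)
      S <- c(S, .sample1(nb))
    }
    S <- sort(S)
    rS <- removable(S)
    draws <- vector("list", n_samples)
    got <- 0L
    step <- 0L
    total_needed <- burn_in + n_samples * thin
    while (got < n_samples) {
      step <- step + 1L
      p <- .sample1(rS)
      v <- S[p]
      base <- S[-p]
      nb <- setdiff(unique(unlist(adj[base], use.names = FALSE)), base)
      w <- .sample1(nb)
      if (w != v) {
        S2 <- sort(c(base, w))
        rS2 <- removable(S2)
        if (stats::runif(1) < length(rS) / length(rS2)) {
          S <- S2
          rS <- rS2
        }
      }
      if (step > burn_in && (step - burn_in) %% thin == 0L) {
        got <- got + 1L
        draws[[got]] <- S
      }
    }
    draws
  })
}

#' Classification accuracy of an edge subset
#'
#' Accuracy of a polynomial-kernel max-margin classifier that sees only the
#' coherence features of the given edge set — the statistic used both for
#' conserved candidates and for the random-subgraph background. By default
#' the accuracy is cross-validated with stratified folds under a fixed seed;
#' resubstitution (train and score on all sessions) is available as a mode.
#'
#' @param edges dual vertex id set (non-empty).
#' @param V |E| x m vertex-value matrix.
#' @param labels binary session labels (>= 2 sessions per class).
#' @param folds CV folds.
#' @param degree polynomial kernel degree.
#' @param mode `"cv"` or `"resubstitution"`.
#' @param seed RNG seed for the fold split.
#' @return accuracy in \[0, 1\].
#' @export
subgraph_accuracy <- function(edges, V, labels, folds = 3L, degree = 3L,
                              mode = c("cv", "resubstitution"), seed = 1L) {
  mode <- match.arg(mode)
  edges <- as.integer(edges)
  if (!length(edges)) stop("empty edge set")
  V <- as.matrix(V)
  y <- .as_label_factor(labels)
  if (any(table(y) < 2L)) stop("need at least 2 sessions per class")
  x <- t(V[edges, , drop = FALSE])
  # exactly duplicated features carry no information; drop them so accuracy
  # is invariant to feature redundancy
  x <- x[, !duplicated(t(x)), drop = FALSE]
  if (mode == "resubstitution")
    return(.svm_accuracy(x, y, x, y, kernel = "polynomial", degree = degree))
  .cv_svm_accuracy(x, y, folds, seed, kernel = "polynomial", degree = degree)
}

#' Background accuracy distribution for a subgraph size
#'
#' Samples `n_samples` uniform random connected subgraphs of the given size
#' and computes each one's classification accuracy under the same fold
#' scheme and seed policy as the candidates, so p-values compare like with
#' like.
#'
#' @inheritParams subgraph_accuracy
#' @param dual the `edge_dual`.
#' @param size subgraph size in edges.
#' @param n_samples number of null subgraphs.
#' @param config a `study_config` (supplies folds, degree, mode, sampler
#'   settings).
#' @param seed RNG seed.
#' @return object of class `background_distribution` with `size`,
#'   `accuracies`, `n_samples`.
#' @export
background_distribution <- function(dual, size, V, labels,
                                    n_samples = 1000L,
                                    config = study_config(), seed = 1L) {
  sets <- sample_connected_subgraphs(
    dual, size, n_samples, seed = .derive_seed(seed, 17L, size),
    burn_in = config$sampler_burnin_per_edge * size,
    thin = config$sampler_thin_per_edge * size)
  acc <- vapply(seq_along(sets), function(i)
    subgraph_accuracy(sets[[i]], V, labels,
                      folds = config$accuracy_folds,
                      degree = config$svm_degree,
                      mode = config$background_mode,
                      seed = .derive_seed(seed, 19L)),
    numeric(1))
  structure(list(size = as.integer(size), accuracies = acc,
                 n_samples = as.integer(n_samples)),
            class = "background_distribution")
}

#' Empirical p-value against a background distribution
#'
#' One-sided, add-one smoothed:
#' `p = (1 + #\{background >= observed\}) / (n + 1)`, so p is always
#' positive (required downstream by the q-value computation).
#'
#' @param observed observed accuracy in \[0, 1\].
#' @param background a `background_distribution` (or numeric vector of null
#'   accuracies).
#' @return p-value in (0, 1\].
#' @export
empirical_pvalue <- function(observed, background) {
  acc <- if (inherits(background, "background_distribution"))
    background$accuracies else as.numeric(background)
  if (!length(acc)) stop("background distribution is empty")
  if (!(observed >= 0 && observed <= 1)) stop("observed accuracy must be in [0, 1]")
  (1 + sum(acc >= observed)) / (length(acc) + 1)
}

#' Storey q-values
#'
#' Converts p-values to q-values (minimum FDR at which each test is called
#' significant). The null proportion is estimated as
#' `pi0 = min(1, #\{p > 0.5\} / (0.5 m))` (Storey's estimator at
#' lambda = 0.5); with fewer than 20 p-values the estimate is unstable and
#' `pi0 = 1` is used, which makes the result coincide exactly with
#' Benjamini-Hochberg step-up adjustment. Output is monotone nondecreasing
#' in p and capped at 1.
#'
#' @param pvalues numeric vector of p-values in (0, 1\].
#' @return q-values in the input order.
#' @export
compute_qvalues <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(p)
  pi0 <- if (m < 20L) 1 else min(1, sum(p > 0.5) / (0.5 * m))
  if (pi0 <= 0) pi0 <- 1 / m
  ord <- order(p)
  q <- pi0 * m * p[ord] / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

#' Retain candidates at the FDR threshold
#'
#' @param candidates list of subgraph candidates carrying `q_value`.
#' @param q_threshold retain candidates with `q_value <= q_threshold`
#'   (boundary inclusive).
#' @return the retained sublist.
#' @export
filter_significant <- function(candidates, q_threshold = 0.015) {
  Filter(function(s) {
    if (is.null(s$q_value)) stop("candidate without q_value")
    s$q_value <= q_threshold
  }, candidates)
}

#' Per-edge summary statistics
#'
#' For each edge: the mean coherence in high- and low-label sessions and the
#' Pearson correlation between edge coherence and the continuous drop-off
#' across sessions (the columns of the biomarker summary table). A constant
#' edge has correlation 0 by convention.
#'
#' @param edges dual vertex id set.
#' @param V |E| x m vertex-value matrix.
#' @param labels binary session labels.
#' @param dropoffs continuous drop-off value per session.
#' @param dual the `edge_dual` (for region-pair naming).
#' @return data.frame with columns `vertex`, `edge` (region-pair name),
#'   `region_a`, `region_b`, `mean_high`, `mean_low`, `correlation`.
#' @export
summarize_edges <- function(edges, V, labels, dropoffs, dual) {
  edges <- as.integer(edges)
  V <- as.matrix(V)
  y <- .as_label_factor(labels)
  dropoffs <- as.numeric(dropoffs)
  if (length(dropoffs) != ncol(V))
    stop("dropoffs must have one value per session")
  if (any(!is.finite(dropoffs)))
    stop("dropoffs must be finite for all sessions (label the networks first)")
  rows <- lapply(edges, function(e) {
    v <- V[e, ]
    corr <- if (stats::sd(v) == 0 || stats::sd(dropoffs) == 0) 0
            else stats::cor(v, dropoffs)
    data.frame(vertex = e,
               edge = dual$vertex_names[e],
               region_a = dual$pairs[e, 1L],
               region_b = dual$pairs[e, 2L],
               mean_high = if (any(y == "high")) mean(v[y == "high"]) else NA_real_,
               mean_low = if (any(y == "low")) mean(v[y == "low"]) else NA_real_,
               correlation = corr)
  })
  do.call(rbind, rows)
}
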