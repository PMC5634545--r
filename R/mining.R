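#' Repeated cross-validated sub-network selection
#'
#' Runs stratified k-fold cross-validation `cv_repeats` times (a fresh fold
#' partition per repeat). For each training fold the penalty and edge count
#' are tuned by inner cross-validation ([tune_snl()]), SNL is refit on the
#' whole training portion at the chosen setting, the top-k edges are
#' recorded, and a linear margin classifier on those edge features is scored
#' on the held-out fold. With the default 9 folds and 5 repeats the ledger
#' holds 45 training runs.
#'
#' @param V |E| x m vertex-value matrix for all sessions.
#' @param labels binary session labels.
#' @param dual the `edge_dual`.
#' @param config a `study_config`.
#' @param seed RNG seed (defaults to the config's).
#' @return an object of class `run_ledger`: a data-frame-like list with one
#'   entry per run (`repeat_id`, `fold_id`, `selected` vertex sets, `lam`,
#'   `k`, `accuracy`) plus `n_runs` and `n_vertices`.
#' @export
run_repeated_cv <- function(V, labels, dual, config = study_config(),
                            seed = config$rng_seed) {
  V <- as.matrix(V)
  y <- .as_label_factor(labels)
  validate_config(config)
  laplacian <- dual_laplacian(dual)
  runs <- vector("list", config$cv_folds * config$cv_repeats)
  i <- 0L
  for (rep_id in seq_len(config$cv_repeats)) {
    fold <- .stratified_folds(y, config$cv_folds, .derive_seed(seed, 11L, rep_id))
    for (fold_id in seq_len(config$cv_folds)) {
      tr <- fold != fold_id
      tuned <- tune_snl(V[, tr, drop = FALSE], y[tr], dual, laplacian,
                        lam_grid = config$lam_grid, k_grid = config$k_grid,
                        inner_folds = config$inner_folds,
                        ridge_eps = config$ridge_eps,
                        seed = .derive_seed(seed, 13L, rep_id, fold_id))
      fit <- snl_fit(V[, tr, drop = FALSE], y[tr], laplacian,
                     lam = tuned$lam, ridge_eps = config$ridge_eps)
      sel <- select_edges(fit, tuned$k, dual)$vertices
      acc <- .svm_accuracy(t(V[sel, tr, drop = FALSE]), droplevels(y[tr]),
                           t(V[sel, !tr, drop = FALSE]), y[!tr],
                           kernel = "linear")
      i <- i + 1L
      runs[[i]] <- list(repeat_id = rep_id, fold_id = fold_id,
                        selected = sel, lam = tuned$lam, k = tuned$k,
                        accuracy = acc, heldout = which(!tr))
    }
  }
  structure(list(runs = runs, n_runs = i, n_vertices = nrow(V)),
            class = "run_ledger")
}

#' @export
print.run_ledger <- function(x, ...) {
  accs <- vapply(x$runs, `[[`, numeric(1), "accuracy")
  cat(sprintf("Run ledger: %d runs, mean held-out accuracy %.3f\n",
              x$n_runs, mean(accs)))
  invisible(x)
}

#' Mine subgraphs conserved across cross-validation runs
#'
#' Enumerates every link-connected dual vertex set of size 1 to `max_edges`
#' that is contained in the selected set of at least
#' `ceiling(frequency_threshold * n_runs)` runs. Because dual vertices carry
#' unique identities (region pairs), frequent-connected-subgraph mining
#' degenerates to set inclusion: enumeration grows connected sets from
#' frequent single vertices and prunes by the antimonotone support bound
#' (growing a set never increases its support). All frequent connected
#' subgraphs are reported, not only maximal ones.
#'
#' @param ledger a `run_ledger`.
#' @param dual the `edge_dual`.
#' @param frequency_threshold fraction of runs required (in (0, 1\]).
#' @param max_edges largest subgraph size enumerated.
#' @return list of `subgraph_candidate` lists, each with `edges` (sorted
#'   dual vertex ids) and `support`; ordered by size then lexicographically.
#' @export
mine_conserved <- function(ledger, dual, frequency_threshold = 1 / 3,
                           max_edges = 8L) {
  stopifnot(inherits(ledger, "run_ledger"), inherits(dual, "edge_dual"))
  if (!(frequency_threshold > 0 && frequency_threshold <= 1))
    stop("frequency_threshold must lie in (0, 1]")
  if (!ledger$n_runs) stop("empty ledger")
  min_support <- as.integer(ceiling(frequency_threshold * ledger$n_runs))
  ne <- nrow(dual$pairs)
  runmat <- matrix(FALSE, ledger$n_runs, ne)
  for (r in seq_len(ledger$n_runs)) runmat[r, ledger$runs[[r]]$selected] <- TRUE
  support_of <- function(vs) {
    sum(rowSums(runmat[, vs, drop = FALSE]) == length(vs))
  }
  single_support <- colSums(runmat)
  frequent_single <- which(single_support >= min_support)
  if (!length(frequent_single)) return(list())
  allowed <- logical(ne); allowed[frequent_single] <- TRUE
  found <- new.env(parent = emptyenv())
  out <- list()
  frontier <- lapply(frequent_single, function(v) {
    assign(as.character(v), TRUE, envir = found)
    list(edges = v, support = as.integer(single_support[v]))
  })
  out <- frontier
  size <- 1L
  while (length(frontier) && size < max_edges) {
    nxt <- list()
    for (cand in frontier) {
      nb <- unique(unlist(dual$adjacency[cand$edges], use.names = FALSE))
      nb <- nb[allowed[nb] & !(nb %in% cand$edges)]
      for (w in nb) {
        vs <- sort(c(cand$edges, w))
        key <- paste(vs, collapse = ",")
        if (exists(key, envir = found, inherits = FALSE)) next
        assign(key, TRUE, envir = found)
        sup <- support_of(vs)
        if (sup >= min_support)
          nxt[[length(nxt) + 1L]] <- list(edges = vs, support = sup)
      }
    }
    out <- c(out, nxt)
    frontier <- nxt
    size <- size + 1L
  }
  keys <- vapply(out, function(s)
    paste(sprintf("%06d", c(length(s$edges), s$edges)), collapse = ","),
    character(1))
  out <- out[order(keys)]
  lapply(out, function(s) structure(s, class = "subgraph_candidate"))
}

#' Union biomarker regions of the significant subgraphs
#'
#' Takes the union of all edges of the given candidates and partitions it
#' into link-connected components (largest first). These are the biomarker
#' regions reported by the pipeline.
#'
#' @param candidates list of subgraph candidates (with `edges`).
#' @param dual the `edge_dual`.
#' @return list of sorted dual vertex id vectors, largest component first.
#' @export
merge_biomarker_regions <- function(candidates, dual) {
  edges <- sort(unique(unlist(lapply(candidates, `[[`, "edges"))))
  if (!length(edges)) return(list())
  dual_connected_components(edges, dual)
}
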