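#' Write the biomarker report
#'
#' Emits three artifacts under `out_dir`, all referencing regions through
#' the atlas (names plus explicit ids, never bare internal indices):
#' \itemize{
#'   \item `biomarker_edges.tsv` — one row per union-biomarker edge with the
#'     region-pair name, mean coherence in high- and low-label sessions, and
#'     the Pearson correlation of edge coherence with the continuous
#'     learning-rate drop-off;
#'   \item `subgraphs.json` — every conserved candidate as an edge list of
#'     region-id pairs with its support, accuracy, p-value and q-value;
#'   \item `biomarker_regions.graphml` — the union of significant-subgraph
#'     edges as a graph over named regions.
#' }
#'
#' @param fit a `biomarker_study` (or a plain list of subgraph candidates,
#'   in which case only `subgraphs.json` is written and `dual` is required).
#' @param atlas an `atlas_table`.
#' @param out_dir output directory (created if needed).
#' @param dual required when `fit` is a candidate list.
#' @return `out_dir`, invisibly.
#' @export
write_biomarker_report <- function(fit, atlas, out_dir, dual = NULL) {
  stopifnot(inherits(atlas, "atlas_table"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(fit, "biomarker_study")) {
    candidates <- fit$candidates
    dual <- fit$dual
  } else {
    candidates <- fit
    if (is.null(dual)) stop("dual required when writing a bare candidate list")
  }
  if (dual$n_regions != nrow(atlas))
    stop(sprintf("atlas defines %d regions but dual has %d",
                 nrow(atlas), dual$n_regions))

  cand_json <- lapply(candidates, function(s) {
    list(edges = lapply(s$edges, function(e)
           as.integer(dual$pairs[e, ])),
         edge_names = vapply(s$edges, function(e)
           paste(.region_name(atlas, dual$pairs[e, ]), collapse = " / "),
           character(1)),
         support = s$support,
         accuracy = if (is.null(s$accuracy)) NA else s$accuracy,
         p_value = if (is.null(s$p_value)) NA else s$p_value,
         q_value = if (is.null(s$q_value)) NA else s$q_value)
  })
  jsonlite::write_json(cand_json, file.path(out_dir, "subgraphs.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")

  if (inherits(fit, "biomarker_study")) {
    es <- fit$edge_summary
    if (is.null(es)) {
      es <- data.frame(vertex = integer(0), region_a = integer(0),
                       region_b = integer(0), mean_high = numeric(0),
                       mean_low = numeric(0), correlation = numeric(0))
    }
    tab <- data.frame(
      functional_edge = if (nrow(es))
        paste(.region_name(atlas, es$region_a), "/",
              .region_name(atlas, es$region_b)) else character(0),
      region_id_a = es$region_a,
      region_id_b = es$region_b,
      avg_high = es$mean_high,
      avg_low = es$mean_low,
      correlation_with_rate = es$correlation,
      stringsAsFactors = FALSE)
    .write_tsv(tab, file.path(out_dir, "biomarker_edges.tsv"))
    write_dual_graphml(fit$regions, dual, atlas,
                       file.path(out_dir, "biomarker_regions.graphml"))
  }
  invisible(out_dir)
}

#' Re-read a subgraph report
#'
#' Parses `subgraphs.json` back into the candidate representation (canonical
#' dual vertex ids), inverting [write_biomarker_report()].
#'
#' @param path path of `subgraphs.json`.
#' @param dual the `edge_dual` the report was written against.
#' @return list of subgraph candidates.
#' @export
read_biomarker_report <- function(path, dual) {
  raw <- jsonlite::read_json(path)
  key <- paste(dual$pairs[, 1L], dual$pairs[, 2L])
  lapply(raw, function(s) {
    ids <- vapply(s$edges, function(pr) {
      pr <- sort(as.integer(unlist(pr)))
      id <- match(paste(pr[1], pr[2]), key)
      if (is.na(id)) stop("unmappable region pair: ", paste(pr, collapse = ","))
      id
    }, integer(1))
    structure(list(edges = sort(ids),
                   support = as.integer(s$support),
                   accuracy = if (is.null(s$accuracy)) NULL else as.numeric(s$accuracy),
                   p_value = if (is.null(s$p_value)) NULL else as.numeric(s$p_value),
                   q_value = if (is.null(s$q_value)) NULL else as.numeric(s$q_value)),
              class = "subgraph_candidate")
  })
}

#' Write / read the cross-validation run ledger as JSON
#'
#' @param ledger a `run_ledger`.
#' @param path output path.
#' @export
write_run_ledger <- function(ledger, path) {
  stopifnot(inherits(ledger, "run_ledger"))
  jsonlite::write_json(
    list(n_runs = ledger$n_runs, n_vertices = ledger$n_vertices,
         runs = lapply(ledger$runs, function(r)
           list(repeat_id = r$repeat_id, fold_id = r$fold_id,
                selected = as.integer(r$selected), lam = r$lam, k = r$k,
                accuracy = r$accuracy, heldout = as.integer(r$heldout)))),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_ledger
#' @export
read_run_ledger <- function(path) {
  raw <- jsonlite::read_json(path)
  runs <- lapply(raw$runs, function(r)
    list(repeat_id = as.integer(r$repeat_id), fold_id = as.integer(r$fold_id),
         selected = sort(as.integer(unlist(r$selected))),
         lam = as.numeric(r$lam), k = as.integer(r$k),
         accuracy = as.numeric(r$accuracy),
         heldout = as.integer(unlist(r$heldout))))
  structure(list(runs = runs, n_runs = as.integer(raw$n_runs),
                 n_vertices = as.integer(raw$n_vertices)),
            class = "run_ledger")
}
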