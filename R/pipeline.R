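#' Mine significant subnetwork biomarkers
#'
#' The end-to-end mining procedure over a set of labeled session networks:
#' repeated stratified cross-validation with per-fold tuning and sub-network
#' learning ([run_repeated_cv()]), frequent-connected-subgraph mining of the
#' selections conserved across runs ([mine_conserved()]), and significance
#' testing of each conserved candidate against a uniform null of random
#' connected subgraphs of matching size, with empirical p-values, Storey
#' q-values, and retention at the FDR threshold.
#'
#' @param networks list of labeled `functional_network`s (or an |E| x m
#'   vertex-value matrix, in which case `labels` must be given and `dual`
#'   must match).
#' @param config a `study_config`.
#' @param labels optional binary labels (taken from the networks when
#'   missing).
#' @param dropoffs optional continuous drop-off per session (taken from the
#'   networks when present); enables the per-edge summary table.
#' @param seed RNG seed (defaults to the config's).
#' @return an object of class `biomarker_study` carrying the run `ledger`,
#'   all conserved `candidates` (with `support`, `accuracy`, `p_value`,
#'   `q_value`), the retained `significant` candidates, the union biomarker
#'   `regions`, per-edge `edge_summary` (when drop-offs are available), the
#'   `backgrounds` per size, the `dual`, and the inputs needed to reproduce
#'   the fit.
#' @examples
#' \donttest{
#' study <- generate_study(plant_spec(n_regions = 8, n_sessions_per_class = 9))
#' cfg <- study_config(cv_folds = 3, cv_repeats = 2,
#'                     background_samples_per_size = 100)
#' fit <- mine_biomarkers(study$networks, cfg)
#' print(fit)
#' }
#' @export
mine_biomarkers <- function(networks, config = study_config(), labels = NULL,
                            dropoffs = NULL, seed = config$rng_seed) {
  validate_config(config)
  if (is.list(networks) && length(networks) &&
      inherits(networks[[1]], "functional_network")) {
    n <- networks[[1]]$n_regions
    dual <- to_edge_dual(networks[[1]])
    V <- vapply(networks, vertex_values, numeric(nrow(dual$pairs)), dual = dual)
    if (is.null(labels)) labels <- vapply(networks, `[[`, character(1), "label")
    if (is.null(dropoffs)) {
      d <- vapply(networks, `[[`, numeric(1), "dropoff")
      if (all(is.finite(d))) dropoffs <- d
    }
  } else stop("networks must be a list of functional_network objects")
  y <- .as_label_factor(labels)

  ledger <- run_repeated_cv(V, y, dual, config, seed = .derive_seed(seed, 1L))
  candidates <- mine_conserved(ledger, dual,
                               frequency_threshold = config$frequency_threshold,
                               max_edges = config$max_subgraph_edges)
  backgrounds <- list()
  if (length(candidates)) {
    sizes <- sort(unique(vapply(candidates, function(s) length(s$edges),
                                integer(1))))
    sig_seed <- .derive_seed(seed, 2L)
    for (sz in sizes) {
      backgrounds[[as.character(sz)]] <- background_distribution(
        dual, sz, V, y, n_samples = config$background_samples_per_size,
        config = config, seed = sig_seed)
    }
    acc_seed <- .derive_seed(sig_seed, 19L)  # same fold scheme as backgrounds
    candidates <- lapply(candidates, function(s) {
      s$accuracy <- subgraph_accuracy(s$edges, V, y,
                                      folds = config$accuracy_folds,
                                      degree = config$svm_degree,
                                      mode = config$background_mode,
                                      seed = acc_seed)
      s$p_value <- empirical_pvalue(s$accuracy,
                                    backgrounds[[as.character(length(s$edges))]])
      s
    })
    qs <- compute_qvalues(vapply(candidates, `[[`, numeric(1), "p_value"))
    for (i in seq_along(candidates)) candidates[[i]]$q_value <- qs[i]
  }
  significant <- filter_significant(candidates, config$q_threshold)
  regions <- merge_biomarker_regions(significant, dual)
  edge_summary <- NULL
  if (!is.null(dropoffs) && length(regions)) {
    edge_summary <- summarize_edges(sort(unique(unlist(regions))), V, y,
                                    dropoffs, dual)
  }
  structure(list(ledger = ledger, candidates = candidates,
                 significant = significant, regions = regions,
                 edge_summary = edge_summary, backgrounds = backgrounds,
                 dual = dual, V = V, labels = as.character(y),
                 dropoffs = dropoffs, config = config, seed = seed),
            class = "biomarker_study")
}

#' @export
print.biomarker_study <- function(x, ...) {
  accs <- vapply(x$ledger$runs, `[[`, numeric(1), "accuracy")
  cat("Subnetwork biomarker study\n")
  cat(sprintf("  %d regions, %d dual vertices, %d sessions (%d high / %d low)\n",
              x$dual$n_regions, nrow(x$dual$pairs), ncol(x$V),
              sum(x$labels == "high"), sum(x$labels == "low")))
  cat(sprintf("  %d CV runs, mean held-out accuracy %.3f\n",
              x$ledger$n_runs, mean(accs)))
  cat(sprintf("  %d conserved candidates, %d significant (q <= %g), %d biomarker region(s)\n",
              length(x$candidates), length(x$significant),
              x$config$q_threshold, length(x$regions)))
  invisible(x)
}

#' @export
summary.biomarker_study <- function(object, ...) {
  x <- object
  df <- if (length(x$candidates)) {
    data.frame(
      edges = vapply(x$candidates, function(s)
        paste(x$dual$vertex_names[s$edges], collapse = "; "), character(1)),
      size = vapply(x$candidates, function(s) length(s$edges), integer(1)),
      support = vapply(x$candidates, `[[`, integer(1), "support"),
      accuracy = vapply(x$candidates, `[[`, numeric(1), "accuracy"),
      p_value = vapply(x$candidates, `[[`, numeric(1), "p_value"),
      q_value = vapply(x$candidates, `[[`, numeric(1), "q_value"),
      significant = vapply(x$candidates, function(s)
        s$q_value <= x$config$q_threshold, logical(1)),
      stringsAsFactors = FALSE)
  } else data.frame()
  structure(list(table = df, n_runs = x$ledger$n_runs,
                 n_regions = length(x$regions)),
            class = "summary.biomarker_study")
}

#' @export
print.summary.biomarker_study <- function(x, ...) {
  cat(sprintf("Conserved candidates (%d), from %d CV runs:\n",
              nrow(x$table), x$n_runs))
  if (nrow(x$table)) print(x$table, digits = 4)
  invisible(x)
}

#' @export
plot.biomarker_study <- function(x, ...) {
  if (!length(x$backgrounds)) {
    graphics::plot.new()
    graphics::title("No conserved candidates")
    return(invisible(x))
  }
  sizes <- names(x$backgrounds)
  old <- graphics::par(mfrow = c(1, length(sizes)))
  on.exit(graphics::par(old))
  for (sz in sizes) {
    bg <- x$backgrounds[[sz]]$accuracies
    graphics::hist(bg, breaks = 20, col = "grey85", border = "white",
                   xlim = c(min(bg, 0.4), 1), main = paste0(sz, "-edge null"),
                   xlab = "classification accuracy")
    cand <- Filter(function(s) length(s$edges) == as.integer(sz), x$candidates)
    for (s in cand)
      graphics::abline(v = s$accuracy,
                       col = if (s$q_value <= x$config$q_threshold) "red3" else "grey40",
                       lwd = 2)
  }
  invisible(x)
}

#' Label session networks from behavioral curves
#'
#' Fits the exponential drop-off of each session's movement-time curve and
#' applies the two-means pivot to split sessions into high/low learning
#' rate.
#'
#' @param networks list of `functional_network`s.
#' @param movement_times list of per-session movement-time vectors.
#' @param repeats clustering repetitions for the pivot.
#' @param seed RNG seed.
#' @return the networks with `label` and `dropoff` filled, plus the
#'   `labeling_result` as attribute `"labeling"`.
#' @export
label_networks <- function(networks, movement_times, repeats = 50L, seed = 1L) {
  if (length(networks) != length(movement_times))
    stop("one movement-time curve per network required")
  if (any(vapply(movement_times, is.null, logical(1))))
    stop("cannot label: session(s) without movement times")
  fits <- lapply(movement_times, fit_dropoff, seed = seed)
  kappas <- vapply(fits, `[[`, numeric(1), "kappa")
  lab <- estimate_label_threshold(kappas, repeats = repeats, seed = seed)
  out <- Map(function(nw, l, k) { nw$label <- l; nw$dropoff <- k; nw },
             networks, lab$labels, kappas)
  attr(out, "labeling") <- lab
  out
}

#' Run the full pipeline and write all artifacts
#'
#' Executes the stages in order — build networks (or take the study's direct
#' coherence matrices), fit drop-offs and label, mine conserved subgraphs,
#' score significance, write the biomarker report — and records a manifest.
#' Rerunning with the same config and seed reproduces every artifact
#' byte for byte.
#'
#' @param study a `synthetic_study` (from [generate_study()]) or a list of
#'   `session_record`s.
#' @param config a `study_config`.
#' @param out_dir output directory (created if needed).
#' @param atlas an `atlas_table`; defaults to the study's.
#' @return the `biomarker_study`, invisibly; artifacts and `manifest.json`
#'   under `out_dir`.
#' @export
run_pipeline <- function(study, config = study_config(), out_dir,
                         atlas = NULL) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)
  if (inherits(study, "synthetic_study")) {
    if (is.null(atlas)) atlas <- study$atlas
    if (!is.null(study$networks)) {
      networks <- study$networks
      mts <- study$movement_times
    } else {
      networks <- lapply(study$sessions, build_network,
                         band = config$frequency_band)
      mts <- lapply(study$sessions, `[[`, "movement_times")
      stages <- c(stages, "build-networks")
    }
  } else if (is.list(study) && length(study) &&
             inherits(study[[1]], "session_record")) {
    networks <- lapply(study, build_network, band = config$frequency_band)
    mts <- lapply(study, `[[`, "movement_times")
    stages <- c(stages, "build-networks")
  } else stop("study must be a synthetic_study or a list of session_record")
  if (is.null(atlas)) atlas <- atlas_table(networks[[1]]$regions)

  networks <- label_networks(networks, mts, repeats = config$label_repeats,
                             seed = .derive_seed(config$rng_seed, 41L))
  stages <- c(stages, "label")
  labeling <- attr(networks, "labeling")

  # per-session coherence matrices and labels
  net_dir <- file.path(out_dir, "networks")
  dir.create(net_dir, showWarnings = FALSE)
  for (i in seq_along(networks)) {
    .write_tsv(as.data.frame(networks[[i]]$coherence, check.names = FALSE),
               file.path(net_dir, sprintf("session_%03d.tsv", i)),
               full_precision = TRUE)
  }
  .write_tsv(data.frame(session = seq_along(networks),
                        dropoff = vapply(networks, `[[`, numeric(1), "dropoff"),
                        label = vapply(networks, `[[`, character(1), "label")),
             file.path(out_dir, "labels.tsv"), full_precision = TRUE)

  fit <- mine_biomarkers(networks, config)
  stages <- c(stages, "mine", "significance")

  write_run_ledger(fit$ledger, file.path(out_dir, "ledger.json"))
  write_biomarker_report(fit, atlas, out_dir)
  stages <- c(stages, "report")

  cfg_path <- file.path(out_dir, "config.yaml")
  write_config(config, cfg_path)
  manifest <- list(stages = stages,
                   seed = config$rng_seed,
                   n_sessions = length(networks),
                   n_regions = networks[[1]]$n_regions,
                   n_runs = fit$ledger$n_runs,
                   labeling_threshold = labeling$threshold,
                   labeling_stability = labeling$stability,
                   n_candidates = length(fit$candidates),
                   n_significant = length(fit$significant),
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   outputs = list(networks = "networks/",
                                  labels = "labels.tsv",
                                  ledger = "ledger.json",
                                  candidates = "subgraphs.json",
                                  edge_table = "biomarker_edges.tsv",
                                  union_graph = "biomarker_regions.graphml"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(fit)
}
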