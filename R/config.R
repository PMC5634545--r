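#' Study configuration
#'
#' Bundles every tunable parameter of the biomarker-mining pipeline with the
#' defaults used throughout: the 0.06--0.12 Hz coherence band, 9-fold
#' cross-validation repeated 5 times, a conservation threshold of one third of
#' the runs, and an FDR (q-value) cutoff of 0.015.
#'
#' @param frequency_band numeric length-2, coherence band in Hz (low, high).
#' @param cv_folds number of outer cross-validation folds.
#' @param cv_repeats number of times the outer cross-validation is repeated.
#' @param frequency_threshold fraction of runs a subgraph must be selected in
#'   to count as conserved.
#' @param q_threshold FDR cutoff; candidates with q-value at or below it are
#'   retained.
#' @param max_subgraph_edges largest conserved subgraph size enumerated.
#' @param background_samples_per_size random connected subgraphs sampled per
#'   subgraph size when building the null accuracy distribution.
#' @param rng_seed base seed; every randomized stage derives its own stream
#'   from it.
#' @param lam_grid candidate topology-penalty weights for the inner grid
#'   search.
#' @param k_grid candidate numbers of selected edges for the inner grid
#'   search.
#' @param inner_folds folds of the inner (tuning) cross-validation.
#' @param ridge_eps relative ridge added to the projection metric
#'   (scaled by trace of the metric over its dimension).
#' @param svm_degree polynomial kernel degree for background/candidate
#'   accuracy.
#' @param accuracy_folds folds used when cross-validating subgraph accuracy.
#' @param background_mode `"cv"` (cross-validated, default) or
#'   `"resubstitution"` accuracy for null subgraphs and candidates.
#' @param label_repeats repetitions of the two-means clustering used to fix
#'   the labeling pivot.
#' @param sampler_burnin_per_edge,sampler_thin_per_edge Metropolis chain
#'   burn-in and thinning, in steps per subgraph edge.
#'
#' @return an object of class `study_config` (a validated list).
#' @seealso [read_config()], [write_config()]
#' @export
study_config <- function(frequency_band = c(0.06, 0.12),
                         cv_folds = 9L,
                         cv_repeats = 5L,
                         frequency_threshold = 1 / 3,
                         q_threshold = 0.015,
                         max_subgraph_edges = 8L,
                         background_samples_per_size = 1000L,
                         rng_seed = 1L,
                         lam_grid = c(0.01, 0.1, 1),
                         k_grid = c(2L, 4L, 8L),
                         inner_folds = 3L,
                         ridge_eps = 1e-8,
                         svm_degree = 3L,
                         accuracy_folds = 3L,
                         background_mode = c("cv", "resubstitution"),
                         label_repeats = 50L,
                         sampler_burnin_per_edge = 100L,
                         sampler_thin_per_edge = 5L) {
  cfg <- list(frequency_band = as.numeric(frequency_band),
              cv_folds = as.integer(cv_folds),
              cv_repeats = as.integer(cv_repeats),
              frequency_threshold = as.numeric(frequency_threshold),
              q_threshold = as.numeric(q_threshold),
              max_subgraph_edges = as.integer(max_subgraph_edges),
              background_samples_per_size = as.integer(background_samples_per_size),
              rng_seed = as.integer(rng_seed),
              lam_grid = as.numeric(lam_grid),
              k_grid = as.integer(k_grid),
              inner_folds = as.integer(inner_folds),
              ridge_eps = as.numeric(ridge_eps),
              svm_degree = as.integer(svm_degree),
              accuracy_folds = as.integer(accuracy_folds),
              background_mode = match.arg(background_mode),
              label_repeats = as.integer(label_repeats),
              sampler_burnin_per_edge = as.integer(sampler_burnin_per_edge),
              sampler_thin_per_edge = as.integer(sampler_thin_per_edge))
  validate_config(cfg)
  structure(cfg, class = "study_config")
}

validate_config <- function(cfg) {
  stopifnot(length(cfg$frequency_band) == 2L)
  if (!(cfg$frequency_band[1] > 0 && cfg$frequency_band[1] < cfg$frequency_band[2]))
    stop("frequency_band must satisfy 0 < low < high")
  if (cfg$cv_folds < 2L) stop("cv_folds must be >= 2")
  if (cfg$cv_repeats < 1L) stop("cv_repeats must be >= 1")
  for (nm in c("frequency_threshold", "q_threshold")) {
    v <- cfg[[nm]]
    if (!(v > 0 && v <= 1)) stop(nm, " must lie in (0, 1]")
  }
  if (!length(cfg$lam_grid) || !length(cfg$k_grid))
    stop("lam_grid and k_grid must be non-empty")
  if (any(cfg$lam_grid < 0)) stop("lam_grid entries must be >= 0")
  if (any(cfg$k_grid < 1L)) stop("k_grid entries must be >= 1")
  if (cfg$ridge_eps <= 0) stop("ridge_eps must be positive")
  invisible(cfg)
}

#' Read / write a study configuration as YAML
#'
#' @param path file path of the YAML configuration.
#' @return `read_config()` returns a `study_config`; `write_config()` returns
#'   the path invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(study_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  do.call(study_config, raw)
}

#' @rdname read_config
#' @param config a `study_config` object.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' @export
print.study_config <- function(x, ...) {
  cat("Study configuration\n")
  cat(sprintf("  coherence band:      %.3f-%.3f Hz\n",
              x$frequency_band[1], x$frequency_band[2]))
  cat(sprintf("  cross-validation:    %d-fold x %d repeats (%d runs)\n",
              x$cv_folds, x$cv_repeats, x$cv_folds * x$cv_repeats))
  cat(sprintf("  conservation:        selected in >= %.3f of runs\n",
              x$frequency_threshold))
  cat(sprintf("  significance:        q <= %g, %d null samples/size\n",
              x$q_threshold, x$background_samples_per_size))
  cat(sprintf("  grids:               lambda {%s}, k {%s}, %d inner folds\n",
              paste(x$lam_grid, collapse = ", "),
              paste(x$k_grid, collapse = ", "), x$inner_folds))
  cat(sprintf("  rng seed:            %d\n", x$rng_seed))
  invisible(x)
}
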