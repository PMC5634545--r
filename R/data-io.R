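#' Atlas tables
#'
#' An atlas table maps contiguous region ids (0-based, matching all on-disk
#' artifacts) to anatomical region names, optionally with a hemisphere tag.
#' All outputs of the package reference regions through the atlas; internal
#' matrix indices never leak to disk.
#'
#' @param region_name character vector of unique region names.
#' @param hemisphere optional character vector of hemisphere tags.
#' @return a `data.frame` of class `atlas_table` with columns `region_id`,
#'   `region_name` and (optionally) `hemisphere`.
#' @export
atlas_table <- function(region_name, hemisphere = NULL) {
  region_name <- as.character(region_name)
  if (anyDuplicated(region_name)) stop("atlas region names must be unique")
  df <- data.frame(region_id = seq_along(region_name) - 1L,
                   region_name = region_name,
                   stringsAsFactors = FALSE)
  if (!is.null(hemisphere)) df$hemisphere <- as.character(hemisphere)
  structure(df, class = c("atlas_table", "data.frame"))
}

#' @rdname atlas_table
#' @param path path of a tab-separated atlas file with columns `region_id`,
#'   `region_name` and optional `hemisphere`.
#' @export
read_atlas <- function(path) {
  df <- .read_tsv(path)
  if (!all(c("region_id", "region_name") %in% names(df)))
    stop("atlas file must have columns region_id and region_name: ", path)
  df <- df[order(df$region_id), , drop = FALSE]
  if (!identical(as.integer(df$region_id), seq_len(nrow(df)) - 1L))
    stop("atlas region_id must be a contiguous, duplicate-free 0-based range")
  atlas_table(df$region_name,
              hemisphere = if ("hemisphere" %in% names(df)) df$hemisphere)
}

#' @rdname atlas_table
#' @param atlas an `atlas_table`.
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "atlas_table"))
  .write_tsv(as.data.frame(atlas), path)
  invisible(path)
}

.region_name <- function(atlas, id) {
  pos <- match(id, atlas$region_id)
  if (anyNA(pos)) stop("region id(s) not in atlas: ",
                       paste(id[is.na(pos)], collapse = ", "))
  atlas$region_name[pos]
}

#' Session records
#'
#' A session record holds one experimental session: the regional activity
#' time-series matrix (time points x regions), the sampling interval (TR, in
#' seconds) and the behavioral curve (movement time per trial bin, seconds).
#'
#' @param subject_id,session_id identifiers.
#' @param timeseries numeric matrix, T time points x N regions, with region
#'   names as column names.
#' @param sampling_interval seconds per sample.
#' @param movement_times numeric vector of per-trial-bin movement times, or
#'   `NULL` when no behavior was recorded (labeling will then fail
#'   explicitly).
#' @return an object of class `session_record`.
#' @export
session_record <- function(subject_id, session_id, timeseries,
                           sampling_interval = 2, movement_times = NULL) {
  timeseries <- as.matrix(timeseries)
  if (nrow(timeseries) < 2L || ncol(timeseries) < 2L)
    stop("time series must have at least 2 time points and 2 regions")
  if (!all(is.finite(timeseries)))
    stop("time series contains non-finite values")
  if (is.null(colnames(timeseries)))
    stop("time-series columns must be named with region names")
  if (!is.null(movement_times)) {
    movement_times <- as.numeric(movement_times)
    if (any(!is.finite(movement_times)) || any(movement_times <= 0))
      stop("movement times must be finite and strictly positive")
  }
  structure(list(subject_id = as.character(subject_id),
                 session_id = as.character(session_id),
                 timeseries = timeseries,
                 sampling_interval = as.numeric(sampling_interval),
                 movement_times = movement_times),
            class = "session_record")
}

#' Read a session from disk
#'
#' The time-series file is tab-separated with a mandatory header row of
#' region names and one row per time point. The optional behavior file has
#' columns `trial_bin` and `movement_time`. When an atlas is supplied the
#' columns are matched by name and reordered into atlas order; a header name
#' absent from the atlas is an error naming the offending region.
#'
#' @param timeseries_path path to the time-series TSV.
#' @param behavior_path path to the behavior TSV, or `NULL`.
#' @param subject_id,session_id identifiers for the record.
#' @param atlas optional `atlas_table` used to validate and order regions.
#' @param sampling_interval seconds per sample (TR).
#' @return a `session_record`.
#' @export
read_session <- function(timeseries_path, behavior_path = NULL,
                         subject_id = "S", session_id = basename(timeseries_path),
                         atlas = NULL, sampling_interval = 2) {
  df <- .read_tsv(timeseries_path)
  ts <- as.matrix(df)
  storage.mode(ts) <- "double"
  if (!all(is.finite(ts)))
    stop("non-finite values in time-series file: ", timeseries_path)
  if (!is.null(atlas)) {
    missing_regions <- setdiff(colnames(ts), atlas$region_name)
    if (length(missing_regions))
      stop("region(s) not in atlas: ", paste(missing_regions, collapse = ", "))
    if (ncol(ts) != nrow(atlas))
      stop(sprintf("session has %d regions but atlas defines %d",
                   ncol(ts), nrow(atlas)))
    ts <- ts[, atlas$region_name, drop = FALSE]
  }
  mt <- NULL
  if (!is.null(behavior_path)) {
    bdf <- .read_tsv(behavior_path)
    if (!all(c("trial_bin", "movement_time") %in% names(bdf)))
      stop("behavior file must have columns trial_bin and movement_time")
    mt <- bdf$movement_time[order(bdf$trial_bin)]
  }
  session_record(subject_id, session_id, ts,
                 sampling_interval = sampling_interval, movement_times = mt)
}

#' @rdname read_session
#' @param session a `session_record`.
#' @export
write_session <- function(session, timeseries_path, behavior_path = NULL) {
  stopifnot(inherits(session, "session_record"))
  df <- as.data.frame(session$timeseries, check.names = FALSE)
  .write_tsv(df, timeseries_path, full_precision = TRUE)
  if (!is.null(behavior_path)) {
    if (is.null(session$movement_times))
      stop("session has no movement times to write")
    bdf <- data.frame(trial_bin = seq_along(session$movement_times) - 1L,
                      movement_time = session$movement_times)
    .write_tsv(bdf, behavior_path, full_precision = TRUE)
  }
  invisible(timeseries_path)
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("Session %s/%s: %d time points x %d regions (TR %.3g s)%s\n",
              x$subject_id, x$session_id, nrow(x$timeseries),
              ncol(x$timeseries), x$sampling_interval,
              if (is.null(x$movement_times)) ", no behavior"
              else sprintf(", %d trial bins", length(x$movement_times))))
  invisible(x)
}
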