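#' Specification of a planted synthetic study
#'
#' Describes a fully synthetic study: session coherence networks over
#' `n_regions` with a planted, connected, class-discriminative edge set, and
#' exponential-decay behavioral curves per class. Planted edges have their
#' mean coherence shifted by `+shift/2` in high-label sessions and
#' `-shift/2` in low-label sessions; all other edges are label-independent.
#'
#' @param n_regions number of regions (>= 3).
#' @param n_sessions_per_class sessions per class.
#' @param planted_edges integer matrix of 0-based region pairs (one row per
#'   planted edge); must form a connected edge set. Default: the 3-edge star
#'   0-1, 1-2, 1-3.
#' @param coherence_shift difference in mean planted-edge coherence between
#'   the classes, in (0, 1).
#' @param base_coherence mean coherence of unplanted edges.
#' @param noise_sd session-to-session coherence standard deviation.
#' @param dropoff_params list with `kappa_high`, `kappa_low`, `A`, `B`,
#'   `noise` for the behavioral curves `MT(b) = A exp(-kappa b) + B + noise`.
#' @param n_trial_bins behavioral curve length.
#' @param rng_seed base seed.
#' @return an object of class `plant_spec`.
#' @export
plant_spec <- function(n_regions = 20L, n_sessions_per_class = 27L,
                       planted_edges = rbind(c(0L, 1L), c(1L, 2L), c(1L, 3L)),
                       coherence_shift = 0.25, base_coherence = 0.5,
                       noise_sd = 0.15,
                       dropoff_params = list(kappa_high = 0.5, kappa_low = 0.05,
                                             A = 2, B = 1, noise = 0.05),
                       n_trial_bins = 20L, rng_seed = 1L) {
  n_regions <- as.integer(n_regions)
  planted_edges <- matrix(as.integer(planted_edges), ncol = 2L)
  planted_edges <- t(apply(planted_edges, 1L, sort))
  if (any(planted_edges < 0L) || any(planted_edges >= n_regions) ||
      any(planted_edges[, 1L] == planted_edges[, 2L]))
    stop("planted edges must be pairs of distinct region ids in 0..n_regions-1")
  if (!(coherence_shift >= 0 && coherence_shift < 1))
    stop("coherence_shift must lie in [0, 1)")
  lo <- base_coherence - coherence_shift
  hi <- base_coherence + coherence_shift
  if (!(lo > 0 && hi < 1))
    stop("infeasible coherence bounds: base +/- shift must stay inside (0, 1)")
  spec <- structure(list(n_regions = n_regions,
                         n_sessions_per_class = as.integer(n_sessions_per_class),
                         planted_edges = planted_edges,
                         coherence_shift = coherence_shift,
                         base_coherence = base_coherence,
                         noise_sd = noise_sd,
                         dropoff_params = dropoff_params,
                         n_trial_bins = as.integer(n_trial_bins),
                         rng_seed = as.integer(rng_seed)),
                    class = "plant_spec")
  dual <- to_edge_dual(n_regions)
  vids <- .planted_vertex_ids(spec, dual)
  if (!.dual_is_connected(vids, dual))
    stop("planted edges must form a connected edge set")
  spec
}

# Canonical dual vertex ids of the planted edges.
.planted_vertex_ids <- function(spec, dual) {
  key <- paste(dual$pairs[, 1L], dual$pairs[, 2L])
  sort(match(paste(spec$planted_edges[, 1L], spec$planted_edges[, 2L]), key))
}

# Draw from N(mean, sd) truncated to (lo, hi) by redraw.
.rnorm_trunc <- function(n, mean, sd, lo = 0, hi = 1) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= lo | out >= hi)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean[pmin(bad, length(mean))], sd)
    bad <- which(out <= lo | out >= hi)
  }
  out
}

#' Generate a synthetic study
#'
#' Two generation modes. `"coherence"` (fast, default) draws session
#' coherence matrices directly: every edge is truncated-normal around its
#' class-conditional mean, so the statistical machinery downstream of
#' network construction is exercised without a signal-processing front end.
#' `"timeseries"` synthesizes regional time series from shared band-limited
#' (0.06--0.12 Hz) latent oscillators so that the estimated coherence
#' approximates the same planted structure; planted pairs additionally share
#' an oscillator whose coupling differs between classes, which exercises the
#' whole pipeline through [band_coherence()].
#'
#' Behavioral curves follow `MT(b) = A exp(-kappa_class b) + B + noise` over
#' trial bins, with `kappa_high`/`kappa_low` per class.
#'
#' @param spec a `plant_spec`.
#' @param mode `"coherence"` or `"timeseries"`.
#' @param n_timepoints,sampling_interval time-series mode dimensions.
#' @param seed RNG seed (defaults to the spec's).
#' @return a list of class `synthetic_study` with `networks` (labeled
#'   `functional_network`s in coherence mode, else `NULL`), `sessions`
#'   (`session_record`s in time-series mode, else `NULL`),
#'   `movement_times`, `labels`, `planted_vertices` (canonical dual ids),
#'   `atlas`, and the generating `spec`.
#' @export
generate_study <- function(spec, mode = c("coherence", "timeseries"),
                           n_timepoints = 256L, sampling_interval = 2,
                           seed = spec$rng_seed) {
  stopifnot(inherits(spec, "plant_spec"))
  mode <- match.arg(mode)
  n <- spec$n_regions
  m <- 2L * spec$n_sessions_per_class
  labels <- rep(c("high", "low"), each = spec$n_sessions_per_class)
  dual <- to_edge_dual(n)
  planted <- .planted_vertex_ids(spec, dual)
  atlas <- atlas_table(sprintf("region_%03d", seq_len(n) - 1L))
  dp <- spec$dropoff_params
  b <- seq_len(spec$n_trial_bins) - 1
  movement_times <- .with_seed(.derive_seed(seed, 23L), lapply(seq_len(m), function(s) {
    kappa <- if (labels[s] == "high") dp$kappa_high else dp$kappa_low
    mt <- dp$A * exp(-kappa * b) + dp$B
    if (dp$noise > 0) mt <- mt + stats::rnorm(length(b), sd = dp$noise)
    pmax(mt, 0.05)
  }))
  networks <- NULL
  sessions <- NULL
  if (mode == "coherence") {
    ne <- nrow(dual$pairs)
    networks <- .with_seed(.derive_seed(seed, 29L), lapply(seq_len(m), function(s) {
      mu <- rep(spec$base_coherence, ne)
      mu[planted] <- spec$base_coherence +
        if (labels[s] == "high") spec$coherence_shift / 2 else -spec$coherence_shift / 2
      vals <- .rnorm_trunc(ne, mu, spec$noise_sd)
      C <- matrix(0, n, n)
      C[cbind(dual$pairs[, 1L] + 1L, dual$pairs[, 2L] + 1L)] <- vals
      C <- C + t(C)
      diag(C) <- 1
      dimnames(C) <- list(atlas$region_name, atlas$region_name)
      functional_network(C, label = labels[s])
    }))
  } else {
    sessions <- .with_seed(.derive_seed(seed, 31L), lapply(seq_len(m), function(s) {
      X <- .synthesize_session_timeseries(spec, labels[s], n_timepoints,
                                          sampling_interval)
      colnames(X) <- atlas$region_name
      session_record(sprintf("sub%02d", (s - 1L) %/% 3L + 1L),
                     sprintf("ses%03d", s), X,
                     sampling_interval = sampling_interval,
                     movement_times = movement_times[[s]])
    }))
  }
  structure(list(networks = networks, sessions = sessions,
                 movement_times = movement_times, labels = labels,
                 planted_vertices = planted, atlas = atlas, spec = spec),
            class = "synthetic_study")
}

# Band-limited unit-variance noise via FFT masking.
.band_noise <- function(nt, dt, band) {
  f <- c(seq(0, floor(nt / 2)), seq(-ceiling(nt / 2) + 1, -1)) / (nt * dt)
  mask <- abs(f) >= band[1] & abs(f) <= band[2]
  z <- stats::fft(stats::rnorm(nt))
  z[!mask] <- 0
  x <- Re(stats::fft(z, inverse = TRUE)) / nt
  x / stats::sd(x)
}

# One session's time series: every region mixes a global band-limited
# oscillator (baseline coherence), a per-planted-edge shared oscillator whose
# coupling is present only in high-label sessions, a private band-limited
# component and white noise. The shared band power of a pair approximates its
# target coherence.
.synthesize_session_timeseries <- function(spec, label, nt, dt,
                                           band = c(0.06, 0.12)) {
  n <- spec$n_regions
  pe <- spec$planted_edges
  g <- .band_noise(nt, dt, band)
  shared <- lapply(seq_len(nrow(pe)), function(i) .band_noise(nt, dt, band))
  w_shift <- if (label == "high") spec$coherence_shift else 0
  X <- matrix(0, nt, n)
  for (r in seq_len(n) - 1L) {
    x <- sqrt(spec$base_coherence) * g
    w_used <- spec$base_coherence
    if (w_shift > 0) {
      for (i in seq_len(nrow(pe))) {
        if (r %in% pe[i, ]) {
          x <- x + sqrt(w_shift) * shared[[i]]
          w_used <- w_used + w_shift
        }
      }
    }
    w_priv <- max(0.05, 1 - w_used)
    x <- x + sqrt(w_priv) * .band_noise(nt, dt, band) + 0.25 * stats::rnorm(nt)
    X[, r + 1L] <- x
  }
  X
}

#' Worked 4-region example network
#'
#' A deterministic fully connected 4-region network with distinct edge
#' coherence values, used for the edge-dual counting identities: its clique
#' has 6 edges and its edge-dual graph has 6 vertices and 12 links.
#'
#' @return a `functional_network` on 4 regions.
#' @export
fig2_fixture <- function() {
  C <- matrix(1, 4, 4)
  vals <- c(0.15, 0.25, 0.35, 0.45, 0.55, 0.65)
  C[upper.tri(C)] <- vals
  C[lower.tri(C)] <- t(C)[lower.tri(C)]
  dimnames(C) <- list(paste0("region_", 0:3), paste0("region_", 0:3))
  functional_network(C)
}
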