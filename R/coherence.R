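#' Functional coherence networks
#'
#' A functional network is an N-region symmetric matrix of pairwise
#' band-limited coherence values in \[0, 1\]; the diagonal is ignored. The
#' implied graph is the clique on all regions, so it has N(N-1)/2 edges. A
#' network may carry a binary global-state label (`"high"`/`"low"` learning
#' rate) and the continuous drop-off parameter it was derived from.
#'
#' @param coherence symmetric numeric matrix with off-diagonal entries in
#'   \[0, 1\].
#' @param label `"high"`, `"low"`, or `NA` when unlabeled.
#' @param dropoff optional learning-rate drop-off parameter of the session.
#' @param regions optional character vector of region names (defaults to the
#'   matrix dimnames).
#' @return an object of class `functional_network`.
#' @export
functional_network <- function(coherence, label = NA_character_,
                               dropoff = NA_real_, regions = NULL) {
  coherence <- as.matrix(coherence)
  n <- nrow(coherence)
  if (n < 2L || ncol(coherence) != n)
    stop("coherence must be a square matrix with N >= 2")
  if (max(abs(coherence - t(coherence))) > 1e-10)
    stop("coherence matrix must be symmetric")
  off <- coherence[upper.tri(coherence)]
  if (any(!is.finite(off)) || any(off < 0) || any(off > 1))
    stop("off-diagonal coherence values must be finite and in [0, 1]")
  coherence <- (coherence + t(coherence)) / 2
  diag(coherence) <- 1
  if (is.null(regions)) regions <- colnames(coherence)
  if (is.null(regions)) regions <- sprintf("region_%03d", seq_len(n) - 1L)
  dimnames(coherence) <- list(regions, regions)
  if (!is.na(label) && !label %in% c("high", "low"))
    stop("label must be 'high', 'low' or NA")
  structure(list(n_regions = n, coherence = coherence, regions = regions,
                 label = label, dropoff = as.numeric(dropoff)),
            class = "functional_network")
}

#' @export
print.functional_network <- function(x, ...) {
  cat(sprintf("Functional network: %d regions, %d edges, label: %s\n",
              x$n_regions, x$n_regions * (x$n_regions - 1L) / 2L,
              if (is.na(x$label)) "unlabeled" else x$label))
  invisible(x)
}

# Continuous wavelet transform (analytic Morlet) of one series at the given
# frequencies (Hz), via FFT. Returns a complex matrix T x length(freqs).
.morlet_cwt <- function(x, dt, freqs, omega0 = 6) {
  n <- length(x)
  w <- 2 * pi * c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) / (n * dt)
  fx <- stats::fft(x - mean(x))
  out <- matrix(0i, n, length(freqs))
  for (j in seq_along(freqs)) {
    s <- omega0 / (2 * pi * freqs[j])
    daughter <- ifelse(w > 0,
                       sqrt(2 * pi * s / dt) * pi^(-0.25) *
                         exp(-(s * w - omega0)^2 / 2),
                       0)
    out[, j] <- stats::fft(fx * daughter, inverse = TRUE) / n
  }
  out
}

# Moving-average smoothing along time (columns are frequencies), reflecting
# at the boundaries so the window never shrinks. Complex input (cross
# spectra) is smoothed componentwise.
.smooth_time <- function(m, win) {
  if (is.complex(m))
    return(.smooth_time(Re(m), win) + 1i * .smooth_time(Im(m), win))
  win <- max(3L, as.integer(win))
  if (win %% 2L == 0L) win <- win + 1L
  h <- (win - 1L) %/% 2L
  n <- nrow(m)
  idx <- c(rev(seq_len(h) + 1L), seq_len(n), n - seq_len(h))
  padded <- m[idx, , drop = FALSE]
  kern <- rep(1 / win, win)
  res <- apply(padded, 2L, function(col)
    as.numeric(stats::filter(col, kern, sides = 2L)))
  matrix(res[(h + 1L):(h + n), ], nrow = n)
}

# Per-band fixed frequency bins (midpoints) spanning [low, high].
.band_bins <- function(band, n_bins = 6L) {
  edges <- seq(band[1], band[2], length.out = n_bins + 1L)
  (edges[-1] + edges[-length(edges)]) / 2
}

# Core smoothed spectra for a set of series at the band bins. Returns a list
# with the CWTs, smoothed auto-spectra and per-frequency smoothing windows /
# edge trims, so build_network() can reuse them across all pairs.
.band_spectra <- function(X, dt, band, n_bins = 6L, omega0 = 6) {
  freqs <- .band_bins(band, n_bins)
  scales <- omega0 / (2 * pi * freqs)
  # Adjacent wavelet coefficients decorrelate over about one scale, so the
  # smoothing window must span several scales to average independent
  # spectral estimates (otherwise the coherence of unrelated series is
  # biased toward 1).
  wins <- pmin(pmax(9L, round(20 * scales / dt)), nrow(X) %/% 2L)
  trims <- pmin(nrow(X) %/% 4L, ceiling(sqrt(2) * scales / dt))
  W <- lapply(seq_len(ncol(X)), function(j) .morlet_cwt(X[, j], dt, freqs, omega0))
  Sauto <- lapply(W, function(wj) {
    s <- Mod(wj)^2
    for (k in seq_along(freqs)) s[, k] <- .smooth_time(s[, k, drop = FALSE], wins[k])
    s
  })
  list(W = W, Sauto = Sauto, freqs = freqs, wins = wins, trims = trims, n = nrow(X))
}

# Band-averaged magnitude-squared coherence for one pair, given spectra.
.pair_coherence <- function(sp, a, b) {
  vals <- numeric(length(sp$freqs))
  for (k in seq_along(sp$freqs)) {
    cross <- .smooth_time(matrix(sp$W[[a]][, k] * Conj(sp$W[[b]][, k]), ncol = 1L),
                          sp$wins[k])
    msc <- Mod(cross)^2 / (sp$Sauto[[a]][, k] * sp$Sauto[[b]][, k])
    keep <- seq.int(sp$trims[k] + 1L, sp$n - sp$trims[k])
    vals[k] <- mean(msc[keep, 1L])
  }
  min(1, max(0, mean(vals)))
}

#' Band-limited magnitude-squared coherence of two series
#'
#' Computes magnitude-squared wavelet coherence (analytic Morlet transform,
#' time-smoothed spectra) averaged over fixed frequency bins covering the
#' requested band. Values lie in \[0, 1\]; identical series give 1 by
#' construction, and the estimate is invariant to rescaling either input by
#' a positive constant.
#'
#' @param x,y numeric series of equal length (at least 32 samples).
#' @param sampling_interval seconds per sample.
#' @param band numeric length-2 frequency band in Hz, inside (0, Nyquist).
#' @param n_bins number of fixed frequency bins spanning the band.
#' @return a coherence value in \[0, 1\].
#' @examples
#' x <- sin(2 * pi * 0.09 * seq(0, 2, by = 2/128) * 64) + rnorm(129, sd = 0.1)
#' band_coherence(x, x, sampling_interval = 2, band = c(0.06, 0.12))
#' @export
band_coherence <- function(x, y, sampling_interval, band = c(0.06, 0.12),
                           n_bins = 6L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 32L) stop("need at least 32 samples")
  nyquist <- 1 / (2 * sampling_interval)
  if (!(band[1] > 0 && band[1] < band[2] && band[2] <= nyquist))
    stop(sprintf("band must lie inside (0, %.4g Hz] (Nyquist)", nyquist))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate signal: zero-variance input series")
  sp <- .band_spectra(cbind(x, y), sampling_interval, band, n_bins)
  .pair_coherence(sp, 1L, 2L)
}

#' Build a session's functional network
#'
#' Populates all N(N-1)/2 pairwise band-limited coherence values for a
#' session's regional time series. The wavelet transforms and smoothed
#' auto-spectra are computed once per region and shared across pairs.
#'
#' @param session a `session_record`.
#' @param band frequency band in Hz.
#' @param n_bins fixed frequency bins spanning the band.
#' @return an unlabeled `functional_network`.
#' @export
build_network <- function(session, band = c(0.06, 0.12), n_bins = 6L) {
  stopifnot(inherits(session, "session_record"))
  X <- session$timeseries
  if (nrow(X) < 32L) stop("need at least 32 time points to estimate coherence")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0))
    stop("degenerate signal: zero-variance time series for region(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  nyquist <- 1 / (2 * session$sampling_interval)
  if (!(band[1] > 0 && band[1] < band[2] && band[2] <= nyquist))
    stop(sprintf("band must lie inside (0, %.4g Hz] (Nyquist)", nyquist))
  n <- ncol(X)
  sp <- .band_spectra(X, session$sampling_interval, band, n_bins)
  C <- diag(n)
  for (a in seq_len(n - 1L)) {
    for (b in seq.int(a + 1L, n)) {
      C[a, b] <- C[b, a] <- .pair_coherence(sp, a, b)
    }
  }
  dimnames(C) <- list(colnames(X), colnames(X))
  functional_network(C)
}
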