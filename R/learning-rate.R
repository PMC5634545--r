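#' Fit the exponential drop-off of a behavioral curve
#'
#' Motor learning shows an exponential drop-off of movement time across trial
#' bins. The model fitted here is `MT(b) = A * exp(-kappa * b) + B` over bins
#' `b = 0, 1, ...`, with the decay rate constrained to `kappa >= 0` and an
#' asymptote `B` (movement time cannot decay to zero). `kappa` is the
#' learning-rate drop-off used downstream for labeling: a large `kappa`
#' marks a fast-learning session.
#'
#' Fitting is nonlinear least squares (Levenberg-Marquardt) from a
#' deterministic initializer (`A = MT[1] - MT[last]`, `B = MT[last]`,
#' `kappa = 1 / (max(B, 0.1) * nbins)`), with five jittered restarts under a
#' fixed seed; the best sum of squares wins, so the result is deterministic.
#'
#' @param movement_times positive numeric vector, one value per trial bin
#'   (at least 4 bins).
#' @param seed seed for the jittered restarts.
#' @return a list with elements `kappa`, `A`, `B`, `residual` (residual
#'   norm) and `fitted`.
#' @examples
#' mt <- 2 * exp(-0.5 * (0:19)) + 1
#' fit_dropoff(mt)$kappa
#' @export
fit_dropoff <- function(movement_times, seed = 1L) {
  mt <- as.numeric(movement_times)
  if (length(mt) < 4L) stop("need at least 4 trial bins")
  if (any(!is.finite(mt)) || any(mt <= 0))
    stop("movement times must be finite and strictly positive")
  b <- seq_along(mt) - 1
  if (diff(range(mt)) < 1e-12) {
    return(list(kappa = 0, A = 0, B = mt[1], residual = 0, fitted = mt))
  }
  A0 <- mt[1] - mt[length(mt)]
  B0 <- mt[length(mt)]
  k0 <- min(2, max(1e-3, 1 / (max(B0, 0.1) * length(mt))))
  starts <- list(c(A = A0, kappa = k0, B = B0))
  .with_seed(seed, {
    for (r in seq_len(5L)) {
      starts[[r + 1L]] <- c(A = A0 * exp(stats::rnorm(1, sd = 0.5)),
                            kappa = min(2, k0 * exp(stats::rnorm(1, sd = 1))),
                            B = B0 * exp(stats::rnorm(1, sd = 0.2)))
    }
  })
  best <- NULL
  diagnostics <- character(0)
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(mt ~ A * exp(-kappa * b) + B,
                        start = as.list(st),
                        lower = c(A = -Inf, kappa = 0, B = 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      diagnostics <- c(diagnostics, conditionMessage(fit))
      next
    }
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("drop-off fit failed to converge after restarts: ",
         paste(unique(diagnostics), collapse = "; "))
  cf <- stats::coef(best$fit)
  list(kappa = unname(cf["kappa"]), A = unname(cf["A"]), B = unname(cf["B"]),
       residual = sqrt(best$rss), fitted = as.numeric(stats::fitted(best$fit)))
}

#' Two-group labeling threshold for drop-off values
#'
#' Clusters the drop-off values into two groups many times (1-D two-means
#' with random initial centers), adopts the modal partition across
#' repetitions, and uses the midpoint between that partition's cluster
#' centers as the labeling pivot. Sessions with drop-off above the pivot are
#' labeled `"high"`. Ties between equally frequent partitions go to the one
#' with the larger between-center gap. `stability` is the fraction of
#' repetitions that produced the modal partition.
#'
#' @param dropoffs numeric vector of session drop-off values (at least 4,
#'   not all identical).
#' @param repeats number of clustering repetitions.
#' @param seed RNG seed.
#' @return a list of class `labeling_result` with `threshold`, `labels`
#'   (character `"high"`/`"low"`), `stability`, and the modal cluster
#'   `centers`.
#' @export
estimate_label_threshold <- function(dropoffs, repeats = 50L, seed = 1L) {
  x <- as.numeric(dropoffs)
  if (length(x) < 4L) stop("need at least 4 sessions")
  if (any(!is.finite(x))) stop("drop-off values must be finite")
  if (diff(range(x)) < 1e-12)
    stop("degenerate clustering: all drop-off values identical, no label split possible")
  # A 1-D 2-means partition is an interval split; identify it by the size of
  # the lower cluster so repetitions can be tallied.
  keys <- integer(repeats)
  gaps <- numeric(repeats)
  centers <- vector("list", repeats)
  ux <- unique(x)
  .with_seed(seed, {
    for (r in seq_len(repeats)) {
      init <- sort(sample(ux, 2L))
      km <- stats::kmeans(x, centers = matrix(init, ncol = 1L))
      cen <- sort(as.numeric(km$centers))
      keys[r] <- sum(x <= mean(cen))
      gaps[r] <- diff(cen)
      centers[[r]] <- cen
    }
  })
  tab <- table(keys)
  modal_keys <- as.integer(names(tab)[tab == max(tab)])
  if (length(modal_keys) > 1L) {
    gap_by_key <- vapply(modal_keys, function(k) max(gaps[keys == k]), numeric(1))
    modal <- modal_keys[which.max(gap_by_key)]
  } else modal <- modal_keys
  rep_idx <- which(keys == modal)[1L]
  cen <- centers[[rep_idx]]
  pivot <- mean(cen)
  structure(list(threshold = pivot,
                 labels = ifelse(x > pivot, "high", "low"),
                 stability = max(tab) / repeats,
                 centers = cen),
            class = "labeling_result")
}

#' @export
print.labeling_result <- function(x, ...) {
  cat(sprintf("Labeling pivot %.4g (stability %.2f): %d high / %d low\n",
              x$threshold, x$stability,
              sum(x$labels == "high"), sum(x$labels == "low")))
  invisible(x)
}
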