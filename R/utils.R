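# Internal helpers shared across modules.

# Derive a child seed from a base seed and integer offsets; stays below 2^31.
.derive_seed <- function(seed, ...) {
  off <- c(...)
  s <- as.double(seed)
  for (o in off) s <- (s * 69069 + as.double(o) + 1) %% 2147483647
  as.integer(s)
}

# Evaluate expr with a local RNG state so callers' streams are untouched.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# sample() safe for length-1 vectors
.sample1 <- function(x) x[sample.int(length(x), 1L)]

.is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x) && x >= 1

# Stratified fold assignment: returns integer vector in 1..k, each class
# spread as evenly as possible over folds. Errors if any fold would miss a
# class entirely (every class must have >= k members).
.stratified_folds <- function(labels, k, seed) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2L)
    stop("exactly two classes required, got: ", paste(classes, collapse = ", "))
  if (any(table(labels) < k))
    stop("stratification impossible: a class has fewer than ", k, " sessions")
  fold <- integer(length(labels))
  .with_seed(seed, {
    for (cl in classes) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# Column-wise cosine similarity of a matrix (features x samples).
.cosine_similarity <- function(V) {
  nrm <- sqrt(colSums(V^2))
  if (any(nrm == 0)) stop("zero-norm session vector: cosine similarity undefined")
  S <- crossprod(sweep(V, 2L, nrm, "/"))
  S[S > 1] <- 1
  S[S < -1] <- -1
  S
}

# Train an SVM on rows of `x` and report accuracy on `xt`.
# `x`, `xt`: numeric matrices (samples x features); `y`, `yt`: factors.
.svm_accuracy <- function(x, y, xt, yt, kernel = "linear", degree = 3L, cost = 1) {
  fit <- e1071::svm(x = x, y = y, kernel = kernel, degree = degree, cost = cost,
                    coef0 = if (kernel == "polynomial") 1 else 0,
                    scale = FALSE, probability = FALSE)
  mean(predict(fit, xt) == yt)
}

# Cross-validated SVM accuracy with stratified folds and a fixed seed.
.cv_svm_accuracy <- function(x, y, folds, seed, kernel = "linear", degree = 3L) {
  fold <- .stratified_folds(y, folds, seed)
  acc <- vapply(seq_len(folds), function(f) {
    tr <- fold != f
    .svm_accuracy(x[tr, , drop = FALSE], droplevels(y[tr]),
                  x[!tr, , drop = FALSE], y[!tr], kernel = kernel, degree = degree)
  }, numeric(1))
  mean(acc)
}

.as_label_factor <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("low", "high"))
  if (length(bad)) stop("labels must be 'high'/'low', got: ", paste(bad, collapse = ", "))
  factor(labels, levels = c("low", "high"))
}

# Format numerics at full double precision for on-disk text tables so that
# write -> read round-trips are bit exact.
.fmt_full <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else as.character(x)
}

.write_tsv <- function(df, path, full_precision = FALSE) {
  out <- df
  if (full_precision)
    for (j in seq_along(out)) if (is.double(out[[j]])) out[[j]] <- .fmt_full(out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
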