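#' Data transformations
#'
#' Three built-in matrix transformations can be applied before scoring: a
#' step (thresholding) function, rank-based quantile normalization, and
#' per-feature z-standardization. Transformations are applied to the full
#' matrix *before* signature subsetting, because quantile and z statistics
#' need the full feature background.
#'
#' @name transformers
NULL

#' Step transformation
#'
#' Replaces every finite value `x` by the number of thresholds `t` with
#' `t <= x`, an integer in `0..length(thresholds)` (left-closed intervals).
#' Missing values stay missing.
#'
#' @param m Expression matrix.
#' @param thresholds Strictly increasing, non-empty numeric vector.
#' @return Transformed matrix, same dimensions and dimnames.
#' @examples
#' m <- matrix(c(-2, 0, 3), 1, dimnames = list("g1", c("a", "b", "c")))
#' transform_step(m, thresholds = 0)
#' @export
transform_step <- function(m, thresholds) {
  m <- as_expression_matrix(m)
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) == 0L) stop("thresholds must be non-empty", call. = FALSE)
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing", call. = FALSE)
  }
  out <- matrix(
    findInterval(m, thresholds),
    nrow = nrow(m), dimnames = dimnames(m)
  )
  out[is.na(m)] <- NA_real_
  storage.mode(out) <- "double"
  out
}

#' Quantile normalization
#'
#' Classic rank-based quantile normalization across columns: each column is
#' sorted, the per-rank mean across columns forms the reference
#' distribution, and each value is replaced by the reference value at its
#' within-column rank. Ties within a column receive the mean of the
#' reference values over their tied rank span. Afterwards every column has
#' exactly the same sorted values.
#'
#' @param m Expression matrix without missing values.
#' @return Transformed matrix.
#' @export
transform_quantile_norm <- function(m) {
  m <- as_expression_matrix(m)
  if (anyNA(m)) {
    stop("quantile normalization requires a complete matrix; impute missing values first",
         call. = FALSE)
  }
  n <- nrow(m)
  sorted <- apply(m, 2, sort)
  if (is.null(dim(sorted))) sorted <- matrix(sorted, nrow = n)
  ref <- rowMeans(sorted)
  out <- m
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    o <- order(x)
    vals <- x[o]
    # positions of tied runs in the sorted column share the mean reference
    run <- cumsum(c(TRUE, vals[-1] != vals[-n]))
    rep_ref <- stats::ave(ref, run, FUN = mean)
    out[o, j] <- rep_ref
  }
  out
}

#' Z-standardization
#'
#' Centers each feature (row) by its mean and scales by its sample standard
#' deviation (denominator n-1), over non-missing entries. Rows with zero
#' standard deviation, or fewer than two non-missing entries, become all
#' zeros with a warning.
#'
#' @param m Expression matrix.
#' @return Transformed matrix.
#' @export
transform_zscore <- function(m) {
  m <- as_expression_matrix(m)
  mu <- rowMeans(m, na.rm = TRUE)
  s <- apply(m, 1, stats::sd, na.rm = TRUE)
  n_ok <- rowSums(!is.na(m))
  degenerate <- is.na(s) | s == 0 | n_ok < 2
  if (any(degenerate)) {
    warning(sum(degenerate), " feature(s) with zero variance or < 2 values set to 0: ",
            paste(utils::head(rownames(m)[degenerate], 5), collapse = ", "),
            call. = FALSE)
    s[degenerate] <- 1
    mu[degenerate] <- 0
  }
  out <- (m - mu) / s
  out[degenerate, ] <- 0
  out[is.na(m)] <- NA_real_
  out
}

transform_ids <- c("identity", "step", "quantile_norm", "zscore")

#' Apply a named transformation
#'
#' Dispatch helper used by the orchestrator and CLI: `"identity"` returns
#' the matrix unchanged, the other IDs call the corresponding
#' `transform_*()` function.
#'
#' @param m Expression matrix.
#' @param transform One of `"identity"`, `"step"`, `"quantile_norm"`,
#'   `"zscore"`, or a function taking and returning a matrix.
#' @param step_thresholds Thresholds for `transform = "step"`.
#' @return Transformed matrix.
#' @export
apply_transform <- function(m, transform = "identity", step_thresholds = NULL) {
  if (is.function(transform)) return(as_expression_matrix(transform(m)))
  transform <- match.arg(transform, transform_ids)
  switch(transform,
    identity = as_expression_matrix(m),
    step = transform_step(m, step_thresholds),
    quantile_norm = transform_quantile_norm(m),
    zscore = transform_zscore(m)
  )
}
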