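#' Available scorers
#'
#' @return Character vector of all scorer IDs understood by [sig_scores()]
#'   and [score_samples()].
#' @export
list_scorers <- function() c(simple_scorer_ids, matrix_scorer_ids)

simple_scorer_ids <- c("sum", "weightedSum", "mean", "trimmedMean",
                       "weightedMean", "median", "mode", "midrange",
                       "midhinge", "trimean", "iqr", "iqm", "mad", "aad")

matrix_scorer_ids <- c("combinedZ", "pca1", "plage", "ssgsea", "gsva")

#' Subset an expression matrix to a signature
#'
#' Restricts rows to the signature's features (in signature order), keeping
#' the aligned weights. Features absent from the matrix are dropped with a
#' warning; an empty intersection is an error.
#'
#' @param m Expression matrix.
#' @param signature A [new_signature()] object.
#' @return A list with `matrix` (the submatrix), `features` (used IDs) and
#'   `weights` (aligned numeric weights).
#' @export
subset_signature <- function(m, signature) {
  if (!is.matrix(m)) m <- as_expression_matrix(m)
  stopifnot(inherits(signature, "tidysig_signature"))
  present <- signature$features %in% rownames(m)
  if (!any(present)) {
    stop("signature '", signature$name, "' shares no features with the matrix",
         call. = FALSE)
  }
  if (any(!present)) {
    warning("signature '", signature$name, "': ", sum(!present),
            " feature(s) absent from the matrix: ",
            paste(utils::head(signature$features[!present], 5), collapse = ", "),
            call. = FALSE)
  }
  feats <- signature$features[present]
  list(matrix = m[feats, , drop = FALSE],
       features = feats,
       weights = signature$weights[present])
}

#' Score a single vector of signature values
#'
#' Computes one of the simple (per-sample, vector-based) scorers on the
#' values of a signature's features in one sample. Quartile-based summaries
#' (median, midhinge, trimean, iqr, iqm) use type-7 linearly interpolated
#' quartiles throughout.
#'
#' Scorer definitions, on the non-missing values `v` with aligned weights
#' `w` (all weights default 1):
#' \describe{
#'   \item{sum, mean}{plain total / arithmetic mean}
#'   \item{weightedSum, weightedMean}{`sum(w*v)` and `sum(w*v)/sum(w)`;
#'     a zero weight total yields `NA` with a warning}
#'   \item{trimmedMean}{mean after dropping `floor(trim * n)` smallest and
#'     largest values}
#'   \item{median}{type-7 second quartile}
#'   \item{mode}{most frequent exact value; ties take the smallest; a
#'     warning is emitted when all values are distinct}
#'   \item{midrange, midhinge, trimean}{`(min+max)/2`, `(Q1+Q3)/2`,
#'     `(Q1+2*Q2+Q3)/4`}
#'   \item{iqr}{`Q3 - Q1`}
#'   \item{iqm}{interquartile mean: mean of the central half of the sorted
#'     data, with fractional end-weights when `n` is not divisible by 4}
#'   \item{mad}{median absolute deviation from the median, by default
#'     without the 1.4826 normal-consistency constant}
#'   \item{aad}{average absolute deviation from the mean}
#' }
#'
#' @param values Numeric vector (one sample's values over the signature).
#' @param scorer One of the simple scorer IDs (see [list_scorers()]).
#' @param weights Optional weights aligned with `values`.
#' @param trim Trim fraction for `trimmedMean`, in `[0, 0.5)`.
#' @param mad_constant If `TRUE`, multiply `mad` by 1.4826.
#' @param na_rm Drop missing values (with their weights) first.
#' @return A single number, or `NA` when no usable values remain.
#' @examples
#' score_vector(c(1, 2, 3, 4, 5), "trimean")
#' score_vector(c(5, 2, 1), "weightedSum", weights = c(1, -1, 1))
#' @export
score_vector <- function(values, scorer, weights = NULL, trim = 0.1,
                         mad_constant = FALSE, na_rm = TRUE) {
  scorer <- match.arg(scorer, simple_scorer_ids)
  if (trim < 0 || trim >= 0.5) stop("trim must be in [0, 0.5)", call. = FALSE)
  v <- as.numeric(values)
  w <- if (is.null(weights)) rep(1, length(v)) else as.numeric(weights)
  if (length(w) != length(v)) stop("weights/values length mismatch", call. = FALSE)
  if (na_rm) {
    keep <- !is.na(v)
    v <- v[keep]
    w <- w[keep]
  } else if (anyNA(v)) {
    return(NA_real_)
  }
  n <- length(v)
  if (n == 0L) return(NA_real_)

  q <- function(p) unname(stats::quantile(v, p, type = 7, names = FALSE))
  switch(scorer,
    sum = sum(v),
    weightedSum = sum(w * v),
    mean = sum(v) / n,
    weightedMean = {
      if (sum(w) == 0) {
        warning("weightedMean: weights sum to zero; score is NA", call. = FALSE)
        NA_real_
      } else sum(w * v) / sum(w)
    },
    trimmedMean = {
      lo <- floor(trim * n)
      sv <- sort(v)
      mean(sv[(lo + 1L):(n - lo)])
    },
    median = q(0.5),
    mode = {
      ux <- unique(v)
      counts <- tabulate(match(v, ux))
      if (max(counts) == 1L && n > 1L) {
        warning("mode: all values distinct; returning the minimum", call. = FALSE)
      }
      min(ux[counts == max(counts)])
    },
    midrange = (min(v) + max(v)) / 2,
    midhinge = (q(0.25) + q(0.75)) / 2,
    trimean = (q(0.25) + 2 * q(0.5) + q(0.75)) / 4,
    iqr = q(0.75) - q(0.25),
    iqm = interquartile_mean(v),
    mad = {
      k <- if (mad_constant) 1.4826 else 1
      k * stats::median(abs(v - stats::median(v)))
    },
    aad = mean(abs(v - mean(v)))
  )
}

# mean of the central half of the sorted data: observation i occupies the
# mass interval [i-1, i); mass inside [n/4, 3n/4) is that observation's
# weight, so end observations get fractional weight when n %% 4 != 0
interquartile_mean <- function(v) {
  n <- length(v)
  sv <- sort(v)
  lo <- n / 4
  hi <- 3 * n / 4
  i <- seq_len(n)
  wt <- pmax(0, pmin(i, hi) - pmax(i - 1, lo))
  sum(wt * sv) / (n / 2)
}
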