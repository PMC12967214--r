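#' Simulate an expression matrix with an embedded signature signal
#'
#' Generates an i.i.d. baseline matrix (normal or log-normal), designates
#' features `1..k` as the true signature, and adds an effect `delta` (on
#' the baseline sampling scale) to the signature features within the first
#' `n_positive` sample columns. Within-signature correlation is not
#' simulated: features are independent, so the generator captures a clean
#' mean-shift signal, not the co-expression structure of real signatures.
#'
#' @param n_features,n_samples Matrix dimensions.
#' @param k Signature size (`k <= n_features`).
#' @param n_positive Number of signal-carrying samples
#'   (`<= n_samples`); they are the first columns.
#' @param delta Effect size added to signature features in positive
#'   samples, on the baseline scale (for `"lognormal"` the shift is added
#'   to the underlying normal, i.e. it is multiplicative on the data
#'   scale).
#' @param baseline `"normal"` or `"lognormal"`.
#' @param mu,sigma Baseline location and scale (`sigma > 0`).
#' @param seed Integer seed; generation is fully deterministic.
#' @return A list with `matrix` (features x samples), `signature` (a
#'   [new_signature()] named `"true_signature"`) and `labels` (a tibble
#'   with `sample_id` and logical `positive`).
#' @examples
#' sim <- simulate_signature_data(50, 20, k = 10, n_positive = 10, delta = 1)
#' dim(sim$matrix)
#' @export
simulate_signature_data <- function(n_features, n_samples, k, n_positive,
                                    delta = 1,
                                    baseline = c("normal", "lognormal"),
                                    mu = 0, sigma = 1, seed = 1L) {
  baseline <- match.arg(baseline)
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (k > n_features) stop("k exceeds n_features", call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (n_positive > n_samples) stop("n_positive exceeds n_samples", call. = FALSE)
  set.seed(as.integer(seed))
  base <- matrix(stats::rnorm(n_features * n_samples, mu, sigma),
                 n_features, n_samples)
  if (n_positive > 0 && delta != 0) {
    base[seq_len(k), seq_len(n_positive)] <-
      base[seq_len(k), seq_len(n_positive)] + delta
  }
  m <- if (baseline == "lognormal") exp(base) else base
  rownames(m) <- sprintf("g%04d", seq_len(n_features))
  colnames(m) <- sprintf("s%03d", seq_len(n_samples))
  list(
    matrix = m,
    signature = new_signature("true_signature", rownames(m)[seq_len(k)]),
    labels = tibble::tibble(
      sample_id = colnames(m),
      positive = seq_len(n_samples) <= n_positive
    )
  )
}

#' Signal-recovery AUC
#'
#' Area under the ROC curve of per-sample scores against binary truth
#' labels, via the rank-sum (Mann-Whitney) identity; tied scores
#' contribute 1/2 per tied positive-negative pair.
#'
#' @param scores Numeric per-sample scores (no missing values).
#' @param labels Logical (or coercible) vector; `TRUE` = positive.
#' @return AUC in `[0, 1]`.
#' @examples
#' recovery_auc(c(1, 2, 3, 4), c(FALSE, TRUE, FALSE, TRUE)) # 0.75
#' @export
recovery_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels must have the same length", call. = FALSE)
  }
  if (anyNA(scores) || anyNA(labels)) stop("missing values not allowed", call. = FALSE)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("need at least one positive and one negative label", call. = FALSE)
  }
  r <- rank(scores) # average ranks handle ties as 1/2 wins
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
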