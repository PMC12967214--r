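#' Combined z-score
#'
#' Row-standardizes the signature submatrix (feature-wise z-scores across
#' samples) and scores sample `j` as `sum(z[, j]) / sqrt(k_j)`, where `k_j`
#' counts the non-missing z entries for that sample. Constant features
#' contribute z = 0 (with a warning); if every signature feature is
#' constant, all scores are missing.
#'
#' @param m Expression matrix (needs >= 2 samples).
#' @param signature A [new_signature()] object.
#' @return A list with `score` (named numeric per sample) and `n_used`
#'   (integer per sample).
#' @export
score_combined_z <- function(m, signature) {
  sub <- subset_signature(m, signature)
  x <- sub$matrix
  if (ncol(x) < 2L) stop("combinedZ needs >= 2 samples", call. = FALSE)
  sds <- apply(x, 1, stats::sd, na.rm = TRUE)
  if (all(is.na(sds) | sds == 0)) {
    warning("combinedZ: all signature features constant; scores are NA",
            call. = FALSE)
    return(list(score = stats::setNames(rep(NA_real_, ncol(x)), colnames(x)),
                n_used = stats::setNames(rep(0L, ncol(x)), colnames(x))))
  }
  z <- suppressWarnings(transform_zscore(x))
  k <- colSums(!is.na(z))
  score <- ifelse(k > 0, colSums(z, na.rm = TRUE) / sqrt(k), NA_real_)
  list(score = stats::setNames(score, colnames(x)),
       n_used = stats::setNames(as.integer(k), colnames(x)))
}

require_complete <- function(x, scorer) {
  if (anyNA(x)) {
    stop(scorer, " requires a complete (no missing values) signature submatrix",
         call. = FALSE)
  }
}

# orient a score vector so it correlates non-negatively with a reference
# per-sample mean; undefined correlation (zero variance) leaves the sign
orient_sign <- function(score, reference) {
  r <- suppressWarnings(stats::cor(score, reference))
  if (!is.na(r) && r < 0) -score else score
}

#' First-principal-component score
#'
#' Centers each signature feature across samples and returns sample
#' coordinates on the first principal axis of the centered submatrix (the
#' direction of maximal variance across samples). The sign is oriented so
#' scores correlate non-negatively with the per-sample signature mean.
#'
#' @inheritParams score_combined_z
#' @return A list with `score` and `n_used` as in [score_combined_z()].
#' @export
score_pca1 <- function(m, signature) {
  sub <- subset_signature(m, signature)
  x <- sub$matrix
  if (ncol(x) < 2L) stop("pca1 needs >= 2 samples", call. = FALSE)
  require_complete(x, "pca1")
  xc <- x - rowMeans(x)
  n_used <- stats::setNames(rep(nrow(x), ncol(x)), colnames(x))
  if (all(xc == 0)) {
    warning("pca1: centered submatrix is all zeros; scores are 0", call. = FALSE)
    return(list(score = stats::setNames(rep(0, ncol(x)), colnames(x)),
                n_used = as.integer(n_used)))
  }
  sv <- svd(xc, nu = 0, nv = 1)
  score <- sv$d[1] * sv$v[, 1]
  score <- orient_sign(score, colMeans(x))
  list(score = stats::setNames(score, colnames(x)), n_used = as.integer(n_used))
}

#' PLAGE score
#'
#' Pathway-level activity: z-standardize each signature feature across
#' samples, take the first right singular vector of the standardized
#' submatrix (unit Euclidean norm) as the per-sample activity, oriented to
#' correlate non-negatively with the per-sample mean of the standardized
#' values.
#'
#' @inheritParams score_combined_z
#' @return A list with `score` and `n_used` as in [score_combined_z()].
#' @export
score_plage <- function(m, signature) {
  sub <- subset_signature(m, signature)
  x <- sub$matrix
  if (ncol(x) < 2L) stop("plage needs >= 2 samples", call. = FALSE)
  require_complete(x, "plage")
  sds <- apply(x, 1, stats::sd)
  if (all(sds == 0)) {
    warning("plage: all signature features constant; scores are NA", call. = FALSE)
    return(list(score = stats::setNames(rep(NA_real_, ncol(x)), colnames(x)),
                n_used = stats::setNames(rep(0L, ncol(x)), colnames(x))))
  }
  z <- suppressWarnings(transform_zscore(x))
  sv <- svd(z, nu = 0, nv = 1)
  score <- sv$v[, 1]
  score <- orient_sign(score, colMeans(z))
  list(score = stats::setNames(score, colnames(x)),
       n_used = stats::setNames(rep(nrow(x), ncol(x)), colnames(x)))
}

#' Single-sample GSEA score
#'
#' For each sample independently, all matrix features are ranked by
#' expression; the enrichment score is the sum over the descending-ordered
#' feature list of the difference between the weighted in-signature
#' cumulative distribution (weights = rank^alpha) and the unweighted
#' out-of-signature cumulative distribution. Ties in expression are broken
#' by ascending feature-ID order, making scores fully deterministic.
#' Missing values are dropped per sample (the universe shrinks
#' accordingly).
#'
#' @inheritParams score_combined_z
#' @param alpha Rank-weighting exponent (> 0 unless exactly 0 for pure
#'   counts); default 0.25.
#' @param normalize If `TRUE`, divide all scores by `max - min` across
#'   samples.
#' @return A list with `score` and `n_used` (in-signature features with a
#'   usable value per sample).
#' @export
score_ssgsea <- function(m, signature, alpha = 0.25, normalize = FALSE) {
  m <- as_expression_matrix(m)
  sub <- subset_signature(m, signature)
  if (length(sub$features) >= nrow(m)) {
    stop("ssgsea: signature covers every matrix feature; no background remains",
         call. = FALSE)
  }
  in_sig_all <- rownames(m) %in% sub$features
  ids <- rownames(m)
  score <- n_used <- stats::setNames(rep(NA_real_, ncol(m)), colnames(m))
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    ok <- !is.na(x)
    xs <- x[ok]
    in_sig <- in_sig_all[ok]
    N <- length(xs)
    k <- sum(in_sig)
    n_used[j] <- k
    if (k == 0L || k == N) next
    ord <- order(-xs, ids[ok])
    ranks_desc <- N - seq_len(N) + 1 # rank of the i-th walked feature
    in_ord <- in_sig[ord]
    w <- ifelse(in_ord, ranks_desc^alpha, 0)
    p_in <- cumsum(w) / sum(w)
    p_out <- cumsum(!in_ord) / (N - k)
    score[j] <- sum(p_in - p_out)
  }
  if (normalize) {
    rng <- range(score, na.rm = TRUE)
    if (diff(rng) > 0) score <- score / diff(rng)
  }
  list(score = score, n_used = stats::setNames(as.integer(n_used), colnames(m)))
}

#' GSVA-style score
#'
#' Three stages per the original gene set variation analysis recipe:
#' (1) each feature's expression is turned into a kernel-estimated
#' cumulative statistic, `zhat[i, j] = mean_k pnorm((x[i,j] - x[i,k]) / h_i)`
#' with Gaussian bandwidth `h_i = sd_i / 4`; (2) per sample, `zhat` is
#' ranked descending and converted to the symmetric rank statistic
#' `t = |N/2 - rank|`; (3) a Kolmogorov-Smirnov-like random walk down the
#' ranked list adds `t^tau` (normalized by the in-signature total) at
#' in-signature features and subtracts `1/(N-k)` elsewhere; the enrichment
#' score is the maximum positive deviation plus the minimum negative
#' deviation of the walk.
#'
#' Constant features get `zhat = 0.5` for all samples with a warning.
#' Rank ties are broken by ascending feature-ID order.
#'
#' @inheritParams score_combined_z
#' @param tau Weight exponent on the symmetric rank statistic; default 1.
#' @return A list with `score` and `n_used` as in [score_combined_z()].
#' @export
score_gsva <- function(m, signature, tau = 1) {
  m <- as_expression_matrix(m)
  if (ncol(m) < 3L) stop("gsva needs >= 3 samples", call. = FALSE)
  require_complete(m, "gsva")
  sub <- subset_signature(m, signature)
  if (length(sub$features) >= nrow(m)) {
    stop("gsva: signature covers every matrix feature; no background remains",
         call. = FALSE)
  }
  N <- nrow(m)
  n <- ncol(m)
  k <- length(sub$features)
  in_sig <- rownames(m) %in% sub$features
  ids <- rownames(m)

  zhat <- matrix(NA_real_, N, n, dimnames = dimnames(m))
  zero_sd <- logical(N)
  for (i in seq_len(N)) {
    x <- m[i, ]
    s <- stats::sd(x)
    if (s == 0) {
      zero_sd[i] <- TRUE
      zhat[i, ] <- 0.5
      next
    }
    h <- max(s / 4, 1e-12 * max(1, abs(mean(x))))
    zhat[i, ] <- rowMeans(stats::pnorm(outer(x, x, "-") / h))
  }
  if (any(zero_sd)) {
    warning("gsva: ", sum(zero_sd), " zero-variance feature(s) set to zhat = 0.5",
            call. = FALSE)
  }

  score <- stats::setNames(rep(NA_real_, n), colnames(m))
  for (j in seq_len(n)) {
    ord <- order(-zhat[, j], ids)
    r <- integer(N)
    r[ord] <- seq_len(N)
    t_stat <- abs(N / 2 - r)
    in_ord <- in_sig[ord]
    t_ord <- t_stat[ord]
    denom <- sum(t_stat[in_sig]^tau)
    incr <- ifelse(in_ord,
                   if (denom > 0) t_ord^tau / denom else 0,
                   -1 / (N - k))
    walk <- cumsum(incr)
    score[j] <- max(0, max(walk)) + min(0, min(walk))
  }
  list(score = score,
       n_used = stats::setNames(rep(k, n), colnames(m)))
}
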