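# Counter-based child-seed derivation: deterministically mixes a master
# seed with arbitrary key components (replicate index, signature name,
# scorer id) into a seed in [0, 2^31 - 2], so replicate streams are
# independent of execution order and of the number of parallel workers.
# Chained LCG-style mixing mod 2^31 - 1; the multiplier keeps every
# intermediate product exactly representable in doubles.
derive_seed <- function(master, ...) {
  m <- 2147483647 # 2^31 - 1
  h <- as.numeric(master) %% m
  for (key in list(...)) {
    ints <- if (is.character(key)) utf8ToInt(paste(key, collapse = "\r"))
            else as.numeric(key)
    for (k in ints) {
      h <- (h * 69069 + (k %% m) + 1) %% m
    }
    h <- (h * 69069 + 97) %% m
  }
  as.integer(h)
}

#' Resample an expression matrix within samples
#'
#' Perturbs the data by resampling each sample column's values across
#' features, independently per column: with replacement draws i.i.d. from
#' the column's values; without replacement applies a uniform random
#' permutation (each column keeps exactly its multiset of values). Feature
#' identity is destroyed while each sample's value distribution is
#' preserved. Uses the current RNG state; seed beforehand for
#' reproducibility.
#'
#' @param m Expression matrix.
#' @param replace Draw with replacement (`TRUE`) or permute (`FALSE`).
#' @return A matrix with the same dimensions and dimnames.
#' @export
resample_matrix <- function(m, replace = FALSE) {
  resample_core(as_expression_matrix(m), replace)
}

resample_core <- function(m, replace) {
  n <- nrow(m)
  out <- m
  for (j in seq_len(ncol(m))) {
    idx <- if (replace) sample.int(n, n, replace = TRUE) else sample.int(n)
    out[, j] <- m[idx, j]
  }
  out
}

#' Draw random same-size signatures from a background pool
#'
#' Each of the `B` signatures has exactly `k` distinct features drawn
#' uniformly without replacement from `pool` (overlap with any original
#' signature is permitted and expected); all weights are 1.
#'
#' @param pool Character vector of candidate feature IDs.
#' @param k Signature size; `1 <= k <= length(pool)`.
#' @param B Number of signatures.
#' @param seed Integer seed; each signature's draw uses a derived child
#'   seed so the set is reproducible and order-independent.
#' @return A list of `B` [new_signature()] objects named `random_1..B`.
#' @export
random_signatures <- function(pool, k, B, seed = 1L) {
  pool <- unique(as.character(pool))
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k > length(pool)) {
    stop("cannot draw k = ", k, " features from a pool of ", length(pool),
         call. = FALSE)
  }
  lapply(seq_len(B), function(r) {
    set.seed(derive_seed(seed, "random_signature", r))
    new_signature(paste0("random_", r), sample(pool, k, replace = FALSE))
  })
}

null_strategies <- c("data_with_replacement", "data_without_replacement",
                     "random_signatures")

#' Build an empirical null distribution of replicate scores
#'
#' Generates `B` replicate scores per sample for one (signature, scorer)
#' pair under one of three strategies: the data strategies re-score the
#' original signature on perturbed data (values resampled within each
#' sample column, with or without replacement), re-applying the
#' transformation to every perturbed dataset; the `random_signatures`
#' strategy re-scores random same-size signatures (drawn from all matrix
#' features) on the original data, transformed once. Replicate `r` uses a
#' child seed derived from `(seed, r)`, so results do not depend on
#' execution order. Scorer failures become missing replicates with a
#' single warning reporting the count.
#'
#' @inheritParams score_samples
#' @param strategy One of `"data_with_replacement"`,
#'   `"data_without_replacement"`, `"random_signatures"`.
#' @param B Number of replicates (>= 1).
#' @param seed Integer master seed.
#' @param exclude_signature For `random_signatures`: drop the original
#'   signature's features from the background pool.
#' @param ... Passed to [score_samples()] (scorer parameters).
#' @return A tibble with columns `sample_id`, `signature`, `scorer`,
#'   `transform`, `strategy`, `B`, `seed`, `replicate`, `score`.
#' @export
build_null <- function(m, signature, scorer, transform = "identity",
                       strategy = "data_without_replacement", B = 99L,
                       seed = 1L, exclude_signature = FALSE, ...) {
  strategy <- match.arg(strategy, null_strategies)
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  m <- as_expression_matrix(m)
  transform_id <- if (is.function(transform)) "custom" else transform

  if (strategy == "random_signatures") {
    sub <- suppressWarnings(subset_signature(m, signature))
    pool <- rownames(m)
    if (exclude_signature) pool <- setdiff(pool, sub$features)
    k <- length(sub$features)
    sigs <- random_signatures(pool, k, B, seed = seed)
    dots <- list(...)
    m_t <- apply_transform(m, transform,
                           step_thresholds = dots$step_thresholds)
    rep_scores <- lapply(seq_len(B), function(r) {
      tryCatch(
        suppressWarnings(
          score_samples_core(m_t, sigs[[r]], scorer,
                             transform = "identity", ...)$score
        ),
        error = function(e) rep(NA_real_, ncol(m))
      )
    })
  } else {
    replace <- strategy == "data_with_replacement"
    rep_scores <- lapply(seq_len(B), function(r) {
      set.seed(derive_seed(seed, "data_resample", r))
      perturbed <- resample_core(m, replace)
      tryCatch(
        suppressWarnings(
          score_samples_core(perturbed, signature, scorer,
                             transform = transform, ...)$score
        ),
        error = function(e) rep(NA_real_, ncol(m))
      )
    })
  }
  failed <- sum(vapply(rep_scores, function(s) all(is.na(s)), logical(1)))
  if (failed > 0L) {
    warning("build_null: ", failed, " of ", B,
            " replicate(s) failed and are recorded as missing", call. = FALSE)
  }
  scores <- do.call(rbind, rep_scores) # B x n_samples
  rep_idx <- rep(seq_len(B), times = ncol(m))
  col_idx <- rep(seq_len(ncol(m)), each = B)
  tibble::tibble(
    sample_id = colnames(m)[col_idx],
    signature = signature$name,
    scorer = scorer,
    transform = transform_id,
    strategy = strategy,
    B = as.integer(B),
    seed = as.integer(seed),
    replicate = rep_idx,
    score = as.numeric(scores[cbind(rep_idx, col_idx)])
  )
}
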