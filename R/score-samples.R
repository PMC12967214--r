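#' Score every sample for one signature and one scorer
#'
#' The uniform scoring interface: any scorer in [list_scorers()] maps a
#' (matrix, signature) pair to one score per sample. Simple scorers reduce
#' the signature's values within each sample; `combinedZ`, `pca1`, `plage`
#' use the signature submatrix across samples; `ssgsea` and `gsva` rank the
#' signature against the full feature background.
#'
#' @param m Expression matrix (or coercible).
#' @param signature A [new_signature()] object.
#' @param scorer A scorer ID from [list_scorers()].
#' @param transform Transformation applied to the full matrix before
#'   scoring: `"identity"`, `"step"`, `"quantile_norm"`, `"zscore"` or a
#'   function. Applied before signature subsetting.
#' @param trim Trim fraction for `trimmedMean`.
#' @param ssgsea_alpha Rank-weight exponent for `ssgsea`.
#' @param ssgsea_normalize Divide ssgsea scores by their cross-sample range.
#' @param gsva_tau Rank-statistic exponent for `gsva`.
#' @param mad_constant Use the 1.4826 consistency constant for `mad`.
#' @param na_rm Drop missing values per sample for simple scorers.
#' @param step_thresholds Thresholds when `transform = "step"`.
#' @return A tibble with columns `sample_id`, `score`, `n_features_used`.
#' @examples
#' m <- matrix(rnorm(40), 8, 5,
#'             dimnames = list(paste0("g", 1:8), paste0("s", 1:5)))
#' sig <- new_signature("sig", c("g1", "g2", "g3"))
#' score_samples(m, sig, "mean")
#' score_samples(m, sig, "ssgsea")
#' @export
score_samples <- function(m, signature, scorer, transform = "identity",
                          trim = 0.1, ssgsea_alpha = 0.25,
                          ssgsea_normalize = FALSE, gsva_tau = 1,
                          mad_constant = FALSE, na_rm = TRUE,
                          step_thresholds = NULL) {
  scorer <- match.arg(scorer, list_scorers())
  m <- as_expression_matrix(m)
  res <- score_samples_core(m, signature, scorer, transform = transform,
                            trim = trim, ssgsea_alpha = ssgsea_alpha,
                            ssgsea_normalize = ssgsea_normalize,
                            gsva_tau = gsva_tau, mad_constant = mad_constant,
                            na_rm = na_rm, step_thresholds = step_thresholds)
  tibble::tibble(
    sample_id = colnames(m),
    score = unname(as.numeric(res$score)),
    n_features_used = as.integer(res$n_used)
  )
}

# tibble-free scoring kernel: assumes m is a validated matrix; used by
# score_samples() and by the resampling replicate loop, where the tibble
# construction would dominate the runtime
score_samples_core <- function(m, signature, scorer, transform = "identity",
                               trim = 0.1, ssgsea_alpha = 0.25,
                               ssgsea_normalize = FALSE, gsva_tau = 1,
                               mad_constant = FALSE, na_rm = TRUE,
                               step_thresholds = NULL) {
  if (!identical(transform, "identity")) {
    m <- apply_transform(m, transform, step_thresholds = step_thresholds)
  }
  if (scorer %in% simple_scorer_ids) {
    sub <- subset_signature(m, signature)
    x <- sub$matrix
    score <- vapply(seq_len(ncol(x)), function(j) {
      score_vector(x[, j], scorer, weights = sub$weights,
                   trim = trim, mad_constant = mad_constant, na_rm = na_rm)
    }, numeric(1))
    n_used <- colSums(!is.na(x))
    list(score = stats::setNames(score, colnames(m)),
         n_used = as.integer(n_used))
  } else {
    switch(scorer,
      combinedZ = score_combined_z(m, signature),
      pca1 = score_pca1(m, signature),
      plage = score_plage(m, signature),
      ssgsea = score_ssgsea(m, signature, alpha = ssgsea_alpha,
                            normalize = ssgsea_normalize),
      gsva = score_gsva(m, signature, tau = gsva_tau)
    )
  }
}
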