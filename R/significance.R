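#' Resampling-based significance for one observed score
#'
#' Compares an observed score against replicate scores from an empirical
#' null distribution. The achieved significance level (ASL) uses the
#' add-one formulation, so it is a valid p-value and never 0: for
#' `alternative = "greater"`,
#' `asl = (1 + #\{replicates >= observed\}) / (1 + B_effective)`;
#' `"less"` is symmetric; `"two_sided"` doubles the smaller one-sided ASL,
#' capped at 1. The standard error is the sample (n-1) standard deviation
#' of the replicates, and the confidence interval is the percentile
#' interval at type-7 quantiles.
#'
#' @param observed The observed score.
#' @param replicates Numeric vector of replicate scores; missing values
#'   are dropped (at least one non-missing value is required).
#' @param alternative `"greater"`, `"less"` or `"two_sided"`.
#' @param conf_level Confidence level in (0, 1); default 0.95.
#' @return A one-row tibble with columns `observed`, `asl`, `se`,
#'   `ci_low`, `ci_high`, `conf_level`, `alternative`, `B_effective`.
#' @examples
#' compute_significance(5, replicates = 1:10, alternative = "greater")
#' @export
compute_significance <- function(observed, replicates,
                                 alternative = c("greater", "less", "two_sided"),
                                 conf_level = 0.95) {
  alternative <- match.arg(alternative)
  if (!is.numeric(conf_level) || conf_level <= 0 || conf_level >= 1) {
    stop("conf_level must be in (0, 1)", call. = FALSE)
  }
  r <- replicates[!is.na(replicates)]
  b <- length(r)
  if (b == 0L) stop("no non-missing replicates", call. = FALSE)
  if (is.na(observed)) {
    return(tibble::tibble(observed = NA_real_, asl = NA_real_, se = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          conf_level = conf_level, alternative = alternative,
                          B_effective = b))
  }
  asl_greater <- (1 + sum(r >= observed)) / (1 + b)
  asl_less <- (1 + sum(r <= observed)) / (1 + b)
  asl <- switch(alternative,
    greater = asl_greater,
    less = asl_less,
    two_sided = min(1, 2 * min(asl_greater, asl_less))
  )
  alpha <- (1 - conf_level) / 2
  ci <- unname(stats::quantile(r, c(alpha, 1 - alpha), type = 7, names = FALSE))
  tibble::tibble(
    observed = observed,
    asl = asl,
    se = if (b > 1) stats::sd(r) else NA_real_,
    ci_low = ci[1],
    ci_high = ci[2],
    conf_level = conf_level,
    alternative = alternative,
    B_effective = b
  )
}

#' Significance table for observed scores against their nulls
#'
#' Joins a score table with replicate null distributions (as produced by
#' [build_null()]) on (sample_id, signature, scorer, transform) and
#' computes one [compute_significance()] row per matching key. Keys
#' without a null pass through with missing inference fields. No
#' multiple-testing adjustment is applied; adjustment strategy is left to
#' the user and their downstream context.
#'
#' @param observed A score table tibble (see [sig_scores()]).
#' @param nulls A replicate tibble from [build_null()] (rows of several
#'   calls may be concatenated).
#' @param alternative,conf_level As in [compute_significance()].
#' @return A tibble with the score-table keys plus `observed`, `asl`,
#'   `se`, `ci_low`, `ci_high`, `conf_level`, `alternative`,
#'   `B_effective`.
#' @export
significance_table <- function(observed, nulls,
                               alternative = c("greater", "less", "two_sided"),
                               conf_level = 0.95) {
  alternative <- match.arg(alternative)
  validate_score_table(observed)
  key_cols <- c("sample_id", "signature", "scorer", "transform")
  null_split <- if (is.null(nulls) || nrow(nulls) == 0L) list() else
    split(nulls$score, interaction(nulls[key_cols], drop = TRUE, sep = "\r"))
  out <- lapply(seq_len(nrow(observed)), function(i) {
    key <- paste(observed$sample_id[i], observed$signature[i],
                 observed$scorer[i], observed$transform[i], sep = "\r")
    reps <- null_split[[key]]
    if (is.null(reps) || all(is.na(reps))) {
      tibble::tibble(observed = observed$score[i], asl = NA_real_,
                     se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                     conf_level = conf_level, alternative = alternative,
                     B_effective = NA_integer_)
    } else {
      compute_significance(observed$score[i], reps,
                           alternative = alternative, conf_level = conf_level)
    }
  })
  dplyr::bind_cols(observed[key_cols], dplyr::bind_rows(out))
}
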