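#' Compute signature scores across scorers, with optional null models
#'
#' The top-level driver: fans out over every (signature x scorer) pair,
#' applies the chosen transformation to the matrix once before scoring,
#' and — when a resampling strategy is requested — builds empirical null
#' distributions and a significance table. The result table always has
#' exactly `|signatures| x |scorers| x |samples|` rows; failures of one
#' (signature, scorer) pair are downgraded to missing scores and a
#' collected warning, never an abort.
#'
#' Parallel execution (fork-based, via the parallel package) and serial
#' execution produce bit-identical results under the same seed: every
#' replicate's RNG seed is derived deterministically from
#' (seed, signature name, scorer id, replicate index), so worker
#' scheduling cannot change the output.
#'
#' @param data Expression matrix, or data frame with feature IDs in the
#'   first column.
#' @param signatures A [new_signature()] object or list of them (e.g. from
#'   [read_gmt()]).
#' @param scorers Character vector of scorer IDs; see [list_scorers()].
#' @param transform Transformation ID (`"identity"`, `"step"`,
#'   `"quantile_norm"`, `"zscore"`) or a function, applied to the full
#'   matrix before signature subsetting. For data-resampling nulls it is
#'   re-applied to every perturbed dataset.
#' @param strategy `"none"`, `"data_with_replacement"`,
#'   `"data_without_replacement"` or `"random_signatures"`.
#' @param B Number of null replicates per (signature, scorer) when
#'   `strategy != "none"`.
#' @param seed Integer master seed for all resampling.
#' @param alternative,conf_level Passed to [significance_table()].
#' @param parallel Use forked workers (one task per signature x scorer).
#' @param workers Number of workers when `parallel = TRUE`.
#' @param exclude_signature Drop the original signature's features from the
#'   random-signature background pool.
#' @param ... Scorer parameters passed to [score_samples()] (`trim`,
#'   `ssgsea_alpha`, `ssgsea_normalize`, `gsva_tau`, `mad_constant`,
#'   `na_rm`, `step_thresholds`).
#' @return A `tidysig_run` object: a list with elements `scores` (score
#'   table tibble), `nulls` (replicate tibble or `NULL`), `significance`
#'   (tibble or `NULL`), `config` (the run configuration as executed) and
#'   `warnings` (character). Use [generics::tidy()] / [generics::glance()]
#'   to extract tidy summaries.
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(200), 20, 10,
#'             dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
#' sigs <- list(new_signature("a", paste0("g", 1:5)),
#'              new_signature("b", paste0("g", 6:12)))
#' run <- sig_scores(m, sigs, scorers = c("mean", "ssgsea"))
#' tidy(run)
#' @export
sig_scores <- function(data, signatures, scorers = c("mean", "median"),
                       transform = "identity",
                       strategy = c("none", "data_with_replacement",
                                    "data_without_replacement",
                                    "random_signatures"),
                       B = 99L, seed = 1L,
                       alternative = c("greater", "less", "two_sided"),
                       conf_level = 0.95, parallel = FALSE, workers = 2L,
                       exclude_signature = FALSE, ...) {
  strategy <- match.arg(strategy)
  alternative <- match.arg(alternative)
  m <- as_expression_matrix(data)
  signatures <- as_signature_list(signatures)
  scorers <- as.character(scorers)
  unknown <- setdiff(scorers, list_scorers())
  if (length(unknown) > 0) {
    stop("unknown scorer(s): ", paste(unknown, collapse = ", "),
         "; valid ids: ", paste(list_scorers(), collapse = ", "),
         call. = FALSE)
  }
  if (strategy != "none" && B < 1) stop("B must be >= 1", call. = FALSE)
  transform_id <- if (is.function(transform)) "custom" else
    match.arg(transform, transform_ids)

  tasks <- expand.grid(sig = names(signatures), scorer = scorers,
                       stringsAsFactors = FALSE)
  run_task <- function(i) {
    sig <- signatures[[tasks$sig[i]]]
    scorer <- tasks$scorer[i]
    warns <- character()
    grab <- function(expr) {
      withCallingHandlers(expr, warning = function(w) {
        warns <<- c(warns, paste0("[", sig$name, "/", scorer, "] ",
                                  conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    }
    scores <- tryCatch(
      grab(score_samples(m, sig, scorer, transform = transform, ...)),
      error = function(e) {
        warns <<- c(warns, paste0("[", sig$name, "/", scorer, "] scoring failed: ",
                                  conditionMessage(e)))
        tibble::tibble(sample_id = colnames(m), score = NA_real_,
                       n_features_used = 0L)
      }
    )
    score_tab <- tibble::tibble(
      sample_id = scores$sample_id,
      signature = sig$name,
      scorer = scorer,
      transform = transform_id,
      score = scores$score,
      n_features_used = scores$n_features_used
    )
    nulls <- NULL
    if (strategy != "none") {
      task_seed <- derive_seed(seed, sig$name, scorer)
      nulls <- tryCatch(
        grab(build_null(m, sig, scorer, transform = transform,
                        strategy = strategy, B = B, seed = task_seed,
                        exclude_signature = exclude_signature, ...)),
        error = function(e) {
          warns <<- c(warns, paste0("[", sig$name, "/", scorer,
                                    "] null failed: ", conditionMessage(e)))
          NULL
        }
      )
    }
    list(scores = score_tab, nulls = nulls, warnings = warns)
  }

  idx <- seq_len(nrow(tasks))
  results <- if (parallel && .Platform$OS.type == "unix") {
    parallel::mclapply(idx, run_task, mc.cores = max(1L, as.integer(workers)))
  } else {
    lapply(idx, run_task)
  }

  scores <- dplyr::bind_rows(lapply(results, `[[`, "scores"))
  scores <- scores[order(scores$signature, scores$scorer, scores$sample_id), ]
  nulls <- NULL
  significance <- NULL
  if (strategy != "none") {
    null_list <- Filter(Negate(is.null), lapply(results, `[[`, "nulls"))
    if (length(null_list) > 0) nulls <- dplyr::bind_rows(null_list)
    significance <- significance_table(scores, nulls,
                                       alternative = alternative,
                                       conf_level = conf_level)
  }
  warnings <- unique(unlist(lapply(results, `[[`, "warnings")))

  config <- list(scorers = scorers, transform = transform_id,
                 strategy = strategy,
                 B = if (strategy == "none") 0L else as.integer(B),
                 seed = as.integer(seed), alternative = alternative,
                 conf_level = conf_level, parallel = parallel,
                 exclude_signature = exclude_signature,
                 extra = list(...))
  structure(list(scores = tibble::as_tibble(scores), nulls = nulls,
                 significance = significance, config = config,
                 warnings = warnings %||% character()),
            class = "tidysig_run")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.tidysig_run <- function(x, ...) {
  n_sig <- length(unique(x$scores$signature))
  n_sc <- length(unique(x$scores$scorer))
  n_sam <- length(unique(x$scores$sample_id))
  cat(sprintf("<tidysig run> %d signature(s) x %d scorer(s) x %d sample(s)\n",
              n_sig, n_sc, n_sam))
  cat(sprintf("  transform: %s | strategy: %s%s\n", x$config$transform,
              x$config$strategy,
              if (x$config$strategy != "none")
                sprintf(" (B = %d, seed = %d)", x$config$B, x$config$seed)
              else ""))
  if (length(x$warnings) > 0) {
    cat(sprintf("  %d warning(s); see $warnings\n", length(x$warnings)))
  }
  invisible(x)
}

#' Tidy a scoring run
#'
#' Returns the long score table; when significance was computed, the
#' inference columns (asl, se, ci bounds) are joined in.
#'
#' @param x A `tidysig_run` from [sig_scores()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy tidysig_run
#' @export
tidy.tidysig_run <- function(x, ...) {
  if (is.null(x$significance)) return(x$scores)
  dplyr::left_join(
    x$scores,
    x$significance[, setdiff(names(x$significance), "observed")],
    by = c("sample_id", "signature", "scorer", "transform")
  )
}

#' One-row summary of a scoring run
#'
#' @param x A `tidysig_run` from [sig_scores()].
#' @param ... Unused.
#' @return A one-row tibble: dimensions, strategy, replicate count, seed,
#'   number of missing scores and collected warnings.
#' @method glance tidysig_run
#' @export
glance.tidysig_run <- function(x, ...) {
  tibble::tibble(
    n_signatures = length(unique(x$scores$signature)),
    n_scorers = length(unique(x$scores$scorer)),
    n_samples = length(unique(x$scores$sample_id)),
    n_missing = sum(is.na(x$scores$score)),
    transform = x$config$transform,
    strategy = x$config$strategy,
    B = x$config$B,
    seed = x$config$seed,
    n_warnings = length(x$warnings)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
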