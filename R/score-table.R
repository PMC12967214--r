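#' Score tables
#'
#' Scores live in long format: one row per
#' (sample_id, signature, scorer, transform) with the score (possibly `NA`)
#' and the number of signature features actually used for that sample.
#'
#' @name score-table
#' @keywords internal
NULL

score_table_cols <- c("sample_id", "signature", "scorer", "transform",
                      "score", "n_features_used")

new_score_table <- function(sample_id = character(), signature = character(),
                            scorer = character(), transform = character(),
                            score = numeric(), n_features_used = integer()) {
  tibble::tibble(
    sample_id = as.character(sample_id),
    signature = as.character(signature),
    scorer = as.character(scorer),
    transform = as.character(transform),
    score = as.numeric(score),
    n_features_used = as.integer(n_features_used)
  )
}

validate_score_table <- function(tab) {
  missing_cols <- setdiff(score_table_cols, names(tab))
  if (length(missing_cols) > 0) {
    stop("score table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(tab$sample_id, tab$signature, tab$scorer, tab$transform, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (sample, signature, scorer, transform) record(s)",
         call. = FALSE)
  }
  invisible(tab)
}

#' Write a score table to TSV
#'
#' Rows are ordered (signature, scorer, sample) lexicographically so output
#' is byte-deterministic; missing scores are written as `NA`; numbers are
#' written at 15 significant digits.
#'
#' @param table A score table tibble (see [sig_scores()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(table, path) {
  validate_score_table(table)
  tab <- table[order(table$signature, table$scorer, table$sample_id), ,
               drop = FALSE]
  lines <- c(
    paste(score_table_cols, collapse = "\t"),
    vapply(seq_len(nrow(tab)), function(i) {
      paste(c(tab$sample_id[i], tab$signature[i], tab$scorer[i],
              tab$transform[i],
              if (is.na(tab$score[i])) "NA" else
                format(tab$score[i], digits = 15, scientific = FALSE, trim = TRUE),
              as.character(tab$n_features_used[i])),
            collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a score table from TSV
#'
#' @param path Path written by [write_scores()].
#' @return A score table tibble.
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = c(rep("character", 4), "numeric", "integer"),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = "NA")
  tab <- tibble::as_tibble(df)
  validate_score_table(tab)
  tab
}
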