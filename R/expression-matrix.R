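#' Coerce to an expression matrix
#'
#' An expression matrix in tidysig is a plain numeric matrix with unique,
#' non-empty feature IDs as rownames and unique, non-empty sample IDs as
#' colnames. Missing values are permitted. Data frames are accepted in the
#' common exchange layout: first column = feature IDs, remaining columns =
#' numeric sample values.
#'
#' @param x A numeric matrix with dimnames, or a data frame whose first
#'   column holds feature identifiers.
#' @return A numeric matrix with feature rownames and sample colnames.
#' @examples
#' df <- data.frame(feature = c("g1", "g2"), s1 = c(1, 2), s2 = c(3, 4))
#' as_expression_matrix(df)
#' @export
as_expression_matrix <- function(x) {
  if (is.data.frame(x)) {
    ids <- as.character(x[[1L]])
    vals <- x[, -1L, drop = FALSE]
    bad <- which(!vapply(vals, is.numeric, logical(1)))
    if (length(bad) > 0) {
      stop("non-numeric sample column(s): ",
           paste(names(vals)[bad], collapse = ", "), call. = FALSE)
    }
    m <- as.matrix(vals)
    rownames(m) <- ids
  } else if (is.matrix(x)) {
    if (!is.numeric(x)) stop("expression matrix must be numeric", call. = FALSE)
    m <- x
  } else {
    stop("cannot coerce ", class(x)[1], " to an expression matrix", call. = FALSE)
  }
  validate_expression_matrix(m)
  m
}

validate_expression_matrix <- function(m) {
  fid <- rownames(m)
  sid <- colnames(m)
  if (is.null(fid) || any(!nzchar(fid)) || anyNA(fid)) {
    stop("feature IDs must be present and non-empty", call. = FALSE)
  }
  if (is.null(sid) || any(!nzchar(sid)) || anyNA(sid)) {
    stop("sample IDs must be present and non-empty", call. = FALSE)
  }
  if (anyDuplicated(fid)) {
    stop("duplicated feature ID(s): ",
         paste(unique(fid[duplicated(fid)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sid)) {
    stop("duplicated sample ID(s): ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "), call. = FALSE)
  }
  invisible(m)
}

delim_for_path <- function(path, delimiter = NULL) {
  if (!is.null(delimiter)) return(delimiter)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an expression matrix from TSV/CSV
#'
#' Expects a header row of sample IDs and a first column of feature IDs.
#' The delimiter is auto-detected from the extension (`.csv` = comma,
#' anything else = tab) unless given. The tokens `"NA"`, `""` and `"NaN"`
#' (case-sensitive) become missing values.
#'
#' @param path Path to the file.
#' @param delimiter Field delimiter; `NULL` (default) auto-detects.
#' @return A numeric expression matrix (features x samples).
#' @seealso [write_expression()], [as_expression_matrix()]
#' @export
read_expression <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- delim_for_path(path, delimiter)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          colClasses = "character", check.names = FALSE,
                          comment.char = "", stringsAsFactors = FALSE,
                          na.strings = NULL)
  if (ncol(df) < 2L) stop("expected a feature-ID column plus >= 1 sample column", call. = FALSE)
  ids <- df[[1L]]
  cells <- as.matrix(df[, -1L, drop = FALSE])
  na_tokens <- c("NA", "", "NaN")
  is_na <- matrix(cells %in% na_tokens, nrow = nrow(cells))
  suppressWarnings(num <- array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(num) & !is_na, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric cell '%s' at feature '%s', sample '%s'",
                 cells[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                 colnames(cells)[bad[1, 2]]), call. = FALSE)
  }
  num[is_na] <- NA_real_
  rownames(num) <- ids
  colnames(num) <- colnames(cells)
  validate_expression_matrix(num)
  num
}

#' Write an expression matrix to TSV/CSV
#'
#' Inverse of [read_expression()]: header row of sample IDs, first column
#' (`feature_id`) of feature IDs, numeric cells at full double precision
#' (15 significant digits), missing values as `NA`.
#'
#' @param m Expression matrix (or coercible via [as_expression_matrix()]).
#' @param path Output path.
#' @param delimiter Field delimiter; `NULL` auto-detects from extension.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, delimiter = NULL) {
  m <- as_expression_matrix(m)
  sep <- delim_for_path(path, delimiter)
  body <- apply(m, 2, format_num_col)
  if (is.null(dim(body))) body <- matrix(body, nrow = nrow(m))
  lines <- c(
    paste(c("feature_id", colnames(m)), collapse = sep),
    vapply(seq_len(nrow(m)), function(i) {
      paste(c(rownames(m)[i], body[i, ]), collapse = sep)
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

format_num_col <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else format(v, digits = 15, scientific = FALSE, trim = TRUE)
  }, character(1))
  out
}
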