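#' Build a signature
#'
#' A signature is a named, ordered set of unique feature IDs with an
#' optional real weight per feature (default 1). Weights carry the
#' coefficients used by the weighted-sum / weighted-mean scorers; signed
#' signatures (up/down components) encode direction as negative weights.
#'
#' @param name Signature identifier.
#' @param features Character vector of unique, non-empty feature IDs.
#' @param weights Optional numeric vector, one weight per feature.
#' @return An object of class `tidysig_signature`: a list with elements
#'   `name`, `features`, `weights`.
#' @examples
#' new_signature("hypoxia_up", c("VEGFA", "SLC2A1", "CA9"))
#' new_signature("signed", c("a", "b"), weights = c(1, -1))
#' @export
new_signature <- function(name, features, weights = NULL) {
  features <- as.character(features)
  if (length(features) == 0L) stop("signature '", name, "' has no features", call. = FALSE)
  if (any(!nzchar(features)) || anyNA(features)) {
    stop("signature '", name, "' has empty feature IDs", call. = FALSE)
  }
  if (anyDuplicated(features)) {
    stop("signature '", name, "' has duplicated features: ",
         paste(unique(features[duplicated(features)]), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(weights)) {
    weights <- rep(1, length(features))
  } else {
    weights <- as.numeric(weights)
    if (length(weights) != length(features)) {
      stop("signature '", name, "': ", length(weights), " weights for ",
           length(features), " features", call. = FALSE)
    }
  }
  structure(list(name = as.character(name), features = features,
                 weights = weights),
            class = "tidysig_signature")
}

#' @export
print.tidysig_signature <- function(x, ...) {
  w <- if (all(x$weights == 1)) "" else " (weighted)"
  cat(sprintf("<signature> %s: %d features%s\n", x$name, length(x$features), w))
  invisible(x)
}

as_signature_list <- function(signatures) {
  if (inherits(signatures, "tidysig_signature")) signatures <- list(signatures)
  if (!is.list(signatures) ||
      !all(vapply(signatures, inherits, logical(1), "tidysig_signature"))) {
    stop("expected a signature or list of signatures (see new_signature())",
         call. = FALSE)
  }
  nm <- vapply(signatures, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    stop("duplicated signature names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  stats::setNames(signatures, nm)
}

#' Read signatures from a GMT file
#'
#' One set per line: name, description, then member feature IDs, all
#' tab-separated. The description is discarded. Duplicated members within a
#' line are collapsed to their first occurrence with a warning. Standard GMT
#' has no weight slot; the extended member syntax `id|weight` (e.g.
#' `"MYC|-1"`) is accepted and fills the signature's weights.
#'
#' @param path Path to a GMT file.
#' @return A named list of [new_signature()] objects.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  sigs <- lapply(keep, function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop("GMT line ", i, ": expected name, description and >= 1 feature (got ",
           length(fields), " field(s))", call. = FALSE)
    }
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (length(members) == 0L) {
      stop("GMT line ", i, ": no feature IDs", call. = FALSE)
    }
    has_w <- grepl("|", members, fixed = TRUE)
    ids <- members
    weights <- rep(1, length(members))
    if (any(has_w)) {
      parts <- strsplit(members[has_w], "|", fixed = TRUE)
      ids[has_w] <- vapply(parts, `[[`, character(1), 1L)
      weights[has_w] <- vapply(parts, function(p) {
        w <- suppressWarnings(as.numeric(p[2]))
        if (is.na(w)) stop("GMT line ", i, ": bad weight in '",
                           paste(p, collapse = "|"), "'", call. = FALSE)
        w
      }, numeric(1))
    }
    if (anyDuplicated(ids)) {
      dup <- unique(ids[duplicated(ids)])
      warning("GMT line ", i, " ('", fields[1], "'): duplicated feature(s) ",
              paste(dup, collapse = ", "), " collapsed to first occurrence",
              call. = FALSE)
      first <- !duplicated(ids)
      ids <- ids[first]
      weights <- weights[first]
    }
    new_signature(fields[1], ids, weights)
  })
  as_signature_list(sigs)
}

#' Write signatures to a GMT file
#'
#' @param signatures A signature or list of signatures.
#' @param path Output path.
#' @param description Description field written for every line.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(signatures, path, description = "na") {
  signatures <- as_signature_list(signatures)
  lines <- vapply(signatures, function(s) {
    members <- ifelse(s$weights == 1, s$features,
                      paste0(s$features, "|",
                             format(s$weights, digits = 15, trim = TRUE)))
    paste(c(s$name, description, members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
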