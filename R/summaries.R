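#' Boxplot statistics per (signature, scorer, transform)
#'
#' Five-number summaries (type-7 quartiles) of scores across samples, with
#' Tukey outliers beyond 1.5 * IQR from the hinges, as the tabular backing
#' of a score-distribution boxplot.
#'
#' @param table A score table tibble.
#' @return A `tidysig_plotdata` tibble (kind `"box_stats"`) with columns
#'   `signature`, `scorer`, `transform`, `n`, `min`, `q1`, `median`, `q3`,
#'   `max` and a list-column `outliers`.
#' @export
box_stats <- function(table) {
  validate_score_table(table)
  if (nrow(table) == 0L) stop("empty score table", call. = FALSE)
  out <- table |>
    dplyr::group_by(.data$signature, .data$scorer, .data$transform) |>
    dplyr::summarise(
      n = sum(!is.na(.data$score)),
      min = suppressWarnings(min(.data$score, na.rm = TRUE)),
      q1 = stats::quantile(.data$score, 0.25, na.rm = TRUE, type = 7,
                           names = FALSE),
      median = stats::quantile(.data$score, 0.5, na.rm = TRUE, type = 7,
                               names = FALSE),
      q3 = stats::quantile(.data$score, 0.75, na.rm = TRUE, type = 7,
                           names = FALSE),
      max = suppressWarnings(max(.data$score, na.rm = TRUE)),
      outliers = list({
        s <- .data$score[!is.na(.data$score)]
        qq <- stats::quantile(s, c(0.25, 0.75), type = 7, names = FALSE)
        fence <- 1.5 * (qq[2] - qq[1])
        s[s < qq[1] - fence | s > qq[2] + fence]
      }),
      .groups = "drop"
    )
  new_plotdata(out, "box_stats")
}

#' Scorer-by-scorer correlation of scores
#'
#' For each signature, the symmetric correlation matrix between scoring
#' metrics over samples (pairwise-complete); high agreement between
#' scorers suggests a signature summarizes well. Pairs with fewer than 3
#' complete observations are missing.
#'
#' @param table A score table tibble with >= 2 scorers.
#' @param method `"pearson"` or `"spearman"`.
#' @return A `tidysig_plotdata` tibble (kind `"scorer_correlation"`) in
#'   long form: `signature`, `scorer_x`, `scorer_y`, `correlation`, `n`.
#' @export
scorer_correlation <- function(table, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  validate_score_table(table)
  scorers <- unique(table$scorer)
  if (length(scorers) < 2L) stop("need >= 2 scorers", call. = FALSE)
  out <- dplyr::bind_rows(lapply(unique(table$signature), function(sg) {
    wide <- table |>
      dplyr::filter(.data$signature == sg) |>
      tidyr::pivot_wider(id_cols = "sample_id", names_from = "scorer",
                         values_from = "score")
    combos <- expand.grid(scorer_x = scorers, scorer_y = scorers,
                          stringsAsFactors = FALSE)
    combos$signature <- sg
    combos$n <- NA_integer_
    combos$correlation <- NA_real_
    for (i in seq_len(nrow(combos))) {
      x <- wide[[combos$scorer_x[i]]]
      y <- wide[[combos$scorer_y[i]]]
      ok <- !is.na(x) & !is.na(y)
      combos$n[i] <- sum(ok)
      if (combos$scorer_x[i] == combos$scorer_y[i]) {
        combos$correlation[i] <- 1
      } else if (sum(ok) >= 3L) {
        combos$correlation[i] <-
          suppressWarnings(stats::cor(x[ok], y[ok], method = method))
      }
    }
    combos
  }))
  out <- tibble::as_tibble(out[, c("signature", "scorer_x", "scorer_y",
                                   "correlation", "n")])
  new_plotdata(out, "scorer_correlation")
}

#' Histogram of an empirical null with the observed score overlaid
#'
#' Equal-width bins spanning the replicates and the observed value
#' together, so the observed overlay always falls inside the plotted
#' range; bin counts sum to the number of non-missing replicates.
#'
#' @param replicates Numeric replicate scores (missing values dropped;
#'   at least one required).
#' @param observed The observed score to overlay.
#' @param bins Number of equal-width bins (>= 1).
#' @return A `tidysig_plotdata` tibble (kind `"null_histogram"`) with
#'   columns `bin_low`, `bin_high`, `count`, `observed`, `B_effective`.
#' @export
null_histogram <- function(replicates, observed, bins = 30L) {
  r <- replicates[!is.na(replicates)]
  if (length(r) == 0L) stop("no non-missing replicates", call. = FALSE)
  if (bins < 1L) stop("bins must be >= 1", call. = FALSE)
  lo <- min(r, observed)
  hi <- max(r, observed)
  if (hi == lo) hi <- lo + 1 # degenerate: single bin holds everything
  edges <- seq(lo, hi, length.out = bins + 1L)
  idx <- pmin(findInterval(r, edges, rightmost.closed = TRUE), bins)
  counts <- tabulate(idx, nbins = bins)
  out <- tibble::tibble(
    bin_low = edges[-length(edges)],
    bin_high = edges[-1L],
    count = as.integer(counts),
    observed = observed,
    B_effective = length(r)
  )
  new_plotdata(out, "null_histogram")
}

#' Wide score grid (heatmap backing)
#'
#' Reshapes the long score table into a rectangular grid with one row per
#' (signature, scorer, transform) and one column per sample; missing
#' scores stay missing cells. Optionally z-scales each complete row.
#'
#' @param table A score table tibble.
#' @param scale_rows Z-scale each row (mean 0, sample SD 1) over
#'   non-missing cells.
#' @return A `tidysig_plotdata` tibble (kind `"score_grid"`): key columns
#'   `signature`, `scorer`, `transform` followed by one numeric column per
#'   sample.
#' @export
score_grid <- function(table, scale_rows = FALSE) {
  validate_score_table(table)
  if (nrow(table) == 0L) stop("empty score table", call. = FALSE)
  wide <- tidyr::pivot_wider(table,
                             id_cols = c("signature", "scorer", "transform"),
                             names_from = "sample_id",
                             values_from = "score")
  if (scale_rows) {
    sample_cols <- setdiff(names(wide), c("signature", "scorer", "transform"))
    vals <- as.matrix(wide[, sample_cols])
    mu <- rowMeans(vals, na.rm = TRUE)
    s <- apply(vals, 1, stats::sd, na.rm = TRUE)
    s[is.na(s) | s == 0] <- 1
    wide[, sample_cols] <- (vals - mu) / s
  }
  new_plotdata(wide, "score_grid")
}

new_plotdata <- function(tbl, kind) {
  structure(tibble::as_tibble(tbl),
            kind = kind,
            class = c("tidysig_plotdata", class(tibble::tibble())))
}

#' @export
print.tidysig_plotdata <- function(x, ...) {
  cat("<plot data:", attr(x, "kind"), ">\n")
  NextMethod()
}

#' Plot a tabular summary
#'
#' Renders the tabular summaries as ggplot2 figures: boxplots of score
#' distributions per scorer, a scorer-correlation heatmap, a score
#' heatmap across samples, or a null histogram with the observed score as
#' a vertical line. The tabular layer is the contract; this is a thin
#' convenience on top.
#'
#' @param object A `tidysig_plotdata` from [box_stats()],
#'   [scorer_correlation()], [null_histogram()] or [score_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tidysig_plotdata
#' @export
autoplot.tidysig_plotdata <- function(object, ...) {
  kind <- attr(object, "kind")
  switch(kind,
    box_stats = ggplot2::ggplot(object) +
      ggplot2::geom_boxplot(
        ggplot2::aes(x = .data$scorer, ymin = .data$min, lower = .data$q1,
                     middle = .data$median, upper = .data$q3,
                     ymax = .data$max, fill = .data$signature),
        stat = "identity") +
      ggplot2::labs(y = "score", x = NULL) +
      ggplot2::theme_minimal(),
    scorer_correlation = ggplot2::ggplot(object) +
      ggplot2::geom_tile(ggplot2::aes(x = .data$scorer_x, y = .data$scorer_y,
                                      fill = .data$correlation)) +
      ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
      ggplot2::facet_wrap(~signature) +
      ggplot2::labs(x = NULL, y = NULL) +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                         hjust = 1)),
    null_histogram = ggplot2::ggplot(object) +
      ggplot2::geom_rect(ggplot2::aes(xmin = .data$bin_low,
                                      xmax = .data$bin_high,
                                      ymin = 0, ymax = .data$count),
                         fill = "grey70", colour = "white") +
      ggplot2::geom_vline(ggplot2::aes(xintercept = .data$observed),
                          colour = "red", linewidth = 1) +
      ggplot2::labs(x = "replicate score", y = "count") +
      ggplot2::theme_minimal(),
    score_grid = {
      long <- tidyr::pivot_longer(object,
        cols = -c("signature", "scorer", "transform"),
        names_to = "sample_id", values_to = "score")
      ggplot2::ggplot(long) +
        ggplot2::geom_tile(ggplot2::aes(
          x = .data$sample_id,
          y = paste(.data$signature, .data$scorer, sep = " / "),
          fill = .data$score)) +
        ggplot2::labs(x = NULL, y = NULL) +
        ggplot2::theme_minimal() +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                           hjust = 1))
    },
    stop("unknown plot data kind: ", kind, call. = FALSE)
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
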