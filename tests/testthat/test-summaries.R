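mk_table <- function(scores, scorer = "mean", signature = "a") {
  tidysig:::new_score_table(
    sample_id = paste0("s", seq_along(scores)),
    signature = signature, scorer = scorer, transform = "identity",
    score = scores, n_features_used = 2L
  )
}

test_that("box stats give the five-number summary and Tukey outliers", {
  bs <- box_stats(mk_table(c(1, 2, 3, 4, 5)))
  expect_equal(unlist(bs[, c("min", "q1", "median", "q3", "max")]),
               c(min = 1, q1 = 2, median = 3, q3 = 4, max = 5))
  expect_length(bs$outliers[[1]], 0)

  out <- box_stats(mk_table(c(1, 2, 3, 4, 100)))
  # type-7 quartiles: q1 = 2, q3 = 4, fence = 4 + 1.5 * 2 = 7
  expect_identical(out$outliers[[1]], 100)

  single <- box_stats(mk_table(3.5))
  expect_equal(unlist(single[, c("min", "q1", "median", "q3", "max")]),
               c(min = 3.5, q1 = 3.5, median = 3.5, q3 = 3.5, max = 3.5))
})

test_that("scorer correlation: unit diagonal, symmetry, affine and rank relations", {
  set.seed(81)
  base <- stats::rnorm(10)
  tab <- dplyr::bind_rows(
    mk_table(base, scorer = "A"),
    mk_table(2 * base + 1, scorer = "B"),
    mk_table(-base^3, scorer = "C")
  )
  pear <- scorer_correlation(tab, method = "pearson")
  expect_true(all(pear$correlation[pear$scorer_x == pear$scorer_y] == 1))
  wide <- tidyr::pivot_wider(pear, id_cols = "scorer_x",
                             names_from = "scorer_y",
                             values_from = "correlation")
  expect_equal(wide$B[wide$scorer_x == "A"], wide$A[wide$scorer_x == "B"],
               tolerance = 1e-12)
  expect_equal(pear$correlation[pear$scorer_x == "A" & pear$scorer_y == "B"],
               1, tolerance = 1e-12)

  spear <- scorer_correlation(tab, method = "spearman")
  expect_equal(spear$correlation[spear$scorer_x == "A" & spear$scorer_y == "C"],
               -1, tolerance = 1e-12)
})

test_that("pairs with fewer than 3 complete observations are missing", {
  tab <- dplyr::bind_rows(
    mk_table(c(1, 2, NA, NA, NA), scorer = "A"),
    mk_table(c(2, 1, 3, 4, 5), scorer = "B")
  )
  out <- scorer_correlation(tab)
  expect_true(is.na(out$correlation[out$scorer_x == "A" & out$scorer_y == "B"]))
})

test_that("null histogram conserves counts and spans the observed value", {
  set.seed(82)
  reps <- stats::rnorm(97)
  h <- null_histogram(reps, observed = 10, bins = 12)
  expect_identical(sum(h$count), 97L)
  expect_identical(unique(h$B_effective), 97L)
  expect_gte(10, max(h$bin_low))
  expect_equal(max(h$bin_high), 10)

  flat <- null_histogram(rep(2, 5), observed = 2, bins = 1)
  expect_identical(flat$count, 5L)
})

test_that("score grid reshapes losslessly and z-scales rows on request", {
  set.seed(83)
  tab <- dplyr::bind_rows(lapply(c("a", "b"), function(sg) {
    dplyr::bind_rows(
      mk_table(stats::rnorm(3), scorer = "mean", signature = sg),
      mk_table(stats::rnorm(3), scorer = "iqr", signature = sg)
    )
  }))
  grid <- score_grid(tab)
  expect_identical(dim(grid), c(4L, 3L + 3L))

  long <- tidyr::pivot_longer(grid, cols = dplyr::all_of(paste0("s", 1:3)),
                              names_to = "sample_id", values_to = "score")
  merged <- dplyr::inner_join(
    tab, long, by = c("sample_id", "signature", "scorer", "transform"))
  expect_identical(nrow(merged), nrow(tab))
  expect_equal(merged$score.x, merged$score.y)

  scaled <- score_grid(tab, scale_rows = TRUE)
  vals <- as.matrix(scaled[, paste0("s", 1:3)])
  expect_true(all(abs(rowMeans(vals)) < 1e-12))
  expect_true(all(abs(apply(vals, 1, stats::sd) - 1) < 1e-12))
})

test_that("autoplot renders every plot-data kind without error", {
  set.seed(84)
  tab <- dplyr::bind_rows(mk_table(stats::rnorm(5), scorer = "mean"),
                          mk_table(stats::rnorm(5), scorer = "iqr"))
  expect_s3_class(ggplot2::autoplot(box_stats(tab)), "ggplot")
  expect_s3_class(ggplot2::autoplot(scorer_correlation(tab)), "ggplot")
  expect_s3_class(ggplot2::autoplot(score_grid(tab)), "ggplot")
  expect_s3_class(ggplot2::autoplot(null_histogram(stats::rnorm(20), 0.5)),
                  "ggplot")
})
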