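test_that("without-replacement resampling preserves each column's multiset", {
  set.seed(51)
  m <- rand_mat(15, 6)
  set.seed(1)
  out <- resample_matrix(m, replace = FALSE)
  for (j in seq_len(ncol(m))) {
    expect_identical(sort(unname(out[, j])), sort(unname(m[, j])))
  }
  expect_identical(dimnames(out), dimnames(m))
})

test_that("resampling is seed-deterministic; single-row with replacement is identity", {
  set.seed(52)
  m <- rand_mat(10, 4)
  set.seed(99); a <- resample_matrix(m, replace = TRUE)
  set.seed(99); b <- resample_matrix(m, replace = TRUE)
  expect_identical(a, b)

  one <- rand_mat(1, 5)
  set.seed(1)
  expect_identical(resample_matrix(one, replace = TRUE), one)
})

test_that("random signatures: size, pool containment, determinism, edge k = |pool|", {
  pool <- paste0("g", 1:12)
  sigs <- random_signatures(pool, k = 4, B = 10, seed = 7)
  expect_length(sigs, 10)
  for (s in sigs) {
    expect_length(s$features, 4)
    expect_false(anyDuplicated(s$features) > 0)
    expect_true(all(s$features %in% pool))
    expect_identical(s$weights, rep(1, 4))
  }
  again <- random_signatures(pool, k = 4, B = 10, seed = 7)
  expect_identical(lapply(sigs, `[[`, "features"),
                   lapply(again, `[[`, "features"))

  full <- random_signatures(pool, k = 12, B = 3, seed = 1)
  for (s in full) expect_identical(sort(s$features), sort(pool))
  expect_error(random_signatures(pool, k = 13, B = 1), "13.*12")
})

test_that("derived child seeds differ across keys and ignore evaluation order", {
  s1 <- tidysig:::derive_seed(1, "sigA", "mean", 1)
  s2 <- tidysig:::derive_seed(1, "sigA", "mean", 2)
  s3 <- tidysig:::derive_seed(1, "sigB", "mean", 1)
  s4 <- tidysig:::derive_seed(2, "sigA", "mean", 1)
  expect_length(unique(c(s1, s2, s3, s4)), 4)
  expect_identical(s1, tidysig:::derive_seed(1, "sigA", "mean", 1))
  expect_true(all(c(s1, s2, s3, s4) >= 0 & c(s1, s2, s3, s4) < 2^31))
})

test_that("build_null on a single-feature matrix reproduces the observed score", {
  m <- rand_mat(1, 4)
  sig <- new_signature("s", "g1")
  nulls <- build_null(m, sig, "mean", strategy = "data_without_replacement",
                      B = 1, seed = 5)
  obs <- score_samples(m, sig, "mean")
  expect_equal(nulls$score, obs$score, tolerance = 1e-14)
  expect_identical(nrow(nulls), 4L)
})

test_that("random-signature nulls with k = |pool| all equal the pool-wide score", {
  set.seed(53)
  m <- rand_mat(6, 3)
  sig <- new_signature("all", rownames(m))
  nulls <- build_null(m, sig, "mean", strategy = "random_signatures",
                      B = 5, seed = 2)
  pool_score <- score_samples(m, sig, "mean")$score
  for (j in seq_len(3)) {
    expect_equal(nulls$score[nulls$sample_id == colnames(m)[j]],
                 rep(pool_score[j], 5), tolerance = 1e-14)
  }
})

test_that("replicate scores are bit-reproducible under a fixed seed", {
  set.seed(54)
  m <- rand_mat(12, 5)
  sig <- new_signature("s", paste0("g", 1:4))
  for (strat in c("data_with_replacement", "data_without_replacement",
                  "random_signatures")) {
    a <- build_null(m, sig, "trimean", strategy = strat, B = 7, seed = 11)
    b <- build_null(m, sig, "trimean", strategy = strat, B = 7, seed = 11)
    expect_identical(a, b, info = strat)
    expect_identical(nrow(a), 7L * 5L)
  }
})

test_that("data-strategy nulls re-apply the transform to each perturbed dataset", {
  set.seed(55)
  m <- rand_mat(8, 4)
  sig <- new_signature("s", paste0("g", 1:3))
  nulls <- build_null(m, sig, "mean", transform = "zscore",
                      strategy = "data_without_replacement", B = 3, seed = 9)
  # recompute replicate 2 by hand through the same pipeline
  set.seed(tidysig:::derive_seed(9, "data_resample", 2))
  pert <- resample_matrix(m, replace = FALSE)
  want <- score_samples(pert, sig, "mean", transform = "zscore")$score
  got <- nulls$score[nulls$replicate == 2]
  expect_equal(got, want, tolerance = 1e-14)
})

test_that("observed mean-score quantile within its random-signature null is uniform", {
  # exchangeable matrix, random true signature: the observed score should
  # fall below the q-th null quantile about q of the time
  set.seed(56)
  n_rep <- 60
  hits <- logical(n_rep)
  q <- 0.25
  for (r in seq_len(n_rep)) {
    m <- rand_mat(40, 8)
    feats <- sample(rownames(m), 6)
    sig <- new_signature("true", feats)
    obs <- score_samples(m, sig, "mean")$score[1]
    nulls <- build_null(m, sig, "mean", strategy = "random_signatures",
                        B = 39, seed = r)
    reps <- nulls$score[nulls$sample_id == colnames(m)[1]]
    hits[r] <- obs < stats::quantile(reps, q, type = 7)
  }
  expect_gt(mean(hits), q - 0.2)
  expect_lt(mean(hits), q + 0.2)
})
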