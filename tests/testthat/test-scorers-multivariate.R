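test_that("combinedZ matches brute-force sum of z-scores over sqrt(k)", {
  set.seed(31)
  m <- rand_mat(20, 10)
  sig <- new_signature("s", paste0("g", c(2, 5, 9, 14, 17)))
  got <- score_combined_z(m, sig)
  z <- t(apply(m[sig$features, ], 1, function(r) (r - mean(r)) / stats::sd(r)))
  want <- colSums(z) / sqrt(5)
  expect_equal(got$score, want, tolerance = 1e-12)
  expect_identical(unname(got$n_used), rep(5L, 10))
})

test_that("combinedZ of a single feature equals its z-score; all-constant is NA", {
  set.seed(32)
  m <- rand_mat(6, 5)
  sig1 <- new_signature("one", "g3")
  z3 <- (m["g3", ] - mean(m["g3", ])) / stats::sd(m["g3", ])
  expect_equal(score_combined_z(m, sig1)$score, z3, tolerance = 1e-12)

  m["g1", ] <- 7
  m["g2", ] <- -1
  expect_warning(out <- score_combined_z(m, new_signature("c", c("g1", "g2"))),
                 "constant")
  expect_true(all(is.na(out$score)))
})

test_that("pca1 recovers the sample pattern of a rank-1 submatrix", {
  set.seed(33)
  p <- stats::rnorm(8)
  coef <- stats::runif(4, 0.5, 2)
  m <- outer(coef, p)
  dimnames(m) <- list(paste0("g", 1:4), paste0("s", 1:8))
  sig <- new_signature("s", rownames(m))
  sc <- score_pca1(m, sig)$score
  expect_equal(abs(stats::cor(sc, p)), 1, tolerance = 1e-10)
})

test_that("pca1 and plage match eigen oracles; degenerate cases handled", {
  set.seed(34)
  for (rep in 1:20) {
    m <- rand_mat(sample(4:10, 1), sample(3:8, 1))
    sig <- new_signature("s", rownames(m))
    expect_equal(score_pca1(m, sig)$score,
                 stats::setNames(oracle_pca1(m), colnames(m)),
                 tolerance = 1e-8)
    expect_equal(score_plage(m, sig)$score,
                 stats::setNames(oracle_plage(m), colnames(m)),
                 tolerance = 1e-8)
  }
  flat <- matrix(5, 3, 4, dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  expect_warning(z <- score_pca1(flat, new_signature("f", rownames(flat))),
                 "zeros")
  expect_identical(unname(z$score), rep(0, 4))
  expect_warning(pl <- score_plage(flat, new_signature("f", rownames(flat))),
                 "constant")
  expect_true(all(is.na(pl$score)))
})

test_that("plage scores have unit norm and duplicated standardized rows change nothing", {
  set.seed(35)
  m <- rand_mat(5, 6)
  sig <- new_signature("s", rownames(m))
  sc <- score_plage(m, sig)$score
  expect_equal(sum(sc^2), 1, tolerance = 1e-12)

  dup <- rbind(m, m)
  rownames(dup) <- paste0("g", 1:10)
  sc_dup <- score_plage(dup, new_signature("d", rownames(dup)))$score
  expect_equal(unname(sc_dup), unname(sc), tolerance = 1e-8)
})

test_that("pca1/plage are invariant under signature feature permutation", {
  set.seed(36)
  m <- rand_mat(9, 6)
  feats <- paste0("g", c(1, 3, 5, 7, 9))
  for (fn in list(score_pca1, score_plage)) {
    a <- fn(m, new_signature("s", feats))$score
    b <- fn(m, new_signature("s", rev(feats)))$score
    expect_equal(a, b, tolerance = 1e-10)
  }
})

test_that("ssgsea matches the position-enumeration oracle and is rank-monotone", {
  set.seed(37)
  for (rep in 1:15) {
    m <- rand_mat(sample(5:10, 1), sample(1:5, 1))
    k <- sample(seq_len(nrow(m) - 1), 1)
    feats <- sample(rownames(m), k)
    sig <- new_signature("s", feats)
    got <- score_ssgsea(m, sig, alpha = 0.25)$score
    expect_equal(unname(got), oracle_ssgsea(m, feats, 0.25), tolerance = 1e-10)
  }

  # the sample whose single signature gene ranks top scores strictly higher
  m <- matrix(c(4, 3, 2, 1,
                1, 3, 2, 4), 4, 2,
              dimnames = list(paste0("g", 1:4), c("top", "bottom")))
  sc <- score_ssgsea(m, new_signature("s", "g1"))$score
  expect_gt(sc["top"], sc["bottom"])
})

test_that("ssgsea with alpha = 0 equals the unweighted ECDF-difference oracle", {
  set.seed(38)
  m <- rand_mat(8, 3)
  feats <- c("g2", "g6", "g7")
  got <- score_ssgsea(m, new_signature("s", feats), alpha = 0)$score
  want <- vapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    in_sig <- rownames(m) %in% feats
    ord <- order(-x, rownames(m))
    es <- 0; pi <- 0; po <- 0
    for (pos in seq_along(ord)) {
      if (in_sig[ord[pos]]) pi <- pi + 1 / sum(in_sig)
      else po <- po + 1 / sum(!in_sig)
      es <- es + (pi - po)
    }
    es
  }, numeric(1))
  expect_equal(unname(got), want, tolerance = 1e-12)
})

test_that("ssgsea score rises when in-signature values move above all others", {
  set.seed(39)
  m <- rand_mat(12, 2)
  feats <- c("g3", "g8")
  before <- score_ssgsea(m, new_signature("s", feats))$score[1]
  m2 <- m
  m2[feats, 1] <- max(m[, 1]) + 1:2
  after <- score_ssgsea(m2, new_signature("s", feats))$score[1]
  expect_gt(after, before)
})

test_that("ssgsea rejects a signature covering every feature", {
  m <- rand_mat(4, 2)
  expect_error(score_ssgsea(m, new_signature("all", rownames(m))),
               "background")
})

test_that("gsva matches the staged reference implementation", {
  set.seed(40)
  for (rep in 1:15) {
    m <- rand_mat(sample(5:10, 1), sample(3:6, 1))
    k <- sample(seq_len(nrow(m) - 1), 1)
    feats <- sample(rownames(m), k)
    got <- score_gsva(m, new_signature("s", feats))$score
    expect_equal(unname(got), oracle_gsva(m, feats), tolerance = 1e-10)
  }
})

test_that("gsva respects sample symmetry and permutation equivariance", {
  set.seed(41)
  m <- rand_mat(6, 4)
  feats <- c("g1", "g4")
  dup <- cbind(m, m[, 2, drop = FALSE])
  colnames(dup) <- c(colnames(m), "s2copy")
  sc <- score_gsva(dup, new_signature("s", feats))$score
  expect_equal(unname(sc["s2"]), unname(sc["s2copy"]), tolerance = 1e-12)

  perm <- sample(ncol(m))
  a <- score_gsva(m, new_signature("s", feats))$score
  b <- score_gsva(m[, perm], new_signature("s", feats))$score
  expect_equal(a[colnames(m)[perm]], b, tolerance = 1e-12)
})

test_that("gsva flags zero-variance features and needs >= 3 samples", {
  set.seed(42)
  m <- rand_mat(5, 4)
  m["g2", ] <- 3
  expect_warning(score_gsva(m, new_signature("s", c("g1", "g3"))), "zero-variance")
  expect_error(score_gsva(rand_mat(5, 2), new_signature("s", "g1")), "samples")
})
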