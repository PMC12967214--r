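# Independent reference implementations used to check the scorers and
# transforms. Deliberately naive: manual quartile interpolation, literal
# position-by-position enumeration for the enrichment walks, eigen
# decompositions for the factor scores.

# type-7 quantile by hand: linear interpolation between order statistics
q7 <- function(v, p) {
  v <- sort(v)
  h <- (length(v) - 1) * p
  lo <- floor(h) + 1
  hi <- ceiling(h) + 1
  v[lo] + (h - lo + 1) * (v[hi] - v[lo])
}

# interquartile mean via replication: each observation becomes 4 equal
# slots, so exact trimming of n slots per end reproduces fractional
# end-weights
oracle_iqm <- function(v) {
  w <- rep(sort(v), each = 4)
  n4 <- length(w)
  mean(w[(n4 / 4 + 1):(3 * n4 / 4)])
}

oracle_simple <- function(v, scorer, w = rep(1, length(v)), trim = 0.1) {
  keep <- !is.na(v)
  v <- v[keep]
  w <- w[keep]
  if (length(v) == 0) return(NA_real_)
  switch(scorer,
    sum = sum(v),
    weightedSum = sum(w * v),
    mean = mean(v),
    weightedMean = sum(w * v) / sum(w),
    trimmedMean = mean(v, trim = trim),
    median = q7(v, 0.5),
    mode = {
      tab <- table(v)
      as.numeric(names(tab)[which.max(tab)]) # table sorts values ascending
    },
    midrange = (min(v) + max(v)) / 2,
    midhinge = (q7(v, 0.25) + q7(v, 0.75)) / 2,
    trimean = (q7(v, 0.25) + 2 * q7(v, 0.5) + q7(v, 0.75)) / 4,
    iqr = q7(v, 0.75) - q7(v, 0.25),
    iqm = oracle_iqm(v),
    mad = stats::mad(v, constant = 1),
    aad = mean(abs(v - mean(v)))
  )
}

rand_mat <- function(nr, nc, prefix = "g", na_frac = 0) {
  m <- matrix(stats::rnorm(nr * nc), nr, nc,
              dimnames = list(paste0(prefix, seq_len(nr)),
                              paste0("s", seq_len(nc))))
  if (na_frac > 0) {
    n_na <- floor(na_frac * length(m))
    if (n_na > 0) m[sample(length(m), n_na)] <- NA
  }
  m
}

# first-principal-axis scores through the sample covariance eigenproblem
oracle_pca1 <- function(x) {
  xc <- x - rowMeans(x)
  C <- xc %*% t(xc) / (ncol(x) - 1)
  u <- eigen(C, symmetric = TRUE)$vectors[, 1]
  score <- as.numeric(t(u) %*% xc)
  r <- suppressWarnings(stats::cor(score, colMeans(x)))
  if (!is.na(r) && r < 0) score <- -score
  score
}

# PLAGE activity through the eigenproblem of the sample-by-sample Gram
# matrix of the row-standardized submatrix
oracle_plage <- function(x) {
  z <- t(apply(x, 1, function(r) (r - mean(r)) / stats::sd(r)))
  G <- t(z) %*% z
  v <- eigen(G, symmetric = TRUE)$vectors[, 1]
  v <- v / sqrt(sum(v^2))
  r <- suppressWarnings(stats::cor(v, colMeans(z)))
  if (!is.na(r) && r < 0) v <- -v
  v
}

# literal per-position enumeration of the single-sample enrichment walk
oracle_ssgsea_one <- function(x, ids, in_sig, alpha) {
  N <- length(x)
  k <- sum(in_sig)
  ord <- order(-x, ids)
  denom_in <- 0
  for (pos in seq_len(N)) {
    f <- ord[pos]
    if (in_sig[f]) denom_in <- denom_in + (N - pos + 1)^alpha
  }
  p_in <- 0
  p_out <- 0
  es <- 0
  for (pos in seq_len(N)) {
    f <- ord[pos]
    if (in_sig[f]) {
      p_in <- p_in + (N - pos + 1)^alpha / denom_in
    } else {
      p_out <- p_out + 1 / (N - k)
    }
    es <- es + (p_in - p_out)
  }
  es
}

oracle_ssgsea <- function(m, sig_features, alpha = 0.25) {
  in_sig <- rownames(m) %in% sig_features
  vapply(seq_len(ncol(m)), function(j) {
    oracle_ssgsea_one(m[, j], rownames(m), in_sig, alpha)
  }, numeric(1))
}

# literal three-stage reference for the kernel-CDF / rank-statistic /
# random-walk enrichment score
oracle_gsva <- function(m, sig_features, tau = 1) {
  N <- nrow(m)
  n <- ncol(m)
  in_sig <- rownames(m) %in% sig_features
  k <- sum(in_sig)
  zhat <- matrix(NA_real_, N, n)
  for (i in seq_len(N)) {
    x <- m[i, ]
    s <- stats::sd(x)
    if (s == 0) {
      zhat[i, ] <- 0.5
    } else {
      h <- max(s / 4, 1e-12 * max(1, abs(mean(x))))
      for (j in seq_len(n)) {
        zhat[i, j] <- mean(stats::pnorm((x[j] - x) / h))
      }
    }
  }
  es <- numeric(n)
  for (j in seq_len(n)) {
    ord <- order(-zhat[, j], rownames(m))
    r <- integer(N)
    r[ord] <- seq_len(N)
    t_stat <- abs(N / 2 - r)
    denom <- sum(t_stat[in_sig]^tau)
    v <- 0
    v_max <- 0
    v_min <- 0
    for (pos in seq_len(N)) {
      f <- ord[pos]
      if (in_sig[f]) {
        v <- v + (if (denom > 0) t_stat[f]^tau / denom else 0)
      } else {
        v <- v - 1 / (N - k)
      }
      v_max <- max(v_max, v)
      v_min <- min(v_min, v)
    }
    es[j] <- v_max + v_min
  }
  es
}
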