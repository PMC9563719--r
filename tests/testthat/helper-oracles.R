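# Independent brute-force oracles, written as straightforward loops so they
# share no code path with the implementation they check.

# GLCM by explicit pixel-pair enumeration.
brute_glcm <- function(img, levels, dr, dc) {
  P <- matrix(0, levels, levels)
  for (r in seq_len(nrow(img))) {
    for (c in seq_len(ncol(img))) {
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= nrow(img) && c2 >= 1 && c2 <= ncol(img)) {
        i <- img[r, c] + 1; j <- img[r2, c2] + 1
        P[i, j] <- P[i, j] + 1
        P[j, i] <- P[j, i] + 1
      }
    }
  }
  P / sum(P)
}

# The four texture statistics by explicit double loop.
brute_glcm_features <- function(P) {
  L <- nrow(P)
  mu_i <- mu_j <- 0
  for (i in 1:L) for (j in 1:L) {
    mu_i <- mu_i + (i - 1) * P[i, j]
    mu_j <- mu_j + (j - 1) * P[i, j]
  }
  v_i <- v_j <- 0
  for (i in 1:L) for (j in 1:L) {
    v_i <- v_i + (i - 1 - mu_i)^2 * P[i, j]
    v_j <- v_j + (j - 1 - mu_j)^2 * P[i, j]
  }
  contrast <- entropy <- unif <- num <- 0
  for (i in 1:L) for (j in 1:L) {
    p <- P[i, j]
    contrast <- contrast + (i - j)^2 * p
    if (p > 0) entropy <- entropy - p * log2(p)
    unif <- unif + p^2
    num <- num + (i - 1 - mu_i) * (j - 1 - mu_j) * p
  }
  corr <- if (v_i <= 0 || v_j <= 0) 0 else num / sqrt(v_i * v_j)
  c(correlation = corr, contrast = contrast, entropy = entropy,
    uniformity = unif)
}

# Univariate PLS via SVD of the cross-covariance at every step (distinct
# code path from the NIPALS implementation); returns fitted values.
pls_svd_oracle <- function(X, y, a, X_new = X) {
  ctr <- colMeans(X); scl <- apply(X, 2, sd); scl[scl <= 0] <- 1
  Xk <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  Nk <- sweep(sweep(X_new, 2, ctr), 2, scl, "/")
  yk <- y - mean(y)
  fit <- rep(mean(y), nrow(X_new))
  for (k in seq_len(a)) {
    w <- svd(crossprod(Xk, matrix(yk)))$u[, 1]
    t_ <- Xk %*% w
    tn <- Nk %*% w
    p_ <- crossprod(Xk, t_) / sum(t_^2)
    q_ <- sum(yk * t_) / sum(t_^2)
    fit <- fit + q_ * tn
    Xk <- Xk - tcrossprod(t_, p_)
    Nk <- Nk - tcrossprod(tn, p_)
    yk <- yk - q_ * t_
  }
  as.numeric(fit)
}

# Pearson correlation by the textbook sum formula.
brute_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}
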