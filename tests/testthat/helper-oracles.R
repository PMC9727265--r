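# Independent oracles used to cross-check the package implementations.

# AUC by brute force over every positive-negative pair (ties count 1/2).
auc_pairwise <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Full Newton-Raphson logistic MLE, independent of glm's IRLS code path.
logistic_newton <- function(X, y, tol = 1e-12, max_iter = 100) {
  X <- cbind(1, as.matrix(X))
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    grad <- drop(t(X) %*% (y - p))
    H <- t(X) %*% (X * W)
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

# ICC(2,1) from explicit variance-component mean squares (matrix input).
icc21_matrix <- function(mat) {
  n <- nrow(mat)
  k <- ncol(mat)
  gm <- mean(mat)
  rm <- rowMeans(mat)
  cm <- colMeans(mat)
  msr <- k * sum((rm - gm)^2) / (n - 1)
  msc <- n * sum((cm - gm)^2) / (k - 1)
  mse <- sum((mat - outer(rm, rep(1, k)) - outer(rep(1, n), cm) + gm)^2) /
    ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# long-format helper for icc()/bland_altman() from a matrix
mat_to_long <- function(mat) {
  tibble::tibble(
    subject_id = rep(rownames(mat) %||% paste0("s", seq_len(nrow(mat))),
                     each = ncol(mat)),
    protocol = rep(colnames(mat) %||% paste0("p", seq_len(ncol(mat))),
                   times = nrow(mat)),
    mesf = as.numeric(t(mat))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
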