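# Exact (dense) t-SNE with perplexity calibration, early exaggeration and
# momentum gradient descent. O(n^2) per iteration; intended for the
# desk-scale spectrum counts this package works with.

tsne_affinities <- function(X, perplexity, tol = 1e-5) {
  D2 <- as.matrix(dist(X))^2
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1; betamin <- -Inf; betamax <- Inf
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sumP <- sum(p)
      if (sumP == 0) { p[] <- 1 / length(p); sumP <- 1 }
      H <- log(sumP) + beta * sum(di * p) / sumP
      diff <- H - logU
      if (abs(diff) < tol) break
      if (diff > 0) {
        betamin <- beta
        beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
      } else {
        betamax <- beta
        beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2
      }
    }
    P[i, -i] <- p / sum(p)
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, .Machine$double.eps)
}

tsne_run <- function(X, perplexity = 30, max_iter = 500, seed = 1,
                     eta = 200, exaggeration = 12, exaggerate_iter = 100) {
  n <- nrow(X)
  P <- tsne_affinities(X, perplexity)
  with_seed(seed, {
    Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
    V <- matrix(0, n, 2)
    Pe <- P * exaggeration
    for (it in seq_len(max_iter)) {
      Puse <- if (it <= exaggerate_iter) Pe else P
      num <- 1 / (1 + as.matrix(dist(Y))^2)
      diag(num) <- 0
      Q <- pmax(num / sum(num), .Machine$double.eps)
      W <- (Puse - Q) * num
      grad <- 4 * (diag(rowSums(W)) - W) %*% Y
      momentum <- if (it <= 250) 0.5 else 0.8
      V <- momentum * V - eta * grad
      Y <- Y + V
      Y <- sweep(Y, 2, colMeans(Y))
    }
    num <- 1 / (1 + as.matrix(dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), .Machine$double.eps)
    kl <- sum(P * log(P / Q))
    list(Y = Y, kl = kl)
  })
}
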