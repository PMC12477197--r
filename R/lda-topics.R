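# Latent Dirichlet Allocation fitted by (collapsed-free) variational EM on
# a document-term count matrix. Vectorized across documents; suitable for
# the few-topic, dense-count setting of discretized spectra.

lda_vem <- function(N, n_topics, alpha = 0.1, seed = 1, max_iter = 60,
                    inner_iter = 2, tol = 1e-6) {
  n_doc <- nrow(N); n_word <- ncol(N)
  with_seed(seed, {
    beta <- matrix(stats::rgamma(n_topics * n_word, shape = 100), n_topics, n_word)
    beta <- beta / rowSums(beta)
    gamma <- matrix(alpha + rowSums(N) / n_topics, n_doc, n_topics)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      for (inner in seq_len(inner_iter)) {
        Tm <- exp(digamma(gamma) - digamma(rowSums(gamma)))
        S <- matrix(0, n_doc, n_word)
        for (k in seq_len(n_topics)) S <- S + outer(Tm[, k], beta[k, ])
        S[S == 0] <- .Machine$double.xmin
        for (k in seq_len(n_topics)) {
          gamma[, k] <- alpha + rowSums(N * (outer(Tm[, k], beta[k, ]) / S))
        }
      }
      beta_new <- beta
      for (k in seq_len(n_topics)) {
        bk <- colSums(N * (outer(Tm[, k], beta[k, ]) / S)) + 1e-10
        beta_new[k, ] <- bk / sum(bk)
      }
      delta <- max(abs(beta_new - beta))
      beta <- beta_new
      # observed-data proxy: expected log-likelihood under mean topic mix
      theta <- gamma / rowSums(gamma)
      M <- theta %*% beta
      ll <- sum(N * log(pmax(M, .Machine$double.xmin)))
      if (delta < tol || abs(ll - ll_old) < tol * abs(ll_old)) break
      ll_old <- ll
    }
    list(theta = gamma / rowSums(gamma), beta = beta, gamma = gamma,
         loglik = ll, iterations = it)
  })
}
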