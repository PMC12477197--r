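# Minimal dense feed-forward networks and a single-layer GRU classifier,
# trained full-batch with Adam, softmax cross-entropy and early stopping on
# a held-out validation split. Gradients are plain backpropagation /
# backpropagation-through-time and are verified against finite differences
# in the test suite.

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

xent_loss <- function(P, Y1) -mean(rowSums(Y1 * log(pmax(P, 1e-12))))

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (i in seq_along(params)) {
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * grads[[i]]
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * grads[[i]]^2
    mhat <- state$m[[i]] / (1 - beta1^state$t)
    vhat <- state$v[[i]] / (1 - beta2^state$t)
    params[[i]] <- params[[i]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

onehot <- function(y, classes) {
  Y <- matrix(0, length(y), length(classes), dimnames = list(NULL, classes))
  Y[cbind(seq_along(y), match(as.character(y), classes))] <- 1
  Y
}

## ---- dense feed-forward network ----

dense_init <- function(n_in, hidden, n_out, seed) {
  sizes <- c(n_in, hidden, n_out)
  with_seed(seed, {
    params <- list()
    for (l in seq_len(length(sizes) - 1)) {
      fan_in <- sizes[l]
      params[[paste0("W", l)]] <- matrix(rnorm(fan_in * sizes[l + 1],
                                               sd = sqrt(2 / fan_in)),
                                         fan_in, sizes[l + 1])
      params[[paste0("b", l)]] <- rep(0, sizes[l + 1])
    }
    params
  })
}

dense_forward <- function(params, X) {
  L <- length(params) / 2
  A <- list(X)
  for (l in seq_len(L)) {
    Z <- sweep(A[[l]] %*% params[[paste0("W", l)]], 2,
               params[[paste0("b", l)]], "+")
    A[[l + 1]] <- if (l < L) pmax(Z, 0) else softmax_rows(Z)
  }
  A
}

dense_loss_grad <- function(params, X, Y1, l2 = 0) {
  L <- length(params) / 2
  A <- dense_forward(params, X)
  P <- A[[L + 1]]
  n <- nrow(X)
  loss <- xent_loss(P, Y1)
  grads <- params
  delta <- (P - Y1) / n
  for (l in rev(seq_len(L))) {
    W <- params[[paste0("W", l)]]
    grads[[paste0("W", l)]] <- crossprod(A[[l]], delta) + l2 * W
    grads[[paste0("b", l)]] <- colSums(delta)
    if (l2 > 0) loss <- loss + l2 / 2 * sum(W^2)
    if (l > 1) delta <- (delta %*% t(W)) * (A[[l]] > 0)
  }
  list(loss = loss, grads = grads)
}

dense_train <- function(X, y, classes, hidden, epochs = 100, lr = 1e-3,
                        l2 = 1e-4, val_frac = 0.15, patience = 8, seed = 1) {
  Y1 <- onehot(y, classes)
  n <- nrow(X)
  idx <- with_seed(derive_seed(seed, 77), sample(n))
  n_val <- max(1, round(val_frac * n))
  val <- idx[seq_len(n_val)]; trn <- idx[-seq_len(n_val)]
  if (length(trn) == 0) { trn <- idx; val <- idx }
  params <- dense_init(ncol(X), hidden, length(classes), seed)
  state <- adam_init(params)
  best <- list(loss = Inf, params = params)
  wait <- 0
  history <- numeric(0)
  for (e in seq_len(epochs)) {
    lg <- dense_loss_grad(params, X[trn, , drop = FALSE],
                          Y1[trn, , drop = FALSE], l2)
    st <- adam_step(params, lg$grads, state, lr)
    params <- st$params; state <- st$state
    vp <- dense_forward(params, X[val, , drop = FALSE])
    vloss <- xent_loss(vp[[length(vp)]], Y1[val, , drop = FALSE])
    history <- c(history, vloss)
    if (vloss < best$loss - 1e-6) {
      best <- list(loss = vloss, params = params); wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= patience) break
    }
  }
  list(params = best$params, classes = classes, history = history)
}

dense_predict_proba <- function(fit, X) {
  A <- dense_forward(fit$params, X)
  P <- A[[length(A)]]
  colnames(P) <- fit$classes
  P
}

## ---- single-layer GRU over patched spectra ----

# Chop rows of X into a sequence of `patch`-point segments (zero-padded).
patchify <- function(X, patch = 50, stride = 50) {
  p <- ncol(X)
  starts <- seq(1, p, by = stride)
  lapply(starts, function(s) {
    cols <- s:min(s + patch - 1, p)
    seg <- X[, cols, drop = FALSE]
    if (length(cols) < patch) {
      seg <- cbind(seg, matrix(0, nrow(X), patch - length(cols)))
    }
    seg
  })
}

gru_init <- function(d, H, K, seed) {
  with_seed(seed, {
    mk <- function(a, b, sdv) matrix(rnorm(a * b, sd = sdv), a, b)
    list(Wz = mk(d, H, sqrt(1 / d)), Uz = mk(H, H, sqrt(1 / H)), bz = rep(0, H),
         Wr = mk(d, H, sqrt(1 / d)), Ur = mk(H, H, sqrt(1 / H)), br = rep(0, H),
         Wh = mk(d, H, sqrt(1 / d)), Uh = mk(H, H, sqrt(1 / H)), bh = rep(0, H),
         Wo = mk(H, K, sqrt(1 / H)), bo = rep(0, K))
  })
}

sigmoid <- function(x) 1 / (1 + exp(-x))

gru_forward <- function(params, seq_x) {
  n <- nrow(seq_x[[1]]); H <- ncol(params$Uz)
  h <- matrix(0, n, H)
  cache <- vector("list", length(seq_x))
  for (t in seq_along(seq_x)) {
    Xt <- seq_x[[t]]
    z <- sigmoid(sweep(Xt %*% params$Wz + h %*% params$Uz, 2, params$bz, "+"))
    r <- sigmoid(sweep(Xt %*% params$Wr + h %*% params$Ur, 2, params$br, "+"))
    hc <- tanh(sweep(Xt %*% params$Wh + (r * h) %*% params$Uh, 2, params$bh, "+"))
    h_new <- (1 - z) * h + z * hc
    cache[[t]] <- list(z = z, r = r, hc = hc, h_prev = h)
    h <- h_new
  }
  logits <- sweep(h %*% params$Wo, 2, params$bo, "+")
  list(P = softmax_rows(logits), h = h, cache = cache)
}

gru_loss_grad <- function(params, seq_x, Y1) {
  fw <- gru_forward(params, seq_x)
  n <- nrow(Y1)
  loss <- xent_loss(fw$P, Y1)
  grads <- lapply(params, function(p) p * 0)
  dlogits <- (fw$P - Y1) / n
  grads$Wo <- crossprod(fw$h, dlogits)
  grads$bo <- colSums(dlogits)
  dh <- dlogits %*% t(params$Wo)
  for (t in rev(seq_along(seq_x))) {
    cc <- fw$cache[[t]]
    Xt <- seq_x[[t]]
    dz <- dh * (cc$hc - cc$h_prev)
    dhc <- dh * cc$z
    dh_prev <- dh * (1 - cc$z)
    dhc_pre <- dhc * (1 - cc$hc^2)
    grads$Wh <- grads$Wh + crossprod(Xt, dhc_pre)
    grads$Uh <- grads$Uh + crossprod(cc$r * cc$h_prev, dhc_pre)
    grads$bh <- grads$bh + colSums(dhc_pre)
    drh <- dhc_pre %*% t(params$Uh)
    dr <- drh * cc$h_prev
    dh_prev <- dh_prev + drh * cc$r
    dz_pre <- dz * cc$z * (1 - cc$z)
    grads$Wz <- grads$Wz + crossprod(Xt, dz_pre)
    grads$Uz <- grads$Uz + crossprod(cc$h_prev, dz_pre)
    grads$bz <- grads$bz + colSums(dz_pre)
    dh_prev <- dh_prev + dz_pre %*% t(params$Uz)
    dr_pre <- dr * cc$r * (1 - cc$r)
    grads$Wr <- grads$Wr + crossprod(Xt, dr_pre)
    grads$Ur <- grads$Ur + crossprod(cc$h_prev, dr_pre)
    grads$br <- grads$br + colSums(dr_pre)
    dh_prev <- dh_prev + dr_pre %*% t(params$Ur)
    dh <- dh_prev
  }
  list(loss = loss, grads = grads)
}

gru_train <- function(X, y, classes, hidden = 32, patch = 50, stride = 50,
                      epochs = 80, lr = 5e-3, val_frac = 0.15, patience = 8,
                      seed = 1) {
  Y1 <- onehot(y, classes)
  n <- nrow(X)
  idx <- with_seed(derive_seed(seed, 78), sample(n))
  n_val <- max(1, round(val_frac * n))
  val <- idx[seq_len(n_val)]; trn <- idx[-seq_len(n_val)]
  if (length(trn) == 0) { trn <- idx; val <- idx }
  params <- gru_init(patch, hidden, length(classes), seed)
  state <- adam_init(params)
  seq_trn <- patchify(X[trn, , drop = FALSE], patch, stride)
  seq_val <- patchify(X[val, , drop = FALSE], patch, stride)
  best <- list(loss = Inf, params = params); wait <- 0
  history <- numeric(0)
  for (e in seq_len(epochs)) {
    lg <- gru_loss_grad(params, seq_trn, Y1[trn, , drop = FALSE])
    st <- adam_step(params, lg$grads, state, lr)
    params <- st$params; state <- st$state
    vloss <- xent_loss(gru_forward(params, seq_val)$P, Y1[val, , drop = FALSE])
    history <- c(history, vloss)
    if (vloss < best$loss - 1e-6) {
      best <- list(loss = vloss, params = params); wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= patience) break
    }
  }
  list(params = best$params, classes = classes, patch = patch,
       stride = stride, history = history)
}

gru_predict_proba <- function(fit, X) {
  P <- gru_forward(fit$params, patchify(X, fit$patch, fit$stride))$P
  colnames(P) <- fit$classes
  P
}
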