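# Dimensionality-reduction views of the preprocessed spectra: t-SNE,
# LDA topic embedding, and OPLS-DA.

new_embedding <- function(coords, labels, method, diagnostics = list()) {
  out <- tibble(id = seq_len(nrow(coords)),
                x = coords[, 1], y = coords[, 2],
                label = if (is.null(labels)) NA_character_ else as.character(labels))
  attr(out, "method") <- method
  attr(out, "diagnostics") <- diagnostics
  class(out) <- c("raman_embedding", class(out))
  out
}

#' t-SNE embedding of a spectra matrix
#'
#' @param X Numeric matrix, one row per spectrum (see [spectra_matrix()]).
#' @param labels Optional group labels carried into the result.
#' @param perplexity t-SNE perplexity; needs at least `3 * perplexity`
#'   rows.
#' @param seed Seed for the random initialization.
#' @param max_iter Gradient-descent iterations.
#' @return A `raman_embedding` tibble (`id`, `x`, `y`, `label`) with the
#'   final KL divergence in `attr(, "diagnostics")`.
#' @export
tsne_embed <- function(X, labels = NULL, perplexity = 30, seed = 1,
                       max_iter = 500) {
  X <- as.matrix(X)
  if (nrow(X) < 3 * perplexity) {
    abort(sprintf("t-SNE with perplexity %g needs at least %d rows, got %d",
                  perplexity, ceiling(3 * perplexity), nrow(X)))
  }
  fit <- tsne_run(X, perplexity = perplexity, max_iter = max_iter, seed = seed)
  new_embedding(fit$Y, labels, "t-SNE", list(kl_divergence = fit$kl))
}

#' LDA topic embedding of a spectra matrix
#'
#' Spectra are discretized to pseudo-counts (`round(intensity * scale)`),
#' a latent Dirichlet allocation topic model is fitted by variational EM,
#' and each spectrum is embedded at its first two topic proportions.
#'
#' @param X Non-negative spectra matrix (area-normalize first).
#' @param labels Optional group labels.
#' @param n_topics Number of topics.
#' @param seed Seed for the topic initialization.
#' @param scale Pseudo-count scale applied before rounding.
#' @param max_iter Variational EM iteration cap.
#' @param clip_negative Tolerated negative intensity mass (fraction of the
#'   positive mass); baseline correction and smoothing leave small negative
#'   ripples, which are clipped to zero. More negative input than this
#'   raises an error.
#' @return A `raman_embedding` tibble; the fitted topic-word matrix and
#'   per-spectrum topic proportions are in `attr(, "diagnostics")`.
#' @export
lada_embed <- function(X, labels = NULL, n_topics = 3, seed = 1,
                       scale = 100, max_iter = 60, clip_negative = 0.05) {
  X <- as.matrix(X)
  neg_mass <- sum(abs(X[X < 0])) / max(sum(X[X > 0]), 1e-12)
  if (neg_mass > clip_negative) {
    abort("negative intensities; area-normalize the spectra before topic modelling")
  }
  N <- round(pmax(X, 0) * scale)
  keep <- colSums(N) > 0
  fit <- lda_vem(N[, keep, drop = FALSE], n_topics = n_topics, seed = seed,
                 max_iter = max_iter)
  theta <- fit$theta
  coords <- cbind(theta[, 1], if (n_topics >= 2) theta[, 2] else rep(0, nrow(theta)))
  new_embedding(coords, labels, "LaDA",
                list(topics = fit$beta, theta = theta, loglik = fit$loglik))
}

# One NIPALS PLS component for multivariate Y.
nipals_pls_component <- function(X, Y, tol = 1e-10, max_iter = 500) {
  u <- Y[, which.max(colSums(Y^2))]
  t_old <- 0
  for (i in seq_len(max_iter)) {
    w <- crossprod(X, u)
    w <- w / sqrt(sum(w^2))
    tt <- X %*% w
    q <- crossprod(Y, tt) / sum(tt^2)
    u <- Y %*% q / sum(q^2)
    if (sqrt(sum((tt - t_old)^2)) < tol) break
    t_old <- tt
  }
  p <- crossprod(X, tt) / sum(tt^2)
  list(w = drop(w), t = drop(tt), p = drop(p), q = drop(q))
}

#' Fit an OPLS-DA model
#'
#' Orthogonal partial least squares discriminant analysis, NIPALS based:
#' the class membership matrix is one-hot encoded, `n_orth` components of
#' X-variation orthogonal to class membership are removed, and predictive
#' PLS components are fitted on the filtered matrix.
#'
#' @param X Spectra matrix (rows = spectra).
#' @param y Class labels (2 or more classes).
#' @param n_orth Number of orthogonal components to remove.
#' @param n_pred Number of predictive components; defaults to
#'   `min(n_classes - 1, 2)`.
#' @return An object of class `oplsda` with predictive/orthogonal scores
#'   and loadings, explained variances `R2X` (split into predictive and
#'   orthogonal parts) and `R2Y`, plus an `embedding` element: the first
#'   two predictive scores (or predictive score 1 vs orthogonal score 1
#'   for two classes).
#' @export
oplsda_fit <- function(X, y, n_orth = 1, n_pred = NULL) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) < 2) abort("OPLS-DA needs at least two classes")
  if (n_orth < 1) abort("`n_orth` must be >= 1")
  n_pred <- n_pred %||% min(nlevels(y) - 1, 2)

  xcenter <- colMeans(X)
  Xc <- sweep(X, 2, xcenter)
  const <- apply(Xc, 2, function(col) all(abs(col) < 1e-12))
  if (any(const)) {
    warn(sprintf("dropping %d constant column(s) after centring", sum(const)))
    Xc <- Xc[, !const, drop = FALSE]
  }
  Y <- stats::model.matrix(~ y - 1)
  colnames(Y) <- levels(y)
  Y <- sweep(Y, 2, colMeans(Y))
  ssx <- sum(Xc^2); ssy <- sum(Y^2)

  # strip orthogonal variation
  T_orth <- NULL; P_orth <- NULL; W_orth <- NULL
  Xf <- Xc
  for (j in seq_len(n_orth)) {
    comp <- nipals_pls_component(Xf, Y)
    w_o <- comp$p - sum(comp$w * comp$p) / sum(comp$w^2) * comp$w
    nrm <- sqrt(sum(w_o^2))
    if (nrm < 1e-12) break
    w_o <- w_o / nrm
    t_o <- drop(Xf %*% w_o)
    p_o <- drop(crossprod(Xf, t_o)) / sum(t_o^2)
    Xf <- Xf - tcrossprod(t_o, p_o)
    T_orth <- cbind(T_orth, t_o); P_orth <- cbind(P_orth, p_o)
    W_orth <- cbind(W_orth, w_o)
  }

  # predictive components on the filtered matrix
  T_pred <- NULL; P_pred <- NULL; W_pred <- NULL; Q_pred <- NULL
  Xd <- Xf; Yd <- Y
  for (a in seq_len(n_pred)) {
    comp <- nipals_pls_component(Xd, Yd)
    T_pred <- cbind(T_pred, comp$t); P_pred <- cbind(P_pred, comp$p)
    W_pred <- cbind(W_pred, comp$w); Q_pred <- cbind(Q_pred, comp$q)
    Xd <- Xd - tcrossprod(comp$t, comp$p)
    Yd <- Yd - tcrossprod(comp$t, comp$q)
  }

  r2x_orth <- if (is.null(T_orth)) 0 else
    sum((T_orth %*% t(P_orth))^2) / ssx
  r2x_pred <- sum((T_pred %*% t(P_pred))^2) / ssx
  r2y <- 1 - sum(Yd^2) / ssy

  coords <- if (ncol(T_pred) >= 2) T_pred[, 1:2] else
    cbind(T_pred[, 1], T_orth[, 1])
  emb <- new_embedding(coords, y, "OPLS-DA",
                       list(R2X_pred = r2x_pred, R2X_orth = r2x_orth,
                            R2Y = r2y))
  structure(list(scores_pred = T_pred, loadings_pred = P_pred,
                 weights_pred = W_pred, q_pred = Q_pred,
                 scores_orth = T_orth, loadings_orth = P_orth,
                 weights_orth = W_orth,
                 R2X_pred = r2x_pred, R2X_orth = r2x_orth, R2Y = r2y,
                 classes = levels(y), y = y, embedding = emb,
                 n_orth = if (is.null(T_orth)) 0 else ncol(T_orth),
                 n_pred = n_pred),
            class = "oplsda")
}

#' @export
print.oplsda <- function(x, ...) {
  cat(sprintf("OPLS-DA: %d predictive + %d orthogonal component(s), %d classes\n",
              x$n_pred, x$n_orth, length(x$classes)))
  cat(sprintf("R2X (pred) %.3f | R2X (orth) %.3f | R2Y %.3f\n",
              x$R2X_pred, x$R2X_orth, x$R2Y))
  invisible(x)
}

#' @describeIn oplsda_fit Component-level summary: one row per predictive
#'   component with its explained Y-variance direction weights norm.
#' @param x An `oplsda` object.
#' @param ... Unused.
#' @export
tidy.oplsda <- function(x, ...) {
  tibble(component = c(paste0("pred", seq_len(ncol(x$scores_pred))),
                       if (!is.null(x$scores_orth))
                         paste0("orth", seq_len(ncol(x$scores_orth)))),
         type = c(rep("predictive", ncol(x$scores_pred)),
                  rep("orthogonal", if (is.null(x$scores_orth)) 0 else
                    ncol(x$scores_orth))),
         score_var = c(apply(x$scores_pred, 2, var),
                       if (!is.null(x$scores_orth))
                         apply(x$scores_orth, 2, var)))
}

#' @describeIn oplsda_fit One-row model summary (R2X split and R2Y).
#' @export
glance.oplsda <- function(x, ...) {
  tibble(n_pred = x$n_pred, n_orth = x$n_orth,
         R2X_pred = x$R2X_pred, R2X_orth = x$R2X_orth, R2Y = x$R2Y)
}
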