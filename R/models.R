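# Classifier protocol: sample-level 80/20 split, SMOTE balancing of the
# training spectra, a twelve-family model registry, sample-level k-fold
# cross-validation, and spectrum-level evaluation.

#' Sample-level train/prediction split
#'
#' Per outcome group, `floor(fraction * n)` samples go to training and the
#' remainder to prediction; all spectra of a sample stay on one side, so
#' no spectrum of a prediction sample can leak into training.
#'
#' @param data A spectra table, or any data frame with `sample_id` and
#'   `group` columns (one row per sample also works).
#' @param fraction Training fraction in (0, 1).
#' @param seed Seed for the random selection.
#' @return A tibble of class `split_plan` with columns `sample_id`,
#'   `group`, `role` (`"training"` / `"prediction"`).
#' @examples
#' d <- tibble::tibble(sample_id = as.character(1:20),
#'                     group = rep(c("A", "B", "C"), length.out = 20))
#' table(split_dataset(d, 0.8, seed = 1)$role)
#' @export
split_dataset <- function(data, fraction = 0.8, seed = 1) {
  if (!all(c("sample_id", "group") %in% names(data))) {
    abort("`data` must have `sample_id` and `group` columns")
  }
  if (fraction <= 0 || fraction >= 1) abort("`fraction` must lie in (0, 1)")
  samples <- dplyr::distinct(as_tibble(data[, c("sample_id", "group")]))
  plan <- with_seed(seed, {
    purrr::map_dfr(split(samples, samples$group), function(d) {
      n <- nrow(d)
      n_tr <- floor(fraction * n)
      if (n_tr < 1 || n_tr >= n) {
        abort(sprintf("group %s has %d samples; the %g split leaves an empty side",
                      d$group[1], n, fraction))
      }
      tr <- sample(n, n_tr)
      d$role <- "prediction"
      d$role[tr] <- "training"
      d
    })
  })
  plan <- plan[order(match(plan$sample_id, samples$sample_id)), ]
  class(plan) <- c("split_plan", class(plan))
  plan
}

#' Subset a spectra table by split role
#'
#' @param data A spectra table.
#' @param plan A [split_dataset()] plan.
#' @param role `"training"` or `"prediction"`.
#' @return The rows of `data` whose sample falls on that side.
#' @export
split_spectra <- function(data, plan, role = c("training", "prediction")) {
  role <- match.arg(role)
  check_dataset(data)
  data[data$sample_id %in% plan$sample_id[plan$role == role], , drop = FALSE]
}

#' SMOTE oversampling of the minority classes
#'
#' Equalizes all classes to the majority count by adding synthetic rows:
#' each synthetic row is a convex combination of a random minority-class
#' row and one of its `k_neighbors` nearest same-class neighbours.
#' Original rows are preserved verbatim (first in the output).
#'
#' @param X Feature matrix (rows = spectra).
#' @param y Class labels.
#' @param k_neighbors Number of same-class nearest neighbours to draw from.
#' @param seed Seed for the sampling.
#' @return A list with the balanced `X`, `y`, and a logical `synthetic`
#'   marker per row.
#' @export
smote_oversample <- function(X, y, k_neighbors = 5, seed = 1) {
  X <- as.matrix(X); y <- factor(y)
  counts <- table(y)
  target <- max(counts)
  small <- names(counts)[counts <= k_neighbors & counts < target]
  if (length(small) > 0) {
    abort(sprintf("class %s has only %d member(s); use k_neighbors < %d",
                  small[1], counts[small[1]], counts[small[1]]))
  }
  newX <- list(); newy <- character(0)
  with_seed(seed, {
    for (cls in names(counts)) {
      need <- target - counts[[cls]]
      if (need == 0) next
      idx <- which(y == cls)
      Xc <- X[idx, , drop = FALSE]
      D <- as.matrix(dist(Xc))
      diag(D) <- Inf
      nn <- t(apply(D, 1, function(r) order(r)[seq_len(min(k_neighbors, length(r) - 1))]))
      base <- sample(length(idx), need, replace = TRUE)
      pick <- nn[cbind(base, sample(ncol(nn), need, replace = TRUE))]
      lam <- runif(need)
      syn <- Xc[base, , drop = FALSE] +
        lam * (Xc[pick, , drop = FALSE] - Xc[base, , drop = FALSE])
      newX[[cls]] <- syn
      newy <- c(newy, rep(cls, need))
    }
  })
  syn_n <- length(newy)
  Xout <- rbind(X, do.call(rbind, newX))
  yout <- factor(c(as.character(y), newy), levels = levels(y))
  list(X = Xout, y = yout,
       synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, syn_n)))
}

## ---- model registry ----

#' The twelve-family classifier registry
#'
#' Traditional families (GB, KNN, RF, LSVM, LDA, LR, QDA, RSVM, NB) train
#' on principal-component scores of the spectra (standard chemometrics
#' practice, and required for full-rank covariance estimates at
#' p >> n); the deep families (MLP, ANN, GRU) consume the full spectrum,
#' the GRU as a sequence of 50-point patches.
#'
#' @return Tibble with columns `name`, `type` and a `grid` list-column of
#'   hyperparameter configurations searched by [cross_validate()].
#' @export
model_registry <- function() {
  cfg <- function(...) list(...)
  tibble(
    name = c("MLP", "ANN", "GRU", "GB", "KNN", "RF", "LSVM", "LDA", "LR",
             "QDA", "RSVM", "NB"),
    type = c("deep", "deep", "deep", rep("traditional", 9)),
    grid = list(
      list(cfg()),                                  # MLP
      list(cfg()),                                  # ANN
      list(cfg()),                                  # GRU
      list(cfg(nrounds = 50), cfg(nrounds = 150)),  # GB
      list(cfg(k = 5), cfg(k = 15)),                # KNN
      list(cfg(num_trees = 300)),                   # RF
      list(cfg(cost = 0.1), cfg(cost = 1), cfg(cost = 10)),  # LSVM
      list(cfg(ncomp = 15), cfg(ncomp = 30)),       # LDA
      list(cfg(decay = 0), cfg(decay = 0.1)),       # LR
      list(cfg(ncomp = 5), cfg(ncomp = 10)),        # QDA
      list(cfg(cost = 1), cfg(cost = 10)),          # RSVM
      list(cfg())                                   # NB
    )
  )
}

model_defaults <- function(name, n, p, class_min) {
  base <- list(ncomp = 30)
  extra <- switch(name,
    MLP = list(hidden = c(128, 64), epochs = 80, lr = 1e-3),
    ANN = list(hidden = 64, epochs = 80, lr = 1e-3),
    GRU = list(hidden = 32, patch = 50, stride = 50, epochs = 150, lr = 5e-3),
    GB = list(nrounds = 100, max_depth = 3, eta = 0.3),
    KNN = list(k = 10),
    RF = list(num_trees = 300),
    LSVM = list(cost = 1),
    LDA = list(),
    LR = list(decay = 0),
    QDA = list(ncomp = min(10, class_min - 1)),
    RSVM = list(cost = 1, subset_frac = 0.1),
    NB = list(),
    abort(sprintf("unknown model '%s'; registry: %s", name,
                  paste(model_registry()$name, collapse = ", "))))
  hp <- modifyList(base, extra)
  hp$ncomp <- max(1, min(hp$ncomp, n - 2, p, if (name == "QDA") class_min - 1 else Inf))
  hp
}

#' Train one registry model
#'
#' @param name Registry family name (see [model_registry()]).
#' @param X Spectra matrix (rows = spectra).
#' @param y Class labels.
#' @param hyperparams Named list overriding the family defaults.
#' @param seed Seed controlling all stochastic parts of the fit.
#' @return An object of class `raman_model` exposing class-probability
#'   prediction via [predict()].
#' @export
train_model <- function(name, X, y, hyperparams = list(), seed = 1) {
  reg <- model_registry()
  if (!name %in% reg$name) {
    abort(sprintf("unknown model '%s'; registry: %s", name,
                  paste(reg$name, collapse = ", ")))
  }
  X <- as.matrix(X); y <- factor(y)
  classes <- levels(y)
  hp <- modifyList(model_defaults(name, nrow(X), ncol(X), min(table(y))), hyperparams)
  type <- reg$type[reg$name == name]

  pca <- NULL; scaling <- NULL
  if (type == "traditional") {
    pca <- prcomp(X, center = TRUE, rank. = hp$ncomp)
    Z <- pca$x
    colnames(Z) <- paste0("PC", seq_len(ncol(Z)))
  } else {
    # centre per column, scale by the pooled SD: per-column standardization
    # would blow up the near-silent spectral regions into unit-variance noise
    mu <- colMeans(X)
    sd_pool <- max(sqrt(mean(apply(X, 2, var))), 1e-8)
    scaling <- list(mu = mu, sd = sd_pool)
    Z <- sweep(X, 2, mu) / sd_pool
  }

  fit <- with_seed(derive_seed(seed, 11), switch(name,
    LDA = MASS::lda(Z, grouping = y),
    QDA = MASS::qda(Z, grouping = y),
    NB = e1071::naiveBayes(Z, y),
    KNN = caret::knn3(Z, y, k = hp$k),
    LR = {
      df <- data.frame(.y = y, Z)
      nnet::multinom(.y ~ ., data = df, trace = FALSE, decay = hp$decay,
                     MaxNWts = 5000, maxit = 200)
    },
    RF = ranger::ranger(y = y, x = as.data.frame(Z), probability = TRUE,
                        num.trees = hp$num_trees,
                        min.node.size = hp$min_node_size %||% 10,
                        seed = derive_seed(seed, 12), num.threads = 1),
    GB = xgboost::xgb.train(
      params = list(objective = "multi:softprob",
                    num_class = length(classes),
                    max_depth = hp$max_depth, eta = hp$eta, nthread = 1),
      data = xgboost::xgb.DMatrix(Z, label = as.integer(y) - 1),
      nrounds = hp$nrounds, verbose = 0),
    LSVM = e1071::svm(Z, y, kernel = "linear", cost = hp$cost,
                      probability = TRUE),
    RSVM = {
      # reduced SVM: RBF kernel fitted on a random stratified subset of
      # candidate support vectors
      idx <- unlist(lapply(split(seq_along(y), y), function(i) {
        m <- max(min(length(i), 10), ceiling(hp$subset_frac * length(i)))
        i[sample.int(length(i), m)]
      }), use.names = FALSE)
      list(svm = e1071::svm(Z[idx, , drop = FALSE], droplevels(y[idx]),
                            kernel = "radial", cost = hp$cost,
                            probability = TRUE),
           subset = idx)
    },
    MLP = dense_train(Z, y, classes, hidden = hp$hidden, epochs = hp$epochs,
                      lr = hp$lr, seed = derive_seed(seed, 13)),
    ANN = dense_train(Z, y, classes, hidden = hp$hidden, epochs = hp$epochs,
                      lr = hp$lr, seed = derive_seed(seed, 14)),
    GRU = gru_train(Z, y, classes, hidden = hp$hidden, patch = hp$patch,
                    stride = hp$stride, epochs = hp$epochs, lr = hp$lr,
                    seed = derive_seed(seed, 15))
  ))
  structure(list(name = name, type = type, fit = fit, pca = pca,
                 scaling = scaling, classes = classes, hyperparams = hp,
                 seed = seed),
            class = "raman_model")
}

#' @export
print.raman_model <- function(x, ...) {
  cat(sprintf("<raman_model> %s (%s), classes: %s\n", x$name, x$type,
              paste(x$classes, collapse = "/")))
  invisible(x)
}

model_features <- function(object, X) {
  X <- as.matrix(X)
  if (!is.null(object$pca)) {
    Z <- predict(object$pca, X)
    colnames(Z) <- paste0("PC", seq_len(ncol(Z)))
    Z
  } else {
    sweep(X, 2, object$scaling$mu) / object$scaling$sd
  }
}

#' Predict class probabilities or labels from a trained model
#'
#' @param object A [train_model()] fit.
#' @param X Spectra matrix on the same grid as the training data.
#' @param type `"prob"` for a class-probability matrix, `"class"` for
#'   labels.
#' @param ... Unused.
#' @export
predict.raman_model <- function(object, X, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  Z <- model_features(object, X)
  cls <- object$classes
  P <- switch(object$name,
    LDA = predict(object$fit, Z)$posterior,
    QDA = predict(object$fit, Z)$posterior,
    NB = predict(object$fit, Z, type = "raw"),
    KNN = predict(object$fit, Z, type = "prob"),
    LR = {
      pr <- predict(object$fit, data.frame(Z), type = "probs")
      if (is.null(dim(pr))) {
        pr <- cbind(1 - pr, pr)
        colnames(pr) <- object$fit$lev
      }
      pr
    },
    RF = predict(object$fit, data = as.data.frame(Z))$predictions,
    GB = {
      pr <- predict(object$fit, xgboost::xgb.DMatrix(Z))
      if (is.null(dim(pr))) pr <- matrix(pr, ncol = length(cls), byrow = TRUE)
      colnames(pr) <- cls
      pr
    },
    LSVM = svm_proba(object$fit, Z),
    RSVM = svm_proba(object$fit$svm, Z),
    MLP = dense_predict_proba(object$fit, Z),
    ANN = dense_predict_proba(object$fit, Z),
    GRU = gru_predict_proba(object$fit, Z)
  )
  P <- align_proba(P, cls)
  if (type == "prob") P else factor(cls[max.col(P, ties.method = "first")],
                                    levels = cls)
}

svm_proba <- function(fit, Z) {
  attr(predict(fit, Z, probability = TRUE), "probabilities")
}

# Reorder/complete probability columns to the full class set.
align_proba <- function(P, classes) {
  P <- as.matrix(P)
  out <- matrix(0, nrow(P), length(classes), dimnames = list(NULL, classes))
  for (cl in intersect(classes, colnames(P))) out[, cl] <- P[, cl]
  sw <- rowSums(out)
  sw[sw == 0] <- 1
  out / sw
}

## ---- cross-validation ----

# Stratified sample-level fold assignment: every spectrum of one sample
# lands in the same fold.
make_folds <- function(sample_ids, y, k_folds, seed) {
  samp <- tibble(sample_id = sample_ids, y = as.character(y))
  samp <- dplyr::distinct(samp)
  bad <- names(which(table(samp$y) < k_folds))
  if (length(bad) > 0) {
    abort(sprintf("class %s has fewer samples (%d) than folds (%d)",
                  bad[1], sum(samp$y == bad[1]), k_folds))
  }
  with_seed(seed, {
    samp$fold <- NA_integer_
    for (cl in unique(samp$y)) {
      i <- which(samp$y == cl)
      samp$fold[i] <- sample(rep(seq_len(k_folds), length.out = length(i)))
    }
  })
  samp$fold[match(sample_ids, samp$sample_id)]
}

#' k-fold cross-validation with a small hyperparameter grid
#'
#' Folds are stratified at the sample level: replicate spectra of one
#' sample never straddle a fold boundary. Traditional families are grid
#' searched over the registry grid; deep families are scored at their
#' default hyperparameters.
#'
#' @param name Registry family name.
#' @param X Spectra matrix.
#' @param y Class labels.
#' @param k_folds Number of folds (>= 2).
#' @param seed Seed for fold assignment and fits.
#' @param sample_ids Optional sample id per row; defaults to one sample
#'   per row.
#' @param hyperparams Fixed overrides applied on top of every grid point.
#' @return A list with `fold_scores` (tibble: config, fold, accuracy),
#'   `best_hyperparams`, and `accuracy` (mean over folds at the best
#'   configuration).
#' @export
cross_validate <- function(name, X, y, k_folds = 5, seed = 1,
                           sample_ids = NULL, hyperparams = list()) {
  if (k_folds < 2) abort("`k_folds` must be >= 2")
  X <- as.matrix(X); y <- factor(y)
  sample_ids <- sample_ids %||% as.character(seq_len(nrow(X)))
  fold <- make_folds(sample_ids, y, k_folds, derive_seed(seed, 21))
  reg <- model_registry()
  grid <- reg$grid[[match(name, reg$name)]]
  if (is.null(grid)) abort(sprintf("unknown model '%s'", name))
  scores <- purrr::imap_dfr(grid, function(cfg, ci) {
    purrr::map_dfr(seq_len(k_folds), function(f) {
      tr <- fold != f
      fit <- train_model(name, X[tr, , drop = FALSE], y[tr],
                         hyperparams = modifyList(cfg, hyperparams),
                         seed = derive_seed(seed, 100 + f))
      pred <- predict(fit, X[!tr, , drop = FALSE], type = "class")
      tibble(config = ci, fold = f, accuracy = mean(pred == y[!tr]))
    })
  })
  by_cfg <- dplyr::summarise(dplyr::group_by(scores, .data$config),
                             accuracy = mean(.data$accuracy), .groups = "drop")
  best <- by_cfg$config[which.max(by_cfg$accuracy)]
  list(fold_scores = scores,
       best_hyperparams = modifyList(grid[[best]], hyperparams),
       accuracy = max(by_cfg$accuracy))
}

## ---- evaluation ----

evaluate_predictions <- function(pred, probs, y_test, name = "model") {
  y_test <- factor(y_test)
  classes <- levels(y_test)
  pred <- factor(as.character(pred), levels = classes)
  confusion <- table(truth = y_test, prediction = pred)
  per_class <- purrr::map_dfr(classes, function(cl) {
    tp <- sum(y_test == cl & pred == cl)
    fn <- sum(y_test == cl & pred != cl)
    tn <- sum(y_test != cl & pred != cl)
    fp <- sum(y_test != cl & pred == cl)
    auc <- NA_real_
    if (!is.null(probs) && cl %in% colnames(probs) &&
        length(unique(y_test == cl)) == 2) {
      auc <- as.numeric(pROC::auc(
        pROC::roc(response = y_test == cl, predictor = probs[, cl],
                  quiet = TRUE, direction = "<", levels = c(FALSE, TRUE))))
    }
    tibble(class = cl,
           sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
           specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
           auc = auc)
  })
  structure(list(model = name,
                 accuracy = mean(pred == y_test, na.rm = TRUE),
                 sensitivity = macro_mean(per_class$sensitivity),
                 specificity = macro_mean(per_class$specificity),
                 per_class = per_class,
                 confusion = confusion,
                 n = length(y_test),
                 has_probabilities = !is.null(probs)),
            class = "model_report")
}

#' Evaluate a trained model on a test set
#'
#' Per-class sensitivity is the one-vs-rest recall, per-class specificity
#' the one-vs-rest true-negative rate, overall values are macro averages,
#' and AUC is computed one-vs-rest from the predicted class probabilities.
#'
#' @param model A [train_model()] fit (or any object with a
#'   [predict()] method returning class probabilities).
#' @param X_test Test spectra matrix.
#' @param y_test True labels.
#' @return A `model_report`: accuracy, macro sensitivity/specificity,
#'   per-class metrics with AUC, and the confusion matrix.
#' @export
evaluate <- function(model, X_test, y_test) {
  if (length(y_test) == 0) abort("empty test set")
  probs <- tryCatch(predict(model, X_test, type = "prob"), error = function(e) NULL)
  pred <- if (!is.null(probs)) {
    cls <- colnames(probs)
    factor(cls[max.col(probs, ties.method = "first")], levels = cls)
  } else {
    predict(model, X_test, type = "class")
  }
  name <- if (inherits(model, "raman_model")) model$name else class(model)[1]
  rep <- evaluate_predictions(pred, probs, y_test, name)
  if (is.null(probs)) rep$has_probabilities <- FALSE
  rep
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("<model_report> %s: accuracy %.3f, sensitivity %.3f, specificity %.3f (n = %d)\n",
              x$model, x$accuracy, x$sensitivity, x$specificity, x$n))
  print(x$confusion)
  invisible(x)
}

#' @describeIn evaluate Per-class metrics as a tibble.
#' @param x A `model_report`.
#' @param ... Unused.
#' @export
tidy.model_report <- function(x, ...) {
  dplyr::mutate(x$per_class, model = x$model, .before = 1)
}

#' @describeIn evaluate One-row summary (accuracy, macro sensitivity,
#'   macro specificity, macro AUC).
#' @export
glance.model_report <- function(x, ...) {
  tibble(model = x$model, accuracy = x$accuracy,
         sensitivity = x$sensitivity, specificity = x$specificity,
         auc = macro_mean(x$per_class$auc), n = x$n)
}
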