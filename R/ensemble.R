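# Stacking of the best base models and mode-based aggregation of
# spectrum-level predictions into one decision per sample.

#' Select the top-k models from a set of evaluation reports
#'
#' Ranked by prediction accuracy; ties broken by macro sensitivity, then
#' alphabetically by name (stable).
#'
#' @param reports A list of `model_report` objects, or a data frame with
#'   `model`, `accuracy`, `sensitivity` columns.
#' @param k How many names to return.
#' @return Character vector of the k best model names, best first.
#' @export
select_top_k <- function(reports, k = 4) {
  if (k <= 0) abort("`k` must be positive")
  tab <- if (is.data.frame(reports)) as_tibble(reports) else
    purrr::map_dfr(reports, glance)
  if (k > nrow(tab)) abort(sprintf("asked for %d models but only %d reports", k, nrow(tab)))
  tab <- dplyr::arrange(tab, dplyr::desc(.data$accuracy),
                        dplyr::desc(.data$sensitivity), .data$model)
  tab$model[seq_len(k)]
}

#' Fit a stacked ensemble
#'
#' Base models produce out-of-fold class probabilities on the training
#' spectra (sample-level folds); a multinomial logistic regression
#' meta-learner is fitted on the concatenated probabilities; the base
#' models are then refitted on the full training data for deployment.
#'
#' @param base_names Character vector of registry model names.
#' @param X_train Training spectra matrix.
#' @param y_train Training labels.
#' @param seed Seed for folds and fits.
#' @param sample_ids Optional sample id per row for sample-level folds.
#' @param k_folds Folds used to build the out-of-fold design.
#' @param hyperparams Optional named list (per base model) of
#'   hyperparameter overrides.
#' @return An object of class `raman_stack`.
#' @export
fit_stack <- function(base_names, X_train, y_train, seed = 1,
                      sample_ids = NULL, k_folds = 5, hyperparams = list()) {
  if (length(base_names) == 0) abort("`base_names` must not be empty")
  X_train <- as.matrix(X_train); y_train <- factor(y_train)
  classes <- levels(y_train)
  sample_ids <- sample_ids %||% as.character(seq_len(nrow(X_train)))
  fold <- make_folds(sample_ids, y_train, k_folds, derive_seed(seed, 31))

  oof <- matrix(NA_real_, nrow(X_train), length(base_names) * length(classes))
  colnames(oof) <- as.vector(outer(classes, base_names,
                                   function(cl, nm) paste(nm, cl, sep = "_")))
  for (b in seq_along(base_names)) {
    nm <- base_names[b]
    hp <- hyperparams[[nm]] %||% list()
    for (f in seq_len(k_folds)) {
      tr <- fold != f
      fit <- train_model(nm, X_train[tr, , drop = FALSE], y_train[tr],
                         hyperparams = hp, seed = derive_seed(seed, 200 + f))
      P <- predict(fit, X_train[!tr, , drop = FALSE], type = "prob")
      oof[!tr, (b - 1) * length(classes) + seq_along(classes)] <- P[, classes]
    }
  }
  meta_df <- data.frame(.y = y_train, oof, check.names = FALSE)
  meta <- with_seed(derive_seed(seed, 32), {
    nnet::multinom(.y ~ ., data = meta_df, trace = FALSE, maxit = 300,
                   MaxNWts = 5000)
  })
  base_models <- setNames(lapply(base_names, function(nm) {
    train_model(nm, X_train, y_train,
                hyperparams = hyperparams[[nm]] %||% list(),
                seed = derive_seed(seed, 300))
  }), base_names)
  structure(list(base_names = base_names, base_models = base_models,
                 meta = meta, classes = classes,
                 prevalence = prop.table(table(y_train))),
            class = "raman_stack")
}

#' @export
print.raman_stack <- function(x, ...) {
  cat(sprintf("<raman_stack> bases: %s; multinomial meta-learner\n",
              paste(x$base_names, collapse = ", ")))
  invisible(x)
}

#' Predict from a stacked ensemble
#'
#' @param object A [fit_stack()] ensemble.
#' @param X Spectra matrix.
#' @param type `"prob"` or `"class"`.
#' @param ... Unused.
#' @export
predict.raman_stack <- function(object, X, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  feats <- do.call(cbind, lapply(object$base_names, function(nm) {
    P <- predict(object$base_models[[nm]], X, type = "prob")[, object$classes]
    colnames(P) <- paste(nm, object$classes, sep = "_")
    P
  }))
  pr <- predict(object$meta, data.frame(feats, check.names = FALSE),
                type = "probs")
  if (is.null(dim(pr))) {
    pr <- cbind(1 - pr, pr)
    colnames(pr) <- object$meta$lev
  }
  P <- align_proba(pr, object$classes)
  if (type == "prob") P else
    factor(object$classes[max.col(P, ties.method = "first")],
           levels = object$classes)
}

#' @describeIn fit_stack Meta-learner coefficients as a tibble.
#' @param x A `raman_stack`.
#' @param ... Unused.
#' @export
tidy.raman_stack <- function(x, ...) {
  co <- stats::coef(x$meta)
  if (is.null(dim(co))) co <- matrix(co, nrow = 1,
                                     dimnames = list(x$classes[2], names(co)))
  as_tibble(co, rownames = "class") |>
    tidyr::pivot_longer(-"class", names_to = "term", values_to = "estimate")
}

## ---- sample-level aggregation ----

mode_label <- function(labels, probabilities = NULL, prevalence = NULL) {
  counts <- table(labels)
  top <- names(counts)[counts == max(counts)]
  if (length(top) > 1 && !is.null(probabilities)) {
    mp <- vapply(top, function(cl) mean(probabilities[, cl]), numeric(1))
    top <- top[mp == max(mp)]
  }
  if (length(top) > 1 && !is.null(prevalence)) {
    pv <- prevalence[top]
    top <- top[which(pv == max(pv))]
  }
  sort(top)[1]
}

#' Aggregate one sample's spectrum predictions into a decision
#'
#' The final label is the mode of the per-spectrum predicted labels; ties
#' are broken by the highest mean predicted probability among the tied
#' labels, then by class prevalence, then alphabetically.
#'
#' @param labels Per-spectrum predicted labels (>= 1).
#' @param probabilities Optional per-spectrum class-probability matrix.
#' @param truth Optional true label; enables `fraction_correct`.
#' @param sample_id Optional identifier carried into the result.
#' @param prevalence Optional named class-prevalence vector for the second
#'   tie-break.
#' @return One-row tibble: `sample_id`, `truth`, `prediction`,
#'   `n_spectra`, `fraction_correct`, plus the per-spectrum labels as a
#'   list-column.
#' @export
aggregate_sample <- function(labels, probabilities = NULL, truth = NULL,
                             sample_id = NA_character_, prevalence = NULL) {
  labels <- as.character(labels)
  if (length(labels) == 0) abort("cannot aggregate an empty set of spectrum predictions")
  final <- mode_label(labels, probabilities, prevalence)
  tibble(sample_id = sample_id,
         truth = if (is.null(truth)) NA_character_ else as.character(truth),
         prediction = final,
         n_spectra = length(labels),
         fraction_correct = if (is.null(truth)) NA_real_ else
           mean(labels == as.character(truth)),
         spectrum_labels = list(labels))
}

#' Aggregate spectrum-level predictions for many samples
#'
#' @param sample_ids Sample id per spectrum.
#' @param labels Predicted label per spectrum.
#' @param probabilities Optional class-probability matrix (rows =
#'   spectra).
#' @param truth Optional named (by sample) or per-spectrum true labels.
#' @param prevalence Optional class-prevalence vector for tie-breaks.
#' @return A tibble of class `sample_decisions`, one row per sample.
#' @export
aggregate_predictions <- function(sample_ids, labels, probabilities = NULL,
                                  truth = NULL, prevalence = NULL) {
  sample_ids <- as.character(sample_ids)
  per_spec_truth <- NULL
  if (!is.null(truth)) {
    per_spec_truth <- if (length(truth) == length(sample_ids)) as.character(truth)
      else as.character(truth[sample_ids])
  }
  ids <- unique(sample_ids)
  out <- purrr::map_dfr(ids, function(sid) {
    i <- sample_ids == sid
    aggregate_sample(labels[i],
                     probabilities = if (!is.null(probabilities))
                       probabilities[i, , drop = FALSE],
                     truth = if (!is.null(per_spec_truth)) per_spec_truth[which(i)[1]],
                     sample_id = sid, prevalence = prevalence)
  })
  class(out) <- c("sample_decisions", class(out))
  out
}

#' Distribution of per-sample prediction accuracy
#'
#' Histogram of the fraction of correctly predicted spectra per sample in
#' fixed 10% bins, plus the share of samples with more than half of their
#' spectra predicted correctly.
#'
#' @param decisions A `sample_decisions` tibble with known truth.
#' @return A list with `histogram` (tibble `bin_lo`, `bin_hi`, `count`)
#'   and `share_over_half`.
#' @export
sample_accuracy_distribution <- function(decisions) {
  fc <- decisions$fraction_correct
  if (anyNA(fc)) abort("decisions must carry known truth (fraction_correct)")
  breaks <- seq(0, 1, by = 0.1)
  bin <- cut(fc, breaks = breaks, include.lowest = TRUE, right = TRUE)
  counts <- as.integer(table(bin))
  list(histogram = tibble(bin_lo = breaks[-11], bin_hi = breaks[-1],
                          count = counts),
       share_over_half = mean(fc > 0.5))
}
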