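# End-to-end pipeline driven by a YAML configuration: load or generate
# spectra, preprocess, summarize peaks, optionally embed, train and
# evaluate the model registry, stack the best models, and aggregate
# per-sample decisions.

config_section <- function(config, name) {
  if (is.null(config[[name]])) {
    abort(sprintf("configuration is missing the `%s` section", name))
  }
  config[[name]]
}

#' Run the full analysis pipeline from a configuration
#'
#' Stages: load or generate the dataset, preprocess all spectra, build the
#' per-peak statistics table, optionally compute embeddings, split samples
#' 80/20 per group, SMOTE-balance the training spectra, train and evaluate
#' every requested model, stack the top models, and aggregate per-sample
#' mode decisions. All artifacts are written as CSV plus a JSON run
#' summary.
#'
#' @param config Path to a YAML file or an equivalent nested list. Required
#'   sections: `dataset`, `preprocess`, `models`, `ensemble`; optional:
#'   `peaks`, `embed`, `seed`, `output_dir`.
#' @param output_dir Overrides `config$output_dir`.
#' @return Invisibly, a list with the in-memory results (reports, stack,
#'   decisions, paths).
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  out <- output_dir %||% config$output_dir %||% abort("no `output_dir` given")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log <- list(seed = seed,
              config_hash = rlang::hash(config),
              package_version = as.character(utils::packageVersion("ramanblast")),
              r_version = R.version.string)

  ## stage 1: dataset
  ds_cfg <- config_section(config, "dataset")
  data <- if (!is.null(ds_cfg$manifest)) {
    read_dataset(ds_cfg$manifest)
  } else if (!is.null(ds_cfg$synthetic)) {
    syn <- ds_cfg$synthetic
    templates <- default_peak_templates(
      separability = syn$separability %||% 1)
    gen_args <- syn[setdiff(names(syn), "separability")]
    gen_args$seed <- gen_args$seed %||% seed
    if (!is.null(gen_args$group_sizes)) {
      gen_args$group_sizes <- unlist(gen_args$group_sizes)
    }
    if (!is.null(gen_args$spectra_per_sample)) {
      gen_args$spectra_per_sample <- unlist(gen_args$spectra_per_sample)
    }
    if (!is.null(gen_args$grid)) gen_args$grid <- unlist(gen_args$grid)
    generate_dataset(do.call(generator_config, gen_args), templates)
  } else {
    abort("`dataset` section must provide either `manifest` or `synthetic`")
  }
  log$n_spectra_input <- nrow(data)

  ## stage 2: preprocessing
  pp_cfg <- config_section(config, "preprocess")
  pp_cfg$range <- unlist(pp_cfg$range %||% c(300, 3400))
  pp <- preprocess_spectra(data, do.call(preprocess_config, pp_cfg))
  readr::write_csv(qc_report(pp), file.path(out, "qc_report.csv"))
  log$n_spectra_kept <- nrow(pp)

  ## peak statistics
  pk_cfg <- config$peaks %||% list()
  stats_tbl <- build_peak_stats(pp,
                                positions = pk_cfg$positions %||% core_peak_positions(),
                                unit = pk_cfg$unit %||% "spectrum")
  readr::write_csv(as_tibble(stats_tbl), file.path(out, "peak_stats.csv"))

  X <- spectra_matrix(pp)
  y <- factor(pp$group, levels = GROUPS)

  ## optional embeddings
  if (!is.null(config$embed)) {
    em_cfg <- config$embed
    embs <- list()
    methods <- em_cfg$methods %||% c("tsne", "lada", "oplsda")
    if ("tsne" %in% methods) {
      embs$tsne <- tsne_embed(X, labels = y,
                              perplexity = em_cfg$perplexity %||% 30,
                              seed = seed, max_iter = em_cfg$max_iter %||% 500)
    }
    if ("lada" %in% methods) {
      embs$lada <- lada_embed(X, labels = y,
                              n_topics = em_cfg$n_topics %||% 3, seed = seed)
    }
    if ("oplsda" %in% methods) {
      embs$oplsda <- oplsda_fit(X, y, n_orth = em_cfg$n_orth %||% 1)$embedding
    }
    emb_tbl <- purrr::map_dfr(embs, function(e) {
      dplyr::mutate(as_tibble(e), method = attr(e, "method"))
    })
    readr::write_csv(emb_tbl, file.path(out, "embeddings.csv"))
  }

  ## stage 3: split, balance, train, evaluate
  md_cfg <- config_section(config, "models")
  plan <- split_dataset(pp, fraction = md_cfg$fraction %||% 0.8, seed = seed)
  train <- split_spectra(pp, plan, "training")
  test <- split_spectra(pp, plan, "prediction")
  X_tr <- spectra_matrix(train); y_tr <- factor(train$group, levels = GROUPS)
  X_te <- spectra_matrix(test);  y_te <- factor(test$group, levels = GROUPS)
  bal <- smote_oversample(X_tr, y_tr,
                          k_neighbors = md_cfg$smote_k %||% 5, seed = seed)
  names_wanted <- md_cfg$names %||% model_registry()$name
  hp <- md_cfg$hyperparams %||% list()
  reports <- lapply(names_wanted, function(nm) {
    fit <- train_model(nm, bal$X, bal$y, hyperparams = hp[[nm]] %||% list(),
                       seed = seed)
    evaluate(fit, X_te, y_te)
  })
  report_tbl <- dplyr::arrange(purrr::map_dfr(reports, glance),
                               dplyr::desc(.data$accuracy))
  report_tbl$rank <- seq_len(nrow(report_tbl))
  readr::write_csv(report_tbl[, c("rank", "model", "accuracy", "sensitivity",
                                  "specificity", "auc", "n")],
                   file.path(out, "model_reports.csv"))

  ## stage 4: stacking + per-sample aggregation
  en_cfg <- config_section(config, "ensemble")
  base_names <- en_cfg$base_names %||%
    select_top_k(report_tbl, en_cfg$top_k %||% 4)
  # synthetic SMOTE rows get fresh pseudo-sample ids so folds stay honest
  smp <- c(train$sample_id, paste0("syn", seq_len(sum(bal$synthetic))))
  stack <- fit_stack(base_names, bal$X, bal$y, seed = seed,
                     sample_ids = smp, k_folds = en_cfg$k_folds %||% 5,
                     hyperparams = hp)
  probs <- predict(stack, X_te, type = "prob")
  labels <- GROUPS[max.col(probs, ties.method = "first")]
  decisions <- aggregate_predictions(test$sample_id, labels, probs,
                                     truth = setNames(as.character(y_te),
                                                      test$sample_id),
                                     prevalence = stack$prevalence)
  readr::write_csv(dplyr::select(decisions, -"spectrum_labels"),
                   file.path(out, "sample_decisions.csv"))
  stack_report <- evaluate_predictions(labels, probs, y_te, "stack")
  conf <- as.data.frame.matrix(stack_report$confusion)
  readr::write_csv(tibble::rownames_to_column(conf, "truth"),
                   file.path(out, "confusion_matrix.csv"))
  dist <- sample_accuracy_distribution(decisions)

  log$n_train_samples <- sum(plan$role == "training")
  log$n_prediction_samples <- sum(plan$role == "prediction")
  log$base_models <- base_names
  log$stack_accuracy <- stack_report$accuracy
  log$sample_mode_accuracy <- mean(decisions$prediction == decisions$truth)
  log$share_samples_over_half_correct <- dist$share_over_half
  jsonlite::write_json(log, file.path(out, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(data = pp, peak_stats = stats_tbl, plan = plan,
                 reports = reports, report_table = report_tbl,
                 stack = stack, stack_report = stack_report,
                 decisions = decisions, distribution = dist,
                 output_dir = out, log = log))
}
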