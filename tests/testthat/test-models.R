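sample_table <- function(sizes) {
  tibble::tibble(
    sample_id = paste0(rep(names(sizes), sizes), unlist(lapply(sizes, seq_len))),
    group = rep(names(sizes), sizes))
}

test_that("the 80/20 split reproduces the study arithmetic", {
  plan <- split_dataset(sample_table(c(A = 58, B = 25, C = 89)), 0.8, seed = 1)
  expect_equal(sum(plan$role == "training"), 137)
  expect_equal(sum(plan$role == "prediction"), 35)
  by_g <- table(plan$group, plan$role)
  expect_equal(as.numeric(by_g[, "training"]), c(46, 20, 71))

  plan2 <- split_dataset(sample_table(c(A = 10, B = 10, C = 10)), 0.8, seed = 2)
  expect_equal(sum(plan2$role == "training"), 24)
  plan3 <- split_dataset(sample_table(c(A = 5, B = 4, C = 3)), 0.8, seed = 3)
  expect_equal(sum(plan3$role == "training"), 9)
  expect_equal(sum(plan3$role == "prediction"), 3)

  expect_identical(split_dataset(sample_table(c(A = 9, B = 9, C = 9)), 0.8, 5),
                   split_dataset(sample_table(c(A = 9, B = 9, C = 9)), 0.8, 5))
  expect_error(split_dataset(sample_table(c(A = 1, B = 5, C = 5)), 0.8, 1),
               "empty side")
})

test_that("no spectrum of a prediction sample can reach the training side", {
  pp <- fx_highsep()
  plan <- split_dataset(pp, 0.8, seed = 7)
  tr <- split_spectra(pp, plan, "training")
  te <- split_spectra(pp, plan, "prediction")
  expect_equal(nrow(tr) + nrow(te), nrow(pp))
  expect_length(intersect(tr$sample_id, te$sample_id), 0)
  # per-group sample partition is exhaustive and disjoint
  expect_setequal(c(tr$sample_id, te$sample_id), pp$sample_id)
})

test_that("SMOTE equalizes class counts with convex synthetic rows", {
  withr::with_seed(10, {
    X <- rbind(matrix(rnorm(100 * 4), 100, 4),
               matrix(rnorm(40 * 4, 2), 40, 4),
               matrix(rnorm(60 * 4, -2), 60, 4))
    y <- rep(c("A", "B", "C"), c(100, 40, 60))
  })
  out <- smote_oversample(X, y, k_neighbors = 5, seed = 2)
  expect_equal(as.numeric(table(out$y)), c(100, 100, 100))
  expect_equal(out$X[seq_len(nrow(X)), ], X)  # originals verbatim

  # every synthetic row lies on a segment between two same-class inputs
  syn_idx <- which(out$synthetic)
  for (i in syn_idx[seq_len(10)]) {
    v <- out$X[i, ]
    cls <- as.character(out$y[i])
    Xc <- X[y == cls, , drop = FALSE]
    found <- FALSE
    for (a in seq_len(nrow(Xc))) {
      d <- sweep(Xc, 2, v)
      base <- Xc[a, ]
      seg <- sweep(Xc, 2, base, "-")
      rel <- v - base
      denom <- rowSums(seg^2)
      lam <- ifelse(denom > 0, (seg %*% rel) / denom, -1)
      ok <- lam >= -1e-8 & lam <= 1 + 1e-8 &
        rowSums((sweep(seg, 1, lam, "*") -
                   matrix(rel, nrow(Xc), ncol(Xc), byrow = TRUE))^2) < 1e-16
      if (any(ok)) { found <- TRUE; break }
    }
    expect_true(found)
  }

  balanced <- smote_oversample(X[1:120, ], rep(c("A", "B"), each = 60), seed = 1)
  expect_equal(balanced$X, X[1:120, ])
  expect_false(any(balanced$synthetic))

  expect_error(smote_oversample(X[1:104, ], rep(c("A", "B"), c(100, 4)),
                                k_neighbors = 5),
               "k_neighbors")
})

test_that("LDA recovers the analytic discriminant direction", {
  withr::with_seed(20, {
    n <- 200
    mu <- c(2, -1)
    X <- rbind(matrix(rnorm(n * 2), n, 2),
               sweep(matrix(rnorm(n * 2), n, 2), 2, mu, "+"))
    y <- rep(c("A", "B"), each = n)
  })
  fit <- train_model("LDA", X, y, hyperparams = list(ncomp = 2), seed = 1)
  # map the LD direction back through the PCA rotation
  dir_fit <- fit$pca$rotation %*% fit$fit$scaling[, 1]
  # Fisher oracle: pooled within-class covariance^-1 (mu_B - mu_A)
  Xc <- X
  for (g in unique(y)) {
    Xc[y == g, ] <- sweep(X[y == g, , drop = FALSE], 2,
                          colMeans(X[y == g, , drop = FALSE]))
  }
  dir_true <- solve(cov(Xc), colMeans(X[y == "B", ]) - colMeans(X[y == "A", ]))
  cosang <- abs(sum(dir_fit * dir_true)) /
    (sqrt(sum(dir_fit^2)) * sqrt(sum(dir_true^2)))
  expect_gt(cosang, 0.99)
})

test_that("simple fits interpolate cleanly separated training data", {
  withr::with_seed(21, {
    X1 <- matrix(c(rnorm(20, 0, 0.1), rnorm(20, 10, 0.1), rnorm(20, 20, 0.1)),
                 ncol = 1)
    y1 <- factor(rep(c("A", "B", "C"), each = 20))
  })
  nb <- train_model("NB", X1, y1, hyperparams = list(ncomp = 1), seed = 1)
  expect_equal(mean(predict(nb, X1, type = "class") == y1), 1)

  # three tiny, far-apart classes: every family that admits n = 2 per class
  X2 <- matrix(c(0, 0.1, 50, 50.1, 100, 100.1), ncol = 1)
  y2 <- factor(rep(c("A", "B", "C"), each = 2))
  for (nm in c("KNN", "RF", "NB", "LR", "LSVM", "LDA")) {
    fit <- train_model(nm, X2, y2,
                       hyperparams = list(ncomp = 1, k = 1,
                                          min_node_size = 1), seed = 2)
    expect_equal(as.character(predict(fit, X2, type = "class")),
                 as.character(y2), label = nm)
  }
  expect_error(train_model("nope", X2, y2), "registry")
})

test_that("probability outputs are aligned and rows sum to one", {
  pp <- fx_highsep()
  X <- spectra_matrix(pp); y <- factor(pp$group)
  for (nm in c("LDA", "GB", "KNN", "LR")) {
    fit <- train_model(nm, X, y, seed = 3)
    P <- predict(fit, X[1:7, ], type = "prob")
    expect_equal(colnames(P), c("A", "B", "C"))
    expect_equal(rowSums(P), rep(1, 7), tolerance = 1e-6)
  }
})

test_that("cross-validation folds partition samples exactly once", {
  sid <- rep(sprintf("s%02d", 1:20), each = 3)
  y <- rep(rep(c("A", "B"), each = 10), each = 3)
  fold <- ramanblast:::make_folds(sid, y, k_folds = 5, seed = 1)
  per_sample <- tapply(fold, sid, function(f) length(unique(f)))
  expect_true(all(per_sample == 1))
  expect_equal(sort(unique(fold)), 1:5)
  # every sample is validated exactly once across folds
  assignment <- unique(data.frame(sid, fold))
  expect_equal(nrow(assignment), 20)
  expect_equal(as.numeric(table(assignment$fold)), rep(4, 5))
  expect_error(ramanblast:::make_folds(sid[1:9], y[1:9], 5, 1), "fewer samples")
})

test_that("cross-validation scores separable data high for LDA", {
  pp <- fx_highsep()
  X <- spectra_matrix(pp); y <- factor(pp$group)
  cv <- cross_validate("LDA", X, y, k_folds = 5, seed = 2,
                       sample_ids = pp$sample_id)
  expect_gt(cv$accuracy, 0.9)
  expect_equal(nrow(cv$fold_scores), 2 * 5)  # two grid points, five folds
})

test_that("evaluation metrics match a hand-computed confusion matrix", {
  # truth x prediction counts: [[8,2,0],[1,4,0],[1,1,18]]
  truth <- factor(rep(c("A", "B", "C"), c(10, 5, 20)))
  pred <- factor(c(rep("A", 8), rep("B", 2),
                   "A", rep("B", 4),
                   "A", "B", rep("C", 18)), levels = c("A", "B", "C"))
  rep_ <- ramanblast:::evaluate_predictions(pred, NULL, truth, "manual")
  expect_equal(rep_$accuracy, 30 / 35)
  pc <- rep_$per_class
  expect_equal(pc$sensitivity[pc$class == "A"], 0.8)
  expect_equal(pc$sensitivity[pc$class == "B"], 0.8)
  expect_equal(pc$sensitivity[pc$class == "C"], 0.9)
  expect_equal(pc$specificity[pc$class == "A"], 1 - 2 / 25)
  # macro averages are the means of the per-class values
  expect_equal(rep_$sensitivity, mean(pc$sensitivity))
  expect_equal(rep_$specificity, mean(pc$specificity))

  # degenerate always-predict-C classifier on a 12/5/18 prediction set
  truth2 <- factor(rep(c("A", "B", "C"), c(12, 5, 18)))
  pred2 <- factor(rep("C", 35), levels = c("A", "B", "C"))
  rep2 <- ramanblast:::evaluate_predictions(pred2, NULL, truth2, "alwaysC")
  expect_equal(rep2$accuracy, 18 / 35)
  expect_equal(rep2$per_class$sensitivity[3], 1)
  expect_equal(rep2$per_class$specificity[3], 0)
})

test_that("a perfect classifier scores one on every metric", {
  truth <- factor(rep(c("A", "B", "C"), each = 5))
  probs <- ramanblast:::onehot(truth, levels(truth)) * 0.98 + 0.01 / 3
  rep_ <- ramanblast:::evaluate_predictions(truth, probs, truth, "perfect")
  expect_equal(rep_$accuracy, 1)
  expect_equal(rep_$sensitivity, 1)
  expect_equal(rep_$specificity, 1)
  expect_equal(rep_$per_class$auc, rep(1, 3))
  g <- glance(rep_)
  expect_equal(g$accuracy, 1)
  expect_s3_class(tidy(rep_), "tbl_df")
})
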