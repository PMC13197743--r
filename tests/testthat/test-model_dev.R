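make_toy <- function(n = 200, p = 4, seed = 1, sep = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- as.integer(sep * (X[, 1] + 0.7 * X[, 2]) + rnorm(n, 0, 0.5) > 0)
  list(X = as.data.frame(X), y = y)
}

test_that("z-scoring is fitted on train only and handles constants", {
  sc <- zscore_fit_apply(matrix(c(0, 10), ncol = 1),
                         others = list(ext = matrix(5, 1, 1)))
  expect_equal(unname(sc$mu), 5)
  expect_equal(unname(sc$sigma), 5)  # population SD of {0, 10}
  expect_equal(as.vector(sc$train), c(-1, 1))
  expect_equal(as.vector(sc$others$ext), 0)

  const <- zscore_fit_apply(matrix(7, 5, 1))
  expect_true(all(const$train == 0))
})

test_that("SMOTE balances classes with on-segment synthetic points", {
  toy <- make_toy(60, 3, seed = 2)
  bal <- smote_oversample(toy$X[1:40, ], rep(c(0, 1), 20), seed = 3)
  expect_equal(bal$n_synthetic, 0L)
  expect_equal(nrow(bal$features), 40)

  X <- as.matrix(toy$X)
  y <- c(rep(1, 10), rep(0, 50))
  out <- smote_oversample(X, y, k = 5, seed = 4)
  expect_equal(sum(out$labels == 1), sum(out$labels == 0))
  expect_equal(out$features[seq_len(nrow(X)), ], X)  # originals verbatim
  synth <- out$features[-seq_len(nrow(X)), , drop = FALSE]
  minority <- X[y == 1, , drop = FALSE]
  # each synthetic point lies on a segment between two minority points
  on_segment <- apply(synth, 1, function(s) {
    for (i in seq_len(nrow(minority) - 1)) {
      for (j in (i + 1):nrow(minority)) {
        a <- minority[i, ]; b <- minority[j, ]
        ab <- b - a
        lam <- sum((s - a) * ab) / sum(ab * ab)
        if (lam > -1e-9 && lam < 1 + 1e-9 &&
            sqrt(sum((a + lam * ab - s)^2)) < 1e-8) return(TRUE)
      }
    }
    FALSE
  })
  expect_true(all(on_segment))

  # k shrinks when the minority class is tiny
  y2 <- c(rep(1, 3), rep(0, 20))
  out2 <- smote_oversample(X[1:23, ], y2, k = 5, seed = 5)
  expect_equal(sum(out2$labels == 1), 20)
  expect_error(smote_oversample(X, rep(0, nrow(X))), "both classes")
})

test_that("evaluate reproduces the closed-form confusion metrics", {
  scores <- c(rep(0.9, 90), rep(0.9, 10), rep(0.1, 90), rep(0.1, 10))
  labels <- c(rep(1, 90), rep(0, 10), rep(0, 90), rep(1, 10))
  m <- evaluate(scores, labels)
  expect_equal(m$tp, 90); expect_equal(m$fp, 10)
  expect_equal(m$tn, 90); expect_equal(m$fn, 10)
  for (v in c("accuracy", "sensitivity", "specificity", "ppv", "npv",
              "f1")) {
    expect_equal(m[[v]], 0.9, info = v)
  }
  expect_equal(evaluate(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
})

test_that("rank-based AUC equals the all-pairs concordance oracle", {
  for (s in 1:5) {
    set.seed(s)
    scores <- round(runif(50), 2)  # rounding forces ties
    labels <- rbinom(50, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_equal(evaluate(scores, labels)$auc,
                 oracle_auc(scores, labels), info = paste("seed", s))
    # invariance under strictly monotone transforms
    expect_equal(evaluate(plogis(3 * scores - 1), labels)$auc,
                 evaluate(scores, labels)$auc)
  }
})

test_that("metric identities hold on random confusion matrices", {
  set.seed(9)
  for (i in 1:200) {
    cm <- rmultinom(1, 50 + sample(200, 1), runif(4, 0.05, 1))
    tp <- cm[1]; fp <- cm[2]; tn <- cm[3]; fn <- cm[4]
    scores <- c(rep(1, tp + fp), rep(0, tn + fn))
    labels <- c(rep(1, tp), rep(0, fp), rep(0, tn), rep(1, fn))
    m <- evaluate(scores, labels)
    expect_equal(m$accuracy, (tp + tn) / sum(cm))
    if (!is.na(m$f1)) {
      expect_equal(m$f1,
                   2 * m$ppv * m$sensitivity / (m$ppv + m$sensitivity),
                   tolerance = 1e-12)
    }
  }
})

test_that("folds are stratified and validation sets stay untouched", {
  toy <- make_toy(103, 4, seed = 11)
  res <- cross_validate(toy$X, toy$y, model_spec("LOGISTIC", seed = 1),
                        seed = 7, return_artifacts = TRUE)
  # fold class proportions within one subject of the cohort proportion
  prop <- mean(toy$y)
  for (f in 1:5) {
    nf <- sum(res$fold == f)
    expect_lte(abs(sum(toy$y[res$fold == f]) - prop * nf), 1)
  }
  # validation folds partition the cohort; no synthetic rows scored
  expect_equal(sum(vapply(res$artifacts, `[[`, numeric(1), "n_val")), 103)
  expect_equal(sort(unique(res$fold)), 1:5)
  # training folds were oversampled to balance
  for (f in 1:5) {
    tr_n <- sum(res$fold != f)
    expect_gte(res$artifacts[[f]]$n_train_after_smote, tr_n)
  }
})

test_that("corrupting validation labels changes no training artifact", {
  toy <- make_toy(80, 3, seed = 13)
  folds <- rep_len(1:5, 80)
  run <- function(y) {
    cross_validate(toy$X, y, model_spec("GBT_LEAFWISE", seed = 2),
                   seed = 3, folds = folds, return_artifacts = TRUE)
  }
  clean <- run(toy$y)
  # flip every label inside one fold at a time: the artifacts of that
  # fold (whose training set excludes it) must be bit-identical
  for (f in 1:5) {
    y_one <- toy$y
    idx <- which(folds == f)
    y_one[idx] <- 1L - y_one[idx]
    dirty_one <- run(y_one)
    expect_identical(dirty_one$artifacts[[f]]$smote_digest,
                     clean$artifacts[[f]]$smote_digest)
    expect_identical(dirty_one$artifacts[[f]]$model_digest,
                     clean$artifacts[[f]]$model_digest)
    expect_identical(dirty_one$artifacts[[f]]$mu,
                     clean$artifacts[[f]]$mu)
    expect_identical(dirty_one$artifacts[[f]]$sigma,
                     clean$artifacts[[f]]$sigma)
  }
})

test_that("every family separates an easy cohort", {
  toy <- make_toy(300, 4, seed = 17, sep = 4)
  for (fam in model_families()) {
    res <- cross_validate(toy$X, toy$y, model_spec(fam, seed = 5),
                          seed = 5)
    expect_gte(res$mean_metrics[["auc"]], 0.97)
  }
})

test_that("subset enumeration and ranking follow the contract", {
  toy <- make_toy(60, 8, seed = 19)
  colnames(toy$X) <- paste0("f", 1:8)
  tab <- subset_search(toy$X, toy$y, sizes = 2, families = "LOGISTIC",
                       seed = 2)
  expect_equal(nrow(tab), choose(8, 2))
  expect_true(all(tab$size == 2))
  # ranked by F1 then AUC
  expect_true(all(diff(tab$f1) <= 1e-12))
  ties <- which(abs(diff(tab$f1)) < 1e-12)
  expect_true(all(tab$auc[ties] >= tab$auc[ties + 1] - 1e-12))

  expect_error(subset_search(toy$X, toy$y, sizes = 1,
                             feature_pool = c("f1", "nope")),
               "configuration error")
})

test_that("model specs validate their hyperparameter keys", {
  expect_error(model_spec("GBT_ORDERED",
                          hyperparameters = list(max_depth = 3)),
               "not in the")
  sp <- model_spec("GBT_ORDERED", hyperparameters = list(
    learning_rate = 0.03, n_estimators = 50))
  expect_equal(sp$hyperparameters$n_estimators, 50)
  expect_equal(sp$hyperparameters$l2_leaf_reg, 3)
  expect_error(model_spec("DEEPNET"))
})

test_that("finalize retrains without oversampling and scores externals", {
  toy <- make_toy(160, 4, seed = 23, sep = 3)
  internal <- cbind(toy$X, label = toy$y)
  ext <- make_toy(60, 4, seed = 29, sep = 3)
  external <- cbind(ext$X, label = ext$y)
  m <- finalize_and_validate(model_spec("LOGISTIC", seed = 1),
                             c("f1", "f2"), internal, external)
  expect_s3_class(m, "trained_model")
  expect_length(m$external_scores, 60)
  expect_gte(m$external_metrics$auc, 0.9)
  # column order in newdata is irrelevant (name-based alignment)
  shuffled <- external[, c("f4", "label", "f2", "f3", "f1")]
  expect_equal(predict(m, shuffled), m$external_scores)
  expect_error(predict(m, external[, c("f3", "f4")]), "lacks")
  expect_error(finalize_and_validate(model_spec("LOGISTIC"),
                                     c("f1", "zzz"), internal),
               "lacks")
})

test_that("cross-validation is reproducible under a fixed seed", {
  toy <- make_toy(90, 3, seed = 31)
  a <- cross_validate(toy$X, toy$y, model_spec("RANDOM_FOREST", seed = 4),
                      seed = 6, return_artifacts = TRUE)
  b <- cross_validate(toy$X, toy$y, model_spec("RANDOM_FOREST", seed = 4),
                      seed = 6, return_artifacts = TRUE)
  expect_identical(a$mean_metrics, b$mean_metrics)
  expect_identical(vapply(a$artifacts, `[[`, character(1), "model_digest"),
                   vapply(b$artifacts, `[[`, character(1), "model_digest"))
})
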