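#' Fit a z-score scaler on training data and apply it everywhere
#'
#' Per-feature mean and SD are estimated on `train` only; every table
#' is transformed as `(x - mu) / sigma`. Constant features (sigma = 0)
#' transform to 0 rather than dividing by zero.
#'
#' @param train numeric matrix or data.frame of training features.
#' @param others optional named list of further tables to transform
#'   with the training scaler.
#' @return list with `train`, `others`, `mu`, `sigma`.
#' @export
zscore_fit_apply <- function(train, others = list()) {
  train <- as.matrix(train)
  stopifnot(nrow(train) > 0)
  mu <- colMeans(train)
  # population SD (divisor n), matching the usual scaler convention
  sigma <- sqrt(colMeans(sweep(train, 2, mu, "-")^2))
  apply_one <- function(x) {
    x <- as.matrix(x)
    out <- sweep(x, 2, mu, "-")
    out <- sweep(out, 2, ifelse(sigma > 0, sigma, 1), "/")
    out[, sigma == 0] <- 0
    out
  }
  list(train = apply_one(train), others = lapply(others, apply_one),
       mu = mu, sigma = sigma)
}

apply_scaler <- function(x, mu, sigma) {
  x <- as.matrix(x)
  out <- sweep(x, 2, mu, "-")
  out <- sweep(out, 2, ifelse(sigma > 0, sigma, 1), "/")
  out[, sigma == 0] <- 0
  out
}

#' SMOTE minority oversampling
#'
#' Synthesizes minority-class rows by interpolating between a minority
#' instance and one of its k nearest minority neighbours:
#' `x + lambda * (xhat - x)` with `lambda ~ Uniform(0, 1)`. Originals
#' are preserved verbatim and the output is exactly class-balanced.
#' When the minority class has fewer than `k + 1` members, k is
#' reduced to `minority size - 1`.
#'
#' @param features numeric matrix.
#' @param labels binary 0/1 vector.
#' @param k number of nearest neighbours (default 5).
#' @param seed integer seed.
#' @return list with `features`, `labels`, and `n_synthetic`.
#' @export
smote_oversample <- function(features, labels, k = 5, seed = 1) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  tab <- table(factor(labels, levels = c(0, 1)))
  if (any(tab == 0)) {
    stop("SMOTE requires both classes present", call. = FALSE)
  }
  n_needed <- abs(tab[["1"]] - tab[["0"]])
  if (n_needed == 0L) {
    return(list(features = features, labels = labels, n_synthetic = 0L))
  }
  minority <- if (tab[["1"]] < tab[["0"]]) 1L else 0L
  mi <- which(labels == minority)
  Xm <- features[mi, , drop = FALSE]
  nm <- nrow(Xm)
  if (nm < 2L) {
    stop("minority class too small to interpolate", call. = FALSE)
  }
  k <- min(k, nm - 1L)
  d <- as.matrix(stats::dist(Xm))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
  set.seed(seed)
  base_i <- sample.int(nm, n_needed, replace = TRUE)
  pick <- nn[cbind(base_i, sample.int(k, n_needed, replace = TRUE))]
  lam <- stats::runif(n_needed)
  synth <- Xm[base_i, , drop = FALSE] +
    lam * (Xm[pick, , drop = FALSE] - Xm[base_i, , drop = FALSE])
  list(features = rbind(features, synth),
       labels = c(labels, rep(minority, n_needed)),
       n_synthetic = as.integer(n_needed))
}

# Stratified fold assignment: within each class, fold ids are a
# shuffled balanced sequence.
stratified_folds <- function(labels, n_folds = 5, seed = 1) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < n_folds) {
      stop("stratification error: class ", cl, " has fewer than ",
           n_folds, " subjects", call. = FALSE)
    }
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  fold
}

#' Confusion-matrix metrics and rank-based AUC
#'
#' Computes TP/FP/TN/FN at `threshold` and the seven screening
#' metrics: accuracy, sensitivity, specificity, F1, AUC, PPV, NPV.
#' AUC is the rank-based concordance probability (Mann-Whitney), ties
#' counted one half. With a single-class label vector AUC is returned
#' as NA with a warning; threshold metrics are still computed.
#'
#' @param scores class-1 probabilities.
#' @param labels binary 0/1 vector of the same length.
#' @param threshold classification cut (default 0.5).
#' @return named list of class `eval_metrics`.
#' @export
evaluate <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  auc <- if (n1 == 0 || n0 == 0) {
    warning("AUC undefined for single-class labels")
    NA_real_
  } else {
    r <- rank(scores)  # average ranks give half-weight to ties
    (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- ratio(tp, tp + fn)
  ppv <- ratio(tp, tp + fp)
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = (tp + tn) / length(labels),
    sensitivity = sens,
    specificity = ratio(tn, tn + fp),
    f1 = if (!is.na(sens) && !is.na(ppv) && (ppv + sens) > 0) {
      2 * ppv * sens / (ppv + sens)
    } else NA_real_,
    auc = auc, ppv = ppv,
    npv = ratio(tn, tn + fn)), class = "eval_metrics")
}

metric_names <- function() {
  c("accuracy", "sensitivity", "specificity", "f1", "auc", "ppv", "npv")
}

#' Stratified k-fold cross-validation with in-fold SMOTE
#'
#' Per fold: the z-score scaler is fitted on the training fold only,
#' SMOTE balances the scaled training fold only, the model is trained,
#' and the untouched validation fold (original class distribution) is
#' scored. Nothing derived from a validation fold enters any training
#' artifact.
#'
#' @param features data.frame/matrix of predictor columns.
#' @param labels binary 0/1 vector.
#' @param spec a [model_spec()].
#' @param n_folds number of folds (default 5).
#' @param seed fold-assignment / SMOTE seed.
#' @param smote_k SMOTE neighbourhood size.
#' @param threshold classification cut.
#' @param scale_in_fold fit the scaler per training fold (default,
#'   leakage-safe). `FALSE` reproduces the literal fit-once-globally
#'   ordering.
#' @param return_artifacts keep per-fold scalers, oversampled-set
#'   digests, and model digests (used by the leakage tests).
#' @param folds optional precomputed fold assignment (integer vector
#'   in `1:n_folds`), bypassing the internal stratified draw; lets
#'   callers corrupt validation labels while holding folds fixed.
#' @return list of class `subset_result`: `features`, `spec`,
#'   `fold_metrics` (list of [evaluate()] outputs), `mean_metrics`,
#'   and optionally `artifacts`.
#' @export
cross_validate <- function(features, labels, spec, n_folds = 5, seed = 1,
                           smote_k = 5, threshold = 0.5,
                           scale_in_fold = TRUE,
                           return_artifacts = FALSE, folds = NULL) {
  X <- as.matrix(features)
  labels <- as.integer(labels)
  fold <- if (is.null(folds)) stratified_folds(labels, n_folds, seed)
          else as.integer(folds)
  global <- if (!scale_in_fold) zscore_fit_apply(X) else NULL
  fold_metrics <- vector("list", n_folds)
  artifacts <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    if (scale_in_fold) {
      sc <- zscore_fit_apply(X[tr, , drop = FALSE],
                             others = list(val = X[!tr, , drop = FALSE]))
      Xtr <- sc$train
      Xval <- sc$others$val
      mu <- sc$mu; sigma <- sc$sigma
    } else {
      Xtr <- global$train[tr, , drop = FALSE]
      Xval <- global$train[!tr, , drop = FALSE]
      mu <- global$mu; sigma <- global$sigma
    }
    sm <- smote_oversample(Xtr, labels[tr], k = smote_k,
                           seed = seed + f)
    fit <- fit_family(spec, sm$features, sm$labels)
    scores <- predict_prob(fit, Xval)
    fold_metrics[[f]] <- evaluate(scores, labels[!tr], threshold)
    if (return_artifacts) {
      artifacts[[f]] <- list(
        mu = mu, sigma = sigma,
        smote_digest = object_digest(sm),
        model_digest = object_digest(fit),
        n_val = sum(!tr), n_train_after_smote = nrow(sm$features))
    }
  }
  mean_metrics <- sapply(metric_names(), function(m) {
    mean(vapply(fold_metrics, function(fm) fm[[m]], numeric(1)))
  })
  structure(list(features = colnames(features), spec = spec,
                 fold = fold, fold_metrics = fold_metrics,
                 mean_metrics = mean_metrics,
                 artifacts = if (return_artifacts) artifacts),
            class = "subset_result")
}

#' Exhaustive feature-subset search across classifier families
#'
#' Every subset of each requested size, crossed with every requested
#' family, is cross-validated; cells are ranked by mean F1
#' (descending), ties broken by mean AUC, then by lexicographic
#' feature names. With the eight canonical parameters the subset
#' counts are C(8,k): 8, 28, 56 and 70 for sizes 1-4. Sizes of five
#' and above are excluded by default because they add only marginal
#' gains; pass them explicitly to override.
#'
#' @param features data.frame of predictor columns (default the eight
#'   canonical parameters must all be present).
#' @param labels binary 0/1 vector.
#' @param sizes subset sizes to enumerate (default 1:4).
#' @param families families to cross (default all six).
#' @param n_folds,seed,smote_k,threshold passed to [cross_validate()].
#' @param feature_pool names to draw subsets from (defaults to all
#'   columns of `features`).
#' @return data.frame ranked best-first with columns `features`
#'   (" + "-joined), `size`, `family`, and the seven mean metrics;
#'   per-cell `subset_result`s in `attr(, "results")`.
#' @export
subset_search <- function(features, labels, sizes = 1:4,
                          families = model_families(), n_folds = 5,
                          seed = 1, smote_k = 5, threshold = 0.5,
                          feature_pool = colnames(features)) {
  if (!all(feature_pool %in% colnames(features))) {
    stop("configuration error: unknown feature name(s): ",
         paste(setdiff(feature_pool, colnames(features)), collapse = ", "),
         call. = FALSE)
  }
  families <- match.arg(families, model_families(), several.ok = TRUE)
  subsets <- unlist(lapply(sizes, function(k) {
    utils::combn(sort(feature_pool), k, simplify = FALSE)
  }), recursive = FALSE)
  rows <- list()
  results <- list()
  cell <- 0L
  for (sub in subsets) {
    for (fam in families) {
      cell <- cell + 1L
      res <- cross_validate(features[, sub, drop = FALSE], labels,
                            model_spec(fam, seed = seed),
                            n_folds = n_folds, seed = seed,
                            smote_k = smote_k, threshold = threshold)
      rows[[cell]] <- data.frame(
        features = paste(sub, collapse = " + "),
        size = length(sub), family = fam,
        t(res$mean_metrics), stringsAsFactors = FALSE)
      results[[cell]] <- res
    }
  }
  tab <- do.call(rbind, rows)
  ord <- order(-tab$f1, -tab$auc, tab$features, tab$family)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  attr(tab, "results") <- results[ord]
  tab
}

#' Train the final model and validate it externally
#'
#' The scaler is refitted on the full internal cohort and the model is
#' retrained without oversampling (preserving the original class
#' distribution); the external cohort is transformed with the internal
#' scaler and scored untouched.
#'
#' @param spec a [model_spec()] (typically the subset-search winner's).
#' @param feature_names selected feature subset.
#' @param internal data.frame with the features and a `label` column.
#' @param external like `internal`; optional.
#' @param threshold classification cut.
#' @return list of class `trained_model`: `spec`, `feature_names`,
#'   `scaler` (mu, sigma), `fit`, `internal_metrics` (resubstitution),
#'   `external_metrics`, `external_scores`.
#' @export
finalize_and_validate <- function(spec, feature_names, internal,
                                  external = NULL, threshold = 0.5) {
  missing_int <- setdiff(c(feature_names, "label"), colnames(internal))
  if (length(missing_int)) {
    stop("internal cohort lacks column(s): ",
         paste(missing_int, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(internal[, feature_names, drop = FALSE])
  y <- as.integer(internal$label)
  sc <- zscore_fit_apply(X)
  fit <- fit_family(spec, sc$train, y)   # no oversampling on retrain
  internal_metrics <- evaluate(predict_prob(fit, sc$train), y, threshold)
  external_metrics <- NULL
  external_scores <- NULL
  if (!is.null(external)) {
    missing_ext <- setdiff(c(feature_names, "label"), colnames(external))
    if (length(missing_ext)) {
      stop("external cohort lacks column(s): ",
           paste(missing_ext, collapse = ", "), call. = FALSE)
    }
    Xe <- apply_scaler(as.matrix(external[, feature_names, drop = FALSE]),
                       sc$mu, sc$sigma)
    external_scores <- predict_prob(fit, Xe)
    external_metrics <- evaluate(external_scores,
                                 as.integer(external$label), threshold)
  }
  structure(list(spec = spec, feature_names = feature_names,
                 scaler = list(mu = sc$mu, sigma = sc$sigma), fit = fit,
                 threshold = threshold,
                 internal_metrics = internal_metrics,
                 external_metrics = external_metrics,
                 external_scores = external_scores),
            class = "trained_model")
}

#' Score new subjects with a finalized model
#'
#' Columns are aligned by name, so column order in `newdata` is
#' irrelevant.
#'
#' @param object a `trained_model`.
#' @param newdata data.frame containing the model's feature columns.
#' @param ... unused.
#' @return numeric class-1 probabilities.
#' @export
predict.trained_model <- function(object, newdata, ...) {
  missing_cols <- setdiff(object$feature_names, colnames(newdata))
  if (length(missing_cols)) {
    stop("newdata lacks feature column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  X <- apply_scaler(
    as.matrix(newdata[, object$feature_names, drop = FALSE]),
    object$scaler$mu, object$scaler$sigma)
  predict_prob(object$fit, X)
}
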