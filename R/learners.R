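#' Classifier families available to the pipeline
#' @return character vector of family identifiers.
#' @export
model_families <- function() {
  c("LOGISTIC", "SVM_RBF", "RANDOM_FOREST",
    "GBT_SECOND_ORDER", "GBT_LEAFWISE", "GBT_ORDERED")
}

family_defaults <- function(family) {
  switch(family,
    LOGISTIC = list(C = 1.0, penalty = "l2", tol = 1e-4),
    SVM_RBF = list(C = 1.0, gamma = "scale", kernel = "rbf"),
    RANDOM_FOREST = list(criterion = "gini", max_features = "sqrt",
                         n_estimators = 100),
    GBT_SECOND_ORDER = list(learning_rate = 0.3, reg_lambda = 1,
                            n_estimators = 100, booster = "gbtree",
                            max_depth = 6),
    GBT_LEAFWISE = list(learning_rate = 0.1, n_estimators = 100,
                        boosting_type = "gbdt", num_leaves = 31,
                        min_child_samples = 20),
    GBT_ORDERED = list(learning_rate = 0.03, n_estimators = 100,
                       loss_function = "Logloss", l2_leaf_reg = 3,
                       depth = 6),
    stop("unknown model family: ", family, call. = FALSE))
}

#' Specify a classifier configuration
#'
#' Hyperparameter defaults follow the screening protocol's fixed
#' settings for each family (e.g. second-order boosting at learning
#' rate 0.3 with L2 lambda 1; leaf-wise boosting at rate 0.1; ordered/
#' symmetric-tree boosting at rate 0.03 with leaf regularization 3;
#' SVM with C = 1 and "scale" gamma; 100-tree gini forest with sqrt
#' feature sampling; L2 logistic regression with C = 1). Keys not in
#' the family's default list are rejected.
#'
#' @param family one of [model_families()].
#' @param hyperparameters named list overriding family defaults.
#' @param seed integer seed consumed when the family is stochastic.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(family = "GBT_ORDERED", hyperparameters = list(),
                       seed = 1L) {
  family <- match.arg(family, model_families())
  defaults <- family_defaults(family)
  bad <- setdiff(names(hyperparameters), names(defaults))
  if (length(bad)) {
    stop("hyperparameters not in the ", family, " grid: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  defaults[names(hyperparameters)] <- hyperparameters
  structure(list(family = family, hyperparameters = defaults,
                 seed = as.integer(seed)),
            class = "model_spec")
}

# Ridge-penalized logistic regression by IRLS; penalty lambda = 1/C on
# the summed log-loss, intercept unpenalized.
fit_ridge_logistic <- function(X, y, C = 1, tol = 1e-4, max_iter = 100) {
  Xd <- cbind(1, X)
  p <- ncol(Xd)
  lambda <- 1 / C
  beta <- numeric(p)
  pen <- c(0, rep(lambda, p - 1))
  for (it in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Xd, Xd * w) + diag(pen, p)
    grad <- crossprod(Xd, y - mu) - pen * beta
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

# Platt-style probability calibration of a decision value.
fit_platt <- function(dec, y) {
  df <- data.frame(dec = dec, y = y)
  fit <- suppressWarnings(stats::glm(y ~ dec, family = stats::binomial(),
                                     data = df))
  stats::coef(fit)
}

#' Fit a classifier on a scaled feature matrix
#'
#' Low-level fit used inside cross-validation; inputs are assumed
#' already z-scored. Randomness (forest bootstraps, SMO index draws)
#' comes from R's RNG seeded with `spec$seed`.
#'
#' @param spec a [model_spec()].
#' @param X numeric matrix (n x p), scaled.
#' @param y binary 0/1 vector.
#' @return object of class `fitted_family` with a `predict_prob`
#'   closure-free representation.
#' @export
fit_family <- function(spec, X, y) {
  stopifnot(inherits(spec, "model_spec"), is.matrix(X),
            length(y) == nrow(X))
  y <- as.numeric(y)
  hp <- spec$hyperparameters
  set.seed(spec$seed)
  fit <- switch(spec$family,
    LOGISTIC = list(beta = fit_ridge_logistic(X, y, C = hp$C,
                                              tol = hp$tol)),
    SVM_RBF = {
      gamma <- if (identical(hp$gamma, "scale")) {
        1 / (ncol(X) * max(stats::var(as.vector(X)), 1e-12))
      } else as.numeric(hp$gamma)
      ys <- ifelse(y > 0, 1, -1)
      sv <- svm_fit_cpp(X, ys, hp$C, gamma, 1e-3, 5L)
      dec <- svm_decision_cpp(X, ys, sv$alpha, sv$b, gamma, X)
      list(X = X, ys = ys, alpha = sv$alpha, b = sv$b, gamma = gamma,
           platt = fit_platt(dec, y))
    },
    RANDOM_FOREST = rf_fit_cpp(X, as.integer(y), hp$n_estimators,
                               max(1L, floor(sqrt(ncol(X)))), 1L),
    GBT_SECOND_ORDER = gbt_fit_cpp(X, y, hp$n_estimators,
                                   hp$learning_rate, hp$reg_lambda,
                                   hp$max_depth, 0L, 0L, 1L,
                                   base_logit(y)),
    GBT_LEAFWISE = gbt_fit_cpp(X, y, hp$n_estimators, hp$learning_rate,
                               0, 30L, hp$num_leaves, 1L,
                               hp$min_child_samples, base_logit(y)),
    GBT_ORDERED = gbt_fit_cpp(X, y, hp$n_estimators, hp$learning_rate,
                              hp$l2_leaf_reg, hp$depth, 0L, 2L, 1L,
                              base_logit(y)))
  structure(list(spec = spec, fit = fit, p = ncol(X)),
            class = "fitted_family")
}

base_logit <- function(y) {
  p1 <- min(max(mean(y), 1e-6), 1 - 1e-6)
  log(p1 / (1 - p1))
}

#' Class-1 probability from a fitted family
#'
#' @param object a `fitted_family`.
#' @param X scaled feature matrix with the training column order.
#' @return numeric vector of probabilities in [0, 1].
#' @export
predict_prob <- function(object, X) {
  stopifnot(inherits(object, "fitted_family"), is.matrix(X),
            ncol(X) == object$p)
  fit <- object$fit
  switch(object$spec$family,
    LOGISTIC = stats::plogis(drop(cbind(1, X) %*% fit$beta)),
    SVM_RBF = {
      dec <- svm_decision_cpp(fit$X, fit$ys, fit$alpha, fit$b,
                              fit$gamma, X)
      stats::plogis(fit$platt[1] + fit$platt[2] * dec)
    },
    RANDOM_FOREST = rf_prob_cpp(fit, X),
    stats::plogis(gbt_margin_cpp(fit, X)))
}

# Model margin on the attribution scale: logit for boosted trees and
# the linear/kernel families, probability for the forest. Computed on
# the link scale directly so separable fits stay finite.
predict_margin <- function(object, X) {
  fit <- object$fit
  switch(object$spec$family,
    RANDOM_FOREST = rf_prob_cpp(fit, X),
    GBT_SECOND_ORDER = gbt_margin_cpp(fit, X),
    GBT_LEAFWISE = gbt_margin_cpp(fit, X),
    GBT_ORDERED = gbt_margin_cpp(fit, X),
    LOGISTIC = drop(cbind(1, X) %*% fit$beta),
    SVM_RBF = {
      dec <- svm_decision_cpp(fit$X, fit$ys, fit$alpha, fit$b,
                              fit$gamma, X)
      fit$platt[1] + fit$platt[2] * dec
    })
}

# Stable digest of any R object (used by leakage and determinism
# checks): serialized bytes -> md5.
object_digest <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(obj, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}
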