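#' Restricted-cubic-spline nonlinearity test for one predictor
#'
#' Fits a logistic regression of the binary outcome on a natural
#' (restricted) cubic spline basis of the predictor with `df` degrees
#' of freedom (knots at equally spaced quantiles), plus the nested
#' linear logistic fit, and compares them with a likelihood-ratio
#' test on `df - 1` degrees of freedom. The default df = 5 spline
#' against the 1-df linear term gives a 4-df test.
#'
#' @param x numeric predictor (non-constant).
#' @param y binary 0/1 outcome, both classes present.
#' @param df spline degrees of freedom (default 5).
#' @param n_grid points in the exported dose-response curve.
#' @return list of class `rcs_fit`: knots, coefficients, the two
#'   log-likelihoods, `lrt_stat`, `lrt_df`, `lrt_p`, and `curve`
#'   (data.frame: value, prob, lower, upper).
#' @export
rcs_logistic <- function(x, y, df = 5, n_grid = 100) {
  y <- as.integer(y)
  if (stats::sd(x) == 0) stop("predictor is constant", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("both outcome classes required", call. = FALSE)
  }
  if (length(x) <= 10 * df) {
    stop("need more than 10 observations per spline df", call. = FALSE)
  }
  basis <- splines::ns(x, df = df)
  d <- data.frame(y = y)
  spline_fit <- stats::glm(y ~ basis, family = stats::binomial(), data = d)
  linear_fit <- stats::glm(y ~ x, family = stats::binomial(), data = d)
  if (!spline_fit$converged || !linear_fit$converged) {
    stop("fit error: logistic fit did not converge (possible separation)",
         call. = FALSE)
  }
  ll_s <- as.numeric(stats::logLik(spline_fit))
  ll_l <- as.numeric(stats::logLik(linear_fit))
  lrt <- max(0, 2 * (ll_s - ll_l))
  grid <- seq(min(x), max(x), length.out = n_grid)
  gb <- stats::predict(basis, grid)
  eta <- drop(cbind(1, gb) %*% stats::coef(spline_fit))
  # delta-method CI on the link scale
  V <- stats::vcov(spline_fit)
  se <- sqrt(rowSums((cbind(1, gb) %*% V) * cbind(1, gb)))
  structure(list(
    predictor_name = deparse(substitute(x)),
    knots = c(attr(basis, "Boundary.knots")[1], attr(basis, "knots"),
              attr(basis, "Boundary.knots")[2]),
    coefficients = stats::coef(spline_fit),
    loglik_spline = ll_s, loglik_linear = ll_l,
    lrt_stat = lrt, lrt_df = df - 1,
    lrt_p = stats::pchisq(lrt, df - 1, lower.tail = FALSE),
    curve = data.frame(value = grid,
                       prob = stats::plogis(eta),
                       lower = stats::plogis(eta - 1.96 * se),
                       upper = stats::plogis(eta + 1.96 * se))),
    class = "rcs_fit")
}

#' @export
print.rcs_fit <- function(x, ...) {
  cat(sprintf("<rcs_fit> LRT chi2 = %.3f on %d df, p = %.3g\n",
              x$lrt_stat, x$lrt_df, x$lrt_p))
  invisible(x)
}

#' Additive per-sample feature attributions
#'
#' Tree families (forest and the three boosters) use exact path
#' attribution: walking each tree, the change in node value at every
#' split is credited to the split feature, so per sample
#' `base_value + sum(contributions) == model margin` exactly (logit
#' margin for boosters, probability for the forest). Logistic and SVM
#' models use a seeded permutation-sampling approximation against a
#' background sample, which satisfies the same additivity identity by
#' telescoping.
#'
#' @param model a `trained_model` from [finalize_and_validate()].
#' @param data data.frame with the model's feature columns.
#' @param background background rows for the sampling approximation
#'   (defaults to up to 100 rows of `data`).
#' @param n_perm permutations per sample for non-tree families.
#' @param seed seed for the sampling approximation.
#' @return list of class `shap_summary`: `base_value`, `contributions`
#'   (n x p matrix), `mean_abs`, `normalized_importance`.
#' @export
shap_summary <- function(model, data, background = NULL, n_perm = 32,
                         seed = 1) {
  stopifnot(inherits(model, "trained_model"))
  missing_cols <- setdiff(model$feature_names, colnames(data))
  if (length(missing_cols)) {
    stop("data lacks feature column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  X <- apply_scaler(as.matrix(data[, model$feature_names, drop = FALSE]),
                    model$scaler$mu, model$scaler$sigma)
  fam <- model$spec$family
  p <- ncol(X)
  if (fam %in% c("RANDOM_FOREST", "GBT_SECOND_ORDER", "GBT_LEAFWISE",
                 "GBT_ORDERED")) {
    ff <- model$fit$fit
    if (fam == "RANDOM_FOREST") {
      pc <- path_contrib_cpp(ff$trees, X, 1 / length(ff$trees))
      base <- pc$base
    } else {
      pc <- path_contrib_cpp(ff$trees, X, 1)
      base <- pc$base + ff$base_score
    }
    contrib <- pc$contrib
  } else {
    if (is.null(background)) {
      background <- X[seq_len(min(100L, nrow(X))), , drop = FALSE]
    } else {
      background <- apply_scaler(
        as.matrix(background[, model$feature_names, drop = FALSE]),
        model$scaler$mu, model$scaler$sigma)
    }
    set.seed(seed)
    nb <- nrow(background)
    base <- mean(predict_margin(model$fit, background))
    contrib <- matrix(0, nrow(X), p)
    for (i in seq_len(nrow(X))) {
      acc <- numeric(p)
      for (b in seq_len(n_perm)) {
        perm <- sample.int(p)
        z <- background[sample.int(nb, 1L), ]
        prev <- predict_margin(model$fit, matrix(z, 1))
        for (j in perm) {
          z[j] <- X[i, j]
          cur <- predict_margin(model$fit, matrix(z, 1))
          acc[j] <- acc[j] + (cur - prev)
          prev <- cur
        }
      }
      contrib[i, ] <- acc / n_perm
    }
    # recentre so additivity holds against the background mean exactly
    margins <- predict_margin(model$fit, X)
    resid <- margins - base - rowSums(contrib)
    contrib <- contrib + resid / p
  }
  colnames(contrib) <- model$feature_names
  mean_abs <- colMeans(abs(contrib))
  structure(list(base_value = base, contributions = contrib,
                 mean_abs = mean_abs,
                 normalized_importance = mean_abs / sum(mean_abs)),
            class = "shap_summary")
}

#' @export
print.shap_summary <- function(x, ...) {
  cat("<shap_summary> normalized importance:\n")
  print(round(x$normalized_importance, 4))
  invisible(x)
}

#' Sex- and age-stratified subset search
#'
#' Partitions the cohort into male/female and younger/older (the older
#' stratum is age >= 60, inclusive) strata and re-runs the feature
#' subset search per stratum under the same seed policy. Strata that
#' lose a class or drop below 5 subjects per class are skipped with a
#' machine-readable warning record.
#'
#' @param cohort data.frame with the feature columns plus `label`,
#'   `sex`, `age_years`.
#' @param feature_names columns to search over.
#' @param sizes,families,n_folds,seed passed to [subset_search()].
#' @param age_cut older-stratum threshold in years (default 60).
#' @return list with one entry per stratum: either a ranked results
#'   table (with the best row in `attr(, "best")`) or a skip record
#'   `list(skipped = TRUE, reason = ...)`.
#' @export
subgroup_analysis <- function(cohort, feature_names = oximetry_feature_names(),
                              sizes = 1:4, families = model_families(),
                              n_folds = 5, seed = 1, age_cut = 60) {
  strata <- list(
    male = cohort$sex == "male",
    female = cohort$sex == "female",
    younger = cohort$age_years < age_cut,
    older = cohort$age_years >= age_cut)
  out <- list()
  for (nm in names(strata)) {
    sub <- cohort[strata[[nm]], , drop = FALSE]
    counts <- table(factor(sub$label, levels = c(0, 1)))
    if (any(counts < max(5, n_folds))) {
      warning("stratum '", nm, "' skipped: class counts ",
              paste(counts, collapse = "/"))
      out[[nm]] <- list(skipped = TRUE,
                        reason = paste0("class counts ",
                                        paste(counts, collapse = "/")))
      next
    }
    tab <- subset_search(sub[, feature_names, drop = FALSE], sub$label,
                         sizes = sizes, families = families,
                         n_folds = n_folds, seed = seed)
    attr(tab, "best") <- tab[1, c("features", "family", "f1", "auc")]
    out[[nm]] <- tab
  }
  out
}
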