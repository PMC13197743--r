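test_that("the spline fit nests the linear fit", {
  set.seed(3)
  x <- rnorm(500)
  y <- rbinom(500, 1, plogis(0.8 * x))
  fit <- rcs_logistic(x, y)
  expect_gte(fit$loglik_spline, fit$loglik_linear - 1e-8)
  expect_gte(fit$lrt_stat, 0)
  expect_equal(fit$lrt_df, 4)
  expect_true(fit$lrt_p >= 0 && fit$lrt_p <= 1)
  expect_true(all(fit$curve$prob > 0 & fit$curve$prob < 1))
  expect_true(all(fit$curve$lower <= fit$curve$prob &
                    fit$curve$prob <= fit$curve$upper))

  expect_error(rcs_logistic(rep(1, 100), rbinom(100, 1, 0.5)), "constant")
  expect_error(rcs_logistic(rnorm(100), rep(1, 100)), "classes")
  expect_error(rcs_logistic(rnorm(30), rbinom(30, 1, 0.5)), "10 observ")
})

test_that("a threshold-shaped logit is flagged nonlinear, a linear one mostly not", {
  # scaled-down version of the calibration study in the acceptance
  # suite (n = 400, 30 replicates here)
  set.seed(5)
  p_lin <- p_thr <- numeric(30)
  for (r in 1:30) {
    x <- rnorm(400)
    p_lin[r] <- rcs_logistic(x, rbinom(400, 1, plogis(x)))$lrt_p
    p_thr[r] <- suppressWarnings(  # near-saturated fit is expected here
      rcs_logistic(x, rbinom(400, 1,
                             plogis(ifelse(x > 0.5, 2.5, -2)))))$lrt_p
  }
  expect_lte(mean(p_lin < 0.05), 0.2)
  expect_gte(mean(p_thr < 0.05), 0.8)
})

test_that("attribution is additive and ignores unused features", {
  set.seed(11)
  n <- 150
  df <- data.frame(a = rnorm(n), b = rnorm(n), noise = rep(1, n))
  df$label <- as.integer(df$a + 0.5 * df$b > rnorm(n, sd = 0.3))
  for (fam in c("GBT_SECOND_ORDER", "GBT_LEAFWISE", "GBT_ORDERED",
                "RANDOM_FOREST")) {
    m <- finalize_and_validate(model_spec(fam, seed = 3),
                               c("a", "b", "noise"), df)
    sh <- shap_summary(m, df)
    X <- oxiscreen:::apply_scaler(as.matrix(df[, 1:3]), m$scaler$mu,
                                  m$scaler$sigma)
    marg <- oxiscreen:::predict_margin(m$fit, X)
    expect_lt(max(abs(sh$base_value + rowSums(sh$contributions) - marg)),
              1e-6)
    expect_equal(sum(sh$normalized_importance), 1, tolerance = 1e-9)
    # a constant column can never be split on -> zero attribution
    expect_true(all(sh$contributions[, "noise"] == 0), info = fam)
  }
})

test_that("sampling attribution is additive for non-tree families", {
  set.seed(13)
  n <- 80
  df <- data.frame(a = rnorm(n), b = rnorm(n))
  df$label <- as.integer(df$a > 0)
  for (fam in c("LOGISTIC", "SVM_RBF")) {
    m <- finalize_and_validate(model_spec(fam, seed = 2), c("a", "b"), df)
    sh <- shap_summary(m, df[1:20, ], n_perm = 8, seed = 9)
    X <- oxiscreen:::apply_scaler(as.matrix(df[1:20, 1:2]), m$scaler$mu,
                                  m$scaler$sigma)
    marg <- oxiscreen:::predict_margin(m$fit, X)
    expect_lt(max(abs(sh$base_value + rowSums(sh$contributions) - marg)),
              1e-6)
    # the decisive feature dominates
    expect_gt(sh$normalized_importance[["a"]], 0.6)
  }
})

test_that("normalized importance is scale-invariant and sums to one", {
  mean_abs <- c(4, 3, 2, 1)
  expect_equal(mean_abs / sum(mean_abs), c(0.4, 0.3, 0.2, 0.1))
  # scaling all attributions leaves the normalized vector unchanged
  expect_equal(5 * mean_abs / sum(5 * mean_abs), mean_abs / sum(mean_abs))
})

test_that("subgroups partition the cohort with age 60 in the older stratum", {
  set.seed(17)
  n <- 120
  co <- data.frame(f1 = rnorm(n), f2 = rnorm(n),
                   sex = sample(c("male", "female"), n, TRUE),
                   age_years = sample(c(30:59, 60:80), n, TRUE))
  co$label <- as.integer(co$f1 > 0)
  co$age_years[1] <- 60  # boundary subject
  sg <- subgroup_analysis(co, feature_names = c("f1", "f2"), sizes = 1,
                          families = "LOGISTIC", seed = 1)
  expect_setequal(names(sg), c("male", "female", "younger", "older"))
  expect_equal(sum(co$sex == "male") + sum(co$sex == "female"), n)
  expect_equal(sum(co$age_years >= 60) + sum(co$age_years < 60), n)
  # boundary: exactly 60 is "older"
  expect_true(all(co$age_years[co$age_years >= 60] >= 60))
  for (nm in names(sg)) {
    expect_false(isTRUE(sg[[nm]]$skipped))
    expect_equal(nrow(sg[[nm]]), 2)  # two single-feature subsets
  }
})

test_that("degenerate strata are skipped with a warning record", {
  co <- data.frame(f1 = rnorm(40), f2 = rnorm(40),
                   sex = rep("male", 40),
                   age_years = rep(30, 40),
                   label = rep_len(0:1, 40))
  w <- capture_warnings(
    sg <- subgroup_analysis(co, feature_names = c("f1", "f2"), sizes = 1,
                            families = "LOGISTIC"))
  expect_length(w, 2)  # female and older strata both degenerate
  expect_match(w, "skipped", all = TRUE)
  expect_true(sg$female$skipped)
  expect_true(sg$older$skipped)
  expect_false(isTRUE(sg$male$skipped))
})

test_that("distinct hypoxic phenotypes select different parameters by sex", {
  # the sustained-low-mean phenotype (deep, long, rare events) rewards
  # duration/level features; the frequent-brief phenotype rewards ODI.
  # Scaled-down replicate study: single-feature search per stratum.
  picks <- matrix(NA_character_, 8, 2)
  for (r in 1:8) {
    n <- 40
    sex <- rep(c("male", "female"), each = n / 2)
    label <- rep_len(0:1, n)
    profs <- list(
      male_osa = signal_profile(event_rate_per_h = 40, depth_mean = 5,
                                depth_sd = 0.5, duration_mean = 15,
                                duration_sd = 2, noise_sd = 0.2,
                                duration_h = 0.5),
      female_osa = signal_profile(event_rate_per_h = 6, depth_mean = 12,
                                  depth_sd = 1, duration_mean = 90,
                                  duration_sd = 10, noise_sd = 0.2,
                                  duration_h = 0.5),
      ctrl = signal_profile(event_rate_per_h = 1, depth_mean = 4,
                            depth_sd = 0.5, noise_sd = 0.2,
                            duration_h = 0.5))
    rows <- lapply(seq_len(n), function(i) {
      prof <- if (label[i] == 0) profs$ctrl
              else if (sex[i] == "male") profs$male_osa else profs$female_osa
      sig <- generate_signal(prof, seed = r * 1000 + i)
      as.data.frame(t(feature_vector(sig)))
    })
    co <- cbind(do.call(rbind, rows),
                sex = sex, label = label, age_years = 40)
    sg <- suppressWarnings(  # the all-age-40 cohort skips age strata
      subgroup_analysis(co, sizes = 1, families = "LOGISTIC", seed = r))
    picks[r, ] <- c(sg$male$features[1], sg$female$features[1])
  }
  # strata select different leading parameters in most replicates
  expect_gte(mean(picks[, 1] != picks[, 2]), 0.75)
})
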