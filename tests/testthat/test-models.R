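test_that("CMSA averaging identity, determinism, and a separating feature", {
  set.seed(10)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  x <- cbind(sep = y + rnorm(n, 0, 0.05), matrix(rnorm(n * 5), n, 5))
  colnames(x) <- c("sep", paste0("noise", 1:5))
  x <- standardize_features(x)$train

  fit <- cmsa_fit(x, NULL, y, family = "logistic", k_folds = 5, seed = 1)
  # averaged coefficients are exactly the mean of the fold vectors
  expect_equal(unname(fit$coefficients),
               unname(rowMeans(fit$fold_coefficients)[1 + seq_len(ncol(x))]))
  expect_equal(fit$intercept, unname(rowMeans(fit$fold_coefficients)[1]))

  scores <- predict_scores(fit, x)
  expect_equal(evaluate_auc(scores, y), 1.0)

  fit2 <- cmsa_fit(x, NULL, y, family = "logistic", k_folds = 5, seed = 1)
  expect_identical(fit$fold_coefficients, fit2$fold_coefficients)
  expect_equal(fit$cv_scores, fit2$cv_scores)

  expect_error(cmsa_fit(x, NULL, y, k_folds = 61, seed = 1), "k_folds")
  expect_error(cmsa_fit(x, NULL, rep(c(0, 1), c(55, 5)), k_folds = 10, seed = 1),
               "stratify")
})

test_that("pure-noise features give chance-level nested cross-validated AUC", {
  set.seed(11)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  x <- matrix(rnorm(n * 200), n, 200,
              dimnames = list(NULL, paste0("n", 1:200)))
  x <- standardize_features(x)$train
  cv <- cross_validate_cmsa(x, NULL, y, family = "logistic", outer_folds = 10,
                            k_folds = 5, seed = 2)
  # null 95% band for AUC at 30 vs 30 is about +/- 0.15 around 0.5
  expect_gte(cv$auc, 0.35)
  expect_lte(cv$auc, 0.65)
})

test_that("ridge fold fits match the closed-form ridge solution", {
  set.seed(12)
  n <- 80
  p <- 4
  x <- scale(matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p))))
  b <- c(1, -0.5, 0.25, 0)
  y <- as.numeric(x %*% b + rnorm(n, 0, 0.01))
  y <- y - mean(y)
  fit <- cmsa_fit(x, NULL, y, family = "linear", k_folds = 4,
                  alpha_grid = 0, lambda_min_ratio = 1e-6, seed = 3)
  for (j in seq_len(4)) {
    tr <- fit$folds != j
    xt <- x[tr, , drop = FALSE]
    xt <- sweep(xt, 2, colMeans(xt))
    yt <- y[tr] - mean(y[tr])
    # glmnet's gaussian objective is expressed on y scaled by its population
    # SD, so the effective ridge penalty is lambda / sd_n(y)
    lam <- fit$fold_lambda[j] / sqrt(mean(yt^2))
    closed <- solve(crossprod(xt) / nrow(xt) + lam * diag(p),
                    crossprod(xt, yt) / nrow(xt))
    expect_equal(unname(fit$fold_coefficients[1 + seq_len(p), j]),
                 as.numeric(closed), tolerance = 1e-4)
  }
  # near-zero penalty floor: averaged coefficients approach the truth
  expect_equal(unname(fit$coefficients), b, tolerance = 0.05)
})

test_that("AUC follows the Mann-Whitney formulation with half-credit ties", {
  expect_equal(evaluate_auc(c(0.9, 0.8, 0.4, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(evaluate_auc(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(evaluate_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(evaluate_auc(1:4, rep(1, 4)), "both classes")
})

test_that("prediction association matches a contingency oracle and flags separation", {
  # binary score vs binary outcome: OR equals the 2x2 cross-product ratio
  score <- rep(c(1, 0), each = 40)
  y <- c(rep(1, 30), rep(0, 10), rep(1, 10), rep(0, 30))
  res <- prediction_association(score, y, family = "logistic")
  expect_equal(res$estimate, (30 * 30) / (10 * 10), tolerance = 1e-4)
  expect_lt(res$p, 0.001)

  expect_error(prediction_association(y, y, family = "logistic"), "separation")

  # linear family returns the regression slope
  set.seed(13)
  s2 <- rnorm(50)
  y2 <- 2 * s2 + rnorm(50, 0, 0.1)
  res2 <- prediction_association(s2, y2, family = "linear")
  expect_equal(res2$estimate, 2, tolerance = 0.05)
})

test_that("null scores give calibrated association p-values", {
  set.seed(14)
  pvals <- replicate(400, {
    y <- rep(c(0, 1), each = 30)
    prediction_association(rnorm(60), y, family = "logistic")$p
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("top features are ranked by |beta| within class, never mixed", {
  fit <- structure(
    list(coefficients = c(m1 = 0.5, m2 = -0.9, m3 = 0.1, c1 = 0.3, c2 = -0.2),
         feature_class = c("methylation", "methylation", "methylation",
                           "coverage", "coverage"),
         feature_names = c("m1", "m2", "m3", "c1", "c2")),
    class = "PenalizedFit"
  )
  top <- suppressWarnings(select_top_features(fit, n_per_class = 1))
  expect_setequal(top$feature, c("m2", "c1"))
  expect_equal(top$feature[top$class == "methylation"], "m2")

  top2 <- suppressWarnings(select_top_features(fit, n_per_class = 10))
  expect_equal(sort(table(top2$class), decreasing = TRUE),
               sort(table(fit$feature_class), decreasing = TRUE))

  fit$feature_class <- rep("methylation", 5)
  expect_error(select_top_features(fit), "both feature classes")
})

test_that("age acceleration is the residual on true age", {
  age <- c(50, 60, 70, 80)
  expect_equal(age_acceleration(age, age)$acceleration, rep(0, 4))
  expect_equal(age_acceleration(age + 5, age)$acceleration, rep(0, 4))
  expect_equal(age_acceleration(2 * age, age)$acceleration, rep(0, 4))
  expect_error(age_acceleration(age, rep(60, 4)), "constant")
  expect_error(age_acceleration(age[1:2], age[1:2]), "at least 3")

  set.seed(15)
  pred <- age + rnorm(4)
  acc <- age_acceleration(pred, age)$acceleration
  expect_equal(sum(acc), 0, tolerance = 1e-10)
  expect_equal(unname(cor(acc, age)), 0, tolerance = 1e-8)
})

test_that("acceleration association recovers a planted effect in sign", {
  set.seed(16)
  n <- 200
  age <- rnorm(n, 64, 9)
  accel <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * accel))
  res <- acceleration_association(accel, y, covariates = data.frame(age = age),
                                  family = "logistic")
  expect_gt(res$coefficient, 0)
  expect_lt(res$p, 0.01)
  expect_error(acceleration_association(rep(1, n), y), "zero-variance")
})

test_that("classifier power grows with the muscle shift and dies under permutation", {
  panel <- generate_reference_panel(5, 150, 10, margin = 0.6,
                                    depth_model = 200, seed = 50)
  aucs <- vapply(c(0, 0.03), function(shift) {
    coh <- generate_cfdna_cohort(panel$truth, 30, 30, case_muscle_shift = shift,
                                 depth_model = 150, seed = 51)
    feats <- build_feature_matrix(coh$counts)
    y <- coh$truth$status[match(feats$samples, coh$truth$covariates$sample)]
    # methylation features only: isolates the tissue-proportion signal from
    # the covariate shift
    cross_validate_cmsa(feats$x[, feats$feature_class == "methylation"], NULL,
                        y, family = "logistic", outer_folds = 5, k_folds = 5,
                        alpha_grid = c(0, 0.5, 1), seed = 52)$auc
  }, numeric(1))
  expect_gte(aucs[2], aucs[1] - 0.03)
  expect_gt(aucs[2], 0.6)

  # permuting labels destroys the signal
  coh <- generate_cfdna_cohort(panel$truth, 30, 30, case_muscle_shift = 0.03,
                               depth_model = 150, seed = 51)
  feats <- build_feature_matrix(coh$counts)
  y <- coh$truth$status[match(feats$samples, coh$truth$covariates$sample)]
  set.seed(53)
  perm_auc <- vapply(1:3, function(i) {
    cross_validate_cmsa(feats$x, NULL, sample(y), family = "logistic",
                        outer_folds = 5, k_folds = 5,
                        alpha_grid = c(0, 0.5, 1), seed = 54 + i)$auc
  }, numeric(1))
  expect_lt(abs(median(perm_auc) - 0.5), 0.1)
})
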