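# Penalized regression with cross-model selection and averaging (CMSA).
#
# CMSA splits the training set into K folds; for each fold an elastic-net
# regularization path is fit on the other K-1 folds (clinical covariates never
# penalized) and the (alpha, lambda) pair minimizing that fold's held-out loss
# is kept. The K fold-wise coefficient vectors are averaged into the final
# model, removing the need to refit at a single chosen lambda. The inner path
# solver is glmnet; the fold logic, hyperparameter selection and averaging
# live here.

stratified_folds <- function(y, k_folds, family) {
  n <- length(y)
  if (k_folds > n) stop("k_folds (", k_folds, ") exceeds sample count (", n, ")")
  fold <- integer(n)
  if (family == "logistic") {
    if (min(table(y)) < k_folds) {
      stop("cannot stratify: a class has fewer members (",
           min(table(y)), ") than k_folds (", k_folds, ")")
    }
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k_folds), length(idx))
    }
  } else {
    fold[sample(n)] <- rep_len(seq_len(k_folds), n)
  }
  fold
}

held_out_loss <- function(eta, y, family) {
  if (family == "logistic") {
    p <- stats::plogis(eta)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -2 * colSums(y * log(p) + (1 - y) * log(1 - p))
  } else {
    colMeans((y - eta)^2)
  }
}

#' Elastic-net fit with cross-model selection and averaging
#'
#' @param x Penalized feature matrix (samples x features), already
#'   standardized; may be NULL or zero-column for a covariate-only baseline
#'   (then an ordinary GLM is fit per fold and averaged the same way).
#' @param covariates Optional unpenalized covariate matrix (e.g. a
#'   `CovariateBlock`).
#' @param y Outcome: binary (0/1, logical or two-level factor) for
#'   `family = "logistic"`, numeric for `"linear"`.
#' @param family Model family.
#' @param k_folds Number of CMSA folds (default 10); folds are stratified by
#'   outcome for logistic models and seeded.
#' @param alpha_grid Elastic-net mixing values, evenly spaced in [0, 1]
#'   (0 = ridge, 1 = lasso).
#' @param n_lambda,lambda_min_ratio Regularization path: `n_lambda` values
#'   from the data-driven maximum down `-log10(lambda_min_ratio)` orders of
#'   magnitude.
#' @param feature_class Optional per-feature class labels
#'   ("methylation"/"coverage") carried into the fit for
#'   [select_top_features()].
#' @param seed RNG seed (fold assignment); the fit is deterministic given it.
#' @return A `PenalizedFit`: averaged `coefficients` (penalized features),
#'   `intercept`, `covariate_coefficients`, `fold_coefficients` matrix,
#'   per-fold `fold_alpha`/`fold_lambda`/`fold_loss`, modal `alpha`, held-out
#'   `cv_scores` (response scale, one per sample) and `cv_auc` (logistic).
#'   Note each fold's validation samples also select that fold's
#'   hyperparameters, so `cv_auc` is mildly optimistic under the null; use
#'   [cross_validate_cmsa()] for an unbiased estimate.
#' @export
cmsa_fit <- function(x, covariates = NULL, y,
                     family = c("logistic", "linear"),
                     k_folds = 10,
                     alpha_grid = c(0, 0.25, 0.5, 0.75, 1),
                     n_lambda = 100, lambda_min_ratio = 1e-4,
                     feature_class = NULL, seed = 1) {
  family <- match.arg(family)
  if (is.null(x)) x <- matrix(numeric(0), nrow = length(y), ncol = 0)
  x <- as.matrix(x)
  cov <- if (is.null(covariates)) {
    matrix(numeric(0), nrow = length(y), ncol = 0)
  } else {
    unclass(as.matrix(covariates))
  }
  if (anyNA(x) || anyNA(cov)) stop("missing values in the model inputs")
  if (family == "logistic") {
    if (is.factor(y) || is.character(y)) {
      y <- as.integer(factor(y)) - 1L
    }
    y <- as.numeric(y)
    if (!all(y %in% c(0, 1))) stop("y must be binary for logistic models")
  } else {
    y <- as.numeric(y)
  }
  n <- length(y)
  stopifnot(nrow(x) == n, nrow(cov) == 0 || nrow(cov) == n)
  p <- ncol(x)
  q <- ncol(cov)
  feat_names <- colnames(x) %||% if (p > 0) paste0("f", seq_len(p)) else character(0)
  cov_names <- colnames(cov) %||% if (q > 0) paste0("c", seq_len(q)) else character(0)
  if (!is.null(feature_class)) stopifnot(length(feature_class) == p)

  glmnet_family <- if (family == "logistic") "binomial" else "gaussian"
  xall <- cbind(x, cov)
  colnames(xall) <- c(feat_names, cov_names)

  with_seed(seed, {
    fold <- stratified_folds(y, k_folds, family)
    coef_mat <- matrix(NA_real_, 1 + p + q, k_folds,
                       dimnames = list(c("(Intercept)", feat_names, cov_names),
                                       NULL))
    fold_alpha <- fold_lambda <- fold_loss <- rep(NA_real_, k_folds)
    cv_scores <- rep(NA_real_, n)

    for (j in seq_len(k_folds)) {
      tr <- fold != j
      te <- !tr
      if (p == 0) {
        # covariate-only baseline: unpenalized GLM, same folding and averaging
        fam <- if (family == "logistic") stats::binomial() else stats::gaussian()
        xtr <- cbind(1, cov[tr, , drop = FALSE])
        fit <- suppressWarnings(stats::glm.fit(xtr, y[tr], family = fam))
        cf <- stats::coef(fit)
        cf[is.na(cf)] <- 0
        coef_mat[, j] <- cf
        eta_te <- cbind(1, cov[te, , drop = FALSE]) %*% coef_mat[, j]
        fold_loss[j] <- sum(held_out_loss(eta_te, y[te], family))
      } else {
        pf <- c(rep(1, p), rep(0, q))
        best <- NULL
        for (a in alpha_grid) {
          gfit <- glmnet::glmnet(
            xall[tr, , drop = FALSE], y[tr], family = glmnet_family,
            alpha = a, nlambda = n_lambda,
            lambda.min.ratio = lambda_min_ratio,
            penalty.factor = pf, standardize = FALSE
          )
          eta <- stats::predict(gfit, xall[te, , drop = FALSE], type = "link")
          losses <- held_out_loss(eta, y[te], family)
          i <- which.min(losses)
          if (is.null(best) || losses[i] < best$loss) {
            best <- list(
              loss = losses[i], alpha = a, lambda = gfit$lambda[i],
              coef = as.numeric(stats::coef(gfit)[, i])
            )
          }
        }
        coef_mat[, j] <- best$coef
        fold_alpha[j] <- best$alpha
        fold_lambda[j] <- best$lambda
        fold_loss[j] <- best$loss
      }
      eta_te <- cbind(1, xall[te, , drop = FALSE]) %*% coef_mat[, j]
      cv_scores[te] <- if (family == "logistic") stats::plogis(eta_te) else eta_te
    }

    avg <- rowMeans(coef_mat)
    alpha_tab <- table(fold_alpha)
    chosen_alpha <- if (p > 0) {
      as.numeric(names(alpha_tab)[which.max(alpha_tab)])
    } else {
      NA_real_
    }
    fit <- structure(
      list(
        coefficients = stats::setNames(avg[1 + seq_len(p)], feat_names),
        intercept = unname(avg[1]),
        covariate_coefficients = stats::setNames(avg[1 + p + seq_len(q)], cov_names),
        fold_coefficients = coef_mat,
        fold_alpha = fold_alpha, fold_lambda = fold_lambda,
        fold_loss = fold_loss,
        alpha = chosen_alpha,
        family = family,
        feature_names = feat_names,
        feature_class = feature_class,
        folds = fold,
        cv_scores = cv_scores,
        seed = seed
      ),
      class = "PenalizedFit"
    )
    fit$cv_auc <- if (family == "logistic") evaluate_auc(cv_scores, y) else NA_real_
    fit
  })
}

#' @export
print.PenalizedFit <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat(sprintf(
    "PenalizedFit (%s, CMSA over %d folds): %d/%d nonzero features, alpha = %s%s\n",
    x$family, ncol(x$fold_coefficients), nz, length(x$coefficients),
    format(x$alpha),
    if (x$family == "logistic") sprintf(", CV AUC = %.3f", x$cv_auc) else ""
  ))
  invisible(x)
}

#' Nested cross-validated performance of the CMSA model
#'
#' The fold-wise validation scores inside [cmsa_fit()] choose their own
#' hyperparameters on the fold they score, so they are optimistically biased
#' under the null. This evaluator wraps the whole CMSA procedure in an outer
#' cross-validation: for each outer fold a complete CMSA model is fit on the
#' remaining samples and applied to the held-out fold, giving honest
#' out-of-sample scores (the cross-validated AUC reported for the
#' classification analyses).
#'
#' @param x,covariates,y,family As [cmsa_fit()].
#' @param outer_folds Number of outer folds (stratified for logistic).
#' @param seed Seed for the outer fold split; inner fits derive their seeds.
#' @param ... Passed to [cmsa_fit()] (e.g. `k_folds`, `alpha_grid`).
#' @return list with `scores` (out-of-sample, response scale), `auc`
#'   (logistic) or `mse` (linear), and `folds`.
#' @export
cross_validate_cmsa <- function(x, covariates = NULL, y,
                                family = c("logistic", "linear"),
                                outer_folds = 10, seed = 1, ...) {
  family <- match.arg(family)
  if (is.factor(y) || is.character(y)) y <- as.integer(factor(y)) - 1L
  y <- as.numeric(y)
  n <- length(y)
  cov <- if (is.null(covariates)) NULL else unclass(as.matrix(covariates))
  fold <- with_seed(seed, stratified_folds(y, outer_folds, family))
  scores <- rep(NA_real_, n)
  for (j in seq_len(outer_folds)) {
    tr <- fold != j
    fit <- cmsa_fit(
      x = if (is.null(x)) NULL else x[tr, , drop = FALSE],
      covariates = if (is.null(cov)) NULL else cov[tr, , drop = FALSE],
      y = y[tr], family = family, seed = seed + 101L * j, ...
    )
    scores[!tr] <- predict_scores(
      fit,
      x = if (is.null(x)) NULL else x[!tr, , drop = FALSE],
      covariates = if (is.null(cov)) NULL else cov[!tr, , drop = FALSE]
    )
  }
  out <- list(scores = scores, folds = fold)
  if (family == "logistic") {
    out$auc <- evaluate_auc(scores, y)
  } else {
    out$mse <- mean((y - scores)^2)
  }
  out
}

#' Predict scores from a CMSA fit
#'
#' @param fit A `PenalizedFit`.
#' @param x Feature matrix containing at least the fit's feature columns.
#' @param covariates Covariate matrix matching the fit's covariate columns.
#' @return Per-sample score: probability for logistic, real for linear.
#' @export
predict_scores <- function(fit, x = NULL, covariates = NULL) {
  stopifnot(inherits(fit, "PenalizedFit"))
  eta <- rep(fit$intercept, max(nrow(x %||% covariates), 1))
  if (length(fit$coefficients) > 0) {
    missing <- setdiff(fit$feature_names, colnames(x))
    if (length(missing) > 0) {
      stop("features missing from x: ",
           paste(utils::head(missing, 5), collapse = ", "),
           if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5))
    }
    eta <- eta + as.numeric(x[, fit$feature_names, drop = FALSE] %*% fit$coefficients)
  }
  if (length(fit$covariate_coefficients) > 0) {
    cn <- names(fit$covariate_coefficients)
    cov <- unclass(as.matrix(covariates))
    missing <- setdiff(cn, colnames(cov))
    if (length(missing) > 0) {
      stop("covariates missing: ", paste(missing, collapse = ", "))
    }
    eta <- eta + as.numeric(cov[, cn, drop = FALSE] %*% fit$covariate_coefficients)
  }
  if (fit$family == "logistic") stats::plogis(eta) else eta
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' Probability that a random positive outscores a random negative, ties
#' counted one half.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (1/TRUE/second factor level = positive).
#' @return AUC in [0, 1].
#' @export
evaluate_auc <- function(scores, labels) {
  if (is.factor(labels) || is.character(labels)) {
    labels <- as.integer(factor(labels)) - 1L
  }
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute AUC")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Test whether model predictions associate with the true outcome
#'
#' Fits a covariate-adjusted GLM of the outcome on the prediction score and
#' returns the score term's effect (odds ratio for logistic, slope for linear)
#' with its Wald p-value. Perfect separation is raised as an error rather than
#' returning a silently divergent estimate.
#'
#' @param scores Per-sample prediction scores.
#' @param y Outcome (binary for logistic).
#' @param covariates Optional covariate matrix or data.frame.
#' @param family "logistic" or "linear".
#' @return list with `estimate` (OR or slope), `coefficient` (log scale for
#'   logistic), `p`.
#' @export
prediction_association <- function(scores, y, covariates = NULL,
                                   family = c("logistic", "linear")) {
  family <- match.arg(family)
  df <- data.frame(score = as.numeric(scores))
  if (!is.null(covariates)) {
    df <- cbind(df, as.data.frame(unclass(as.matrix(covariates))))
  }
  if (nrow(df) <= ncol(df) + 2) stop("too few samples for the association model")
  if (family == "logistic") {
    if (is.factor(y) || is.character(y)) y <- as.integer(factor(y)) - 1L
    df$y <- as.numeric(y)
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm(y ~ ., data = df, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
          sep <<- TRUE
        }
        invokeRestart("muffleWarning")
      }
    )
    if (sep || fit$deviance < max(1e-8, 1e-6 * fit$null.deviance) ||
        any(abs(stats::coef(fit)["score"]) > 1e3, na.rm = TRUE)) {
      stop("perfect (or quasi-perfect) separation: the score term diverges")
    }
    sm <- summary(fit)$coefficients
    list(estimate = exp(sm["score", "Estimate"]),
         coefficient = sm["score", "Estimate"],
         p = sm["score", "Pr(>|z|)"])
  } else {
    df$y <- as.numeric(y)
    fit <- stats::lm(y ~ ., data = df)
    sm <- summary(fit)$coefficients
    list(estimate = sm["score", "Estimate"],
         coefficient = sm["score", "Estimate"],
         p = sm["score", "Pr(>|t|)"])
  }
}

#' Top features per class by averaged coefficient magnitude
#'
#' Selects the `n_per_class` features with the largest absolute averaged beta
#' within each feature class (methylation and coverage are never mixed); ties
#' broken by feature name.
#'
#' @param fit A `PenalizedFit` carrying `feature_class`.
#' @param n_per_class Features per class (default 1000).
#' @return data.frame with `feature`, `class`, `beta`.
#' @export
select_top_features <- function(fit, n_per_class = 1000) {
  stopifnot(inherits(fit, "PenalizedFit"))
  if (is.null(fit$feature_class)) {
    stop("fit does not carry feature classes; pass feature_class to cmsa_fit()")
  }
  if (length(unique(fit$feature_class)) < 2) {
    stop("fit must contain both feature classes")
  }
  out <- lapply(split(seq_along(fit$coefficients), fit$feature_class), function(idx) {
    b <- fit$coefficients[idx]
    ord <- order(-abs(b), names(b))
    if (length(idx) < n_per_class) {
      warning("fewer than ", n_per_class, " features in class; returning all")
    }
    take <- utils::head(ord, n_per_class)
    data.frame(feature = names(b)[take],
               class = fit$feature_class[idx][take],
               beta = unname(b[take]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Epigenetic age acceleration
#'
#' Residual of methylation-predicted age regressed on true age (ordinary least
#' squares). Regressing rather than differencing makes the acceleration
#' uncorrelated with true age by construction, so a constant offset or scaling
#' of the predictions does not masquerade as acceleration.
#'
#' @param predicted_age Methylation-predicted ages (years).
#' @param true_age Chronological ages (years); must vary.
#' @return list with `acceleration` (per-sample residual, years), `intercept`,
#'   `slope`.
#' @export
age_acceleration <- function(predicted_age, true_age) {
  stopifnot(length(predicted_age) == length(true_age))
  if (length(true_age) < 3) stop("need at least 3 samples")
  if (stats::sd(true_age) == 0) stop("true age is constant; cannot regress")
  fit <- stats::lm(predicted_age ~ true_age)
  list(acceleration = unname(stats::residuals(fit)),
       intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]))
}

#' Association between age acceleration and an outcome
#'
#' [prediction_association()] with the acceleration as exposure; covariates
#' should include true age (plus sex, SIRE, cfDNA concentration, total input).
#'
#' @param accel Acceleration vector (or the list from [age_acceleration()]).
#' @param outcome Outcome vector.
#' @param covariates Covariate matrix/data.frame including true age.
#' @param family "logistic" or "linear".
#' @return As [prediction_association()].
#' @export
acceleration_association <- function(accel, outcome, covariates = NULL,
                                     family = c("logistic", "linear")) {
  if (is.list(accel) && !is.null(accel$acceleration)) accel <- accel$acceleration
  if (stats::sd(accel) == 0) stop("zero-variance age acceleration")
  prediction_association(accel, outcome, covariates, family = match.arg(family))
}
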