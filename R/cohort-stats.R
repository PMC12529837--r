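# Cohort-level statistics and QC: per-tissue case/control association with
# FDR control, genetic-sex inference from chrX/chr19 read dosage, binomial
# read downsampling, on-target saturation, and screening-test arithmetic.

#' Benjamini-Hochberg false discovery rate control
#'
#' Standard step-up BH with monotonicity enforcement (via
#' [stats::p.adjust()]).
#'
#' @param pvalues P-values in [0, 1] (NA allowed and propagated).
#' @param q FDR level.
#' @return list with `qvalues` and `reject` flags.
#' @export
bh_fdr <- function(pvalues, q = 0.10) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  qv <- stats::p.adjust(pvalues, method = "BH")
  list(qvalues = qv, reject = !is.na(qv) & qv <= q)
}

#' Per-tissue case/control association of deconvolved proportions
#'
#' For each tissue, a two-sided Mann-Whitney U test (normal approximation with
#' tie correction) on the estimated proportions, and a covariate-adjusted
#' logistic regression of case/control status on the proportion. BH correction
#' at `fdr_q` is applied across tissues to the logistic-regression p-values
#' (the inferential model); Mann-Whitney p-values are reported unadjusted.
#'
#' @param alpha Samples x tissues proportion matrix, or a
#'   `DeconvolutionResult`.
#' @param status Case/control status ("case" = positive, or 0/1).
#' @param covariates Optional covariate matrix/data.frame (age, sex, SIRE...).
#' @param fdr_q FDR level for the significance flag.
#' @return data.frame (`tissue`, `mwu_p`, `log_odds`, `logit_p`, `q`,
#'   `significant`), a tissue association table.
#' @export
tissue_case_control_tests <- function(alpha, status, covariates = NULL,
                                      fdr_q = 0.10) {
  if (inherits(alpha, "DeconvolutionResult")) alpha <- alpha$alpha
  alpha <- as.matrix(alpha)
  if (is.factor(status) || is.character(status)) {
    status <- as.integer(status == "case")
  }
  status <- as.numeric(status)
  if (length(unique(status)) < 2) stop("both classes must be present")
  stopifnot(nrow(alpha) == length(status))
  tissues <- colnames(alpha) %||% paste0("tissue", seq_len(ncol(alpha)))
  cov_df <- if (is.null(covariates)) NULL else as.data.frame(unclass(as.matrix(covariates)))

  res <- lapply(seq_len(ncol(alpha)), function(t) {
    prop <- alpha[, t]
    if (stats::sd(prop) == 0) {
      warning("constant proportions for tissue ", tissues[t],
              "; Mann-Whitney p set to 1")
      mwu_p <- 1
      lor <- NA_real_
      lp <- NA_real_
    } else {
      mwu_p <- stats::wilcox.test(prop[status == 1], prop[status == 0],
                                  exact = FALSE)$p.value
      df <- data.frame(y = status, prop = prop)
      if (!is.null(cov_df)) df <- cbind(df, cov_df)
      fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                         family = stats::binomial()))
      sm <- summary(fit)$coefficients
      lor <- sm["prop", "Estimate"]
      lp <- sm["prop", "Pr(>|z|)"]
    }
    data.frame(tissue = tissues[t], mwu_p = mwu_p, log_odds = lor,
               logit_p = lp, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  adj <- bh_fdr(out$logit_p, fdr_q)
  out$q <- adj$qvalues
  out$significant <- adj$reject
  rownames(out) <- NULL
  out
}

#' Infer genetic sex from chrX/chr19 read dosage
#'
#' Individuals with two X chromosomes have the same copy number for chrX and
#' chr19, so their mapped-read ratio is approximately 1; one X halves it to
#' about 0.5. The call threshold defaults to 0.75, the midpoint.
#'
#' @param chr19_reads,chrX_reads Mapped read counts (chr19 must be > 0).
#' @param xx_threshold Ratio at or above which the call is XX.
#' @return data.frame with `ratio` (chrX/chr19) and `call` ("XX"/"XY").
#' @export
infer_genetic_sex <- function(chr19_reads, chrX_reads, xx_threshold = 0.75) {
  if (any(chr19_reads <= 0)) stop("chr19_reads must be positive")
  ratio <- chrX_reads / chr19_reads
  data.frame(ratio = ratio, call = ifelse(ratio >= xx_threshold, "XX", "XY"),
             stringsAsFactors = FALSE)
}

#' Binomial read downsampling of a count table
#'
#' Thins methylated and unmethylated reads independently as
#' Binomial(count, keep_proportion) — the exact count-level equivalent of
#' uniform read subsampling from an alignment.
#'
#' @param counts A [methylome_counts()] object.
#' @param keep_proportion Probability of keeping each read, in [0, 1].
#' @param seed RNG seed.
#' @return A thinned [methylome_counts()] object.
#' @export
downsample_counts <- function(counts, keep_proportion, seed = 1) {
  stopifnot(inherits(counts, "MethylomeCounts"),
            keep_proportion >= 0, keep_proportion <= 1)
  if (keep_proportion == 1) return(counts)
  with_seed(seed, {
    m <- counts$meth
    u <- counts$total - counts$meth
    m[] <- stats::rbinom(length(m), as.vector(m), keep_proportion)
    u[] <- stats::rbinom(length(u), as.vector(u), keep_proportion)
    methylome_counts(counts$sites, m, m + u,
                     sample_names = colnames(counts$meth))
  })
}

#' Classification performance across downsampling levels
#'
#' For each keep proportion: thin the counts, rebuild the feature matrices and
#' re-evaluate the CMSA classifier, recording the cross-validated AUC. The
#' undownsampled row (proportion 1) reproduces the baseline AUC exactly under
#' the same seed. `evaluation = "cmsa"` (default) records the K-fold CMSA
#' validation AUC, the quantity the downsampling analyses report;
#' `evaluation = "nested"` wraps each level in [cross_validate_cmsa()] for an
#' unbiased estimate.
#'
#' @param counts A [methylome_counts()] object.
#' @param proportions Keep proportions, sorted descending.
#' @param status Case/control labels.
#' @param covariates Optional unpenalized covariate matrix (rows named by
#'   sample).
#' @param feature_args List of overrides for [build_feature_matrix()].
#' @param cmsa_args List of overrides for [cmsa_fit()] (e.g. `k_folds`).
#' @param evaluation AUC estimator (see above).
#' @param outer_folds Outer folds for `evaluation = "nested"`.
#' @param seed Seed used both for thinning and the classifier at every level.
#' @return data.frame with `proportion`, `cv_auc`, `n_samples`, `n_features`.
#' @export
downsampling_experiment <- function(counts, proportions, status,
                                    covariates = NULL,
                                    feature_args = list(),
                                    cmsa_args = list(),
                                    evaluation = c("cmsa", "nested"),
                                    outer_folds = 10, seed = 1) {
  evaluation <- match.arg(evaluation)
  if (is.unsorted(rev(proportions), strictly = FALSE)) {
    stop("proportions must be sorted descending")
  }
  names(status) <- colnames(counts$meth)
  rows <- lapply(proportions, function(p) {
    thinned <- downsample_counts(counts, p, seed = seed)
    feats <- do.call(build_feature_matrix, c(list(counts = thinned), feature_args))
    y <- status[feats$samples]
    cov <- if (is.null(covariates)) NULL else covariates[feats$samples, , drop = FALSE]
    auc <- if (evaluation == "cmsa") {
      do.call(cmsa_fit, c(
        list(x = feats$x, covariates = cov, y = y, family = "logistic",
             feature_class = feats$feature_class, seed = seed),
        cmsa_args
      ))$cv_auc
    } else {
      do.call(cross_validate_cmsa, c(
        list(x = feats$x, covariates = cov, y = y, family = "logistic",
             outer_folds = outer_folds, seed = seed),
        cmsa_args
      ))$auc
    }
    data.frame(proportion = p, cv_auc = auc,
               n_samples = length(y), n_features = ncol(feats$x))
  })
  do.call(rbind, rows)
}

#' On-target saturation
#'
#' `1 - (median on-target depth after deduplication / before deduplication)`:
#' the fraction of on-target coverage that was PCR duplication, a measure of
#' library saturation.
#'
#' @param median_depth_pre_dedup,median_depth_post_dedup Median on-target
#'   depths before/after UMI deduplication (`pre > 0`, `post <= pre`).
#' @return Saturation proportion in [0, 1].
#' @export
on_target_saturation <- function(median_depth_pre_dedup,
                                 median_depth_post_dedup) {
  if (any(median_depth_pre_dedup <= 0)) stop("pre-deduplication depth must be > 0")
  if (any(median_depth_post_dedup > median_depth_pre_dedup)) {
    stop("post-deduplication depth cannot exceed pre-deduplication depth")
  }
  1 - median_depth_post_dedup / median_depth_pre_dedup
}

#' Positive predictive value of a screening test
#'
#' `PPV = sens * prev / (sens * prev + (1 - spec) * (1 - prev))`. At the
#' disease prevalence plausible in a specialty clinic (about 5%), a test with
#' 90% sensitivity and specificity yields a PPV of about 32%.
#'
#' @param sensitivity,specificity,prevalence Proportions in [0, 1].
#' @return PPV in [0, 1].
#' @export
positive_predictive_value <- function(sensitivity, specificity, prevalence) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1,
            prevalence >= 0, prevalence <= 1)
  den <- sensitivity * prevalence + (1 - specificity) * (1 - prevalence)
  if (den == 0) stop("undefined PPV: no positive test results")
  sensitivity * prevalence / den
}
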