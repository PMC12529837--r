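# Feature engineering: turns QC'd CpG counts into the two model input
# matrices (methylation proportion and normalized coverage) and the encoded
# covariate block. The pipeline order is fixed: sample/site QC -> methylation
# proportions -> soft-impute -> low-variance filter (coverage normalized and
# filtered in parallel) -> covariate encoding -> standardization.

#' Sample and site quality-control filter
#'
#' Removes samples with more than `max_sample_missing` of sites at zero depth
#' (no reads covering the CpG), then removes sites whose median read coverage
#' across the remaining samples falls below `min_site_median_depth` (default:
#' median of 1 read or less is dropped). The sample filter runs first because
#' site medians change after sample removal.
#'
#' @param counts A [methylome_counts()] object.
#' @param max_sample_missing Maximum tolerated zero-depth site fraction per
#'   sample (strictly greater is dropped).
#' @param min_site_median_depth Minimum median depth a site must reach.
#' @return list with `counts` (filtered), `dropped_samples`, `dropped_sites`
#'   (site ids `chrom:pos`).
#' @export
qc_filter <- function(counts, max_sample_missing = 0.10,
                      min_site_median_depth = 2) {
  stopifnot(inherits(counts, "MethylomeCounts"))
  miss_frac <- colMeans(counts$total == 0)
  drop_samp <- miss_frac > max_sample_missing
  if (all(drop_samp)) {
    stop("all samples exceed the missingness threshold (",
         max_sample_missing, ")")
  }
  samples <- colnames(counts$total) %||% as.character(seq_len(ncol(counts$total)))
  kept <- counts[, !drop_samp]
  med <- apply(kept$total, 1, stats::median)
  # "median of min_site_median_depth - 1 reads or less is removed": a
  # fractional median (e.g. 1.5 with an even sample count) survives
  drop_site <- med <= min_site_median_depth - 1
  out <- kept[!drop_site, ]
  list(
    counts = out,
    dropped_samples = samples[drop_samp],
    dropped_sites = site_ids(counts$sites)[drop_site]
  )
}

#' Methylation-proportion feature matrix
#'
#' methylated/total per entry; zero-depth entries are missing (NA).
#'
#' @param counts QC'd [methylome_counts()].
#' @return samples x sites matrix with attribute `feature_class =
#'   "methylation"`; column names are site ids.
#' @export
methylation_proportions <- function(counts) {
  stopifnot(inherits(counts, "MethylomeCounts"))
  prop <- counts$meth / counts$total
  prop[counts$total == 0] <- NA_real_
  m <- t(prop)
  colnames(m) <- site_ids(counts$sites)
  attr(m, "feature_class") <- "methylation"
  m
}

#' Soft-thresholded SVD matrix completion
#'
#' Iterative SoftImpute: missing entries are initialized at column means, then
#' the matrix is repeatedly SVD-decomposed, its singular values shrunk by
#' `lambda` (and truncated at `rank_max`), and only the missing entries
#' refilled from the reconstruction, until the imputed values stabilize.
#' Observed entries are returned unchanged; imputed values are clipped to
#' [0, 1] (methylation proportions).
#'
#' @param x Numeric matrix with NAs; every row and column needs at least one
#'   observed entry.
#' @param rank_max Maximum rank of the reconstruction.
#' @param lambda Soft-threshold applied to singular values (0 = hard low-rank).
#' @param max_iter,tol Convergence: relative change of the imputed entries.
#' @param clip Range to clip imputed values to, or NULL.
#' @return The completed matrix.
#' @export
soft_impute_complete <- function(x, rank_max = min(dim(x)) - 1L, lambda = 0,
                                 max_iter = 200, tol = 1e-5, clip = c(0, 1)) {
  stopifnot(is.matrix(x), rank_max >= 1)
  miss <- is.na(x)
  if (!any(miss)) return(x)
  if (any(colSums(!miss) == 0)) stop("fully-missing column; cannot impute")
  if (any(rowSums(!miss) == 0)) stop("fully-missing row; cannot impute")
  col_mean <- colMeans(x, na.rm = TRUE)
  z <- x
  z[miss] <- col_mean[col(x)[miss]]
  old <- z[miss]
  for (it in seq_len(max_iter)) {
    sv <- svd(z)
    dshr <- pmax(sv$d - lambda, 0)
    rk <- min(rank_max, sum(dshr > 0))
    if (rk == 0) break
    recon <- sv$u[, seq_len(rk), drop = FALSE] %*%
      (dshr[seq_len(rk)] * t(sv$v[, seq_len(rk), drop = FALSE]))
    new <- recon[miss]
    z[miss] <- new
    rel <- sqrt(sum((new - old)^2)) / max(sqrt(sum(old^2)), 1e-12)
    old <- new
    if (rel < tol) break
  }
  if (!is.null(clip)) z[miss] <- pmin(pmax(z[miss], clip[1]), clip[2])
  z
}

#' Normalized coverage feature matrix
#'
#' Per-sample depth at each CpG divided by the sample's total sequencing
#' reads. Zero-depth entries are 0 (absence of reads is itself informative for
#' coverage features, unlike methylation proportions).
#'
#' @param counts QC'd [methylome_counts()].
#' @param per_sample_total_reads Total sequencing reads per sample (> 0);
#'   defaults to the column sums of the on-target depth matrix.
#' @return samples x sites matrix with attribute `feature_class = "coverage"`.
#' @export
normalized_coverage <- function(counts, per_sample_total_reads = NULL) {
  stopifnot(inherits(counts, "MethylomeCounts"))
  totals <- per_sample_total_reads %||% colSums(counts$total)
  stopifnot(length(totals) == ncol(counts$total))
  if (any(totals <= 0)) stop("zero total reads for sample(s): ",
                             paste(which(totals <= 0), collapse = ", "))
  m <- t(sweep(counts$total, 2, totals, "/"))
  colnames(m) <- site_ids(counts$sites)
  attr(m, "feature_class") <- "coverage"
  m
}

#' Drop the lowest-variance features
#'
#' Removes features whose variance is at or below the `bottom_quantile`
#' quantile of feature variances (ties at the threshold are all removed). With
#' a single feature the quantile is degenerate and the feature is kept.
#'
#' @param x samples x features matrix (>= 2 samples).
#' @param bottom_quantile Quantile of the variance distribution to drop.
#' @return list with `matrix` (surviving features) and `dropped` (names).
#' @export
low_variance_filter <- function(x, bottom_quantile = 0.05) {
  stopifnot(is.matrix(x), nrow(x) >= 2)
  if (ncol(x) <= 1) return(list(matrix = x, dropped = character(0)))
  fc <- attr(x, "feature_class")
  v <- apply(x, 2, stats::var)
  thr <- stats::quantile(v, bottom_quantile, names = FALSE)
  drop <- v <= thr
  out <- x[, !drop, drop = FALSE]
  attr(out, "feature_class") <- fc
  list(matrix = out,
       dropped = colnames(x)[drop] %||% as.character(which(drop)))
}

#' Encode cohort covariates for the penalized models
#'
#' Sex and SIRE are fully one-hot encoded (no reference level dropped, the
#' convention when covariates are unpenalized); age, cfDNA concentration and
#' total cfDNA input enter as continuous columns; a cohort indicator is
#' one-hot appended when the metadata has more than one cohort (or the
#' template requires it). Column order is deterministic: sex levels, SIRE
#' levels, age, cfdna_conc, total_input, cohort levels.
#'
#' @param metadata data.frame with `sex`, `sire`, `age`, `cfdna_conc`,
#'   `total_input` and optionally `cohort`; no missing values allowed.
#' @param template A previous `CovariateBlock` whose factor levels to reuse;
#'   an unseen category then raises an error.
#' @return Numeric matrix (class `CovariateBlock`) with a `levels` attribute.
#' @export
encode_covariates <- function(metadata, template = NULL) {
  need <- c("sex", "sire", "age", "cfdna_conc", "total_input")
  stopifnot(is.data.frame(metadata), all(need %in% names(metadata)))
  if (anyNA(metadata[, intersect(c(need, "cohort"), names(metadata))])) {
    stop("missing covariate values are not allowed")
  }
  lv <- if (!is.null(template)) attr(template, "levels") else NULL
  one_hot <- function(x, levels, prefix) {
    x <- as.character(x)
    unseen <- setdiff(unique(x), levels)
    if (length(unseen) > 0) {
      stop("unseen ", prefix, " categor(ies): ", paste(unseen, collapse = ", "))
    }
    m <- vapply(levels, function(l) as.numeric(x == l), numeric(length(x)))
    m <- matrix(m, nrow = length(x),
                dimnames = list(NULL, paste0(prefix, "_", levels)))
    m
  }
  sex_lv <- lv$sex %||% sort(unique(as.character(metadata$sex)))
  sire_lv <- lv$sire %||% sort(unique(as.character(metadata$sire)))
  blocks <- list(
    one_hot(metadata$sex, sex_lv, "sex"),
    one_hot(metadata$sire, sire_lv, "sire"),
    matrix(c(metadata$age, metadata$cfdna_conc, metadata$total_input),
           ncol = 3, dimnames = list(NULL, c("age", "cfdna_conc", "total_input")))
  )
  cohort_lv <- lv$cohort
  if (is.null(cohort_lv) && "cohort" %in% names(metadata) &&
      length(unique(metadata$cohort)) > 1) {
    cohort_lv <- sort(unique(as.character(metadata$cohort)))
  }
  if (!is.null(cohort_lv)) {
    blocks <- c(blocks, list(one_hot(metadata$cohort, cohort_lv, "cohort")))
  }
  out <- do.call(cbind, blocks)
  rownames(out) <- if ("sample" %in% names(metadata)) metadata$sample else NULL
  attr(out, "levels") <- list(sex = sex_lv, sire = sire_lv, cohort = cohort_lv)
  class(out) <- c("CovariateBlock", class(out))
  out
}

#' Standardize feature matrices to mean zero, variance one
#'
#' By default (`scale_test = "separate"`, the conservative choice made to
#' prevent any train-to-test leakage) the test matrix is standardized with its
#' OWN column means and SDs, not the training parameters;
#' `scale_test = "train"` gives the conventional mode.
#'
#' @param train samples x features matrix (nonzero variance in every column).
#' @param test Optional matrix with the same columns.
#' @param scale_test "separate" (each matrix with its own parameters) or
#'   "train" (apply training parameters to the test set).
#' @return list with `train`, `test` (NULL if absent), and the training
#'   `center`/`scale` vectors.
#' @export
standardize_features <- function(train, test = NULL,
                                 scale_test = c("separate", "train")) {
  scale_test <- match.arg(scale_test)
  stopifnot(is.matrix(train))
  std <- function(m) {
    mu <- colMeans(m)
    sd <- apply(m, 2, stats::sd)
    if (any(sd == 0)) {
      stop("zero-variance feature(s): ",
           paste(utils::head(colnames(m)[sd == 0], 5), collapse = ", "))
    }
    list(x = sweep(sweep(m, 2, mu, "-"), 2, sd, "/"), center = mu, scale = sd)
  }
  tr <- std(train)
  te <- NULL
  if (!is.null(test)) {
    stopifnot(ncol(test) == ncol(train))
    te <- if (scale_test == "separate") {
      std(test)$x
    } else {
      sweep(sweep(test, 2, tr$center, "-"), 2, tr$scale, "/")
    }
  }
  list(train = tr$x, test = te, center = tr$center, scale = tr$scale)
}

#' Run the full on-target feature pipeline on a cohort count table
#'
#' Convenience wrapper fixing the pipeline order: [qc_filter()] ->
#' [methylation_proportions()] -> [soft_impute_complete()] ->
#' [low_variance_filter()], with [normalized_coverage()] ->
#' [low_variance_filter()] in parallel, then column binding and
#' [standardize_features()]. The off-target variant (site missingness
#' threshold, no imputation) is reached via `max_site_missing` and
#' `impute = FALSE`.
#'
#' @param counts A [methylome_counts()] object.
#' @param use_coverage Include normalized-coverage features.
#' @param total_reads Per-sample totals for coverage normalization.
#' @param max_sample_missing,min_site_median_depth QC thresholds.
#' @param max_site_missing Optional site-level missingness cap (off-target
#'   mode drops sites with more than 5% missingness instead of imputing).
#' @param impute Impute the methylation matrix with SoftImpute.
#' @param rank_max,lambda SoftImpute parameters.
#' @param bottom_quantile Low-variance filter quantile.
#' @param standardize Scale features to mean 0, SD 1.
#' @return list with `x` (samples x features matrix), `feature_class`
#'   (per-column "methylation"/"coverage"), `samples`, `dropped`.
#' @export
build_feature_matrix <- function(counts, use_coverage = TRUE,
                                 total_reads = NULL,
                                 max_sample_missing = 0.10,
                                 min_site_median_depth = 2,
                                 max_site_missing = NULL,
                                 impute = TRUE,
                                 rank_max = 10, lambda = 0,
                                 bottom_quantile = 0.05,
                                 standardize = TRUE) {
  qc <- qc_filter(counts, max_sample_missing, min_site_median_depth)
  cnt <- qc$counts
  if (!is.null(max_site_missing)) {
    frac <- rowMeans(cnt$total == 0)
    cnt <- cnt[frac <= max_site_missing, ]
  }
  meth <- methylation_proportions(cnt)
  if (impute && anyNA(meth)) {
    meth_cls <- attr(meth, "feature_class")
    meth <- soft_impute_complete(meth, rank_max = min(rank_max, min(dim(meth)) - 1L),
                                 lambda = lambda)
    attr(meth, "feature_class") <- meth_cls
  } else if (anyNA(meth)) {
    # off-target mode: drop any site still carrying missing entries
    keep <- colSums(is.na(meth)) == 0
    meth <- meth[, keep, drop = FALSE]
    attr(meth, "feature_class") <- "methylation"
  }
  meth <- low_variance_filter(meth, bottom_quantile)$matrix
  colnames(meth) <- paste0("meth|", colnames(meth))
  blocks <- list(meth)
  classes <- rep("methylation", ncol(meth))
  if (use_coverage) {
    cov <- normalized_coverage(cnt, total_reads)
    cov <- low_variance_filter(cov, bottom_quantile)$matrix
    colnames(cov) <- paste0("cov|", colnames(cov))
    blocks <- c(blocks, list(cov))
    classes <- c(classes, rep("coverage", ncol(cov)))
  }
  x <- do.call(cbind, blocks)
  if (standardize) x <- standardize_features(x)$train
  list(x = x, feature_class = classes,
       samples = colnames(cnt$total),
       dropped = list(samples = qc$dropped_samples, sites = qc$dropped_sites))
}
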