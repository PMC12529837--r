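# Tissue-of-origin deconvolution of cfDNA methylation read counts.
#
# Model: each cfDNA read in sample s at region l originates from tissue k with
# probability alpha[s,k] and is methylated with probability beta[k,l]; the
# reference panel's methylated counts are Binomial(reference depth, beta[k,l]).
# Both alpha and beta are estimated jointly by EM, so noisy reference tissues
# are refined by the cfDNA data and extra "unknown" tissues (zero reference
# counts) can absorb cell types missing from the panel.

#' Sum CpG counts into TIM-centred regions
#'
#' Adjacent CpGs are locally correlated in methylation, so summing reads in a
#' window around each target CpG reduces sampling noise. All CpGs within
#' `flank_bp` of the target (inclusive, same chromosome) are summed; targets
#' with no covered CpG get total 0.
#'
#' @param counts A [methylome_counts()] object (samples or reference
#'   replicates/tissues as columns).
#' @param targets TIM records (`chrom`, `pos`) from [select_tims()].
#' @param flank_bp Window half-width in bp (default 250, i.e. +/- 250 bp).
#' @return A [region_counts()] object, one row per target.
#' @export
aggregate_regions <- function(counts, targets, flank_bp = 250) {
  stopifnot(inherits(counts, "MethylomeCounts"),
            all(c("chrom", "pos") %in% names(targets)))
  key <- paste0(targets$chrom, ":", targets$pos)
  if (anyDuplicated(key)) {
    stop("duplicate target positions: ", key[duplicated(key)][1])
  }
  gr_sites <- GenomicRanges::GRanges(
    counts$sites$chrom,
    IRanges::IRanges(start = counts$sites$pos + 1L, width = 1L)
  )
  gr_regions <- GenomicRanges::GRanges(
    targets$chrom,
    IRanges::IRanges(start = targets$pos - flank_bp + 1L,
                     end = targets$pos + flank_bp + 1L)
  )
  hits <- GenomicRanges::findOverlaps(gr_regions, gr_sites)
  n_reg <- nrow(targets)
  meth <- matrix(0L, n_reg, ncol(counts$meth),
                 dimnames = list(NULL, colnames(counts$meth)))
  total <- meth
  if (length(hits) > 0) {
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    mm <- rowsum(counts$meth[s, , drop = FALSE], q)
    tt <- rowsum(counts$total[s, , drop = FALSE], q)
    idx <- as.integer(rownames(mm))
    meth[idx, ] <- as.integer(mm)
    total[idx, ] <- as.integer(tt)
  }
  regions <- data.frame(
    chrom = targets$chrom,
    target_pos = targets$pos,
    start = targets$pos - flank_bp,
    end = targets$pos + flank_bp,
    stringsAsFactors = FALSE
  )
  region_counts(regions, meth, total)
}

#' Joint binomial log-likelihood of the deconvolution model
#'
#' Sum over samples and regions of the binomial log-pmf of the sample's
#' methylated count under mixture methylation probability
#' `sum_k alpha[s,k] * beta[k,l]`, plus the binomial log-likelihood of the
#' reference counts under `beta` (known tissues only; unknown components carry
#' zero reference counts). Zero-depth entries contribute nothing
#' (`0 * log 0 := 0`).
#'
#' @param alpha Samples x tissues proportion matrix (rows on the simplex).
#' @param beta Tissues x regions methylation probability matrix in [0, 1].
#' @param sample_counts,reference_counts [region_counts()] objects; reference
#'   may be NULL to score the sample term alone.
#' @return Scalar log-likelihood.
#' @export
em_log_likelihood <- function(alpha, beta, sample_counts,
                              reference_counts = NULL) {
  if (any(beta < 0 | beta > 1)) stop("beta must lie in [0, 1]")
  x <- t(sample_counts$meth)   # samples x regions
  d <- t(sample_counts$total)
  p <- alpha %*% beta
  ll <- sum(stats::dbinom(x, d, p, log = TRUE))
  if (!is.null(reference_counts)) {
    y <- t(reference_counts$meth)  # tissues x regions
    r <- t(reference_counts$total)
    k <- nrow(y)
    ll <- ll + sum(stats::dbinom(y, r, beta[seq_len(k), , drop = FALSE],
                                 log = TRUE))
  }
  ll
}

# Per-region sample log-likelihood, used to name the offending region when the
# likelihood goes non-finite.
region_loglik <- function(alpha, beta, sample_counts) {
  x <- t(sample_counts$meth)
  d <- t(sample_counts$total)
  p <- alpha %*% beta
  colSums(stats::dbinom(x, d, p, log = TRUE))
}

#' EM deconvolution of cfDNA tissue proportions (CelFiE-style)
#'
#' Estimates per-sample tissue proportions `alpha` and per-tissue region
#' methylation `beta` by maximizing the joint binomial likelihood of the cfDNA
#' counts and the reference counts (see [em_log_likelihood()]). The E-step
#' assigns each sample's methylated/unmethylated reads to tissues in
#' proportion to `alpha[s,k] * beta[k,l]` and `alpha[s,k] * (1 - beta[k,l])`;
#' the M-step sets `alpha[s,k]` proportional to the reads assigned to tissue k
#' and `beta[k,l]` to the pooled (reference + assigned sample) methylated
#' fraction. `n_unknown` extra components with zero reference counts absorb
#' tissues missing from the panel. The algorithm is restarted from
#' `n_restarts` random initializations (alpha rows ~ Dirichlet(1); known beta
#' at reference proportions with a 0.5/1 pseudocount; unknown beta ~ U(0,1))
#' and the restart with the highest final log-likelihood is returned.
#'
#' @param sample_counts cfDNA [region_counts()] (columns = samples).
#' @param reference_counts Reference [region_counts()] (columns = tissues),
#'   aligned on identical regions.
#' @param n_unknown Number of unknown components (default 2, the choice made
#'   for a ~100-sample cohort).
#' @param n_restarts Random restarts (default 10).
#' @param max_iter,tol Convergence: stop when `max |delta alpha| < tol` or
#'   after `max_iter` iterations.
#' @param seed RNG seed; the fit is deterministic given the seed.
#' @return A `DeconvolutionResult`: `alpha` (samples x (K known + U unknown)),
#'   `beta` ((K+U) x regions), `loglik_trace` (best restart, non-decreasing),
#'   `restart_logliks`, `n_restarts`, `seed`, `regions`, `excluded_regions`.
#' @export
celfie_em <- function(sample_counts, reference_counts, n_unknown = 2,
                      n_restarts = 10, max_iter = 1000, tol = 1e-4, seed = 1) {
  stopifnot(inherits(sample_counts, "RegionCounts"),
            inherits(reference_counts, "RegionCounts"),
            n_unknown >= 0, n_restarts >= 1, max_iter >= 1, tol > 0)
  if (!identical(paste0(sample_counts$regions$chrom, ":",
                        sample_counts$regions$target_pos),
                 paste0(reference_counts$regions$chrom, ":",
                        reference_counts$regions$target_pos))) {
    stop("sample and reference counts must be aligned on identical regions")
  }
  k_known <- ncol(reference_counts$meth)
  if (k_known < 1) stop("reference panel must contain at least one tissue")
  tissue_names <- colnames(reference_counts$meth) %||%
    paste0("tissue", seq_len(k_known))

  # drop regions with zero depth everywhere (no information at all)
  dead <- rowSums(sample_counts$total) == 0 & rowSums(reference_counts$total) == 0
  excluded <- which(dead)
  if (length(excluded) > 0) {
    warning(length(excluded),
            " region(s) with zero depth in all samples and tissues excluded")
    keep <- !dead
    sample_counts <- region_counts(sample_counts$regions[keep, , drop = FALSE],
                                   sample_counts$meth[keep, , drop = FALSE],
                                   sample_counts$total[keep, , drop = FALSE])
    reference_counts <- region_counts(reference_counts$regions[keep, , drop = FALSE],
                                      reference_counts$meth[keep, , drop = FALSE],
                                      reference_counts$total[keep, , drop = FALSE])
  }

  x <- t(sample_counts$meth)      # S x L
  d <- t(sample_counts$total)
  y <- t(reference_counts$meth)   # K x L
  r <- t(reference_counts$total)
  n_s <- nrow(x)
  n_l <- ncol(x)
  k <- k_known + n_unknown
  if (n_unknown > 0) {
    y <- rbind(y, matrix(0, n_unknown, n_l))
    r <- rbind(r, matrix(0, n_unknown, n_l))
  }
  comp_names <- c(tissue_names,
                  if (n_unknown > 0) paste0("unknown", seq_len(n_unknown)))
  eps <- 1e-12

  run_em <- function(alpha, beta) {
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      beta <- pmin(pmax(beta, eps), 1 - eps)
      p <- alpha %*% beta            # S x L mixture methylation prob
      q <- alpha %*% (1 - beta)
      xm <- x / pmax(p, eps)         # methylated reads / mixture prob
      xu <- (d - x) / pmax(q, eps)
      # E-step responsibilities folded into the two M-step sufficient stats:
      a_new <- alpha * (xm %*% t(beta) + xu %*% t(1 - beta))  # S x K reads
      rs <- rowSums(a_new)
      zero <- rs <= 0                # sample with no reads: keep current alpha
      a_new[zero, ] <- alpha[zero, , drop = FALSE]
      rs[zero] <- 1
      alpha_new <- a_new / rs

      m_meth <- beta * (t(alpha) %*% xm)        # K x L expected methylated
      m_un <- (1 - beta) * (t(alpha) %*% xu)
      num <- y + m_meth
      den <- r + m_meth + m_un
      beta_new <- ifelse(den > 0, num / pmax(den, eps), beta)

      delta <- max(abs(alpha_new - alpha))
      alpha <- alpha_new
      beta <- pmin(pmax(beta_new, eps), 1 - eps)
      ll <- em_log_likelihood(alpha, beta, sample_counts, reference_counts)
      if (!is.finite(ll)) {
        rl <- region_loglik(alpha, beta, sample_counts)
        bad <- which(!is.finite(rl))[1]
        stop("non-finite likelihood at region ",
             sample_counts$regions$chrom[bad], ":",
             sample_counts$regions$target_pos[bad])
      }
      trace <- c(trace, ll)
      if (delta < tol) break
    }
    list(alpha = alpha, beta = beta, trace = trace)
  }

  with_seed(seed, {
    beta_ref_init <- (y + 0.5) / (r + 1)  # pseudocount keeps beta off 0/1
    best <- NULL
    restart_lls <- numeric(n_restarts)
    for (rst in seq_len(n_restarts)) {
      alpha0 <- rdirichlet(n_s, rep(1, k))
      beta0 <- beta_ref_init
      if (n_unknown > 0) {
        beta0[k_known + seq_len(n_unknown), ] <-
          stats::runif(n_unknown * n_l)
      }
      fit <- run_em(alpha0, beta0)
      restart_lls[rst] <- fit$trace[length(fit$trace)]
      if (is.null(best) || restart_lls[rst] > best$ll) {
        best <- list(ll = restart_lls[rst], fit = fit, restart = rst)
      }
    }
    alpha <- best$fit$alpha
    beta <- best$fit$beta
    dimnames(alpha) <- list(colnames(sample_counts$meth), comp_names)
    dimnames(beta) <- list(comp_names, NULL)
    structure(
      list(alpha = alpha, beta = beta,
           loglik_trace = best$fit$trace,
           restart_logliks = restart_lls,
           best_restart = best$restart,
           n_unknown = n_unknown, n_restarts = n_restarts, seed = seed,
           regions = sample_counts$regions, excluded_regions = excluded),
      class = "DeconvolutionResult"
    )
  })
}

#' @export
print.DeconvolutionResult <- function(x, ...) {
  cat(sprintf(
    "DeconvolutionResult: %d samples x %d components (%d unknown), final loglik %.2f\n",
    nrow(x$alpha), ncol(x$alpha), x$n_unknown,
    x$loglik_trace[length(x$loglik_trace)]
  ))
  invisible(x)
}
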