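# Synthetic-data generators. These state the world the rest of the pipeline is
# tested against: tissue-specific hyper/hypomethylated CpG profiles read out by
# binomial sampling, cfDNA mixtures with known tissue proportions and a
# case-elevated skeletal-muscle-like component, covariates correlated with
# case status, site-level missingness, methylation-standard pools, and sex
# chromosome read counts.

#' Simulate a multi-tissue WGBS reference panel with planted TIMs
#'
#' Draws a methylation probability matrix `beta_true` (tissues x sites) in
#' which most sites are uninformative (a shared baseline plus small tissue
#' noise) and `tims_per_tissue` sites per tissue are planted tissue-informative
#' markers: the target tissue sits at `(1 + margin)/2` and all other tissues at
#' `(1 - margin)/2` for a hypermethylated TIM (reversed for hypomethylated), so
#' the tissue-vs-others-mean gap equals `margin` by construction. Replicate
#' count matrices are then drawn binomially at depths from `depth_model`.
#'
#' @param n_tissues,n_sites,tims_per_tissue Panel dimensions. Requires
#'   `n_sites >= n_tissues * tims_per_tissue`.
#' @param hyper_fraction Fraction of planted TIMs that are hypermethylated.
#' @param margin Planted gap between the TIM tissue's methylation and the mean
#'   of the other tissues, in (0, 1].
#' @param replicates WGBS replicates per tissue (the design uses at least two).
#' @param depth_model A [depth_spec()] or a bare number for constant depth.
#' @param seed RNG seed; output is a pure function of arguments + seed.
#' @param tissue_names Tissue labels; default `tissue1..K`.
#' @param chrom,site_spacing_bp Coordinate layout: sites are placed every
#'   `site_spacing_bp` bp on `chrom` so planted TIMs are not lost to the
#'   500 bp spacing rule by construction.
#' @return list with `counts` (named list tissue -> [methylome_counts()], one
#'   column per replicate) and `truth` (a `ReferencePanelTruth`: `tissue_names`,
#'   `beta_true`, `planted_tims`, `site_coords`).
#' @export
generate_reference_panel <- function(n_tissues, n_sites, tims_per_tissue,
                                     hyper_fraction = 0.5, margin = 0.6,
                                     replicates = 2,
                                     depth_model = depth_spec(100),
                                     seed = 1,
                                     tissue_names = paste0("tissue", seq_len(n_tissues)),
                                     chrom = "chr1",
                                     site_spacing_bp = 1000L) {
  stopifnot(n_tissues >= 1, tims_per_tissue >= 1, replicates >= 1,
            margin > 0, margin <= 1,
            hyper_fraction >= 0, hyper_fraction <= 1)
  n_planted <- n_tissues * tims_per_tissue
  if (n_sites < n_planted) {
    stop(sprintf(
      "infeasible TIM planting: n_sites (%d) < n_tissues * tims_per_tissue (%d)",
      n_sites, n_planted
    ))
  }
  stopifnot(length(tissue_names) == n_tissues)

  with_seed(seed, {
    base <- stats::runif(n_sites, 0.1, 0.9)
    beta <- matrix(rep(base, each = n_tissues), nrow = n_tissues)
    beta <- beta + matrix(stats::rnorm(n_tissues * n_sites, 0, 0.03),
                          nrow = n_tissues)
    beta <- pmin(pmax(beta, 0.01), 0.99)
    rownames(beta) <- tissue_names

    planted_sites <- sample.int(n_sites, n_planted)
    planted_tissue <- rep(seq_len(n_tissues), each = tims_per_tissue)
    direction <- ifelse(stats::runif(n_planted) < hyper_fraction, "hyper", "hypo")
    hi <- (1 + margin) / 2
    lo <- (1 - margin) / 2
    for (i in seq_len(n_planted)) {
      s <- planted_sites[i]
      t <- planted_tissue[i]
      if (direction[i] == "hyper") {
        beta[, s] <- lo
        beta[t, s] <- hi
      } else {
        beta[, s] <- hi
        beta[t, s] <- lo
      }
    }

    site_coords <- data.frame(
      chrom = chrom,
      pos = as.integer((seq_len(n_sites) - 1L) * site_spacing_bp)
    )

    counts <- stats::setNames(vector("list", n_tissues), tissue_names)
    for (t in seq_len(n_tissues)) {
      depth <- matrix(draw_depths(depth_model, n_sites * replicates),
                      nrow = n_sites)
      meth <- matrix(stats::rbinom(n_sites * replicates, as.vector(depth),
                                   rep(beta[t, ], replicates)),
                     nrow = n_sites)
      counts[[t]] <- methylome_counts(
        site_coords, meth, depth,
        sample_names = paste0(tissue_names[t], "_rep", seq_len(replicates))
      )
    }

    planted <- data.frame(
      tissue = tissue_names[planted_tissue],
      site = planted_sites,
      chrom = site_coords$chrom[planted_sites],
      pos = site_coords$pos[planted_sites],
      direction = direction,
      stringsAsFactors = FALSE
    )
    truth <- structure(
      list(tissue_names = tissue_names, beta_true = beta,
           planted_tims = planted, site_coords = site_coords,
           margin = margin),
      class = "ReferencePanelTruth"
    )
    list(counts = counts, truth = truth)
  })
}

#' Default covariate model for the synthetic cohort
#'
#' Mirrors the cohort summaries of an ALS case/control study without claiming
#' to reproduce them: age ~ Normal(64, 9) years, sex Bernoulli(0.5), three
#' self-identified race/ethnicity (SIRE) categories, cfDNA plasma
#' concentration lognormal in ng/uL with the case mean about twice the control
#' mean (cases release more cfDNA), and total cfDNA library input in ng.
#' Case-only phenotypes: ALSFRS-R (0-48), ALSFRS-R slope (points/month,
#' negative = decline) and FVC (% predicted).
#'
#' @param age_mean,age_sd Age distribution (years).
#' @param p_female Probability of female sex.
#' @param sire_levels,sire_probs SIRE categories and sampling probabilities.
#' @param conc_meanlog,conc_sdlog Control cfDNA concentration lognormal
#'   parameters (ng/uL).
#' @param conc_case_multiplier Multiplicative shift of the case concentration.
#' @param input_meanlog,input_sdlog Total cfDNA input lognormal parameters (ng).
#' @return A `covariate_spec` list.
#' @export
covariate_spec <- function(age_mean = 64, age_sd = 9, p_female = 0.5,
                           sire_levels = c("groupA", "groupB", "groupC"),
                           sire_probs = c(0.6, 0.25, 0.15),
                           conc_meanlog = log(0.15), conc_sdlog = 0.7,
                           conc_case_multiplier = 2,
                           input_meanlog = log(20), input_sdlog = 0.5) {
  structure(
    list(age_mean = age_mean, age_sd = age_sd, p_female = p_female,
         sire_levels = sire_levels, sire_probs = sire_probs,
         conc_meanlog = conc_meanlog, conc_sdlog = conc_sdlog,
         conc_case_multiplier = conc_case_multiplier,
         input_meanlog = input_meanlog, input_sdlog = input_sdlog),
    class = "covariate_spec"
  )
}

#' Simulate a case/control cfDNA cohort from a reference panel truth
#'
#' Each sample's tissue proportions are drawn from a Dirichlet distribution
#' centred on `control_alpha` (concentration `concentration`); for cases the
#' centre's muscle-like component is raised by `case_muscle_shift` with the
#' remaining tissues renormalized proportionally. Reads at each site are drawn
#' binomially from the alpha-weighted mixture of the true tissue methylation
#' profiles, at depths from `depth_model`, with a fraction `missing_rate` of
#' entries zeroed out (site-level missing completely at random). Case cfDNA
#' concentration is drawn with a higher mean than controls.
#'
#' @param truth A `ReferencePanelTruth` from [generate_reference_panel()].
#' @param n_cases,n_controls Cohort sizes.
#' @param control_alpha Named simplex of control tissue proportions; default
#'   proportional to `2^-(0:(K-1))` (blood-dominant, the shifted tissue last
#'   at a few percent).
#' @param case_muscle_shift Additive shift of the case mean for `shift_tissue`.
#' @param shift_tissue Tissue receiving the case shift; defaults to a tissue
#'   named "muscle" if present, else the last tissue.
#' @param unknown_profile Optional `list(beta =, proportion =)`: a methylation
#'   profile absent from the reference that contributes a fixed proportion to
#'   every sample (for unknown-component deconvolution tests).
#' @param depth_model,missing_rate,covariate_model,seed See other generators.
#' @param concentration Dirichlet concentration (inter-individual variability
#'   of tissue proportions; 100 gives a SD of about 0.02 on a 5% component).
#' @param cohort Cohort label recorded in the metadata.
#' @return list with `counts` ([methylome_counts()], columns = samples) and
#'   `truth` (a `CohortTruth`: `alpha_true`, `status`, `covariates`,
#'   `phenotypes`).
#' @export
generate_cfdna_cohort <- function(truth, n_cases, n_controls,
                                  control_alpha = NULL,
                                  case_muscle_shift = 0.03,
                                  shift_tissue = NULL,
                                  unknown_profile = NULL,
                                  depth_model = depth_spec(150),
                                  missing_rate = 0.02,
                                  covariate_model = covariate_spec(),
                                  concentration = 100,
                                  seed = 1,
                                  cohort = "cohortA") {
  stopifnot(inherits(truth, "ReferencePanelTruth"),
            n_cases >= 0, n_controls >= 0, n_cases + n_controls >= 1,
            case_muscle_shift >= 0,
            missing_rate >= 0, missing_rate < 1)
  tissues <- truth$tissue_names
  k <- length(tissues)
  if (is.null(control_alpha)) {
    control_alpha <- 2^-(0:(k - 1))
    control_alpha <- stats::setNames(control_alpha / sum(control_alpha), tissues)
  }
  stopifnot(length(control_alpha) == k, abs(sum(control_alpha) - 1) < 1e-8)
  if (is.null(names(control_alpha))) names(control_alpha) <- tissues
  if (is.null(shift_tissue)) {
    shift_tissue <- if ("muscle" %in% tissues) "muscle" else tissues[k]
  }
  ti <- match(shift_tissue, tissues)
  if (is.na(ti)) stop("shift_tissue not in the reference panel: ", shift_tissue)

  case_alpha <- control_alpha
  if (case_alpha[ti] + case_muscle_shift >= 1) {
    stop(sprintf(
      "case_muscle_shift %.3f pushes tissue '%s' proportion to %.3f >= 1; cannot renormalize on the simplex",
      case_muscle_shift, shift_tissue, case_alpha[ti] + case_muscle_shift
    ))
  }
  scale_others <- (1 - (control_alpha[ti] + case_muscle_shift)) /
    (1 - control_alpha[ti])
  case_alpha <- control_alpha * scale_others
  case_alpha[ti] <- control_alpha[ti] + case_muscle_shift

  n <- n_cases + n_controls
  n_sites <- nrow(truth$site_coords)
  cm <- covariate_model

  with_seed(seed, {
    status <- c(rep("case", n_cases), rep("control", n_controls))
    alpha <- matrix(NA_real_, n, k, dimnames = list(NULL, tissues))
    if (n_cases > 0) {
      alpha[status == "case", ] <- rdirichlet(n_cases, concentration * case_alpha)
    }
    if (n_controls > 0) {
      alpha[status == "control", ] <- rdirichlet(n_controls, concentration * control_alpha)
    }

    beta_mix <- alpha %*% truth$beta_true  # samples x sites
    alpha_out <- alpha
    if (!is.null(unknown_profile)) {
      stopifnot(length(unknown_profile$beta) == n_sites,
                unknown_profile$proportion > 0, unknown_profile$proportion < 1)
      p_u <- unknown_profile$proportion
      beta_mix <- (1 - p_u) * beta_mix +
        p_u * matrix(unknown_profile$beta, n, n_sites, byrow = TRUE)
      alpha_out <- cbind(alpha * (1 - p_u), unknown = p_u)
    }

    depth <- matrix(draw_depths(depth_model, n_sites * n), nrow = n_sites)
    meth <- matrix(stats::rbinom(n_sites * n, as.vector(depth),
                                 as.vector(t(beta_mix))),
                   nrow = n_sites)
    if (missing_rate > 0) {
      drop <- matrix(stats::runif(n_sites * n) < missing_rate, nrow = n_sites)
      depth[drop] <- 0L
      meth[drop] <- 0L
    }
    sample_names <- sprintf("S%03d", seq_len(n))
    counts <- methylome_counts(truth$site_coords, meth, depth,
                               sample_names = sample_names)

    is_case <- status == "case"
    conc <- stats::rlnorm(n,
      meanlog = cm$conc_meanlog + ifelse(is_case, log(cm$conc_case_multiplier), 0),
      sdlog = cm$conc_sdlog)
    covariates <- data.frame(
      sample = sample_names,
      status = status,
      age = stats::rnorm(n, cm$age_mean, cm$age_sd),
      sex = ifelse(stats::runif(n) < cm$p_female, "female", "male"),
      sire = sample(cm$sire_levels, n, replace = TRUE, prob = cm$sire_probs),
      cfdna_conc = conc,
      total_input = stats::rlnorm(n, cm$input_meanlog, cm$input_sdlog),
      cohort = cohort,
      stringsAsFactors = FALSE
    )
    phenotypes <- data.frame(
      sample = sample_names,
      alsfrs_r = ifelse(is_case,
                        pmin(48, pmax(0, round(stats::rnorm(n, 38, 6)))), NA),
      alsfrs_slope = ifelse(is_case, stats::rnorm(n, -0.8, 0.5), NA),
      fvc = ifelse(is_case, stats::rnorm(n, 80, 15), NA)
    )
    rownames(alpha_out) <- sample_names
    cohort_truth <- structure(
      list(alpha_true = alpha_out, status = status,
           covariates = covariates, phenotypes = phenotypes,
           shift_tissue = shift_tissue, case_muscle_shift = case_muscle_shift),
      class = "CohortTruth"
    )
    list(counts = counts, truth = cohort_truth)
  })
}

#' Simulate a universal methylation-standard pool
#'
#' Emulates pooled methylation standards in which CpGs are methylated a fixed
#' fraction of the time on average (e.g. a 1:3 molar mixture of fully
#' methylated and fully unmethylated molecules gives 25%): each site's
#' methylated count is Binomial(depth, methylated_fraction).
#'
#' @param methylated_fraction Designed methylation level in [0, 1].
#' @param n_sites Number of CpGs.
#' @param depth Constant read depth per CpG (> 0).
#' @param seed RNG seed.
#' @return A single-sample [methylome_counts()] object.
#' @export
generate_methylation_standard <- function(methylated_fraction, n_sites, depth,
                                          seed = 1) {
  stopifnot(methylated_fraction >= 0, methylated_fraction <= 1, n_sites >= 1)
  if (depth <= 0) stop("depth must be a positive read count")
  with_seed(seed, {
    sites <- data.frame(chrom = "chr1", pos = as.integer(seq_len(n_sites) - 1L))
    meth <- matrix(stats::rbinom(n_sites, depth, methylated_fraction), ncol = 1)
    total <- matrix(as.integer(depth), n_sites, 1)
    methylome_counts(sites, meth, total, sample_names = "standard")
  })
}

#' Simulate chr19 and chrX mapped-read counts by karyotype
#'
#' Read counts are Poisson with mean proportional to chromosome copy number:
#' chr19 has two copies in everyone; chrX has two copies in XX and one in XY,
#' so the expected chrX/chr19 ratio is 1 for XX and 0.5 for XY.
#'
#' @param karyotype "XX" or "XY".
#' @param reads_per_autosome_copy Expected mapped reads per chromosome copy
#'   (> 0).
#' @param seed RNG seed.
#' @return list with `chr19_reads` and `chrX_reads`.
#' @export
generate_sex_read_counts <- function(karyotype = c("XX", "XY"),
                                     reads_per_autosome_copy, seed = 1) {
  karyotype <- match.arg(karyotype)
  if (!is.numeric(reads_per_autosome_copy) || reads_per_autosome_copy <= 0) {
    stop("reads_per_autosome_copy must be > 0")
  }
  x_copies <- if (karyotype == "XX") 2 else 1
  with_seed(seed, {
    list(
      chr19_reads = stats::rpois(1, 2 * reads_per_autosome_copy),
      chrX_reads = stats::rpois(1, x_copies * reads_per_autosome_copy)
    )
  })
}

#' Simulate genomic windows for probe design
#'
#' Uniform-random ACGT sequences of the probe length (default 120 bp), with an
#' optional CG dinucleotide forced across the centre so a target CpG sits
#' mid-window.
#'
#' @param n Number of windows.
#' @param length Window length in bp (>= 2).
#' @param cpg_at_center Force a CG spanning the window centre.
#' @param seed RNG seed.
#' @return data.frame with `window_id`, `seq`, and `cpg_offset` (0-based offset
#'   of the CpG C; NA when `cpg_at_center = FALSE`).
#' @export
generate_probe_windows <- function(n, length = 120, cpg_at_center = TRUE,
                                   seed = 1) {
  stopifnot(n >= 1, length >= 2)
  offset <- floor(length / 2) - 1L  # 0-based; 59 for a 120-mer
  with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i) {
      b <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
      if (cpg_at_center) {
        b[offset + 1L] <- "C"
        b[offset + 2L] <- "G"
      }
      paste(b, collapse = "")
    }, character(1))
    data.frame(
      window_id = paste0("window", seq_len(n)),
      seq = seqs,
      cpg_offset = if (cpg_at_center) offset else NA_integer_,
      stringsAsFactors = FALSE
    )
  })
}
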