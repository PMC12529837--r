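# Tissue-informative marker (TIM) selection and bisulfite capture probe
# design. A TIM is a CpG whose methylation in one tissue diverges maximally
# from the mean methylation of all other tissues; the panel is then filtered
# for cfDNA coverage, common SNPs, repeats and 500 bp spacing, and each
# surviving TIM gets a methylated/unmethylated capture probe pair.

#' Average reference methylation per tissue
#'
#' Per tissue and CpG, the unweighted mean of per-replicate methylation
#' proportions (methylated/total). Replicates with zero depth at a site are
#' excluded from that site's mean; a site with zero depth in all replicates is
#' missing (NA).
#'
#' @param replicate_counts Named list, tissue -> [methylome_counts()] whose
#'   columns are WGBS replicates.
#' @return Numeric matrix, tissues x sites, of mean methylation proportions,
#'   with the site coordinates attached as attribute `sites`.
#' @export
estimate_reference_methylation <- function(replicate_counts) {
  stopifnot(is.list(replicate_counts), length(replicate_counts) >= 1)
  if (is.null(names(replicate_counts)) || any(names(replicate_counts) == "")) {
    stop("replicate_counts must be a named list (tissue -> MethylomeCounts)")
  }
  sites <- replicate_counts[[1]]$sites
  beta <- t(vapply(replicate_counts, function(mc) {
    stopifnot(inherits(mc, "MethylomeCounts"))
    if (ncol(mc$meth) < 1) stop("tissue with no replicates")
    if (!identical(mc$sites$pos, sites$pos)) {
      stop("replicate count sets must share one site list")
    }
    prop <- mc$meth / mc$total          # 0/0 -> NaN at zero-depth replicates
    m <- rowMeans(prop, na.rm = TRUE)   # NaN rows: all replicates zero-depth
    m[is.nan(m)] <- NA_real_
    m
  }, numeric(nrow(sites))))
  rownames(beta) <- names(replicate_counts)
  attr(beta, "sites") <- sites
  beta
}

#' Score every (site, tissue) pair for tissue informativeness
#'
#' For each CpG and each tissue in turn, the score is the absolute distance
#' between that tissue's methylation proportion and the mean methylation of
#' all other tissues. Direction is "hyper" when the tissue exceeds the
#' others' mean, "hypo" when below, and "none" on exact equality (zero
#' information; never selectable). Missing reference entries propagate as
#' missing scores; the others' mean uses the non-missing other tissues.
#'
#' @param beta_hat Tissues x sites matrix from
#'   [estimate_reference_methylation()] (>= 2 tissues).
#' @param sites Optional site coordinate data.frame (`chrom`, `pos`); taken
#'   from `attr(beta_hat, "sites")` when present.
#' @return A long data.frame (`site`, `chrom`, `pos`, `tissue`, `tissue_beta`,
#'   `others_mean`, `score`, `direction`), the TIM score table.
#' @export
compute_tim_scores <- function(beta_hat, sites = attr(beta_hat, "sites")) {
  stopifnot(is.matrix(beta_hat))
  k <- nrow(beta_hat)
  if (k < 2) stop("at least two tissues are required to score TIMs")
  n <- ncol(beta_hat)
  tissues <- rownames(beta_hat) %||% paste0("tissue", seq_len(k))

  obs <- !is.na(beta_hat)
  col_sum <- colSums(ifelse(obs, beta_hat, 0))
  col_n <- colSums(obs)

  out <- vector("list", k)
  for (t in seq_len(k)) {
    bt <- beta_hat[t, ]
    n_others <- col_n - obs[t, ]
    others_mean <- (col_sum - ifelse(obs[t, ], bt, 0)) / n_others
    others_mean[n_others == 0] <- NA_real_
    score <- abs(bt - others_mean)
    direction <- rep(NA_character_, n)
    ok <- !is.na(score)
    direction[ok] <- ifelse(bt[ok] > others_mean[ok], "hyper",
                            ifelse(bt[ok] < others_mean[ok], "hypo", "none"))
    out[[t]] <- data.frame(
      site = seq_len(n),
      chrom = if (!is.null(sites)) sites$chrom else NA_character_,
      pos = if (!is.null(sites)) sites$pos else NA_integer_,
      tissue = tissues[t],
      tissue_beta = bt,
      others_mean = others_mean,
      score = score,
      direction = direction,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# 0-based half-open mask data.frame (or GRanges) -> GRanges
as_mask_granges <- function(mask) {
  if (inherits(mask, "GRanges")) return(mask)
  stopifnot(is.data.frame(mask), all(c("chrom", "start", "end") %in% names(mask)))
  GenomicRanges::GRanges(
    mask$chrom,
    IRanges::IRanges(start = mask$start + 1L, end = mask$end)
  )
}

sites_in_mask <- function(chrom, pos, mask) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start = pos + 1L, width = 1L))
  IRanges::overlapsAny(gr, as_mask_granges(mask))
}

#' Select the TIM panel from a score table
#'
#' Applies the selection pipeline in a fixed order: (1) per tissue, rank by
#' score descending (ties broken by lower position then chromosome) and keep
#' the top `n_per_tissue` candidates; (2) remove any CpG claimed by two or
#' more tissues from all lists; (3) drop candidates whose mean cfDNA coverage
#' is below `min_depth` in any supplied coverage table; (4) drop candidates
#' overlapping the common-SNP or repeat masks; (5) sort by (chrom, pos) and,
#' within each run of sites closer than `spacing_bp`, keep only the first
#' (lowest-coordinate) site so no two probes target the same region.
#'
#' @param scores Score table from [compute_tim_scores()] (needs `chrom`/`pos`).
#' @param n_per_tissue Candidate pool per tissue before QC (the design default
#'   is 300 potential sites per tissue).
#' @param spacing_bp Minimum spacing between panel sites (bp).
#' @param coverage Optional list of per-site mean-depth vectors (aligned with
#'   the score table's site index), e.g. from cfDNA WGBS datasets.
#' @param min_depth Minimum mean depth required in every coverage table.
#' @param snp_mask,repeat_mask Optional interval masks (data.frame
#'   `chrom`/`start`/`end`, 0-based half-open, or GRanges).
#' @param window_halfwidth Half-width of the probe window recorded per TIM.
#' @return data.frame of TIM records: `chrom`, `pos`, `tissue`, `direction`,
#'   `score`, `window_start`, `window_end`.
#' @export
select_tims <- function(scores, n_per_tissue = 300, spacing_bp = 500,
                        coverage = NULL, min_depth = 10,
                        snp_mask = NULL, repeat_mask = NULL,
                        window_halfwidth = 60) {
  stopifnot(is.data.frame(scores),
            all(c("site", "chrom", "pos", "tissue", "score", "direction") %in%
                  names(scores)))
  if (!is.null(coverage) && !is.list(coverage)) coverage <- list(coverage)

  # (1) per-tissue top-N by score; equal-beta ("none") and missing scores are
  # never selectable
  cand <- scores[!is.na(scores$score) & scores$direction %in% c("hyper", "hypo"), ]
  cand <- do.call(rbind, lapply(split(cand, cand$tissue), function(d) {
    d <- d[order(-d$score, d$pos, d$chrom), ]
    utils::head(d, n_per_tissue)
  }))
  if (is.null(cand)) cand <- scores[0, ]

  # (2) a CpG claimed as a TIM by two or more tissues is removed from all lists
  dup_sites <- unique(cand$site[duplicated(cand$site)])
  cand <- cand[!(cand$site %in% dup_sites), ]

  # (3) cfDNA coverage screen: mean depth >= min_depth in every table
  if (!is.null(coverage)) {
    for (cv in coverage) {
      stopifnot(length(cv) >= max(cand$site))
      cand <- cand[cv[cand$site] >= min_depth, ]
    }
  }

  # (4) common-SNP and repeat masks
  if (nrow(cand) > 0 && !is.null(snp_mask)) {
    cand <- cand[!sites_in_mask(cand$chrom, cand$pos, snp_mask), ]
  }
  if (nrow(cand) > 0 && !is.null(repeat_mask)) {
    cand <- cand[!sites_in_mask(cand$chrom, cand$pos, repeat_mask), ]
  }

  # (5) 500 bp spacing: within each maximal run of sites whose successive gaps
  # are < spacing_bp, keep only the first site
  cand <- cand[order(cand$chrom, cand$pos), ]
  if (nrow(cand) > 1) {
    keep <- logical(nrow(cand))
    for (grp in split(seq_len(nrow(cand)), cand$chrom)) {
      gaps <- diff(cand$pos[grp])
      keep[grp] <- c(TRUE, gaps >= spacing_bp)
    }
    cand <- cand[keep, ]
  }

  missing_tissues <- setdiff(unique(scores$tissue), unique(cand$tissue))
  if (length(missing_tissues) > 0) {
    warning("no TIMs survived QC for tissue(s): ",
            paste(missing_tissues, collapse = ", "))
  }

  out <- data.frame(
    chrom = cand$chrom,
    pos = cand$pos,
    tissue = cand$tissue,
    direction = cand$direction,
    score = cand$score,
    window_start = pmax(0L, cand$pos - as.integer(window_halfwidth)),
    window_end = cand$pos + as.integer(window_halfwidth),
    site = cand$site,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Design the methylated/unmethylated capture probe pair for a TIM window
#'
#' Bisulfite treatment converts unmethylated cytosine to uracil (read as
#' thymine); on the forward strand this means every C outside a methylated CpG
#' is read as T, so a probe binding the converted strand sees G -> A changes on
#' its own sequence. The unmethylated probe therefore converts every guanine
#' to adenine; the methylated probe converts only guanines not immediately
#' preceded by a cytosine (i.e. not the G of a CG dinucleotide, whose C is
#' protected when methylated). A G at the first position has no preceding base
#' and is treated as non-CpG.
#'
#' @param window_seq Genomic window sequence over A/C/G/T (forward strand).
#' @param cpg_offset 0-based offset of the target CpG's C within the window;
#'   `substr(window_seq, cpg_offset + 1, cpg_offset + 2)` must be "CG".
#' @return list with `methylated_probe` and `unmethylated_probe`, both the
#'   same length as the input window.
#' @export
design_probes <- function(window_seq, cpg_offset) {
  stopifnot(is.character(window_seq), length(window_seq) == 1L)
  window_seq <- toupper(window_seq)
  if (grepl("[^ACGT]", window_seq)) {
    stop("window sequence contains non-ACGT characters")
  }
  stopifnot(is.numeric(cpg_offset), cpg_offset >= 0,
            cpg_offset + 2 <= nchar(window_seq))
  if (substr(window_seq, cpg_offset + 1, cpg_offset + 2) != "CG") {
    stop(sprintf("no CG dinucleotide at 0-based offset %d", cpg_offset))
  }
  list(
    methylated_probe = gsub("(?<!C)G", "A", window_seq, perl = TRUE),
    unmethylated_probe = gsub("G", "A", window_seq, fixed = TRUE)
  )
}

#' Design probes for every TIM in a panel
#'
#' @param tims TIM records from [select_tims()].
#' @param windows data.frame with one row per TIM (same order): `seq` and
#'   `cpg_offset`, e.g. from [generate_probe_windows()] or extracted from a
#'   genome FASTA.
#' @return `tims` with `methylated_probe` and `unmethylated_probe` columns.
#' @export
design_probe_set <- function(tims, windows) {
  stopifnot(nrow(tims) == nrow(windows),
            all(c("seq", "cpg_offset") %in% names(windows)))
  pairs <- lapply(seq_len(nrow(windows)), function(i) {
    design_probes(windows$seq[i], windows$cpg_offset[i])
  })
  tims$methylated_probe <- vapply(pairs, `[[`, character(1), "methylated_probe")
  tims$unmethylated_probe <- vapply(pairs, `[[`, character(1), "unmethylated_probe")
  tims
}
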