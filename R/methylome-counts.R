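#' Methylation count container
#'
#' Holds paired methylated/total read-count matrices over a common set of CpG
#' sites, for either cfDNA samples (columns = samples) or reference tissue
#' replicates (columns = replicates). Coordinates are 0-based, forward strand
#' (bedGraph convention). A site with `total = 0` carries no information and is
#' treated as missing downstream.
#'
#' @param sites data.frame with columns `chrom` and `pos` (0-based CpG C
#'   position).
#' @param meth Integer matrix, sites x samples, methylated read counts.
#' @param total Integer matrix, sites x samples, total read counts.
#' @param sample_names Optional column names.
#' @return A `MethylomeCounts` object (list with `sites`, `meth`, `total`).
#' @export
methylome_counts <- function(sites, meth, total, sample_names = colnames(total)) {
  meth <- as.matrix(meth)
  total <- as.matrix(total)
  stopifnot(
    is.data.frame(sites),
    all(c("chrom", "pos") %in% names(sites)),
    nrow(meth) == nrow(sites),
    all(dim(meth) == dim(total))
  )
  if (any(meth < 0) || any(total < 0) || any(meth > total)) {
    stop("count matrices must satisfy 0 <= methylated <= total elementwise")
  }
  if (!is.null(sample_names)) {
    colnames(meth) <- colnames(total) <- sample_names
  }
  structure(
    list(sites = sites[, c("chrom", "pos")], meth = meth, total = total),
    class = "MethylomeCounts"
  )
}

#' @export
print.MethylomeCounts <- function(x, ...) {
  cat(sprintf(
    "MethylomeCounts: %d sites x %d samples (%.1f%% zero-depth entries)\n",
    nrow(x$meth), ncol(x$meth), 100 * mean(x$total == 0)
  ))
  invisible(x)
}

#' @export
dim.MethylomeCounts <- function(x) dim(x$meth)

# Subset sites (i) and/or samples (j); used by QC filtering and region work.
#' @export
`[.MethylomeCounts` <- function(x, i, j) {
  if (missing(i)) i <- seq_len(nrow(x$meth))
  if (missing(j)) j <- seq_len(ncol(x$meth))
  methylome_counts(
    x$sites[i, , drop = FALSE],
    x$meth[i, j, drop = FALSE],
    x$total[i, j, drop = FALSE]
  )
}

#' Region-level count container
#'
#' Like [methylome_counts()] but rows are TIM-centred regions rather than
#' single CpGs; produced by [aggregate_regions()].
#'
#' @param regions data.frame with `chrom`, `target_pos`, `start`, `end`.
#' @param meth,total Count matrices, regions x samples (or tissues).
#' @return A `RegionCounts` object.
#' @export
region_counts <- function(regions, meth, total) {
  meth <- as.matrix(meth)
  total <- as.matrix(total)
  stopifnot(
    is.data.frame(regions),
    all(c("chrom", "target_pos") %in% names(regions)),
    nrow(meth) == nrow(regions),
    all(dim(meth) == dim(total))
  )
  if (any(meth < 0) || any(meth > total)) {
    stop("count matrices must satisfy 0 <= methylated <= total elementwise")
  }
  structure(
    list(regions = regions, meth = meth, total = total),
    class = "RegionCounts"
  )
}

#' @export
print.RegionCounts <- function(x, ...) {
  cat(sprintf(
    "RegionCounts: %d regions x %d columns\n", nrow(x$meth), ncol(x$meth)
  ))
  invisible(x)
}
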