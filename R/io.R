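# Plain-text readers/writers for the formats the pipeline exchanges:
# Bismark-coverage/bedGraph methylation counts, BED interval masks, BED6 TIM
# panels and FASTA probe sequences.

#' Write per-sample Bismark-coverage style count files
#'
#' One file per sample with columns chrom, start (0-based), end, methylation
#' percentage, methylated count, unmethylated count. Zero-depth sites are
#' written with percentage 0.
#'
#' @param counts A [methylome_counts()] object.
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix; files are `<prefix><sample>.cov`.
#' @return Invisibly, the written file paths.
#' @export
write_bismark_cov <- function(counts, dir, prefix = "") {
  stopifnot(inherits(counts, "MethylomeCounts"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  samples <- colnames(counts$meth) %||% paste0("sample", seq_len(ncol(counts$meth)))
  paths <- character(length(samples))
  for (j in seq_along(samples)) {
    m <- counts$meth[, j]
    t <- counts$total[, j]
    pct <- ifelse(t > 0, 100 * m / t, 0)
    df <- data.frame(
      chrom = counts$sites$chrom,
      start = counts$sites$pos,
      end = counts$sites$pos + 1L,
      pct = round(pct, 6),
      meth = m,
      unmeth = t - m
    )
    paths[j] <- file.path(dir, paste0(prefix, samples[j], ".cov"))
    utils::write.table(df, paths[j], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(paths)
}

#' Read Bismark-coverage style count files into a MethylomeCounts object
#'
#' Files are aligned on the union of their (chrom, pos) sites; sites absent
#' from a file get total count 0 (missing).
#'
#' @param files Character vector of file paths.
#' @param sample_names Sample names; default file basenames without extension.
#' @return A [methylome_counts()] object.
#' @export
read_bismark_cov <- function(files, sample_names = NULL) {
  stopifnot(length(files) >= 1)
  if (is.null(sample_names)) {
    sample_names <- sub("\\.[^.]*$", "", basename(files))
  }
  tabs <- lapply(files, function(f) {
    df <- utils::read.table(f, sep = "\t", header = FALSE,
                            col.names = c("chrom", "start", "end", "pct",
                                          "meth", "unmeth"),
                            colClasses = c("character", "integer", "integer",
                                           "numeric", "integer", "integer"))
    df
  })
  key <- unique(do.call(rbind, lapply(tabs, function(d) d[, c("chrom", "start")])))
  key <- key[order(key$chrom, key$start), ]
  ids <- paste0(key$chrom, ":", key$start)
  n <- nrow(key)
  meth <- matrix(0L, n, length(files))
  total <- matrix(0L, n, length(files))
  for (j in seq_along(tabs)) {
    idx <- match(paste0(tabs[[j]]$chrom, ":", tabs[[j]]$start), ids)
    meth[idx, j] <- tabs[[j]]$meth
    total[idx, j] <- tabs[[j]]$meth + tabs[[j]]$unmeth
  }
  methylome_counts(
    data.frame(chrom = key$chrom, pos = key$start),
    meth, total, sample_names = sample_names
  )
}

#' Read a BED interval mask
#'
#' Reads the first three columns of a BED file as 0-based half-open intervals,
#' the convention used for the SNP and repeat masks in TIM selection.
#'
#' @param file Path to a BED file.
#' @return data.frame with `chrom`, `start`, `end`.
#' @export
read_bed <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = FALSE)[, 1:3]
  names(df) <- c("chrom", "start", "end")
  df$chrom <- as.character(df$chrom)
  df
}

#' Write a TIM panel as BED6
#'
#' The name field encodes `tissue|direction|score`; the BED score column is the
#' selection score scaled to 0-1000.
#'
#' @param tims A TIM record data.frame from [select_tims()].
#' @param file Output path.
#' @export
write_tim_bed <- function(tims, file) {
  df <- data.frame(
    chrom = tims$chrom,
    start = tims$pos,
    end = tims$pos + 1L,
    name = sprintf("%s|%s|%.6g", tims$tissue, tims$direction, tims$score),
    score = as.integer(round(pmin(1, tims$score) * 1000)),
    strand = "."
  )
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Write capture probe pairs as FASTA
#'
#' Headers follow `{chrom}:{pos}|{tissue}|{meth|unmeth}`.
#'
#' @param probes data.frame with columns `chrom`, `pos`, `tissue`,
#'   `methylated_probe`, `unmethylated_probe` (see [design_probes()]).
#' @param file Output FASTA path.
#' @export
write_probe_fasta <- function(probes, file) {
  seqs <- c(probes$methylated_probe, probes$unmethylated_probe)
  hdr <- c(
    sprintf("%s:%d|%s|meth", probes$chrom, probes$pos, probes$tissue),
    sprintf("%s:%d|%s|unmeth", probes$chrom, probes$pos, probes$tissue)
  )
  ord <- order(rep(seq_len(nrow(probes)), 2L))
  x <- Biostrings::DNAStringSet(seqs[ord])
  names(x) <- hdr[ord]
  Biostrings::writeXStringSet(x, file)
  invisible(file)
}
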