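test_that("reference methylation averages per-replicate proportions", {
  one <- list(liver = toy_counts(matrix(3), matrix(10)))
  expect_equal(unname(estimate_reference_methylation(one)[1, 1]), 0.3)

  two <- list(liver = toy_counts(cbind(4, 6), cbind(10, 10)))
  expect_equal(unname(estimate_reference_methylation(two)[1, 1]), 0.5)

  # zero-depth replicate excluded from the mean
  zd <- list(liver = toy_counts(cbind(5, 0), cbind(10, 0)))
  expect_equal(unname(estimate_reference_methylation(zd)[1, 1]), 0.5)

  # all replicates zero-depth -> missing
  allz <- list(liver = toy_counts(cbind(0, 0), cbind(0, 0)))
  expect_true(is.na(estimate_reference_methylation(allz)[1, 1]))

  expect_error(estimate_reference_methylation(list(toy_counts(matrix(1), matrix(2)))),
               "named")
})

test_that("TIM scores are the distance to the other-tissue mean", {
  b <- rbind(A = c(0.5, 0.9, 0.0), B = c(0.5, 0.1, 0.9), C = c(0.5, 0.2, 0.7))
  sc <- compute_tim_scores(b)

  tied <- sc[sc$site == 1, ]
  expect_equal(tied$score, rep(0, 3))
  expect_equal(tied$direction, rep("none", 3))

  a2 <- sc[sc$site == 2 & sc$tissue == "A", ]
  expect_equal(a2$score, 0.75)  # 0.9 - mean(0.1, 0.2)
  expect_equal(a2$direction, "hyper")

  a3 <- sc[sc$site == 3 & sc$tissue == "A", ]
  expect_equal(a3$score, 0.8)   # |0 - mean(0.9, 0.7)|
  expect_equal(a3$direction, "hypo")

  expect_error(compute_tim_scores(b[1, , drop = FALSE]), "two tissues")

  # permutation-equivariant in tissue order, invariant to site order
  perm <- compute_tim_scores(b[c(3, 1, 2), ])
  for (t in rownames(b)) {
    expect_equal(perm$score[perm$tissue == t], sc$score[sc$tissue == t])
  }
  sperm <- compute_tim_scores(b[, c(2, 3, 1)])
  expect_equal(sort(sperm$score), sort(sc$score))

  # missing reference entries propagate as missing scores
  bna <- b
  bna["A", 2] <- NA
  scna <- compute_tim_scores(bna)
  expect_true(is.na(scna$score[scna$site == 2 & scna$tissue == "A"]))
  expect_false(anyNA(scna$score[scna$site == 2 & scna$tissue != "A"]))
})

test_that("panel selection recovers planted TIMs and matches a rank oracle", {
  panel <- generate_reference_panel(3, 30, 10, margin = 0.8, replicates = 2,
                                    depth_model = 1e4, seed = 5)
  beta_hat <- estimate_reference_methylation(panel$counts)
  sc <- compute_tim_scores(beta_hat)
  tims <- select_tims(sc, n_per_tissue = 10)

  # exhaustive oracle: per tissue, brute-force rank the 30 sites by the
  # recomputed distance and take the top 10
  oracle <- do.call(rbind, lapply(seq_len(3), function(t) {
    gap <- vapply(seq_len(30), function(s) {
      abs(beta_hat[t, s] - mean(beta_hat[-t, s]))
    }, numeric(1))
    data.frame(tissue = rownames(beta_hat)[t],
               site = order(gap, decreasing = TRUE)[1:10])
  }))
  expect_setequal(paste(tims$tissue, tims$site),
                  paste(oracle$tissue, oracle$site))
  # ... which is exactly the planted set at this margin and depth
  expect_setequal(paste(tims$tissue, tims$site),
                  paste(panel$truth$planted_tims$tissue,
                        panel$truth$planted_tims$site))

  # stored scores reproduce exactly from beta_hat
  for (i in seq_len(nrow(tims))) {
    t <- match(tims$tissue[i], rownames(beta_hat))
    expect_equal(unname(tims$score[i]),
                 unname(abs(beta_hat[t, tims$site[i]] -
                              mean(beta_hat[-t, tims$site[i]]))))
  }
})

test_that("selection QC rules: conflicts, coverage, masks, spacing", {
  mk <- function(site, pos, tissue, score, direction = "hyper") {
    data.frame(site = site, chrom = "chr1", pos = pos, tissue = tissue,
               tissue_beta = NA_real_, others_mean = NA_real_,
               score = score, direction = direction, stringsAsFactors = FALSE)
  }

  # a CpG top-ranked for two tissues disappears from the panel entirely
  sc <- rbind(
    mk(1, 100, "A", 0.9), mk(2, 5000, "A", 0.5),
    mk(1, 100, "B", 0.8), mk(3, 9000, "B", 0.4)
  )
  out <- suppressWarnings(select_tims(sc, n_per_tissue = 2))
  expect_false(1 %in% out$site)
  expect_setequal(out$site, c(2, 3))

  # spacing: survivors at 100 and 550 (450 apart) keep only the first
  sc2 <- rbind(mk(1, 100, "A", 0.9), mk(2, 550, "A", 0.8))
  out2 <- select_tims(sc2, n_per_tissue = 2)
  expect_equal(out2$pos, 100)

  # chain runs: 100, 550, 1000 all mutually chained (gaps 450) -> first only
  sc3 <- rbind(mk(1, 100, "A", 0.9), mk(2, 550, "A", 0.8), mk(3, 1000, "A", 0.7))
  expect_equal(select_tims(sc3, n_per_tissue = 3)$pos, 100)

  # coverage: a site under 10X mean depth in any cfDNA table is dropped
  sc4 <- rbind(mk(1, 100, "A", 0.9), mk(2, 5000, "A", 0.8))
  cov1 <- c(50, 9)
  cov2 <- c(50, 50)
  out4 <- select_tims(sc4, n_per_tissue = 2, coverage = list(cov1, cov2))
  expect_equal(out4$site, 1)

  # masks are 0-based half-open; pos 100 inside [90, 101), pos 5000 outside
  snp <- data.frame(chrom = "chr1", start = 90L, end = 101L)
  out5 <- select_tims(sc4, n_per_tissue = 2, snp_mask = snp)
  expect_equal(out5$site, 2)

  # equal-beta direction "none" is never selected
  sc6 <- mk(1, 100, "A", 0, direction = "none")
  expect_warning(out6 <- select_tims(sc6, n_per_tissue = 1), "no TIMs")
  expect_equal(nrow(out6), 0)
})

test_that("probe conversion follows the bisulfite G->A rules", {
  p1 <- design_probes("ACGT", 1)
  expect_equal(p1$methylated_probe, "ACGT")
  expect_equal(p1$unmethylated_probe, "ACAT")

  p2 <- design_probes("GCGG", 1)
  expect_equal(p2$methylated_probe, "ACGA")
  expect_equal(p2$unmethylated_probe, "ACAA")

  # no G anywhere: both probes equal the input
  p3 <- design_probes("ATCGTTAC", 2)
  expect_equal(p3$unmethylated_probe, gsub("G", "A", "ATCGTTAC"))
  noG <- design_probes("TTCGTT", 2)  # only the CpG G
  expect_equal(noG$methylated_probe, "TTCGTT")

  expect_error(design_probes("ACNT", 1), "non-ACGT")
  expect_error(design_probes("ACTT", 1), "no CG")

  # unmethylated probes carry no G, so unmeth conversion is idempotent;
  # re-converting the methylated probe loses exactly the CG guanines
  w <- generate_probe_windows(5, 60, seed = 6)
  for (i in seq_len(5)) {
    pp <- design_probes(w$seq[i], w$cpg_offset[i])
    expect_false(grepl("G", pp$unmethylated_probe))
    expect_equal(gsub("G", "A", pp$methylated_probe), pp$unmethylated_probe)
    expect_equal(nchar(pp$methylated_probe), nchar(w$seq[i]))
  }
})
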