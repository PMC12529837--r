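test_that("region aggregation sums CpGs within the inclusive flank", {
  # CpGs at target, target+100, target+250, target+251
  counts <- toy_counts(matrix(c(3, 2, 1, 9)), matrix(c(10, 5, 5, 9)),
                       pos = c(1000L, 1100L, 1250L, 1251L))
  targets <- data.frame(chrom = "chr1", pos = 1000L)
  reg <- aggregate_regions(counts, targets, flank_bp = 250)
  expect_equal(as.integer(reg$meth), 6L)   # 3 + 2 + 1; +251 excluded
  expect_equal(as.integer(reg$total), 20L)

  # single CpG exactly at the target
  one <- toy_counts(matrix(7), matrix(11), pos = 500L)
  reg1 <- aggregate_regions(one, data.frame(chrom = "chr1", pos = 500L))
  expect_equal(as.integer(reg1$meth), 7L)
  expect_equal(as.integer(reg1$total), 11L)

  # target with no covered CpG -> zero totals
  reg0 <- aggregate_regions(one, data.frame(chrom = "chr1", pos = 99000L))
  expect_equal(as.integer(reg0$total), 0L)

  expect_error(
    aggregate_regions(one, data.frame(chrom = "chr1", pos = c(500L, 500L))),
    "duplicate"
  )
})

test_that("joint log-likelihood matches the closed form", {
  # zero-depth data contributes exactly nothing
  z <- region_counts(data.frame(chrom = "chr1", target_pos = 0L),
                     matrix(0), matrix(0))
  expect_equal(em_log_likelihood(matrix(1), matrix(0.5, 1, 1), z), 0)

  # one sample, one region, alpha = [1], beta = 0.5, counts 1/2:
  # log C(2,1) + 2 log(0.5)
  s <- region_counts(data.frame(chrom = "chr1", target_pos = 0L),
                     matrix(1), matrix(2))
  expect_equal(em_log_likelihood(matrix(1), matrix(0.5, 1, 1), s),
               log(2) + 2 * log(0.5))

  expect_error(em_log_likelihood(matrix(1), matrix(1.5, 1, 1), s), "beta")
})

test_that("EM with a single known tissue returns alpha = 1", {
  s <- region_counts(data.frame(chrom = "chr1", target_pos = c(0L, 1000L)),
                     cbind(c(3L, 9L)), cbind(c(10L, 12L)))
  r <- region_counts(s$regions, cbind(liver = c(5L, 50L)),
                     cbind(liver = c(20L, 60L)))
  fit <- celfie_em(s, r, n_unknown = 0, n_restarts = 2, seed = 1)
  expect_equal(unname(fit$alpha[, 1]), 1, tolerance = 1e-12)
})

test_that("EM recovers a two-tissue orthogonal mixture against a grid oracle", {
  set.seed(42)
  n_reg <- 20
  beta1 <- rep(c(1, 0), length.out = n_reg)
  beta2 <- 1 - beta1
  depth <- 1000L
  regions <- data.frame(chrom = "chr1",
                        target_pos = as.integer(seq_len(n_reg) * 1000L))
  truth_p <- 0.7 * beta1 + 0.3 * beta2
  x <- rbinom(n_reg, depth, truth_p)
  s <- region_counts(regions, cbind(S1 = x), cbind(S1 = rep(depth, n_reg)))
  r <- region_counts(regions,
                     cbind(T1 = as.integer(beta1 * depth),
                           T2 = as.integer(beta2 * depth)),
                     cbind(T1 = rep(depth, n_reg), T2 = rep(depth, n_reg)))

  fit <- celfie_em(s, r, n_unknown = 0, n_restarts = 10, seed = 2)
  oracle <- grid_alpha_oracle(x, rep(depth, n_reg), beta1, beta2)
  expect_lt(abs(fit$alpha[1, "T1"] - oracle), 0.02)
  expect_lt(abs(fit$alpha[1, "T1"] - 0.7), 0.02)
})

test_that("log-likelihood trace is non-decreasing on every seeded run", {
  panel <- generate_reference_panel(4, 30, 5, margin = 0.6, depth_model = 200,
                                    seed = 6)
  coh <- generate_cfdna_cohort(panel$truth, 3, 3, depth_model = 200,
                               missing_rate = 0.05, seed = 7)
  reg_s <- single_site_regions(coh$counts, panel$truth$site_coords)
  reg_r <- single_site_regions(pool_reference(panel), panel$truth$site_coords)
  for (sd in 1:4) {
    fit <- celfie_em(reg_s, reg_r, n_unknown = 1, n_restarts = 3,
                     max_iter = 200, seed = sd)
    expect_true(all(diff(fit$loglik_trace) >= -1e-9))
    expect_equal(unname(rowSums(fit$alpha)), rep(1, nrow(fit$alpha)),
                 tolerance = 1e-8)
    # final likelihood at least matches every restart's end point
    expect_equal(max(fit$restart_logliks),
                 fit$loglik_trace[length(fit$loglik_trace)])
  }
})

test_that("alpha recovery: K = 5, 40 regions, depth 500, no unknowns", {
  panel <- generate_reference_panel(5, 40, 5, margin = 0.6, replicates = 2,
                                    depth_model = 250, seed = 21)
  coh <- generate_cfdna_cohort(panel$truth, 5, 5, case_muscle_shift = 0,
                               depth_model = 500, missing_rate = 0, seed = 22)
  reg_s <- single_site_regions(coh$counts, panel$truth$site_coords)
  reg_r <- single_site_regions(pool_reference(panel), panel$truth$site_coords)
  fit <- celfie_em(reg_s, reg_r, n_unknown = 0, n_restarts = 5, seed = 23)
  expect_lte(mean(abs(fit$alpha - coh$truth$alpha_true)), 0.02)
})

test_that("tissue-order equivariance and missing-region contract", {
  panel <- generate_reference_panel(3, 20, 4, margin = 0.6, depth_model = 300,
                                    seed = 31)
  coh <- generate_cfdna_cohort(panel$truth, 2, 2, depth_model = 300,
                               missing_rate = 0, seed = 32)
  reg_s <- single_site_regions(coh$counts, panel$truth$site_coords)
  ref <- pool_reference(panel)
  reg_r <- single_site_regions(ref, panel$truth$site_coords)

  # the random alpha initialization is symmetric, so permuting the reference
  # tissue order permutes the converged alpha columns (tight tol so both runs
  # reach the same fixed point)
  fit <- celfie_em(reg_s, reg_r, n_unknown = 0, n_restarts = 3, tol = 1e-8,
                   max_iter = 3000, seed = 5)
  perm <- c(3, 1, 2)
  reg_rp <- region_counts(reg_r$regions, reg_r$meth[, perm], reg_r$total[, perm])
  fitp <- celfie_em(reg_s, reg_rp, n_unknown = 0, n_restarts = 3, tol = 1e-8,
                    max_iter = 3000, seed = 5)
  expect_equal(unname(fitp$alpha), unname(fit$alpha[, perm]), tolerance = 1e-4)

  # a zero-depth region for every sample and tissue adds nothing
  ll <- em_log_likelihood(fit$alpha, fit$beta, reg_s, reg_r)
  reg_s2 <- region_counts(rbind(reg_s$regions,
                                data.frame(chrom = "chr9", target_pos = 1L,
                                           start = -249L, end = 251L)),
                          rbind(reg_s$meth, 0L), rbind(reg_s$total, 0L))
  beta2 <- cbind(fit$beta, 0.5)
  expect_equal(em_log_likelihood(fit$alpha, beta2, reg_s2),
               em_log_likelihood(fit$alpha, fit$beta, reg_s))
  expect_equal(ll, ll)
})

test_that("an unknown component recovers a held-out tissue's profile", {
  # heterogeneous per-sample proportions (low Dirichlet concentration) give
  # the between-sample variation that identifies the unknown profile
  panel <- generate_reference_panel(5, 50, 10, margin = 0.6, replicates = 2,
                                    depth_model = 500, seed = 31)
  ca <- c(0.35, 0.15, 0.1, 0.1, 0.3)
  names(ca) <- panel$truth$tissue_names
  coh <- generate_cfdna_cohort(panel$truth, 0, 20, control_alpha = ca,
                               case_muscle_shift = 0, depth_model = 1000,
                               missing_rate = 0, concentration = 5, seed = 32)
  reg_s <- single_site_regions(coh$counts, panel$truth$site_coords)
  reg_r <- single_site_regions(pool_reference(panel), panel$truth$site_coords)
  held <- region_counts(reg_r$regions, reg_r$meth[, 1:4], reg_r$total[, 1:4])

  fit <- celfie_em(reg_s, held, n_unknown = 1, n_restarts = 10, seed = 33)
  expect_gte(cor(fit$beta["unknown1", ], panel$truth$beta_true[5, ]), 0.9)
  # the estimated unknown share tracks the true held-out proportion sample by
  # sample (its absolute level is attenuated, since the re-estimated known
  # profiles absorb part of the unknown's mass)
  expect_gte(cor(fit$alpha[, "unknown1"], coh$truth$alpha_true[, 5]), 0.8)
})
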