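test_that("detection-P rule is strict: 10% failures kept, 20% dropped", {
  cohort <- make_cohort(6, 4, 6, 1)  # 10 samples
  betas <- make_beta_rows(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5), cohort)
  detp <- matrix(0, nrow(betas), ncol(betas), dimnames = dimnames(betas))
  detp[1, 1:2] <- 0.5   # 20% of samples failed -> dropped
  detp[2, 1] <- 0.5     # exactly 10% -> kept ("more than 10%")
  got <- filter_detection_p(betas, detp)
  expect_equal(got$dropped, rownames(betas)[1])
  expect_equal(rownames(got$betas), rownames(betas)[2:3])

  all_ok <- filter_detection_p(betas, detp * 0)
  expect_length(all_ok$dropped, 0L)
})

test_that("failure cutoff is inclusive: detP exactly 0.01 counts as failed", {
  cohort <- make_cohort(6, 4, 6, 1)
  betas <- make_beta_rows(0.5, 0.5, cohort)
  detp <- matrix(0, 1, 10, dimnames = dimnames(betas))
  detp[1, 1:2] <- 0.01
  expect_equal(filter_detection_p(betas, detp)$dropped, rownames(betas))
})

test_that("blocklist removal logs counts and tolerates absent ids", {
  cohort <- make_cohort(4, 4, 4, 1)
  betas <- make_beta_rows(c(0.3, 0.4, 0.5), c(0.3, 0.4, 0.5), cohort)
  got <- apply_blocklist(betas, rownames(betas)[2])
  expect_equal(nrow(got$betas), 2L)
  expect_identical(apply_blocklist(betas, character(0))$betas, betas)
  expect_warning(got2 <- apply_blocklist(betas, "cgNOPE"), "not present")
  expect_identical(got2$betas, betas)
})

test_that("region subset keeps inclusive boundaries, drops other chromosomes", {
  cohort <- make_cohort(4, 4, 4, 1)
  betas <- make_beta_rows(rep(0.5, 4), rep(0.5, 4), cohort)
  manifest <- rbind(
    make_probe(rownames(betas)[1], binding_pos = 26000000L),
    make_probe(rownames(betas)[2], binding_pos = 25999999L),
    make_probe(rownames(betas)[3], binding_pos = 35000000L),
    make_probe(rownames(betas)[4], chromosome = "7", binding_pos = 30000000L))
  got <- subset_region(betas, manifest, hla_regions("hla_extended"))
  expect_equal(rownames(got), rownames(betas)[c(1, 3)])
})

test_that("dmp_ttest reports case-minus-control differences and flags degeneracy", {
  cohort <- make_cohort(42, 42)
  betas <- make_beta_rows(c(0.8049, 0.5), c(0.7651, 0.5), cohort)
  got <- dmp_ttest(betas, cohort)
  expect_equal(got$difference[1], -0.0398, tolerance = 1e-12)
  expect_equal(got$mean_beta_control[1], 0.8049, tolerance = 1e-12)
  expect_equal(got$mean_beta_case[1], 0.7651, tolerance = 1e-12)
  expect_equal(got$difference,
               got$mean_beta_case - got$mean_beta_control,
               tolerance = 1e-12)

  # identical constant distributions: zero variance -> flagged, P missing
  const <- matrix(0.5, 1, 84, dimnames = list("cgZV", cohort$sample_id))
  zv <- dmp_ttest(const, cohort)
  expect_equal(zv$flag, "zero_variance")
  expect_true(is.na(zv$p_ttest))
  expect_equal(zv$difference, 0)
})

test_that("dmp_ttest matches stats::t.test for Student and Welch", {
  set.seed(5)
  cohort <- make_cohort(10, 12, 10, 2)
  betas <- matrix(runif(3 * 22, 0.2, 0.8), 3,
                  dimnames = list(paste0("p", 1:3), cohort$sample_id))
  betas[2, 4] <- NA  # exercise pairwise missing handling
  for (ve in c(TRUE, FALSE)) {
    got <- dmp_ttest(betas, cohort, var_equal = ve)
    for (i in 1:3) {
      ref <- t.test(betas[i, cohort$group == "case"],
                    betas[i, cohort$group == "control"], var.equal = ve)
      expect_equal(got$p_ttest[i], ref$p.value, tolerance = 1e-12)
      expect_equal(got$t_stat[i], unname(ref$statistic), tolerance = 1e-12)
    }
  }
})

test_that("a group with <2 non-missing values is flagged untestable", {
  cohort <- make_cohort(4, 4, 4, 1)
  betas <- make_beta_rows(0.4, 0.6, cohort)
  betas[1, cohort$group == "case"][1:3] <- NA
  got <- dmp_ttest(betas, cohort)
  expect_equal(got$flag, "untestable")
  expect_true(is.na(got$p_ttest))
})

test_that("regression equals the t-test difference when the covariate is orthogonal", {
  # noiseless fixture, covariate constant-free and orthogonal to group
  cohort <- make_cohort(4, 4, 2, 2)
  betas <- make_beta_rows(0.5, 0.55, cohort)
  got <- dmp_regression(betas, cohort)
  tt <- dmp_ttest(betas, cohort)
  expect_lt(abs(got$coef_regression - tt$difference[1]), 1e-10)
})

test_that("regression agrees with lm() per probe", {
  set.seed(17)
  cohort <- make_cohort(12, 12, 12, 3)
  betas <- matrix(runif(2 * 24, 0.2, 0.8), 2,
                  dimnames = list(c("pA", "pB"), cohort$sample_id))
  betas[2, 5] <- NA
  got <- dmp_regression(betas, cohort)
  for (i in 1:2) {
    d <- data.frame(y = betas[i, ], case = cohort$group == "case",
                    carr = cohort$dqb1_0602_carrier)
    ref <- summary(lm(y ~ case + carr, d))$coefficients
    expect_equal(got$coef_regression[i], ref["caseTRUE", 1], tolerance = 1e-10)
    expect_equal(got$p_regression[i], ref["caseTRUE", 4], tolerance = 1e-10)
    expect_equal(got$p_covariate[i], ref["carrTRUE", 4], tolerance = 1e-10)
  }
})

test_that("collinear designs are flagged inestimable, not fatal", {
  cohort <- make_cohort(4, 4, 4, 4)  # carrier == everyone
  betas <- make_beta_rows(0.5, 0.5, cohort)
  got <- dmp_regression(betas, cohort)
  expect_equal(got$flag, "inestimable")
  expect_true(is.na(got$p_regression))
})

test_that("bonferroni computes the threshold and compares strictly", {
  bf <- bonferroni(c(0.004, 0.005, 0.006), alpha_family = 0.05, n_tests = 10)
  expect_equal(bf$threshold, 0.005)
  expect_equal(bf$significant, c(TRUE, FALSE, FALSE))  # exact threshold: not significant
  expect_equal(bonferroni(0.04, n_tests = 1)$threshold, 0.05)
  expect_error(bonferroni(0.5, n_tests = 0), class = "hlameth_config_error")
})

test_that("compare_cell_types counts overlap and methylation direction", {
  mk <- function(ids, p, d) data.frame(probe_id = ids, p_ttest = p, difference = d)
  a <- mk(paste0("cg", 1:6), c(0.01, 0.02, 0.03, 0.04, 0.049, 0.9),
          c(-1, -1, -1, 1, -1, 1) * 0.05)
  b <- mk(paste0("cg", 1:6), c(0.01, 0.02, 0.03, 0.5, 0.6, 0.04),
          rep(-0.05, 6))
  got <- compare_cell_types(a, b)
  expect_equal(got$n_significant_a, 5L)
  expect_equal(got$n_significant_b, 4L)
  expect_equal(got$n_common, 3L)
  expect_equal(got$hypo_fraction_a, 4 / 5)
  expect_equal(got$hyper_fraction_b, 0)

  disjoint <- compare_cell_types(mk("cg1", 0.01, -1), mk("cg2", 0.01, -1))
  expect_equal(disjoint$n_common, 0L)
  same <- compare_cell_types(a, a)
  expect_equal(same$n_common, same$n_significant_a)
})

test_that("run_dmp applies stages in order with non-increasing counts", {
  spec <- simulation_spec(n_probes = 150L, seed = 3L,
                          detection_fail_rate = 0.02)
  sim <- simulate_study(spec)
  res <- run_dmp(sim$betas, sim$detp, sim$manifest, sim$cohort,
                 hla_regions("hla_extended"),
                 blocklist = sim$manifest$probe_id[1:5])
  cn <- res$counts
  expect_lte(cn[["in_region"]],
             cn[["probes_in"]] - cn[["dropped_detection_p"]] - cn[["dropped_blocklist"]])
  expect_lte(cn[["tested"]], cn[["in_region"]])
  expect_equal(res$alpha_threshold, 0.05 / cn[["tested"]])
  # re-running with the same inputs is bit-identical
  res2 <- run_dmp(sim$betas, sim$detp, sim$manifest, sim$cohort,
                  hla_regions("hla_extended"),
                  blocklist = sim$manifest$probe_id[1:5])
  expect_identical(res$results, res2$results)
})

test_that("t-test and adjusted P ranks agree when carrier status is balanced", {
  # carriers split evenly across groups and no carrier effect: the
  # covariate is noise, so p_case tracks the unadjusted P in rank
  spec <- simulation_spec(n_probes = 400L, seed = 21L,
                          carrier_count_cases = 21L, carrier_count_controls = 21L,
                          effect_probes = data.frame(mechanism = character(0),
                                                     delta = numeric(0)))
  sim <- simulate_study(spec)
  tt <- dmp_ttest(sim$betas, sim$cohort)
  rg <- dmp_regression(sim$betas, sim$cohort)
  rho <- cor(tt$p_ttest, rg$p_regression, method = "spearman")
  expect_gt(rho, 0.95)
})
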