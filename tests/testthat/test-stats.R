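test_that("pooled-proportion z statistic matches hand evaluation", {
  # equal proportions: numerator zero
  z0 <- proportion_ztest(proportion_sample(0.4, 80),
                         proportion_sample(0.4, 40))
  expect_equal(z0$statistic, 0)
  expect_equal(z0$p_value, 1)
  # direct evaluation: p_hat = 110/150, Z = 0.2 / sqrt(...) = 2.611
  z <- proportion_ztest(proportion_sample(0.8, 100),
                        proportion_sample(0.6, 50))
  expect_equal(z$statistic, 2.611165, tolerance = 1e-6)
  expect_lt(z$p_value, 0.01)
  # antisymmetry
  zr <- proportion_ztest(proportion_sample(0.6, 50),
                         proportion_sample(0.8, 100))
  expect_equal(zr$statistic, -z$statistic)
  expect_equal(zr$p_value, z$p_value)
  # degenerate pooled proportion
  zd <- proportion_ztest(proportion_sample(0, 10), proportion_sample(0, 10))
  expect_true(zd$degenerate)
  expect_equal(zd$p_value, 1)
  expect_error(proportion_sample(1.2, 10))
  expect_error(proportion_sample(0.5, 0))
})

test_that("z-test equals an independent formula oracle on random inputs", {
  set.seed(99)
  for (i in 1:100) {
    nT <- sample(10:500, 1); nB <- sample(10:500, 1)
    pT <- round(stats::runif(1), 3); pB <- round(stats::runif(1), 3)
    got <- proportion_ztest(proportion_sample(pT, nT),
                            proportion_sample(pB, nB))
    phat <- (nT * pT + nB * pB) / (nT + nB)
    if (phat <= 0 || phat >= 1) {
      expect_true(got$degenerate)
      next
    }
    zo <- (pT - pB) / sqrt(phat * (1 - phat) * (1 / nT + 1 / nB))
    expect_equal(got$statistic, zo, tolerance = 1e-9)
    expect_equal(got$p_value, 2 * stats::pnorm(-abs(zo)), tolerance = 1e-9)
  }
})

test_that("permutation test p-values obey the add-one bound and determinism", {
  vals <- c(rnorm(12, 10), rnorm(12, 0))
  labs <- rep(c("a", "b"), each = 12)
  p <- permutation_ratio_test(labs, vals, n_perm = 1000, seed = 4)
  expect_equal(p$p_value, 1 / 1001)     # more extreme than every permutation
  p2 <- permutation_ratio_test(labs, vals, n_perm = 1000, seed = 4)
  expect_identical(p$p_value, p2$p_value)
  expect_identical(p$null, p2$null)
  # identical values in both groups -> p = 1
  same <- rep(5, 24)
  ps <- permutation_ratio_test(labs, same, n_perm = 200, seed = 1)
  expect_equal(ps$p_value, 1)
  expect_error(permutation_ratio_test(rep("a", 10), rnorm(10)), "two groups")
})

test_that("bootstrap CI degenerates correctly and stays ordered", {
  b <- bootstrap_ci(rep(3, 10), seed = 1)
  expect_equal(b$lower, 3)
  expect_equal(b$upper, 3)
  b0 <- bootstrap_ci(rnorm(20), level = 0, seed = 1)
  expect_equal(b0$lower, b0$upper)
  set.seed(2)
  b1 <- bootstrap_ci(rnorm(50, 5), seed = 7)
  expect_lte(b1$lower, b1$estimate)
  expect_gte(b1$upper, b1$estimate)
  expect_error(bootstrap_ci(1), "at least 2")
})

test_that("usage tables are proper frequency distributions", {
  ann <- tibble::tibble(
    id = sprintf("r%02d", 1:12), sample_id = "S",
    compartment = rep(c("blood", "tumor"), each = 6),
    v_call = sample(c("IGHV4-59*01", "IGHV4-4*01", "IGHV3-23*01"), 12,
                    replace = TRUE),
    j_call = "IGHJ4*02", d_call = "IGHD2-15*01", c_call = "IgG1")
  u <- usage_tables(ann, key = "v", test = TRUE)
  sums <- tapply(u$frequencies$frequency, u$frequencies$group, sum)
  expect_equal(as.numeric(sums), c(1, 1))
  expect_true(all(u$tests$p_value >= 0 & u$tests$p_value <= 1))
  expect_true(all(u$tests$p_adj >= u$tests$p_value - 1e-12))
  # single sequence: one cell with frequency 1
  u1 <- usage_tables(ann[1, ], key = "vj")
  expect_equal(u1$frequencies$frequency, 1)
  # gene x isotype key
  u2 <- usage_tables(ann, key = "v_isotype")
  expect_true(all(grepl("\\|IgG1$", u2$frequencies$key)))
})

test_that("repertoire summary recovers the configured unproductive rate", {
  model <- demo_model_cached()
  s <- quick_sim(n_cells = 150, seed = 25, unproductive_rate = 0.15)
  ann <- annotate_repertoire(s$reads[s$reads$chain == "heavy", ], model,
                             with_d = FALSE)
  summ <- repertoire_summary(ann)
  expect_true(all(summ$fraction_of_sample > 0))
  overall <- sum(summ$n * summ$pct_unproductive / 100) / sum(summ$n)
  n_h <- sum(ann$chain == "heavy")
  # unproductive extras arrive at ~rate/(1+rate) of emitted heavy reads,
  # plus SHM-broken rearrangements; binomial 3-sigma band around that floor
  p0 <- 0.15 / 1.15
  expect_gt(overall, p0 - 3 * sqrt(p0 * (1 - p0) / n_h))
  # germline-identical set: zero mutation load, R/(R+S) = 0 by convention
  s0 <- quick_sim(n_cells = 30, seed = 26, shm_rate = 0,
                  unproductive_rate = 0)
  ann0 <- annotate_repertoire(s0$reads[s0$reads$chain == "heavy", ], model)
  summ0 <- repertoire_summary(ann0)
  expect_true(all(summ0$pct_total_mutations == 0))
  expect_true(all(summ0$r_total_ratio == 0))
  expect_true(all(summ0$pct_unproductive == 0))
})
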