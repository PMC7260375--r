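test_that("AUC equals brute-force pair counting on random small samples", {
  set.seed(2)
  for (r in 1:100) {
    ni <- sample(3:20, 1); na <- sample(3:20, 1)
    intact <- sample(1:10, ni, replace = TRUE) + rnorm(ni, 0, 0.01 * (r %% 2))
    affected <- sample(1:10, na, replace = TRUE) + rnorm(na, 0, 0.01 * (r %% 2))
    expect_equal(compute_auc(intact, affected),
                 auc_bruteforce(intact, affected), tolerance = 1e-12)
  }
  expect_equal(compute_auc(c(1, 2, 3), c(2.5, 4, 5)), 8 / 9)
  expect_equal(compute_auc(c(1, 2), c(5, 6)), 1)        # complete separation
  x <- rnorm(50)
  expect_equal(compute_auc(x, x), 0.5)                  # identical samples
  # orientation flips the role of "worse"
  expect_equal(compute_auc(c(5, 6), c(1, 2), "lower_is_worse"), 1)
  expect_error(compute_auc(numeric(), c(1)), "non-empty")
})

test_that("agreement ICC matches the hand-worked ANOVA example and aov()", {
  expect_equal(compute_icc_agreement(rbind(c(1, 2), c(2, 3), c(3, 4))), 0.8)
  set.seed(3)
  for (r in 1:50) {
    m <- matrix(rnorm(10), 5, 2)
    expect_equal(compute_icc_agreement(m), icc_aov_oracle(m),
                 tolerance = 1e-9)
  }
  expect_equal(compute_icc_agreement(cbind(1:5, 1:5)), 1)  # perfect retest
  expect_error(compute_icc_agreement(rbind(c(1, 2), c(2, 3))), "at least 3")
  # null: two independent columns give ICC near zero
  set.seed(4)
  icc_null <- compute_icc_agreement(cbind(rnorm(200), rnorm(200)))
  expect_gt(icc_null, -0.25)
  expect_lt(icc_null, 0.25)
})

test_that("SRD closed form and SRD% scaling", {
  # Sigma = 1, ICC = 0.5 -> SRD = 1.96
  paired <- cbind(c(0, 0, 1, 1, 2, 2), c(2, 1, 0, 2, 1, 0))
  paired <- (paired - mean(paired)) / sd(as.vector(paired))  # Sigma exactly 1
  s <- compute_srd(paired, icc = 0.5, normalized_range = 1)
  expect_equal(s$srd, 1.96)
  expect_equal(compute_srd(paired, icc = 1, normalized_range = 10)$srd, 0)
  # Sigma = 2, ICC = 0.75 -> 1.96 * sqrt(2) * 2 * 0.5
  s2 <- compute_srd(paired * 2, icc = 0.75, normalized_range = 100)
  expect_equal(s2$srd, 1.96 * sqrt(2) * 2 * 0.5)
  expect_equal(s2$srd_pct, 100 * s2$srd / 100)
  expect_error(compute_srd(paired, icc = 1.2, normalized_range = 1), "ICC")
  expect_error(compute_srd(paired, icc = 0.5, normalized_range = 0), "positive")
})

test_that("learning slope eta and its paired t-test", {
  same <- cbind(1:5, 1:5)
  e <- compute_eta(same, 10)
  expect_equal(e$eta, 0)
  expect_equal(e$paired_t_p, 1)
  shifted <- cbind(c(1, 2, 3, 4), c(-1, 0, 1, 2))  # mean diff -2
  expect_equal(compute_eta(shifted, 20)$eta, -10)
  expect_error(compute_eta(cbind(1:2, 1:2), 10), "at least 3")
  expect_error(compute_eta(same, 0), "zero range")
  # planted session shift of -5% of the realized range centers eta on -5
  set.seed(5)
  etas <- replicate(100, {
    b <- rnorm(60); e1 <- rnorm(60, 0, 0.4); e2 <- rnorm(60, 0, 0.4)
    test <- b + e1
    rng <- diff(range(test))
    retest <- b + e2 - 0.05 * rng
    compute_eta(cbind(test, retest), rng)$eta
  })
  expect_lt(abs(mean(etas) + 5), 0.5)
})

test_that("nearest-rank percentiles and the data-driven cutoffs", {
  expect_equal(percentile(1:100, 80), 80)
  expect_equal(percentile(rep(3, 7), 20), 3)
  expect_equal(percentile(rep(3, 7), 80), 3)
  # linear variant is the type-7 quantile
  expect_equal(percentile(1:10, 25, type = "linear"),
               unname(quantile(1:10, 0.25)))
  cuts <- percentile_cutoffs(1:100, 1:100)
  expect_equal(cuts$srd_cutoff, 80)
  expect_equal(cuts$eta_cutoff, 20)
})

test_that("step-2 filter applies all four criteria with recorded reasons", {
  scores <- data.frame(
    metric = c("good", "low_auc", "low_icc", "big_srd", "learner"),
    auc = c(0.8, 0.6, 0.9, 0.8, 0.8),
    icc = c(0.75, 0.8, 0.5, 0.75, 0.75),
    srd_pct = c(20, 20, 20, 90, 20),
    eta = c(-2, -2, -2, -2, -50))
  cuts <- list(srd_cutoff = 50, eta_cutoff = -10)
  out <- step2_filter(scores, cuts, step1_keep = c("good", "low_auc"))
  expect_identical(out$metric[out$pass_step2], "good")
  expect_identical(out$metric[out$pass_steps_1_2], "good")
  expect_match(out$reason[out$metric == "low_auc"], "AUC")
  expect_match(out$reason[out$metric == "big_srd"], "SRD")
  expect_match(out$reason[out$metric == "learner"], "eta")
  # boundary conventions: ICC inclusive, eta strict
  b <- data.frame(metric = c("icc_b", "eta_b"), auc = 0.9,
                  icc = c(0.70, 0.9), srd_pct = 10, eta = c(-2, -10))
  outb <- step2_filter(b, cuts)
  expect_true(outb$pass_step2[outb$metric == "icc_b"])
  expect_false(outb$pass_step2[outb$metric == "eta_b"])
  # all-zero AUC -> empty survivor set
  z <- data.frame(metric = letters[1:3], auc = 0, icc = 0.9,
                  srd_pct = 10, eta = 0)
  expect_equal(sum(step2_filter(z, cuts)$pass_step2), 0)
  # monotonicity: adding a criterion never enlarges the survivor set
  no_eta <- step2_filter(scores, list(srd_cutoff = 50, eta_cutoff = -Inf))
  expect_true(all(out$pass_step2 <= no_eta$pass_step2))
})

test_that("AUC agrees with pROC on a moderate sample", {
  skip_if_not_installed("pROC")
  set.seed(6)
  intact <- rnorm(80); affected <- rnorm(60, 1)
  expect_equal(
    compute_auc(intact, affected),
    as.numeric(suppressMessages(pROC::auc(
      pROC::roc(c(rep(0, 80), rep(1, 60)), c(intact, affected),
                direction = "<", quiet = TRUE)))),
    tolerance = 1e-12)
})
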