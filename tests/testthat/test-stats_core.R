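test_that("CMH matches the independent reference on random tables", {
  set.seed(101)
  for (i in 1:20) {
    tab <- random_strat_table(sample(2:4, 1))
    got <- cmh_test(tab)
    ref <- mantelhaen_ref(tab)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
    expect_equal(got$or_mh, unname(ref$estimate), tolerance = 1e-10)
    expect_equal(c(got$ci_low, got$ci_high), as.vector(ref$conf.int),
                 tolerance = 1e-10)
  }
})

test_that("single-stratum CMH is the conditional score test on the 2x2", {
  a <- 12; b <- 30; c0 <- 5; d <- 40
  got <- cmh_test(a, a + b, c0, c0 + d)
  N <- a + b + c0 + d
  pearson <- chisq.test(matrix(c(a, b, c0, d), 2, byrow = TRUE),
                        correct = FALSE)$statistic
  expect_equal(got$statistic, unname(pearson) * (N - 1) / N,
               tolerance = 1e-12)
})

test_that("CMH degenerate and null cases behave as contracted", {
  # two identical strata with equal carrier rates in both arms
  r <- cmh_test(c(4, 4), c(40, 40), c(4, 4), c(40, 40))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  expect_equal(r$or_mh, 1)

  # all strata carrier-free: flagged, p = 1, OR undefined
  r0 <- cmh_test(c(0, 0), c(10, 20), c(0, 0), c(15, 25))
  expect_true(r0$degenerate)
  expect_equal(r0$p, 1)
  expect_true(is.na(r0$or_mh))
  expect_equal(r0$n_strata_informative, 0L)

  expect_error(cmh_test(5, 4, 0, 10), "\\[0, total\\]")
})

test_that("MH OR is invariant to stratum order and carrier-free strata", {
  set.seed(77)
  tab <- random_strat_table(3)
  base <- cmh_test(tab)
  perm <- cmh_test(tab[c(3, 1, 2), ])
  expect_equal(perm$or_mh, base$or_mh)
  expect_equal(perm$statistic, base$statistic)

  padded <- rbind(tab, data.frame(case_carriers = 0, case_total = 50,
                                  control_carriers = 0, control_total = 60))
  expect_equal(cmh_test(padded)$or_mh, base$or_mh)
  expect_equal(cmh_test(padded)$statistic, base$statistic)
  expect_equal(cmh_test(padded)$n_strata_informative,
               base$n_strata_informative)
})

test_that("CMH resists Simpson-style confounding that inflates pooling", {
  # per-stratum truth OR = 1; pooling mixes a high-rate/high-case stratum
  a1 <- 40; n1c <- 200; c1 <- 160; n1t <- 800    # 20% carriers both arms
  a2 <- 400; n2c <- 800; c2 <- 100; n2t <- 200   # 50% carriers both arms
  strat <- cmh_test(c(a1, a2), c(n1c, n2c), c(c1, c2), c(n1t, n2t))
  pooled <- cmh_test(a1 + a2, n1c + n2c, c1 + c2, n1t + n2t)
  expect_equal(strat$or_mh, 1, tolerance = 1e-12)
  expect_equal(strat$statistic, 0, tolerance = 1e-12)
  expect_gt(pooled$or_mh, 2)
  expect_lt(pooled$p, 1e-10)
})

test_that("fisher_or reproduces sample odds ratios and exact p-values", {
  res <- fisher_or(5, 5197, 1, 8666)
  expect_equal(round(res$or, 2), 8.34)
  expect_equal(res$p, fisher.test(matrix(c(5, 5197, 1, 8666), 2,
                                         byrow = TRUE))$p.value)

  expect_equal(fisher_or(1, 1, 1, 1)$or, 1)
  expect_equal(fisher_or(1, 1, 1, 1)$p, 1)
  expect_equal(fisher_or(3, 7, 3, 7)$or, 1)
  expect_equal(fisher_or(5, 0, 1, 3)$or, Inf)
  expect_error(fisher_or(0, 0, 0, 0), "all-zero")
  expect_error(fisher_or(-1, 2, 3, 4), "nonnegative")
})

test_that("burden logistic recovers a null effect and flags degeneracy", {
  set.seed(202)
  n <- 1200
  samples <- sample_table(data.frame(
    sample_id = sprintf("s%04d", 1:n), dataset_id = "d",
    array_group = rep(c("GSA", "OmniExpress"), each = n / 2),
    sex = "M", status = sample(c("case", "control"), n, TRUE),
    lrr_sd = runif(n, 0.05, 0.2), baf_drift = 0.002, gcwf = 0,
    n_cnv_raw = rpois(n, 4), ancestry_cluster = rep(1:2, each = n / 2),
    stringsAsFactors = FALSE))
  st <- build_strata(samples)
  reps <- replicate(30, {
    burden <- rpois(n, 1.5)
    fit_burden_logistic(samples, burden, st$assignment)$log_or
  })
  expect_lt(abs(mean(reps)), 3 * sd(reps) / sqrt(length(reps)))

  expect_error(fit_burden_logistic(samples, rep(0, n), st$assignment),
               "constant")
  # perfect separation: burden identifies cases exactly
  sep <- as.numeric(samples$status == "case")
  expect_error(fit_burden_logistic(samples, sep, st$assignment),
               "not identifiable")
})

test_that("burden logistic CI covers a planted effect", {
  set.seed(303)
  n <- 4000
  covered <- 0L
  n_rep <- 25
  for (r in seq_len(n_rep)) {
    group <- rep(1:2, each = n / 2)
    burden <- rpois(n, c(1, 2)[group])  # burden confounded with stratum
    eta <- -0.5 + log(1.5) * burden + 0.4 * (group == 2)
    status <- ifelse(runif(n) < plogis(eta), "case", "control")
    samples <- sample_table(data.frame(
      sample_id = sprintf("s%04d", 1:n), dataset_id = "d",
      array_group = c("GSA", "OmniExpress")[group], sex = "M",
      status = status, lrr_sd = 0.1, baf_drift = 0.002, gcwf = 0,
      n_cnv_raw = rpois(n, 3), ancestry_cluster = group,
      stringsAsFactors = FALSE))
    st <- build_strata(samples)
    fit <- fit_burden_logistic(samples, burden, st$assignment)
    if (fit$ci_low <= 1.5 && 1.5 <= fit$ci_high) covered <- covered + 1L
  }
  expect_gte(covered, round(0.8 * n_rep))
})

test_that("two-round doubling is capped, monotone and validated", {
  expect_equal(adjust_two_rounds(0.25), 0.5)
  expect_equal(adjust_two_rounds(0.7), 1)
  expect_equal(adjust_two_rounds(1), 1)
  p <- sort(runif(20))
  expect_true(all(diff(adjust_two_rounds(p)) >= 0))
  expect_error(adjust_two_rounds(0), "\\(0, 1\\]")
  expect_error(adjust_two_rounds(1.1), "\\(0, 1\\]")
})

test_that("genomic lambda is 1 at the null median and detects inflation", {
  expect_equal(genomic_lambda(0.5), 1)
  set.seed(42)
  u <- runif(10000)
  expect_equal(genomic_lambda(u), 1, tolerance = 0.05)
  expect_gt(genomic_lambda(u / 2), genomic_lambda(u))
  expect_error(genomic_lambda(numeric(0)), "no p-values")
  expect_error(genomic_lambda(c(0.5, 0)), "\\(0, 1\\]")
})

mk_assignment <- function(n_per_arm = 5, n_strata = 2) {
  n <- 2 * n_per_arm * n_strata
  data.frame(
    sample_id = sprintf("s%03d", seq_len(n)),
    stratum_id = rep(sprintf("st%d", seq_len(n_strata)), each = 2 * n_per_arm),
    status = rep(rep(c("case", "control"), each = n_per_arm), n_strata),
    stringsAsFactors = FALSE)
}

test_that("min(P) permutation engine honours its contracts", {
  asg <- mk_assignment(10, 2)
  carrier <- matrix(FALSE, 3, nrow(asg),
                    dimnames = list(paste0("L", 1:3), asg$sample_id))
  # no carriers anywhere: all observed p = 1, threshold 1, adjusted 1
  null <- minp_permutation(carrier, asg, n_perm = 200, seed = 4)
  expect_true(all(null$observed$p == 1))
  expect_equal(null$threshold, 1)
  expect_true(all(null$p_adjusted == 1))

  # determinism: same seed gives bit-identical thresholds and adjusted p
  set.seed(8)
  carrier[] <- runif(length(carrier)) < 0.3
  n1 <- minp_permutation(carrier, asg, n_perm = 300, seed = 21)
  n2 <- minp_permutation(carrier, asg, n_perm = 300, seed = 21)
  expect_identical(n1$min_p, n2$min_p)
  expect_identical(n1$p_adjusted, n2$p_adjusted)

  # n_perm = 0: observed only
  n0 <- minp_permutation(carrier, asg, n_perm = 0, seed = 1)
  expect_null(n0$min_p)
  expect_true(is.na(n0$threshold))

  expect_warning(minp_permutation(carrier, asg, n_perm = 50, seed = 1),
                 "n_perm")
  expect_error(minp_permutation(carrier[0, , drop = FALSE], asg, 100, seed = 1),
               "no loci")

  # adjusted p is monotone in raw p within the family
  ord <- order(n1$observed$p)
  expect_true(all(diff(n1$p_adjusted[ord]) >= 0))
})

test_that("permutation adjusted p-values are valid under the null", {
  # stratified null cohort; P(adjusted p <= alpha) should not exceed
  # alpha by more than Monte-Carlo error
  asg <- mk_assignment(15, 2)
  n_rep <- 120
  hit <- logical(n_rep)
  set.seed(500)
  seeds <- sample.int(1e6, n_rep)
  for (r in seq_len(n_rep)) {
    carrier <- matrix(runif(8 * nrow(asg)) < 0.25, 8, nrow(asg),
                      dimnames = list(paste0("L", 1:8), asg$sample_id))
    null <- minp_permutation(carrier, asg, n_perm = 200, seed = seeds[r])
    hit[r] <- any(null$p_adjusted <= 0.05)
  }
  # 3 binomial SEs above 0.05 at n_rep = 120 is ~0.11
  expect_lte(mean(hit), 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))
})
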