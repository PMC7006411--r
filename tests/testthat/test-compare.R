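test_that("the highest ranked therapy is the argmin of the predicted summaries", {
  m <- matrix(c(0.30, 0.20, 0.50, 0.45, 0.15, 0.40), nrow = 1,
              dimnames = list(NULL, DMT_LEVELS))
  preds <- structure(list(summary = m, response = "relapse", duration = 1),
                     class = "counterfactual_predictions")
  rk <- rank_therapies(preds)
  expect_equal(rk$dmt_star, "NA.")
  expect_false(rk$tie)
  expect_equal(rk$order, "NA.,FTY,DMF,TERI,IF,GA")

  # all equal: alphabetical tie-break, flagged
  m2 <- matrix(0.3, 1, 6, dimnames = list(NULL, DMT_LEVELS))
  rk2 <- rank_therapies(structure(list(summary = m2, response = "relapse"),
                                  class = "counterfactual_predictions"))
  expect_equal(rk2$dmt_star, "DMF")
  expect_true(rk2$tie)

  expect_error(rank_therapies(structure(
    list(summary = m * NA, response = "relapse"),
    class = "counterfactual_predictions")), "missing")
})

test_that("ranking is invariant under a common rescaling of exposure duration", {
  reg <- generate_registry(sim_config(n_patients = 150, n_sites = 4, seed = 31),
                           trajectories = FALSE)
  p1 <- true_counterfactuals(reg$truth, reg$cycles, "relapse")
  p2 <- p1
  p2$summary <- p1$summary * 3   # NB mean scales linearly in duration
  expect_identical(rank_therapies(p1)$dmt_star, rank_therapies(p2)$dmt_star)
})

test_that("ATE weights rebalance confounded covariates towards the pooled population", {
  set.seed(13)
  n <- 3000
  cyc <- data.frame(age = rnorm(n, 40, 10), relapses_count = rpois(n, 1.2),
                    edss_baseline = round(pmin(pmax(rnorm(n, 2.5, 1.3), 0), 6) * 2) / 2,
                    diagnosis_distance = rgamma(n, 2, 0.4))
  lin <- 0.6 * scale(cyc$relapses_count) + 0.5 * scale(cyc$edss_baseline)
  received <- runif(n) < plogis(-0.3 + lin)
  w <- estimate_weights(cyc, received)
  bal <- attr(w, "balance")
  expect_gt(max(bal$smd_before), 0.1)         # confounding present
  expect_lt(max(bal$smd_after), 0.1)          # restored balance
  # weighted group means approach the pooled means (the defining property)
  for (v in c("age", "relapses_count", "diagnosis_distance")) {
    pooled <- mean(cyc[[v]])
    wt_mean <- sum(cyc[[v]][received] * w[received]) / sum(w[received])
    expect_lt(abs(wt_mean - pooled) / sd(cyc[[v]]), 0.05)
  }
  expect_true(all(attr(w, "ess") > 0))
})

test_that("identical covariate distributions give near-uniform weights; empty groups error", {
  set.seed(14)
  n <- 2000
  cyc <- data.frame(age = rnorm(n, 40, 10), relapses_count = rpois(n, 1),
                    edss_baseline = 2, diagnosis_distance = rgamma(n, 2, 0.4))
  received <- rep(c(TRUE, FALSE), n / 2)
  w <- estimate_weights(cyc, received)
  expect_lt(max(abs(w - 1)), 0.35)
  expect_error(estimate_weights(cyc, rep(TRUE, n)), "nonempty")
})

test_that("the weighted NB GLM recovers a known rate ratio and a null slope", {
  set.seed(15)
  n <- 4000
  cyc <- data.frame(index_duration = runif(n, 0.5, 3),
                    age = rnorm(n, 40, 10), relapses_count = rpois(n, 1),
                    edss_baseline = round(runif(n, 0, 6) * 2) / 2,
                    diagnosis_distance = rgamma(n, 2, 0.5))
  took <- runif(n) < 0.5
  cyc$n_relapses <- rnbinom(n, size = 1.5,
                            mu = cyc$index_duration * 0.6 * ifelse(took, 0.5, 1))
  w <- estimate_weights(cyc, took)
  res <- weighted_outcome_glm(cyc, took, w, "relapse")
  expect_lt(abs(res$slope - (-log(2))), 0.1)
  expect_lt(res$p_value, 0.001)

  # identical laws in both groups: slope near zero, not significant
  cyc$n_relapses <- rnbinom(n, size = 1.5, mu = cyc$index_duration * 0.6)
  res0 <- weighted_outcome_glm(cyc, took, w, "relapse")
  expect_lt(abs(res0$slope), 0.1)

  expect_error(weighted_outcome_glm(
    transform(cyc, index_duration = 0), took, w, "relapse"), "duration")
})

test_that("the weighted binomial GLM detects a protective effect on CDP", {
  set.seed(16)
  n <- 4000
  cyc <- data.frame(index_duration = runif(n, 0.5, 3),
                    age = rnorm(n, 40, 10), relapses_count = rpois(n, 1),
                    edss_baseline = round(runif(n, 0, 6) * 2) / 2,
                    diagnosis_distance = rgamma(n, 2, 0.5))
  took <- runif(n) < 0.5
  eta <- -2.2 + log(cyc$index_duration) - 0.7 * took
  cyc$cdp <- runif(n) < plogis(eta)
  w <- estimate_weights(cyc, took)
  res <- weighted_outcome_glm(cyc, took, w, "cdp")
  expect_lt(abs(res$slope - (-0.7)), 0.2)
  expect_lt(res$p_value, 0.01)
})

test_that("the adherence comparison applies the 10-observation floor per condition", {
  reg <- generate_registry(sim_config(n_patients = 400, n_sites = 5, seed = 37),
                           trajectories = FALSE)
  rk <- rank_therapies(true_counterfactuals(reg$truth, reg$cycles, "relapse"))
  tab <- run_adherence_comparison(reg$cycles, rk, "relapse")
  expect_s3_class(tab, "weighted_comparison")
  expect_lte(nrow(tab), 6)
  small <- tab$n_received < 10 | tab$n_not_received < 10
  expect_true(all(is.na(tab$slope[small])))
  expect_true(all(!is.na(tab$excluded_reason[small])))
  ok <- !small & is.na(tab$excluded_reason)
  expect_true(all(is.finite(tab$slope[ok])))
})
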