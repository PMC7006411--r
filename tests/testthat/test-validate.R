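test_that("calibration bins are equally populated and partition the predictions", {
  set.seed(1)
  p <- runif(40); o <- rpois(40, 1)
  tab <- calibration(p, o, n_bins = 20)
  expect_equal(tab$n, rep(2, 20))
  expect_equal(sum(tab$n), 40)

  # remainder spread over leading bins: counts differ by at most one
  p <- runif(47); o <- rpois(47, 1)
  tab <- calibration(p, o, n_bins = 20)
  expect_lte(max(tab$n) - min(tab$n), 1)
  expect_equal(sum(tab$n), 47)
  expect_true(all(diff(tab$mean_predicted) >= 0))

  # constant predictions: the stable-order tie rule still yields equal bins
  tab <- calibration(rep(0.3, 40), o[1:40], n_bins = 20)
  expect_equal(tab$n, rep(2, 20))
  expect_true(all(tab$mean_predicted == 0.3))

  expect_error(calibration(runif(10), rpois(10, 1), n_bins = 20), "fewer")

  # stratified calibration returns one table per stratum
  tab <- calibration(runif(60), rpois(60, 1), n_bins = 5,
                     by = rep(c("a", "b"), 30))
  expect_equal(nrow(tab), 10)
})

test_that("well-calibrated predictions land near the diagonal", {
  set.seed(3)
  mu <- rgamma(4000, 2, 2)
  y <- rnbinom(4000, size = 1.5, mu = mu)
  tab <- calibration(mu, y, n_bins = 20)
  low <- tab$mean_predicted < 1
  expect_lt(max(abs(tab$mean_predicted[low] - tab$mean_observed[low])), 0.25)
})

test_that("duration matching follows the half-year rule and the brute-force oracle", {
  expect_equal(nrow(match_pairs(c(0.3, 0.6))), 1)   # min < 0.5, diff 0.3
  expect_equal(nrow(match_pairs(c(1.0, 2.5))), 0)   # diff 1.5 > 1.0
  expect_equal(nrow(match_pairs(c(0.4, 0.95))), 0)  # min < 0.5, diff > 0.5
  expect_equal(nrow(match_pairs(c(0.6, 1.55))), 1)  # min >= 0.5, diff <= 1

  set.seed(7)
  for (k in 1:5) {
    d <- runif(60, 0.1, 4)
    got <- match_pairs(d)
    oracle <- bf_match_pairs(d)
    expect_equal(unname(got[, 1]), oracle[, 1])
    expect_equal(unname(got[, 2]), oracle[, 2])
  }
})

test_that("the concordance index honours ties and matches the brute-force oracle", {
  pairs <- match_pairs(c(1, 1.2))
  expect_equal(c_index(pairs, c(0.1, 0.9), c(0, 1)), 1.0)
  expect_equal(c_index(pairs, c(0.9, 0.1), c(0, 1)), 0.0)
  expect_equal(c_index(pairs, c(0.5, 0.5), c(0, 1)), 0.5)
  expect_warning(ci <- c_index(pairs, c(0.1, 0.9), c(1, 1)), "discordant")
  expect_true(is.na(ci))

  set.seed(11)
  for (k in 1:5) {
    d <- runif(50, 0.2, 3)
    s <- round(runif(50), 2)   # rounded scores force some ties
    e <- rbinom(50, 1, 0.4)
    pairs <- match_pairs(d)
    expect_equal(c_index(pairs, s, e), bf_cindex(pairs, s, e))
  }
})

test_that("mean squared error matches its definition", {
  expect_equal(mse(1:5, 1:5), 0)
  expect_equal(mse(rep(0.5, 4), c(0, 1, 1, 0)), 0.25)
  set.seed(2)
  p <- rnorm(30); o <- rnorm(30)
  expect_equal(mse(p, o), sum((p - o)^2) / 30, tolerance = 1e-15)
  expect_error(mse(1:3, 1:4), "length")
})

test_that("measures are invariant to the ordering of the cycles", {
  reg <- generate_registry(sim_config(n_patients = 150, n_sites = 4, seed = 17),
                           trajectories = FALSE)
  tm <- true_model(reg$truth, "relapse")
  cyc <- reg$cycles
  perm <- sample(nrow(cyc))
  m1 <- dmtrank:::.measure_set(cyc, predict_mean(tm, cyc),
                               pointwise_nll(tm, cyc), "relapse")
  m2 <- dmtrank:::.measure_set(cyc[perm, ], predict_mean(tm, cyc[perm, ]),
                               pointwise_nll(tm, cyc[perm, ]), "relapse")
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("repeated k-fold cross-validation is reproducible and scores every cycle once", {
  reg <- generate_registry(sim_config(n_patients = 80, n_sites = 4, seed = 19),
                           trajectories = FALSE)
  tm_fitter <- function(train, seed) true_model(reg$truth, "relapse")
  spec <- model_spec("relapse", "predictive")
  r1 <- run_kfold(spec, reg$cycles, k = 2, repeats = 3, seed = 5,
                  fitter = tm_fitter)
  r2 <- run_kfold(spec, reg$cycles, k = 2, repeats = 3, seed = 5,
                  fitter = tm_fitter)
  expect_identical(r1, r2)
  expect_equal(unique(r1$n), 80)
  expect_true(all(c("oos_mean", "oos_se", "ins_mean", "ins_se") %in% names(r1)))
  expect_false(any(is.na(r1$oos_se)))

  # a failing fold drops the repeat with a warning, others survive
  flaky <- local({
    calls <- 0
    function(train, seed) {
      calls <<- calls + 1
      if (calls == 1) stop("synthetic non-convergence")
      true_model(reg$truth, "relapse")
    }
  })
  expect_warning(r3 <- run_kfold(spec, reg$cycles, k = 2, repeats = 2,
                                 seed = 5, fitter = flaky), "dropped")
})

test_that("leave-one-site-out fits once per site and tabulates per-site NLL", {
  reg <- generate_registry(sim_config(n_patients = 90, n_sites = 3, seed = 23),
                           trajectories = FALSE)
  fits <- 0
  fitter <- function(train, seed) {
    fits <<- fits + 1
    expect_lt(length(unique(train$site_id)), 3)
    true_model(reg$truth, "relapse")
  }
  res <- run_leave_one_site_out(model_spec("relapse", "predictive"),
                                reg$cycles, seed = 2, fitter = fitter)
  expect_equal(fits, 3)
  expect_equal(nrow(res$per_site), 3)
  expect_equal(sum(res$per_site$n), nrow(reg$cycles))
  expect_equal(sum(res$per_site$nll),
               res$report$oos_mean[res$report$measure == "nll"],
               tolerance = 1e-10)
})

test_that("forecast windows are right-closed and stratified MSEs aggregate to the pooled MSE", {
  cyc <- make_cycles(6, index_duration = c(0.4, 0.5, 1.5, 1.6, 3.5, 5.0),
                     n_relapses = c(0L, 1L, 2L, 0L, 1L, 3L))
  pred <- c(0.2, 0.8, 1.5, 0.5, 1.2, 2.0)
  nll <- rep(1, 6)
  tab <- window_stratified_eval(cyc, pred, nll, "relapse")
  expect_equal(tab$n, c(2, 1, 1, 1, 0, 1))       # 0.5 and 1.5 right-closed
  expect_true(is.na(tab$mse[5]))
  pooled <- mse(pred, cyc$n_relapses)
  expect_equal(sum(tab$n * tab$mse, na.rm = TRUE) / sum(tab$n), pooled,
               tolerance = 1e-12)
})

test_that("the sensitivity scan reports full agreement for the identity variant", {
  reg <- generate_registry(sim_config(n_patients = 250, n_sites = 5, seed = 29),
                           trajectories = FALSE)
  res <- sensitivity_scan(model_spec("relapse", "non_personalized"),
                          reg$cycles, prior_scales = 1, seed = 3,
                          mcmc = list(chains = 2, iter = 100, warmup = 150,
                                      on_nonconvergence = "ignore"))
  expect_equal(res$agreement, 1)
})
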