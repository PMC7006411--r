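## Performance measures (equally-populated-bin calibration, MSE, pointwise
## NLL, duration-matched concordance) and the out-of-sample validation
## schemes (repeated k-fold by patient, leave-one-site-out, test set),
## forecast-window stratification, nested-model comparison, and the
## prior/sample-size sensitivity scan.

#' Equally-populated-bin calibration table
#'
#' Sorts cycles by predicted outcome and splits them into `n_bins` bins of
#' equal population (any remainder spread over the leading bins, so counts
#' differ by at most one); ties in the predictions are kept in their original
#' order, so constant predictions simply produce equally-sized bins with
#' identical ranges. Per bin, the mean predicted and mean observed outcome
#' are returned.
#'
#' @param predictions predicted outcomes.
#' @param observations observed outcomes, same length.
#' @param n_bins number of bins (default 20).
#' @param by optional stratification factor (e.g. index therapy); calibration
#'   is then computed per stratum.
#' @return A `calibration_table` data frame with columns `bin`, `n`,
#'   `pred_lo`, `pred_hi`, `mean_predicted`, `mean_observed` (and `stratum`
#'   when `by` is given).
#' @export
calibration <- function(predictions, observations, n_bins = 20, by = NULL) {
  stopifnot(length(predictions) == length(observations))
  if (!is.null(by)) {
    parts <- lapply(split(seq_along(predictions), by), function(ix) {
      calibration(predictions[ix], observations[ix], n_bins)
    })
    out <- do.call(rbind, Map(cbind, stratum = names(parts), parts))
    rownames(out) <- NULL
    return(out)
  }
  n <- length(predictions)
  if (n < n_bins) stop("fewer observations (", n, ") than bins (", n_bins, ")")
  ord <- order(predictions)
  base <- n %/% n_bins
  counts <- rep(base, n_bins) + c(rep(1, n %% n_bins), rep(0, n_bins - n %% n_bins))
  bin <- rep(seq_len(n_bins), counts)
  p <- predictions[ord]
  o <- observations[ord]
  out <- data.frame(
    bin = seq_len(n_bins),
    n = counts,
    pred_lo = tapply(p, bin, min),
    pred_hi = tapply(p, bin, max),
    mean_predicted = tapply(p, bin, mean),
    mean_observed = tapply(o, bin, mean),
    row.names = NULL
  )
  class(out) <- c("calibration_table", "data.frame")
  out
}

#' Duration-matched pair set
#'
#' Two therapy cycles are comparable when their exposure durations are
#' roughly equal: the difference may be at most 6 months (0.5 years) when the
#' smaller of the two durations is below half a year, and at most 12 months
#' (1 year) otherwise.
#'
#' @param durations positive exposure durations in years.
#' @return A `matched_pairs` matrix with two columns (`i`, `j`), `i < j`,
#'   each unordered pair at most once.
#' @export
match_pairs <- function(durations) {
  stopifnot(all(durations > 0))
  n <- length(durations)
  if (n < 2) {
    return(structure(matrix(integer(), 0, 2, dimnames = list(NULL, c("i", "j"))),
                     class = c("matched_pairs", "matrix")))
  }
  dmin <- outer(durations, durations, pmin)
  diff <- abs(outer(durations, durations, `-`))
  ok <- diff <= ifelse(dmin < 0.5, 0.5, 1.0) & upper.tri(diff)
  ix <- which(ok, arr.ind = TRUE)
  m <- cbind(i = ix[, 1], j = ix[, 2])
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  structure(m, class = c("matched_pairs", "matrix"))
}

#' Concordance index over duration-matched pairs
#'
#' Among matched pairs with discordant binary outcomes, the fraction in which
#' the higher predicted score accompanies the event; prediction ties credit
#' 0.5 (Harrell's convention); pairs with equal outcomes are skipped.
#'
#' @param pairs a [match_pairs()] result (or any 2-column index matrix).
#' @param scores predicted scores (higher = more disease activity).
#' @param events observed binary outcomes (0/1 or logical).
#' @return The concordance in \[0, 1\], or `NA` (with a warning) when no
#'   outcome-discordant pair exists.
#' @export
c_index <- function(pairs, scores, events) {
  events <- as.integer(events)
  i <- pairs[, 1]; j <- pairs[, 2]
  use <- events[i] != events[j]
  if (!any(use)) {
    warning("no outcome-discordant matched pairs; concordance undefined")
    return(NA_real_)
  }
  i <- i[use]; j <- j[use]
  s_event <- ifelse(events[i] == 1L, scores[i], scores[j])
  s_none <- ifelse(events[i] == 1L, scores[j], scores[i])
  mean((s_event > s_none) + 0.5 * (s_event == s_none))
}

#' Mean squared error
#'
#' @param predictions predicted outcomes (relapse model: posterior mean
#'   count; CDP model: predicted event probability).
#' @param observations observed outcomes (count, or 0/1).
#' @export
mse <- function(predictions, observations) {
  if (length(predictions) != length(observations)) {
    stop("predictions and observations differ in length")
  }
  mean((predictions - observations)^2)
}

## Binarized observed outcome for the concordance analysis.
.binary_outcome <- function(cycles, response) {
  if (response == "relapse") as.integer(cycles$n_relapses >= 1)
  else as.integer(cycles$cdp)
}

## The three measures on one prediction set.
.measure_set <- function(cycles, pred, nll, response) {
  obs <- if (response == "relapse") cycles$n_relapses else as.integer(cycles$cdp)
  pairs <- match_pairs(cycles$index_duration)
  ci <- suppressWarnings(c_index(pairs, pred, .binary_outcome(cycles, response)))
  c(mse = mse(pred, obs), nll = sum(nll), c_index = ci,
    n = length(pred), n_pairs = nrow(pairs))
}

## default fitter: the MCMC fit, with non-convergence reported by the caller
.default_fitter <- function(spec, mcmc) {
  force(spec); force(mcmc)
  function(train, seed) {
    fit_hbglm(spec, train,
              chains = mcmc$chains %||% 2,
              iter = mcmc$iter %||% 500,
              warmup = mcmc$warmup %||% 500,
              seed = seed,
              on_nonconvergence = mcmc$on_nonconvergence %||% "error")
  }
}

#' Repeated k-fold cross-validation by patient
#'
#' Per repeat, patients are assigned to `k` folds at random (seeded); each
#' fold's cycles receive exactly one out-of-sample prediction (from the model
#' fitted without that fold) and exactly one in-sample prediction (from one
#' randomly selected model whose training data contained the fold). Measures
#' are computed on predictions for the observed index therapy only. Standard
#' errors over repeats are reported when `repeats > 1`. Folds whose fit fails
#' (e.g. non-convergence) drop the whole repeat with a warning.
#'
#' @param spec a [model_spec()] (ignored when `fitter` is given).
#' @param cohort filtered cycle data frame.
#' @param k folds (default 10).
#' @param repeats repetitions (default 40).
#' @param seed integer seed.
#' @param fitter `function(train, seed)` returning an object supporting
#'   [predict_mean()] / [pointwise_nll()]; defaults to [fit_hbglm()] with
#'   `mcmc` settings. Pass `function(train, seed) true_model(truth, resp)` to
#'   score the generating model.
#' @param mcmc list of MCMC settings for the default fitter
#'   (`chains`, `iter`, `warmup`, `on_nonconvergence`).
#' @return A `validation_report` data frame: per measure, out-of-sample and
#'   in-sample mean (and SE over repeats), with observation and matched-pair
#'   counts.
#' @export
run_kfold <- function(spec, cohort, k = 10, repeats = 40, seed = 1L,
                      fitter = NULL, mcmc = list()) {
  stopifnot(nrow(cohort) >= k)
  response <- spec$response
  fitter <- fitter %||% .default_fitter(spec, mcmc)
  per_rep <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    rep_seed <- seed + 1000L * (r - 1L)
    patients <- unique(cohort$patient_id)
    fold_of_patient <- withr_seed(rep_seed, {
      setNames(sample(rep_len(seq_len(k), length(patients))), patients)
    })
    fold <- fold_of_patient[as.character(cohort$patient_id)]
    models <- vector("list", k)
    failed <- FALSE
    for (f in seq_len(k)) {
      models[[f]] <- tryCatch(
        fitter(cohort[fold != f, , drop = FALSE], rep_seed + f),
        error = function(e) {
          warning("repeat ", r, ", fold ", f, " dropped: ",
                  conditionMessage(e))
          NULL
        }
      )
      if (is.null(models[[f]])) { failed <- TRUE; break }
    }
    if (failed) next
    oos_pred <- oos_nll <- is_pred <- is_nll <- numeric(nrow(cohort))
    is_fold <- withr_seed(rep_seed + 500L, {
      vapply(seq_len(k), function(f) sample(setdiff(seq_len(k), f), 1), 0L)
    })
    for (f in seq_len(k)) {
      ix <- which(fold == f)
      part <- cohort[ix, , drop = FALSE]
      oos_pred[ix] <- predict_mean(models[[f]], part)
      oos_nll[ix] <- pointwise_nll(models[[f]], part)
      m_in <- models[[is_fold[f]]]   # a model trained on fold f
      is_pred[ix] <- predict_mean(m_in, part)
      is_nll[ix] <- pointwise_nll(m_in, part)
    }
    per_rep[[r]] <- rbind(
      oos = .measure_set(cohort, oos_pred, oos_nll, response),
      ins = .measure_set(cohort, is_pred, is_nll, response)
    )
  }
  per_rep <- per_rep[!vapply(per_rep, is.null, TRUE)]
  if (length(per_rep) == 0) stop("all repeats failed")
  .validation_report("kfold", response, spec$complexity, per_rep)
}

.validation_report <- function(scheme, response, complexity, per_rep) {
  measures <- c("mse", "nll", "c_index")
  get <- function(row, m) vapply(per_rep, function(x) x[row, m], 0)
  repeated <- length(per_rep) > 1
  out <- data.frame(
    scheme = scheme, response = response, complexity = complexity,
    measure = measures,
    oos_mean = vapply(measures, function(m) mean(get("oos", m)), 0),
    oos_se = if (repeated) {
      vapply(measures, function(m) sd(get("oos", m)) / sqrt(length(per_rep)), 0)
    } else NA_real_,
    ins_mean = vapply(measures, function(m) mean(get("ins", m)), 0),
    ins_se = if (repeated) {
      vapply(measures, function(m) sd(get("ins", m)) / sqrt(length(per_rep)), 0)
    } else NA_real_,
    n = mean(get("oos", "n")),
    n_pairs = mean(get("oos", "n_pairs")),
    row.names = NULL
  )
  class(out) <- c("validation_report", "data.frame")
  out
}

#' Leave-one-site-out cross-validation
#'
#' Per clinical site, fits the model on every other site and predicts the
#' held-out site's cycles with the random intercepts zeroed, so each cycle is
#' predicted exactly once out of sample. In-sample predictions reuse, per
#' site, the model fitted without one randomly chosen other site. Also
#' returns the per-site NLL table.
#'
#' @inheritParams run_kfold
#' @return A list with `report` (a `validation_report`) and `per_site`
#'   (data frame: site, n cycles, summed out-of-sample NLL).
#' @export
run_leave_one_site_out <- function(spec, cohort, seed = 1L, fitter = NULL,
                                   mcmc = list()) {
  sites <- sort(unique(as.character(cohort$site_id)))
  if (length(sites) < 3) stop("at least 3 clinical sites are required")
  response <- spec$response
  fitter <- fitter %||% .default_fitter(spec, mcmc)
  models <- list()
  for (s in sites) {
    models[[s]] <- fitter(cohort[cohort$site_id != s, , drop = FALSE],
                          seed + match(s, sites))
  }
  oos_pred <- oos_nll <- is_pred <- is_nll <- numeric(nrow(cohort))
  other <- withr_seed(seed, {
    setNames(vapply(sites, function(s) sample(setdiff(sites, s), 1), ""), sites)
  })
  per_site <- data.frame(site = sites, n = NA_integer_, nll = NA_real_)
  for (s in sites) {
    ix <- which(cohort$site_id == s)
    part <- cohort[ix, , drop = FALSE]
    oos_pred[ix] <- predict_mean(models[[s]], part)
    oos_nll[ix] <- pointwise_nll(models[[s]], part)
    is_pred[ix] <- predict_mean(models[[other[[s]]]], part)
    is_nll[ix] <- pointwise_nll(models[[other[[s]]]], part)
    per_site[per_site$site == s, c("n", "nll")] <- c(length(ix), sum(oos_nll[ix]))
  }
  per_rep <- list(rbind(
    oos = .measure_set(cohort, oos_pred, oos_nll, response),
    ins = .measure_set(cohort, is_pred, is_nll, response)
  ))
  list(report = .validation_report("loso", response, spec$complexity, per_rep),
       per_site = per_site)
}

#' Test-set evaluation
#'
#' Fits on the development set and evaluates the three measures on the test
#' set (out-of-sample) and the development set (in-sample).
#'
#' @inheritParams run_kfold
#' @param train,test patient-disjoint cycle data frames from [split_test()].
#' @export
run_test_set <- function(spec, train, test, seed = 1L, fitter = NULL,
                         mcmc = list()) {
  fitter <- fitter %||% .default_fitter(spec, mcmc)
  model <- fitter(train, seed)
  per_rep <- list(rbind(
    oos = .measure_set(test, predict_mean(model, test),
                       pointwise_nll(model, test), spec$response),
    ins = .measure_set(train, predict_mean(model, train),
                       pointwise_nll(model, train), spec$response)
  ))
  list(report = .validation_report("test", spec$response, spec$complexity,
                                   per_rep),
       model = model)
}

#' Forecast-window stratified evaluation
#'
#' Computes the three measures within exposure-duration strata
#' (right-closed intervals, default (0, 0.5\], (0.5, 1.5\], ..., (4.5, 5.5\]
#' years); concordance pairs are matched within each stratum. Empty strata
#' are reported with `NA` measures.
#'
#' @param cycles evaluated cycles (with `index_duration`).
#' @param predictions per-cycle predicted outcomes.
#' @param nll per-cycle negative log-likelihoods.
#' @param response `"relapse"` or `"cdp"`.
#' @param windows list of `c(lo, hi)` interval bounds, right-closed.
#' @return Data frame of per-window measures and counts.
#' @export
window_stratified_eval <- function(cycles, predictions, nll, response,
                                   windows = list(c(0, 0.5), c(0.5, 1.5),
                                                  c(1.5, 2.5), c(2.5, 3.5),
                                                  c(3.5, 4.5), c(4.5, 5.5))) {
  rows <- lapply(windows, function(w) {
    ix <- which(cycles$index_duration > w[1] & cycles$index_duration <= w[2])
    if (length(ix) == 0) {
      return(data.frame(window_lo = w[1], window_hi = w[2], n = 0L,
                        mse = NA_real_, nll = NA_real_, c_index = NA_real_))
    }
    m <- .measure_set(cycles[ix, , drop = FALSE], predictions[ix], nll[ix],
                      response)
    data.frame(window_lo = w[1], window_hi = w[2], n = length(ix),
               mse = m[["mse"]], nll = m[["nll"]], c_index = m[["c_index"]])
  })
  do.call(rbind, rows)
}

#' Nested-model comparison
#'
#' Runs the chosen validation scheme for the non-personalized, prognostic and
#' predictive complexities of one or both responses and stacks the reports.
#'
#' @param cohort filtered cycle data frame (development set for
#'   `scheme = "test"` use `train`/`test`).
#' @param responses character vector among `"relapse"`, `"cdp"`.
#' @param scheme `"kfold"` or `"test"`.
#' @param train,test used when `scheme = "test"`.
#' @param prior optional shared [prior_config()] overrides per response.
#' @inheritParams run_kfold
#' @export
compare_nested <- function(cohort = NULL, responses = c("relapse", "cdp"),
                           scheme = c("kfold", "test"), k = 10, repeats = 5,
                           train = NULL, test = NULL, seed = 1L,
                           mcmc = list()) {
  scheme <- match.arg(scheme)
  complexities <- c("non_personalized", "prognostic", "predictive")
  out <- list()
  for (resp in responses) {
    for (cx in complexities) {
      spec <- model_spec(resp, cx)
      rep <- if (scheme == "kfold") {
        run_kfold(spec, cohort, k = k, repeats = repeats, seed = seed,
                  mcmc = mcmc)
      } else {
        run_test_set(spec, train, test, seed = seed, mcmc = mcmc)$report
      }
      out[[paste(resp, cx)]] <- rep
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Prior and sample-size sensitivity of the therapy ranking
#'
#' Refits the model under each prior variant and/or training subsample and
#' reports, per variant, the fraction of cycles whose highest-ranked therapy
#' (DMT*) is unchanged relative to the baseline fit, along with the cycles
#' whose baseline predictions were near-tied (where rank flips are expected).
#'
#' @param spec a [model_spec()] (typically predictive).
#' @param cohort filtered cycle data frame.
#' @param prior_scales numeric vector of common prior-scale multipliers
#'   (1 = the default priors).
#' @param subsample_fractions numeric vector of training fractions (1 = all).
#' @param seed integer seed.
#' @param tie_tol near-tie tolerance on the prediction summary scale.
#' @inheritParams run_kfold
#' @return Data frame: variant description, agreement fraction, fraction of
#'   near-tied cycles, n.
#' @export
sensitivity_scan <- function(spec, cohort, prior_scales = c(1, 2),
                             subsample_fractions = 1, seed = 1L,
                             tie_tol = 1e-6, mcmc = list()) {
  base_fit <- .default_fitter(spec, mcmc)(cohort, seed)
  base_rank <- rank_therapies(counterfactual_grid(base_fit, cohort),
                              tie_tol = tie_tol)
  rows <- list()
  for (ps in prior_scales) {
    for (fr in subsample_fractions) {
      train <- cohort
      if (fr < 1) {
        keep <- withr_seed(seed + round(1000 * fr), {
          sample(nrow(cohort), round(fr * nrow(cohort)))
        })
        train <- cohort[sort(keep), , drop = FALSE]
      }
      v_spec <- spec
      v_spec$prior <- scale_prior(spec$prior, ps)
      fit <- if (ps == 1 && fr == 1) base_fit
             else .default_fitter(v_spec, mcmc)(train, seed)
      rk <- rank_therapies(counterfactual_grid(fit, cohort), tie_tol = tie_tol)
      rows[[length(rows) + 1]] <- data.frame(
        prior_scale = ps, subsample = fr,
        agreement = mean(rk$dmt_star == base_rank$dmt_star),
        tied_fraction = mean(base_rank$tie | rk$tie),
        n = nrow(cohort)
      )
    }
  }
  do.call(rbind, rows)
}
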