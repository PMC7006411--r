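## Synthetic registry generator: known fixed effects, therapy interactions,
## site random intercepts, exposure-offset NB relapse counts and Bernoulli
## CDP events. The generator writes the same cycle schema the cohort module
## reads and returns the realized ground truth for recovery and validation
## tests.

## Default true coefficients, on the design scale (continuous predictors
## standardized, reference levels as in build_design). Values chosen once to
## emulate a plausible adult RRMS registry: annualized relapse rate ~0.45 on
## the reference therapy, lower rates on the high-efficacy therapies
## (Natalizumab, Fingolimod), recent relapse activity the strongest
## individual predictor, and a CDP risk of ~10-15% over a typical cycle.
default_beta_relapse <- function() {
  c("(Intercept)" = log(0.45),
    "index_dmtFTY" = -0.25, "index_dmtGA" = 0.10, "index_dmtIF" = 0.05,
    "index_dmtNA." = -0.50, "index_dmtTERI" = 0.15,
    "age" = -0.15, "genderM" = -0.05, "edss_baseline" = 0.10,
    "second_line" = 0.20, "relapses_count" = 0.30,
    "relapse_distance" = -0.10, "diagnosis_distance" = -0.05,
    "dmts_count" = 0.10, "current_duration" = -0.10,
    "index_dmtNA.:relapses_count" = -0.15,
    "index_dmtFTY:second_line" = -0.10)
}

default_beta_cdp <- function() {
  c("(Intercept)" = -2.5,
    "index_dmtFTY" = -0.20, "index_dmtGA" = 0.05, "index_dmtIF" = 0.05,
    "index_dmtNA." = -0.30, "index_dmtTERI" = 0.10,
    "age" = 0.10, "genderM" = 0.05, "edss_baseline" = 0.30,
    "second_line" = 0.20, "relapses_count" = 0.15,
    "index_dmtNA.:diagnosis_distance" = 0.10)
}

#' Synthetic-registry configuration
#'
#' Defaults emulate the modelled population: ~3400 one-cycle-per-patient
#' therapy cycles across 78 clinical sites, six index therapies, site
#' random-intercept sd 0.25, NB shape 1.5. True coefficients are named vectors
#' on the design scale (names matching [build_design()] columns; omitted terms
#' are zero). All marginals are overridable.
#'
#' @param n_patients,n_sites cohort dimensions (`n_sites >= 2`).
#' @param site_sd sd of the clinical-site random intercepts (>= 0).
#' @param dispersion NB shape (> 0); variance is `mu + mu^2 / dispersion`.
#' @param beta_relapse,beta_cdp named true-coefficient vectors.
#' @param assignment `"random"` (uniform therapy allocation) or `"covariate"`
#'   (sicker patients steered towards second-line therapies; used for
#'   confounding tests).
#' @param complexity design complexity the truth lives in.
#' @param seed integer seed; same seed, same registry, byte for byte.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 3400, n_sites = 78, site_sd = 0.25,
                       dispersion = 1.5,
                       beta_relapse = default_beta_relapse(),
                       beta_cdp = default_beta_cdp(),
                       assignment = c("random", "covariate"),
                       complexity = "predictive",
                       seed = 1L) {
  assignment <- match.arg(assignment)
  stopifnot(n_sites >= 2, site_sd >= 0, dispersion > 0, n_patients >= n_sites)
  structure(
    list(n_patients = n_patients, n_sites = n_sites, site_sd = site_sd,
         dispersion = dispersion, beta_relapse = beta_relapse,
         beta_cdp = beta_cdp, assignment = assignment,
         complexity = complexity, seed = as.integer(seed)),
    class = "sim_config"
  )
}

.round_half <- function(x) round(x * 2) / 2

## align a named coefficient vector to design columns (missing terms -> 0)
.align_coef <- function(coef, cols) {
  out <- setNames(numeric(length(cols)), cols)
  unknown <- setdiff(names(coef), cols)
  if (length(unknown) > 0) {
    stop("true coefficients name unknown design columns: ",
         paste(unknown, collapse = ", "))
  }
  out[names(coef)] <- coef
  out
}

#' Generate a synthetic registry
#'
#' Draws covariates from documented RRMS-like marginals, assigns clinical
#' sites and index therapies, realizes site intercepts
#' `u_s ~ Normal(0, site_sd^2)`, and simulates outcomes from the models the
#' fitting stage assumes: relapse counts
#' `NB(mean = T * exp(x'beta + u_s), shape = dispersion)` and CDP events
#' `Bernoulli(plogis(x'gamma + u_s + log T))`. EDSS trajectories consistent
#' with the baseline EDSS and the simulated CDP labels are emitted alongside.
#'
#' @param config a [sim_config()].
#' @param trajectories also build per-patient EDSS trajectories (default
#'   `TRUE`).
#' @return A list with `cycles` (cohort-schema data frame), `trajectories`
#'   (named list of [edss_trajectory()]; `NULL` if not requested) and `truth`
#'   (class `ground_truth`: realized site intercepts, aligned coefficient
#'   vectors, per-cycle true linear predictors, and expected outcomes per
#'   therapy with intercepts zeroed).
#' @export
generate_registry <- function(config, trajectories = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_sites < 2) stop("n_sites must be at least 2")
  n <- config$n_patients
  set.seed(config$seed)

  site_w <- rgamma(config$n_sites, shape = 2)
  site_id <- sample(seq_len(config$n_sites), n, replace = TRUE,
                    prob = site_w / sum(site_w))
  u <- if (config$site_sd > 0) rnorm(config$n_sites, 0, config$site_sd)
       else rep(0, config$n_sites)

  age <- pmin(pmax(rnorm(n, 41, 10.5), 18), 75)
  gender <- ifelse(runif(n) < 0.71, "F", "M")
  edss_baseline <- pmin(.round_half(rbeta(n, 1.8, 3.8) * 6.5), 6.5)
  diagnosis_distance <- pmax(rgamma(n, shape = 1.8, scale = 4), 0.05)
  relapse_distance <- pmax(rexp(n, rate = 1 / 0.8), 0.02)
  relapses_count <- rpois(n, 1.0)
  dmts_count <- rpois(n, 1.2)
  second_line <- dmts_count > 0 & runif(n) < 0.35
  current_dmt <- ifelse(dmts_count == 0, "NONE",
                        sample(DMT_LEVELS, n, replace = TRUE))
  current_duration <- ifelse(current_dmt == "NONE", 0,
                             rgamma(n, shape = 1.5, scale = 1))
  index_duration <- pmin(pmax(rgamma(n, shape = 1.6, scale = 1.125), 0.1), 6)

  if (config$assignment == "random") {
    index_dmt <- sample(DMT_LEVELS, n, replace = TRUE)
  } else {
    z_rel <- (relapses_count - mean(relapses_count)) /
      max(sd(relapses_count), 1e-8)
    z_edss <- (edss_baseline - mean(edss_baseline)) /
      max(sd(edss_baseline), 1e-8)
    sev <- 0.8 * z_rel + 0.5 * z_edss
    index_dmt <- vapply(seq_len(n), function(i) {
      sc <- setNames(rep(0, 6), DMT_LEVELS)
      sc[SECOND_LINE_DMTS] <- sev[i]
      w <- exp(sc - max(sc))
      sample(DMT_LEVELS, 1, prob = w / sum(w))
    }, character(1))
  }

  cycles <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    site_id = sprintf("S%03d", site_id),
    index_dmt = index_dmt, current_dmt = current_dmt,
    age = age, gender = gender, edss_baseline = edss_baseline,
    diagnosis_distance = diagnosis_distance,
    relapse_distance = relapse_distance,
    relapses_count = relapses_count, dmts_count = dmts_count,
    second_line = second_line, current_duration = current_duration,
    index_duration = index_duration,
    cycle_start = 0, cycle_end = round(index_duration * 365.25),
    stringsAsFactors = FALSE
  )

  spec <- model_spec("relapse", config$complexity)
  design <- build_design(cycles, spec)
  beta_r <- .align_coef(config$beta_relapse, colnames(design$X))
  beta_c <- .align_coef(config$beta_cdp, colnames(design$X))

  eta_r <- as.numeric(design$X %*% beta_r) + u[site_id] + design$offset
  eta_c <- as.numeric(design$X %*% beta_c) + u[site_id] + design$offset
  cycles$n_relapses <- rnbinom(n, size = config$dispersion, mu = exp(eta_r))
  p_cdp <- plogis(eta_c)
  cycles$cdp <- runif(n) < p_cdp

  ## expected outcome per therapy with intercepts zeroed (the ranking truth)
  mu_by_dmt <- p_by_dmt <- matrix(NA_real_, n, length(DMT_LEVELS),
                                  dimnames = list(NULL, DMT_LEVELS))
  for (d in DMT_LEVELS) {
    cf <- cycles
    cf$index_dmt <- d
    Xd <- build_design(cf, spec, transforms = design$transforms,
                       site_levels = design$site_levels,
                       columns = design$columns)$X
    mu_by_dmt[, d] <- exp(as.numeric(Xd %*% beta_r) + design$offset)
    p_by_dmt[, d] <- plogis(as.numeric(Xd %*% beta_c) + design$offset)
  }

  truth <- structure(
    list(
      beta_relapse = beta_r, beta_cdp = beta_c,
      u = setNames(u, sprintf("S%03d", seq_len(config$n_sites))),
      site_sd = config$site_sd, dispersion = config$dispersion,
      transforms = design$transforms, site_levels = design$site_levels,
      complexity = config$complexity,
      patient_id = cycles$patient_id,
      eta_relapse = eta_r, eta_cdp = eta_c,
      mu_relapse_observed = exp(as.numeric(design$X %*% beta_r) + design$offset),
      p_cdp_observed = plogis(as.numeric(design$X %*% beta_c) + design$offset),
      mu_by_dmt = mu_by_dmt, p_by_dmt = p_by_dmt
    ),
    class = "ground_truth"
  )

  traj <- if (trajectories) .build_trajectories(cycles) else NULL
  list(cycles = cycles, trajectories = traj, truth = truth)
}

## EDSS trajectories consistent with baseline EDSS and CDP labels: a valid
## baseline measurement shortly before the cycle start, stable follow-up, and
## for CDP cycles a sustained + confirmed worsening at the proper threshold.
.build_trajectories <- function(cycles) {
  out <- vector("list", nrow(cycles))
  for (r in seq_len(nrow(cycles))) {
    ref <- min(cycles$edss_baseline[r], 6)
    start <- cycles$cycle_start[r]
    end <- max(cycles$cycle_end[r], start + 240)
    relapse <- start - round(cycles$relapse_distance[r] * 365.25)
    thr <- if (ref <= 5.5) 1.0 else 0.5
    ## the baseline measurement must itself be >= 84 days post-relapse; with
    ## the relapse at least a week before the start this stays within the
    ## +91-day window and closer to the start than any later measurement
    base_t <- max(start - 30, relapse + 84)
    times <- base_t
    edss <- ref
    if (isTRUE(cycles$cdp[r])) {
      t0 <- start + min(120, (end - start) %/% 3)
      times <- c(times, t0, t0 + 120)
      edss <- c(edss, ref + thr, ref + thr)
    } else {
      times <- c(times, start + 100, start + 220)
      edss <- c(edss, ref, ref)
    }
    out[[r]] <- edss_trajectory(cycles$patient_id[r], times,
                                pmin(edss, 10), relapse)
  }
  names(out) <- as.character(cycles$patient_id)
  out
}

#' Generate labelled EDSS trajectories for the progression detector
#'
#' Emits EDSS series constructed to contain or avoid a confirmed disability
#' progression, with the truth label fixed by construction (never by running
#' the detector). Templates cover the rule's edge cases: genuine sustained +
#' confirmed progressions at both thresholds (baseline above/below 5.5),
#' transient rises that revert before confirmation, rises never confirmed by
#' a later measurement, sub-threshold (0.5-point) rises below EDSS 5.5, flat
#' series, and rises whose only confirming measurement is invalidated by the
#' 84-days-post-relapse rule.
#'
#' @param n number of trajectories.
#' @param seed integer seed.
#' @param cycle_start,cycle_end cycle window (days).
#' @return List with `trajectories`, logical `labels`, `templates`,
#'   `cycle_start`, `cycle_end`.
#' @export
generate_trajectories_with_cdp <- function(n = 500, seed = 1L,
                                           cycle_start = 0, cycle_end = 730) {
  set.seed(seed)
  templates <- c("progression", "high_baseline_progression", "transient_rise",
                 "unconfirmed_rise", "subthreshold_rise", "stable",
                 "post_relapse_invalid_confirmation")
  tpl <- sample(templates, n, replace = TRUE)
  trajectories <- vector("list", n)
  labels <- logical(n)
  for (i in seq_len(n)) {
    ref <- sample(seq(1, 5, by = 0.5), 1)
    ## onset strictly after the +91-day baseline window, so the pre-start
    ## measurement is always the cycle's baseline EDSS
    t0 <- cycle_start + sample(95:300, 1)
    gap <- sample(91:200, 1)          # onset-to-confirmation distance
    base_t <- cycle_start - sample(10:120, 1)
    relapse <- numeric()
    switch(tpl[i],
      progression = {
        times <- c(base_t, t0, t0 + gap)
        edss <- c(ref, ref + 1, ref + 1)
        labels[i] <- TRUE
      },
      high_baseline_progression = {
        ref <- 6
        times <- c(base_t, t0, t0 + gap)
        edss <- c(ref, ref + 0.5, ref + 0.5)
        labels[i] <- TRUE
      },
      transient_rise = {
        times <- c(base_t, t0, t0 + sample(20:60, 1), t0 + gap)
        edss <- c(ref, ref + 1, ref, ref)
        labels[i] <- FALSE
      },
      unconfirmed_rise = {
        times <- c(base_t, t0)
        edss <- c(ref, ref + 1)
        labels[i] <- FALSE
      },
      subthreshold_rise = {
        times <- c(base_t, t0, t0 + gap)
        edss <- c(ref, ref + 0.5, ref + 0.5)
        labels[i] <- FALSE
      },
      stable = {
        times <- c(base_t, t0, t0 + gap)
        edss <- c(ref, ref, ref)
        labels[i] <- FALSE
      },
      post_relapse_invalid_confirmation = {
        tc <- t0 + gap
        times <- c(base_t, t0, tc)
        edss <- c(ref, ref + 1, ref + 1)
        relapse <- tc - sample(10:83, 1)  # confirmation < 84 d post relapse
        if (relapse <= t0) relapse <- t0 + 1
        labels[i] <- FALSE
      }
    )
    trajectories[[i]] <- edss_trajectory(sprintf("T%05d", i), times,
                                         pmin(edss, 10), relapse)
  }
  list(trajectories = trajectories, labels = labels, templates = tpl,
       cycle_start = cycle_start, cycle_end = cycle_end)
}

#' The generator's true model as a prediction object
#'
#' Wraps a `ground_truth` so that it exposes the same prediction interface as
#' an MCMC fit ([predict_mean()], [pointwise_nll()]); used to score the
#' generating model itself, e.g. in the no-overfitting limit of the
#' validation schemes.
#'
#' @param truth a `ground_truth` from [generate_registry()].
#' @param response `"relapse"` or `"cdp"`.
#' @export
true_model <- function(truth, response = c("relapse", "cdp")) {
  response <- match.arg(response)
  structure(list(truth = truth, response = response), class = "true_model")
}

.truth_rows <- function(model, cycles) {
  ix <- match(as.character(cycles$patient_id), model$truth$patient_id)
  if (anyNA(ix)) stop("cycles not present in the ground truth")
  ix
}

#' @export
predict_mean.true_model <- function(model, cycles) {
  ix <- .truth_rows(model, cycles)
  if (model$response == "relapse") model$truth$mu_relapse_observed[ix]
  else model$truth$p_cdp_observed[ix]
}

#' @export
pointwise_nll.true_model <- function(model, cycles) {
  ix <- .truth_rows(model, cycles)
  if (model$response == "relapse") {
    -dnbinom(as.integer(cycles$n_relapses), size = model$truth$dispersion,
             mu = model$truth$mu_relapse_observed[ix], log = TRUE)
  } else {
    -dbinom(as.integer(cycles$cdp), 1L, model$truth$p_cdp_observed[ix],
            log = TRUE)
  }
}

#' Counterfactual summaries of the true model
#'
#' Expected outcome per therapy (intercepts zeroed) as a
#' `counterfactual_predictions` object, rankable with [rank_therapies()].
#'
#' @inheritParams true_model
#' @param cycles cycle data frame (subset of the generated registry).
#' @export
true_counterfactuals <- function(truth, cycles, response = c("relapse", "cdp")) {
  response <- match.arg(response)
  ix <- match(as.character(cycles$patient_id), truth$patient_id)
  m <- if (response == "relapse") truth$mu_by_dmt[ix, , drop = FALSE]
       else truth$p_by_dmt[ix, , drop = FALSE]
  structure(list(summary = m, response = response,
                 duration = cycles$index_duration),
            class = "counterfactual_predictions")
}
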