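## Counterfactual posterior prediction (random intercepts zeroed) and
## pointwise log-likelihood.

## n x D matrix of linear predictors (u = 0) for cycles under the fit's
## coding; duration enters as a log offset.
.eta_draws <- function(fit, cycles, duration) {
  spec <- fit$spec
  design <- build_design(cycles, spec, transforms = fit$design$transforms,
                         site_levels = fit$design$site_levels,
                         columns = fit$design$columns)
  eta <- design$X %*% t(fit$draws$beta)
  eta + log(duration)
}

#' Counterfactual posterior predictions for one therapy
#'
#' For every cycle, sets the index therapy (and all its interaction columns)
#' to `dmt`, zeroes the clinical-site random intercept, applies the offset
#' `log(duration)`, and evaluates the posterior predictive distribution under
#' every posterior draw. A new patient thereby receives identical predictions
#' regardless of clinical site.
#'
#' Summaries are computed analytically from the per-draw means: the mean
#' predicted outcome (relapse count, or CDP probability), the fraction of
#' predictive mass on zero relapses (relapse model) and on no CDP (CDP
#' model). Set `sample_draws = TRUE` to additionally return sampled outcome
#' draws.
#'
#' @param fit an [fit_hbglm()] result.
#' @param cycles cycle data frame.
#' @param dmt one of [DMT_LEVELS].
#' @param duration exposure in years (scalar or per-cycle); defaults to the
#'   observed `index_duration`.
#' @param sample_draws return an n x draws matrix of sampled outcomes.
#' @return A list of class `cf_pred` with `summaries` (data frame: `mean`,
#'   and `p_zero` or `p_no_cdp`), the requested `dmt`, `duration`, `response`
#'   and optionally `draws`.
#' @export
predict_counterfactual <- function(fit, cycles, dmt, duration = NULL,
                                   sample_draws = FALSE) {
  stopifnot(dmt %in% DMT_LEVELS)
  duration <- duration %||% cycles$index_duration
  if (any(duration <= 0)) stop("duration must be positive")
  cf <- cycles
  cf$index_dmt <- dmt
  eta <- .eta_draws(fit, cf, duration)
  if (fit$spec$response == "relapse") {
    mu <- exp(eta)
    phi <- rep(fit$draws$phi, each = nrow(mu))
    summaries <- data.frame(
      mean = rowMeans(mu),
      p_zero = rowMeans((phi / (phi + mu))^phi)
    )
  } else {
    p <- plogis(eta)
    summaries <- data.frame(mean = rowMeans(p), p_no_cdp = rowMeans(1 - p))
  }
  out <- list(summaries = summaries, dmt = dmt, duration = duration,
              response = fit$spec$response)
  if (sample_draws) {
    if (fit$spec$response == "relapse") {
      out$draws <- matrix(rnbinom(length(mu), size = phi, mu = mu),
                          nrow = nrow(mu))
    } else {
      out$draws <- matrix(rbinom(length(p), 1L, p), nrow = nrow(p))
    }
  }
  class(out) <- "cf_pred"
  out
}

#' Counterfactual predictions across all six therapies
#'
#' Runs [predict_counterfactual()] for each therapy at a common duration and
#' collects the ranking summary (mean predicted relapse count, or predicted
#' CDP probability) into an n x 6 matrix.
#'
#' @inheritParams predict_counterfactual
#' @param dmts therapies to predict for (default all six).
#' @return An object of class `counterfactual_predictions`: list with
#'   `summary` (n x length(dmts) matrix), `response`, `duration`.
#' @export
counterfactual_grid <- function(fit, cycles, duration = NULL,
                                dmts = DMT_LEVELS) {
  duration <- duration %||% cycles$index_duration
  cols <- lapply(dmts, function(d) {
    predict_counterfactual(fit, cycles, d, duration)$summaries$mean
  })
  m <- do.call(cbind, cols)
  colnames(m) <- dmts
  structure(list(summary = m, response = fit$spec$response,
                 duration = duration),
            class = "counterfactual_predictions")
}

## running log-sum-exp merge of two vectors
.lse2 <- function(a, b) {
  m <- pmax(a, b)
  r <- m + log(exp(a - m) + exp(b - m))
  r[is.infinite(m)] <- m[is.infinite(m)]
  r
}

#' Pointwise negative log-likelihood
#'
#' Computes, per cycle, minus the log of the posterior-draw average of the
#' sampling density at the observed outcome (the log pointwise predictive
#' density with flipped sign); the population total is the sum over cycles.
#' Predictions use zeroed random intercepts by default, matching the
#' counterfactual prediction contract; set `zero_intercepts = FALSE` to use
#' the fitted site intercepts.
#'
#' @param fit an `hbglm_fit`.
#' @param cycles cycle data frame with observed outcomes.
#' @param zero_intercepts zero the site random intercepts (default `TRUE`).
#' @return List with `pointwise` (per-cycle NLL) and `total`.
#' @export
pointwise_log_lik <- function(fit, cycles, zero_intercepts = TRUE) {
  y <- response_vector(cycles, fit$spec)
  eta <- .eta_draws(fit, cycles, cycles$index_duration)
  if (!zero_intercepts) {
    site <- match(as.character(cycles$site_id), fit$design$site_levels)
    if (anyNA(site)) stop("unseen clinical site; use zero_intercepts = TRUE")
    eta <- eta + t(fit$draws$u)[site, , drop = FALSE]
  }
  D <- ncol(eta)
  lse <- rep(-Inf, nrow(eta))
  chunk <- 500L
  for (start in seq(1L, D, by = chunk)) {
    ix <- start:min(start + chunk - 1L, D)
    if (fit$spec$response == "relapse") {
      ll <- dnbinom(y, size = rep(fit$draws$phi[ix], each = length(y)),
                    mu = exp(eta[, ix, drop = FALSE]), log = TRUE)
    } else {
      p <- plogis(eta[, ix, drop = FALSE])
      ll <- dbinom(y, 1L, p, log = TRUE)
    }
    dim(ll) <- c(length(y), length(ix))
    lse <- .lse2(lse, apply(ll, 1, function(v) {
      m <- max(v); m + log(sum(exp(v - m)))
    }))
  }
  pointwise <- -(lse - log(D))
  list(pointwise = pointwise, total = sum(pointwise))
}

## ---- prediction interface used by the validation suite -------------------
## Both the MCMC fit and the generator's true model expose:
##   predict_mean(model, cycles): mean predicted outcome at the observed
##     index therapy and duration, random intercepts zeroed
##   pointwise_nll(model, cycles): per-cycle negative log-likelihood

#' Mean predicted outcome at the observed index therapy
#' @param model a fitted model (`hbglm_fit` or `true_model`).
#' @param cycles cycle data frame.
#' @export
predict_mean <- function(model, cycles) UseMethod("predict_mean")

#' Per-cycle negative log-likelihood at the observed index therapy
#' @inheritParams predict_mean
#' @export
pointwise_nll <- function(model, cycles) UseMethod("pointwise_nll")

#' @export
predict_mean.hbglm_fit <- function(model, cycles) {
  eta <- .eta_draws(model, cycles, cycles$index_duration)
  if (model$spec$response == "relapse") rowMeans(exp(eta))
  else rowMeans(plogis(eta))
}

#' @export
pointwise_nll.hbglm_fit <- function(model, cycles) {
  pointwise_log_lik(model, cycles)$pointwise
}
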