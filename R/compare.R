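## Personalized therapy ranking (DMT*) and the propensity-score-weighted
## comparison of observed outcomes between receivers and non-receivers of the
## highest ranked therapy.

#' Rank therapies per cycle
#'
#' Orders the six therapies ascending by the predicted summary (mean
#' predicted relapse count for the relapse model; predicted CDP probability
#' for the CDP model); DMT* is the first. Ties are broken alphabetically
#' (deterministic) and flagged when the two best summaries differ by less
#' than `tie_tol`.
#'
#' @param preds a `counterfactual_predictions` object
#'   ([counterfactual_grid()] or [true_counterfactuals()]).
#' @param tie_tol near-tie tolerance on the summary scale (default 1e-6).
#' @return A `ranking_result` data frame: per cycle, `dmt_star`, the
#'   predicted summary per therapy, the full ranked `order` (comma-separated)
#'   and a `tie` flag.
#' @export
rank_therapies <- function(preds, tie_tol = 1e-6) {
  m <- preds$summary
  if (anyNA(m)) stop("missing therapy prediction")
  ## columns ordered alphabetically, so which.min's first-index rule is the
  ## alphabetical tie-break
  stopifnot(!is.unsorted(colnames(m)))
  star_ix <- apply(m, 1, which.min)
  sorted2 <- apply(m, 1, function(v) sort(v)[2])
  best <- m[cbind(seq_len(nrow(m)), star_ix)]
  out <- data.frame(
    dmt_star = colnames(m)[star_ix],
    tie = (sorted2 - best) < tie_tol,
    order = apply(m, 1, function(v) paste(colnames(m)[order(v)], collapse = ",")),
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(m))
  attr(out, "response") <- preds$response
  class(out) <- c("ranking_result", "data.frame")
  out
}

#' EDSS categories for the propensity model
#'
#' Default categorization of the baseline EDSS into three disability strata
#' (0-1.5, 2.0-3.5, 4.0-6.0); breaks configurable.
#'
#' @param edss numeric EDSS values.
#' @param breaks right-closed upper bounds of the leading categories.
#' @export
edss_category <- function(edss, breaks = c(1.5, 3.5)) {
  cut(edss, breaks = c(-Inf, breaks, Inf), labels = FALSE)
}

## weighted standardized mean difference of one covariate between two groups
.smd <- function(x, g, w) {
  wm <- function(v, wt) sum(v * wt) / sum(wt)
  m1 <- wm(x[g], w[g]); m0 <- wm(x[!g], w[!g])
  s <- sqrt((var(x[g]) + var(x[!g])) / 2)
  if (s == 0) return(0)
  abs(m1 - m0) / s
}

#' Propensity-score ATE weights
#'
#' Fits a logistic propensity model for receiving the highest ranked therapy
#' on age, relapses count, categorized EDSS and diagnosis distance, and
#' returns average-treatment-effect weights (received: `1/e(x)`; not
#' received: `1/(1-e(x))`), normalized to mean one, so both groups are
#' reweighted towards the pooled population. Balance diagnostics
#' (standardized mean differences before/after, effective sample sizes) are
#' attached.
#'
#' @param cycles cycle data frame.
#' @param received logical: cycle's index therapy equals its DMT*.
#' @param covariates covariate column names; `edss_baseline` is categorized
#'   via [edss_category()] before entering the model.
#' @return Numeric weight vector with attributes `balance` (data frame of
#'   SMDs before/after) and `ess` (effective sample size per group).
#' @export
estimate_weights <- function(cycles, received,
                             covariates = c("age", "relapses_count",
                                            "edss_baseline",
                                            "diagnosis_distance")) {
  stopifnot(length(received) == nrow(cycles))
  if (!any(received) || all(received)) {
    stop("both groups (received DMT* and not) must be nonempty")
  }
  df <- cycles[, covariates, drop = FALSE]
  if ("edss_baseline" %in% covariates) {
    df$edss_baseline <- factor(edss_category(df$edss_baseline))
  }
  ## covariates without variation carry no information and break the glm
  df <- df[, vapply(df, function(v) length(unique(v)) > 1, TRUE), drop = FALSE]
  df$.received <- as.integer(received)
  ps_fit <- glm(.received ~ ., data = df, family = binomial())
  e <- fitted(ps_fit)
  if (any(e < 1e-8 | e > 1 - 1e-8)) {
    stop("propensity model separates the groups (fitted probabilities at 0/1)")
  }
  w <- ifelse(received, 1 / e, 1 / (1 - e))
  w <- w / mean(w)
  num <- cycles[, covariates, drop = FALSE]
  if ("edss_baseline" %in% covariates) {
    num$edss_baseline <- edss_category(num$edss_baseline)
  }
  balance <- data.frame(
    covariate = covariates,
    smd_before = vapply(num, .smd, 0, g = received, w = rep(1, nrow(cycles))),
    smd_after = vapply(num, .smd, 0, g = received, w = w),
    row.names = NULL
  )
  attr(w, "balance") <- balance
  attr(w, "ess") <- c(received = sum(w[received])^2 / sum(w[received]^2),
                      not_received = sum(w[!received])^2 / sum(w[!received]^2))
  w
}

## HC0 sandwich (design-based) covariance for a weighted GLM. `mu_eta` and
## `variance` follow the family at the fitted values; `w` are the propensity
## weights used as prior weights.
.sandwich_vcov <- function(X, y, mu, w, variance, mu_eta) {
  score <- X * (w * (y - mu) * mu_eta / variance)
  info <- crossprod(X, X * (w * mu_eta^2 / variance))
  bread <- solve(info)
  bread %*% crossprod(score) %*% bread
}

#' Survey-weighted outcome GLM for the adherence comparison
#'
#' Fits the weighted outcome model with an indicator for having received the
#' highest ranked therapy and a log-duration offset: a negative-binomial GLM
#' for observed relapse counts, or a quasi-binomial GLM for observed CDP
#' events. A negative slope on the indicator means lower disease activity
#' among receivers. Standard errors are design-based (HC0 sandwich, treating
#' the propensity weights as survey weights) and the p-value is a Wald test
#' on the slope.
#'
#' @param cycles cycle data frame (positive `index_duration`).
#' @param received logical took-DMT* indicator.
#' @param weights ATE weights from [estimate_weights()].
#' @param response `"relapse"` or `"cdp"`.
#' @return List with `slope`, `se`, `p_value`, `n_received`,
#'   `n_not_received` and the underlying `fit`.
#' @export
weighted_outcome_glm <- function(cycles, received, weights,
                                 response = c("relapse", "cdp")) {
  response <- match.arg(response)
  if (any(cycles$index_duration <= 0)) stop("non-positive cycle duration")
  df <- data.frame(
    y = if (response == "relapse") as.integer(cycles$n_relapses)
        else as.integer(cycles$cdp),
    took = as.integer(received),
    off = log(cycles$index_duration),
    w = weights
  )
  X <- cbind("(Intercept)" = 1, took = df$took)
  if (response == "relapse") {
    fit <- suppressWarnings(
      MASS::glm.nb(y ~ took + offset(off), data = df, weights = w)
    )
    mu <- fitted(fit)
    theta <- fit$theta
    V <- .sandwich_vcov(X, df$y, mu, df$w, variance = mu + mu^2 / theta,
                        mu_eta = mu)
  } else {
    fit <- suppressWarnings(
      glm(y ~ took + offset(off), data = df, family = quasibinomial(),
          weights = w)
    )
    mu <- fitted(fit)
    V <- .sandwich_vcov(X, df$y, mu, df$w, variance = mu * (1 - mu),
                        mu_eta = mu * (1 - mu))
  }
  slope <- coef(fit)[["took"]]
  se <- sqrt(V["took", "took"])
  list(slope = slope, se = se,
       p_value = 2 * pnorm(-abs(slope / se)),
       n_received = sum(received), n_not_received = sum(!received),
       fit = fit)
}

#' Adherence comparison across DMT* levels
#'
#' For each therapy appearing as some patient's highest ranked therapy,
#' splits its cycles into receivers (index therapy equals DMT*) and
#' non-receivers, applies the eligibility rules (both groups present with at
#' least `min_n` observations each), computes ATE weights and the weighted
#' outcome GLM, and reports one row per DMT* level. Ineligible levels are
#' kept in the table with the exclusion reason.
#'
#' @param cycles cycle data frame.
#' @param ranking a [rank_therapies()] result aligned with `cycles`.
#' @param response `"relapse"` or `"cdp"`.
#' @param min_n per-group observation floor (default 10).
#' @param covariates propensity covariates (see [estimate_weights()]).
#' @return A `weighted_comparison` data frame with columns `dmt_star`,
#'   `slope`, `p_value`, `n_received`, `n_not_received`, `excluded_reason`.
#' @export
run_adherence_comparison <- function(cycles, ranking,
                                     response = c("relapse", "cdp"),
                                     min_n = 10,
                                     covariates = c("age", "relapses_count",
                                                    "edss_baseline",
                                                    "diagnosis_distance")) {
  response <- match.arg(response)
  stopifnot(nrow(ranking) == nrow(cycles))
  rows <- list()
  for (d in intersect(DMT_LEVELS, unique(ranking$dmt_star))) {
    ix <- which(ranking$dmt_star == d)
    part <- cycles[ix, , drop = FALSE]
    received <- part$index_dmt == d
    row <- data.frame(dmt_star = d, slope = NA_real_, p_value = NA_real_,
                      n_received = sum(received),
                      n_not_received = sum(!received),
                      excluded_reason = NA_character_,
                      stringsAsFactors = FALSE)
    if (sum(received) < min_n || sum(!received) < min_n) {
      row$excluded_reason <- sprintf("fewer than %d observations per condition",
                                     min_n)
    } else {
      res <- tryCatch({
        w <- estimate_weights(part, received, covariates)
        weighted_outcome_glm(part, received, w, response)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        row$excluded_reason <- conditionMessage(res)
      } else {
        row$slope <- res$slope
        row$p_value <- res$p_value
      }
    }
    rows[[d]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("weighted_comparison", "data.frame")
  out
}
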