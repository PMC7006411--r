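## Model specifications (three nested complexities) and design-matrix
## construction with stored standardization transforms.

#' Prior configuration
#'
#' Default weakly-informative priors of the hierarchical models: intercept
#' Normal(0, 10), fixed effects Normal(0, 2.5) (location, scale = sd; the
#' weakly-informative scheme presumes unit-scale predictors, hence continuous
#' predictors are standardized in [build_design()]), negative-binomial shape
#' Half-Cauchy(0, 5) (relapse model only) and random-intercept standard
#' deviation Gamma(1, 1) (shape, rate).
#'
#' @param response `"relapse"` or `"cdp"`.
#' @param intercept,fixed_effects length-2 numeric (location, scale).
#' @param dispersion length-2 numeric (location, scale) of the Half-Cauchy on
#'   the NB shape; ignored for the CDP model.
#' @param site_sd length-2 numeric (shape, rate) of the Gamma on the
#'   random-intercept sd.
#' @return A `prior_config` list.
#' @export
prior_config <- function(response = c("relapse", "cdp"),
                         intercept = c(0, 10),
                         fixed_effects = c(0, 2.5),
                         dispersion = c(0, 5),
                         site_sd = c(1, 1)) {
  response <- match.arg(response)
  stopifnot(intercept[2] > 0, fixed_effects[2] > 0, dispersion[2] > 0,
            site_sd[1] > 0, site_sd[2] > 0)
  structure(
    list(response = response, intercept = intercept,
         fixed_effects = fixed_effects,
         dispersion = if (response == "relapse") dispersion else NULL,
         site_sd = site_sd),
    class = "prior_config"
  )
}

#' Scale a prior configuration
#'
#' Multiplies the normal and half-Cauchy scales by a common factor (used by
#' the prior-sensitivity scan); the Gamma prior on the site sd is rescaled via
#' its rate (rate / factor scales the implied sd by the factor).
#'
#' @param prior a [prior_config()].
#' @param factor positive scale multiplier.
#' @export
scale_prior <- function(prior, factor) {
  stopifnot(factor > 0)
  prior$intercept[2] <- prior$intercept[2] * factor
  prior$fixed_effects[2] <- prior$fixed_effects[2] * factor
  if (!is.null(prior$dispersion)) {
    prior$dispersion[2] <- prior$dispersion[2] * factor
  }
  prior$site_sd[2] <- prior$site_sd[2] / factor
  prior
}

## Fixed-effect formulas of the three nested complexities. The clinical site
## (random intercept) and the log index-duration offset sit outside the fixed
## effects.
.complexity_formula <- function(complexity) {
  prognostic_terms <- paste(
    "index_dmt", "age", "gender", "edss_baseline", "second_line",
    "current_dmt", "current_duration", "current_dmt:current_duration",
    "diagnosis_distance", "relapse_distance", "relapses_count", "dmts_count",
    sep = " + "
  )
  rhs <- switch(complexity,
    non_personalized = "index_dmt",
    prognostic = prognostic_terms,
    predictive = paste(
      prognostic_terms,
      "index_dmt:diagnosis_distance", "index_dmt:gender",
      "index_dmt:relapses_count", "index_dmt:second_line",
      sep = " + "
    ),
    stop("unknown complexity: ", complexity)
  )
  as.formula(paste("~", rhs))
}

#' Model specification
#'
#' Binds a response (`relapse`: negative binomial with log link; `cdp`:
#' binomial with logit link), a nesting complexity and a prior configuration.
#' The three complexities are strictly nested: the non-personalized model has
#' only the index therapy (plus site intercept and log-duration offset); the
#' prognostic model adds the patient characteristics; the predictive model
#' adds four interaction blocks between the index therapy and diagnosis
#' distance, gender, relapses count, and the second-line indicator.
#'
#' @param response `"relapse"` or `"cdp"`.
#' @param complexity `"non_personalized"`, `"prognostic"` or `"predictive"`.
#' @param prior a [prior_config()]; defaults to the standard priors.
#' @return A `model_spec` list.
#' @export
model_spec <- function(response = c("relapse", "cdp"),
                       complexity = c("predictive", "prognostic",
                                      "non_personalized"),
                       prior = NULL) {
  response <- match.arg(response)
  complexity <- match.arg(complexity)
  structure(
    list(response = response, complexity = complexity,
         prior = prior %||% prior_config(response),
         formula = .complexity_formula(complexity)),
    class = "model_spec"
  )
}

.as_factor_checked <- function(x, levels, what) {
  x <- as.character(x)
  bad <- setdiff(unique(x), levels)
  if (length(bad) > 0) {
    stop("unseen ", what, " level(s) at prediction time: ",
         paste(bad, collapse = ", "))
  }
  factor(x, levels = levels)
}

## Prepare the model frame: factors with fixed (alphabetical) levels and
## standardized continuous predictors. `transforms` from a previous call
## freezes the centering/scaling for prediction.
.model_frame <- function(cycles, transforms = NULL) {
  mf <- data.frame(
    index_dmt = .as_factor_checked(cycles$index_dmt, DMT_LEVELS, "index therapy"),
    current_dmt = .as_factor_checked(cycles$current_dmt,
                                     sort(CURRENT_DMT_LEVELS), "current therapy"),
    gender = .as_factor_checked(cycles$gender, c("F", "M"), "gender"),
    second_line = as.numeric(cycles$second_line)
  )
  if (is.null(transforms)) {
    transforms <- lapply(CONTINUOUS_PREDICTORS, function(v) {
      s <- sd(cycles[[v]])
      ## current_duration is scaled but not centered: zero must stay zero so
      ## that the no-previous-therapy level (current_dmt == NONE, duration 0)
      ## does not make the therapy-duration interaction collinear with the
      ## NONE dummy
      list(center = if (v == "current_duration") 0 else mean(cycles[[v]]),
           scale = if (is.na(s) || s == 0) 1 else s)
    })
    names(transforms) <- CONTINUOUS_PREDICTORS
  }
  for (v in CONTINUOUS_PREDICTORS) {
    mf[[v]] <- (cycles[[v]] - transforms[[v]]$center) / transforms[[v]]$scale
  }
  list(frame = mf, transforms = transforms)
}

#' Build the design matrix for a model specification
#'
#' Dummy-codes categorical predictors against alphabetically-first reference
#' levels (index therapy: DMF; current therapy: DMF with an explicit NONE
#' level; gender: F), centers and scales continuous predictors (transforms
#' stored for prediction-time reuse), forms interaction columns as products of
#' the coded columns, and returns the log index-duration offset and the
#' clinical-site index separately from the fixed effects.
#'
#' @param cycles filtered therapy-cycle data frame.
#' @param spec a [model_spec()].
#' @param transforms standardization transforms from a previous design (for
#'   prediction); `NULL` to estimate them from `cycles`.
#' @param site_levels site levels from a previous design; `NULL` to take them
#'   from `cycles`.
#' @param columns column names from a previous design (for prediction-time
#'   consistency); `NULL` to derive them, dropping structurally empty
#'   (all-zero) columns such as the NONE-level therapy-duration interaction.
#' @return A list with `X` (fixed-effect matrix incl. intercept), `offset`
#'   (log index duration), `site` (integer site index), `site_levels`,
#'   `transforms`, `columns`, `assign` (term number per column) and
#'   `term_labels`.
#' @export
build_design <- function(cycles, spec, transforms = NULL, site_levels = NULL,
                         columns = NULL) {
  prep <- .model_frame(cycles, transforms)
  X <- model.matrix(spec$formula, prep$frame)
  asg <- attr(X, "assign")
  if (is.null(columns)) {
    keep <- colSums(abs(X)) > 0
    X <- X[, keep, drop = FALSE]
    asg <- asg[keep]
  } else {
    missing <- setdiff(columns, colnames(X))
    if (length(missing) > 0) {
      stop("design columns not reproducible at prediction time: ",
           paste(missing, collapse = ", "))
    }
    asg <- asg[match(columns, colnames(X))]
    X <- X[, columns, drop = FALSE]
  }
  if (is.null(site_levels)) {
    site_levels <- sort(unique(as.character(cycles$site_id)))
  }
  site <- match(as.character(cycles$site_id), site_levels)
  structure(
    list(
      X = X,
      offset = log(cycles$index_duration),
      site = site,
      site_levels = site_levels,
      transforms = prep$transforms,
      columns = colnames(X),
      assign = asg,
      term_labels = attr(terms(spec$formula), "term.labels")
    ),
    class = "hbglm_design"
  )
}

## Columns of X belonging to index-therapy interaction terms (the predictive
## model's extra blocks over the prognostic model).
interaction_columns <- function(design) {
  inter <- grep("^index_dmt:", design$term_labels)
  which(design$assign %in% inter)
}

#' Observed response vector for a specification
#'
#' @param cycles cycle data frame.
#' @param spec a [model_spec()].
#' @return Integer vector: relapse counts or 0/1 CDP indicators.
#' @export
response_vector <- function(cycles, spec) {
  if (spec$response == "relapse") as.integer(cycles$n_relapses)
  else as.integer(cycles$cdp)
}
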