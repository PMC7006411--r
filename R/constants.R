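#' @useDynLib dmtrank, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm rbinom rpois rgamma rnbinom runif rbeta rexp plogis
#'   qlogis dnbinom dbinom sd quantile median glm binomial quasibinomial coef
#'   fitted model.matrix as.formula terms setNames complete.cases qnorm pnorm
#'   var
#' @importFrom utils head write.csv read.csv
"_PACKAGE"

## Time constants (days). The source data are day-resolved; "months" in the
## clinical definitions are mapped to fixed day counts so that every window is
## applied bit-exactly. One month = 30.44 days on average; the specific
## windows below are the rounded multiples used throughout.
DAYS_PER_MONTH <- 30.44
DAYS_3_MONTHS <- 91L    # CDP sustainment window and post-start EDSS window
DAYS_6_MONTHS <- 183L   # pre-start EDSS window
DAYS_12_MONTHS <- 365L
DAYS_POST_RELAPSE <- 84L # an EDSS is valid only >= 84 days after any relapse

#' The six index disease-modifying therapies
#'
#' Dimethylfumarat (DMF), Fingolimod (FTY), Glatirameracetat (GA),
#' Interferon-beta-1 (IF), Natalizumab (NA.) and Teriflunomide (TERI).
#' Natalizumab is coded `"NA."` to avoid clashing with R's missing-value
#' literal in factor levels and CSV round-trips.
#'
#' @export
DMT_LEVELS <- c("DMF", "FTY", "GA", "IF", "NA.", "TERI")

## Current (pre-cycle) therapy adds an explicit none/other level.
CURRENT_DMT_LEVELS <- c(DMT_LEVELS, "NONE")

## Second-line DMTs by European Medical Agency label.
SECOND_LINE_DMTS <- c("FTY", "NA.")

## Predictors that must be available for a cycle to pass quality criteria.
PREDICTOR_COLUMNS <- c(
  "age", "gender", "index_dmt", "current_dmt", "diagnosis_distance",
  "relapses_count", "dmts_count", "second_line", "current_duration",
  "index_duration"
)

## Continuous predictors that are centered and scaled in the design matrix.
CONTINUOUS_PREDICTORS <- c(
  "age", "edss_baseline", "diagnosis_distance", "relapse_distance",
  "relapses_count", "dmts_count", "current_duration"
)

`%||%` <- function(a, b) if (is.null(a)) b else a
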