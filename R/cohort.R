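## Cohort construction: EDSS trajectories, endpoint derivation (confirmed
## disability progression), and the quality / inclusion filters that turn a
## raw therapy-cycle table into the analysis cohort.

#' Construct an EDSS trajectory
#'
#' Timestamped EDSS measurements plus relapse dates for one patient. Times are
#' in days since an arbitrary per-registry epoch; EDSS values must lie on the
#' half-point grid in \[0, 10\]; measurement times must be strictly
#' increasing.
#'
#' @param patient_id identifier (scalar).
#' @param times numeric vector of measurement times (days).
#' @param edss numeric vector of EDSS scores, same length as `times`.
#' @param relapse_dates numeric vector of relapse times (days), possibly empty.
#' @return An object of class `edss_trajectory`.
#' @export
edss_trajectory <- function(patient_id, times, edss, relapse_dates = numeric()) {
  stopifnot(length(times) == length(edss))
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("measurement times must be strictly increasing")
  }
  if (any(edss < 0 | edss > 10 | abs(edss * 2 - round(edss * 2)) > 1e-8)) {
    stop("EDSS values must be on the half-point grid in [0, 10]")
  }
  structure(
    list(
      patient_id = patient_id,
      times = as.numeric(times),
      edss = as.numeric(edss),
      relapse_dates = sort(as.numeric(relapse_dates))
    ),
    class = "edss_trajectory"
  )
}

## An EDSS measurement is valid iff it was taken at least 84 days after every
## preceding relapse (i.e. after the most recent relapse before it).
.edss_valid <- function(traj) {
  if (length(traj$relapse_dates) == 0) {
    return(rep(TRUE, length(traj$times)))
  }
  vapply(traj$times, function(t) {
    prior <- traj$relapse_dates[traj$relapse_dates < t]
    length(prior) == 0 || (t - max(prior)) >= DAYS_POST_RELAPSE
  }, logical(1))
}

#' Baseline EDSS for a therapy cycle
#'
#' Returns the valid EDSS measurement closest to the cycle start within the
#' window \[start - 183 days, start + 91 days\] (at most 6 months before or 3
#' months after the start). A measurement is valid only if taken at least 84
#' days after every preceding relapse. Ties in distance are broken towards the
#' earlier measurement.
#'
#' @param traj an [edss_trajectory()].
#' @param cycle_start cycle start time (days).
#' @return The baseline EDSS score, or `NA_real_` if no measurement qualifies.
#' @export
baseline_edss <- function(traj, cycle_start) {
  ok <- .edss_valid(traj) &
    traj$times >= cycle_start - DAYS_6_MONTHS &
    traj$times <= cycle_start + DAYS_3_MONTHS
  if (!any(ok)) {
    return(NA_real_)
  }
  t_ok <- traj$times[ok]
  e_ok <- traj$edss[ok]
  d <- abs(t_ok - cycle_start)
  e_ok[order(d, t_ok)][1]
}

#' Detect confirmed disability progression within a therapy cycle
#'
#' A confirmed disability progression (CDP) is a worsening relative to the
#' baseline EDSS of at least 1.0 point when the baseline is 5.5 or lower, and
#' of at least 0.5 point otherwise. The worsening must be sustained for at
#' least 3 months (91 days) and confirmed by at least one other valid EDSS
#' measurement at or above the progressed level. The confirming measurement
#' must itself satisfy the 84-days-post-relapse validity rule and is required
#' to lie at least 91 days after the onset (sustainment defines the
#' confirmation window); no valid measurement between onset and confirmation
#' may fall back below the progressed level.
#'
#' @param traj an [edss_trajectory()].
#' @param cycle_start,cycle_end cycle boundaries (days).
#' @return A list with `cdp` (logical; `NA` when no valid baseline EDSS
#'   exists, in which case the cycle is undeterminable and excluded upstream)
#'   and `time` (onset time of the first qualifying worsening, or `NA`).
#' @export
detect_cdp <- function(traj, cycle_start, cycle_end) {
  ref <- baseline_edss(traj, cycle_start)
  if (is.na(ref)) {
    return(list(cdp = NA, time = NA_real_))
  }
  threshold <- if (ref <= 5.5) 1.0 else 0.5
  level <- ref + threshold
  valid <- .edss_valid(traj)
  in_cycle <- traj$times > cycle_start & traj$times <= cycle_end
  cand <- which(valid & in_cycle & traj$edss >= level)
  for (i in cand) {
    t0 <- traj$times[i]
    later <- which(valid & in_cycle & traj$times >= t0 + DAYS_3_MONTHS &
                     traj$edss >= level)
    for (j in later) {
      between <- which(valid & traj$times > t0 & traj$times < traj$times[j])
      if (all(traj$edss[between] >= level)) {
        return(list(cdp = TRUE, time = t0))
      }
    }
  }
  list(cdp = FALSE, time = NA_real_)
}

#' Derive endpoints from trajectories
#'
#' Fills `edss_baseline` and `cdp` columns of a cycle table from the patients'
#' EDSS trajectories, using [baseline_edss()] and [detect_cdp()]. Cycles whose
#' CDP status is undeterminable (no valid baseline) get `edss_baseline = NA`
#' and are removed later by the quality criteria.
#'
#' @param cycles therapy-cycle data frame with `patient_id`, `cycle_start`,
#'   `cycle_end` columns (days).
#' @param trajectories named list of [edss_trajectory()] keyed by patient id.
#' @return `cycles` with `edss_baseline` and `cdp` recomputed.
#' @export
derive_endpoints <- function(cycles, trajectories) {
  for (r in seq_len(nrow(cycles))) {
    traj <- trajectories[[as.character(cycles$patient_id[r])]]
    if (is.null(traj)) next
    cycles$edss_baseline[r] <- baseline_edss(traj, cycles$cycle_start[r])
    res <- detect_cdp(traj, cycles$cycle_start[r], cycles$cycle_end[r])
    cycles$cdp[r] <- res$cdp
  }
  cycles
}

.filter_report <- function(steps, n_input, n_output) {
  stopifnot(sum(steps) == n_input - n_output)
  structure(
    list(steps = steps, n_input = n_input, n_output = n_output),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Cohort filter report:", x$n_input, "->", x$n_output, "cycles\n")
  for (nm in names(x$steps)) {
    cat(sprintf("  removed %5d  %s\n", x$steps[[nm]], nm))
  }
  invisible(x)
}

#' Apply data-quality criteria
#'
#' Removes, in order: cycles with any missing predictor; cycles without a
#' documented pre-index relapse (missing `relapse_distance`); cycles without a
#' valid pre-index EDSS (missing `edss_baseline`); and extreme cycles with an
#' annualized relapse rate strictly above 12 per year
#' (`n_relapses / index_duration > 12`; a rate of exactly 12 is retained).
#'
#' @param cycles therapy-cycle data frame.
#' @return A list with the filtered `cycles` and a `report`
#'   ([print.filter_report()]) itemizing removals per criterion.
#' @export
apply_quality_criteria <- function(cycles) {
  n0 <- nrow(cycles)
  steps <- c()

  keep <- complete.cases(cycles[, PREDICTOR_COLUMNS, drop = FALSE])
  steps["missing predictor"] <- sum(!keep)
  cycles <- cycles[keep, , drop = FALSE]

  keep <- !is.na(cycles$relapse_distance)
  steps["no pre-index relapse"] <- sum(!keep)
  cycles <- cycles[keep, , drop = FALSE]

  keep <- !is.na(cycles$edss_baseline)
  steps["no pre-index EDSS"] <- sum(!keep)
  cycles <- cycles[keep, , drop = FALSE]

  keep <- cycles$n_relapses / cycles$index_duration <= 12
  steps["annualized relapse rate > 12"] <- sum(!keep)
  cycles <- cycles[keep, , drop = FALSE]

  if (nrow(cycles) == 0) {
    stop("cohort exhausted: no cycles remain after quality criteria")
  }
  list(cycles = cycles, report = .filter_report(steps, n0, nrow(cycles)))
}

#' Apply inclusion criteria
#'
#' Retains cycles with age >= 18, baseline EDSS <= 6 and index therapy among
#' the six studied DMTs; removes therapies prescribed within 6 months of MS
#' diagnosis without a previous treatment failure (operationalized as
#' `diagnosis_distance <= 0.5` years and `dmts_count == 0`); keeps exactly one
#' uniformly chosen cycle per patient (seeded); finally drops clinical sites
#' with fewer than two remaining patients, iterating the site rule to a fixed
#' point.
#'
#' @param cycles quality-filtered therapy-cycle data frame.
#' @param seed integer seed for the per-patient random selection.
#' @return A list with `cycles` and a `report` as in [apply_quality_criteria()].
#' @export
apply_inclusion_criteria <- function(cycles, seed = 1L) {
  n0 <- nrow(cycles)
  steps <- c()

  keep <- cycles$age >= 18
  steps["age < 18"] <- sum(!keep)
  cycles <- cycles[keep, , drop = FALSE]

  keep <- cycles$edss_baseline <= 6
  steps["baseline EDSS > 6"] <- sum(!keep)
  cycles <- cycles[keep, , drop = FALSE]

  keep <- cycles$index_dmt %in% DMT_LEVELS
  steps["index therapy not studied"] <- sum(!keep)
  cycles <- cycles[keep, , drop = FALSE]

  keep <- cycles$diagnosis_distance > 0.5 | cycles$dmts_count >= 1
  steps["first therapy within 6 months of diagnosis"] <- sum(!keep)
  cycles <- cycles[keep, , drop = FALSE]

  ## one cycle per patient, uniform, reproducible given the seed
  n_before <- nrow(cycles)
  rows <- withr_seed(seed, {
    unlist(lapply(split(seq_len(nrow(cycles)), cycles$patient_id), function(ix) {
      if (length(ix) == 1) ix else ix[sample.int(length(ix), 1)]
    }), use.names = FALSE)
  })
  cycles <- cycles[sort(rows), , drop = FALSE]
  steps["multiple cycles per patient"] <- n_before - nrow(cycles)

  ## iterate single-patient-site exclusion to a fixed point
  n_before <- nrow(cycles)
  repeat {
    pat_per_site <- tapply(cycles$patient_id, cycles$site_id,
                           function(p) length(unique(p)))
    bad <- names(pat_per_site)[pat_per_site < 2]
    if (length(bad) == 0) break
    cycles <- cycles[!(cycles$site_id %in% bad), , drop = FALSE]
  }
  steps["site with a single patient"] <- n_before - nrow(cycles)

  if (nrow(cycles) == 0) {
    stop("cohort exhausted: no cycles remain after inclusion criteria")
  }
  list(cycles = cycles, report = .filter_report(steps, n0, nrow(cycles)))
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Patient-level train/test split
#'
#' Splits a cycle table into a development and a test part by patient, so no
#' patient contributes cycles to both. Patients are drawn uniformly at random
#' (seeded) into the test set until its cycle count reaches
#' `round(fraction * nrow(cycles))`.
#'
#' @param cycles therapy-cycle data frame.
#' @param fraction test fraction in (0, 1); default 0.1.
#' @param seed integer seed.
#' @return A list with `train` and `test` data frames.
#' @export
split_test <- function(cycles, fraction = 0.1, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  target <- round(fraction * nrow(cycles))
  patients <- unique(cycles$patient_id)
  ord <- withr_seed(seed, sample(patients))
  n_cycles <- cumsum(table(cycles$patient_id)[as.character(ord)])
  n_take <- which(n_cycles >= target)[1]
  test_patients <- if (is.na(n_take)) ord else ord[seq_len(n_take)]
  in_test <- cycles$patient_id %in% test_patients
  list(train = cycles[!in_test, , drop = FALSE],
       test = cycles[in_test, , drop = FALSE])
}

#' Read and write cycle/trajectory tables
#'
#' The cycle CSV has one row per therapy cycle with the documented header
#' (`patient_id, site_id, index_dmt, current_dmt, age, gender, edss_baseline,
#' diagnosis_distance, relapse_distance, relapses_count, dmts_count,
#' second_line, current_duration, index_duration, n_relapses, cdp,
#' cycle_start, cycle_end`). The EDSS CSV has columns
#' (`patient_id, time, edss`) and the relapse CSV (`patient_id, time`), times
#' in days.
#'
#' @param path file path.
#' @param cycles data frame to write.
#' @name cohort_io
#' @export
read_cycles <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  x$second_line <- as.logical(x$second_line)
  if ("cdp" %in% names(x)) x$cdp <- as.logical(x$cdp)
  x
}

#' @rdname cohort_io
#' @export
write_cycles <- function(cycles, path) {
  write.csv(cycles, path, row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @param edss_path,relapse_path paths of the EDSS and relapse-date CSVs.
#' @export
read_trajectories <- function(edss_path, relapse_path) {
  e <- read.csv(edss_path, stringsAsFactors = FALSE)
  r <- read.csv(relapse_path, stringsAsFactors = FALSE)
  ids <- unique(e$patient_id)
  out <- lapply(ids, function(id) {
    ei <- e[e$patient_id == id, , drop = FALSE]
    ei <- ei[order(ei$time), , drop = FALSE]
    edss_trajectory(id, ei$time, ei$edss, r$time[r$patient_id == id])
  })
  names(out) <- as.character(ids)
  out
}
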