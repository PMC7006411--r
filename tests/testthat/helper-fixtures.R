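# Fixture builders and independent brute-force oracles shared across tests.

# one-row-per-cycle table with sensible defaults, overridable per column
make_cycles <- function(n = 1, ...) {
  out <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    site_id = rep_len(c("S1", "S2"), n),
    index_dmt = rep_len(DMT_LEVELS, n),
    current_dmt = "NONE",
    age = 40,
    gender = "F",
    edss_baseline = 2.0,
    diagnosis_distance = 5,
    relapse_distance = 0.5,
    relapses_count = 1L,
    dmts_count = 1L,
    second_line = FALSE,
    current_duration = 0,
    index_duration = 1.5,
    n_relapses = 1L,
    cdp = FALSE,
    cycle_start = 0,
    cycle_end = 548,
    stringsAsFactors = FALSE
  )
  args <- list(...)
  for (nm in names(args)) out[[nm]] <- args[[nm]]
  out
}

# brute-force duration-matching oracle (direct transcription of the rule)
bf_match_pairs <- function(durations) {
  out <- NULL
  n <- length(durations)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      lim <- if (min(durations[i], durations[j]) < 0.5) 0.5 else 1.0
      if (abs(durations[i] - durations[j]) <= lim) out <- rbind(out, c(i, j))
    }
  }
  if (is.null(out)) matrix(integer(), 0, 2) else out
}

# brute-force concordance oracle
bf_cindex <- function(pairs, scores, events) {
  events <- as.integer(events)
  num <- den <- 0
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (events[i] == events[j]) next
    hi <- if (events[i] == 1) i else j
    lo <- if (events[i] == 1) j else i
    den <- den + 1
    if (scores[hi] > scores[lo]) num <- num + 1
    else if (scores[hi] == scores[lo]) num <- num + 0.5
  }
  if (den == 0) NA_real_ else num / den
}

# hand-built single-draw fit object for closed-form likelihood checks
manual_fit <- function(response, beta, columns, transforms, phi = NULL,
                       site_levels = c("S1", "S2")) {
  spec <- model_spec(response, "non_personalized")
  structure(
    list(
      draws = list(beta = matrix(beta, nrow = 1,
                                 dimnames = list(NULL, columns)),
                   u = matrix(0, 1, length(site_levels),
                              dimnames = list(NULL, site_levels)),
                   sigma = 0, phi = phi),
      chain_id = 1L,
      rhat = c(),
      design = list(site_levels = site_levels, transforms = transforms,
                    columns = columns, assign = NULL, term_labels = NULL),
      spec = spec,
      mcmc = list(), converged = TRUE
    ),
    class = "hbglm_fit"
  )
}

# small fitted registry + fit pair reused by prediction tests (cached)
local_small_fit <- local({
  cache <- new.env()
  function(response = "relapse") {
    key <- response
    if (is.null(cache[[key]])) {
      reg <- generate_registry(sim_config(n_patients = 400, n_sites = 6,
                                          seed = 99),
                               trajectories = FALSE)
      fit <- fit_hbglm(model_spec(response, "predictive"), reg$cycles,
                       chains = 2, iter = 150, warmup = 200, seed = 1,
                       on_nonconvergence = "ignore")
      cache[[key]] <- list(reg = reg, fit = fit)
    }
    cache[[key]]
  }
})
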