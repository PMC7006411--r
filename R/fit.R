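## MCMC fitting of the hierarchical Bayesian GLMs and convergence
## diagnostics.

#' Fit a hierarchical Bayesian GLM
#'
#' Samples the posterior of the negative-binomial (relapse, log link) or
#' binomial (CDP, logit link) hierarchical GLM with clinical-site random
#' intercepts and a log index-duration offset, under the priors of the
#' [model_spec()]. Sampling uses an in-package adaptive
#' Metropolis-within-Gibbs algorithm (componentwise random-walk updates with
#' warmup scale adaptation and an intercept/random-intercept recentering
#' move); chains are run sequentially and seeded, so fits are fully
#' reproducible.
#'
#' Convergence of every parameter is assessed with the Gelman-Rubin potential
#' scale reduction statistic (split R-hat). If any R-hat exceeds
#' `rhat_threshold` the fit fails loudly (default), naming the offending
#' parameters.
#'
#' @param spec a [model_spec()].
#' @param cycles filtered therapy-cycle data frame (>= 2 clinical sites).
#' @param chains number of chains (default 4).
#' @param iter post-warmup draws per chain (default 1000).
#' @param warmup warmup iterations per chain (default 1000).
#' @param seed integer seed; chain c uses `seed + c - 1`.
#' @param rhat_threshold convergence threshold (default 1.1).
#' @param on_nonconvergence `"error"` (default), `"warn"` or `"ignore"`.
#' @return An object of class `hbglm_fit` with elements `draws` (list:
#'   `beta` — draws x coefficients, `u` — draws x sites, `sigma`, `phi`),
#'   `chain_id`, `rhat` (named), `design` metadata, `spec`, and the MCMC
#'   settings.
#' @export
fit_hbglm <- function(spec, cycles, chains = 4, iter = 1000, warmup = 1000,
                      seed = 1L, rhat_threshold = 1.1,
                      on_nonconvergence = c("error", "warn", "ignore")) {
  on_nonconvergence <- match.arg(on_nonconvergence)
  design <- build_design(cycles, spec)
  S <- length(design$site_levels)
  if (S < 2) stop("at least 2 clinical sites are required")
  y <- response_vector(cycles, spec)
  family <- if (spec$response == "relapse") 0L else 1L

  beta_init <- numeric(ncol(design$X))
  beta_init[1] <- if (family == 0L) {
    log((sum(y) + 0.5) / sum(exp(design$offset)))
  } else {
    qlogis(min(max(mean(y), 0.02), 0.98)) - mean(design$offset)
  }

  ## whiten the likelihood: run the sampler on gamma with X = Z (R/sqrt(n)),
  ## Z'Z = n I and Z[,1] = 1; beta = T gamma with T = (R/sqrt(n))^{-1}
  n <- nrow(design$X)
  qrX <- qr(design$X)
  Rm <- qr.R(qrX)
  if (any(abs(diag(Rm)) < 1e-8 * max(abs(diag(Rm))))) {
    stop("design matrix is rank deficient")
  }
  flip <- sign(diag(Rm))
  Qm <- qr.Q(qrX) %*% diag(flip, length(flip))
  Rm <- diag(flip, length(flip)) %*% Rm
  Z <- Qm * sqrt(n)
  Rs <- Rm / sqrt(n)
  Tmat <- backsolve(Rs, diag(ncol(Rs)))
  gamma_init <- as.numeric(Rs %*% beta_init)

  prior <- spec$prior
  prior_sd <- c(prior$intercept[2],
                rep(prior$fixed_effects[2], ncol(design$X) - 1L))
  res <- vector("list", chains)
  for (ch in seq_len(chains)) {
    res[[ch]] <- withr_seed(seed + ch - 1L, {
      .mcmc_chain(
        as.numeric(y), Z, Tmat, design$offset,
        as.integer(design$site - 1L), S, family, prior_sd,
        if (family == 0L) prior$dispersion[2] else 1.0,
        prior$site_sd[1], prior$site_sd[2],
        as.integer(iter), as.integer(warmup), gamma_init
      )
    })
  }

  beta <- do.call(rbind, lapply(res, `[[`, "beta"))
  colnames(beta) <- colnames(design$X)
  u <- do.call(rbind, lapply(res, `[[`, "u"))
  colnames(u) <- design$site_levels
  sigma <- unlist(lapply(res, `[[`, "sigma"))
  phi <- if (family == 0L) unlist(lapply(res, `[[`, "phi")) else NULL
  chain_id <- rep(seq_len(chains), each = iter)

  params <- cbind(beta, u, site_sd = sigma)
  if (!is.null(phi)) params <- cbind(params, dispersion = phi)
  rhat <- apply(params, 2, split_rhat, chain_id = chain_id)

  fit <- structure(
    list(
      draws = list(beta = beta, u = u, sigma = sigma, phi = phi),
      chain_id = chain_id,
      rhat = rhat,
      design = design[c("site_levels", "transforms", "columns", "assign",
                        "term_labels")],
      spec = spec,
      mcmc = list(chains = chains, iter = iter, warmup = warmup, seed = seed),
      converged = all(rhat < rhat_threshold, na.rm = TRUE)
    ),
    class = "hbglm_fit"
  )

  if (!fit$converged && on_nonconvergence != "ignore") {
    bad <- names(rhat)[!is.na(rhat) & rhat >= rhat_threshold]
    msg <- paste0("MCMC did not converge (split R-hat >= ", rhat_threshold,
                  ") for: ", paste(head(bad, 10), collapse = ", "),
                  if (length(bad) > 10) ", ..." else "")
    if (on_nonconvergence == "error") stop(msg) else warning(msg)
  }
  fit
}

#' Split Gelman-Rubin R-hat
#'
#' Splits each chain in half and computes the potential scale reduction
#' statistic over the resulting groups. Returns 1 for parameters with zero
#' within-group variance.
#'
#' @param x draws (all chains concatenated).
#' @param chain_id chain index per draw.
#' @export
split_rhat <- function(x, chain_id) {
  groups <- unlist(lapply(unique(chain_id), function(c) {
    n <- sum(chain_id == c)
    rep(c(2 * c - 1, 2 * c), c(ceiling(n / 2), floor(n / 2)))
  }))
  xs <- split(x, groups)
  m <- length(xs)
  n <- min(lengths(xs))
  xs <- lapply(xs, function(v) v[seq_len(n)])
  means <- vapply(xs, mean, 0)
  vars <- vapply(xs, var, 0)
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @export
print.hbglm_fit <- function(x, ...) {
  cat("Hierarchical Bayesian", toupper(x$spec$response), "model (",
      x$spec$complexity, ")\n", sep = " ")
  cat(" ", ncol(x$draws$beta), "fixed effects,", ncol(x$draws$u),
      "site intercepts,", nrow(x$draws$beta), "posterior draws\n")
  cat("  max split R-hat:", round(max(x$rhat, na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' Posterior summary of the fixed effects
#'
#' @param object an `hbglm_fit`.
#' @param prob central credible-interval mass (default 0.95).
#' @param ... unused.
#' @return Data frame with posterior mean, median, sd, MAD and interval
#'   bounds per coefficient, plus the site sd and (relapse) dispersion.
#' @export
summary.hbglm_fit <- function(object, prob = 0.95, ...) {
  a <- (1 - prob) / 2
  mat <- cbind(object$draws$beta, site_sd = object$draws$sigma)
  if (!is.null(object$draws$phi)) mat <- cbind(mat, dispersion = object$draws$phi)
  data.frame(
    term = colnames(mat),
    mean = colMeans(mat),
    median = apply(mat, 2, median),
    sd = apply(mat, 2, sd),
    mad = apply(mat, 2, function(v) median(abs(v - median(v)))),
    lower = apply(mat, 2, quantile, probs = a),
    upper = apply(mat, 2, quantile, probs = 1 - a),
    rhat = object$rhat[colnames(mat)],
    row.names = NULL
  )
}
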