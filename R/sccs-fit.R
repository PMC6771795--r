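# Conditional Poisson likelihood for the self-controlled case series.
# Conditional on each person's total event count, the counts over that
# person's intervals are multinomial with probabilities proportional to
# interval_length * exp(linear predictor); person-level intercepts cancel.

sccs_loglik_parts <- function(X, n_ev, logl, person, beta) {
  eta <- drop(X %*% beta) + logl
  grp <- match(person, unique(person))
  mxg <- as.vector(tapply(eta, grp, max))
  w <- exp(eta - mxg[grp])
  denom <- drop(rowsum(w, grp))
  p <- w / denom[grp]
  n_g <- drop(rowsum(n_ev, grp))
  ll <- sum(n_ev * eta) - sum(n_g * (log(denom) + mxg))
  wt <- n_g[grp] * p                                # N_p * p_i
  mean_x <- rowsum(X * p, grp)                      # per-person E[x]
  grad <- colSums(X * n_ev) - colSums(mean_x * n_g)
  info <- crossprod(X, X * wt) - crossprod(mean_x * sqrt(n_g))
  list(ll = ll, grad = grad, info = info)
}

# Five-knot cubic spline basis on age-in-months: boundary knots at the 5th
# and 95th, interior knots at the 27.5th, 50th and 72.5th percentiles of
# included person-time.
age_spline_basis <- function(age_months, weights) {
  qs <- wtd_quantile(age_months, weights, c(0.05, 0.275, 0.5, 0.725, 0.95))
  if (length(unique(round(qs, 6))) < 5L) return(NULL)
  ## values beyond the 5th/95th percentile boundary knots are expected
  suppressWarnings(
    splines::bs(age_months, knots = qs[2:4], Boundary.knots = qs[c(1, 5)],
                degree = 3L))
}

wtd_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1L]], numeric(1))
}

# Five-knot cyclic cubic spline basis on month-of-year, evaluated at month
# midpoints; the wrap-around constraint makes December continuous with
# January.
season_spline_basis <- function(month_of_year) {
  sm <- mgcv::smoothCon(mgcv::s(m, bs = "cc", k = 5),
                        data = data.frame(m = month_of_year - 0.5),
                        knots = list(m = seq(0, 12, length.out = 5)),
                        absorb.cons = TRUE)[[1L]]
  sm$X
}

#' Fit the self-controlled case series model
#'
#' Maximizes the summed per-person multinomial log-likelihood by
#' Newton-Raphson (gradient tolerance 1e-8, at most 100 iterations, with
#' step-halving). The linear predictor contains the exposure indicator, a
#' pre-exposure indicator (its own coefficient, reported but not part of
#' the headline estimate), and, when `adjust_age_season` is on, a five-knot
#' cubic spline on age in months plus a five-knot cyclic cubic spline on
#' month of year. Spline bases that are degenerate or aliased on the data
#' at hand are reduced or dropped with a message. A monotone likelihood is
#' reported as non-estimable.
#'
#' @param intervals interval table from [partition_observation()] (columns
#'   person_id, days, events, exposed, pre_exposure, month_of_year,
#'   age_months).
#' @param adjust_age_season include the age and season splines.
#' @param design,exposure labels stored in the returned estimate.
#' @param tol,max_iter Newton-Raphson controls.
#' @return an [effect_estimate()] row for the exposure coefficient
#'   (IRR = exp(estimate)), with attributes `coefficients`, `loglik`,
#'   `iterations`, `converged`.
#' @export
fit_sccs <- function(intervals, adjust_age_season = TRUE,
                     design = "sccs", exposure = "exposure",
                     tol = 1e-8, max_iter = 100L) {
  iv <- as.data.table(intervals)
  stopifnot(nrow(iv) > 0, all(iv$days > 0))
  iv <- iv[, .(person_id, days = as.numeric(days),
               events = as.numeric(events),
               exposed = as.numeric(exposed),
               pre_exposure = as.numeric(pre_exposure),
               month_of_year = month_of_year, age_months = age_months)]
  setorder(iv, person_id)
  ## persons without events contribute nothing to the conditional likelihood
  with_ev <- iv[, .(tot = sum(events)), by = person_id][tot > 0, person_id]
  iv <- iv[person_id %in% with_ev]
  if (!nrow(iv) || all(iv$exposed == iv$exposed[1L])) {
    return(fail_sccs(design, exposure, iv, "no exposure variation"))
  }

  cols <- list(exposed = iv$exposed)
  if (any(iv$pre_exposure > 0)) cols$pre_exposure <- iv$pre_exposure
  if (adjust_age_season) {
    ab <- age_spline_basis(iv$age_months, iv$days)
    if (is.null(ab)) {
      message("age spline dropped: too little age variation")
    } else {
      for (j in seq_len(ncol(ab))) cols[[paste0("age_s", j)]] <- ab[, j]
    }
    if (uniqueN(iv$month_of_year) >= 3L) {
      sb <- season_spline_basis(iv$month_of_year)
      for (j in seq_len(ncol(sb))) cols[[paste0("season_s", j)]] <- sb[, j]
    } else {
      message("season spline dropped: fewer than 3 distinct months")
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)

  ## drop aliased columns (constant within every person, or linearly
  ## dependent after within-person centering)
  person <- iv$person_id
  grp <- match(person, unique(person))
  Xc <- X - rowsum(X * iv$days, grp)[grp, , drop = FALSE] /
    drop(rowsum(iv$days, grp))[grp]
  qr_x <- qr(Xc)
  keep <- sort(qr_x$pivot[seq_len(qr_x$rank)])
  if (!(1L %in% keep)) {
    return(fail_sccs(design, exposure, iv, "exposure aliased"))
  }
  if (length(keep) < ncol(X)) {
    message(sprintf("dropped %d aliased column(s): %s",
                    ncol(X) - length(keep),
                    paste(colnames(X)[-keep], collapse = ", ")))
  }
  X <- X[, keep, drop = FALSE]

  n_ev <- iv$events
  logl <- log(iv$days)
  beta <- rep(0, ncol(X))
  parts <- sccs_loglik_parts(X, n_ev, logl, person, beta)
  converged <- FALSE
  diverged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    step <- tryCatch(solve(parts$info, parts$grad), error = function(e) NULL)
    if (is.null(step)) {
      diverged <- TRUE
      break
    }
    new_beta <- beta + step
    new_parts <- sccs_loglik_parts(X, n_ev, logl, person, new_beta)
    h <- 0L
    while (!is.finite(new_parts$ll) || new_parts$ll < parts$ll - 1e-12) {
      h <- h + 1L
      if (h > 30L) break
      new_beta <- beta + step / 2^h
      new_parts <- sccs_loglik_parts(X, n_ev, logl, person, new_beta)
    }
    beta <- new_beta
    parts <- new_parts
    if (abs(beta[1L]) > 15) {
      diverged <- TRUE
      break
    }
    if (max(abs(parts$grad)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (diverged || !converged) {
    return(fail_sccs(design, exposure, iv,
                     if (diverged) "monotone likelihood / separation"
                     else "did not converge"))
  }
  vc <- solve(parts$info)
  coefs <- data.table(term = colnames(X), estimate = beta,
                      se = sqrt(diag(vc)))
  est <- effect_estimate(
    design = design, exposure = exposure,
    log_estimate = coefs$estimate[1L], standard_error = coefs$se[1L],
    n_cases = uniqueN(person), n_persons = uniqueN(person)
  )
  setattr(est, "coefficients", coefs)
  setattr(est, "loglik", parts$ll)
  setattr(est, "iterations", it)
  setattr(est, "converged", TRUE)
  est
}

fail_sccs <- function(design, exposure, iv, note) {
  effect_estimate(design = design, exposure = exposure,
                  log_estimate = NA_real_, standard_error = NA_real_,
                  n_cases = uniqueN(iv$person_id),
                  n_persons = uniqueN(iv$person_id),
                  estimable = FALSE, note = note)
}

#' Run the self-controlled case series design end to end
#'
#' Composes era construction (30-day persistence gap), risk-window
#' construction (365-day extension for the simple-design variant, 30-day
#' for the nested-design variant, each with a 30-day pre-exposure window),
#' partition of observed time (first 365 days excluded, month-constant age
#' and season), and the conditional Poisson fit with spline adjustment.
#' Deterministic: the design involves no sampling.
#'
#' @param dataset a `claims_dataset`.
#' @param variant "crockett" (365-day extension) or "chou" (30-day).
#' @param exposure drug identifier.
#' @param adjust_age_season include spline adjustment (default TRUE).
#' @param condition outcome condition whose occurrences are the events.
#' @return an [effect_estimate()] row (IRR scale).
#' @export
run_sccs_design <- function(dataset, variant = c("crockett", "chou"),
                            exposure,
                            adjust_age_season = TRUE,
                            condition = dataset$config$outcome_condition) {
  variant <- match.arg(variant)
  extension <- if (variant == "crockett") 365L else 30L
  label <- paste0("sccs_", variant)
  tryCatch({
    eras <- build_drug_eras(
      dataset$drug_exposures[drug_id == exposure],
      persistence_gap = dataset$config$persistence_gap_days)
    win <- build_risk_windows(eras, extension_days = extension,
                              observation_periods = dataset$observation_periods)
    ev <- dataset$condition_occurrences[condition_id == condition,
                                        .(person_id, day)]
    iv <- partition_observation(dataset$observation_periods, ev, win,
                                dataset$persons[, .(person_id, birth_date)])
    if (!nrow(iv)) {
      return(effect_estimate(label, exposure, NA_real_, NA_real_,
                             estimable = FALSE, note = "no included events"))
    }
    fit_sccs(iv, adjust_age_season = adjust_age_season,
             design = label, exposure = exposure)
  }, error = function(e) {
    stop(sprintf("SCCS (%s) failed for '%s': %s",
                 variant, exposure, conditionMessage(e)), call. = FALSE)
  })
}
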