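#' Fit the systematic error model from negative-control estimates
#'
#' Each negative-control log estimate \eqn{\hat\theta_i} with standard error
#' \eqn{\tau_i} is modeled as Normal(mu, sigma^2 + tau_i^2); (mu, sigma) are
#' estimated by maximum likelihood with sigma bounded at zero (a boundary
#' solution sigma = 0 is allowed and reported). mu is the mean residual bias
#' on the log scale and sigma the spread of bias beyond random error.
#'
#' @param estimates data.table of [effect_estimate()] rows for negative
#'   controls; non-estimable rows are excluded.
#' @param min_controls minimum number of estimable controls (default 5).
#' @return object of class `systematic_error_model`: list(mu, sigma,
#'   n_controls_used, loglik).
#' @export
fit_systematic_error <- function(estimates, min_controls = 5L) {
  e <- as.data.table(estimates)
  e <- e[estimable == TRUE & is.finite(log_estimate) &
           is.finite(standard_error)]
  if (nrow(e) < min_controls) {
    stop(sprintf("need at least %d estimable negative-control estimates, have %d",
                 min_controls, nrow(e)))
  }
  theta <- e$log_estimate
  tau <- e$standard_error
  nll <- function(par) {
    -sum(dnorm(theta, par[1L], sqrt(par[2L]^2 + tau^2), log = TRUE))
  }
  opt <- optim(c(mean(theta), max(sd(theta), 1e-3)), nll,
               method = "L-BFGS-B", lower = c(-Inf, 0),
               control = list(factr = 10, pgtol = 1e-10, maxit = 500))
  structure(list(mu = opt$par[1L], sigma = opt$par[2L],
                 n_controls_used = nrow(e), loglik = -opt$value),
            class = "systematic_error_model")
}

#' @export
print.systematic_error_model <- function(x, ...) {
  cat(sprintf(
    "<systematic_error_model> mu = %.4f, sigma = %.4f (from %d controls)\n",
    x$mu, x$sigma, x$n_controls_used))
  invisible(x)
}

#' Calibrated p-value against the empirical null
#'
#' Two-sided tail probability of the log estimate under
#' Normal(mu, sigma^2 + se^2). With mu = 0 and sigma = 0 this equals the
#' nominal two-sided Wald p-value exactly.
#'
#' @param log_estimate,standard_error estimate on the log scale and its SE
#'   (vectorized).
#' @param model a `systematic_error_model`.
#' @return p-values in `[0, 1]`.
#' @export
calibrated_p <- function(log_estimate, standard_error, model) {
  2 * pnorm(-abs(log_estimate - model$mu) /
              sqrt(model$sigma^2 + standard_error^2))
}

#' Calibrated and nominal significance boundaries over a grid of SEs
#'
#' For each standard error tau, the two log-estimate values where the
#' calibrated p-value equals `alpha`
#' (`mu +/- z * sqrt(sigma^2 + tau^2)`), plus the nominal boundary
#' `+/- z * tau`. These are the plot-ready curves for
#' estimate-versus-standard-error panels.
#'
#' @param model a `systematic_error_model`.
#' @param se_grid standard errors at which to evaluate the boundary.
#' @param alpha significance level (default 0.05).
#' @return data.table (standard_error, calibrated_low, calibrated_high,
#'   nominal_low, nominal_high).
#' @export
significance_boundary <- function(model, se_grid, alpha = 0.05) {
  z <- qnorm(1 - alpha / 2)
  s <- sqrt(model$sigma^2 + se_grid^2)
  data.table(
    standard_error = se_grid,
    calibrated_low = model$mu - z * s,
    calibrated_high = model$mu + z * s,
    nominal_low = -z * se_grid,
    nominal_high = z * se_grid
  )
}

#' Standardized difference of two proportions
#'
#' `(p1 - p2) / sqrt((p1 (1 - p1) + p2 (1 - p2)) / 2)`, the scale-free
#' difference in a binary characteristic's prevalence between exposure
#' groups; sign convention exposed minus unexposed. When both proportions
#' are 0 or both are 1 the difference is 0 by convention; when both are
#' degenerate but unequal (one group all-positive, the other all-negative)
#' the pooled variance vanishes and the value is capped at
#' `sign(p1 - p2) * sqrt(2)`, the value the formula takes just inside the
#' degenerate corner (e.g. at p1 = 1, p2 = 1/2). |S.Diff| > 0.1
#' conventionally flags imbalance.
#'
#' @param p_exposed,p_unexposed proportions in `[0, 1]` (vectorized).
#' @return signed standardized differences.
#' @export
standardized_difference <- function(p_exposed, p_unexposed) {
  stopifnot(all(p_exposed >= 0 & p_exposed <= 1),
            all(p_unexposed >= 0 & p_unexposed <= 1))
  v <- (p_exposed * (1 - p_exposed) + p_unexposed * (1 - p_unexposed)) / 2
  out <- ifelse(v == 0,
                sign(p_exposed - p_unexposed) * sqrt(2),
                (p_exposed - p_unexposed) / sqrt(pmax(v, .Machine$double.xmin)))
  ifelse(p_exposed == p_unexposed, 0, out)
}

#' Covariate balance between exposed and unexposed persons
#'
#' For every characteristic, the proportion of exposed and of unexposed
#' persons with at least one occurrence in the year up to a month before
#' the anchor date (`[anchor - 365, anchor - 31]`; the last month is
#' excluded to avoid picking up precursors of the outcome), and the
#' standardized difference. The anchor is the first exposure start for
#' exposed persons and the date 12 months after enrollment start for
#' unexposed persons (the control index-date convention). Unexposed
#' persons must have at least 12 months of enrollment.
#'
#' @param dataset a `claims_dataset`.
#' @param exposure_drug drug identifier defining the exposed group.
#' @param condition_concepts,drug_concepts characteristics to tabulate;
#'   defaults: every simulated comorbidity/indication condition and every
#'   drug other than the exposure and the outcome treatment.
#' @param lookback_days,gap_days window `[anchor - lookback, anchor - gap]`.
#' @param threshold absolute standardized difference flagged as imbalance.
#' @return data.table (characteristic, type, p_exposed, p_unexposed,
#'   s_diff, flagged), proportions as exact count ratios.
#' @export
balance_table <- function(dataset, exposure_drug,
                          condition_concepts = NULL, drug_concepts = NULL,
                          lookback_days = 365L, gap_days = 31L,
                          threshold = 0.1) {
  if (is.null(condition_concepts)) {
    condition_concepts <- setdiff(
      unique(dataset$condition_occurrences$condition_id),
      dataset$config$outcome_condition)
  }
  if (is.null(drug_concepts)) {
    drug_concepts <- setdiff(unique(dataset$drug_exposures$drug_id),
                             c(exposure_drug, dataset$config$treatment_drug))
  }
  exp_rec <- dataset$drug_exposures[drug_id == exposure_drug]
  first_exp <- if (nrow(exp_rec)) {
    exp_rec[, .(anchor = min(start)), by = person_id]
  } else {
    data.table(person_id = integer(), anchor = integer())
  }
  op <- dataset$observation_periods
  unexp <- op[!(person_id %in% first_exp$person_id)]
  unexp <- unexp[obs_end >= obs_start + 365L,
                 .(person_id, anchor = obs_start + 365L)]
  groups <- rbind(first_exp[, .(person_id, anchor, exposed = TRUE)],
                  unexp[, .(person_id, anchor, exposed = FALSE)])
  if (!nrow(groups)) {
    return(data.table(characteristic = character(), type = character(),
                      p_exposed = numeric(), p_unexposed = numeric(),
                      s_diff = numeric(), flagged = logical()))
  }
  groups[, ws := anchor - as.integer(lookback_days)]
  groups[, we := anchor - as.integer(gap_days)]
  n1 <- sum(groups$exposed)
  n0 <- sum(!groups$exposed)

  one_row <- function(label, type, tab) {
    hit <- if (nrow(tab)) {
      if (type == "condition") {
        groups[tab, on = .(person_id, ws <= day, we >= day),
               which = TRUE, nomatch = 0L]
      } else {
        groups[tab, on = .(person_id, ws <= end, we >= start),
               which = TRUE, nomatch = 0L]
      }
    } else integer(0)
    has <- rep(FALSE, nrow(groups))
    has[unique(hit)] <- TRUE
    p1 <- if (n1) sum(has & groups$exposed) / n1 else 0
    p0 <- if (n0) sum(has & !groups$exposed) / n0 else 0
    data.table(characteristic = label, type = type,
               p_exposed = p1, p_unexposed = p0,
               s_diff = standardized_difference(p1, p0))
  }
  rows <- c(
    lapply(condition_concepts, function(cc) {
      one_row(cc, "condition",
              dataset$condition_occurrences[condition_id == cc,
                                            .(person_id, day)])
    }),
    lapply(drug_concepts, function(dc) {
      one_row(dc, "drug",
              dataset$drug_exposures[drug_id == dc, .(person_id, start, end)])
    })
  )
  out <- rbindlist(rows)
  out[, flagged := abs(s_diff) > threshold]
  out[]
}

#' Nominal and calibrated type-I error over negative controls
#'
#' The fraction of estimable negative-control estimates with nominal
#' p < alpha, and the fraction with leave-one-out calibrated p < alpha
#' (each control is calibrated against a systematic error model fitted on
#' the other controls, so a control is never tested against a model that
#' contains it).
#'
#' @param estimates data.table of [effect_estimate()] rows for negative
#'   controls.
#' @param alpha significance level (default 0.05).
#' @param min_controls minimum number of estimable estimates (default 10).
#' @return list(n_used, n_excluded, nominal_type1, calibrated_type1,
#'   calibrated_p): the last is the vector of leave-one-out calibrated
#'   p-values in the row order of the estimable estimates.
#' @export
evaluate_error_rates <- function(estimates, alpha = 0.05,
                                 min_controls = 10L) {
  e <- as.data.table(estimates)
  est <- e[estimable == TRUE & is.finite(log_estimate)]
  if (nrow(est) < min_controls) {
    stop(sprintf("need at least %d estimable estimates, have %d",
                 min_controls, nrow(est)))
  }
  nominal <- mean(est$p_value < alpha)
  loo <- vapply(seq_len(nrow(est)), function(i) {
    mod <- fit_systematic_error(est[-i])
    calibrated_p(est$log_estimate[i], est$standard_error[i], mod)
  }, numeric(1))
  list(n_used = nrow(est),
       n_excluded = nrow(e) - nrow(est),
       nominal_type1 = nominal,
       calibrated_type1 = mean(loo < alpha),
       calibrated_p = loo)
}
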