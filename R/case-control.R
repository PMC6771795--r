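#' Assess drug exposure in a window before the index date
#'
#' A member is exposed when any era of the drug intersects
#' `[index_date - window_days, index_date - 1]`; the index day itself is
#' excluded, so same-day treatment of the outcome does not count as prior
#' exposure.
#'
#' @param members data.table with person_id and index_date (e.g. matched-set
#'   members).
#' @param drug_eras eras of a single drug, from [build_drug_eras()].
#' @param window_days lookback window length (365 for the simple design,
#'   30 for the nested design).
#' @return copy of `members` with a logical `exposed` column.
#' @export
assess_exposure <- function(members, drug_eras, window_days) {
  m <- as.data.table(members)
  m <- copy(m)[, row_id := .I]
  m[, ws := index_date - as.integer(window_days)]
  m[, we := index_date - 1L]
  m[, exposed := FALSE]
  if (nrow(drug_eras)) {
    e <- as.data.table(drug_eras)[, .(person_id, era_start, era_end)]
    hit <- m[e, on = .(person_id, ws <= era_end, we >= era_start),
             which = TRUE, nomatch = 0L]
    if (length(hit)) m[unique(hit), exposed := TRUE]
  }
  m[, c("ws", "we", "row_id") := NULL]
  m[]
}

#' Assess baseline covariates for nested-design members
#'
#' Binary indicators of any occurrence of each concept in the year before
#' the index date (`[index - 365, index - 1]`), plus the integer severity
#' score. Concepts may be condition or drug identifiers.
#'
#' @param members data.table with person_id and index_date.
#' @param dataset a `claims_dataset`.
#' @param severity_scores data.table (person_id, severity_score) from
#'   [simulate_severity_score()]; NULL omits the score.
#' @param condition_concepts,drug_concepts character vectors of concept ids;
#'   each becomes an indicator column named after the concept.
#' @param lookback_days window length (default 365).
#' @return copy of `members` with one column per concept and, when supplied,
#'   `severity_score`.
#' @export
assess_covariates_chou <- function(members, dataset, severity_scores = NULL,
                                   condition_concepts = character(0),
                                   drug_concepts = character(0),
                                   lookback_days = 365L) {
  m <- copy(as.data.table(members))
  m[, ws := index_date - as.integer(lookback_days)]
  m[, we := index_date - 1L]
  for (cc in condition_concepts) {
    occ <- dataset$condition_occurrences[condition_id == cc,
                                         .(person_id, day)]
    hit <- if (nrow(occ)) {
      m[occ, on = .(person_id, ws <= day, we >= day),
        which = TRUE, nomatch = 0L]
    } else integer(0)
    m[, (cc) := FALSE]
    if (length(hit)) m[unique(hit), (cc) := TRUE]
  }
  for (dc in drug_concepts) {
    rec <- dataset$drug_exposures[drug_id == dc, .(person_id, start, end)]
    hit <- if (nrow(rec)) {
      m[rec, on = .(person_id, ws <= end, we >= start),
        which = TRUE, nomatch = 0L]
    } else integer(0)
    m[, (dc) := FALSE]
    if (length(hit)) m[unique(hit), (dc) := TRUE]
  }
  m[, c("ws", "we") := NULL]
  if (!is.null(severity_scores)) {
    m <- merge(m, severity_scores, by = "person_id", all.x = TRUE, sort = FALSE)
    m[is.na(severity_score), severity_score := 0L]
  }
  m[]
}

# Conditional log-likelihood, gradient and Hessian over 1:m matched sets.
# For each set the contribution is the case's linear predictor minus the
# log-sum of exponentiated linear predictors over all members.
clogit_loglik_parts <- function(X, y, set, beta) {
  eta <- drop(X %*% beta)
  grp <- match(set, unique(set))
  mxg <- as.vector(tapply(eta, grp, max))
  w <- exp(eta - mxg[grp])
  denom <- drop(rowsum(w, grp))
  p <- w / denom[grp]
  ll <- sum(eta[y]) - sum(log(denom) + mxg)
  mean_x <- rowsum(X * p, grp)                       # per-set E[x]
  grad <- colSums(X[y, , drop = FALSE]) - colSums(mean_x)
  info <- crossprod(X, X * p) - crossprod(mean_x)    # observed information
  list(ll = ll, grad = grad, info = info)
}

#' Fit conditional logistic regression on matched sets
#'
#' Maximizes the conditional likelihood for 1:m matched sets by
#' Newton-Raphson (gradient tolerance 1e-8, at most 100 iterations, with
#' step-halving). Standard errors come from the inverse observed
#' information. Covariate columns with no within-set variation anywhere are
#' dropped; sets without variation contribute zero to the likelihood and
#' are harmless. A monotone likelihood (all informative sets discordant in
#' one direction) is detected by coefficient divergence and reported as
#' non-estimable rather than as a huge finite number.
#'
#' @param members data.table with set_id, is_case, and the covariate columns
#'   named in `terms`; exactly one case per set.
#' @param terms covariate column names; the first is the exposure of
#'   interest and is the coefficient reported in the estimate.
#' @param design label stored in the returned estimate.
#' @param exposure exposure label stored in the returned estimate.
#' @param tol,max_iter Newton-Raphson controls.
#' @return an [effect_estimate()] row for the first term, with attributes
#'   `coefficients` (full table), `loglik`, `iterations`, `converged`.
#' @export
fit_conditional_logistic <- function(members, terms = "exposed",
                                     design = "case_control",
                                     exposure = terms[1L],
                                     tol = 1e-8, max_iter = 100L) {
  m <- as.data.table(members)
  stopifnot(all(terms %in% names(m)), nrow(m) > 0)
  counts <- m[, .(nc = sum(is_case)), by = set_id]
  stopifnot(all(counts$nc == 1L))
  setorder(m, set_id)
  X <- as.matrix(m[, lapply(.SD, as.numeric), .SDcols = terms])
  y <- m$is_case
  set <- m$set_id

  # drop columns constant within every set
  varying <- vapply(seq_len(ncol(X)), function(j) {
    any(tapply(X[, j], set, function(v) max(v) > min(v)))
  }, logical(1))
  if (!varying[1L]) {
    return(fail_estimate(design, exposure, m,
                         note = "no within-set variation in exposure"))
  }
  keep <- which(varying)
  Xk <- X[, keep, drop = FALSE]

  beta <- rep(0, ncol(Xk))
  parts <- clogit_loglik_parts(Xk, y, set, beta)
  converged <- FALSE
  diverged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    step <- tryCatch(solve(parts$info, parts$grad),
                     error = function(e) NULL)
    if (is.null(step)) {
      diverged <- TRUE
      break
    }
    new_beta <- beta + step
    new_parts <- clogit_loglik_parts(Xk, y, set, new_beta)
    h <- 0L
    while (!is.finite(new_parts$ll) || new_parts$ll < parts$ll - 1e-12) {
      h <- h + 1L
      if (h > 30L) break
      new_beta <- beta + step / 2^h
      new_parts <- clogit_loglik_parts(Xk, y, set, new_beta)
    }
    beta <- new_beta
    parts <- new_parts
    if (max(abs(beta)) > 15) {
      diverged <- TRUE
      break
    }
    if (max(abs(parts$grad)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (diverged || !converged) {
    return(fail_estimate(design, exposure, m,
                         note = if (diverged) {
                           "monotone likelihood / separation"
                         } else "did not converge"))
  }
  vc <- solve(parts$info)
  coefs <- data.table(term = terms[keep], estimate = beta,
                      se = sqrt(diag(vc)))
  j <- match(terms[1L], coefs$term)
  est <- effect_estimate(
    design = design, exposure = exposure,
    log_estimate = coefs$estimate[j], standard_error = coefs$se[j],
    n_cases = sum(y), n_controls = sum(!y)
  )
  setattr(est, "coefficients", coefs)
  setattr(est, "loglik", parts$ll)
  setattr(est, "iterations", it)
  setattr(est, "converged", TRUE)
  est
}

fail_estimate <- function(design, exposure, m, note) {
  effect_estimate(design = design, exposure = exposure,
                  log_estimate = NA_real_, standard_error = NA_real_,
                  n_cases = sum(m$is_case), n_controls = sum(!m$is_case),
                  estimable = FALSE, note = note)
}

#' Evaluate the conditional logistic log-likelihood at given coefficients
#'
#' Exposed for audit and for comparing the optimizer's solution against
#' grid evaluations.
#'
#' @inheritParams fit_conditional_logistic
#' @param beta coefficient vector matching `terms`.
#' @return the conditional log-likelihood value.
#' @export
conditional_logistic_loglik <- function(members, beta, terms = "exposed") {
  m <- as.data.table(members)
  setorder(m, set_id)
  X <- as.matrix(m[, lapply(.SD, as.numeric), .SDcols = terms])
  clogit_loglik_parts(X, m$is_case, m$set_id, beta)$ll
}

#' Run a case-control design end to end
#'
#' Composes case identification, control matching, exposure (and, for the
#' nested design, covariate) assessment, and the conditional logistic fit,
#' for one or several exposure drugs.
#'
#' For the simple (`"crockett"`) design, cases, controls and matching do not
#' depend on the exposure, so one matched-set construction serves every
#' exposure; exposure is assessed over the 365 days before index and the
#' model is exposure-only. For the nested (`"chou"`) design each exposure
#' drug is analysed within its own indication-defined nesting cohort
#' (indication condition `ind_<drug>`), exposure is assessed over the 30
#' days before index, and the model adjusts for the comorbidity indicators
#' and the severity score when `adjust = TRUE`.
#'
#' @param dataset a `claims_dataset`.
#' @param design "crockett" or "chou".
#' @param exposures character vector of drug identifiers.
#' @param seed matching seed.
#' @param ratio controls per case (default 3 for crockett, 4 for chou).
#' @param window_days exposure window (default 365 for crockett, 30 for
#'   chou).
#' @param adjust include covariate adjustment (nested design only).
#' @return data.table of [effect_estimate()] rows, one per exposure.
#' @export
run_case_control_design <- function(dataset,
                                    design = c("crockett", "chou"),
                                    exposures,
                                    seed = 1L,
                                    ratio = NULL,
                                    window_days = NULL,
                                    adjust = TRUE) {
  design <- match.arg(design)
  eras_all <- build_drug_eras(
    dataset$drug_exposures[drug_id %in% exposures],
    persistence_gap = dataset$config$persistence_gap_days)

  if (design == "crockett") {
    if (is.null(ratio)) ratio <- 3L
    if (is.null(window_days)) window_days <- 365L
    cases <- identify_cases_crockett(dataset)
    sets <- match_controls_crockett(cases, dataset, ratio = ratio, seed = seed)
    out <- lapply(exposures, function(d) {
      tryCatch({
        mm <- assess_exposure(sets, eras_all[drug_id == d], window_days)
        fit_conditional_logistic(mm, terms = "exposed",
                                 design = "case_control_crockett",
                                 exposure = d)
      }, error = function(e) {
        stop(sprintf("case-control (crockett) failed for '%s': %s",
                     d, conditionMessage(e)), call. = FALSE)
      })
    })
    return(rbindlist(out))
  }

  ## nested design: per-exposure indication nesting
  if (is.null(ratio)) ratio <- 4L
  if (is.null(window_days)) window_days <- 30L
  sev <- simulate_severity_score(dataset)
  comorbs <- paste0("comorb_", seq_len(dataset$config$n_comorbidities))
  out <- lapply(exposures, function(d) {
    tryCatch({
      nest <- build_nesting_cohort_chou(dataset,
                                        indication_condition = paste0("ind_", d),
                                        entry_drugs = d)
      cases <- identify_cases_chou(dataset, nest)
      if (nrow(cases) < 2L) {
        return(effect_estimate("case_control_chou", d, NA_real_, NA_real_,
                               n_cases = nrow(cases), estimable = FALSE,
                               note = "too few cases"))
      }
      sets <- match_controls_chou(cases, nest, dataset,
                                  max_ratio = ratio,
                                  seed = seed + substream_seed(0L, d) %% 1000L)
      mm <- assess_exposure(sets, eras_all[drug_id == d], window_days)
      terms <- "exposed"
      if (adjust) {
        mm <- assess_covariates_chou(mm, dataset, severity_scores = sev,
                                     condition_concepts = comorbs)
        terms <- c("exposed", comorbs, "severity_score")
      }
      fit_conditional_logistic(mm, terms = terms,
                               design = "case_control_chou", exposure = d)
    }, error = function(e) {
      stop(sprintf("case-control (chou) failed for '%s': %s",
                   d, conditionMessage(e)), call. = FALSE)
    })
  })
  rbindlist(out)
}
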