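#' Construct an effect-estimate record
#'
#' One row per fitted design/exposure pair, on the log (OR or IRR) scale.
#' The 95% CI is `exp(log_estimate -/+ 1.96 * standard_error)` and the
#' p-value is the two-sided Wald test, unless the fit was flagged
#' non-estimable, in which case all inferential fields are `NA`.
#'
#' @param design label ("case_control_crockett", "sccs_chou", ...).
#' @param exposure drug identifier.
#' @param log_estimate,standard_error point estimate and SE on the log scale.
#' @param n_cases,n_controls,n_persons design-specific sample sizes.
#' @param estimable FALSE when the likelihood was monotone (separation) or
#'   the optimizer failed; such estimates are excluded from calibration.
#' @param note free-text diagnostic.
#' @return one-row data.table.
#' @export
effect_estimate <- function(design, exposure, log_estimate, standard_error,
                            n_cases = NA_integer_, n_controls = NA_integer_,
                            n_persons = NA_integer_, estimable = TRUE,
                            note = "") {
  if (!estimable || !is.finite(log_estimate) || !is.finite(standard_error)) {
    estimable <- FALSE
    log_estimate <- NA_real_
    standard_error <- NA_real_
  }
  data.table(
    design = design,
    exposure = exposure,
    log_estimate = log_estimate,
    standard_error = standard_error,
    ci_95_low = exp(log_estimate - 1.96 * standard_error),
    ci_95_high = exp(log_estimate + 1.96 * standard_error),
    p_value = if (estimable) {
      2 * pnorm(-abs(log_estimate) / standard_error)
    } else NA_real_,
    n_cases = as.integer(n_cases),
    n_controls = as.integer(n_controls),
    n_persons = as.integer(n_persons),
    estimable = estimable,
    note = note
  )
}
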