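#' Run the full bias-quantification experiment
#'
#' Simulates a claims population with known confounding, runs the simple
#' case-control design and the matching SCCS variant over every negative
#' control exposure (plus any drugs with non-null true effects), fits the
#' systematic error model per design, computes nominal and leave-one-out
#' calibrated type-I error, significance-boundary curves, and a covariate
#' balance table, and summarizes the residual-bias contrast between the two
#' designs. Fully reproducible from `config` (all randomness flows from
#' `config$rng_seed`); outputs carry no timestamps.
#'
#' @param config a [simulation_config()].
#' @param sccs_variant risk-window variant for the SCCS arm ("crockett",
#'   the 365-day extension matching the 365-day case-control exposure
#'   window, or "chou").
#' @param balance_exposure drug for the balance table (default: first
#'   negative control).
#' @param out_dir optional directory; when given, all tables are written as
#'   CSV (estimates.csv, balance.csv, error_models.csv, boundary.csv,
#'   summary.csv) and the simulated dataset under `<out_dir>/data/`.
#' @return list with elements `estimates` (both designs, with truth and
#'   full-model calibrated p), `error_models`, `error_rates`, `boundary`,
#'   `balance`, `summary`, `config`.
#' @export
run_experiment <- function(config,
                           sccs_variant = "crockett",
                           balance_exposure = NULL,
                           out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  t0 <- proc.time()[["elapsed"]]
  stage <- function(msg) {
    message(sprintf("[%7.1fs] %s", proc.time()[["elapsed"]] - t0, msg))
  }

  stage("simulating population")
  ds <- simulate_population(config)
  validate_claims_dataset(ds)
  ncs <- ds$negative_controls
  if (length(ncs) < 5L) stop("experiment needs at least 5 negative controls")
  extra <- setdiff(names(ds$truth)[ds$truth != 0], config$treatment_drug)
  exposures <- c(ncs, extra)
  if (is.null(balance_exposure)) balance_exposure <- ncs[1L]

  stage(sprintf("case-control design over %d exposures", length(exposures)))
  cc <- run_case_control_design(ds, design = "crockett",
                                exposures = exposures,
                                seed = substream_seed(config$rng_seed,
                                                      "matching"))

  stage(sprintf("SCCS (%s variant) over %d exposures",
                sccs_variant, length(exposures)))
  sccs <- rbindlist(lapply(exposures, function(d) {
    run_sccs_design(ds, variant = sccs_variant, exposure = d)
  }))

  estimates <- rbind(cc, sccs)
  estimates[, truth := ds$truth[exposure]]

  stage("calibration and diagnostics")
  nc_est <- estimates[exposure %in% ncs]
  designs <- unique(estimates$design)
  error_models <- lapply(setNames(designs, designs), function(dg) {
    fit_systematic_error(nc_est[design == dg])
  })
  estimates[, calibrated_p_value :=
              calibrated_p(log_estimate, standard_error,
                           error_models[[.BY$design]]),
            by = design]
  error_rates <- lapply(setNames(designs, designs), function(dg) {
    evaluate_error_rates(nc_est[design == dg])
  })
  se_grid <- seq(0.01, 1, by = 0.01)
  boundary <- rbindlist(lapply(designs, function(dg) {
    cbind(design = dg, significance_boundary(error_models[[dg]], se_grid))
  }))
  balance <- balance_table(ds, balance_exposure)

  summarize <- function(dg) {
    e <- nc_est[design == dg & estimable == TRUE]
    data.table(
      design = dg,
      n_negative_controls = length(ncs),
      n_estimable = nrow(e),
      mean_abs_log_estimate = mean(abs(e$log_estimate)),
      mean_log_estimate = mean(e$log_estimate),
      nominal_type1 = error_rates[[dg]]$nominal_type1,
      calibrated_type1 = error_rates[[dg]]$calibrated_type1,
      bias_mu = error_models[[dg]]$mu,
      bias_sigma = error_models[[dg]]$sigma,
      n_cases = max(estimates[design == dg, n_cases], na.rm = TRUE),
      n_flagged_balance_rows = sum(balance$flagged)
    )
  }
  summary <- rbindlist(lapply(designs, summarize))

  out <- list(estimates = estimates[], error_models = error_models,
              error_rates = error_rates, boundary = boundary,
              balance = balance, summary = summary, config = config)

  if (!is.null(out_dir)) {
    stage(sprintf("writing report bundle to %s", out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fwrite(estimates, file.path(out_dir, "estimates.csv"))
    fwrite(balance, file.path(out_dir, "balance.csv"))
    fwrite(boundary, file.path(out_dir, "boundary.csv"))
    fwrite(summary, file.path(out_dir, "summary.csv"))
    em <- rbindlist(lapply(names(error_models), function(dg) {
      data.table(design = dg, mu = error_models[[dg]]$mu,
                 sigma = error_models[[dg]]$sigma,
                 n_controls_used = error_models[[dg]]$n_controls_used)
    }))
    fwrite(em, file.path(out_dir, "error_models.csv"))
    write_claims_dataset(ds, file.path(out_dir, "data"))
  }
  stage("done")
  out
}
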