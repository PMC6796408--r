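## End-to-end study reproduction, JSON/text reports, and the function-level
## command interface behind the packaged Rscript front-end.

#' Published reference values for the lifetime-abuse / CVD-risk model
#'
#' The standardized coefficients, fit indices, and R-squared values reported
#' in the original published analysis of the Women's Health Effects Study
#' cohort, used to annotate reproduction reports with printed value and
#' absolute deviation.  These are reference constants, not package output.
#'
#' @return list with `fit_indices`, `paths` (data frame), `r_squared`.
#' @export
whes_reference <- function() {
  list(
    fit_indices = c(chi2 = 148.94, df = 75, chi2_df = 1.99,
                    rmsea = .07, cfi = .94, tli = .92),
    paths = data.frame(
      outcome = c("DepIntercept", "DepSlope", "Smoking", "Smoking",
                  "BodyWeight", "BodyWeight", "BodyWeight", "BodyWeight",
                  "CVDRisk", "CVDRisk", "CVDRisk", "CVDRisk", "CVDRisk"),
      predictor = c("LifetimeAbuse", "LifetimeAbuse", "LifetimeAbuse", "DepSlope",
                    "LifetimeAbuse", "DepIntercept", "DepSlope", "Smoking",
                    "LifetimeAbuse", "DepSlope", "Smoking", "BodyWeight", "AgeLat"),
      direct = c(.428, -.020, .349, .122, .213, .012, .031, -.153,
                 -.135, -.167, .091, .526, .347),
      ci_lower = c(.254, -.247, .204, -.100, .023, -.180, -.210, -.296,
                   -.314, -.350, -.053, .392, .212),
      ci_upper = c(.585, .213, .487, .316, .402, .223, .295, .005,
                   .056, .040, .226, .620, .453),
      stringsAsFactors = FALSE),
    r_squared = c(DepIntercept = .18, DepSlope = .000, Smoking = .14,
                  BodyWeight = .05, CVDRisk = .41),
    slope_loadings = c(CESD1 = .00, CESD2 = .31, CESD3 = .63, CESD4 = .68, CESD5 = .70),
    disturbance_correlation = -.53)
}

#' Reproduce the lifetime-abuse / CVD-risk analysis end to end
#'
#' Loads the packaged moment tables (or user-supplied ones), builds the
#' final published model, fits it by maximum likelihood with the three abuse
#' indicators standardized, decomposes standardized effects, and optionally
#' attaches parametric-bootstrap confidence intervals.
#'
#' @param moments a [moment_set]; defaults to [whes_moments()].
#' @param error_fractions passed to [build_whes_model()].
#' @param bootstrap number of bootstrap replicates (0 to skip).
#' @param seed seed for the bootstrap.
#' @param level bootstrap confidence level.
#' @return list of class `whes_study` with `fit`, `effects`, `boot`.
#' @export
whes_study <- function(moments = whes_moments(),
                       error_fractions = default_error_fractions(),
                       bootstrap = 0, seed = 1, level = 0.95) {
  model <- build_whes_model(error_fractions = error_fractions)
  fit <- fit_sem(model, moments, standardize = c("CTQ", "ISA", "ASA"))
  eff <- effects_table(fit)
  boot <- if (bootstrap > 0) {
    parametric_bootstrap(fit, b = bootstrap, seed = seed, level = level)
  } else NULL
  structure(list(fit = fit, effects = eff, boot = boot), class = "whes_study")
}

#' @export
print.whes_study <- function(x, digits = 3, ...) {
  print(x$fit, digits = digits)
  cat("\nStandardized causal effects (reference value and absolute deviation in brackets):\n")
  ref <- whes_reference()
  eff <- x$effects
  key <- paste(eff$outcome, eff$predictor)
  rkey <- paste(ref$paths$outcome, ref$paths$predictor)
  for (i in seq_len(nrow(eff))) {
    j <- match(key[i], rkey)
    annot <- if (!is.na(j)) sprintf("  [ref %.3f, dev %.3f]", ref$paths$direct[j],
                                    abs(eff$direct[i] - ref$paths$direct[j])) else ""
    cat(sprintf("  %-13s <- %-14s direct %7.3f  indirect %7.3f  total %7.3f%s\n",
                eff$outcome[i], eff$predictor[i], eff$direct[i], eff$indirect[i],
                eff$total[i], annot))
  }
  if (!is.null(x$boot)) { cat("\n"); print(x$boot, digits = digits) }
  invisible(x)
}

#' Write the machine-readable JSON report of a study reproduction
#'
#' Full-precision estimates, standardized solution, fit indices, R-squared,
#' effects, residual summary, convergence diagnostics, and (when present)
#' bootstrap intervals.
#'
#' @param study a `whes_study` (or any list with a `fit` element).
#' @param path output JSON path.
#' @export
report_json <- function(study, path) {
  fit <- study$fit
  payload <- list(
    fit_indices = list(chi2 = fit$chi2, df = fit$df, chi2_df = fit$chi2 / max(fit$df, 1),
                       p_value = fit$p_value, rmsea = fit$rmsea, cfi = fit$cfi,
                       tli = fit$tli,
                       baseline_chi2 = fit$baseline$chi2, baseline_df = fit$baseline$df),
    estimates = as.list(fit$theta),
    standardized = fit$standardized,
    r_squared = as.list(fit$r_squared),
    effects = study$effects,
    residual_summary = list(largest_abs = max(abs(fit$residuals)),
                            largest_positive = max(fit$residuals),
                            n_above_2 = sum(abs(fit$residuals[upper.tri(fit$residuals, diag = TRUE)]) > 2)),
    convergence = list(converged = fit$converged, n_iterations = fit$n_iterations,
                       grad_norm = fit$grad_norm, heywood = fit$heywood,
                       pd_repair = fit$pd_repair),
    wald = fit$wald)
  if (!is.null(study$boot)) {
    payload$bootstrap <- list(ci = study$boot$ci, n_requested = study$boot$n_requested,
                              n_converged = study$boot$n_converged,
                              seed = study$boot$seed, level = study$boot$level)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

validate_config <- function(config, need_paths = character()) {
  for (p in need_paths) {
    if (!is.null(config[[p]]) && !file.exists(config[[p]])) {
      stop("configured path does not exist: ", config[[p]])
    }
  }
  if (!is.null(config$bootstrap) && config$bootstrap < 0) stop("bootstrap must be >= 0")
  if (!is.null(config$level) && (config$level <= 0 || config$level >= 1)) {
    stop("confidence level must be in (0, 1)")
  }
  invisible(config)
}

#' Fit subcommand: moments -> model -> fit -> effects -> reports
#'
#' Function-level implementation of the command-line `fit` subcommand.
#' `config` is a list with optional elements `descriptives`, `correlations`
#' (CSV paths; the packaged tables are used when absent), `model` (a
#' declarative model file for non-default models), `bootstrap`, `seed`,
#' `level`, `out_dir`, `quiet`.
#'
#' @param config named list; see above.
#' @return invisibly, integer exit status (0 on success); writes
#'   `report.json` and `report.txt` into `out_dir`.
#' @export
cmd_fit <- function(config = list()) {
  status <- tryCatch({
    validate_config(config, c("descriptives", "correlations", "model"))
    moments <- if (!is.null(config$descriptives)) {
      load_moments(config$descriptives, config$correlations)
    } else whes_moments()
    out_dir <- config$out_dir %||% "."
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(config$model)) {
      model <- read_model_spec(config$model)
      fit <- fit_sem(model, moments, standardize = config$standardize %||% character())
      study <- structure(list(fit = fit, effects = effects_table(fit), boot = NULL),
                         class = "whes_study")
      if ((config$bootstrap %||% 0) > 0) {
        study$boot <- parametric_bootstrap(fit, b = config$bootstrap,
                                           seed = config$seed %||% 1,
                                           level = config$level %||% 0.95)
      }
    } else {
      study <- whes_study(moments = moments, bootstrap = config$bootstrap %||% 0,
                          seed = config$seed %||% 1, level = config$level %||% 0.95)
    }
    report_json(study, file.path(out_dir, "report.json"))
    txt <- utils::capture.output(print(study))
    writeLines(txt, file.path(out_dir, "report.txt"))
    if (!isTRUE(config$quiet)) writeLines(txt)
    if (!study$fit$converged) 0L else 0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

#' Simulate subcommand: generate data, optionally run a recovery experiment
#'
#' `config` elements: `n` (records), `seed`, `coarsen` (logical), `means`
#' (logical, add published means), `recovery` (logical), `replicates`,
#' `out_dir`.  The generating truth is the fitted solution of the packaged
#' study; datasets are written as CSV with a JSON truth sidecar.
#'
#' @param config named list; see above.
#' @return invisibly, integer exit status.
#' @export
cmd_simulate <- function(config = list()) {
  status <- tryCatch({
    validate_config(config)
    out_dir <- config$out_dir %||% "."
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    moments <- whes_moments()
    study <- whes_study(moments = moments)
    params <- study$fit$params
    n <- config$n %||% 227
    seed <- config$seed %||% 1
    coarsen <- if (isTRUE(config$coarsen)) whes_coarsening() else NULL
    means <- if (isTRUE(config$means)) moments$means else NULL
    if (isTRUE(config$recovery)) {
      repn <- config$replicates %||% 20
      repo <- recovery_experiment(build_whes_model(), params, n_list = n,
                                  replicates = repn, seed = seed,
                                  standardize = c("CTQ", "ISA", "ASA"))
      utils::write.csv(repo, file.path(out_dir, "recovery.csv"), row.names = FALSE)
      if (!isTRUE(config$quiet)) print(utils::head(as.data.frame(repo), 20))
    } else {
      ds <- generate_data(params, n = n, seed = seed, coarsen = coarsen, means = means)
      write_dataset(ds, file.path(out_dir, "synthetic.csv"))
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
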