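## Synthetic per-subject data with the model's statistical structure, for
## engine validation, parameter recovery, and bootstrap/coverage experiments.

matrix_sqrt <- function(S) {
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (!is.null(ch)) return(t(ch))
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values))) {
    stop("inadmissible (co)variance matrix: negative eigenvalue ", signif(min(e$values), 4))
  }
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow = nrow(S))
}

#' Coarsening used when emulating the study's discrete indicators
#'
#' Probit-style discretization: the binary adult-sexual-assault indicator is
#' dichotomized at the Gaussian quantile matching a target prevalence
#' (default 38.8%), and smoking is trichotomized at quantiles matching the
#' never/past/current shares (default 33.0/30.0/37.0%, codes 0/1/2).
#'
#' @param asa_prevalence target share of 1s for `ASA`.
#' @param smoke_shares target category shares for `SMOKE` (sums to 1).
#' @return list understood by [generate_data()]'s `coarsen` argument.
#' @export
whes_coarsening <- function(asa_prevalence = 0.388,
                            smoke_shares = c(75, 68, 84) / 227) {
  list(ASA = list(type = "binary", prevalence = asa_prevalence),
       SMOKE = list(type = "ordinal", shares = smoke_shares, codes = seq_along(smoke_shares) - 1))
}

#' Generate per-subject records from a parameter assignment
#'
#' Draws the exogenous latents, disturbances, and measurement errors from
#' zero-mean Gaussians with the assembled symmetric matrix `S`, propagates
#' them through the structural equations (`x = (I - A)^-1 u`), and returns
#' the observed indicators.  The sample covariance converges to
#' [implied_covariance()] of the generating parameters as `n` grows.
#' Optional coarsening discretizes indicators at Gaussian quantiles matching
#' target shares, and optional `means` offsets reproduce published means.
#'
#' @param params a `sem_params` object (e.g. `fit$params`).
#' @param n number of records.
#' @param seed integer seed, or `NULL` to continue the current RNG stream
#'   (used by the bootstrap's master-seed scheme).
#' @param coarsen `NULL` for none, or a list as from [whes_coarsening()].
#' @param means optional named vector of means added to observed columns.
#' @return object of class `synthetic_dataset`: `data` (data frame),
#'   `truth` (the generating `sem_params`), `seed`, `coarsening`.
#' @export
generate_data <- function(params, n, seed = NULL, coarsen = NULL, means = NULL) {
  stopifnot(inherits(params, "sem_params"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  m <- length(params$variable_names)
  L <- matrix_sqrt(params$S)
  U <- matrix(stats::rnorm(n * m), n, m) %*% t(L)
  IA_inv <- solve(diag(m) - params$A)
  X <- U %*% t(IA_inv)
  colnames(X) <- params$variable_names
  X <- X[, params$observed, drop = FALSE]
  implied_sd <- sqrt(diag(implied_covariance(params)))
  if (!is.null(means)) {
    for (nm in intersect(names(means), colnames(X))) X[, nm] <- X[, nm] + means[[nm]]
  }
  applied <- list()
  if (!is.null(coarsen)) {
    for (nm in names(coarsen)) {
      if (!nm %in% colnames(X)) next
      spec <- coarsen[[nm]]
      mu <- if (!is.null(means) && nm %in% names(means)) means[[nm]] else 0
      sdv <- implied_sd[[nm]]
      if (spec$type == "binary") {
        thr <- mu + sdv * stats::qnorm(1 - spec$prevalence)
        X[, nm] <- as.numeric(X[, nm] > thr)
        applied[[nm]] <- list(type = "binary", threshold = thr)
      } else if (spec$type == "ordinal") {
        cuts <- mu + sdv * stats::qnorm(cumsum(spec$shares[-length(spec$shares)]))
        X[, nm] <- spec$codes[findInterval(X[, nm], cuts) + 1]
        applied[[nm]] <- list(type = "ordinal", thresholds = cuts, codes = spec$codes)
      } else stop("unknown coarsening type: ", spec$type)
    }
  }
  structure(list(data = as.data.frame(X), truth = params,
                 seed = if (is.null(seed)) NA_integer_ else seed,
                 coarsening = applied),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", nrow(x$data), "records x", ncol(x$data), "indicators",
      if (length(x$coarsening)) paste0("(coarsened: ", paste(names(x$coarsening), collapse = ", "), ")") else "",
      "\n")
  invisible(x)
}

#' Export a synthetic dataset as CSV plus a JSON truth sidecar
#'
#' @param ds a `synthetic_dataset`.
#' @param csv_path output CSV of the records.
#' @param sidecar_path output JSON carrying the generating parameters, seed,
#'   and coarsening description (defaults to `csv_path` with `.json`).
#' @export
write_dataset <- function(ds, csv_path, sidecar_path = sub("\\.csv$", ".json", csv_path)) {
  utils::write.csv(ds$data, csv_path, row.names = FALSE)
  jsonlite::write_json(
    list(seed = ds$seed, theta = as.list(ds$truth$theta),
         error_variances = as.list(ds$truth$error_variances),
         coarsening = ds$coarsening),
    sidecar_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(ds)
}

## typical magnitude of a parameter's class, used as the recovery scale for
## parameters whose true value is near zero
parameter_scales <- function(model, theta) {
  pth <- model$paths[model$paths$status == "free", ]
  cls <- ifelse(pth$kind == "directed",
                ifelse(pth$target %in% model$variables$name[model$variables$kind == "observed"],
                       "loading", "structural"),
                ifelse(pth$source == pth$target, "variance", "covariance"))
  cls <- cls[match(names(theta), pth$label)]
  cm <- tapply(abs(theta), cls, mean)
  pmax(abs(theta), as.numeric(cm[cls]))
}

#' Parameter-recovery experiment
#'
#' For each sample size in `n_list`, simulates `replicates` datasets from
#' `params_true`, refits the model to each (via [moments_from_data()] and
#' [fit_sem()]), and reports the mean bias and RMSE of every free parameter.
#' Parameters whose absolute mean bias exceeds `tolerance` times their scale
#' at the largest `n` are flagged.  The scale of a parameter is
#' `max(|truth|, mean |truth| within its class)` (loading / structural
#' coefficient / variance / covariance), so near-zero parameters are judged
#' against the typical magnitude of their kind.
#'
#' @param model a [sem_model].
#' @param params_true generating `sem_params`.
#' @param n_list integer sample sizes.
#' @param replicates datasets per sample size.
#' @param seed master seed.
#' @param standardize passed to [fit_sem()] when refitting.
#' @param coarsen optional coarsening (recovery under coarsening is
#'   attenuated by construction).
#' @param tolerance relative bias flag threshold (default 0.02).
#' @return data frame with one row per (n, parameter): `truth`, `mean_est`,
#'   `bias`, `rel_bias`, `rmse`, `flagged`.
#' @export
recovery_experiment <- function(model, params_true, n_list, replicates = 20,
                                seed = 1, standardize = character(),
                                coarsen = NULL, tolerance = 0.02) {
  set.seed(seed)
  theta_true <- params_true$theta
  scales <- parameter_scales(model, theta_true)
  out <- list()
  for (n in n_list) {
    ests <- matrix(NA_real_, replicates, length(theta_true),
                   dimnames = list(NULL, names(theta_true)))
    for (r in seq_len(replicates)) {
      ds <- generate_data(params_true, n = n, seed = NULL, coarsen = coarsen)
      # the fixed error variances are constants of the generating model, not
      # estimated quantities, so refits hold them at their true values
      rf <- tryCatch(
        fit_sem(model, moments_from_data(ds$data), standardize = standardize,
                se = FALSE, start = theta_true, max_restarts = 3, grad_tol = 1e-4,
                error_variances = params_true$error_variances),
        error = function(e) NULL)
      if (!is.null(rf)) ests[r, ] <- rf$theta
    }
    bias <- colMeans(ests, na.rm = TRUE) - theta_true
    rmse <- sqrt(colMeans(sweep(ests, 2, theta_true)^2, na.rm = TRUE))
    out[[length(out) + 1]] <- data.frame(
      n = n, parameter = names(theta_true), truth = as.numeric(theta_true),
      mean_est = as.numeric(colMeans(ests, na.rm = TRUE)),
      bias = as.numeric(bias), rel_bias = as.numeric(bias / scales),
      rmse = as.numeric(rmse),
      n_converged = colSums(!is.na(ests)),
      row.names = NULL)
  }
  rep <- do.call(rbind, out)
  nmax <- max(n_list)
  rep$flagged <- rep$n == nmax & abs(rep$rel_bias) > tolerance
  class(rep) <- c("recovery_report", "data.frame")
  rep
}
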