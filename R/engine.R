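## ML covariance-structure engine: RAM assembly, discrepancy, fitting,
## fit indices, standardized solution, residuals, Wald tests.

#' Assemble RAM matrices for a parameter assignment
#'
#' Builds the directed-coefficient matrix `A` (rows receive), the symmetric
#' (co)variance matrix `S`, and the observed-variable selector from a
#' [sem_model], a named vector of free-parameter values, and the resolved
#' fixed error variances.  The constrained phantom disturbance is recomputed
#' here from the current parent (co)variances, so the constraint holds at
#' every engine iteration.
#'
#' @param model a [sem_model].
#' @param theta named numeric vector covering [free_parameters()].
#' @param error_variances named vector of fixed observed error variances
#'   (`error_fraction * sample variance`), usually from [fit_sem()].
#' @return object of class `sem_params`: list with `A`, `S`, `observed`
#'   (indices), `variable_names`, `theta`, `error_variances`, `model`.
#' @export
sem_params <- function(model, theta, error_variances = NULL) {
  labs <- free_parameters(model)
  miss <- setdiff(labs, names(theta))
  if (length(miss) > 0) stop("theta missing parameter(s): ", paste(miss, collapse = ", "))
  vs <- model$variables
  ord <- order(vs$kind != "observed") # observed first, stable
  vn <- vs$name[ord]
  kind <- vs$kind[ord]
  m <- length(vn)
  A <- matrix(0, m, m, dimnames = list(vn, vn))
  S <- matrix(0, m, m, dimnames = list(vn, vn))
  pth <- model$paths
  val <- ifelse(pth$status == "fixed", pth$value, theta[pth$label])
  for (i in seq_len(nrow(pth))) {
    s <- pth$source[i]; t <- pth$target[i]
    if (pth$kind[i] == "directed") {
      A[t, s] <- val[i]
    } else {
      S[s, t] <- S[t, s] <- val[i]
    }
  }
  if (!is.null(error_variances)) {
    ev <- error_variances[names(error_variances) %in% vn]
    diag(S)[names(ev)] <- diag(S)[names(ev)] + ev
  }
  if (!is.null(model$phantom)) {
    ph <- model$phantom
    w <- A[ph$variable, ph$parents]
    expl <- as.numeric(w %*% S[ph$parents, ph$parents] %*% w)
    f <- ph$error_fraction
    if (isTRUE(ph$fixed) && !is.null(ph$value)) {
      S[ph$variable, ph$variable] <- ph$value
    } else {
      S[ph$variable, ph$variable] <- f / (1 - f) * expl
    }
  }
  structure(list(A = A, S = S, observed = which(kind == "observed"),
                 variable_names = vn, theta = theta[labs],
                 error_variances = error_variances, model = model),
            class = "sem_params")
}

#' @export
print.sem_params <- function(x, ...) {
  cat("sem_params:", length(x$theta), "free parameters over",
      length(x$variable_names), "variables\n")
  print(round(x$theta, 4))
  invisible(x)
}

implied_full <- function(params) {
  m <- length(params$variable_names)
  IA <- diag(m) - params$A
  B <- tryCatch(solve(IA), error = function(e)
    stop("inadmissible parameters: (I - A) is singular"))
  C <- B %*% params$S %*% t(B)
  (C + t(C)) / 2
}

#' Model-implied covariance matrix of the observed variables
#'
#' `Sigma(theta) = F (I - A)^-1 S (I - A)^-T F'` with `A` the directed
#' coefficients, `S` the symmetric (co)variances and `F` the selector of
#' observed rows.
#'
#' @param x a `sem_params` object (from [sem_params()] or a fit), or a
#'   [sem_model] combined with `theta`/`error_variances`.
#' @param theta,error_variances used when `x` is a [sem_model].
#' @return symmetric covariance matrix over the observed variables.
#' @export
implied_covariance <- function(x, theta = NULL, error_variances = NULL) {
  params <- if (inherits(x, "sem_params")) x else sem_params(x, theta, error_variances)
  C <- implied_full(params)
  C[params$observed, params$observed]
}

#' Maximum-likelihood discrepancy between two covariance matrices
#'
#' `F = log|Sigma| + tr(S Sigma^-1) - log|S| - p`, the ML fit function for
#' multivariate-normal covariance structures: nonnegative, and zero exactly
#' when `Sigma = S`.  Scaled by `N - 1` it is the model chi-square.
#'
#' @param sample_cov,implied_cov symmetric positive-definite matrices of the
#'   same dimension.
#' @return the discrepancy (a single nonnegative number).
#' @export
ml_discrepancy <- function(sample_cov, implied_cov) {
  p <- nrow(sample_cov)
  if (nrow(implied_cov) != p) stop("dimension mismatch")
  for (nm in c("sample_cov", "implied_cov")) {
    M <- get(nm)
    if (!isSymmetric(unname(M), tol = 1e-7)) stop(nm, " is not symmetric")
    ev <- min(eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 0) stop(nm, " is not positive definite (min eigenvalue ", signif(ev, 4), ")")
  }
  as.numeric(determinant(implied_cov)$modulus - determinant(sample_cov)$modulus +
               sum(diag(sample_cov %*% solve(implied_cov))) - p)
}

## error variances implied by the fixed-reliability construction
resolve_error_variances <- function(model, sample_cov) {
  if (is.null(model$error_fractions)) return(NULL)
  nm <- names(model$error_fractions)
  v <- diag(sample_cov)[nm]
  stats::setNames(as.numeric(model$error_fractions) * as.numeric(v), nm)
}

## reference indicator of a latent: first observed variable it loads on with
## a fixed coefficient (preferring value 1), else any observed it loads on
reference_indicator <- function(model, latent) {
  pth <- model$paths
  obs <- model$variables$name[model$variables$kind == "observed"]
  load <- pth[pth$kind == "directed" & pth$source == latent & pth$target %in% obs, , drop = FALSE]
  if (nrow(load) == 0) return(NA_character_)
  fx1 <- load$target[load$status == "fixed" & !is.na(load$value) & load$value == 1]
  if (length(fx1) > 0) return(fx1[1])
  load$target[1]
}

## documented starting-value heuristics (overridden by paths$start)
start_values <- function(model, sample_cov) {
  pth <- model$paths
  labs <- free_parameters(model)
  th <- stats::setNames(rep(NA_real_, length(labs)), labs)
  obs <- model$variables$name[model$variables$kind == "observed"]
  ind_var <- function(v) {
    if (v %in% obs) return(sample_cov[v, v])
    ref <- reference_indicator(model, v)
    if (is.na(ref)) 1 else sample_cov[ref, ref]
  }
  has_incoming <- function(v) any(pth$kind == "directed" & pth$target == v)
  for (i in seq_len(nrow(pth))) {
    if (pth$status[i] != "free") next
    lab <- pth$label[i]
    if (!is.na(th[lab])) next
    if (!is.na(pth$start[i])) { th[lab] <- pth$start[i]; next }
    s <- pth$source[i]; t <- pth$target[i]
    th[lab] <- if (pth$kind[i] == "directed") {
      0.1
    } else if (s == t) {
      if (has_incoming(s)) 0.5 * ind_var(s)                 # disturbance
      else {                                                 # exogenous variance
        fr <- 0
        ref <- if (s %in% obs) s else reference_indicator(model, s)
        if (!is.na(ref) && ref %in% names(model$error_fractions)) fr <- model$error_fractions[[ref]]
        (1 - fr) * ind_var(s)
      }
    } else {
      rs <- if (s %in% obs) s else reference_indicator(model, s)
      rt <- if (t %in% obs) t else reference_indicator(model, t)
      if (!is.na(rs) && !is.na(rt)) sample_cov[rs, rt] else 0
    }
  }
  th
}

#' Chi-square of the independence baseline model
#'
#' The baseline frees every observed variance and fixes all covariances to
#' zero, the conventional reference for CFI/TLI.  Its ML discrepancy has the
#' closed form `log|diag(S)| - log|S|`.
#'
#' @param moments a [moment_set] (or a covariance matrix, in which case `n`
#'   must be given).
#' @param standardize passed to [to_covariance()] for `moment_set` input.
#' @param n sample size when `moments` is a matrix.
#' @param n_scale `"n-1"` (default) or `"n"` chi-square scaling.
#' @return list with `chi2` and `df` (`p(p-1)/2`).
#' @export
baseline_chi2 <- function(moments, standardize = character(), n = NULL,
                          n_scale = c("n-1", "n")) {
  n_scale <- match.arg(n_scale)
  if (inherits(moments, "moment_set")) {
    S <- to_covariance(moments, standardize)
    n <- moments$n
  } else {
    S <- moments
    if (is.null(n)) stop("n must be supplied with a covariance matrix")
  }
  p <- nrow(S)
  Fb <- as.numeric(sum(log(diag(S))) - determinant(S)$modulus)
  scale <- if (n_scale == "n-1") n - 1 else n
  list(chi2 = scale * max(Fb, 0), df = (p * (p - 1L)) %/% 2L)
}

#' Fit indices from the model and baseline chi-squares
#'
#' RMSEA `= sqrt(max(chi2 - df, 0) / (df (n - 1)))`;
#' CFI `= 1 - max(chi2 - df, 0) / max(chi2_b - df_b, chi2 - df, 0)`;
#' TLI `= ((chi2_b/df_b) - (chi2/df)) / ((chi2_b/df_b) - 1)`; and the
#' chi-square reference p-value.
#'
#' @param chi2,df fitted model chi-square and degrees of freedom.
#' @param chi2_b,df_b independence-baseline chi-square and df.
#' @param n sample size.
#' @return list with `rmsea`, `cfi`, `tli`, `p_value`.
#' @export
fit_indices <- function(chi2, df, chi2_b, df_b, n) {
  stopifnot(df > 0, df_b > 0, n > 1)
  rmsea <- sqrt(max(chi2 - df, 0) / (df * (n - 1)))
  denom <- max(chi2_b - df_b, chi2 - df, 0)
  cfi <- if (denom == 0) 1 else 1 - max(chi2 - df, 0) / denom
  rb <- chi2_b / df_b
  tli <- if (abs(rb - 1) < 1e-12) 1 else (rb - chi2 / df) / (rb - 1)
  list(rmsea = rmsea, cfi = cfi, tli = tli,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Standardized residual covariances
#'
#' `(s_ij - sigma_ij) / sqrt((sigma_ii sigma_jj + sigma_ij^2) / n)`, the
#' covariance residual divided by its approximate sampling SD.
#'
#' @param sample_cov,implied_cov same-dimension covariance matrices.
#' @param n sample size.
#' @return symmetric matrix of standardized residuals.
#' @export
standardized_residuals <- function(sample_cov, implied_cov, n) {
  stopifnot(all(dim(sample_cov) == dim(implied_cov)))
  d <- diag(implied_cov)
  (sample_cov - implied_cov) / sqrt((outer(d, d) + implied_cov^2) / n)
}

#' Standardized solution for a parameter assignment
#'
#' Rescales every path to the correlation metric.  Directed coefficients are
#' multiplied by `sd(source)/sd(target)` using model-implied total SDs.
#' Covariance paths between two different variables are rescaled to the
#' correlation between the corresponding exogenous/disturbance terms
#' (divided by the square roots of the `S`-matrix variances, so a covariance
#' between disturbances becomes the disturbance correlation).  Variance
#' paths are divided by the variable's implied total variance, so a
#' disturbance standardizes to the unexplained variance share `1 - R^2`.
#'
#' @param params a `sem_params` object (e.g. `fit$params`).
#' @return data frame with columns `source`, `target`, `kind`, `status`,
#'   `label`, `estimate`, `std`.
#' @export
standardize_solution <- function(params) {
  C <- implied_full(params)
  sdv <- sqrt(diag(C))
  if (any(sdv <= 0 | !is.finite(sdv))) {
    stop("zero or undefined implied variance for: ",
         paste(params$variable_names[sdv <= 0 | !is.finite(sdv)], collapse = ", "))
  }
  model <- params$model
  pth <- model$paths
  est <- ifelse(pth$status == "fixed", pth$value, params$theta[pth$label])
  std <- numeric(nrow(pth))
  for (i in seq_len(nrow(pth))) {
    s <- pth$source[i]; t <- pth$target[i]
    std[i] <- if (pth$kind[i] == "directed") {
      est[i] * sdv[s] / sdv[t]
    } else if (s == t) {
      est[i] / C[s, s]
    } else {
      est[i] / sqrt(params$S[s, s] * params$S[t, t])
    }
  }
  data.frame(source = pth$source, target = pth$target, kind = pth$kind,
             status = pth$status, label = pth$label, estimate = est, std = std,
             stringsAsFactors = FALSE)
}

#' Squared multiple correlations of endogenous latent variables
#'
#' `1 - disturbance variance / implied variance` for every latent with at
#' least one incoming directed path.
#'
#' @param params a `sem_params` object.
#' @return named numeric vector.
#' @export
r_squared <- function(params) {
  C <- implied_full(params)
  model <- params$model
  lat <- model$variables$name[model$variables$kind == "latent"]
  endo <- lat[vapply(lat, function(v)
    any(model$paths$kind == "directed" & model$paths$target == v), logical(1))]
  out <- vapply(endo, function(v) 1 - params$S[v, v] / C[v, v], numeric(1))
  stats::setNames(out, endo)
}

## compile a model into index arrays so the objective avoids per-evaluation
## data-frame work: templates for A and S plus linear indices of the free
## entries, the phantom constraint, and the observed selector
compile_model <- function(model, error_variances = NULL) {
  labs <- free_parameters(model)
  vs <- model$variables
  ord <- order(vs$kind != "observed")
  vn <- vs$name[ord]
  kind <- vs$kind[ord]
  m <- length(vn)
  A <- matrix(0, m, m, dimnames = list(vn, vn))
  S <- matrix(0, m, m, dimnames = list(vn, vn))
  pth <- model$paths
  si <- match(pth$source, vn); ti <- match(pth$target, vn)
  pi <- match(pth$label, labs)
  fx <- pth$status == "fixed"
  dirp <- pth$kind == "directed"
  A[cbind(ti[dirp & fx], si[dirp & fx])] <- pth$value[dirp & fx]
  S[cbind(si[!dirp & fx], ti[!dirp & fx])] <- pth$value[!dirp & fx]
  S[cbind(ti[!dirp & fx], si[!dirp & fx])] <- pth$value[!dirp & fx]
  if (!is.null(error_variances)) {
    ev <- error_variances[names(error_variances) %in% vn]
    diag(S)[names(ev)] <- diag(S)[names(ev)] + ev
  }
  dir_free <- which(dirp & !fx)
  cov_free <- which(!dirp & !fx)
  ph <- NULL
  if (!is.null(model$phantom)) {
    ph <- list(idx = match(model$phantom$variable, vn),
               parents = match(model$phantom$parents, vn),
               ratio = model$phantom$error_fraction / (1 - model$phantom$error_fraction),
               fixed = isTRUE(model$phantom$fixed),
               value = model$phantom$value)
  }
  dir_s <- si[dir_free]; dir_t <- ti[dir_free]; dir_p <- pi[dir_free]
  cov_s <- si[cov_free]; cov_t <- ti[cov_free]; cov_p <- pi[cov_free]
  assemble <- function(th) {
    A2 <- A; S2 <- S
    if (length(dir_free)) A2[cbind(ti[dir_free], si[dir_free])] <- th[pi[dir_free]]
    if (length(cov_free)) {
      S2[cbind(si[cov_free], ti[cov_free])] <- th[pi[cov_free]]
      S2[cbind(ti[cov_free], si[cov_free])] <- th[pi[cov_free]]
    }
    if (!is.null(ph)) {
      if (ph$fixed && !is.null(ph$value)) {
        S2[ph$idx, ph$idx] <- ph$value
      } else {
        w <- A2[ph$idx, ph$parents]
        S2[ph$idx, ph$idx] <- ph$ratio *
          as.numeric(w %*% S2[ph$parents, ph$parents, drop = FALSE] %*% w)
      }
    }
    list(A = A2, S = S2)
  }
  list(assemble = assemble, labels = labs, variable_names = vn,
       observed = which(kind == "observed"), m = m, phantom = ph,
       dir_s = dir_s, dir_t = dir_t, dir_p = dir_p,
       cov_s = cov_s, cov_t = cov_t, cov_p = cov_p)
}

## objective and analytic gradient closures over the free parameters.
## Gradient by RAM calculus: with Binv = (I-A)^-1, C = Binv S Binv',
## Sigma the observed block of C, and D = Sigma^-1 (Sigma - S_obs) Sigma^-1
## embedded as W, dF/dA[t,s] = 2 (C W Binv)[s, t] and
## dF/dS[i,j] = 2 (Binv' W Binv)[i,j] (half on the diagonal); the
## constrained phantom disturbance contributes chain-rule terms through
## dF/dS[ph,ph].
make_engine <- function(model, sample_cov, error_variances) {
  cm <- compile_model(model, error_variances)
  obs_names <- cm$variable_names[cm$observed]
  Sobs <- sample_cov[obs_names, obs_names]
  ld_S <- as.numeric(determinant(Sobs)$modulus)
  p <- length(obs_names)
  Im <- diag(cm$m)
  oi <- cm$observed
  q <- length(cm$labels)
  core <- function(th) {
    ram <- cm$assemble(th)
    IAi <- tryCatch(solve(Im - ram$A), error = function(e) NULL)
    if (is.null(IAi)) return(NULL)
    C <- IAi %*% ram$S %*% t(IAi)
    Sig <- C[oi, oi]
    Sig <- (Sig + t(Sig)) / 2
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    list(ram = ram, IAi = IAi, C = C, ch = ch)
  }
  objective <- function(th) {
    k <- core(th)
    if (is.null(k)) return(1e10)
    out <- 2 * sum(log(diag(k$ch))) + sum(chol2inv(k$ch) * Sobs) - ld_S - p
    if (!is.finite(out)) return(1e10)
    out
  }
  gradient <- function(th) {
    k <- core(th)
    if (is.null(k)) return(numeric(q))
    Sinv <- chol2inv(k$ch)
    D <- Sinv - Sinv %*% Sobs %*% Sinv
    W <- matrix(0, cm$m, cm$m)
    W[oi, oi] <- D
    M1 <- k$C %*% W %*% k$IAi
    M2 <- crossprod(k$IAi, W) %*% k$IAi
    g <- numeric(q)
    for (j in seq_along(cm$dir_p)) {
      g[cm$dir_p[j]] <- g[cm$dir_p[j]] + 2 * M1[cm$dir_s[j], cm$dir_t[j]]
    }
    for (j in seq_along(cm$cov_p)) {
      i1 <- cm$cov_s[j]; i2 <- cm$cov_t[j]
      g[cm$cov_p[j]] <- g[cm$cov_p[j]] +
        if (i1 == i2) M2[i1, i1] else 2 * M2[i1, i2]
    }
    ph <- cm$phantom
    if (!is.null(ph) && !(ph$fixed && !is.null(ph$value))) {
      dFph <- M2[ph$idx, ph$idx]
      w <- k$ram$A[ph$idx, ph$parents]
      Sp <- k$ram$S[ph$parents, ph$parents, drop = FALSE]
      for (j in seq_along(cm$cov_p)) {
        i1m <- match(cm$cov_s[j], ph$parents); i2m <- match(cm$cov_t[j], ph$parents)
        if (is.na(i1m) || is.na(i2m)) next
        dSph <- if (i1m == i2m) ph$ratio * w[i1m]^2 else ph$ratio * 2 * w[i1m] * w[i2m]
        g[cm$cov_p[j]] <- g[cm$cov_p[j]] + dFph * dSph
      }
      Sw <- as.numeric(Sp %*% w)
      for (j in seq_along(cm$dir_p)) {
        if (cm$dir_t[j] != ph$idx) next
        km <- match(cm$dir_s[j], ph$parents)
        if (is.na(km)) next
        g[cm$dir_p[j]] <- g[cm$dir_p[j]] + dFph * ph$ratio * 2 * Sw[km]
      }
    }
    g
  }
  hessian <- function(th) {
    J <- pracma::jacobian(function(x) gradient(x), th)
    (J + t(J)) / 2
  }
  list(objective = objective, gradient = gradient, hessian = hessian, compiled = cm)
}

#' Fit a structural model to sample moments by maximum likelihood
#'
#' Minimizes the ML discrepancy between the model-implied covariance and the
#' covariance assembled from the moment set, then derives the chi-square
#' (`(N - 1) * F_min` by default), fit indices against the independence
#' baseline, the standardized solution, squared multiple correlations,
#' standardized residuals, and Wald tests from the inverse observed
#' information.
#'
#' Optimization is quasi-Newton (port routine, then BFGS polish, then Newton
#' steps on the numerical Hessian); starting values follow documented
#' heuristics (exogenous (co)variances at sample moments, structural
#' coefficients at 0.1, disturbances at 50% of the reference indicator's
#' variance) unless a `start` is recorded on the path.  Non-convergence
#' triggers up to `max_restarts` jittered restarts.  Negative estimated
#' variances (Heywood cases) are flagged with a warning, not bounded away.
#'
#' @param model a [sem_model].
#' @param moments a [moment_set].
#' @param standardize variables forced to unit variance before fitting (the
#'   published analysis standardizes `CTQ`, `ISA`, `ASA`).
#' @param se compute standard errors / Wald tests (skipped during bootstrap
#'   replications for speed).
#' @param n_scale chi-square scaling, `"n-1"` (default) or `"n"`.
#' @param start optional named vector overriding the starting values.
#' @param error_variances optional named vector of fixed observed error
#'   variances, overriding the `error_fraction * sample variance` resolution
#'   (used e.g. to refit against a covariance generated from known
#'   parameters with the same error constants).
#' @param max_restarts jittered restarts on non-convergence (default 20).
#' @param grad_tol convergence tolerance on the discrepancy-gradient maximum
#'   norm.
#' @param pd_floor eigenvalue floor for [nearest_pd()] repair of the input.
#' @param quiet suppress progress messages.
#' @return object of class `sem_fit`; see the fields in the examples of
#'   `print.sem_fit`.
#' @export
fit_sem <- function(model, moments, standardize = character(), se = TRUE,
                    n_scale = c("n-1", "n"), start = NULL, max_restarts = 20,
                    grad_tol = 1e-8, pd_floor = NULL, quiet = TRUE,
                    error_variances = NULL) {
  n_scale <- match.arg(n_scale)
  stopifnot(inherits(model, "sem_model"), inherits(moments, "moment_set"))
  df <- count_df(model)
  S0 <- to_covariance(moments, standardize)
  S <- nearest_pd(S0, eigen_floor = pd_floor, quiet = quiet)
  repair <- attr(S, "repair_max_change")
  obs <- model$variables$name[model$variables$kind == "observed"]
  miss <- setdiff(obs, rownames(S))
  if (length(miss) > 0) stop("moments missing observed variable(s): ", paste(miss, collapse = ", "))
  S <- S[obs, obs]
  errv <- if (is.null(error_variances)) resolve_error_variances(model, S) else error_variances
  labs <- free_parameters(model)
  th0 <- start_values(model, S)
  if (!is.null(start)) th0[names(start)] <- start
  engine <- make_engine(model, S, errv)
  objective <- engine$objective

  best <- NULL
  n_iter <- 0L
  set_jitter <- function(th, k) th * stats::runif(length(th), 0.8, 1.2) + ifelse(th == 0, 0.01 * k, 0)
  for (attempt in 0:max_restarts) {
    th_try <- if (attempt == 0) th0 else set_jitter(th0, attempt)
    opt <- tryCatch(stats::nlminb(th_try, objective, gradient = engine$gradient,
                                  control = list(iter.max = 2000, eval.max = 4000,
                                                 rel.tol = 1e-12)),
                    error = function(e) NULL)
    if (is.null(opt) || opt$objective >= 1e9) next
    cand <- list(par = opt$par, objective = opt$objective, iterations = opt$iterations)
    if (is.null(best) || cand$objective < best$objective) best <- cand
    n_iter <- n_iter + cand$iterations
    g <- engine$gradient(best$par)
    if (max(abs(g)) < 100 * grad_tol || best$objective < 1e-12) break
  }
  if (is.null(best)) stop("optimization failed from all starting values")
  theta <- stats::setNames(best$par, labs)

  ## Newton polish on the Hessian (jacobian of the analytic gradient):
  ## sharpens the optimum and yields the observed information for SEs
  H <- NULL
  g <- engine$gradient(theta)
  if (max(abs(g)) > grad_tol / 100 || se) {
    for (it in 1:5) {
      H <- engine$hessian(theta)
      step <- tryCatch(solve(H, g), error = function(e) NULL)
      if (is.null(step)) break
      cand <- theta - step
      fc <- objective(cand)
      if (!is.finite(fc) || fc > best$objective + 1e-12) break
      theta <- stats::setNames(cand, labs); best$objective <- fc
      g <- engine$gradient(theta)
      n_iter <- n_iter + 1L
      if (max(abs(g)) < grad_tol / 100) break
    }
  }
  converged <- max(abs(g)) < grad_tol
  if (!converged) {
    warning("fit did not reach the gradient tolerance (max |grad| = ",
            signif(max(abs(g)), 3), "); results flagged")
  }

  params <- sem_params(model, theta, errv)
  Fmin <- best$objective
  n <- moments$n
  scale <- if (n_scale == "n-1") n - 1 else n
  chi2 <- scale * Fmin
  Sigma <- implied_covariance(params)[obs, obs]
  base <- baseline_chi2(S, n = n, n_scale = n_scale)
  idx <- if (df > 0) fit_indices(chi2, df, base$chi2, base$df, n) else
    list(rmsea = 0, cfi = 1, tli = 1, p_value = 1)

  ## admissibility: any estimated variance negative?
  est_var <- diag(params$S)
  heywood <- any(est_var < -1e-10)
  if (heywood) {
    warning("Heywood case: negative estimated variance for ",
            paste(params$variable_names[est_var < -1e-10], collapse = ", "))
  }

  std <- tryCatch(standardize_solution(params), error = function(e) NULL)
  r2 <- tryCatch(r_squared(params), error = function(e) NULL)

  fit <- structure(list(
    model = model, moments = moments, standardize = standardize,
    params = params, theta = theta,
    discrepancy_min = Fmin, chi2 = chi2, df = df,
    p_value = idx$p_value, rmsea = idx$rmsea, cfi = idx$cfi, tli = idx$tli,
    baseline = base,
    standardized = std, r_squared = r2,
    sample_cov = S, implied_cov = Sigma,
    residuals = standardized_residuals(S, Sigma, n),
    n = n, n_scale = n_scale,
    converged = converged, n_iterations = as.integer(n_iter),
    grad_norm = max(abs(g)), heywood = heywood,
    pd_repair = repair,
    std_errors = NULL, wald = NULL), class = "sem_fit")
  if (se) {
    fit$wald <- wald_tests(fit, hessian = H)
    fit$std_errors <- stats::setNames(fit$wald$se, fit$wald$label)
  }
  fit
}

#' Wald tests for the free parameters of a fitted model
#'
#' Standard errors from the inverse observed information, i.e. the Hessian
#' of `(N - 1)/2` times the ML discrepancy at the optimum (central finite
#' differences), with two-sided normal p-values.
#'
#' @param fit a `sem_fit`.
#' @param hessian optional precomputed Hessian of the discrepancy.
#' @return data frame with `label`, `estimate`, `se`, `z`, `p`; `se` is `NA`
#'   (with a warning) when the information matrix is singular.
#' @export
wald_tests <- function(fit, hessian = NULL) {
  errv <- fit$params$error_variances
  if (is.null(hessian)) {
    engine <- make_engine(fit$model, fit$sample_cov, errv)
    hessian <- engine$hessian(fit$theta)
  }
  scale <- if (fit$n_scale == "n-1") fit$n - 1 else fit$n
  info <- scale / 2 * hessian
  V <- tryCatch(solve(info), error = function(e) NULL)
  labs <- names(fit$theta)
  if (is.null(V) || any(diag(V) < 0)) {
    warning("observed information singular or indefinite; standard errors unavailable")
    se <- rep(NA_real_, length(labs))
  } else {
    se <- sqrt(diag(V))
  }
  z <- ifelse(is.na(se) | se == 0, ifelse(fit$theta == 0, 0, NA), fit$theta / se)
  p <- ifelse(is.na(z), NA_real_, 2 * stats::pnorm(-abs(z)))
  p[!is.na(z) & z == 0] <- 1
  data.frame(label = labs, estimate = as.numeric(fit$theta), se = se, z = z, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.sem_fit <- function(x, digits = 3, ...) {
  cat("Maximum-likelihood covariance-structure fit\n")
  cat(sprintf("  chi2 = %.2f on df = %d (p %s), chi2/df = %.2f\n",
              x$chi2, x$df, format.pval(x$p_value, digits = 3), x$chi2 / max(x$df, 1)))
  cat(sprintf("  RMSEA = %.3f  CFI = %.3f  TLI = %.3f\n", x$rmsea, x$cfi, x$tli))
  cat(sprintf("  converged: %s (max |grad| %.2g, %d iterations)%s\n",
              x$converged, x$grad_norm, x$n_iterations,
              if (x$heywood) "  [Heywood case]" else ""))
  lr <- max(abs(x$residuals))
  cat(sprintf("  largest |standardized residual| = %.2f (largest positive %.2f)\n",
              lr, max(x$residuals)))
  if (!is.null(x$r_squared)) {
    cat("  R-squared:\n")
    print(round(x$r_squared, digits))
  }
  invisible(x)
}
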