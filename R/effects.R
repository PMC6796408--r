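## Direct / indirect / total effect decomposition and bootstrap intervals.

check_acyclic <- function(B) {
  nz <- abs(B) > 0
  nodes <- rownames(B)
  if (has_cycle(rep(nodes, times = colSums(nz)),
                nodes[unlist(apply(nz, 2, which))],
                nodes)) {
    stop("coefficient matrix contains a cycle; effects require a recursive system")
  }
}

#' Total and indirect effects of a recursive coefficient matrix
#'
#' For a directed-coefficient matrix `B` (entry `B[t, s]` is the effect of
#' `s` on `t`) over an acyclic system, the total-effect matrix is
#' `T = (I - B)^-1 - I` and the indirect effects are `T - B` (all compound
#' paths of length two or more).
#'
#' @param std_coeffs square named coefficient matrix (rows receive).
#' @return list with matrices `direct`, `indirect`, `total`.
#' @seealso [enumerate_paths()] for the path-product cross-check.
#' @export
total_effects <- function(std_coeffs) {
  B <- as.matrix(std_coeffs)
  stopifnot(nrow(B) == ncol(B))
  if (nrow(B) == 0) return(list(direct = B, indirect = B, total = B))
  if (is.null(rownames(B))) rownames(B) <- colnames(B) <- paste0("v", seq_len(nrow(B)))
  check_acyclic(B)
  Tm <- solve(diag(nrow(B)) - B) - diag(nrow(B))
  dimnames(Tm) <- dimnames(B)
  list(direct = B, indirect = Tm - B, total = Tm)
}

#' Enumerate all directed paths between two variables
#'
#' Depth-first enumeration of every directed path from `source` to `target`
#' with the product of coefficients along each; the sum of products over
#' paths of length >= 2 equals the indirect effect.  Serves as the
#' independent oracle for [total_effects()].
#'
#' @param std_coeffs square named coefficient matrix (rows receive).
#' @param source,target variable names.
#' @return list of `list(path = <character vector>, product = <number>)`.
#' @export
enumerate_paths <- function(std_coeffs, source, target) {
  B <- as.matrix(std_coeffs)
  check_acyclic(B)
  nodes <- rownames(B)
  stopifnot(source %in% nodes, target %in% nodes)
  out <- list()
  walk <- function(v, path, prod) {
    if (v == target && length(path) > 1) {
      out[[length(out) + 1]] <<- list(path = path, product = prod)
      return(invisible())
    }
    succ <- nodes[B[, v] != 0]
    for (w in succ) {
      if (w %in% path) next
      walk(w, c(path, w), prod * B[w, v])
    }
  }
  walk(source, source, 1)
  out
}

## standardized structural coefficient matrix over the structural latents:
## latents touched by at least one free latent-to-latent directed path
structural_matrix <- function(fit) {
  std <- fit$standardized
  lat <- fit$model$variables$name[fit$model$variables$kind == "latent"]
  struct <- std[std$kind == "directed" & std$source %in% lat & std$target %in% lat, , drop = FALSE]
  vars <- unique(c(struct$source[struct$status == "free"],
                   struct$target[struct$status == "free"]))
  vars <- lat[lat %in% vars] # keep model order
  B <- matrix(0, length(vars), length(vars), dimnames = list(vars, vars))
  keep <- struct$source %in% vars & struct$target %in% vars
  for (i in which(keep)) B[struct$target[i], struct$source[i]] <- struct$std[i]
  B
}

#' Standardized direct, indirect, and total effects of a fitted model
#'
#' Decomposes the standardized structural solution into direct, indirect
#' (`total - direct`), and total effects for every predictor -> outcome pair
#' connected by at least one path.  `total = direct + indirect` holds to
#' machine precision before any rounding.
#'
#' @param fit a `sem_fit`.
#' @return data frame of class `effects_table` with columns `outcome`,
#'   `predictor`, `direct`, `indirect`, `total`.
#' @export
effects_table <- function(fit) {
  B <- structural_matrix(fit)
  if (nrow(B) == 0) {
    out <- data.frame(outcome = character(), predictor = character(),
                      direct = numeric(), indirect = numeric(), total = numeric())
    class(out) <- c("effects_table", "data.frame")
    return(out)
  }
  eff <- total_effects(B)
  rows <- which(eff$total != 0 | eff$direct != 0, arr.ind = TRUE)
  out <- data.frame(
    outcome = rownames(B)[rows[, 1]],
    predictor = colnames(B)[rows[, 2]],
    direct = eff$direct[rows],
    indirect = eff$indirect[rows],
    total = eff$total[rows],
    stringsAsFactors = FALSE)
  out <- out[order(match(out$outcome, rownames(B)), match(out$predictor, colnames(B))), ]
  rownames(out) <- NULL
  class(out) <- c("effects_table", "data.frame")
  out
}

#' @export
print.effects_table <- function(x, digits = 3, ...) {
  y <- x
  for (cl in c("direct", "indirect", "total")) y[[cl]] <- round(y[[cl]], digits)
  NextMethod(object = y)
  invisible(x)
}

## one bootstrap replicate: draw data, refit, return standardized free paths
replicate_fit <- function(fit, n, data = NULL) {
  if (is.null(data)) {
    ds <- generate_data(fit$params, n = n, seed = NULL)
    X <- ds$data
  } else {
    X <- data[sample.int(nrow(data), n, replace = TRUE), , drop = FALSE]
  }
  mrep <- tryCatch(moments_from_data(X), error = function(e) NULL)
  if (is.null(mrep)) return(NULL)
  rf <- tryCatch(
    fit_sem(fit$model, mrep, standardize = fit$standardize, se = FALSE,
            n_scale = fit$n_scale, start = fit$theta, max_restarts = 2,
            grad_tol = 1e-4),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(rf) || !rf$converged) return(NULL)
  std <- rf$standardized
  free <- std$status == "free"
  stats::setNames(std$std[free], std$label[free])
}

#' Bootstrap confidence intervals for standardized coefficients
#'
#' Parametric bootstrap by default: `b` datasets of `n` records are simulated
#' from the fitted implied distribution, each is refitted (warm-started at
#' the point estimate), and percentile intervals are formed from the
#' replicate standardized coefficients.  When per-subject `data` are
#' supplied, rows are resampled nonparametrically instead.  Non-converged
#' replicates are dropped and counted; more than 50% failures flags the
#' result as unstable.
#'
#' @param fit a `sem_fit`.
#' @param b number of replicates (published analysis: 500).
#' @param n records per replicate; defaults to the fitted sample size.
#' @param seed master seed; replicate streams derive from it
#'   deterministically.
#' @param level confidence level (default .95, percentile intervals).
#' @param data optional raw per-subject data frame for nonparametric
#'   resampling.
#' @return object of class `sem_boot`: `replicates` (matrix b_converged x
#'   parameters), `ci` (data frame), `n_requested`, `n_converged`, `seed`,
#'   `level`, `unstable`.
#' @export
parametric_bootstrap <- function(fit, b = 500, n = NULL, seed = 1, level = 0.95,
                                 data = NULL) {
  stopifnot(b >= 1, level > 0, level < 1)
  if (is.null(n)) n <- fit$n
  set.seed(seed)
  reps <- vector("list", b)
  for (i in seq_len(b)) reps[[i]] <- replicate_fit(fit, n, data)
  ok <- !vapply(reps, is.null, logical(1))
  if (!any(ok)) stop("no bootstrap replicate converged")
  M <- do.call(rbind, reps[ok])
  a <- (1 - level) / 2
  ci <- data.frame(
    label = colnames(M),
    estimate = vapply(colnames(M), function(l) {
      std <- fit$standardized
      std$std[match(l, std$label)]
    }, numeric(1)),
    lower = apply(M, 2, stats::quantile, probs = a),
    upper = apply(M, 2, stats::quantile, probs = 1 - a),
    row.names = NULL, stringsAsFactors = FALSE)
  unstable <- mean(!ok) > 0.5
  if (unstable) warning("more than 50% of bootstrap replicates failed to converge; flagged unstable")
  structure(list(replicates = M, ci = ci, n_requested = b,
                 n_converged = sum(ok), seed = seed, level = level,
                 unstable = unstable, n = n,
                 type = if (is.null(data)) "parametric" else "nonparametric"),
            class = "sem_boot")
}

#' @export
print.sem_boot <- function(x, digits = 3, ...) {
  cat(sprintf("%s bootstrap: %d/%d replicates converged (n = %d, %.0f%% percentile intervals)%s\n",
              x$type, x$n_converged, x$n_requested, x$n,
              100 * x$level, if (x$unstable) " [UNSTABLE]" else ""))
  y <- x$ci
  for (cl in c("estimate", "lower", "upper")) y[[cl]] <- round(y[[cl]], digits)
  print(y)
  invisible(x)
}
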