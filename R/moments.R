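#' Construct a validated set of sample moments
#'
#' A `moment_set` bundles the summary statistics a covariance-structure
#' analysis consumes: variable names, means, standard deviations, a
#' correlation matrix, and the sample size.  It is the in-memory form of a
#' published descriptives table plus correlation matrix.
#'
#' @param means named numeric vector of variable means (instrument units).
#' @param sds numeric vector of positive standard deviations, same order.
#' @param correlations square symmetric correlation matrix with unit diagonal
#'   and all entries in `[-1, 1]`.
#' @param n positive integer sample size; must exceed the number of variables.
#' @param variable_names optional character vector; defaults to
#'   `names(means)` or the dimnames of `correlations`.
#' @return an object of class `moment_set`.
#' @seealso [load_moments()], [to_covariance()], [whes_moments()]
#' @export
moment_set <- function(means, sds, correlations, n, variable_names = NULL) {
  if (is.null(variable_names)) {
    variable_names <- names(means)
    if (is.null(variable_names)) variable_names <- rownames(correlations)
  }
  if (is.null(variable_names)) {
    stop("variable names must be supplied (named means or dimnames on the correlation matrix)")
  }
  p <- length(variable_names)
  if (length(means) != p) stop("length of means (", length(means), ") does not match ", p, " variables")
  if (length(sds) != p) stop("length of sds (", length(sds), ") does not match ", p, " variables")
  if (!is.matrix(correlations) || nrow(correlations) != p || ncol(correlations) != p) {
    stop("correlation matrix must be ", p, "x", p, ", got ",
         paste(dim(correlations), collapse = "x"))
  }
  if (anyDuplicated(variable_names)) stop("duplicated variable names")
  if (any(is.na(sds))) {
    stop("missing SD for variable(s): ", paste(variable_names[is.na(sds)], collapse = ", "))
  }
  if (any(sds <= 0)) {
    stop("non-positive SD for variable(s): ", paste(variable_names[sds <= 0], collapse = ", "))
  }
  bad <- which(abs(correlations - t(correlations)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("correlation matrix not symmetric at cell (",
         variable_names[bad[1, 1]], ", ", variable_names[bad[1, 2]], ")")
  }
  if (any(abs(diag(correlations) - 1) > 1e-8)) {
    stop("correlation diagonal not 1 for variable: ",
         variable_names[which(abs(diag(correlations) - 1) > 1e-8)[1]])
  }
  out <- which(abs(correlations) > 1 + 1e-12, arr.ind = TRUE)
  if (nrow(out) > 0) {
    stop("correlation outside [-1, 1] at cell (",
         variable_names[out[1, 1]], ", ", variable_names[out[1, 2]], "): ",
         correlations[out[1, , drop = FALSE]])
  }
  n <- as.integer(n)
  if (is.na(n) || n < p + 1) stop("sample size n must be at least p + 1 = ", p + 1)
  means <- as.numeric(means); sds <- as.numeric(sds)
  names(means) <- names(sds) <- variable_names
  dimnames(correlations) <- list(variable_names, variable_names)
  structure(
    list(variable_names = variable_names, means = means, sds = sds,
         correlations = correlations, n = n),
    class = "moment_set")
}

#' @export
print.moment_set <- function(x, ...) {
  cat("moment_set:", length(x$variable_names), "variables, n =", x$n, "\n")
  df <- data.frame(mean = x$means, sd = x$sds)
  print(round(df, 3))
  invisible(x)
}

canonical_name <- function(x) toupper(gsub("[^A-Za-z0-9]", "", trimws(x)))

#' Read published moment tables from CSV files
#'
#' Reads a descriptives table (columns `variable`, `mean`, `sd`, `n`) and a
#' square correlation matrix (header row plus a first column of names) and
#' returns a validated [moment_set].  Variable names are matched after
#' canonicalization (case and punctuation insensitive); the variable order of
#' the returned object follows the correlations file.
#'
#' @param descriptives_path CSV with columns `variable`, `mean`, `sd`, `n`.
#' @param correlations_path CSV: first column of names, then a p x p block.
#' @return a [moment_set].
#' @export
load_moments <- function(descriptives_path, correlations_path) {
  if (!file.exists(descriptives_path)) stop("descriptives file not found: ", descriptives_path)
  if (!file.exists(correlations_path)) stop("correlations file not found: ", correlations_path)
  desc <- utils::read.csv(descriptives_path, stringsAsFactors = FALSE)
  need <- c("variable", "mean", "sd", "n")
  if (!all(need %in% names(desc))) {
    stop("descriptives file must have columns: ", paste(need, collapse = ", "))
  }
  corr <- utils::read.csv(correlations_path, stringsAsFactors = FALSE, check.names = FALSE)
  cn <- as.character(corr[[1]])
  Rm <- as.matrix(corr[, -1, drop = FALSE])
  if (nrow(Rm) != ncol(Rm)) {
    stop("correlation matrix is not square: ", nrow(Rm), " rows, ", ncol(Rm), " columns")
  }
  storage.mode(Rm) <- "double"
  key_desc <- canonical_name(desc$variable)
  key_corr <- canonical_name(cn)
  miss <- setdiff(key_corr, key_desc)
  if (length(miss) > 0) stop("variables in correlations but not descriptives: ", paste(miss, collapse = ", "))
  extra <- setdiff(key_desc, key_corr)
  if (length(extra) > 0) stop("variables in descriptives but not correlations: ", paste(extra, collapse = ", "))
  ord <- match(key_corr, key_desc)
  desc <- desc[ord, ]
  moment_set(means = desc$mean, sds = desc$sd, correlations = Rm,
             n = desc$n[1], variable_names = cn)
}

#' Write a moment_set back to the two-file CSV representation
#'
#' Inverse of [load_moments()]; round-trips exactly at the stored precision.
#'
#' @param m a [moment_set].
#' @param descriptives_path,correlations_path output CSV paths.
#' @param digits decimal digits retained in the files.
#' @export
write_moments <- function(m, descriptives_path, correlations_path, digits = 6) {
  desc <- data.frame(variable = m$variable_names,
                     mean = round(m$means, digits),
                     sd = round(m$sds, digits),
                     n = m$n)
  utils::write.csv(desc, descriptives_path, row.names = FALSE, quote = FALSE)
  corr <- data.frame(variable = m$variable_names,
                     round(m$correlations, digits), check.names = FALSE)
  names(corr) <- c("variable", m$variable_names)
  utils::write.csv(corr, correlations_path, row.names = FALSE, quote = FALSE)
  invisible(m)
}

#' Moments of the packaged lifetime-abuse / CVD-risk study tables
#'
#' Loads the packaged fixtures transcribing the published descriptives and
#' correlation tables for the Women's Health Effects Study cohort
#' (14 indicators, N = 227).  Two entries of the descriptives fixture are
#' derived rather than printed: the SD of the binary adult-sexual-assault
#' indicator comes from its prevalence (38.8%) via [binary_sd()], and the
#' mean/SD of the 0/1/2-coded smoking indicator come from the category
#' counts 75/68/84 via [categorical_moments()].
#'
#' @return a [moment_set] with 14 variables and n = 227.
#' @export
whes_moments <- function() {
  load_moments(
    system.file("extdata", "table1_descriptives.csv", package = "phantomsem", mustWork = TRUE),
    system.file("extdata", "table2_correlations.csv", package = "phantomsem", mustWork = TRUE))
}

#' Standard deviation of a 0/1 indicator from its prevalence
#'
#' For a binary variable coded 0/1 with success probability `p`, the
#' (population-divisor) SD is `sqrt(p * (1 - p))`.  Used to supply the SD of
#' a dichotomous indicator when only its prevalence is published.
#'
#' @param prevalence proportion of 1s, strictly between 0 and 1.
#' @return the SD as a single number.
#' @export
binary_sd <- function(prevalence) {
  if (!is.numeric(prevalence) || length(prevalence) != 1 ||
      is.na(prevalence) || prevalence <= 0 || prevalence >= 1) {
    stop("prevalence must be a single number strictly between 0 and 1")
  }
  sqrt(prevalence * (1 - prevalence))
}

#' Mean and SD of a coded categorical variable from category counts
#'
#' Computes the population-style (divisor n) mean and SD of a variable whose
#' categories are assigned numeric codes, from the published category counts.
#' Used for ordinal indicators such as never/past/current smoking coded
#' 0/1/2.
#'
#' @param counts named positive counts per category.
#' @param codes named numeric codes; names must cover `names(counts)`.
#' @return list with elements `mean` and `sd`.
#' @export
categorical_moments <- function(counts, codes) {
  if (length(counts) == 0) stop("counts must be non-empty")
  if (is.null(names(counts)) || is.null(names(codes))) stop("counts and codes must be named")
  if (any(counts <= 0)) stop("counts must be positive")
  miss <- setdiff(names(counts), names(codes))
  if (length(miss) > 0) stop("codes missing for categories: ", paste(miss, collapse = ", "))
  x <- codes[names(counts)]
  n <- sum(counts)
  mu <- sum(counts * x) / n
  v <- sum(counts * (x - mu)^2) / n
  list(mean = mu, sd = sqrt(v))
}

#' Assemble the covariance matrix a covariance-structure fit consumes
#'
#' Converts a [moment_set] into a covariance matrix,
#' `cov[i, j] = r[i, j] * sd_i * sd_j`, optionally forcing selected variables
#' to unit variance (the published analysis standardizes the three abuse
#' indicators, which are measured on incommensurate scales).
#'
#' @param m a [moment_set].
#' @param standardize character vector of variable names whose SD is set to 1.
#' @return symmetric covariance matrix with dimnames.
#' @export
to_covariance <- function(m, standardize = character()) {
  stopifnot(inherits(m, "moment_set"))
  unknown <- setdiff(standardize, m$variable_names)
  if (length(unknown) > 0) stop("unknown variable(s) in standardize: ", paste(unknown, collapse = ", "))
  sds <- m$sds
  sds[standardize] <- 1
  S <- m$correlations * (sds %o% sds)
  S <- (S + t(S)) / 2
  dimnames(S) <- list(m$variable_names, m$variable_names)
  S
}

#' Compute sample moments from per-subject records
#'
#' Convenience for feeding generated or raw data back through the
#' moment-table pipeline: computes means, SDs (n - 1 divisor, as a sample
#' covariance), and the correlation matrix.
#'
#' @param data data frame or matrix of numeric records (rows = subjects).
#' @return a [moment_set].
#' @export
moments_from_data <- function(data) {
  X <- as.matrix(data)
  moment_set(means = colMeans(X), sds = apply(X, 2, stats::sd),
             correlations = stats::cor(X), n = nrow(X),
             variable_names = colnames(X))
}

#' Repair a symmetric matrix to positive definiteness
#'
#' Correlations printed at two decimals can produce a covariance matrix with
#' a (slightly) non-positive eigenvalue.  `nearest_pd` returns its input
#' unchanged when the smallest eigenvalue already exceeds `eigen_floor`;
#' otherwise eigenvalues are clipped to the floor (the Frobenius-nearest
#' symmetric repair), the unit diagonal is restored for correlation inputs,
#' and the repair magnitude is reported via a message and the
#' `"repair_max_change"` attribute.
#'
#' @param matrix symmetric numeric matrix.
#' @param eigen_floor smallest admissible eigenvalue (default `1e-8` times
#'   the mean diagonal).
#' @param quiet suppress the repair message.
#' @return a symmetric positive-definite matrix with attribute
#'   `repair_max_change` (0 when untouched).
#' @export
nearest_pd <- function(matrix, eigen_floor = NULL, quiet = FALSE) {
  if (!isSymmetric(unname(matrix), tol = 1e-8)) stop("input matrix is not symmetric")
  if (is.null(eigen_floor)) eigen_floor <- 1e-8 * mean(diag(matrix))
  e <- eigen((matrix + t(matrix)) / 2, symmetric = TRUE)
  if (min(e$values) > eigen_floor) {
    attr(matrix, "repair_max_change") <- 0
    return(matrix)
  }
  vals <- pmax(e$values, eigen_floor)
  out <- e$vectors %*% diag(vals, nrow = length(vals)) %*% t(e$vectors)
  out <- (out + t(out)) / 2
  is_corr <- all(abs(diag(matrix) - 1) < 1e-8)
  if (is_corr) {
    d <- sqrt(diag(out))
    out <- out / (d %o% d)
    diag(out) <- 1
  }
  dimnames(out) <- dimnames(matrix)
  delta <- max(abs(out - matrix))
  if (!quiet) {
    message(sprintf("nearest_pd: repaired matrix (min eigenvalue %.3g), max elementwise change %.3g",
                    min(e$values), delta))
  }
  attr(out, "repair_max_change") <- delta
  out
}
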