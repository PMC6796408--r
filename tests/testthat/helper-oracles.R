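## shared fixtures and independent oracles, built in code

# random symmetric positive-definite matrix
rand_pd <- function(p, jitter = 0.5) {
  A <- matrix(stats::rnorm(p * p), p)
  S <- tcrossprod(A) / p + jitter * diag(p)
  dimnames(S) <- list(paste0("v", 1:p), paste0("v", 1:p))
  S
}

# random sparse acyclic coefficient matrix (lower-triangular under a
# permutation, so guaranteed recursive)
rand_dag <- function(k, density = 0.4) {
  B <- matrix(0, k, k, dimnames = list(paste0("v", 1:k), paste0("v", 1:k)))
  for (i in 2:k) for (j in 1:(i - 1)) {
    if (stats::runif(1) < density) B[i, j] <- stats::runif(1, -1, 1)
  }
  perm <- sample(k)
  B[perm, perm]
}

# brute-force indirect effect: sum of coefficient products over all directed
# paths of length >= 2, found by depth-first search on the raw matrix
dfs_indirect <- function(B, from, to) {
  k <- nrow(B)
  total <- 0
  walk <- function(v, prod, len) {
    for (w in seq_len(k)) {
      if (B[w, v] == 0) next
      pr <- prod * B[w, v]
      if (w == to && len + 1 >= 2) total <<- total + pr
      walk(w, pr, len + 1)
    }
  }
  walk(from, 1, 0)
  total
}

# two-variable observed path model y ~ x with free slope and variances
two_var_model <- function() {
  sem_model(
    variables = data.frame(name = c("x", "y"), kind = "observed"),
    paths = data.frame(
      source = c("x", "x", "y"), target = c("y", "x", "y"),
      kind = c("directed", "covariance", "covariance"),
      status = "free", value = NA_real_,
      label = c("b", "vx", "vy")))
}

# saturated model over observed variables: every moment a free parameter
saturated_model <- function(vn) {
  pairs <- expand.grid(i = seq_along(vn), j = seq_along(vn))
  pairs <- pairs[pairs$i <= pairs$j, ]
  sem_model(
    variables = data.frame(name = vn, kind = "observed"),
    paths = data.frame(
      source = vn[pairs$i], target = vn[pairs$j], kind = "covariance",
      status = "free", value = NA_real_,
      label = paste0("s_", pairs$i, "_", pairs$j)))
}

# the study fit is reused across many tests; compute it once per run
whes_cache <- new.env(parent = emptyenv())
get_whes_fit <- function() {
  if (is.null(whes_cache$fit)) {
    whes_cache$fit <- fit_sem(build_whes_model(), whes_moments(),
                              standardize = c("CTQ", "ISA", "ASA"))
  }
  whes_cache$fit
}

# published standardized direct effects, used as inputs to decomposition
# checks (predictor in columns, outcome in rows)
published_direct_effects <- function() {
  vars <- c("LifetimeAbuse", "DepIntercept", "DepSlope", "Smoking",
            "BodyWeight", "CVDRisk", "AgeLat")
  B <- matrix(0, 7, 7, dimnames = list(vars, vars))
  B["DepIntercept", "LifetimeAbuse"] <- .428
  B["DepSlope", "LifetimeAbuse"] <- -.020
  B["Smoking", "LifetimeAbuse"] <- .349
  B["Smoking", "DepSlope"] <- .122
  B["BodyWeight", "LifetimeAbuse"] <- .213
  B["BodyWeight", "DepIntercept"] <- .012
  B["BodyWeight", "DepSlope"] <- .031
  B["BodyWeight", "Smoking"] <- -.153
  B["CVDRisk", "LifetimeAbuse"] <- -.135
  B["CVDRisk", "DepSlope"] <- -.167
  B["CVDRisk", "Smoking"] <- .091
  B["CVDRisk", "BodyWeight"] <- .526
  B["CVDRisk", "AgeLat"] <- .347
  B
}
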