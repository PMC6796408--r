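test_that("implied covariance reproduces hand path algebra on tiny models", {
  # no directed paths: Sigma equals the assembled S block
  m0 <- sem_model(
    variables = data.frame(name = c("x", "y"), kind = "observed"),
    paths = data.frame(source = c("x", "y"), target = c("x", "y"),
                       kind = "covariance", status = "fixed", value = c(2, 3)))
  expect_equal(implied_covariance(m0, stats::setNames(numeric(0), character(0))),
               diag(c(2, 3)), ignore_attr = TRUE)

  # single path x -> y, unit exogenous variance, zero disturbance:
  # cov(x, y) = b and var(y) = b^2
  m1 <- sem_model(
    variables = data.frame(name = c("x", "y"), kind = "observed"),
    paths = data.frame(source = c("x", "x", "y"), target = c("y", "x", "y"),
                       kind = c("directed", "covariance", "covariance"),
                       status = "fixed", value = c(0.7, 1, 0)))
  Sig <- implied_covariance(m1, stats::setNames(numeric(0), character(0)))
  expect_equal(Sig["x", "y"], 0.7)
  expect_equal(Sig["y", "y"], 0.49)
})

test_that("ml discrepancy: zero at equality, closed-form value, permutation invariance", {
  S <- rand_pd(4)
  expect_equal(ml_discrepancy(S, S), 0, tolerance = 1e-12)
  # S = diag(2,2), Sigma = diag(1,1): F = 2 (log(1/2) + 2 - 1)
  expect_equal(ml_discrepancy(diag(c(2, 2)), diag(c(1, 1))),
               2 * (log(1 / 2) + 2 - 1), tolerance = 1e-12)
  set.seed(21)
  A <- rand_pd(5); B <- rand_pd(5)
  perm <- sample(5)
  expect_equal(ml_discrepancy(A[perm, perm], B[perm, perm]),
               ml_discrepancy(A, B), tolerance = 1e-10)
  expect_error(ml_discrepancy(matrix(c(1, 2, 2, 1), 2), diag(2)),
               "not positive definite.*eigenvalue")
})

test_that("ml discrepancy is a divergence on random PD pairs", {
  set.seed(31)
  for (i in 1:200) {
    p <- sample(2:6, 1)
    A <- rand_pd(p); B <- rand_pd(p)
    expect_gt(ml_discrepancy(A, B), 0)
  }
})

test_that("baseline independence model has the closed-form chi-square", {
  # diagonal covariance: baseline fits perfectly
  mi <- moment_set(means = c(a = 0, b = 0), sds = c(2, 3),
                   correlations = diag(2), n = 100)
  expect_equal(baseline_chi2(mi)$chi2, 0, tolerance = 1e-12)
  # 14-variable fixture: df = p(p-1)/2 = 91
  expect_equal(baseline_chi2(whes_moments())$df, 91L)
  # 2 x 2 with correlation r: chi2 = -(n-1) log(1 - r^2)
  r <- 0.43; n <- 150
  m2 <- moment_set(means = c(a = 0, b = 0), sds = c(1, 1),
                   correlations = matrix(c(1, r, r, 1), 2), n = n)
  expect_equal(baseline_chi2(m2)$chi2, -(n - 1) * log(1 - r^2), tolerance = 1e-10)
})

test_that("fit indices follow their defining formulas", {
  idx <- fit_indices(chi2 = 75, df = 75, chi2_b = 900, df_b = 91, n = 227)
  expect_equal(idx$rmsea, 0)
  expect_equal(idx$cfi, 1)
  # published chi-square and df give the printed RMSEA
  idx2 <- fit_indices(chi2 = 148.94, df = 75, chi2_b = 900, df_b = 91, n = 227)
  expect_equal(idx2$rmsea, sqrt((148.94 - 75) / (75 * 226)), tolerance = 1e-12)
  expect_equal(round(idx2$rmsea, 2), 0.07)
  # with equal df the two incremental indices coincide (algebraic identity)
  idx3 <- fit_indices(chi2 = 130, df = 80, chi2_b = 700, df_b = 80, n = 200)
  expect_equal(idx3$tli, idx3$cfi, tolerance = 1e-12)
  expect_equal(idx3$p_value, pchisq(130, 80, lower.tail = FALSE))
})

test_that("standardized residuals: zero at equality, scale invariant, hand formula", {
  S <- rand_pd(3)
  expect_equal(standardized_residuals(S, S, 100), matrix(0, 3, 3),
               ignore_attr = TRUE)
  Sig <- rand_pd(3)
  expect_equal(standardized_residuals(5 * S, 5 * Sig, 80),
               standardized_residuals(S, Sig, 80), tolerance = 1e-12)
  s <- matrix(c(2, 1, 1, 3), 2); sig <- matrix(c(1.8, 0.7, 0.7, 3.1), 2)
  r12 <- (1 - 0.7) / sqrt((1.8 * 3.1 + 0.7^2) / 50)
  expect_equal(standardized_residuals(s, sig, 50)[1, 2], r12, tolerance = 1e-12)
})

test_that("the analytic gradient matches numerical differentiation", {
  model <- build_whes_model()
  m <- whes_moments()
  S <- to_covariance(m, c("CTQ", "ISA", "ASA"))
  S <- nearest_pd(S, quiet = TRUE)
  obs <- model$variables$name[model$variables$kind == "observed"]
  S <- S[obs, obs]
  errv <- phantomsem:::resolve_error_variances(model, S)
  eng <- phantomsem:::make_engine(model, S, errv)
  set.seed(41)
  th <- phantomsem:::start_values(model, S)
  for (jit in list(1, runif(length(th), 0.9, 1.1))) {
    thj <- th * jit
    expect_equal(eng$gradient(thj), pracma::grad(eng$objective, thj),
                 tolerance = 1e-5)
  }
})

test_that("fitting a model to its own implied covariance recovers the parameters", {
  fit <- get_whes_fit()
  Sig <- implied_covariance(fit$params)
  m_self <- moment_set(means = rep(0, 14), sds = sqrt(diag(Sig)),
                       correlations = stats::cov2cor(Sig), n = 227,
                       variable_names = rownames(Sig))
  refit <- fit_sem(build_whes_model(), m_self, se = FALSE,
                   error_variances = fit$params$error_variances)
  expect_lt(refit$discrepancy_min, 1e-9)
  expect_equal(refit$theta, fit$theta, tolerance = 1e-3)
})

test_that("standardized coefficient of a single-predictor model is the implied correlation", {
  mm <- moment_set(means = c(x = 0, y = 0), sds = c(2, 5),
                   correlations = matrix(c(1, .41, .41, 1), 2), n = 120)
  fit <- fit_sem(two_var_model(), mm, se = FALSE)
  std <- fit$standardized
  b_std <- std$std[std$label %in% "b"]
  expect_equal(b_std, 0.41, tolerance = 1e-6)
})

test_that("Wald standard errors match the closed-form regression result", {
  set.seed(51)
  n <- 400
  x <- rnorm(n); y <- 0.6 * x + rnorm(n, sd = 0.9)
  mm <- moments_from_data(cbind(x = x, y = y))
  fit <- fit_sem(two_var_model(), mm)
  sxx <- var(x); sxy <- cov(x, y); syy <- var(y)
  b_hat <- sxy / sxx
  ve <- syy - sxy^2 / sxx
  se_closed <- sqrt(ve / (sxx * (n - 1)))
  w <- fit$wald
  expect_equal(w$estimate[w$label == "b"], b_hat, tolerance = 1e-6)
  expect_equal(w$se[w$label == "b"], se_closed, tolerance = 0.02)
  # a zero estimate yields z = 0 and p = 1
  mm0 <- moment_set(means = c(x = 0, y = 0), sds = c(1, 1),
                    correlations = diag(2), n = 100)
  fit0 <- fit_sem(two_var_model(), mm0)
  w0 <- fit0$wald
  expect_equal(w0$estimate[w0$label == "b"], 0, tolerance = 1e-8)
  expect_equal(w0$p[w0$label == "b"], 1, tolerance = 1e-6)
})

test_that("results are invariant to observed-variable ordering", {
  m <- whes_moments()
  set.seed(61)
  perm <- sample(14)
  m2 <- moment_set(means = m$means[perm], sds = m$sds[perm],
                   correlations = m$correlations[perm, perm], n = m$n,
                   variable_names = m$variable_names[perm])
  fit <- get_whes_fit()
  fit2 <- fit_sem(build_whes_model(), m2, standardize = c("CTQ", "ISA", "ASA"),
                  se = FALSE)
  expect_equal(fit2$chi2, fit$chi2, tolerance = 1e-6)
  expect_equal(fit2$theta, fit$theta, tolerance = 1e-4)
})
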