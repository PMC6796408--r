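test_that("packaged study tables load with the printed values in table order", {
  m <- whes_moments()
  expect_s3_class(m, "moment_set")
  expect_length(m$variable_names, 14)
  expect_equal(m$n, 227L)
  expect_equal(unname(m$means["AGE"]), 39.4)
  expect_equal(unname(m$sds["AGE"]), 9.8)
  expect_equal(m$correlations["SBP", "DBP"], 0.66)
  expect_equal(m$correlations["CTQ", "ISA"], 0.34)
  expect_equal(m$correlations["WC", "BMI"], 0.89)
  # derived entries of the fixture equal their documented derivations
  expect_equal(unname(m$sds["ASA"]), binary_sd(0.388), tolerance = 1e-6)
  smoke <- categorical_moments(c(never = 75, past = 68, current = 84),
                               c(never = 0, past = 1, current = 2))
  expect_equal(unname(m$means["SMOKE"]), smoke$mean, tolerance = 1e-6)
  expect_equal(unname(m$sds["SMOKE"]), smoke$sd, tolerance = 1e-6)
})

test_that("moment validation names the offending cell or variable", {
  R <- diag(2); R[1, 2] <- R[2, 1] <- 1.2
  expect_error(moment_set(means = c(a = 0, b = 0), sds = c(1, 1),
                          correlations = R, n = 50),
               "outside \\[-1, 1\\].*a.*b")
  R2 <- diag(2); R2[1, 2] <- .3
  expect_error(moment_set(means = c(a = 0, b = 0), sds = c(1, 1),
                          correlations = R2, n = 50), "not symmetric")
  expect_error(moment_set(means = c(a = 0, b = 0), sds = c(1, NA),
                          correlations = diag(2), n = 50), "missing SD.*b")
  expect_error(moment_set(means = c(a = 0, b = 0, c = 0), sds = c(1, 1),
                          correlations = diag(2), n = 50), "does not match")
  expect_error(moment_set(means = c(a = 0, b = 0), sds = c(1, 1),
                          correlations = diag(2), n = 2), "at least")
  # file-level: mismatched variable sets between the two CSVs
  d1 <- tempfile(fileext = ".csv"); d2 <- tempfile(fileext = ".csv")
  writeLines(c("variable,mean,sd,n", "x,0,1,50", "y,0,1,50"), d1)
  writeLines(c("variable,x,z", "x,1,0.5", "z,0.5,1"), d2)
  expect_error(load_moments(d1, d2), "Z")
})

test_that("derived SDs match direct arithmetic", {
  expect_equal(binary_sd(0.5), 0.5)
  expect_equal(binary_sd(0.388), sqrt(0.388 * 0.612))
  expect_equal(binary_sd(0.01), sqrt(0.01 * 0.99))
  expect_error(binary_sd(0), "between 0 and 1")
  expect_error(binary_sd(1.1), "between 0 and 1")

  cm <- categorical_moments(c(a = 10, b = 10), c(a = 0, b = 1))
  expect_equal(cm$mean, 0.5)
  expect_equal(cm$sd, 0.5)
  # weighted arithmetic oracle for the smoking counts
  x <- rep(c(0, 1, 2), c(75, 68, 84))
  cm2 <- categorical_moments(c(never = 75, past = 68, current = 84),
                             c(never = 0, past = 1, current = 2))
  expect_equal(cm2$mean, mean(x))
  expect_equal(cm2$sd, sqrt(mean((x - mean(x))^2)))
  expect_equal(categorical_moments(c(only = 7), c(only = 3))$sd, 0)
  expect_error(categorical_moments(c(a = 1), c(b = 0)), "codes missing")
  expect_error(categorical_moments(numeric(0), c(a = 0)), "non-empty")
})

test_that("to_covariance rescales correlations and honors standardization", {
  m <- whes_moments()
  S <- to_covariance(m)
  expect_equal(S["SBP", "DBP"], 0.66 * 15.5 * 9.5)
  expect_equal(S["AGE", "AGE"], 9.8^2)
  Sz <- to_covariance(m, standardize = c("CTQ", "ISA", "ASA"))
  expect_equal(Sz["CTQ", "ISA"], 0.34)
  expect_equal(Sz["CTQ", "CTQ"], 1)
  expect_equal(Sz["AGE", "CTQ"], -0.02 * 9.8)
  expect_error(to_covariance(m, "NOPE"), "unknown variable")
  # identity correlations give a diagonal matrix of variances
  mi <- moment_set(means = c(a = 0, b = 0), sds = c(2, 3),
                   correlations = diag(2), n = 30)
  expect_equal(to_covariance(mi), diag(c(4, 9)),
               ignore_attr = TRUE)
})

test_that("moments computed from data invert to the sample covariance", {
  set.seed(11)
  X <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  m <- moments_from_data(X)
  expect_equal(to_covariance(m), cov(X), tolerance = 1e-12)
})

test_that("moment tables round-trip through the CSV representation", {
  m <- whes_moments()
  d <- tempfile(fileext = ".csv"); r <- tempfile(fileext = ".csv")
  write_moments(m, d, r)
  m2 <- load_moments(d, r)
  expect_equal(m2$variable_names, m$variable_names)
  expect_equal(m2$means, m$means, tolerance = 1e-6)
  expect_equal(m2$sds, m$sds, tolerance = 1e-6)
  expect_equal(m2$correlations, m$correlations, tolerance = 1e-6)
  expect_equal(m2$n, m$n)
})

test_that("nearest_pd leaves PD input untouched, repairs by eigenvalue clipping, and is idempotent", {
  I5 <- diag(5)
  expect_equal(nearest_pd(I5, quiet = TRUE), I5, ignore_attr = TRUE)
  expect_equal(attr(nearest_pd(I5, quiet = TRUE), "repair_max_change"), 0)

  bad <- matrix(c(1, 1, 1, 1), 2) # singular correlation matrix
  rep1 <- nearest_pd(bad, eigen_floor = 1e-6, quiet = TRUE)
  expect_lt(rep1[1, 2], 1)
  expect_gt(min(eigen(rep1, symmetric = TRUE)$values), 0)
  expect_equal(diag(rep1), c(1, 1))
  rep2 <- nearest_pd(rep1, eigen_floor = 1e-6, quiet = TRUE)
  expect_equal(unclass(rep2), unclass(rep1), tolerance = 1e-10, ignore_attr = TRUE)

  # the printed correlation matrix needs at most a sub-0.01 repair
  R <- whes_moments()$correlations
  repR <- nearest_pd(R, quiet = TRUE)
  expect_lt(attr(repR, "repair_max_change"), 0.01)

  expect_error(nearest_pd(matrix(c(1, 2, 0, 1), 2)), "not symmetric")
})
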