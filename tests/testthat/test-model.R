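test_that("the final study model reproduces the published degrees-of-freedom accounting", {
  m <- build_whes_model()
  expect_equal(count_df(m), 75L)
  expect_length(free_parameters(m), 30)
  # 13 structural latent-to-latent free paths
  lat <- m$variables$name[m$variables$kind == "latent"]
  struct <- m$paths[m$paths$kind == "directed" & m$paths$status == "free" &
                      m$paths$source %in% lat & m$paths$target %in% lat, ]
  expect_equal(nrow(struct), 13)
  # no slope loadings free: two more degrees of freedom
  expect_equal(count_df(build_whes_model(free_slope_times = integer())), 77L)
  expect_error(build_whes_model(error_fractions = c(AGE = .01)), "missing")
})

test_that("freeing any fixed path lowers df by exactly one", {
  m <- build_whes_model()
  fixed_idx <- which(m$paths$status == "fixed")
  for (i in fixed_idx[c(1, 5, 12)]) {
    m2 <- m
    m2$paths$status[i] <- "free"
    m2$paths$label[i] <- "extra_parameter"
    m2$paths$value[i] <- NA_real_
    m2 <- sem_model(m2$variables, m2$paths, m2$error_fractions, m2$phantom)
    expect_equal(count_df(m2), count_df(m) - 1L)
  }
})

test_that("default error fractions encode the published reliabilities", {
  ef <- default_error_fractions()
  expect_equal(unname(ef["CTQ"]), 0.06)   # 1 - alpha, alpha = .94
  expect_equal(unname(ef["ISA"]), 0.15)
  expect_equal(unname(ef["ASA"]), 0.15)
  expect_true(all(ef[paste0("CESD", 1:5)] == 0.30))
  expect_equal(unname(ef["BMI"]), 0.16)
  expect_equal(unname(ef["WC"]), 0.05)
  expect_equal(unname(ef["SBP"]), 0.25)
  expect_equal(unname(ef["DBP"]), 0.25)
  expect_equal(unname(ef["SMOKE"]), 0.05)
  expect_equal(unname(ef["AGE"]), 0.01)
  expect_equal(unname(ef["phantom"]), 0.20)
})

test_that("phantom composite variance follows the sum-of-moments formula", {
  expect_equal(phantom_explained_variance(c(1, 1, 1), c(0, 0, 0)), 3)
  expect_equal(phantom_explained_variance(c(1, 1, 1), c(.34, .35, .16)), 4.70)
  # homogeneity: scaling all inputs scales the output
  v <- c(1.2, 0.8, 1.1); cv <- c(.3, .2, .1)
  expect_equal(phantom_explained_variance(3 * v, 3 * cv),
               3 * phantom_explained_variance(v, cv))
  expect_error(phantom_explained_variance(c(-1, 1, 1), c(0, 0, 0)), "positive")
  expect_error(phantom_explained_variance(c(.1, .1, .1), c(-.2, -.2, -.2)),
               "inadmissible")
})

test_that("the phantom disturbance stays at 20% of total variance for any parameter value", {
  model <- build_whes_model()
  fit <- get_whes_fit()
  for (mult in c(0.5, 1, 2.3)) {
    th <- fit$theta * mult
    pr <- sem_params(model, th, fit$params$error_variances)
    expl <- phantom_explained_variance(
      th[c("v_ChildAbuse", "v_PartnerAbuse", "v_ASAlat")],
      th[c("c_ChildAbuse_PartnerAbuse", "c_ChildAbuse_ASAlat", "c_PartnerAbuse_ASAlat")])
    d <- pr$S["LifetimeAbuse", "LifetimeAbuse"]
    expect_equal(d, 0.25 * expl, tolerance = 1e-12)
    expect_equal(d / (d + expl), 0.20, tolerance = 1e-12)
  }
})

test_that("model validation rejects ill-formed specifications", {
  vars <- data.frame(name = c("x", "y"), kind = "observed")
  cyc <- data.frame(source = c("x", "y"), target = c("y", "x"),
                    kind = "directed", status = "free", label = c("a", "b"))
  expect_error(sem_model(vars, cyc), "cycle")
  nolab <- data.frame(source = "x", target = "y", kind = "directed",
                      status = "free")
  expect_error(sem_model(vars, nolab), "without a label")
  noval <- data.frame(source = "x", target = "y", kind = "directed",
                      status = "fixed")
  expect_error(sem_model(vars, noval), "without a value")
  ghost <- data.frame(source = "x", target = "z", kind = "directed",
                      status = "fixed", value = 1)
  expect_error(sem_model(vars, ghost), "unknown variable")
  overfit <- data.frame(source = c("x", "x", "y", "x"), target = c("x", "y", "y", "y"),
                        kind = c("covariance", "covariance", "covariance", "directed"),
                        status = "free", label = c("a", "b", "c", "d"))
  expect_error(sem_model(vars, overfit), "negative degrees of freedom")
})

test_that("models round-trip through the declarative text format", {
  m <- build_whes_model()
  f <- tempfile(fileext = ".model")
  write_model_spec(m, f)
  m2 <- read_model_spec(f)
  expect_equal(count_df(m2), count_df(m))
  expect_equal(free_parameters(m2), free_parameters(m))
  expect_equal(m2$variables$name, m$variables$name)
  expect_equal(m2$paths[c("source", "target", "kind", "status")],
               m$paths[c("source", "target", "kind", "status")])
  expect_equal(m2$error_fractions, m$error_fractions, tolerance = 1e-12)
  expect_equal(m2$phantom$parents, m$phantom$parents)
  expect_equal(m2$phantom$error_fraction, m$phantom$error_fraction)
})
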