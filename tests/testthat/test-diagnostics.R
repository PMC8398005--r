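test_that("prediction metrics follow the published formulas", {
  ## hand-derived toy pair: ME uses pred - obs, MPE/RMSE use (obs - pred)/obs
  m <- prediction_metrics(c(2, 4), c(3, 3))
  expect_equal(m$ME, 0)
  expect_equal(m$MPE, -12.5)
  expect_equal(m$RMSE, 100 * sqrt(0.15625), tolerance = 1e-12)

  perfect <- prediction_metrics(c(1, 5, 9), c(1, 5, 9))
  expect_equal(perfect$ME, 0); expect_equal(perfect$MPE, 0)
  expect_equal(perfect$RMSE, 0); expect_equal(perfect$R2, 100)

  ## ME antisymmetry under swapping predictions and observations
  a <- runif(10, 1, 20); b <- runif(10, 1, 20)
  expect_equal(prediction_metrics(a, b)$ME, -prediction_metrics(b, a)$ME)

  expect_error(prediction_metrics(numeric(0), numeric(0)), "no observations")
  expect_error(prediction_metrics(c(0, 1), c(1, 1)), "LLOQ")
})

test_that("RMSE dominates the absolute MPE", {
  set.seed(8)
  for (i in 1:20) {
    obs <- runif(15, 0.5, 30); pred <- obs * exp(rnorm(15, 0, 0.4))
    m <- prediction_metrics(obs, pred)
    expect_gte(m$RMSE, abs(m$MPE))
  }
})

test_that("IWRES scales residuals by the residual error model", {
  add <- residual_error_spec("additive", 2, 0)
  expect_equal(compute_iwres(c(5, 9), c(5, 5), add), c(0, 2))
  prop <- residual_error_spec("proportional", 0, 0.2)
  expect_equal(compute_iwres(12, 10, prop), 1.0)
})

test_that("PWRES matches the analytic form in the no-IIV additive limit", {
  m <- get_model("A")
  m$residual <- residual_error_spec("additive", 1.5, 0)
  m$random_effects <- random_effects_spec(c(CL = 0, V1 = 0))
  s <- make_subject(trough_at = 3)
  f <- population_predict(m, s)
  s$observations$conc <- f + 2.4
  pw <- compute_pwres(m, s, K = 2000, rng_seed = 2)
  expect_equal(pw, 2.4 / 1.5, tolerance = 0.08)
  ## and residuals vanish when the observation equals the prediction
  s$observations$conc <- f
  expect_lt(abs(compute_pwres(m, s, K = 2000, rng_seed = 2)), 0.05)
})

test_that("PWRES under the true model is standardised", {
  co <- simulate_small(make_cohort(60, trough_at = c(2, 4, 6)),
                       get_model("A"), seed = 13)
  pw <- unlist(lapply(unclass(co), function(s)
    compute_pwres(get_model("A"), s, K = 500, rng_seed = 6)))
  expect_lt(abs(mean(pw)), 0.12)
  expect_lt(abs(var(pw) - 1), 0.25)
})

test_that("decorrelated simulation vectors have near-identity covariance", {
  s <- make_subject(trough_at = c(2, 4, 6))
  a <- get_model("A")
  d <- withr::with_seed(4, ifxeval:::.decorrelate_subject(a, s, 4000,
                                                          include_obs = FALSE))
  C <- cov(t(d$simstar))
  expect_lt(max(abs(C - diag(3))), 0.1)
})

test_that("NPDE reduce to standardised residuals in the additive no-IIV limit", {
  m <- get_model("A")
  m$residual <- residual_error_spec("additive", 1.5, 0)
  m$random_effects <- random_effects_spec(c(CL = 0, V1 = 0))
  s <- make_subject(id = "N1", trough_at = 3)
  f <- population_predict(m, s)
  s$observations$conc <- f + 1.5      # one residual SD above the mean
  nd <- compute_npde(m, ifx_cohort(list(s)), K = 4000, rng_seed = 9)
  expect_equal(nd$npde, 1, tolerance = 0.1)
})

test_that("NPDE values live on the mid-rank discrete grid for tiny K", {
  K <- 4
  co <- simulate_small(make_cohort(4, trough_at = c(3, 5)), get_model("A"),
                       seed = 14)
  nd <- compute_npde(get_model("A"), co, K = K, rng_seed = 3)
  # mid-rank grid (ties count half): an observation at the simulation
  # median (r = K/2) maps to pde 0.5 and NPDE 0
  allowed <- qnorm((seq(0, K, by = 0.5) + 0.5) / (K + 1))
  expect_true(all(vapply(nd$npde, function(x)
    any(abs(x - allowed) < 1e-12), TRUE)))
})

test_that("NPDE under the true model are near standard normal", {
  co <- simulate_small(make_cohort(60, trough_at = c(2, 4, 6)),
                       get_model("A"), seed = 77)
  nd <- compute_npde(get_model("A"), co, K = 400, rng_seed = 5)
  expect_lt(abs(mean(nd$npde)), 0.15)
  expect_lt(abs(var(nd$npde) - 1), 0.3)
  tst <- npde_tests(nd$npde)
  expect_gt(tst$mean_p, 0.01)
  expect_gt(tst$variance_p, 0.01)
})

test_that("NPDE detect a misspecified clearance with the right sign", {
  truth <- get_model("A")
  truth$typical_values$CL <- truth$typical_values$CL / 2   # halve elimination
  co <- simulate_small(make_cohort(40, trough_at = c(2, 4, 6)), truth,
                       seed = 19)
  nd <- compute_npde(get_model("A"), co, K = 300, rng_seed = 8)
  tst <- npde_tests(nd$npde)
  expect_gt(tst$mean, 0)          # true concentrations exceed the model's
  expect_lt(tst$mean_p, 1e-4)
})

test_that("npde_tests behave under null, shifted and degenerate samples", {
  x <- withr::with_seed(31, rnorm(500))
  tst <- npde_tests(x)
  expect_true(all(c(tst$mean_p, tst$variance_p, tst$shapiro_p,
                    tst$symmetry_p) > 0.001))
  expect_false(tst$degenerate)
  shifted <- npde_tests(x + 1)
  expect_lt(shifted$mean_p, 1e-10)
  skewed <- npde_tests(withr::with_seed(32, rexp(500) - 1))
  expect_lt(skewed$symmetry_p, 0.01)
  expect_lt(skewed$shapiro_p, 0.01)
  degen <- npde_tests(rep(0.3, 20))
  expect_true(degen$degenerate)
  expect_error(npde_tests(rnorm(5)), "at least 8")
})

test_that("eta shrinkage spans its 0-1 range as designed", {
  em <- matrix(0, 10, 2, dimnames = list(NULL, c("CL", "V1")))
  expect_equal(eta_shrinkage(em, c(CL = 0.3, V1 = 0.3)),
               c(CL = 1, V1 = 1))
  big <- withr::with_seed(3, matrix(rnorm(4000, 0, 0.3), ncol = 2,
                                    dimnames = list(NULL, c("CL", "V1"))))
  shr <- eta_shrinkage(big, c(CL = 0.3, V1 = 0.3))
  expect_lt(max(abs(shr)), 0.05)
  expect_warning(eta_shrinkage(big, c(CL = 0, V1 = 0.3)), "undefined")
})
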