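## model A variant with near-zero residual error: the noiseless limit used
## for parameter-recovery checks
tiny_sigma_model <- function(base = get_model("A")) {
  base$residual <- residual_error_spec("additive", 1e-6, 0)
  base
}

test_that("population predictions ignore the variability configuration", {
  s <- make_subject(trough_at = c(2, 4))
  a <- get_model("A")
  a2 <- a
  a2$random_effects <- random_effects_spec(c(CL = 0.9, V1 = 0.9), iov_cl = 0.5)
  expect_identical(population_predict(a, s), population_predict(a2, s))
})

test_that("population prediction composes the covariate model with the solver", {
  s <- make_subject(trough_at = c(3, 5), cov = cov_record(WT = 90, SEX = "male"))
  a <- get_model("A")
  direct <- predict_concentration(typical_parameters(a, covariates_at(s, 0)),
                                  s$doses, s$observations$time)$conc
  expect_equal(population_predict(a, s), direct, tolerance = 1e-12)
})

test_that("MAP returns the prior mode without observations", {
  s <- make_subject()
  s$observations <- s$observations[0, ]
  est <- map_estimate(get_model("A"), s)
  expect_equal(unname(est$eta), c(0, 0))
  expect_equal(unclass(est$parameters),
               unclass(typical_parameters(get_model("A"), covariates_at(s, 0))))
})

test_that("MAP recovers individual parameters from rich noiseless data", {
  m <- tiny_sigma_model()
  set.seed(3)
  for (i in 1:3) {
    s <- make_subject(id = paste0("R", i), n_inf = 10,
                      trough_at = 2:10, offset = 0.4)
    eta_true <- c(CL = rnorm(1, 0, 0.3), V1 = rnorm(1, 0, 0.3))
    s$observations$conc <- ifxeval:::predict_subject(m, s, eta_true)
    est <- map_estimate(m, s)
    expect_equal(est$eta, eta_true, tolerance = 1e-3)
    typ <- typical_parameters(m, covariates_at(s, 0))
    expect_rel_equal(est$parameters$CL, typ$CL * exp(eta_true[["CL"]]), 1e-3)
    expect_rel_equal(est$parameters$V1, typ$V1 * exp(eta_true[["V1"]]), 1e-3)
  }
})

test_that("single-observation MAP matches a brute-force grid search", {
  ## 1-compartment, additive error, eta on CL only: 1-D posterior
  m <- get_model("A")
  m$residual <- residual_error_spec("additive", 1, 0)
  m$random_effects <- random_effects_spec(c(CL = 0.3))
  s <- make_subject(n_inf = 1, trough_at = NULL)
  s$observations <- data.frame(time = 10, conc = 20, blq = FALSE)

  ## independent closed-form forward model for the oracle
  cov <- covariates_at(s, 0)
  typ <- typical_parameters(m, cov)
  amt <- s$doses$amount[1L]; D <- s$doses$duration[1L]; t1 <- 10
  f_eta <- function(eta) {
    cl <- typ$CL * exp(eta); k <- cl / typ$V1
    (amt / D / cl) * (1 - exp(-k * D)) * exp(-k * (t1 - D))
  }
  grid <- seq(-1.5, 1.5, by = 1e-4)
  post <- dnorm(s$observations$conc, vapply(grid, f_eta, 1), 1, log = TRUE) +
    dnorm(grid, 0, 0.3, log = TRUE)
  eta_grid <- grid[which.max(post)]
  est <- map_estimate(m, s)
  expect_equal(unname(est$eta), eta_grid, tolerance = 1e-4)
})

test_that("individual predictions beat population predictions on average", {
  co <- simulate_small(make_cohort(20, trough_at = c(2, 4, 6)),
                       get_model("A"), seed = 21)
  rms <- function(x) sqrt(mean(x^2))
  err_p <- err_i <- numeric(0)
  for (s in unclass(co)) {
    est <- map_estimate(get_model("A"), s)
    err_p <- c(err_p, s$observations$conc - population_predict(get_model("A"), s))
    err_i <- c(err_i, s$observations$conc -
                 individual_predict(get_model("A"), s, est))
  }
  expect_lt(rms(err_i), rms(err_p))
  ## eta = 0 estimate reproduces PPRED exactly
  s <- co[[1L]]
  est0 <- map_estimate(get_model("A"), s)
  est0$eta[] <- 0
  expect_equal(individual_predict(get_model("A"), s, est0),
               population_predict(get_model("A"), s), tolerance = 1e-12)
})

test_that("MAP estimation is deterministic and respects the window", {
  s <- simulate_small(make_cohort(1, trough_at = c(2, 4, 6)),
                      get_model("A"), seed = 5)[[1L]]
  e1 <- map_estimate(get_model("A"), s)
  e2 <- map_estimate(get_model("A"), s)
  expect_identical(e1, e2)
  ## restricting the window changes the data actually used
  ew <- map_estimate(get_model("A"), s, window = s$doses$time[3L])
  expect_equal(ew$n_obs, 1L)
})

test_that("eta estimates shrink towards zero as data get sparser", {
  a <- get_model("A")
  rich <- simulate_small(make_cohort(25, n_inf = 8, trough_at = 2:8),
                         a, seed = 41)
  sparse <- lapply(unclass(rich), function(s) {
    s$observations <- s$observations[1L, , drop = FALSE]
    s
  })
  est_rich <- lapply(unclass(rich), function(s) map_estimate(a, s))
  est_sparse <- lapply(sparse, function(s) map_estimate(a, s))
  shr_rich <- eta_shrinkage(est_rich, a$random_effects$omega)
  shr_sparse <- eta_shrinkage(est_sparse, a$random_effects$omega)
  expect_gt(shr_sparse[["CL"]], shr_rich[["CL"]])
  ## eta estimates centre near zero under the true model
  etas <- do.call(rbind, lapply(est_rich, `[[`, "eta"))
  expect_lt(abs(mean(etas[, "CL"])), 0.2)
})
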