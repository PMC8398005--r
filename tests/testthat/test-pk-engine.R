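two_cmt <- list(CL = 0.35, V1 = 3.4, V2 = 1.3, Q = 0.15)
one_cmt <- list(CL = 0.25, V1 = 5.0)
dose1 <- data.frame(time = 0, amount = 400, duration = 2 / 24)

test_that("no drug before or at the start of the first infusion", {
  for (p in list(one_cmt, two_cmt)) {
    prof <- predict_concentration(p, dose1, c(0, 5, 30))
    expect_equal(prof$conc[1L], 0)
    expect_true(all(prof$conc >= 0))
  }
})

test_that("short-infusion limit approaches the bolus concentration amount/V1", {
  p <- one_cmt
  conc <- predict_concentration(p, data.frame(time = 0, amount = 400,
                                              duration = 1e-7), 1e-7)$conc
  expect_equal(conc, 400 / p$V1, tolerance = 1e-4)
})

test_that("predictions are additive over dose events (superposition)", {
  doses <- data.frame(time = c(0, 30), amount = c(300, 500), duration = 2 / 24)
  tt <- c(1, 15, 29, 31, 60, 120)
  for (p in list(one_cmt, two_cmt)) {
    both <- predict_concentration(p, doses, tt)$conc
    d1 <- predict_concentration(p, doses[1, ], tt)$conc
    d2 <- predict_concentration(p, doses[2, ], tt)$conc
    expect_equal(both, d1 + d2, tolerance = 1e-12)
  }
})

test_that("closed form agrees with the ODE oracle on randomized cases", {
  set.seed(11)
  for (i in 1:10) {
    two <- i %% 2 == 0
    p <- list(CL = runif(1, 0.1, 0.6), V1 = runif(1, 1.5, 6))
    if (two) { p$V2 <- runif(1, 0.5, 5); p$Q <- runif(1, 0.05, 1.5) }
    nd <- sample(1:4, 1)
    doses <- data.frame(time = sort(runif(nd, 0, 80)),
                        amount = runif(nd, 100, 800),
                        duration = runif(nd, 0.05, 0.2))
    doses$time[1L] <- 0
    tt <- sort(runif(12, 0, 120))
    a <- predict_concentration(p, doses, tt)$conc
    b <- ode_oracle(p, doses, tt)$conc
    expect_rel_equal(a, pmax(b, 0), 1e-6)
  }
})

test_that("single-dose exposure integrates to amount/CL", {
  p <- two_cmt
  f <- function(t) predict_concentration(p, dose1, t)$conc
  D <- dose1$duration[1L]   # integrand has a kink at the end of infusion
  auc <- integrate(f, 0, D, rel.tol = 1e-10)$value +
    integrate(f, D, 2000, subdivisions = 2000L, rel.tol = 1e-10)$value
  expect_equal(auc, 400 / p$CL, tolerance = 1e-6)
})

test_that("concentrations decay towards zero after the last dose", {
  late <- predict_concentration(two_cmt, dose1, c(100, 500, 2000))$conc
  expect_true(all(diff(late) < 0))
  expect_lt(late[3L], 1e-6)
})

test_that("piecewise propagation matches superposition for constant parameters", {
  doses <- data.frame(time = c(0, 21, 42), amount = 400, duration = 2 / 24)
  tt <- c(0.05, 10, 20.9, 21.5, 41.9, 70)
  for (p in list(one_cmt, two_cmt)) {
    seg <- data.frame(start = 0, CL = p$CL, V1 = p$V1,
                      V2 = p$V2 %||% NA_real_, Q = p$Q %||% NA_real_)
    a <- predict_concentration(p, doses, tt)$conc
    b <- ifxeval:::predict_piecewise(seg, doses, tt)
    expect_rel_equal(b, a, 1e-10)
  }
})

test_that("piecewise propagation with time-varying clearance matches the ODE oracle", {
  doses <- data.frame(time = c(0, 21, 42), amount = 400, duration = 2 / 24)
  seg <- data.frame(start = c(0, 21, 42), CL = c(0.3, 0.45, 0.25),
                    V1 = 3.4, V2 = 1.3, Q = 0.15)
  tt <- c(5, 20.9, 25, 41.9, 50, 80)
  a <- ifxeval:::predict_piecewise(seg, doses, tt)
  b <- ode_oracle(doses = doses, times = tt, segments = seg)$conc
  expect_rel_equal(a, b, 1e-6)
})

test_that("invalid structural parameters are rejected", {
  expect_error(predict_concentration(list(CL = -1, V1 = 5), dose1, 1),
               "positive")
  expect_error(predict_concentration(list(CL = 0.3, V1 = 5, V2 = 2), dose1, 1),
               "jointly")
})

test_that("residual SD follows the error-model conventions", {
  comb_sd <- residual_error_spec("combined", 0.72, 0.223, "sd_additive")
  expect_equal(residual_sd(comb_sd, 0), 0.72)
  expect_equal(residual_sd(comb_sd, 10), 0.72 + 2.23)
  prop <- residual_error_spec("proportional", 0, 0.175561)
  expect_equal(residual_sd(prop, 10), 1.75561)
  comb_var <- residual_error_spec("combined", 3, 0.4, "variance_additive")
  expect_equal(residual_sd(comb_var, 10), 5)   # sqrt(3^2 + 4^2)
  expect_error(residual_sd(prop, -1), "non-negative")
})

test_that("individual simulation honours the random-effects configuration", {
  s <- make_subject(trough_at = c(2, 4, 6))
  a <- get_model("A")
  ## omega = 0, no residual: the typical prediction
  a0 <- a; a0$random_effects <- random_effects_spec(c(CL = 0, V1 = 0))
  y0 <- simulate_individual(a0, s, 5, include_residual = FALSE)
  expect_equal(as.numeric(y0), population_predict(a, s), tolerance = 1e-12)
  ## same seed, bit-identical; different seed differs
  expect_identical(simulate_individual(a, s, 7), simulate_individual(a, s, 7))
  expect_false(identical(as.numeric(simulate_individual(a, s, 7)),
                         as.numeric(simulate_individual(a, s, 8))))
})

test_that("simulated clearance matches log-normal moments of the configured omega", {
  s <- make_subject(trough_at = 3)
  a <- get_model("A")
  omega_cl <- a$random_effects$omega[["CL"]]
  etas <- vapply(1:4000, function(i)
    attr(simulate_individual(a, s, i, include_residual = FALSE), "eta")[["CL"]],
    numeric(1))
  cl <- exp(etas)   # CL / typical CL
  cv_emp <- sd(cl) / mean(cl)
  cv_theory <- sqrt(exp(omega_cl^2) - 1)
  expect_rel_equal(cv_emp, cv_theory, 0.05)
  expect_lt(abs(mean(etas)), 3 * omega_cl / sqrt(4000))
})

test_that("batch simulation reproduces the single-draw path distributionally", {
  s <- make_subject(trough_at = c(3, 5))
  a <- get_model("A")
  sims <- withr::with_seed(1, ifxeval:::simulate_batch(a, s, 3000))
  singles <- t(vapply(1:600, function(i)
    as.numeric(simulate_individual(a, s, i)), numeric(2)))
  expect_rel_equal(colMeans(sims), colMeans(singles), 0.15)
  expect_rel_equal(apply(sims, 2, sd), apply(singles, 2, sd), 0.2)
})
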