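## Shared fixtures: small hand-built subjects and cohorts.

`%||%` <- function(a, b) if (is.null(a)) b else a

## a single-record covariate table with sensible defaults
cov_record <- function(time = 0, WT = 70, SEX = "female", AGE = 40,
                       DISEASE = "Crohn", MTX = 0, IMM = 0, ADA = 0,
                       ALB = 40, HBI = 4, PERIOD = "maintenance") {
  data.frame(time = time, WT = WT, SEX = SEX, AGE = AGE, DISEASE = DISEASE,
             MTX = MTX, IMM = IMM, ADA = ADA, ALB = ALB, HBI = HBI,
             PERIOD = PERIOD)
}

## subject on a regular q6w-like schedule with troughs before chosen infusions
make_subject <- function(id = "T1", n_inf = 6, interval = 42, amount = 400,
                         duration = 2 / 24, trough_at = c(3, 5),
                         offset = 0.5, cov = cov_record()) {
  dose_times <- (seq_len(n_inf) - 1) * interval
  doses <- data.frame(time = dose_times, amount = amount, duration = duration)
  obs <- if (length(trough_at)) {
    data.frame(time = dose_times[trough_at] - offset,
               conc = NA_real_, blq = FALSE)
  } else {
    data.frame(time = numeric(0), conc = numeric(0), blq = logical(0))
  }
  ifx_subject(id, doses, obs, cov)
}

make_cohort <- function(n = 5, ...) {
  ifx_cohort(lapply(seq_len(n), function(i)
    make_subject(id = sprintf("T%02d", i), ...)))
}

## fill concentrations by simulation under a model
simulate_small <- function(cohort, model, seed = 1, residual = TRUE) {
  simulate_dataset(cohort, model, rng_seed = seed, include_residual = residual)
}

## cohort configuration scaled down for fast tests
small_config <- function(n_subjects = 20, ...) {
  cohort_config(n_subjects = n_subjects,
                n_infusions = list(mu = 6, size = 8, shift = 2,
                                   range = c(2, 12)),
                ...)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-12)), tol)
}
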