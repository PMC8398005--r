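## Concentration prediction for linear 1- and 2-compartment models under
## sequences of zero-order IV infusions.
##
## Three routes:
##   * closed-form superposition of per-infusion analytic solutions
##     (constant parameters) -- the default, vectorised over parameter draws;
##   * exact piecewise propagation via the 2x2 matrix exponential, for
##     parameters that change over time (covariate changes, inter-occasion
##     variability on CL);
##   * numeric ODE integration (deSolve) as an independent oracle.
##
## Internal units: days, mg, L, mg/L. Eigenvalues of the two-compartment
## system use the sum/product form (beta = k10*k21/alpha) to avoid
## cancellation when Q << CL.

check_params <- function(params) {
  if (is.null(params$CL) || is.null(params$V1))
    stop("structural parameters require CL and V1")
  two <- !is.null(params$V2) || !is.null(params$Q)
  if (two && (is.null(params$V2) || is.null(params$Q)))
    stop("V2 and Q must be jointly present or jointly absent")
  vals <- unlist(params[c("CL", "V1", if (two) c("V2", "Q"))])
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("structural parameters must be positive and finite")
  two
}

## Batch prediction: pm is a list of equal-length parameter vectors (CL, V1
## and optionally V2, Q), one element per draw. Returns a K x length(times)
## matrix of central-compartment concentrations.
predict_batch <- function(pm, doses, times) {
  K <- length(pm$CL)
  Tn <- length(times)
  out <- matrix(0, K, Tn)
  if (Tn == 0L) return(out)
  two <- !is.null(pm$V2)
  if (two) {
    k10 <- pm$CL / pm$V1; k12 <- pm$Q / pm$V1; k21 <- pm$Q / pm$V2
    s <- k10 + k12 + k21
    disc <- sqrt(pmax(s^2 - 4 * k10 * k21, 0))
    a <- (s + disc) / 2
    b <- (k10 * k21) / a
    cA <- ((a - k21) / (a - b)) / a / pm$V1   # coefficient/lambda, per unit rate
    cB <- ((k21 - b) / (a - b)) / b / pm$V1
  } else {
    k <- pm$CL / pm$V1
  }
  for (i in seq_len(nrow(doses))) {
    te <- pmax(times - doses$time[i], 0)
    h <- pmax(te - doses$duration[i], 0)
    rate <- doses$amount[i] / doses$duration[i]
    if (two) {
      out <- out +
        rate * cA * (exp(-outer(a, h)) - exp(-outer(a, te))) +
        rate * cB * (exp(-outer(b, h)) - exp(-outer(b, te)))
    } else {
      out <- out + (rate / pm$CL) * (exp(-outer(k, h)) - exp(-outer(k, te)))
    }
  }
  out
}

#' Closed-form concentration prediction
#'
#' Superposition of analytic per-infusion solutions for a linear one- or
#' two-compartment model with constant parameters. One-compartment when `V2`
#' and `Q` are absent.
#'
#' @param params List with `CL`, `V1` (and `V2`, `Q` for two compartments);
#'   L/day and L.
#' @param doses `data.frame` with `time`, `amount` (mg), `duration` (days).
#' @param times Numeric vector of prediction times (days).
#' @return `data.frame` with columns `time` and `conc` (mg/L).
#' @export
predict_concentration <- function(params, doses, times) {
  check_params(params)
  stopifnot(all(times >= 0), all(doses$amount > 0), all(doses$duration > 0))
  pm <- lapply(params[c("CL", "V1", "V2", "Q")], function(x) x)
  pm <- pm[!vapply(pm, is.null, logical(1))]
  conc <- drop(predict_batch(pm, doses, times))
  quick_df(list(time = as.numeric(times), conc = as.numeric(conc)))
}

## ---- piecewise-constant parameters ---------------------------------------

## Integration plan for piecewise-constant parameters: breakpoints at
## segment starts, infusion starts/ends and output times, with the constant
## infusion rate and the active segment precomputed per interval. The plan
## depends only on the schedule, so MAP objective evaluations (which only
## rescale parameters) reuse it.
piecewise_plan <- function(starts, doses, times) {
  breaks <- sort(unique(c(0, starts, doses$time,
                          doses$time + doses$duration, times)))
  breaks <- breaks[breaks >= 0]
  nb <- length(breaks)
  rate <- numeric(max(nb - 1L, 0L))
  lo <- breaks[-nb]; hi <- breaks[-1L]
  for (d in seq_len(nrow(doses))) {
    sel <- lo >= doses$time[d] - 1e-12 &
      hi <= doses$time[d] + doses$duration[d] + 1e-12
    rate[sel] <- rate[sel] + doses$amount[d] / doses$duration[d]
  }
  list(breaks = breaks, dt = hi - lo,
       seg_idx = pmax(findInterval(breaks, starts), 1L),
       rate = rate, out_idx = match(times, breaks))
}

## Exact propagation of compartment amounts along a plan; CL/V1/V2/Q are
## per-segment vectors (V2/Q NULL for one-compartment models).
run_piecewise_plan <- function(plan, CL, V1, V2 = NULL, Q = NULL) {
  two <- !is.null(V2)
  nb <- length(plan$breaks)
  conc <- numeric(nb)
  x1 <- 0; x2 <- 0
  si <- plan$seg_idx
  for (i in seq_len(nb - 1L)) {
    s <- si[i]
    dt <- plan$dt[i]; r <- plan$rate[i]
    if (two) {
      k10 <- CL[s] / V1[s]; k12 <- Q[s] / V1[s]; k21 <- Q[s] / V2[s]
      ssum <- k10 + k12 + k21
      disc <- sqrt(max(ssum^2 - 4 * k10 * k21, 0))
      a <- (ssum + disc) / 2; b <- (k10 * k21) / a
      xp1 <- r / k10; xp2 <- (k12 / k21) * xp1
      m11 <- -(k10 + k12); m12 <- k21; m21 <- k12; m22 <- -k21
      if (disc > 1e-9 * ssum) {
        ea <- exp(-a * dt); eb <- exp(-b * dt); den <- b - a
        e11 <- (ea * (m11 + b) - eb * (m11 + a)) / den
        e12 <- (ea - eb) * m12 / den
        e21 <- (ea - eb) * m21 / den
        e22 <- (ea * (m22 + b) - eb * (m22 + a)) / den
      } else {
        ## repeated eigenvalue: Jordan-form limit
        ea <- exp(-a * dt)
        e11 <- ea * (1 + (m11 + a) * dt); e12 <- ea * m12 * dt
        e21 <- ea * m21 * dt; e22 <- ea * (1 + (m22 + a) * dt)
      }
      d1 <- x1 - xp1; d2 <- x2 - xp2
      x1 <- xp1 + e11 * d1 + e12 * d2
      x2 <- xp2 + e21 * d1 + e22 * d2
    } else {
      k <- CL[s] / V1[s]
      xp <- r / k
      x1 <- xp + (x1 - xp) * exp(-k * dt)
    }
    conc[i + 1L] <- x1 / V1[si[i + 1L]]
  }
  conc[plan$out_idx]
}

## back-compatible wrapper over the plan machinery
predict_piecewise <- function(segments, doses, times) {
  plan <- piecewise_plan(segments$start, doses, times)
  two <- !is.na(segments$V2[1L])
  run_piecewise_plan(plan, segments$CL, segments$V1,
                     if (two) segments$V2, if (two) segments$Q)
}

#' Numeric ODE oracle
#'
#' Stiff-safe numeric integration of the compartmental mass-balance equations
#' with infusions as piecewise-constant inputs. Independent cross-check for
#' the closed-form engine; integration proceeds segment by segment between
#' input discontinuities at tight tolerances.
#'
#' @inheritParams predict_concentration
#' @param segments Optional `data.frame(start, CL, V1, V2, Q)` of
#'   piecewise-constant parameters (overrides `params`).
#' @param rtol,atol Integration tolerances.
#' @return `data.frame` with columns `time` and `conc` (mg/L).
#' @export
ode_oracle <- function(params = NULL, doses, times, segments = NULL,
                       rtol = 1e-11, atol = 1e-11) {
  if (is.null(segments)) {
    two <- check_params(params)
    segments <- quick_df(list(start = 0, CL = params$CL, V1 = params$V1,
                              V2 = if (two) params$V2 else NA_real_,
                              Q = if (two) params$Q else NA_real_))
  }
  two <- !is.na(segments$V2[1L])
  breaks <- sort(unique(c(0, segments$start, doses$time,
                          doses$time + doses$duration, times)))
  breaks <- breaks[breaks >= 0]
  seg_idx <- pmax(findInterval(breaks, segments$start), 1L)
  x <- if (two) c(A1 = 0, A2 = 0) else c(A1 = 0)
  conc_at_break <- numeric(length(breaks))
  conc_at_break[1L] <- x[["A1"]] / segments$V1[seg_idx[1L]]

  for (i in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[i]; t1 <- breaks[i + 1L]
    sg <- segments[seg_idx[i], ]
    active <- doses$time <= t0 + 1e-12 & (doses$time + doses$duration) >= t1 - 1e-12
    r <- sum(doses$amount[active] / doses$duration[active])
    rhs <- if (two) {
      function(t, y, p) {
        k10 <- sg$CL / sg$V1; k12 <- sg$Q / sg$V1; k21 <- sg$Q / sg$V2
        list(c(r - (k10 + k12) * y[1L] + k21 * y[2L],
               k12 * y[1L] - k21 * y[2L]))
      }
    } else {
      function(t, y, p) list(r - (sg$CL / sg$V1) * y[1L])
    }
    sol <- deSolve::lsoda(y = x, times = c(t0, t1), func = rhs, parms = NULL,
                          rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1L] < 0) stop("ODE integration failed on [",
                                          t0, ", ", t1, "]")
    x <- sol[nrow(sol), -1L]
    conc_at_break[i + 1L] <- x[[1L]] / segments$V1[seg_idx[i + 1L]]
  }
  quick_df(list(time = as.numeric(times),
                conc = as.numeric(conc_at_break[match(times, breaks)])))
}

## ---- residual error -------------------------------------------------------

#' Residual standard deviation at a prediction
#'
#' @param spec A [residual_error_spec()].
#' @param f Predicted concentration(s), mg/L; must be non-negative.
#' @return Residual SD(s), mg/L (vectorised over `f`).
#' @export
residual_sd <- function(spec, f) {
  stopifnot(inherits(spec, "residual_error_spec"))
  if (any(f < 0)) stop("residual_sd: prediction must be non-negative")
  switch(spec$kind,
    additive = rep(spec$sigma_add, length(f)),
    proportional = spec$sigma_prop * f,
    combined = if (spec$convention == "sd_additive") {
      spec$sigma_add + spec$sigma_prop * f
    } else {
      sqrt(spec$sigma_add^2 + (spec$sigma_prop * f)^2)
    })
}

## ---- model-level prediction -----------------------------------------------

## Subject covariate fields a model's covariate terms depend on.
model_cov_fields <- function(model) {
  if (!length(model$covariate_model)) return(character(0))
  unique(.cov_source[vapply(model$covariate_model, `[[`, "", "covariate")])
}

## Piecewise-constant structural parameters for one subject: breakpoints at
## covariate changes and (when any kappa is nonzero) at occasion boundaries,
## one occasion per inter-infusion interval indexed from the first dose.
parameter_segments <- function(model, subject, eta = NULL, kappa = NULL) {
  starts <- 0
  ch <- covariate_change_times(subject, model_cov_fields(model))
  starts <- c(starts, ch)
  use_iov <- !is.null(kappa) && any(kappa != 0)
  if (use_iov) starts <- c(starts, subject$doses$time)
  starts <- sort(unique(starts))
  two <- model$n_compartments == 2L
  n <- length(starts)
  seg <- list(start = starts, CL = numeric(n), V1 = numeric(n),
              V2 = rep(NA_real_, n), Q = rep(NA_real_, n))
  for (i in seq_len(n)) {
    pars <- typical_parameters(model, covariates_at(subject, starts[i]))
    if (!is.null(eta)) for (p in names(eta)) pars[[p]] <- pars[[p]] * exp(eta[[p]])
    if (use_iov) {
      occ <- max(findInterval(starts[i], subject$doses$time), 1L)
      pars$CL <- pars$CL * exp(kappa[min(occ, length(kappa))])
    }
    seg$CL[i] <- pars$CL; seg$V1[i] <- pars$V1
    if (two) { seg$V2[i] <- pars$V2; seg$Q[i] <- pars$Q }
  }
  quick_df(seg)
}

## Precomputed prediction context for one subject under one model: typical
## parameters per covariate segment (occasion boundaries included when IOV
## is in play) plus the integration plan for a fixed set of output times.
## Objective evaluations that only rescale parameters reuse it.
subject_plan <- function(model, subject, times, use_iov = FALSE) {
  ch <- covariate_change_times(subject, model_cov_fields(model))
  starts <- sort(unique(c(0, ch, if (use_iov) subject$doses$time)))
  typ <- lapply(starts, function(t0)
    typical_parameters(model, covariates_at(subject, t0)))
  two <- model$n_compartments == 2L
  list(starts = starts,
       CL = vapply(typ, `[[`, 1, "CL"),
       V1 = vapply(typ, `[[`, 1, "V1"),
       V2 = if (two) vapply(typ, `[[`, 1, "V2"),
       Q = if (two) vapply(typ, `[[`, 1, "Q"),
       occ = pmax(findInterval(starts, subject$doses$time), 1L),
       doses = subject$doses, times = times,
       plan = piecewise_plan(starts, subject$doses, times))
}

predict_with_plan <- function(sp, eta = NULL, kappa = NULL) {
  CL <- sp$CL; V1 <- sp$V1; V2 <- sp$V2; Q <- sp$Q
  if (!is.null(eta)) {
    if ("CL" %in% names(eta)) CL <- CL * exp(eta[["CL"]])
    if ("V1" %in% names(eta)) V1 <- V1 * exp(eta[["V1"]])
    if (!is.null(V2) && "V2" %in% names(eta)) V2 <- V2 * exp(eta[["V2"]])
    if (!is.null(Q) && "Q" %in% names(eta)) Q <- Q * exp(eta[["Q"]])
  }
  if (!is.null(kappa) && any(kappa != 0))
    CL <- CL * exp(kappa[pmin(sp$occ, length(kappa))])
  run_piecewise_plan(sp$plan, CL, V1, V2, Q)
}

## Concentration at given times for one subject under a model, at random
## effects eta (named, log scale) and per-occasion kappa on CL.
predict_subject <- function(model, subject, eta = NULL, kappa = NULL,
                            times = NULL) {
  if (is.null(times)) times <- subject$observations$time
  seg <- parameter_segments(model, subject, eta, kappa)
  if (nrow(seg) == 1L) {
    pm <- list(CL = seg$CL, V1 = seg$V1)
    if (!is.na(seg$V2[1L])) { pm$V2 <- seg$V2; pm$Q <- seg$Q }
    drop(predict_batch(pm, subject$doses, times))
  } else {
    predict_piecewise(seg, subject$doses, times)
  }
}

#' Simulate one individual under a model
#'
#' Draws log-normal inter-individual random effects (and per-occasion
#' inter-occasion effects on CL where the model has them), applies the
#' covariate model, predicts at the subject's observation times, and
#' optionally adds residual noise (truncated at zero).
#'
#' @param model A [poppk_model()].
#' @param subject An [ifx_subject()] with dosing history and observation times.
#' @param rng_seed Integer seed; the draw is a pure function of it.
#' @param include_residual Add residual noise?
#' @return Numeric vector of simulated concentrations (mg/L) at the subject's
#'   observation times, with attributes `eta` and `kappa` holding the drawn
#'   random effects.
#' @export
simulate_individual <- function(model, subject, rng_seed,
                                include_residual = TRUE) {
  with_seed(rng_seed, {
    re <- model$random_effects
    om <- re$omega[re$omega > 0]
    eta <- if (length(om)) stats::setNames(stats::rnorm(length(om), 0, om),
                                           names(om)) else NULL
    kappa <- if (re$iov_cl > 0)
      stats::rnorm(nrow(subject$doses), 0, re$iov_cl) else NULL
    f <- predict_subject(model, subject, eta, kappa)
    y <- if (include_residual && length(f)) {
      pmax(f + stats::rnorm(length(f), 0, residual_sd(model$residual, f)), 0)
    } else f
    attr(y, "eta") <- eta
    attr(y, "kappa") <- kappa
    y
  })
}

## K simulated replicate observation vectors for one subject (K x n matrix).
## Caller controls the RNG state. Fast vectorised path when parameters are
## constant over time; falls back to per-draw piecewise prediction otherwise.
simulate_batch <- function(model, subject, K, include_residual = TRUE) {
  re <- model$random_effects
  om <- re$omega[re$omega > 0]
  times <- subject$observations$time
  n <- length(times)
  varying <- re$iov_cl > 0 ||
    length(covariate_change_times(subject, model_cov_fields(model))) > 0
  if (!varying) {
    typ <- typical_parameters(model, covariates_at(subject, 0))
    eta <- matrix(stats::rnorm(K * length(om)), K) %*% diag(om, length(om))
    colnames(eta) <- names(om)
    pm <- list(CL = rep(typ$CL, K), V1 = rep(typ$V1, K))
    if (model$n_compartments == 2L) {
      pm$V2 <- rep(typ$V2, K); pm$Q <- rep(typ$Q, K)
    }
    for (p in names(om)) pm[[p]] <- pm[[p]] * exp(eta[, p])
    f <- predict_batch(pm, subject$doses, times)
  } else {
    f <- matrix(0, K, n)
    for (k in seq_len(K)) {
      eta <- if (length(om)) stats::setNames(stats::rnorm(length(om), 0, om),
                                             names(om)) else NULL
      kappa <- if (re$iov_cl > 0)
        stats::rnorm(nrow(subject$doses), 0, re$iov_cl) else NULL
      f[k, ] <- predict_subject(model, subject, eta, kappa)
    }
  }
  if (include_residual && n) {
    sd <- residual_sd(model$residual, pmax(f, 0))
    f <- pmax(f + stats::rnorm(length(f), 0, sd), 0)
  }
  f
}
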