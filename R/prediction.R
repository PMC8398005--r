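## Population and individual (MAP empirical-Bayes) prediction under a fixed
## population model.
##
## MAP estimation maximises
##   log N(y | f(theta_typ * e^eta), sd_res(f)) + log N(eta | 0, Omega)
## over eta (and per-occasion kappa on CL when the model has inter-occasion
## variability), with population parameters fixed. Optimisation runs in
## unconstrained eta-space (log-normal reparameterisation) from eta = 0 plus
## four jittered starts to hedge against multimodality.

#' Population predictions (PPRED)
#'
#' Model prediction at the subject's observation times with all random
#' effects at zero and covariate effects applied (time-varying covariates
#' carried forward).
#'
#' @param model A [poppk_model()].
#' @param subject An [ifx_subject()].
#' @param times Prediction times in days (default: the subject's observation
#'   times).
#' @return Numeric vector of concentrations, mg/L.
#' @export
population_predict <- function(model, subject, times = NULL) {
  predict_subject(model, subject, eta = NULL, kappa = NULL, times = times)
}

## observations retained for estimation: quantified, concentration known,
## inside the window (scalar upper bound or c(lower, upper))
.estimation_obs <- function(subject, window = NULL) {
  obs <- subject$observations
  keep <- !is.na(obs$conc) & !obs$blq
  if (!is.null(window)) {
    if (length(window) == 1L) window <- c(-Inf, window)
    keep <- keep & obs$time >= window[1L] & obs$time <= window[2L] + 1e-9
  }
  obs[keep, , drop = FALSE]
}

#' MAP empirical-Bayes individual estimate
#'
#' Mode of the individual random-effect posterior given the model's fixed
#' population parameters and the subject's observations. With inter-occasion
#' variability, per-occasion effects on CL are estimated jointly for the
#' occasions that contain observations (others stay at zero). With no
#' observations the prior mode (eta = 0) is returned.
#'
#' @param model A [poppk_model()].
#' @param subject An [ifx_subject()] with observed concentrations.
#' @param window Optional estimation window: an upper time bound (days) or a
#'   `c(lower, upper)` range; only observations inside it are used.
#' @param control List: `tol` (objective convergence tolerance, default
#'   1e-8), `n_starts` (total optimiser starts, default 5).
#' @return Object of class `ifx_map`: list with `eta` (named, log scale),
#'   `kappa` (per occasion, zeros where not estimated), `parameters`
#'   (structural parameters at the baseline covariates), `log_posterior`,
#'   `convergence` (`TRUE` if the best start converged), `n_obs`.
#' @export
map_estimate <- function(model, subject, window = NULL,
                         control = list(tol = 1e-8, n_starts = 5L)) {
  re <- model$random_effects
  om <- re$omega[re$omega > 0]
  p <- length(om)
  obs <- .estimation_obs(subject, window)
  n_occ <- nrow(subject$doses)
  occ_of_obs <- pmax(findInterval(obs$time, subject$doses$time + 1e-12), 1L)
  est_occ <- if (re$iov_cl > 0 && nrow(obs)) sort(unique(occ_of_obs)) else integer(0)
  q <- length(est_occ)

  empty <- structure(list(
    eta = stats::setNames(rep(0, p), names(om)),
    kappa = rep(0, n_occ), parameters = typical_parameters(
      model, covariates_at(subject, 0)),
    log_posterior = 0, convergence = TRUE, n_obs = nrow(obs)),
    class = "ifx_map")
  if (nrow(obs) == 0L || (p == 0L && q == 0L)) return(empty)

  y <- obs$conc
  sp <- subject_plan(model, subject, obs$time, use_iov = q > 0)
  unpack <- function(theta) {
    eta <- stats::setNames(theta[seq_len(p)], names(om))
    kappa <- rep(0, n_occ)
    if (q) kappa[est_occ] <- theta[p + seq_len(q)]
    list(eta = eta, kappa = kappa)
  }
  nll <- function(theta) {
    z <- unpack(theta)
    f <- predict_with_plan(sp, z$eta, if (q) z$kappa else NULL)
    sd <- pmax(residual_sd(model$residual, pmax(f, 0)), 1e-8)
    -sum(stats::dnorm(y, f, sd, log = TRUE)) -
      sum(stats::dnorm(z$eta, 0, om, log = TRUE)) -
      (if (q) sum(stats::dnorm(z$kappa[est_occ], 0, re$iov_cl, log = TRUE)) else 0)
  }

  tol <- control$tol %||% 1e-8
  n_starts <- control$n_starts %||% 5L
  starts <- list(rep(0, p + q))
  if (n_starts > 1L) {
    jit <- with_seed(104729L, lapply(seq_len(n_starts - 1L), function(i)
      stats::rnorm(p + q, 0, 0.5 * c(om, rep(re$iov_cl, q)))))
    starts <- c(starts, jit)
  }
  best <- NULL
  for (s0 in starts) {
    fit <- tryCatch(
      stats::nlminb(s0, nll, control = list(abs.tol = tol, rel.tol = tol,
                                            iter.max = 500L)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$objective < best$objective))
      best <- fit
  }
  if (is.null(best)) {
    empty$convergence <- FALSE
    return(empty)
  }
  z <- unpack(best$par)
  pars <- typical_parameters(model, covariates_at(subject, 0))
  for (nm in names(z$eta)) pars[[nm]] <- pars[[nm]] * exp(z$eta[[nm]])
  structure(list(eta = z$eta, kappa = z$kappa, parameters = pars,
                 log_posterior = -best$objective,
                 convergence = best$convergence == 0L,
                 n_obs = nrow(obs)),
            class = "ifx_map")
}

#' @export
print.ifx_map <- function(x, ...) {
  cat(sprintf("<ifx_map> n_obs = %d, log-posterior = %.4g, converged: %s\n",
              x$n_obs, x$log_posterior, x$convergence))
  cat("  eta:", paste(sprintf("%s=%.4f", names(x$eta), x$eta), collapse = ", "),
      "\n")
  if (any(x$kappa != 0))
    cat("  kappa (occasions):",
        paste(sprintf("%.3f", x$kappa), collapse = " "), "\n")
  invisible(x)
}

#' Individual predictions (IPRED)
#'
#' Noiseless prediction at the MAP-estimated individual parameters. Occasions
#' beyond the estimation window keep kappa = 0 (prior mode), so forecasts use
#' last-known individual parameters.
#'
#' @param model A [poppk_model()].
#' @param subject An [ifx_subject()].
#' @param estimate An `ifx_map` from [map_estimate()].
#' @param times Prediction times (default: the subject's observation times).
#' @return Numeric vector of concentrations, mg/L.
#' @export
individual_predict <- function(model, subject, estimate, times = NULL) {
  stopifnot(inherits(estimate, "ifx_map"))
  kappa <- if (any(estimate$kappa != 0)) estimate$kappa else NULL
  predict_subject(model, subject, estimate$eta, kappa, times = times)
}
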