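## Predictive-performance metrics and simulation-based residual diagnostics.
##
## Metric conventions (as used for external evaluation of population PK
## models): ME = mean(pred - obs) in mg/L; MPE and RMSE are relative to the
## observation, in percent:
##   MPE%  = 100 * mean((obs - pred) / obs)
##   RMSE% = 100 * sqrt(mean(((obs - pred) / obs)^2))
## PWRES and NPDE are simulation-based: K replicate observation vectors per
## subject give an empirical mean and covariance; the observed vector is
## decorrelated with the Cholesky factor. NPDE additionally ranks the
## decorrelated observation within the decorrelated simulations and maps the
## rank through the standard-normal quantile function.

#' Prediction-performance metrics
#'
#' @param observations Observed concentrations, mg/L (all positive; data are
#'   LLOQ-filtered upstream).
#' @param predictions Predicted concentrations, mg/L, aligned with
#'   `observations`.
#' @return Object of class `metrics_report`: `n`, `ME` (mg/L) with `ME_CI`
#'   (95% t-interval) and `ME_p` (Student test), `MPE` (%), `RMSE` (%),
#'   `R2` (%), `spearman_p`.
#' @export
prediction_metrics <- function(observations, predictions) {
  n <- length(observations)
  if (n == 0L) stop("prediction_metrics: no observations")
  if (length(predictions) != n) stop("prediction_metrics: length mismatch")
  if (any(observations <= 0))
    stop("prediction_metrics: non-positive observation; ",
         "apply the LLOQ filter before computing relative metrics")
  err <- predictions - observations
  pe <- (observations - predictions) / observations
  ME <- mean(err)
  if (n >= 2L && stats::sd(err) > 0) {
    tt <- stats::t.test(err)
    ME_CI <- as.numeric(tt$conf.int); ME_p <- tt$p.value
  } else {
    ME_CI <- c(ME, ME); ME_p <- NA_real_
  }
  R2 <- if (n >= 3L && stats::sd(observations) > 0 && stats::sd(predictions) > 0)
    100 * stats::cor(observations, predictions)^2 else NA_real_
  spearman_p <- if (n >= 3L && stats::sd(predictions) > 0)
    suppressWarnings(stats::cor.test(observations, predictions,
                                     method = "spearman"))$p.value
  else NA_real_
  structure(list(n = n, ME = ME, ME_CI = ME_CI, ME_p = ME_p,
                 MPE = 100 * mean(pe), RMSE = 100 * sqrt(mean(pe^2)),
                 R2 = R2, spearman_p = spearman_p),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> n = %d\n  ME   = %.3f mg/L [%.3f; %.3f], p = %s\n  MPE  = %.1f %%\n  RMSE = %.1f %%\n  R2   = %s %%, Spearman p = %s\n",
    x$n, x$ME, x$ME_CI[1L], x$ME_CI[2L],
    if (is.na(x$ME_p)) "NA" else sprintf("%.4f", x$ME_p),
    x$MPE, x$RMSE,
    if (is.na(x$R2)) "NA" else sprintf("%.1f", x$R2),
    if (is.na(x$spearman_p)) "NA" else sprintf("%.2g", x$spearman_p)))
  invisible(x)
}

## Lower Cholesky factor with an eigenvalue floor for (near-)singular
## empirical covariances; attribute "floored" records the fallback.
safe_chol_lower <- function(S) {
  S <- (S + t(S)) / 2
  L <- tryCatch(t(chol(S)), error = function(e) NULL)
  floored <- FALSE
  if (is.null(L)) {
    ev <- eigen(S, symmetric = TRUE)
    lam <- pmax(ev$values, max(ev$values, 0) * 1e-8 + 1e-12)
    L <- t(chol(ev$vectors %*% (lam * t(ev$vectors))))
    floored <- TRUE
  }
  attr(L, "floored") <- floored
  L
}

## Decorrelated residuals for one subject: list(ystar, simstar).
## The decorrelation mean and Cholesky factor are estimated from an
## auxiliary calibration batch of the same size as the reference batch, so
## the observation and the reference simulations are exactly exchangeable
## after the transform (ranking inside the estimating batch would otherwise
## distort the finite-K size of the NPDE tests).
.decorrelate_subject <- function(model, subject, K, include_obs = TRUE) {
  sims <- simulate_batch(model, subject, 2L * K, include_residual = TRUE)
  calib <- sims[seq_len(K), , drop = FALSE]
  ref <- sims[K + seq_len(K), , drop = FALSE]
  m <- colMeans(calib)
  S <- stats::cov(calib)
  L <- safe_chol_lower(S)
  y <- subject$observations$conc
  list(ystar = if (include_obs) forwardsolve(L, y - m) else NULL,
       simstar = forwardsolve(L, t(ref) - m),   # n x K
       floored = attr(L, "floored"))
}

#' Population-weighted residuals (PWRES)
#'
#' Simulation-based: K replicates of the subject's observation vector give an
#' empirical mean and covariance; PWRES is the Cholesky-decorrelated
#' difference between the observed vector and the simulation mean.
#'
#' @param model A [poppk_model()].
#' @param subject An [ifx_subject()] with observed concentrations.
#' @param K Number of simulated replicates (>= 100).
#' @param rng_seed Integer seed.
#' @return Numeric vector of PWRES, one per observation.
#' @export
compute_pwres <- function(model, subject, K = 1000L, rng_seed = 1) {
  stopifnot(K >= 100L)
  seed <- subject_seed(rng_seed, subject)
  with_seed(seed, .decorrelate_subject(model, subject, K)$ystar)
}

#' Individual-weighted residuals (IWRES)
#'
#' @param observations Observed concentrations, mg/L.
#' @param ipred Individual predictions, mg/L, aligned.
#' @param residual_spec A [residual_error_spec()].
#' @return `(obs - ipred) / residual_sd(spec, ipred)`.
#' @export
compute_iwres <- function(observations, ipred, residual_spec) {
  stopifnot(length(observations) == length(ipred))
  (observations - ipred) / pmax(residual_sd(residual_spec, pmax(ipred, 0)), 1e-12)
}

## per-subject seed that depends on the subject id, not its position, so
## cohort-level diagnostics are invariant to subject ordering
subject_seed <- function(rng_seed, subject) {
  id <- as.character(subject$subject_id)
  h <- sum(utf8ToInt(id) * seq_len(nchar(id)))
  derive_seed(rng_seed, h)
}

#' Normalized prediction distribution errors (NPDE)
#'
#' For each subject, 2K replicate observation vectors are simulated under
#' the model; the first K estimate the decorrelation mean and Cholesky
#' factor, and the observed vector is ranked among the remaining K reference
#' replicates after both are decorrelated (the split keeps observation and
#' reference simulations exactly exchangeable); the prediction discrepancy
#' `pde` is the mid-rank position `(r + 1/2) / (K + 1)` of the decorrelated
#' observation among the K decorrelated simulations, with
#' `r = #(sims below) + (#(sims equal))/2` (deterministic, never exactly 0
#' or 1); NPDE is its standard-normal quantile. Under the true model NPDE
#' follow N(0, 1); the mid-rank position keeps the finite-K NPDE variance
#' unbiased (a clamped strict-rank `r/K` convention does not), and the
#' half-weighting of ties handles the probability atom that residual
#' truncation at zero puts on very low concentrations.
#'
#' @param model A [poppk_model()].
#' @param dataset An [ifx_cohort()] with observed concentrations.
#' @param K Simulated replicates per subject (1000 for reported runs;
#'   reducible for fast checks).
#' @param rng_seed Integer seed.
#' @return `data.frame(subject_id, time, obs, ppred, npde)`, one row per
#'   observation.
#' @export
compute_npde <- function(model, dataset, K = 1000L, rng_seed = 1) {
  stopifnot(K >= 2L)
  rows <- lapply(unclass(dataset), function(s) {
    if (!nrow(s$observations)) return(NULL)
    d <- with_seed(subject_seed(rng_seed, s),
                   .decorrelate_subject(model, s, K))
    r_mid <- rowSums(d$simstar < d$ystar) + 0.5 * rowSums(d$simstar == d$ystar)
    pde <- (r_mid + 0.5) / (K + 1)
    quick_df(list(subject_id = rep(as.character(s$subject_id),
                                   length(pde)),
                  time = s$observations$time,
                  obs = s$observations$conc,
                  ppred = population_predict(model, s),
                  npde = stats::qnorm(pde)))
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

## Miao-Gel-Gastwirth-type symmetry test: the scaled mean-median statistic
## referred to a sign-flip (symmetrization) resampling distribution, which
## keeps the test's finite-sample size honest where the asymptotic normal
## reference (variance 0.5708/n) is conservative. Deterministic: the
## resampling runs under a fixed internal seed.
symmetry_test <- function(x, B = 400L) {
  n <- length(x)
  stat <- function(z) {
    mz <- stats::median(z)
    J <- sqrt(pi / 2) * mean(abs(z - mz))
    if (J == 0) return(NA_real_)
    (mean(z) - mz) / J
  }
  t0 <- stat(x)
  if (is.na(t0)) return(NA_real_)
  m <- stats::median(x)
  d <- abs(x - m)
  ts <- with_seed(28011L, vapply(seq_len(B), function(b)
    stat(m + sample(c(-1, 1), n, replace = TRUE) * d), numeric(1)))
  (1 + sum(abs(ts) >= abs(t0), na.rm = TRUE)) / (B + 1)
}

#' Statistical tests on an NPDE sample
#'
#' The four standard checks that NPDE follow N(0, 1): mean = 0 (Wilcoxon
#' signed-rank), variance = 1 (two-sided chi-squared variance test, the
#' common implementation of the "Fisher" variance comparison), normality
#' (Shapiro-Wilk), and symmetry about the median (Miao-Gel-Gastwirth-type).
#'
#' @param npde Numeric vector (n >= 8) of NPDE values.
#' @return Object of class `npde_test_report`: `n`, `mean`, `mean_p`,
#'   `variance`, `variance_p`, `shapiro_p`, `symmetry_p`, `degenerate`.
#' @export
npde_tests <- function(npde) {
  npde <- npde[is.finite(npde)]
  n <- length(npde)
  if (n < 8L) stop("npde_tests: need at least 8 values")
  s2 <- stats::var(npde)
  if (s2 == 0) {
    return(structure(list(n = n, mean = mean(npde), mean_p = NA_real_,
                          variance = 0, variance_p = NA_real_,
                          shapiro_p = NA_real_, symmetry_p = NA_real_,
                          degenerate = TRUE),
                     class = "npde_test_report"))
  }
  mean_p <- stats::wilcox.test(npde, mu = 0, exact = FALSE)$p.value
  stat <- (n - 1) * s2
  variance_p <- min(1, 2 * min(stats::pchisq(stat, n - 1),
                               stats::pchisq(stat, n - 1, lower.tail = FALSE)))
  shapiro_p <- stats::shapiro.test(
    if (n > 5000L) npde[round(seq(1L, n, length.out = 5000L))] else npde)$p.value
  structure(list(n = n, mean = mean(npde), mean_p = mean_p,
                 variance = s2, variance_p = variance_p,
                 shapiro_p = shapiro_p, symmetry_p = symmetry_test(npde),
                 degenerate = FALSE),
            class = "npde_test_report")
}

#' @export
print.npde_test_report <- function(x, ...) {
  cat(sprintf(
    "<npde_test_report> n = %d%s\n  mean     = %.3f (Wilcoxon p = %s)\n  variance = %.3f (chi-squared p = %s)\n  normality (Shapiro-Wilk) p = %s\n  symmetry p = %s\n",
    x$n, if (x$degenerate) " [degenerate]" else "",
    x$mean, format(x$mean_p, digits = 3),
    x$variance, format(x$variance_p, digits = 3),
    format(x$shapiro_p, digits = 3), format(x$symmetry_p, digits = 3)))
  invisible(x)
}

#' Eta-shrinkage
#'
#' `1 - sd(eta_hat) / omega` per parameter: 0 for informative data, 1 when
#' all individual estimates collapse to the prior mode.
#'
#' @param eta_estimates Matrix (subjects x parameters) of MAP eta estimates,
#'   columns named by parameter, or a list of `ifx_map` objects.
#' @param omega Named inter-individual SDs (default: taken per column name
#'   from `omega`).
#' @return Named vector of shrinkage fractions (`NA` where omega = 0, with a
#'   warning).
#' @export
eta_shrinkage <- function(eta_estimates, omega) {
  if (is.list(eta_estimates) && !is.matrix(eta_estimates))
    eta_estimates <- do.call(rbind, lapply(eta_estimates, `[[`, "eta"))
  if (nrow(eta_estimates) < 2L) stop("eta_shrinkage: need >= 2 subjects")
  out <- stats::setNames(rep(NA_real_, ncol(eta_estimates)),
                         colnames(eta_estimates))
  for (p in colnames(eta_estimates)) {
    w <- omega[[p]]
    if (is.null(w) || w == 0) {
      warning("eta_shrinkage: omega is zero for ", p, "; shrinkage undefined")
    } else {
      out[p] <- 1 - stats::sd(eta_estimates[, p]) / w
    }
  }
  out
}
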