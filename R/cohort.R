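## Synthetic TDM cohort generator.
##
## Emulates the marginal structure of a real-world inflammatory-disease
## infliximab TDM population: ~157 subjects, 52.2% female, median weight
## 68 kg (24-150), median 23 infusions per subject at median 44-day
## intervals, median dose 400 mg, trough-only sampling with a median of 2
## samples per subject, 7.6% ADA-positive, and a Crohn-dominated disease mix.
## Continuous covariates use truncated log-normals whose medians equal the
## population medians; infusion counts use a shifted negative binomial.
## Joint covariate correlations are deliberately not modelled.

## truncated log-normal sampler parameterised by its (untruncated) median
rlnorm_trunc <- function(n, median, sdlog, range) {
  mlog <- log(median)
  plo <- stats::plnorm(range[1L], mlog, sdlog)
  phi <- stats::plnorm(range[2L], mlog, sdlog)
  stats::qlnorm(stats::runif(n, plo, phi), mlog, sdlog)
}

rnbinom_trunc <- function(n, mu, size, shift, range) {
  lo <- range[1L] - shift; hi <- range[2L] - shift
  plo <- if (lo > 0) stats::pnbinom(lo - 1L, size = size, mu = mu) else 0
  phi <- stats::pnbinom(hi, size = size, mu = mu)
  shift + stats::qnbinom(stats::runif(n, plo, phi), size = size, mu = mu)
}

rnorm_trunc <- function(n, mean, sd, range) {
  plo <- stats::pnorm(range[1L], mean, sd)
  phi <- stats::pnorm(range[2L], mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Synthetic cohort configuration
#'
#' Defaults encode the study-population summaries (medians, ranges, category
#' frequencies) of the external evaluation dataset; the parametric forms
#' around them are package assumptions, all overridable. Disease percentages
#' are normalised to sum to 1 (the source population contains multi-pathology
#' patients, so the raw percentages sum to slightly more than 100%).
#'
#' @param n_subjects Number of subjects.
#' @param female_fraction Fraction of female subjects.
#' @param weight,age,interval,dose Lists `(median, sdlog, range)` for
#'   truncated log-normal draws (kg, years, days, mg). Doses are rounded to
#'   `dose$round_to` mg and constant per subject.
#' @param disease_mix Named probabilities over Crohn/AS/UC/PsA/RA.
#' @param ada_prevalence Probability of anti-drug-antibody positivity
#'   (assigned at baseline, constant over time).
#' @param immunomodulators Named probabilities of concurrent azathioprine,
#'   methotrexate, mercaptopurine and other immunomodulators (independent
#'   draws; `IMM` = any of them, `MTX` its own flag).
#' @param n_infusions List `(mu, size, shift, range)`: infusions per subject
#'   as `shift + NegBin(mu, size)` truncated to `range`.
#' @param n_samples List `(values, probs)`: samples (troughs) per subject.
#' @param trough_offset_max Maximum time before an infusion at which the
#'   trough is drawn (days; sampling offset is uniform on (0, max)).
#' @param infusion_duration Infusion length in days (default 2 h).
#' @param albumin List `(mean, sd, range)` for serum albumin, g/L.
#' @param hbi_lambda Poisson mean of the Harvey-Bradshaw index.
#' @param induction_days Days since first dose classified as the induction
#'   period (the `PERIOD` covariate switches to maintenance afterwards).
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 157,
                          female_fraction = 0.522,
                          weight = list(median = 68, sdlog = 0.25, range = c(24, 150)),
                          age = list(median = 39.5, sdlog = 0.35, range = c(8.5, 87.7)),
                          disease_mix = c(Crohn = 0.739, AS = 0.140, UC = 0.115,
                                          PsA = 0.019, RA = 0.019),
                          ada_prevalence = 0.076,
                          immunomodulators = c(azathioprine = 0.312,
                                               methotrexate = 0.197,
                                               mercaptopurine = 0.038,
                                               other = 0.013),
                          n_infusions = list(mu = 22, size = 8, shift = 2,
                                             range = c(2, 45)),
                          interval = list(median = 44, sdlog = 0.2, range = c(14, 79)),
                          dose = list(median = 400, sdlog = 0.25,
                                      range = c(180, 1000), round_to = 10),
                          n_samples = list(values = 1:6,
                                           probs = c(0.30, 0.35, 0.15, 0.10, 0.06, 0.04)),
                          trough_offset_max = 1,
                          infusion_duration = 2 / 24,
                          albumin = list(mean = 40, sd = 4, range = c(25, 55)),
                          hbi_lambda = 4,
                          induction_days = 56) {
  cfg <- list(n_subjects = n_subjects, female_fraction = female_fraction,
              weight = weight, age = age,
              disease_mix = disease_mix / sum(disease_mix),
              ada_prevalence = ada_prevalence,
              immunomodulators = immunomodulators,
              n_infusions = n_infusions, interval = interval, dose = dose,
              n_samples = n_samples, trough_offset_max = trough_offset_max,
              infusion_duration = infusion_duration, albumin = albumin,
              hbi_lambda = hbi_lambda, induction_days = induction_days)
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  fr <- c(cfg$female_fraction, cfg$ada_prevalence, cfg$immunomodulators)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (abs(sum(cfg$disease_mix) - 1) > 1e-8) stop("disease mixture must sum to 1")
  for (nm in c("weight", "age", "interval", "dose")) {
    d <- cfg[[nm]]
    if (d$median < d$range[1L] || d$median > d$range[2L])
      stop("infeasible config: ", nm, " median outside its range")
    if (d$sdlog <= 0) stop(nm, " sdlog must be positive")
  }
  if (abs(sum(cfg$n_samples$probs) - 1) > 1e-8)
    stop("samples-per-subject probabilities must sum to 1")
  if (cfg$n_infusions$range[1L] < cfg$n_infusions$shift)
    stop("infusion count range incompatible with shift")
  if (cfg$trough_offset_max <= 0 ||
      cfg$trough_offset_max >= cfg$interval$range[1L])
    stop("trough offset must be positive and below the smallest interval")
  invisible(cfg)
}

#' Generate a virtual TDM cohort
#'
#' Draws covariates, dosing histories and trough sampling times per the
#' configuration; concentrations are left unset (see [simulate_dataset()]).
#' A pure function of `(config, rng_seed)`.
#'
#' @param config A [cohort_config()].
#' @param rng_seed Integer seed.
#' @return An [ifx_cohort()].
#' @export
generate_cohort <- function(config = cohort_config(), rng_seed = 1) {
  validate_cohort_config(config)
  n <- config$n_subjects
  with_seed(rng_seed, {
    female <- stats::runif(n) < config$female_fraction
    wt <- rlnorm_trunc(n, config$weight$median, config$weight$sdlog,
                       config$weight$range)
    age <- rlnorm_trunc(n, config$age$median, config$age$sdlog, config$age$range)
    disease <- sample(names(config$disease_mix), n, replace = TRUE,
                      prob = config$disease_mix)
    ada <- stats::runif(n) < config$ada_prevalence
    imm_draws <- do.call(cbind, lapply(config$immunomodulators,
                                       function(p) stats::runif(n) < p))
    mtx <- imm_draws[, "methotrexate"]
    imm <- rowSums(imm_draws) > 0
    alb <- rnorm_trunc(n, config$albumin$mean, config$albumin$sd,
                       config$albumin$range)
    hbi <- stats::rpois(n, config$hbi_lambda)
    n_inf <- rnbinom_trunc(n, config$n_infusions$mu, config$n_infusions$size,
                           config$n_infusions$shift, config$n_infusions$range)
    n_samp <- sample(config$n_samples$values, n, replace = TRUE,
                     prob = config$n_samples$probs)

    subjects <- vector("list", n)
    for (i in seq_len(n)) {
      ni <- n_inf[i]
      ivals <- rlnorm_trunc(ni - 1L, config$interval$median,
                            config$interval$sdlog, config$interval$range)
      dose_times <- cumsum(c(0, ivals))
      amt <- round(rlnorm_trunc(1L, config$dose$median, config$dose$sdlog,
                                config$dose$range) / config$dose$round_to) *
        config$dose$round_to
      doses <- quick_df(list(time = dose_times,
                             amount = rep(amt, ni),
                             duration = rep(config$infusion_duration, ni),
                             occasion = seq_len(ni)))
      ns <- min(n_samp[i], ni - 1L)
      at_inf <- sort((2:ni)[sample.int(ni - 1L, ns)])
      offs <- stats::runif(ns, 0, config$trough_offset_max)
      obs <- quick_df(list(time = dose_times[at_inf] - offs,
                           conc = rep(NA_real_, ns),
                           blq = rep(FALSE, ns)))
      sex_i <- if (female[i]) "female" else "male"
      cov <- quick_df(list(
        time = c(0, config$induction_days),
        WT = rep(wt[i], 2L), SEX = rep(sex_i, 2L), AGE = rep(age[i], 2L),
        DISEASE = rep(disease[i], 2L),
        MTX = rep(as.numeric(mtx[i]), 2L), IMM = rep(as.numeric(imm[i]), 2L),
        ADA = rep(as.numeric(ada[i]), 2L), ALB = rep(alb[i], 2L),
        HBI = rep(as.numeric(hbi[i]), 2L),
        PERIOD = c("induction", "maintenance")))
      subjects[[i]] <- ifx_subject(sprintf("S%04d", i), doses, obs, cov)
    }
    ifx_cohort(subjects)
  })
}

#' Fill a cohort's observations by simulation under a model
#'
#' Simulates each subject's concentrations under `true_model` (random effects
#' plus residual noise) and stores the drawn random effects on the subject
#' (`$true_eta`, `$true_kappa`) for recovery tests.
#'
#' @param cohort An [ifx_cohort()] from [generate_cohort()].
#' @param true_model A [poppk_model()].
#' @param rng_seed Integer seed.
#' @param include_residual Add residual noise (default `TRUE`).
#' @return The cohort with concentrations filled in.
#' @export
simulate_dataset <- function(cohort, true_model, rng_seed = 1,
                             include_residual = TRUE) {
  out <- lapply(seq_along(cohort), function(i) {
    s <- cohort[[i]]
    y <- simulate_individual(true_model, s, derive_seed(rng_seed, i),
                             include_residual = include_residual)
    s$observations$conc <- as.numeric(y)
    s$true_eta <- attr(y, "eta")
    s$true_kappa <- attr(y, "kappa")
    s
  })
  structure(out, class = "ifx_cohort")
}

#' Apply assay quantification limits
#'
#' Drops observations below the lower limit of quantification and above the
#' acceptance ceiling for diluted samples; subjects left without observations
#' are removed. Exclusions are logged in the `exclusions` attribute.
#'
#' @param cohort An [ifx_cohort()] with concentrations.
#' @param lloq Lower limit of quantification, mg/L (default 0.3).
#' @param uloq Upper acceptance limit, mg/L (default 40).
#' @return Filtered `ifx_cohort` with attribute `exclusions`
#'   (`data.frame(subject_id, time, conc, reason)`).
#' @export
apply_quantification_limits <- function(cohort, lloq = 0.3, uloq = 40) {
  stopifnot(lloq < uloq)
  logs <- list()
  out <- list()
  for (s in unclass(cohort)) {
    obs <- s$observations
    known <- !is.na(obs$conc)
    low <- known & obs$conc < lloq
    high <- known & obs$conc > uloq
    if (any(low | high)) {
      logs[[length(logs) + 1L]] <- quick_df(list(
        subject_id = rep(as.character(s$subject_id), sum(low | high)),
        time = obs$time[low | high], conc = obs$conc[low | high],
        reason = ifelse(low[low | high], "below LLOQ", "above ULOQ")))
    }
    s$observations <- obs[!(low | high), , drop = FALSE]
    rownames(s$observations) <- NULL
    if (nrow(s$observations) > 0L) out[[length(out) + 1L]] <- s
  }
  res <- structure(out, class = "ifx_cohort")
  attr(res, "exclusions") <- if (length(logs)) do.call(rbind, logs) else
    quick_df(list(subject_id = character(0), time = numeric(0),
                  conc = numeric(0), reason = character(0)))
  res
}
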