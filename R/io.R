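## Event-stream dataset I/O and the evaluation orchestrator.
##
## CSV dialect (NONMEM-style event stream, one row per event):
##   ID    subject identifier
##   TIME  days since the subject's first dose (first dose at 0)
##   EVT   "dose", "obs" or "cov"
##   AMT   dose amount, mg (dose rows)
##   DUR   infusion duration, days (dose rows)
##   DV    observed concentration, mg/L (obs rows)
##   WT SEX AGE DISEASE MTX IMM ADA ALB HBI PERIOD   (cov rows; carried
##         forward from the most recent record at or before an event)
## Missing values are written as ".".

EVENT_COLUMNS <- c("ID", "TIME", "EVT", "AMT", "DUR", "DV", COVARIATE_COLUMNS)

.fmt <- function(x) {
  out <- rep(".", length(x))
  ok <- !is.na(x)
  out[ok] <- if (is.numeric(x)) sprintf("%.17g", x[ok]) else as.character(x[ok])
  out
}

#' Write a cohort as an event-stream CSV
#'
#' @param cohort An [ifx_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(cohort, path) {
  blocks <- lapply(unclass(cohort), function(s) {
    id <- as.character(s$subject_id)
    cv <- s$covariates
    for (col in setdiff(COVARIATE_COLUMNS, names(cv))) cv[[col]] <- NA
    rows <- list(
      data.frame(ID = id, TIME = cv$time, EVT = "cov", AMT = NA_real_,
                 DUR = NA_real_, DV = NA_real_,
                 cv[COVARIATE_COLUMNS], check.names = FALSE),
      data.frame(ID = id, TIME = s$doses$time, EVT = "dose",
                 AMT = s$doses$amount, DUR = s$doses$duration, DV = NA_real_,
                 stats::setNames(as.list(rep(NA, length(COVARIATE_COLUMNS))),
                                 COVARIATE_COLUMNS), check.names = FALSE))
    if (nrow(s$observations))
      rows[[3L]] <- data.frame(
        ID = id, TIME = s$observations$time, EVT = "obs", AMT = NA_real_,
        DUR = NA_real_, DV = s$observations$conc,
        stats::setNames(as.list(rep(NA, length(COVARIATE_COLUMNS))),
                        COVARIATE_COLUMNS), check.names = FALSE)
    block <- do.call(rbind, rows)
    block[order(block$TIME, match(block$EVT, c("cov", "obs", "dose"))), ]
  })
  tab <- do.call(rbind, blocks)
  out <- as.data.frame(lapply(tab, .fmt), check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.num_in <- function(x) {
  x[x == "."] <- NA_character_
  as.numeric(x)
}
.chr_in <- function(x) {
  x[x == "."] <- NA_character_
  x
}

#' Read an event-stream CSV into a cohort
#'
#' Assembles subjects from dose, observation and covariate rows, applies the
#' quantification limits, and reports exclusions via the `exclusions`
#' attribute. Malformed files (unknown columns, unsorted times, observations
#' before the first dose) raise errors naming the offending rows.
#'
#' @param path CSV file path.
#' @param lloq,uloq Quantification limits passed to
#'   [apply_quantification_limits()]; set `apply_limits = FALSE` to skip.
#' @param apply_limits Apply the limits (default `TRUE`).
#' @return An [ifx_cohort()].
#' @export
read_dataset <- function(path, lloq = 0.3, uloq = 40, apply_limits = TRUE) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  unknown <- setdiff(names(raw), EVENT_COLUMNS)
  if (length(unknown))
    stop("read_dataset: unknown column(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(c("ID", "TIME", "EVT"), names(raw))
  if (length(missing))
    stop("read_dataset: missing column(s): ", paste(missing, collapse = ", "))
  raw$.row <- seq_len(nrow(raw)) + 1L   # file line numbers (after header)
  time <- .num_in(raw$TIME)
  if (any(is.na(time)))
    stop("read_dataset: non-numeric TIME at row(s) ",
         paste(raw$.row[is.na(time)], collapse = ", "))
  bad_evt <- !raw$EVT %in% c("dose", "obs", "cov")
  if (any(bad_evt))
    stop("read_dataset: unknown EVT at row(s) ",
         paste(raw$.row[bad_evt], collapse = ", "))

  subjects <- lapply(split(seq_len(nrow(raw)), factor(raw$ID, levels = unique(raw$ID))),
                     function(ix) {
    rr <- raw[ix, , drop = FALSE]
    tt <- time[ix]
    dsel <- rr$EVT == "dose"; osel <- rr$EVT == "obs"; csel <- rr$EVT == "cov"
    if (!any(dsel)) stop("read_dataset: subject ", rr$ID[1L], " has no dose")
    if (is.unsorted(tt[dsel]))
      stop("read_dataset: unsorted dose times for subject ", rr$ID[1L],
           " near row ", rr$.row[dsel][1L])
    first_dose <- min(tt[dsel])
    early <- osel & tt < first_dose
    if (any(early))
      stop("read_dataset: observation before first dose at row(s) ",
           paste(rr$.row[early], collapse = ", "))
    doses <- quick_df(list(time = tt[dsel], amount = .num_in(rr$AMT[dsel]),
                           duration = .num_in(rr$DUR[dsel])))
    obs <- quick_df(list(time = tt[osel], conc = .num_in(rr$DV[osel]),
                         blq = rep(FALSE, sum(osel))))
    cov <- data.frame(time = tt[csel])
    for (col in COVARIATE_COLUMNS) {
      if (!col %in% names(rr)) next
      v <- .chr_in(rr[[col]][csel])
      if (all(is.na(v))) next
      cov[[col]] <- if (col %in% c("SEX", "DISEASE", "PERIOD")) v else as.numeric(v)
    }
    cov <- cov[order(cov$time), , drop = FALSE]
    ifx_subject(rr$ID[1L], doses, obs, cov)
  })
  cohort <- ifx_cohort(unname(subjects))
  if (apply_limits) cohort <- apply_quantification_limits(cohort, lloq, uloq)
  cohort
}

## ---- evaluation orchestrator ----------------------------------------------

#' Run the full external-evaluation pipeline
#'
#' For each requested model: draw the subpopulation matching its
#' construction-population rules, compute population and MAP-individual
#' predictions, the prediction-performance metrics for both, NPDE with the
#' four statistical tests, a prediction-corrected VPC, and (optionally) the
#' same metrics and NPDE tests for the covariate-stripped model variant.
#'
#' @param config List with elements:
#'   `models` (ids, default all registered), one of `dataset` (CSV path) or
#'   `cohort` (an [ifx_cohort()]) or `simulate`
#'   (`list(true_model =, cohort_config =)`), `K` (NPDE replicates, default
#'   1000), `n_replicates` (VPC replicates, default 1000), `n_bins`
#'   (default 8), `seed` (default 1), `lloq`/`uloq`, `with_stripped`
#'   (default `TRUE`), `output_dir` (optional; writes tidy CSVs and a JSON
#'   summary embedding the seed and configuration).
#' @return Named list (one element per model id) of evaluation results;
#'   models whose subpopulation is empty yield `n_subjects = 0` entries.
#' @export
run_evaluation <- function(config = list()) {
  models <- config$models %||% list_models()
  K <- config$K %||% 1000L
  n_replicates <- config$n_replicates %||% 1000L
  n_bins <- config$n_bins %||% 8L
  seed <- config$seed %||% 1L
  lloq <- config$lloq %||% 0.3
  uloq <- config$uloq %||% 40
  with_stripped <- config$with_stripped %||% TRUE

  cohort <- if (!is.null(config$cohort)) {
    apply_quantification_limits(config$cohort, lloq, uloq)
  } else if (!is.null(config$dataset)) {
    read_dataset(config$dataset, lloq, uloq)
  } else if (!is.null(config$simulate)) {
    sim <- config$simulate
    cc <- sim$cohort_config %||% cohort_config()
    raw <- generate_cohort(cc, derive_seed(seed, 1L))
    sim_model <- if (inherits(sim$true_model, "poppk_model")) sim$true_model
                 else get_model(sim$true_model %||% "A")
    apply_quantification_limits(
      simulate_dataset(raw, sim_model, derive_seed(seed, 2L)), lloq, uloq)
  } else stop("run_evaluation: config needs one of dataset, cohort, simulate")

  eval_one <- function(model, sub) {
    if (!length(sub)) return(list(n_subjects = 0L))
    obs <- unlist(lapply(unclass(sub), function(s) s$observations$conc))
    ppred <- unlist(lapply(unclass(sub), function(s) population_predict(model, s)))
    ipred <- unlist(lapply(unclass(sub), function(s)
      individual_predict(model, s, map_estimate(model, s))))
    npde <- compute_npde(model, sub, K = K, rng_seed = derive_seed(seed, 3L))
    list(n_subjects = length(sub), n_obs = length(obs),
         metrics_ppred = prediction_metrics(obs, ppred),
         metrics_ipred = prediction_metrics(obs, ipred),
         npde_tests = npde_tests(npde$npde))
  }

  results <- list()
  for (id in models) {
    model <- get_model(id)
    sub <- subpopulation_filter(model, cohort)
    res <- eval_one(model, sub)
    if (res$n_subjects > 0L) {
      res$vpc <- run_pcvpc(model, sub, n_replicates = n_replicates,
                           n_bins = n_bins, rng_seed = derive_seed(seed, 4L))
      if (with_stripped)
        res$stripped <- eval_one(strip_covariates(model), sub)
    }
    results[[id]] <- res
  }

  if (!is.null(config$output_dir))
    write_evaluation_report(results, config, config$output_dir)
  invisible(results)
}

## tidy CSV + JSON report bundle
write_evaluation_report <- function(results, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  metric_rows <- list()
  test_rows <- list()
  for (id in names(results)) {
    r <- results[[id]]
    if (r$n_subjects == 0L) next
    for (variant in c("full", if (!is.null(r$stripped)) "stripped")) {
      rr <- if (variant == "full") r else r$stripped
      for (type in c("ppred", "ipred")) {
        m <- rr[[paste0("metrics_", type)]]
        metric_rows[[length(metric_rows) + 1L]] <- quick_df(list(
          model = id, variant = variant, prediction = toupper(type),
          n = m$n, ME = m$ME, ME_lo = m$ME_CI[1L], ME_hi = m$ME_CI[2L],
          ME_p = m$ME_p, MPE = m$MPE, RMSE = m$RMSE, R2 = m$R2,
          spearman_p = m$spearman_p))
      }
      tst <- rr$npde_tests
      test_rows[[length(test_rows) + 1L]] <- quick_df(list(
        model = id, variant = variant, n = tst$n, mean = tst$mean,
        mean_p = tst$mean_p, variance = tst$variance,
        variance_p = tst$variance_p, shapiro_p = tst$shapiro_p,
        symmetry_p = tst$symmetry_p))
    }
    if (!is.null(r$vpc))
      utils::write.csv(as.data.frame(r$vpc),
                       file.path(dir, paste0("vpc_", id, ".csv")),
                       row.names = FALSE)
  }
  utils::write.csv(do.call(rbind, metric_rows), file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, test_rows), file.path(dir, "npde_tests.csv"),
                   row.names = FALSE)
  summary <- list(
    seed = config$seed %||% 1L,
    config = config[setdiff(names(config), c("cohort"))],
    models = lapply(results, function(r)
      list(n_subjects = r$n_subjects, n_obs = r$n_obs %||% 0L)))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  invisible(dir)
}
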