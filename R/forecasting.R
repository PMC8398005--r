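## Bayesian trough forecasting.
##
## Individual parameters are MAP-estimated from the data available up to the
## n-th infusion (the trough drawn just before dose n is the last datum);
## troughs at infusions n, n+1 and n+2 are then predicted noiselessly at the
## estimated parameters, using the actually administered doses, and compared
## with the observed troughs per horizon.

## infusion index each trough belongs to: the next infusion after the sample
## (a sample drawn at or just before dose j belongs to infusion j)
obs_infusion_index <- function(subject) {
  dt <- subject$doses$time
  findInterval(subject$observations$time - 1e-9, dt) + 1L
}

#' Forecast troughs for one subject
#'
#' @param model A [poppk_model()].
#' @param subject An [ifx_subject()] with an observed trough at infusion
#'   `n_index`.
#' @param n_index Index of the anchor infusion n.
#' @return `data.frame(subject_id, horizon, infusion, time, observed,
#'   predicted)` with one row per available horizon (`"n"`, `"n+1"`,
#'   `"n+2"`); horizons without an observed trough are absent.
#' @export
forecast_subject <- function(model, subject, n_index) {
  nd <- nrow(subject$doses)
  stopifnot(n_index >= 1L, n_index <= nd)
  inf_idx <- obs_infusion_index(subject)
  if (!any(inf_idx == n_index))
    stop("subject ", subject$subject_id,
         ": no observed trough at infusion ", n_index)
  window_end <- subject$doses$time[n_index]

  ## future covariate values are unknown at forecast time: predictions carry
  ## the last covariate record inside the estimation window forward
  s_known <- subject
  keep_cov <- subject$covariates$time <= window_end + 1e-9
  if (!any(keep_cov)) keep_cov[1L] <- TRUE
  s_known$covariates <- subject$covariates[keep_cov, , drop = FALSE]

  est <- map_estimate(model, s_known, window = window_end)

  rows <- list()
  for (h in 0:2) {
    sel <- which(inf_idx == n_index + h)
    if (!length(sel)) next
    times <- subject$observations$time[sel]
    pred <- individual_predict(model, s_known, est, times = times)
    rows[[length(rows) + 1L]] <- quick_df(list(
      subject_id = rep(as.character(subject$subject_id), length(sel)),
      horizon = rep(c("n", "n+1", "n+2")[h + 1L], length(sel)),
      infusion = rep(n_index + h, length(sel)),
      time = times,
      observed = subject$observations$conc[sel],
      predicted = as.numeric(pred)))
  }
  do.call(rbind, rows)
}

#' Run the forecasting pipeline over a cohort
#'
#' Per subject, the anchor infusion n is the earliest infusion (>= 2) with an
#' observed trough that is followed by at least one later trough; subjects
#' without such a pair are skipped.
#'
#' @param model A [poppk_model()].
#' @param cohort An [ifx_cohort()] with observed concentrations.
#' @param n_index Optional fixed anchor infusion for all subjects.
#' @return Combined forecast records (see [forecast_subject()]).
#' @export
run_forecast <- function(model, cohort, n_index = NULL) {
  rows <- lapply(unclass(cohort), function(s) {
    idx <- obs_infusion_index(s)
    n <- n_index
    if (is.null(n)) {
      cand <- sort(unique(idx[idx >= 2L & idx <= nrow(s$doses)]))
      cand <- cand[vapply(cand, function(j) any(idx > j), logical(1))]
      if (!length(cand)) return(NULL)
      n <- cand[1L]
    } else if (!any(idx == n)) return(NULL)
    forecast_subject(model, s, n)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("run_forecast: no subject has forecastable troughs")
  do.call(rbind, rows)
}

#' Per-horizon forecast error table
#'
#' Delegates to [prediction_metrics()] per horizon; horizons without records
#' are omitted.
#'
#' @param records Forecast records from [forecast_subject()] /
#'   [run_forecast()].
#' @return Object of class `forecast_table`: `data.frame(horizon, n, ME,
#'   MPE, RMSE)`.
#' @export
forecast_metrics <- function(records) {
  stopifnot(all(c("subject_id", "horizon", "observed", "predicted") %in%
                  names(records)))
  if (anyDuplicated(records[c("subject_id", "horizon", "time")]))
    stop("forecast_metrics: duplicate subject/horizon records")
  out <- lapply(c("n", "n+1", "n+2"), function(h) {
    r <- records[records$horizon == h, , drop = FALSE]
    if (!nrow(r)) return(NULL)
    m <- prediction_metrics(r$observed, r$predicted)
    quick_df(list(horizon = h, n = m$n, ME = m$ME, MPE = m$MPE, RMSE = m$RMSE))
  })
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  class(res) <- c("forecast_table", "data.frame")
  res
}

#' @export
print.forecast_table <- function(x, ...) {
  cat("<forecast_table> per-horizon prediction errors\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
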