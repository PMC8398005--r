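## Subject and cohort containers for therapeutic-drug-monitoring data.
##
## A subject bundles a dosing history (zero-order IV infusions), trough
## observations, and time-stamped covariate records. Times are in days since
## the first dose (first dose at t = 0); amounts in mg; concentrations in mg/L.

#' Construct a TDM subject
#'
#' @param subject_id Identifier (character or integer).
#' @param doses `data.frame` with columns `time` (days), `amount` (mg),
#'   `duration` (days, infusion length) and optionally `occasion`
#'   (defaults to the dose index: one occasion per inter-infusion interval).
#' @param observations `data.frame` with columns `time` (days), `conc`
#'   (mg/L, may be `NA` before simulation) and optionally `blq` (logical).
#' @param covariates `data.frame` with a `time` column plus any of
#'   `WT, SEX, AGE, DISEASE, MTX, IMM, ADA, ALB, HBI, PERIOD`. Values are
#'   carried forward from the most recent record at or before an event time.
#'
#' @return An object of class `ifx_subject`.
#' @export
ifx_subject <- function(subject_id, doses, observations = NULL, covariates) {
  doses <- as.data.frame(doses)
  stopifnot(all(c("time", "amount", "duration") %in% names(doses)))
  if (nrow(doses) < 1L) stop("subject ", subject_id, ": at least one dose is required")
  if (is.unsorted(doses$time)) stop("subject ", subject_id, ": doses must be sorted by time")
  if (any(doses$amount <= 0)) stop("subject ", subject_id, ": dose amounts must be positive")
  if (any(doses$duration <= 0)) stop("subject ", subject_id, ": infusion durations must be positive")
  if (is.null(doses$occasion)) doses$occasion <- seq_len(nrow(doses))

  if (is.null(observations)) {
    observations <- quick_df(list(time = numeric(0), conc = numeric(0), blq = logical(0)))
  }
  observations <- as.data.frame(observations)
  stopifnot("time" %in% names(observations))
  if (is.null(observations$conc)) observations$conc <- rep(NA_real_, nrow(observations))
  if (is.null(observations$blq)) observations$blq <- rep(FALSE, nrow(observations))
  if (nrow(observations) && any(observations$time < doses$time[1L]))
    stop("subject ", subject_id, ": observation before first dose")
  observations <- observations[order(observations$time), , drop = FALSE]
  rownames(observations) <- NULL

  covariates <- as.data.frame(covariates)
  stopifnot("time" %in% names(covariates))
  if (is.unsorted(covariates$time)) stop("subject ", subject_id, ": covariate records must be sorted by time")
  if (!is.null(covariates$WT) && any(covariates$WT <= 0, na.rm = TRUE))
    stop("subject ", subject_id, ": WT must be positive")
  if (!is.null(covariates$ALB) && any(covariates$ALB <= 0, na.rm = TRUE))
    stop("subject ", subject_id, ": ALB must be positive")
  if (!is.null(covariates$HBI) && any(covariates$HBI < 0, na.rm = TRUE))
    stop("subject ", subject_id, ": HBI must be non-negative")
  if (!is.null(covariates$DISEASE)) {
    bad <- setdiff(unique(stats::na.omit(as.character(covariates$DISEASE))), DISEASES)
    if (length(bad)) stop("subject ", subject_id, ": unknown DISEASE ", paste(bad, collapse = ", "))
  }

  structure(list(subject_id = subject_id, doses = doses,
                 observations = observations, covariates = covariates),
            class = "ifx_subject")
}

#' @export
print.ifx_subject <- function(x, ...) {
  cat(sprintf("<ifx_subject %s> %d infusions, %d observations, %d covariate record(s)\n",
              x$subject_id, nrow(x$doses), nrow(x$observations), nrow(x$covariates)))
  invisible(x)
}

#' Covariate record in force at a given time
#'
#' Last-observation-carried-forward lookup of the subject's time-stamped
#' covariates: returns the most recent record at or before `time` (the first
#' record if `time` precedes all records).
#'
#' @param subject An [ifx_subject()].
#' @param time Time in days.
#' @return A one-row `data.frame` of covariate values.
#' @export
covariates_at <- function(subject, time) {
  ct <- subject$covariates$time
  i <- findInterval(time, ct)
  i[i < 1L] <- 1L
  subject$covariates[i, setdiff(names(subject$covariates), "time"), drop = FALSE]
}

## Times (relative to the first covariate record) at which any covariate value
## changes; used to build piecewise-constant parameter segments. `fields`
## restricts the comparison to the covariates a model actually uses.
covariate_change_times <- function(subject, fields = NULL) {
  cv <- subject$covariates
  if (nrow(cv) <= 1L) return(numeric(0))
  cols <- setdiff(names(cv), "time")
  if (!is.null(fields)) cols <- intersect(cols, fields)
  if (!length(cols)) return(numeric(0))
  keep <- vapply(2:nrow(cv), function(i) {
    a <- cv[i - 1L, cols, drop = FALSE]; b <- cv[i, cols, drop = FALSE]
    !isTRUE(all.equal(a, b, check.attributes = FALSE))
  }, logical(1))
  cv$time[c(FALSE, keep)]
}

#' Bundle subjects into a cohort
#'
#' @param subjects List of [ifx_subject()] objects.
#' @return Object of class `ifx_cohort` (a list of subjects).
#' @export
ifx_cohort <- function(subjects) {
  stopifnot(all(vapply(subjects, inherits, logical(1), "ifx_subject")))
  ids <- vapply(subjects, function(s) as.character(s$subject_id), character(1))
  if (anyDuplicated(ids)) stop("duplicate subject ids in cohort")
  structure(subjects, class = "ifx_cohort")
}

#' @export
print.ifx_cohort <- function(x, ...) {
  nobs <- sum(vapply(x, function(s) nrow(s$observations), integer(1)))
  cat(sprintf("<ifx_cohort> %d subjects, %d observations\n", length(x), nobs))
  invisible(x)
}

#' @export
`[.ifx_cohort` <- function(x, i) {
  structure(unclass(x)[i], class = "ifx_cohort")
}
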