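## Registry of the eight published infliximab population PK models (A-H).
##
## Each model is stored as typical structural parameters (CL, V1, V2, Q) at a
## reference covariate set plus a list of multiplicative covariate terms, a
## random-effects spec (log-normal inter-individual variability; model G also
## carries inter-occasion variability on CL), a residual-error spec, and the
## construction-population eligibility rules used to draw the matching
## subpopulation for external evaluation.
##
## Covariate term forms (all multiplicative on the parameter):
##   power:       (x / center) ^ coefficient        (WT, ALB terms)
##   exp_linear:  exp(coefficient * x)              (0/1 flags, sex)
##   ratio_power: coefficient ^ (x - center)        (e.g. 1.345^SEX, 0.964^(HBI-6))
##   factor:      1 + coefficient * x               (e.g. (1 + 1.59 * ADA))

MODEL_IDS <- LETTERS[1:8]

#' Residual error specification
#'
#' @param kind `"additive"`, `"proportional"` or `"combined"`.
#' @param sigma_add Additive standard deviation, mg/L.
#' @param sigma_prop Proportional standard deviation, as a fraction of the
#'   prediction.
#' @param convention How combined errors compose: `"sd_additive"`
#'   (`sd = sigma_add + sigma_prop * f`, the Monolix convention used by the
#'   models published from Monolix) or `"variance_additive"`
#'   (`sd = sqrt(sigma_add^2 + (sigma_prop * f)^2)`, the NONMEM convention).
#' @return Object of class `residual_error_spec`.
#' @export
residual_error_spec <- function(kind = c("combined", "additive", "proportional"),
                                sigma_add = 0, sigma_prop = 0,
                                convention = c("variance_additive", "sd_additive")) {
  kind <- match.arg(kind)
  convention <- match.arg(convention)
  stopifnot(sigma_add >= 0, sigma_prop >= 0, sigma_prop < 1)
  if (kind == "additive" && (sigma_add <= 0 || sigma_prop != 0))
    stop("additive error requires sigma_add > 0 and sigma_prop = 0")
  if (kind == "proportional" && (sigma_prop <= 0 || sigma_add != 0))
    stop("proportional error requires sigma_prop > 0 and sigma_add = 0")
  if (kind == "combined" && (sigma_add <= 0 || sigma_prop <= 0))
    stop("combined error requires both sigmas > 0")
  structure(list(kind = kind, sigma_add = sigma_add, sigma_prop = sigma_prop,
                 convention = convention),
            class = "residual_error_spec")
}

#' Random effects specification
#'
#' Inter-individual variability is log-normal with a diagonal covariance:
#' `omega` holds per-parameter standard deviations on the log scale.
#' `iov_cl` is the inter-occasion standard deviation on log-CL (one occasion
#' per inter-infusion interval).
#'
#' @param omega Named non-negative numeric vector (names among CL, V1, V2, Q).
#' @param iov_cl Non-negative scalar.
#' @return Object of class `random_effects_spec`.
#' @export
random_effects_spec <- function(omega = c(CL = 0.30, V1 = 0.30), iov_cl = 0) {
  stopifnot(all(omega >= 0), iov_cl >= 0,
            all(names(omega) %in% c("CL", "V1", "V2", "Q")))
  structure(list(omega = omega, iov_cl = iov_cl), class = "random_effects_spec")
}

cov_term <- function(parameter, covariate, form, coefficient, center = 0) {
  stopifnot(parameter %in% c("CL", "V1", "V2", "Q"),
            form %in% c("power", "exp_linear", "ratio_power", "factor"))
  list(parameter = parameter, covariate = covariate, form = form,
       coefficient = coefficient, center = center)
}

#' Population PK model object
#'
#' Normally obtained from the registry via [get_model()]; the constructor is
#' exported so that variant models can be built in tests and sensitivity
#' analyses.
#'
#' @param model_id Single letter A-H (or another label for custom models).
#' @param name Human-readable reference.
#' @param n_compartments 1 or 2.
#' @param typical_values Named list with `CL`, `V1` and, for two-compartment
#'   models, `V2` and `Q` (L/day and L), valid at the reference covariates.
#' @param covariate_model List of terms built with the internal `cov_term()`
#'   (parameter, covariate, form, coefficient, center).
#' @param random_effects A [random_effects_spec()].
#' @param residual A [residual_error_spec()].
#' @param eligibility List describing the construction population:
#'   `diseases` (subset of Crohn/UC/AS/PsA/RA), `ada_free`, `adults_only`,
#'   `max_time` (days since first dose; `Inf` if unrestricted).
#' @param sex_coding `"male1"` if the model's sex covariate is 1 for males
#'   (the usual coding) or `"female1"` for the reverse.
#' @param reference_covariates Covariate set at which all covariate factors
#'   equal 1, so the model returns `typical_values` exactly.
#' @return Object of class `poppk_model`.
#' @export
poppk_model <- function(model_id, name, n_compartments, typical_values,
                        covariate_model, random_effects, residual, eligibility,
                        sex_coding = "male1", reference_covariates) {
  stopifnot(n_compartments %in% c(1L, 2L),
            all(c("CL", "V1") %in% names(typical_values)),
            inherits(random_effects, "random_effects_spec"),
            inherits(residual, "residual_error_spec"),
            sex_coding %in% c("male1", "female1"))
  if (n_compartments == 2L && !all(c("V2", "Q") %in% names(typical_values)))
    stop("two-compartment model requires V2 and Q typical values")
  if (any(unlist(typical_values) <= 0)) stop("typical values must be positive")
  m <- structure(list(model_id = model_id, name = name,
                      n_compartments = as.integer(n_compartments),
                      typical_values = typical_values,
                      covariate_model = covariate_model,
                      random_effects = random_effects, residual = residual,
                      eligibility = eligibility, sex_coding = sex_coding,
                      reference_covariates = reference_covariates),
                 class = "poppk_model")
  ## construction invariant: the reference covariates reproduce the typicals
  ref <- typical_parameters(m, reference_covariates)
  for (p in names(typical_values))
    if (!isTRUE(all.equal(ref[[p]], typical_values[[p]], tolerance = 1e-12)))
      stop("model ", model_id, ": covariate model does not reproduce typical ", p,
           " at reference covariates")
  m
}

#' @export
print.poppk_model <- function(x, ...) {
  cat(sprintf("<poppk_model %s> %s\n  %d-compartment; CL = %g L/day, V1 = %g L",
              x$model_id, x$name, x$n_compartments,
              x$typical_values$CL, x$typical_values$V1))
  if (x$n_compartments == 2L)
    cat(sprintf(", V2 = %g L, Q = %g L/day", x$typical_values$V2, x$typical_values$Q))
  cat(sprintf("\n  residual: %s (sigma_add = %g mg/L, sigma_prop = %g, %s)\n",
              x$residual$kind, x$residual$sigma_add, x$residual$sigma_prop,
              x$residual$convention))
  cat(sprintf("  %d covariate term(s); omega: %s; IOV(CL) = %g\n",
              length(x$covariate_model),
              paste(sprintf("%s=%g", names(x$random_effects$omega),
                            x$random_effects$omega), collapse = ", "),
              x$random_effects$iov_cl))
  invisible(x)
}

## ---- covariate derivation -------------------------------------------------

## Underlying subject field needed for each derived covariate name.
.cov_source <- c(WT = "WT", ALB = "ALB", HBI = "HBI", SEX = "SEX",
                 CROHN = "DISEASE", UC = "DISEASE", RA = "DISEASE",
                 IBD = "DISEASE", MTX = "MTX", IMM = "IMM", ADA = "ADA",
                 PED = "AGE", PERIOD = "PERIOD")

.get_cov <- function(cov, field, model_id, covariate) {
  v <- cov[[field]]
  if (is.data.frame(cov)) v <- v[1L]
  if (is.null(v) || is.na(v))
    stop("model ", model_id, ": required covariate '", covariate,
         "' (field ", field, ") is missing", call. = FALSE)
  v
}

derive_covariate <- function(name, cov, model) {
  id <- model$model_id
  src <- .cov_source[[name]]
  if (is.null(src)) stop("unknown covariate name '", name, "'")
  v <- .get_cov(cov, src, id, name)
  switch(name,
    WT = , ALB = , HBI = as.numeric(v),
    SEX = {
      male <- if (is.character(v) || is.factor(v)) {
        as.character(v) == "male"
      } else as.numeric(v) == 1
      if (model$sex_coding == "male1") as.numeric(male) else as.numeric(!male)
    },
    CROHN = as.numeric(as.character(v) == "Crohn"),
    UC = as.numeric(as.character(v) == "UC"),
    RA = as.numeric(as.character(v) == "RA"),
    IBD = as.numeric(as.character(v) %in% c("Crohn", "UC")),
    MTX = , IMM = , ADA = as.numeric(v),
    PED = as.numeric(as.numeric(v) < 15),
    PERIOD = if (is.character(v) || is.factor(v)) {
      as.numeric(as.character(v) == "induction")
    } else as.numeric(v)
  )
}

eval_term <- function(term, x) {
  switch(term$form,
    power = (x / term$center)^term$coefficient,
    exp_linear = exp(term$coefficient * x),
    ratio_power = term$coefficient^(x - term$center),
    factor = 1 + term$coefficient * x)
}

#' Individual typical structural parameters
#'
#' Applies a model's covariate equations to one covariate record (all random
#' effects at zero).
#'
#' @param model A [poppk_model()].
#' @param cov Named list or one-row `data.frame` of covariates (`WT`, `SEX`,
#'   `AGE`, `DISEASE`, `MTX`, `IMM`, `ADA`, `ALB`, `HBI`, `PERIOD` as the
#'   model requires). `SEX` may be `"female"`/`"male"` or 0/1 (0 = female);
#'   `PERIOD` may be `"induction"`/`"maintenance"` or 1/0.
#' @return Object of class `structural_parameters`: list with `CL`, `V1` and,
#'   for two-compartment models, `V2`, `Q`.
#' @export
typical_parameters <- function(model, cov) {
  pars <- model$typical_values
  for (term in model$covariate_model) {
    x <- derive_covariate(term$covariate, cov, model)
    f <- eval_term(term, x)
    if (!is.finite(f) || f <= 0)
      stop("model ", model$model_id, ": covariate factor for ", term$covariate,
           " on ", term$parameter, " is not positive (", f, ")")
    pars[[term$parameter]] <- pars[[term$parameter]] * f
  }
  structure(pars, class = "structural_parameters")
}

#' Remove all covariate effects from a model
#'
#' Returns a variant whose covariate factors are fixed at their reference
#' value of 1 for any covariate record, leaving the typical values unchanged.
#' Used for the covariate-free re-evaluation. Idempotent.
#'
#' @param model A [poppk_model()].
#' @return A `poppk_model` with an empty covariate model.
#' @export
strip_covariates <- function(model) {
  model$covariate_model <- list()
  model
}

## ---- eligibility ----------------------------------------------------------

subject_eligible <- function(model, subject) {
  el <- model$eligibility
  cv <- subject$covariates
  if (!is.null(el$diseases) && !is.null(cv$DISEASE) &&
      !all(as.character(cv$DISEASE) %in% el$diseases)) return(FALSE)
  if (isTRUE(el$ada_free)) {
    ada <- cv$ADA %||% 0
    if (any(as.numeric(ada) == 1, na.rm = TRUE)) return(FALSE)
  }
  if (isTRUE(el$adults_only)) {
    age <- cv$AGE
    if (!is.null(age) && any(as.numeric(age) < 15, na.rm = TRUE)) return(FALSE)
  }
  if (is.finite(el$max_time %||% Inf)) {
    if (!any(subject$observations$time <= el$max_time)) return(FALSE)
  }
  TRUE
}

#' Subpopulation matching a model's construction population
#'
#' Filters a cohort down to the subjects satisfying the model's
#' construction-population rules (disease mix, ADA status, adults only, or a
#' restriction to the first months of treatment). Order is preserved. For
#' models restricted in time (model D: first six months), observations beyond
#' the window are dropped from the retained subjects.
#'
#' @param model A [poppk_model()].
#' @param cohort An [ifx_cohort()] or list of subjects.
#' @return An `ifx_cohort` with the eligible subjects.
#' @export
subpopulation_filter <- function(model, cohort) {
  keep <- Filter(function(s) subject_eligible(model, s), unclass(cohort))
  mt <- model$eligibility$max_time %||% Inf
  if (is.finite(mt)) {
    keep <- lapply(keep, function(s) {
      s$observations <- s$observations[s$observations$time <= mt, , drop = FALSE]
      rownames(s$observations) <- NULL
      s
    })
  }
  structure(keep, class = "ifx_cohort")
}

## ---- the registry ---------------------------------------------------------

.build_registry <- function() {
  ref_abc <- list(WT = 67, SEX = "female", AGE = 40, DISEASE = "AS", MTX = 0)
  all5 <- DISEASES

  A <- poppk_model("A", "Passot et al. 2016", 1L,
    typical_values = list(CL = 0.23, V1 = 5.2),
    covariate_model = list(
      cov_term("CL", "WT", "power", 0.603, 67),
      cov_term("CL", "SEX", "exp_linear", 0.181),
      cov_term("CL", "CROHN", "exp_linear", 0.384),
      cov_term("CL", "UC", "exp_linear", 0.472),
      cov_term("CL", "RA", "exp_linear", 0.392),
      cov_term("CL", "MTX", "exp_linear", -0.336),
      cov_term("V1", "WT", "power", 0.277, 67),
      cov_term("V1", "SEX", "exp_linear", 0.209),
      cov_term("V1", "CROHN", "exp_linear", 0.399),
      cov_term("V1", "UC", "exp_linear", 0.417),
      cov_term("V1", "PED", "exp_linear", -0.396)),
    random_effects = random_effects_spec(),
    residual = residual_error_spec("combined", 0.72, 0.223, "sd_additive"),
    eligibility = list(diseases = all5, ada_free = TRUE, adults_only = FALSE,
                       max_time = Inf),
    reference_covariates = ref_abc)

  B <- poppk_model("B", "Ternant et al. 2017 (PK)", 1L,
    typical_values = list(CL = 0.24, V1 = 5.3),
    covariate_model = list(
      cov_term("CL", "WT", "power", 0.52, 67),
      cov_term("CL", "IBD", "exp_linear", 0.36),
      cov_term("CL", "RA", "exp_linear", 0.44),
      cov_term("CL", "MTX", "exp_linear", -0.37),
      cov_term("V1", "SEX", "exp_linear", 0.14),
      cov_term("V1", "IBD", "exp_linear", 0.25)),
    random_effects = random_effects_spec(),
    residual = residual_error_spec("combined", 0.80, 0.22, "sd_additive"),
    eligibility = list(diseases = all5, ada_free = TRUE, adults_only = FALSE,
                       max_time = Inf),
    reference_covariates = ref_abc)

  C <- poppk_model("C", "Ternant et al. 2017 (TLD)", 1L,
    typical_values = list(CL = 0.20, V1 = 5.3),
    covariate_model = list(
      cov_term("CL", "WT", "power", 0.68, 67),
      cov_term("CL", "IBD", "exp_linear", 0.43),
      cov_term("CL", "RA", "exp_linear", 0.50),
      cov_term("CL", "MTX", "exp_linear", -0.47),
      cov_term("V1", "SEX", "exp_linear", 0.19),
      cov_term("V1", "IBD", "exp_linear", 0.27)),
    random_effects = random_effects_spec(),
    residual = residual_error_spec("proportional", 0, 0.29, "sd_additive"),
    eligibility = list(diseases = all5, ada_free = TRUE, adults_only = FALSE,
                       max_time = Inf),
    reference_covariates = ref_abc)

  D <- poppk_model("D", "Aubourg et al. 2015", 2L,
    typical_values = list(CL = 0.336, V1 = 2.6, V2 = 4.5, Q = 1.992),
    covariate_model = list(
      cov_term("CL", "SEX", "exp_linear", 0.305),
      cov_term("V1", "WT", "power", 0.22, 60),
      cov_term("V1", "SEX", "exp_linear", 0.208)),
    random_effects = random_effects_spec(),
    residual = residual_error_spec("combined", 2.3, 0.21, "sd_additive"),
    eligibility = list(diseases = "Crohn", ada_free = TRUE, adults_only = FALSE,
                       max_time = 183),
    reference_covariates = list(WT = 60, SEX = "female"))

  ## Model E: sex coding reversed relative to the other models (configurable);
  ## central volume uses the power form 4.94 * 0.964^(HBI - 6).
  E <- poppk_model("E", "Buurman et al. 2015", 2L,
    typical_values = list(CL = 0.199, V1 = 4.94, V2 = 3.13, Q = 0.068),
    covariate_model = list(
      cov_term("CL", "SEX", "ratio_power", 1.345),
      cov_term("CL", "ADA", "ratio_power", 1.722),
      cov_term("CL", "PERIOD", "ratio_power", 1.40),
      cov_term("V1", "HBI", "ratio_power", 0.964, 6)),
    random_effects = random_effects_spec(),
    residual = residual_error_spec("combined", 0.98, 0.217, "variance_additive"),
    eligibility = list(diseases = c("Crohn", "UC"), ada_free = FALSE,
                       adults_only = FALSE, max_time = Inf),
    sex_coding = "female1",
    reference_covariates = list(SEX = "male", ADA = 0,
                                PERIOD = "maintenance", HBI = 6))

  ## Model F: residual error not reported in the source publication; the
  ## median combined error of the published models is imputed.
  F <- poppk_model("F", "Dotan et al. 2014", 2L,
    typical_values = list(CL = 0.381, V1 = 2.37, V2 = 1.37, Q = 0.122),
    covariate_model = list(
      cov_term("CL", "WT", "power", 0.612, 70),
      cov_term("CL", "ALB", "power", -1.39, 40),
      cov_term("CL", "ADA", "factor", 1.59),
      cov_term("Q", "WT", "power", 1.15, 70),
      cov_term("V1", "WT", "power", 0.696, 70),
      cov_term("V2", "WT", "power", 0.604, 70)),
    random_effects = random_effects_spec(),
    residual = residual_error_spec("combined", 0.80, 0.22, "variance_additive"),
    eligibility = list(diseases = c("Crohn", "UC"), ada_free = FALSE,
                       adults_only = TRUE, max_time = Inf),
    reference_covariates = list(WT = 70, ALB = 40, ADA = 0))

  G <- poppk_model("G", "Fasanmade et al. 2011", 2L,
    typical_values = list(CL = 0.3523, V1 = 3.406, V2 = 1.274, Q = 0.1469),
    covariate_model = list(
      cov_term("CL", "WT", "power", -0.313, 65),
      cov_term("CL", "ALB", "power", -0.855, 41),
      cov_term("CL", "ADA", "ratio_power", 1.292),
      cov_term("CL", "IMM", "ratio_power", 0.863),
      cov_term("V1", "WT", "power", -0.233, 65),
      cov_term("V2", "WT", "power", -0.588, 65)),
    random_effects = random_effects_spec(iov_cl = 0.183),
    residual = residual_error_spec("combined", 0.371, 0.292, "variance_additive"),
    eligibility = list(diseases = "Crohn", ada_free = FALSE,
                       adults_only = FALSE, max_time = Inf),
    reference_covariates = list(WT = 65, ALB = 41, ADA = 0, IMM = 0))

  H <- poppk_model("H", "Wojciechowski et al. 2017 / Xu et al. 2012", 2L,
    typical_values = list(CL = 0.294, V1 = 3.33, V2 = 1.14, Q = 0.079),
    covariate_model = list(
      cov_term("CL", "WT", "power", 0.614, 70),
      cov_term("CL", "ALB", "power", -1.17, 30),
      cov_term("CL", "ADA", "exp_linear", 0.257),
      cov_term("Q", "WT", "power", 1.1, 70),
      cov_term("V1", "WT", "power", 0.691, 70),
      cov_term("V2", "WT", "power", 0.59, 70)),
    random_effects = random_effects_spec(),
    residual = residual_error_spec("proportional", 0, 0.175561, "variance_additive"),
    eligibility = list(diseases = c("Crohn", "UC", "RA"), ada_free = FALSE,
                       adults_only = FALSE, max_time = Inf),
    reference_covariates = list(WT = 70, ALB = 30, ADA = 0))

  list(A = A, B = B, C = C, D = D, E = E, F = F, G = G, H = H)
}

.registry_env <- new.env(parent = emptyenv())

registry <- function() {
  if (is.null(.registry_env$models)) .registry_env$models <- .build_registry()
  .registry_env$models
}

#' Retrieve a registered model
#'
#' @param model_id One of `"A"` to `"H"`.
#' @return A [poppk_model()].
#' @export
#' @examples
#' get_model("A")
get_model <- function(model_id) {
  m <- registry()[[as.character(model_id)]]
  if (is.null(m)) stop("unknown model id '", model_id, "'; registered: ",
                       paste(MODEL_IDS, collapse = ", "))
  m
}

#' List registered model ids
#' @return Character vector of model identifiers.
#' @export
list_models <- function() names(registry())

## ---- registry serialisation ----------------------------------------------

## Numbers are written as %.17g strings so the YAML round-trip is bit-exact.
.num_out <- function(x) sprintf("%.17g", x)

model_to_list <- function(m) {
  list(model_id = m$model_id, name = m$name,
       n_compartments = m$n_compartments,
       typical_values = lapply(m$typical_values, .num_out),
       covariate_model = lapply(m$covariate_model, function(tm)
         list(parameter = tm$parameter, covariate = tm$covariate,
              form = tm$form, coefficient = .num_out(tm$coefficient),
              center = .num_out(tm$center))),
       random_effects = list(
         omega = as.list(stats::setNames(.num_out(m$random_effects$omega),
                                         names(m$random_effects$omega))),
         iov_cl = .num_out(m$random_effects$iov_cl)),
       residual = list(kind = m$residual$kind,
                       sigma_add = .num_out(m$residual$sigma_add),
                       sigma_prop = .num_out(m$residual$sigma_prop),
                       convention = m$residual$convention),
       eligibility = list(diseases = as.list(m$eligibility$diseases),
                          ada_free = isTRUE(m$eligibility$ada_free),
                          adults_only = isTRUE(m$eligibility$adults_only),
                          max_time = .num_out(m$eligibility$max_time)),
       sex_coding = m$sex_coding,
       reference_covariates = m$reference_covariates)
}

model_from_list <- function(x) {
  res <- x$residual
  spec <- if (res$kind == "additive") {
    residual_error_spec("additive", as.numeric(res$sigma_add), 0, res$convention)
  } else if (res$kind == "proportional") {
    residual_error_spec("proportional", 0, as.numeric(res$sigma_prop), res$convention)
  } else {
    residual_error_spec("combined", as.numeric(res$sigma_add),
                        as.numeric(res$sigma_prop), res$convention)
  }
  poppk_model(
    model_id = x$model_id, name = x$name,
    n_compartments = as.integer(x$n_compartments),
    typical_values = lapply(x$typical_values, as.numeric),
    covariate_model = lapply(x$covariate_model, function(tm)
      cov_term(tm$parameter, tm$covariate, tm$form,
               as.numeric(tm$coefficient), as.numeric(tm$center))),
    random_effects = random_effects_spec(
      omega = vapply(x$random_effects$omega, as.numeric, numeric(1)),
      iov_cl = as.numeric(x$random_effects$iov_cl)),
    residual = spec,
    eligibility = list(diseases = unlist(x$eligibility$diseases),
                       ada_free = x$eligibility$ada_free,
                       adults_only = x$eligibility$adults_only,
                       max_time = as.numeric(x$eligibility$max_time)),
    sex_coding = x$sex_coding,
    reference_covariates = x$reference_covariates)
}

#' Write / read the model registry as a YAML config
#'
#' One document entry per model; numeric values are serialised at full double
#' precision so that a write/read cycle reproduces every coefficient exactly.
#'
#' @param models List of [poppk_model()] objects (default: the full registry).
#' @param path File path.
#' @return `read_model_registry` returns a named list of `poppk_model`s.
#' @export
write_model_registry <- function(path, models = registry()) {
  yaml::write_yaml(lapply(models, model_to_list), path)
  invisible(path)
}

#' @rdname write_model_registry
#' @export
read_model_registry <- function(path) {
  lapply(yaml::read_yaml(path), model_from_list)
}
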