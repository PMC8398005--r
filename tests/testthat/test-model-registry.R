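test_that("registered covariate models reproduce published typical values at reference covariates", {
  expected <- list(
    A = c(CL = 0.23, V1 = 5.2),
    B = c(CL = 0.24, V1 = 5.3),
    C = c(CL = 0.20, V1 = 5.3),
    D = c(CL = 0.336, V1 = 2.6, V2 = 4.5, Q = 1.992),
    E = c(CL = 0.199, V1 = 4.94, V2 = 3.13, Q = 0.068),
    F = c(CL = 0.381, V1 = 2.37, V2 = 1.37, Q = 0.122),
    G = c(CL = 0.3523, V1 = 3.406, V2 = 1.274, Q = 0.1469),
    H = c(CL = 0.294, V1 = 3.33, V2 = 1.14, Q = 0.079))
  for (id in names(expected)) {
    m <- get_model(id)
    p <- typical_parameters(m, m$reference_covariates)
    expect_equal(unlist(p)[names(expected[[id]])], expected[[id]],
                 tolerance = 1e-15, label = paste("model", id))
  }
})

test_that("model metadata matches the published specifications", {
  f <- get_model("F")
  expect_equal(f$residual$kind, "combined")
  expect_equal(f$residual$sigma_add, 0.80)
  expect_equal(f$residual$sigma_prop, 0.22)
  h <- get_model("H")
  expect_equal(h$residual$kind, "proportional")
  expect_equal(h$residual$sigma_prop, 0.175561)
  expect_equal(get_model("G")$random_effects$iov_cl, 0.183)
  expect_equal(get_model("A")$residual$convention, "sd_additive")
  expect_equal(get_model("E")$residual$convention, "variance_additive")
  expect_error(get_model("Z"), "unknown model id")
})

test_that("covariate equations apply multiplicative factors as printed", {
  f <- get_model("F")
  p <- typical_parameters(f, list(WT = 70, ALB = 40, ADA = 1))
  expect_equal(p$CL, 0.381 * (1 + 1.59), tolerance = 1e-12)   # 0.98679

  ## weight at its centering value leaves the weight factor at 1
  a <- get_model("A")
  ref <- a$reference_covariates
  p_ref <- typical_parameters(a, ref)
  ref$DISEASE <- "PsA"   # PsA has no disease term in model A
  expect_equal(typical_parameters(a, ref)$CL, p_ref$CL)

  ## male sex multiplies model A clearance by e^0.181
  ref <- a$reference_covariates; ref$SEX <- "male"
  expect_equal(typical_parameters(a, ref)$CL, 0.23 * exp(0.181),
               tolerance = 1e-12)

  ## model E codes sex the other way round: female carries the 1.345 factor
  e <- get_model("E")
  pf <- typical_parameters(e, list(SEX = "female", ADA = 0,
                                   PERIOD = "maintenance", HBI = 6))
  expect_equal(pf$CL, 0.199 * 1.345, tolerance = 1e-12)
})

test_that("missing required covariates raise errors naming them", {
  expect_error(typical_parameters(get_model("A"), list(SEX = "female")),
               "'WT'")
  expect_error(typical_parameters(get_model("G"),
                                  list(WT = 65, ADA = 0, IMM = 0)),
               "'ALB'")
})

test_that("parameters stay positive over random valid covariate records", {
  set.seed(42)
  for (i in 1:40) {
    cov <- list(WT = runif(1, 24, 150), SEX = sample(c("female", "male"), 1),
                AGE = runif(1, 8, 85),
                DISEASE = sample(c("Crohn", "UC", "AS", "PsA", "RA"), 1),
                MTX = rbinom(1, 1, 0.3), IMM = rbinom(1, 1, 0.4),
                ADA = rbinom(1, 1, 0.1), ALB = runif(1, 25, 55),
                HBI = rpois(1, 5), PERIOD = sample(c("induction", "maintenance"), 1))
    for (id in list_models()) {
      p <- typical_parameters(get_model(id), cov)
      expect_true(all(unlist(p) > 0), label = paste("model", id, "draw", i))
    }
  }
})

test_that("strip_covariates pins every factor at reference and is idempotent", {
  g <- get_model("G")
  sg <- strip_covariates(g)
  cov_pos <- list(WT = 100, ALB = 30, ADA = 1, IMM = 1)
  cov_neg <- list(WT = 50, ALB = 50, ADA = 0, IMM = 0)
  expect_equal(typical_parameters(sg, cov_pos), typical_parameters(sg, cov_neg))
  expect_equal(unclass(typical_parameters(sg, cov_pos)), g$typical_values)
  expect_identical(strip_covariates(sg), sg)
  ## full and stripped agree at the reference covariates
  expect_equal(typical_parameters(g, g$reference_covariates),
               typical_parameters(sg, g$reference_covariates))
})

test_that("subpopulation filter enforces construction-population rules", {
  base <- make_subject(id = "S1", trough_at = c(2, 4))
  ada_pos <- make_subject(id = "S2", cov = cov_record(ADA = 1))
  late_only <- make_subject(id = "S3", n_inf = 10, trough_at = c(8, 10))
  child <- make_subject(id = "S4", cov = cov_record(AGE = 10))
  as_pat <- make_subject(id = "S5", cov = cov_record(DISEASE = "AS"))
  cohort <- ifx_cohort(list(base, ada_pos, late_only, child, as_pat))

  ids <- function(x) vapply(unclass(x), function(s) s$subject_id, "")

  ## A: any disease, but no ADA detected
  expect_equal(ids(subpopulation_filter(get_model("A"), cohort)),
               c("S1", "S3", "S4", "S5"))
  ## D: Crohn, ADA-free, observations within the first six months only
  d_sub <- subpopulation_filter(get_model("D"), cohort)
  expect_equal(ids(d_sub), c("S1", "S4"))
  expect_true(all(vapply(unclass(d_sub),
                         function(s) all(s$observations$time <= 183), TRUE)))
  ## F: Crohn/UC adults (ADA allowed)
  expect_equal(ids(subpopulation_filter(get_model("F"), cohort)),
               c("S1", "S2", "S3"))
  ## G: Crohn only
  expect_false("S5" %in% ids(subpopulation_filter(get_model("G"), cohort)))
  ## empty in, empty out
  expect_length(subpopulation_filter(get_model("A"), ifx_cohort(list())), 0)
})

test_that("registry YAML round-trip is bit-exact", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_registry(path)
  back <- read_model_registry(path)
  expect_identical(names(back), list_models())
  for (id in list_models())
    expect_equal(back[[id]], get_model(id), tolerance = 0)
})
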