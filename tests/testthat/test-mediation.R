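# cross-sectional cohort with a single planted mediator used in several
# tests; three groups so that birth mode and antibiotic class are separately
# identifiable
mediation_sim <- function(seed, r2 = 0.3, lfc = -1.5, direct = 0.3) {
  sim_config(
    n_infants_per_group = c(VD = 30, "VD-cep" = 15, "CS-cep" = 15),
    timepoints = 6, seed = seed,
    group_effects = if (lfc != 0)
      data.frame(taxon = "Bacteroides", group = c("VD-cep", "CS-cep"),
                 week_min = 1, week_max = 12, lfc = lfc) else NULL,
    mediation_spec = list(list(
      outcome = "symptom", family = "gaussian", intercept = 10,
      exposure_var = "abx_class", exposure_level = "cephalosporin",
      direct = direct,
      mediators = data.frame(taxon = "Bacteroides", beta = sqrt(r2)),
      sigma = sqrt(1 - r2), max_week = 52)),
    contaminant_taxa = c())
}

test_that("variance explained is invariant to affine rescaling of the outcome", {
  sim <- simulate_cohort(mediation_sim(41))
  prof <- absolute_profile(sim$counts, sim$qpcr, sim$copy_numbers)
  ab <- profile_matrix(prof, "absolute")
  y <- sim$wellbeing$symptom   # questionnaire rows align with sample rows
  m1 <- select_mediator_taxa(y, ab)
  m2 <- select_mediator_taxa(3 + 7 * y, ab)
  expect_equal(m1$selected, m2$selected)
  expect_equal(m1$variance_explained, m2$variance_explained,
               tolerance = 1e-10)
})

test_that("an outcome exactly linear in one taxon gives variance explained near one", {
  sim <- simulate_cohort(mediation_sim(42))
  prof <- absolute_profile(sim$counts, sim$qpcr, sim$copy_numbers)
  ab <- profile_matrix(prof, "absolute")
  y <- 2 + 5 * log10(ab[, "Bacteroides"] + 1)
  m <- suppressWarnings(select_mediator_taxa(y, ab))
  expect_true("Bacteroides" %in% m$selected)
  expect_gt(m$variance_explained, 0.999)
})

test_that("no candidates means an empty mediator set with zero variance explained", {
  set.seed(43)
  ab <- matrix(0, 30, 4, dimnames = list(paste0("s", 1:30), paste0("t", 1:4)))
  m <- select_mediator_taxa(rnorm(30), ab)
  expect_length(m$selected, 0)
  expect_equal(m$variance_explained, 0)
})

test_that("stepwise selection is deterministic and capped at n/10 terms", {
  set.seed(44)
  ab <- matrix(10^rnorm(60 * 20, 5), 60, 20,
               dimnames = list(paste0("s", 1:60), paste0("t", 1:20)))
  y <- rnorm(60)
  m1 <- select_mediator_taxa(y, ab)
  m2 <- select_mediator_taxa(y, ab)
  expect_identical(m1$selected, m2$selected)
  expect_lte(length(m1$selected), 6)
})

test_that("pure-noise candidates keep the selected model's variance explained modest", {
  set.seed(45)
  ve <- replicate(15, {
    ab <- matrix(10^rnorm(60 * 50, 5), 60, 50,
                 dimnames = list(paste0("s", 1:60), paste0("t", 1:50)))
    select_mediator_taxa(rnorm(60), ab)$variance_explained
  })
  expect_lte(median(ve), 0.15)
})

test_that("exposure models flag planted effects and reject constant outcomes", {
  sim <- simulate_cohort(mediation_sim(46))
  linked <- link_wellbeing(sim$metadata, sim$wellbeing)
  linked$const <- 1
  expect_error(outcome_exposure_model("const", linked, 6), "constant")
  # defecation-style NB outcome with planted birth-mode effect
  cfg <- sim_config(
    n_infants_per_group = c(VD = 30, "VD-cep" = 15, "CS-cep" = 15),
    timepoints = 6, seed = 47, group_effects = NULL,
    mediation_spec = list(list(
      outcome = "defecation_rate", family = "nb", intercept = log(4),
      exposure_var = "abx_class", exposure_level = "cephalosporin",
      direct = 0.5, mediators = data.frame(taxon = character(0),
                                           beta = numeric(0)),
      size = 8, max_week = 52)))
  sim2 <- simulate_cohort(cfg)
  linked2 <- link_wellbeing(sim2$metadata, sim2$wellbeing)
  em <- outcome_exposure_model("defecation_rate", linked2, 6)
  expect_true(em$family %in% c("negbin", "poisson"))
  expect_lt(em$terms$p[em$terms$term == "abx_class"], 0.05)
})

test_that("a planted chain is recovered and labelled mediated; a direct-only effect is not", {
  sim <- simulate_cohort(mediation_sim(48, r2 = 0.4, lfc = -2, direct = 0.1))
  prof <- absolute_profile(sim$counts, sim$qpcr, sim$copy_numbers)
  pm <- path_model(prof, sim$metadata, sim$wellbeing, "symptom", 6,
                   covariates = character(0))
  expect_true("Bacteroides" %in% pm$mediators$taxon)
  expect_true("Bacteroides" %in% pm$edges$taxon)
  expect_gt(pm$variance_explained, 0.1)
  # marginal antibiotic effect present, attenuated by the mediator
  expect_true(pm$exposure_terms$mediated[
    pm$exposure_terms$term == "abx_class"])
  # direct-only scenario: exposure moves the outcome but no taxon does
  simd <- simulate_cohort(mediation_sim(49, r2 = 0, lfc = 0, direct = 1.5))
  profd <- absolute_profile(simd$counts, simd$qpcr, simd$copy_numbers)
  pmd <- path_model(profd, simd$metadata, simd$wellbeing, "symptom", 6,
                    covariates = character(0))
  et <- pmd$exposure_terms
  expect_lt(et$p[et$term == "abx_class"], 0.05)     # marginal effect present
  expect_false(any(et$mediated))                    # but nothing mediates it
  # empty mediator set implies an empty edge list
  ed <- exposure_taxon_links(character(0), profile_matrix(profd, "absolute"),
                             simd$metadata, 6)
  expect_equal(nrow(ed), 0)
})
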