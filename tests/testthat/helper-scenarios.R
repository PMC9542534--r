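# Scenario constructors for the validation studies (also mirrored by
# scripts/acceptance.R). All sizes and effect magnitudes are study conditions,
# fixed here and documented in the methods vignette.

# single planted log fold change, two groups of 25 infants, one timepoint
scenario_power <- function(seed, lfc = -1.5) {
  sim_config(
    n_infants_per_group = c(VD = 25, "CS-cep" = 25), timepoints = 4,
    seed = seed,
    group_effects = data.frame(taxon = "Bifidobacterium", group = "CS-cep",
                               week_min = 1, week_max = 12, lfc = lfc),
    mediation_spec = list(), contaminant_taxa = c())
}

# global null with 500 taxa, 15 infants per group, one timepoint
scenario_null <- function(seed) {
  sim_config(
    n_infants_per_group = c(VD = 15, "CS-cep" = 15), timepoints = 4,
    n_taxa = 500, seed = seed, group_effects = NULL,
    mediation_spec = list(), contaminant_taxa = c())
}

# exposure -> taxon -> outcome chain at n = 60 with total planted R^2 = 0.3.
# The antibiotic exposure shifts the mediator by lfc, which inflates the
# mediator's outcome-relevant variance beyond 1; beta is scaled so that the
# taxon term explains exactly r2 of the outcome variance.
scenario_mediation <- function(seed, r2 = 0.3, lfc = -1.5, direct = 0.3,
                               null = FALSE) {
  zsd <- sqrt(0.8^2 + 0.7^2)
  p_exposed <- 0.5   # VD-cep + CS-cep infants among 60
  vz <- 1 + p_exposed * (1 - p_exposed) * (lfc / zsd)^2
  beta <- sqrt(r2 / vz)
  sim_config(
    n_infants_per_group = c(VD = 30, "VD-cep" = 15, "CS-cep" = 15),
    timepoints = 6, seed = seed,
    group_effects = if (!null)
      data.frame(taxon = "Bacteroides", group = c("VD-cep", "CS-cep"),
                 week_min = 1, week_max = 12, lfc = lfc) else NULL,
    mediation_spec = list(list(
      outcome = "symptom", family = "gaussian", intercept = 10,
      exposure_var = "abx_class", exposure_level = "cephalosporin",
      direct = if (null) 0 else direct,
      mediators = if (null)
        data.frame(taxon = character(0), beta = numeric(0))
      else data.frame(taxon = "Bacteroides", beta = beta),
      sigma = sqrt(1 - r2), max_week = 52)),
    contaminant_taxa = c())
}

# matched-load compositional masking: ten taxa dominating ~80% of the
# community increase 5-fold in absolute abundance in the exposed group
masking_taxa <- c("Streptococcus", "Veillonella", "Clostridium", "Blautia",
                  "Faecalibacterium", "Enterococcus", "Lactobacillus",
                  "Staphylococcus", "Klebsiella", "Escherichia")

scenario_masking <- function(seed) {
  sim_config(
    n_infants_per_group = c(VD = 25, "CS-cep" = 25), timepoints = 4,
    seed = seed,
    group_effects = data.frame(taxon = masking_taxa, group = "CS-cep",
                               week_min = 1, week_max = 12, lfc = 1.6),
    base_logw = setNames(rep(2, length(masking_taxa)), masking_taxa),
    mediation_spec = list(), contaminant_taxa = c())
}

# standard processing: counts -> absolute profile
profile_of <- function(sim) {
  absolute_profile(sim$counts, sim$qpcr, sim$copy_numbers)
}

# brute-force Benjamini-Hochberg step-up, the independent oracle
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- pmin(1, rev(cummin(rev(q))))
  out <- numeric(m)
  out[o] <- q
  out
}
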