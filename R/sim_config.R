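#' Configuration of the longitudinal infant-cohort simulator
#'
#' Collects every tunable of the synthetic cohort: group sizes over the five
#' birth-mode x intrapartum-antibiotic study groups, sampling schedule,
#' taxonomy, sequencing-depth model, age-increasing total-load curve,
#' planted group effects on absolute abundances, contaminant taxa seeded into
#' blank controls, 16S copy numbers, and the exposure-taxon-symptom mediation
#' structure of the simulated well-being outcomes.
#'
#' Default group sizes mirror the qPCR-quantified subset of the worked-example
#' cohort (26 / 7 / 13 / 33 / 13 infants), so printed-count checks double as
#' fixture checks. The default load curve grows from 1e9 to 4e10 16S copies/g
#' over the first year, emulating the age-driven increase of total bacterial
#' load in infancy.
#'
#' @param n_infants_per_group named integer vector over
#'   \code{c("VD","VD-cep","VD-pen","CS-cep","CS-other")}; zeros allowed.
#' @param timepoints ordered ages in weeks.
#' @param n_taxa number of taxa (taxonomy rows beyond the built-in table are
#'   synthesised).
#' @param seed integer seed; identical config + seed gives bit-identical output.
#' @param depth_mean,depth_dispersion negative-binomial sequencing-depth model
#'   (mean reads and size parameter).
#' @param load_curve per-timepoint geometric-mean total load, 16S copies/g.
#' @param group_effects data.frame(taxon, group, week_min, week_max, lfc):
#'   natural-log fold changes on the absolute (cells/g) scale relative to the
#'   unexposed VD reference, active in the given age window.
#' @param contaminant_taxa named numeric vector of mean blank read counts for
#'   reagent-contaminant taxa (must be taxa of the taxonomy).
#' @param copy_numbers rrnDB-style data.frame(name, rank, mean16S).
#' @param mediation_spec list of outcome specifications; see
#'   \code{default_mediation_spec()}.
#' @param infant_sd infant-level random-intercept SD on the natural-log
#'   abundance scale (repeated-measures correlation; free choice, default 0.8).
#' @param resid_sd residual SD of log abundances (overdispersion), default 0.7.
#' @param qpcr_cv coefficient of variation of the multiplicative log-normal
#'   qPCR measurement noise (triplicate qPCR; default 15\%).
#' @param base_logw optional named numeric overriding baseline log community
#'   weights of the taxonomy.
#' @param n_runs,blanks_per_run sequencing runs and extraction/PCR blanks per
#'   run.
#' @param prop_helmi probability an infant belongs to the deeply sequenced
#'   cohort (\code{"HELMi"}) rather than the low-biomass one (\code{"Jorvi"}).
#' @param discordant_taxon internal; set via
#'   \code{\link{simulate_discordant_taxon}}.
#' @return object of class \code{qmp_sim_config}.
#' @export
sim_config <- function(n_infants_per_group = c("VD" = 26, "VD-cep" = 7,
                                               "VD-pen" = 13, "CS-cep" = 33,
                                               "CS-other" = 13),
                       timepoints = c(1, 4, 6, 12, 26, 39, 52),
                       n_taxa = 34,
                       seed = 1,
                       depth_mean = 26000,
                       depth_dispersion = 5,
                       load_curve = NULL,
                       group_effects = default_group_effects(),
                       contaminant_taxa = c(Achromobacter = 60, Ralstonia = 25),
                       copy_numbers = default_copy_numbers(),
                       mediation_spec = default_mediation_spec(),
                       infant_sd = 0.8,
                       resid_sd = 0.7,
                       qpcr_cv = 0.15,
                       base_logw = NULL,
                       n_runs = 3,
                       blanks_per_run = 2,
                       prop_helmi = 0.6,
                       discordant_taxon = NULL) {
  groups <- c("VD", "VD-cep", "VD-pen", "CS-cep", "CS-other")
  if (!all(names(n_infants_per_group) %in% groups) ||
      is.null(names(n_infants_per_group)))
    stop("configuration error: group labels must be drawn from ",
         paste(groups, collapse = ", "))
  full <- setNames(integer(5), groups)
  full[names(n_infants_per_group)] <- as.integer(n_infants_per_group)
  if (any(full < 0) || sum(full) == 0)
    stop("configuration error: group sizes must be non-negative, not all zero")
  timepoints <- sort(unique(as.numeric(timepoints)))
  taxonomy <- default_taxonomy(n_taxa)
  if (!is.null(base_logw)) {
    if (!all(names(base_logw) %in% taxonomy$taxon))
      stop("configuration error: base_logw names outside the taxon set")
    taxonomy$base_logw[match(names(base_logw), taxonomy$taxon)] <- base_logw
  }
  if (is.null(load_curve)) {
    # geometric interpolation 1e9 -> 4e10 over the first year
    load_curve <- 10^stats::approx(c(1, 52), c(9, 10.6), xout = timepoints,
                                   rule = 2)$y
  }
  load_curve <- setNames(rep_len(as.numeric(load_curve), length(timepoints)),
                         as.character(timepoints))
  if (any(!is.finite(load_curve)) || any(load_curve <= 0))
    stop("configuration error: load curve must be positive and finite")
  # built-in defaults adapt silently to a truncated taxonomy;
  # user-supplied maps with unknown taxa are configuration errors
  if (missing(group_effects) && !is.null(group_effects))
    group_effects <- group_effects[group_effects$taxon %in% taxonomy$taxon, ,
                                   drop = FALSE]
  if (missing(contaminant_taxa))
    contaminant_taxa <- contaminant_taxa[names(contaminant_taxa) %in%
                                           taxonomy$taxon]
  if (missing(mediation_spec))
    mediation_spec <- Filter(function(m)
      all(m$mediators$taxon %in% taxonomy$taxon), mediation_spec)
  if (!is.null(group_effects) && nrow(group_effects)) {
    need <- c("taxon", "group", "week_min", "week_max", "lfc")
    if (!all(need %in% names(group_effects)))
      stop("configuration error: group_effects needs columns ",
           paste(need, collapse = ", "))
    if (!all(group_effects$taxon %in% taxonomy$taxon))
      stop("configuration error: group_effects taxa outside the taxon set")
    if (!all(group_effects$group %in% groups))
      stop("configuration error: group_effects groups outside the group set")
    if (any(!is.finite(group_effects$lfc)))
      stop("configuration error: effect sizes must be finite")
  }
  if (length(contaminant_taxa)) {
    if (!all(names(contaminant_taxa) %in% taxonomy$taxon))
      stop("configuration error: contaminant taxa outside the taxon set")
    if (any(contaminant_taxa < 0))
      stop("configuration error: blank-count means must be non-negative")
  }
  if (any(copy_numbers$mean16S < 1))
    stop("configuration error: copy numbers must be >= 1")
  for (m in mediation_spec) {
    if (!all(m$mediators$taxon %in% taxonomy$taxon))
      stop("configuration error: mediator taxa outside the taxon set")
    if (any(!is.finite(m$mediators$beta)) || !is.finite(m$direct))
      stop("configuration error: effect sizes must be finite")
  }
  if (depth_mean < 1 || depth_dispersion <= 0)
    stop("configuration error: depths must be >= 1")
  if (!is.null(discordant_taxon) &&
      !discordant_taxon %in% taxonomy$taxon)
    stop("discordant taxon not present in the taxon set")
  structure(list(
    n_infants_per_group = full, timepoints = timepoints, n_taxa = n_taxa,
    taxonomy = taxonomy, seed = as.integer(seed), depth_mean = depth_mean,
    depth_dispersion = depth_dispersion, load_curve = load_curve,
    group_effects = group_effects, contaminant_taxa = contaminant_taxa,
    copy_numbers = copy_numbers, mediation_spec = mediation_spec,
    infant_sd = infant_sd, resid_sd = resid_sd, qpcr_cv = qpcr_cv,
    n_runs = n_runs, blanks_per_run = blanks_per_run,
    prop_helmi = prop_helmi, discordant_taxon = discordant_taxon),
    class = "qmp_sim_config")
}

#' Default planted group effects of the cohort simulator
#'
#' Natural-log fold changes on absolute abundance emulating the canonical
#' early-life exposure signature: Bacteroides and relatives depleted
#' specifically in cesarean birth, bifidobacteria depleted by both cesarean
#' birth and intrapartum antibiotics in vaginal delivery, and Bacilli
#' (staphylococci, enterococci, lactobacilli, streptococci) increased in all
#' exposure groups during the first three months.
#'
#' @return data.frame(taxon, group, week_min, week_max, lfc).
#' @export
default_group_effects <- function() {
  exposed <- c("VD-cep", "VD-pen", "CS-cep", "CS-other")
  cs <- c("CS-cep", "CS-other")
  eff <- function(taxa, groups, wmin, wmax, lfc)
    expand.grid(taxon = taxa, group = groups, week_min = wmin, week_max = wmax,
                lfc = lfc, stringsAsFactors = FALSE)
  out <- rbind(
    eff("Bacteroides", cs, 1, 12, -3.0),
    eff("Parabacteroides", cs, 1, 12, -2.0),
    eff("Collinsella", cs, 1, 12, -2.0),
    eff("Bifidobacterium", exposed, 1, 6, -2.5),
    eff(c("Staphylococcus", "Enterococcus", "Lactobacillus", "Streptococcus"),
        exposed, 1, 12, 1.5),
    eff(c("Actinomyces", "Rothia"), c("VD-cep", "CS-cep", "CS-other"),
        1, 6, 2.0),
    eff("Escherichia", exposed, 4, 12, 1.0)
  )
  rownames(out) <- NULL
  out
}

#' Default mediation structure of the simulated well-being outcomes
#'
#' Each entry plants one exposure-to-outcome path partially mediated by
#' taxon abundances: the outcome is generated from a log-link (or logit-link)
#' linear predictor combining standardized log mediator abundances and a
#' direct exposure term. Crying intensity is a 0-100 visual-analogue score
#' simulated as a scaled beta-binomial; defecation rate and the symptom
#' intensities are negative-binomial counts, matching the outcome model
#' families used downstream.
#'
#' @return list of mediation specifications.
#' @export
default_mediation_spec <- function() {
  med <- function(taxon, beta) data.frame(taxon = taxon, beta = beta,
                                          stringsAsFactors = FALSE)
  list(
    list(outcome = "crying_vas", family = "vas", intercept = stats::qlogis(0.30),
         exposure_var = "abx_class", exposure_level = "cephalosporin",
         direct = 0.30, mediators = med("Bacteroides", -0.35), phi = 8,
         max_week = 26),
    list(outcome = "defecation_rate", family = "nb", intercept = log(4),
         exposure_var = "birth_mode", exposure_level = "CS",
         direct = 0.15, mediators = med(c("Bacteroides", "Veillonella"),
                                        c(-0.15, -0.10)), size = 8,
         max_week = 39),
    list(outcome = "stomach_pain", family = "nb", intercept = log(3),
         exposure_var = "abx_class", exposure_level = "cephalosporin",
         direct = 0.20, mediators = med(c("Collinsella", "Escherichia",
                                          "Streptococcus"),
                                        c(-0.15, 0.15, 0.10)), size = 6,
         max_week = 39),
    list(outcome = "flatulence", family = "nb", intercept = log(3),
         exposure_var = "birth_mode", exposure_level = "CS",
         direct = 0.15, mediators = med(c("Bacteroides", "Alistipes"),
                                        c(-0.10, -0.10)), size = 6,
         max_week = 39)
  )
}
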