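#' Simulate a longitudinal infant cohort with planted ground truth
#'
#' Generates a full synthetic dataset with the statistical structure the
#' downstream analysis assumes: five birth-mode x intrapartum-antibiotic
#' study groups, per-taxon log-normal absolute abundances with infant-level
#' random intercepts, an age-increasing total bacterial load, negative
#' binomial sequencing depths with multinomial read sampling of
#' copy-number-inflated relative abundances, reagent contaminants shared
#' between samples and blank controls, log-normal qPCR measurement noise,
#' and parent-reported well-being outcomes generated from planted
#' exposure-taxon-symptom mediation paths. All latent quantities are
#' returned as ground truth.
#'
#' @param config a \code{\link{sim_config}} object.
#' @return object of class \code{qmp_sim}: a list with elements
#'   \code{counts} (a \code{\link{count_table}} of samples),
#'   \code{blanks} (a \code{count_table} of blank controls),
#'   \code{qpcr} (data.frame sample_id, copies_per_g),
#'   \code{copy_numbers}, \code{metadata}, \code{wellbeing},
#'   \code{truth} (true cells/g and copies/g matrices, true pre-noise loads,
#'   planted group effects, mediation structure and linear predictors), and
#'   the \code{config}.
#' @export
simulate_cohort <- function(config = sim_config()) {
  if (!inherits(config, "qmp_sim_config"))
    stop("config must be built with sim_config()")
  set.seed(config$seed)
  taxa <- config$taxonomy$taxon
  n_taxa <- length(taxa)
  tps <- config$timepoints
  groups <- names(config$n_infants_per_group)

  ## ---- infants -----------------------------------------------------------
  inf <- do.call(rbind, lapply(groups, function(g) {
    n <- config$n_infants_per_group[[g]]
    if (n == 0) return(NULL)
    data.frame(group = g, idx = seq_len(n), stringsAsFactors = FALSE)
  }))
  inf$infant_id <- sprintf("%s_%02d", gsub("-", "", inf$group), inf$idx)
  inf$birth_mode <- ifelse(startsWith(inf$group, "CS"),
                           ifelse(inf$idx %% 2 == 0, "elective CS",
                                  "emergency CS"), "VD")
  inf$antibiotic <- c("VD" = "none", "VD-cep" = "cefuroxime",
                      "VD-pen" = "penicillin", "CS-cep" = "cefuroxime",
                      "CS-other" = "clindamycin")[inf$group]
  inf$antibiotic[inf$group == "CS-cep" & inf$idx %% 3 == 0] <- "cephalexin"
  inf$antibiotic[inf$group == "CS-other" & inf$idx %% 2 == 0] <- "combination"
  inf$abx_class <- c("none" = "none", "penicillin" = "penicillin",
                     "cefuroxime" = "cephalosporin",
                     "cephalexin" = "cephalosporin",
                     "clindamycin" = "other", "combination" = "other")[
                       inf$antibiotic]
  inf$cohort <- ifelse(stats::runif(nrow(inf)) < config$prop_helmi,
                       "HELMi", "Jorvi")
  inf$probiotics <- sample(c("none", "Lactobacillus", "Bifidobacterium",
                             "both", "Saccharomyces"), nrow(inf),
                           replace = TRUE,
                           prob = c(.5, .2, .15, .1, .05))
  inf$solids_intro <- pmax(12, round(stats::rnorm(nrow(inf), 20, 2)))

  ## ---- samples -----------------------------------------------------------
  meta <- merge(inf, data.frame(age_weeks = tps), by = NULL)
  meta <- meta[order(meta$infant_id, meta$age_weeks), ]
  meta$sample_id <- sprintf("%s_w%02d", meta$infant_id, meta$age_weeks)
  meta$run <- sprintf("run%d", sample.int(config$n_runs, nrow(meta),
                                          replace = TRUE))
  meta$protocol_modified <- stats::runif(nrow(meta)) < 0.10
  meta$breastfeeding <- vapply(meta$age_weeks, function(a) {
    p <- if (a <= 6) c(.70, .25, .05) else if (a <= 26) c(.40, .40, .20)
         else c(.05, .45, .50)
    sample(c("exclusive", "partial", "none"), 1, prob = p)
  }, character(1))
  meta$weeks_since_solids <- pmax(0, meta$age_weeks - meta$solids_intro)
  n_samp <- nrow(meta)

  ## ---- true abundances ---------------------------------------------------
  cn <- resolve_copy_numbers(config$taxonomy, config$copy_numbers)$copy_number
  sd_tot2 <- config$infant_sd^2 + config$resid_sd^2
  # per-timepoint community shares (copies scale)
  share <- vapply(seq_along(tps), function(j) {
    w <- config$taxonomy$base_logw + config$taxonomy$trend * (j - 1)
    exp(w) / sum(exp(w))
  }, numeric(n_taxa))           # taxa x timepoints
  tp_idx <- match(meta$age_weeks, tps)
  # expected log copies: load share, variance-corrected so E[sum copies]=load
  mu <- t(vapply(seq_len(n_samp), function(s) {
    j <- tp_idx[s]
    log(config$load_curve[j] * share[, j]) - sd_tot2 / 2
  }, numeric(n_taxa)))          # samples x taxa
  dimnames(mu) <- list(meta$sample_id, taxa)
  # planted group effects (natural-log fold changes on the absolute scale)
  ge <- config$group_effects
  if (!is.null(ge) && nrow(ge)) {
    for (k in seq_len(nrow(ge))) {
      sel <- meta$group == ge$group[k] & meta$age_weeks >= ge$week_min[k] &
        meta$age_weeks <= ge$week_max[k]
      mu[sel, ge$taxon[k]] <- mu[sel, ge$taxon[k]] + ge$lfc[k]
    }
  }
  # discordant taxon: expectation pinned near its first-timepoint level with
  # a mild increase while the community load keeps growing
  if (!is.null(config$discordant_taxon)) {
    dt <- config$discordant_taxon
    base <- log(config$load_curve[1] * share[match(dt, taxa), 1]) - sd_tot2 / 2
    mu[, dt] <- base + 0.10 * (tp_idx - 1)
  }
  b <- matrix(stats::rnorm(nrow(inf) * n_taxa, 0, config$infant_sd),
              nrow(inf), n_taxa, dimnames = list(inf$infant_id, taxa))
  eps <- matrix(stats::rnorm(n_samp * n_taxa, 0, config$resid_sd),
                n_samp, n_taxa)
  log_copies <- mu + b[meta$infant_id, , drop = FALSE] + eps
  true_copies <- exp(log_copies)
  true_cells <- sweep(true_copies, 2, cn, "/")
  true_load <- rowSums(true_copies)

  ## ---- qPCR and sequencing ----------------------------------------------
  sdlog <- sqrt(log(1 + config$qpcr_cv^2))
  qpcr <- data.frame(sample_id = meta$sample_id,
                     copies_per_g = true_load *
                       exp(stats::rnorm(n_samp, 0, sdlog)),
                     stringsAsFactors = FALSE)
  depth <- pmax(1L, stats::rnbinom(n_samp, mu = config$depth_mean,
                                   size = config$depth_dispersion))
  counts <- t(vapply(seq_len(n_samp), function(s)
    stats::rmultinom(1, depth[s], prob = true_copies[s, ])[, 1],
    integer(n_taxa)))
  dimnames(counts) <- list(meta$sample_id, taxa)

  ## ---- contaminants and blanks ------------------------------------------
  ct <- config$contaminant_taxa
  if (length(ct)) {
    for (tx in names(ct))
      counts[, tx] <- counts[, tx] + stats::rpois(n_samp, ct[[tx]])
  }
  blank_ids <- as.vector(outer(seq_len(config$blanks_per_run),
                               seq_len(config$n_runs),
                               function(b, r) sprintf("blank_run%d_%d", r, b)))
  blanks <- matrix(0L, length(blank_ids), n_taxa,
                   dimnames = list(blank_ids, taxa))
  for (tx in names(ct))
    blanks[, tx] <- stats::rpois(length(blank_ids), ct[[tx]])
  blank_meta <- data.frame(
    sample_id = blank_ids,
    run = rep(sprintf("run%d", seq_len(config$n_runs)),
              each = config$blanks_per_run),
    cohort = "HELMi", stringsAsFactors = FALSE)

  ## ---- well-being outcomes ----------------------------------------------
  zsd <- sqrt(sd_tot2)
  wb <- data.frame(infant_id = meta$infant_id, age_weeks = meta$age_weeks,
                   stringsAsFactors = FALSE)
  eta_store <- list()
  for (m in config$mediation_spec) {
    # standardized log abundance relative to the reference-group expectation,
    # so planted group effects on the mediator propagate into the outcome
    zm <- vapply(seq_len(nrow(m$mediators)), function(k) {
      tx <- m$mediators$taxon[k]
      (log(true_copies[, tx]) -
         mu_reference(config, tx, tp_idx, share, taxa, sd_tot2)) / zsd
    }, numeric(n_samp))
    eta <- m$intercept + as.vector(zm %*% m$mediators$beta) +
      m$direct * exposure_indicator(meta, m$exposure_var, m$exposure_level)
    y <- switch(m$family,
      nb = stats::rnbinom(n_samp, mu = exp(eta), size = m$size),
      vas = {
        p <- stats::plogis(eta)
        pr <- stats::rbeta(n_samp, p * m$phi, (1 - p) * m$phi)
        stats::rbinom(n_samp, 100, pr)
      },
      gaussian = eta + stats::rnorm(n_samp, 0, m$sigma),
      stop("unknown outcome family: ", m$family))
    if (!is.null(m$max_week)) y[meta$age_weeks > m$max_week] <- NA
    wb[[m$outcome]] <- y
    eta_store[[m$outcome]] <- eta
  }
  wb$overall_health <- sample(1:5, n_samp, replace = TRUE,
                              prob = c(.02, .03, .10, .35, .50))
  abx_courses <- stats::rpois(nrow(inf), 0.5)
  wb$abx_courses <- abx_courses[match(meta$infant_id, inf$infant_id)]

  ## ---- assemble ----------------------------------------------------------
  meta_out <- meta[, c("sample_id", "infant_id", "age_weeks", "group",
                       "birth_mode", "antibiotic", "abx_class", "cohort",
                       "run", "protocol_modified", "breastfeeding",
                       "weeks_since_solids", "probiotics")]
  rownames(meta_out) <- NULL
  structure(list(
    counts = count_table(counts, config$taxonomy[, 1:5],
                         data.frame(sample_id = meta$sample_id,
                                    run = meta$run, cohort = meta$cohort,
                                    stringsAsFactors = FALSE)),
    blanks = count_table(blanks, config$taxonomy[, 1:5], blank_meta),
    qpcr = qpcr,
    copy_numbers = config$copy_numbers,
    metadata = meta_out,
    wellbeing = wb,
    truth = list(true_cells = true_cells, true_copies = true_copies,
                 true_load = true_load, group_effects = config$group_effects,
                 mediation = config$mediation_spec,
                 outcome_linear_predictors = eta_store,
                 discordant_taxon = config$discordant_taxon),
    config = config), class = "qmp_sim")
}

# reference-group expected log copies (no group effect, no discordance pin)
mu_reference <- function(config, tx, tp_idx, share, taxa, sd_tot2) {
  j <- tp_idx
  log(config$load_curve[j] * share[match(tx, taxa), j]) - sd_tot2 / 2
}

exposure_indicator <- function(meta, var, level) {
  x <- switch(var,
              birth_mode = ifelse(meta$birth_mode == "VD", "VD", "CS"),
              abx_class = meta$abx_class,
              group = meta$group,
              stop("unknown exposure variable: ", var))
  as.numeric(x == level)
}

#' @export
print.qmp_sim <- function(x, ...) {
  cat(sprintf(paste0("<qmp_sim> %d infants, %d timepoints, %d taxa, ",
                     "%d samples (+%d blanks)\n"),
              sum(x$config$n_infants_per_group), length(x$config$timepoints),
              ncol(x$counts$counts), nrow(x$counts$counts),
              nrow(x$blanks$counts)))
  print(x$config$n_infants_per_group)
  invisible(x)
}

#' Plant a scale-discordant taxon into a simulated cohort
#'
#' Re-simulates the cohort with one taxon's true absolute abundance pinned to
#' a slowly, monotonically increasing trajectory while the total bacterial
#' load keeps its default strong age-driven growth. The taxon's true relative
#' abundance therefore decreases with age even though its absolute abundance
#' does not: the classic artifact in which relative profiles show a taxon
#' (e.g. Enterobacteriales) declining while its absolute abundance rises.
#'
#' @param config a \code{\link{sim_config}}.
#' @param taxon taxon to render discordant; must exist in the taxonomy and
#'   must not be a blank-only contaminant taxon.
#' @return a \code{qmp_sim} whose ground truth records the discordant taxon.
#' @export
simulate_discordant_taxon <- function(config, taxon) {
  if (!inherits(config, "qmp_sim_config"))
    stop("config must be built with sim_config()")
  if (!taxon %in% config$taxonomy$taxon)
    stop("taxon '", taxon, "' not present in the taxon set")
  if (taxon %in% names(config$contaminant_taxa))
    stop("taxon '", taxon,
         "' is a blank contaminant; cannot plant a discordant trajectory")
  config$discordant_taxon <- taxon
  simulate_cohort(config)
}
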