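#' Link well-being questionnaires to fecal sampling points
#'
#' Each questionnaire record is linked to the cohort sample of the same
#' infant whose sampling age is nearest to the questionnaire age.
#'
#' @param cohort per-sample cohort frame (\code{sample_id}, \code{infant_id},
#'   \code{age_weeks}).
#' @param wellbeing questionnaire records (\code{infant_id},
#'   \code{age_weeks}, outcome columns).
#' @return cohort frame with the outcome columns appended.
#' @export
link_wellbeing <- function(cohort, wellbeing) {
  outcome_cols <- setdiff(names(wellbeing), c("infant_id", "age_weeks"))
  out <- cohort
  for (cl in outcome_cols) out[[cl]] <- NA
  for (i in seq_len(nrow(cohort))) {
    w <- wellbeing[wellbeing$infant_id == cohort$infant_id[i], , drop = FALSE]
    if (!nrow(w)) next
    j <- which.min(abs(w$age_weeks - cohort$age_weeks[i]))
    for (cl in outcome_cols) out[[cl]][i] <- w[[cl]][j]
  }
  out
}

# per-term P values of a fitted outcome model: likelihood-ratio tests for the
# count families, F tests for the Gaussian model
term_p_table <- function(fit) {
  if (inherits(fit, "negbin") || inherits(fit, "glm")) {
    dr <- suppressWarnings(stats::drop1(fit, test = "LRT"))
    data.frame(term = rownames(dr)[-1], p = dr$`Pr(>Chi)`[-1],
               stringsAsFactors = FALSE)
  } else {
    dr <- stats::drop1(fit, test = "F")
    data.frame(term = rownames(dr)[-1], p = dr$`Pr(>F)`[-1],
               stringsAsFactors = FALSE)
  }
}

# fit the outcome regression for a given family with graceful fallback
fit_outcome <- function(form, dat, family) {
  if (family == "gaussian")
    return(list(fit = stats::lm(form, data = dat), family = "gaussian"))
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(form, data = dat,
                                  control = stats::glm.control(maxit = 50))),
    error = function(e) e)
  if (inherits(fit, "error") || !fit$converged)
    return(list(fit = stats::glm(form, family = stats::poisson(),
                                 data = dat), family = "poisson"))
  list(fit = fit, family = "negbin")
}

#' Exposure effects on a well-being outcome
#'
#' Regression of the outcome on birth mode and antibiotic class as separate
#' exposure factors, adjusted for feeding type and probiotic use, at one
#' fecal sampling point. Count-valued outcomes (defecation rate, VAS scores
#' and symptom intensities rounded to integer scores) are modelled negative
#' binomially with a Poisson fallback on non-convergence; continuous outcomes
#' use a Gaussian linear model (\code{family = "auto"} decides from the data,
#' and the choice is recorded).
#'
#' @param outcome outcome column name.
#' @param data linked frame from \code{\link{link_wellbeing}} restricted or
#'   restrictable to one timepoint.
#' @param timepoint age in weeks.
#' @param covariates adjustment covariates.
#' @param family \code{"auto"}, \code{"negbin"} or \code{"gaussian"}.
#' @return list(fit, family, terms): \code{terms} holds per-factor two-sided
#'   P values (likelihood ratio for count families, F for Gaussian).
#' @export
outcome_exposure_model <- function(outcome, data, timepoint,
                                   covariates = c("breastfeeding",
                                                  "probiotics"),
                                   family = "auto") {
  design <- build_design(data, timepoint,
                         exposure = c("birth_mode", "abx_class"),
                         covariates = covariates)
  dat <- design$data
  y <- dat[[outcome]]
  keep <- !is.na(y)
  dat <- dat[keep, , drop = FALSE]
  y <- y[keep]
  if (family == "auto")
    family <- if (all(y == round(y)) && all(y >= 0)) "negbin" else "gaussian"
  dat$.y <- if (family == "gaussian") y else round(y)
  if (length(unique(dat$.y)) < 2)
    stop("outcome '", outcome, "' is constant at timepoint ", timepoint)
  form <- stats::update(design$formula, .y ~ .)
  fo <- fit_outcome(form, dat, family)
  list(fit = fo$fit, family = fo$family, terms = term_p_table(fo$fit),
       data = dat, formula = form, design = design)
}

# deterministic forward-backward AIC selection over candidate columns of
# `dat`, starting from the empty model, capped at max_terms predictors; a
# step is taken only when it improves AIC by more than `margin` (the
# strong-support threshold on the Akaike scale, the overfitting guard for
# wide candidate sets)
step_aic <- function(y, dat, candidates, max_terms, margin = 4) {
  selected <- character(0)
  fit0 <- stats::lm(y ~ 1, data = dat)
  best_aic <- stats::AIC(fit0)
  repeat {
    moves <- list()
    if (length(selected) < max_terms)
      for (v in setdiff(candidates, selected))
        moves[[paste0("+", v)]] <- c(selected, v)
    for (v in selected)
      moves[[paste0("-", v)]] <- setdiff(selected, v)
    if (!length(moves)) break
    aics <- vapply(moves, function(vars) {
      f <- if (length(vars))
        stats::as.formula(paste("y ~", paste(sprintf("`%s`", vars),
                                             collapse = " + ")))
      else y ~ 1
      stats::AIC(stats::lm(f, data = dat))
    }, numeric(1))
    if (min(aics) >= best_aic - margin) break
    pick <- names(aics)[which.min(aics)]
    selected <- moves[[pick]]
    best_aic <- min(aics)
  }
  f <- if (length(selected))
    stats::as.formula(paste("y ~", paste(sprintf("`%s`", selected),
                                         collapse = " + ")))
  else y ~ 1
  list(selected = selected, fit = stats::lm(f, data = dat), aic = best_aic)
}

#' Select taxa predicting an outcome by stepwise AIC
#'
#' Deterministic forward-backward Akaike-criterion selection over
#' log10-transformed taxon abundances (prevalence-filtered candidates) as
#' predictors of the outcome, starting from the intercept-only model and
#' capped at n/10 predictors to bound overfitting. Variance explained is the
#' squared Pearson correlation between fitted and observed outcome (0 when no
#' taxon improves on the intercept).
#'
#' @param outcome numeric outcome vector.
#' @param abundance matrix of abundances (samples x taxa) aligned with
#'   \code{outcome}.
#' @param prevalence candidate prevalence gate (strict, default 0.30).
#' @param max_terms cap on model size; default \code{floor(n/10)}.
#' @param pseudocount pseudo-count of the log transform.
#' @param aic_margin minimum AIC improvement a step must achieve (default 4,
#'   the conventional strong-support threshold; guards against overfitting
#'   with wide candidate sets).
#' @return list(selected, coefficients, variance_explained, pseudo_r2, aic,
#'   fit).
#' @export
select_mediator_taxa <- function(outcome, abundance, prevalence = 0.30,
                                 max_terms = NULL, pseudocount = 1,
                                 aic_margin = 4) {
  keep <- !is.na(outcome)
  outcome <- outcome[keep]
  abundance <- abundance[keep, , drop = FALSE]
  n <- length(outcome)
  if (is.null(max_terms)) max_terms <- max(1, floor(n / 10))
  candidates <- prevalence_filter(abundance, prevalence)
  dat <- as.data.frame(log10(abundance[, candidates, drop = FALSE] +
                               pseudocount))
  sel <- step_aic(outcome, dat, candidates, max_terms, margin = aic_margin)
  ve <- if (length(sel$selected) == 0) 0 else {
    r <- suppressWarnings(stats::cor(stats::fitted(sel$fit), outcome))
    if (is.na(r)) 0 else r^2
  }
  co <- if (length(sel$selected)) {
    cs <- stats::coef(summary(sel$fit))
    idx <- match(sel$selected, gsub("`", "", rownames(cs)))
    data.frame(taxon = sel$selected, estimate = cs[idx, 1], p = cs[idx, 4],
               stringsAsFactors = FALSE)
  } else data.frame(taxon = character(0), estimate = numeric(0),
                    p = numeric(0))
  co$sign <- sign(co$estimate)
  tss <- sum((outcome - mean(outcome))^2)
  pseudo_r2 <- if (tss > 0) 1 - sum(stats::residuals(sel$fit)^2) / tss else 0
  list(selected = sel$selected, coefficients = co, variance_explained = ve,
       pseudo_r2 = pseudo_r2, aic = sel$aic, fit = sel$fit)
}

#' Exposure-to-taxon association edges
#'
#' For each selected mediator taxon, tests the birth-mode and
#' antibiotic-class factors with the differential-abundance model cascade and
#' keeps edges with P < alpha, recording the association sign (e.g. cesarean
#' birth, low Bacteroides: negative edge).
#'
#' @param taxa mediator taxon names.
#' @param abundance abundance matrix (samples x taxa) on the analysis scale.
#' @param cohort cohort frame rows aligned with \code{abundance}.
#' @param timepoint age in weeks.
#' @param alpha edge significance level.
#' @param unit cells/g per count unit before rounding.
#' @param covariates adjustment covariates.
#' @return data.frame(taxon, exposure, level, estimate, p, sign).
#' @export
exposure_taxon_links <- function(taxa, abundance, cohort, timepoint,
                                 alpha = 0.05, unit = 1e4,
                                 covariates = c("breastfeeding",
                                                "probiotics")) {
  if (!length(taxa))
    return(data.frame(taxon = character(0), exposure = character(0),
                      level = character(0), estimate = numeric(0),
                      p = numeric(0), sign = numeric(0)))
  design <- build_design(cohort, timepoint,
                         exposure = c("birth_mode", "abx_class"),
                         covariates = covariates)
  ab <- abundance[design$data$sample_id, , drop = FALSE]
  out <- list()
  for (tx in taxa) {
    fit <- tryCatch(fit_cascade(round(ab[, tx] / unit), design),
                    error = function(e) NULL)
    if (is.null(fit)) next
    coefs <- cascade_coef_table(fit)
    for (var in c("birth_mode", "abx_class")) {
      levs <- levels(design$data[[var]])[-1]
      for (lv in levs) {
        rn <- paste0(var, lv)
        if (!rn %in% rownames(coefs)) next
        p <- coefs[rn, ncol(coefs)]
        if (!is.na(p) && p < alpha)
          out[[length(out) + 1]] <- data.frame(
            taxon = tx, exposure = var, level = lv,
            estimate = coefs[rn, 1], p = p,
            sign = sign(coefs[rn, 1]), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(taxon = character(0), exposure = character(0),
                      level = character(0), estimate = numeric(0),
                      p = numeric(0), sign = numeric(0)))
  do.call(rbind, out)
}

#' Assemble the mediation path diagram for one outcome and timepoint
#'
#' Merges the exposure-to-outcome, exposure-to-taxon and taxon-to-outcome
#' associations into one path graph. An exposure effect is declared
#' "mediated" when it is significant marginally, at least one selected taxon
#' carries both an exposure edge and an outcome edge, and the direct exposure
#' term loses significance once the mediator taxa enter the outcome model
#' (direct-effect attenuation).
#'
#' @param exposure_model result of \code{\link{outcome_exposure_model}}.
#' @param mediator_model result of \code{\link{select_mediator_taxa}}.
#' @param edges result of \code{\link{exposure_taxon_links}}.
#' @param abundance abundance matrix aligned with the exposure model's data
#'   (used for the joint attenuation model).
#' @param outcome,timepoint labels for the result.
#' @param alpha significance level of the attenuation rule.
#' @param pseudocount log-transform pseudo-count.
#' @return object of class \code{qmp_path}.
#' @export
assemble_path_diagram <- function(exposure_model, mediator_model, edges,
                                  abundance, outcome, timepoint,
                                  alpha = 0.05, pseudocount = 1) {
  dat <- exposure_model$data
  med <- mediator_model$selected
  ## joint model: exposures + mediator log abundances
  joint_terms <- exposure_model$terms
  if (length(med)) {
    jd <- dat
    ab <- abundance[dat$sample_id, med, drop = FALSE]
    for (tx in med) jd[[paste0("med_", make.names(tx))]] <-
      log10(ab[, tx] + pseudocount)
    jform <- stats::update(exposure_model$formula,
                           stats::as.formula(paste(". ~ . +",
                             paste(paste0("med_", make.names(med)),
                                   collapse = " + "))))
    jfam <- if (exposure_model$family == "gaussian") "gaussian" else "negbin"
    jfit <- fit_outcome(jform, jd, jfam)$fit
    jdr <- term_p_table(jfit)
    joint <- data.frame(term = jdr$term, p_joint = jdr$p,
                        stringsAsFactors = FALSE)
    joint_terms <- merge(exposure_model$terms,
                         joint[joint$term %in% exposure_model$terms$term, ],
                         by = "term", all.x = TRUE)
  } else joint_terms$p_joint <- joint_terms$p
  full_edge_taxa <- intersect(med, edges$taxon)
  is_exposure <- joint_terms$term %in% c("birth_mode", "abx_class")
  joint_terms$mediated <- is_exposure & joint_terms$p < alpha &
    !is.na(joint_terms$p_joint) & joint_terms$p_joint >= alpha &
    length(full_edge_taxa) > 0
  structure(list(outcome = outcome, timepoint = timepoint,
                 exposure_terms = joint_terms,
                 mediators = mediator_model$coefficients,
                 edges = edges,
                 variance_explained = mediator_model$variance_explained,
                 pseudo_r2 = mediator_model$pseudo_r2,
                 aic = mediator_model$aic,
                 full_path_taxa = full_edge_taxa),
            class = "qmp_path")
}

#' @export
print.qmp_path <- function(x, ...) {
  cat(sprintf("<qmp_path> %s at week %s: taxa explain %.0f%% of variation\n",
              x$outcome, x$timepoint, 100 * x$variance_explained))
  et <- x$exposure_terms
  for (i in seq_len(nrow(et)))
    cat(sprintf("  %s: P = %.3g%s\n", et$term[i], et$p[i],
                if (isTRUE(et$mediated[i])) " (mediated by taxa)" else ""))
  if (nrow(x$mediators)) {
    cat("  mediator taxa:",
        paste(sprintf("%s(%s)", x$mediators$taxon,
                      ifelse(x$mediators$sign > 0, "+", "-")),
              collapse = ", "), "\n")
    if (nrow(x$edges))
      cat("  exposure->taxon edges:",
          paste(sprintf("%s:%s(%s)", x$edges$level, x$edges$taxon,
                        ifelse(x$edges$sign > 0, "+", "-")),
                collapse = ", "), "\n")
  }
  invisible(x)
}

#' Mediation path analysis of one outcome at one timepoint
#'
#' The full path-model procedure: model the outcome on birth mode and
#' antibiotic class (negative binomial, covariate-adjusted), select mediator
#' taxa predicting the outcome by stepwise AIC over log genus-level absolute
#' abundances, test exposure-to-taxon links with the model cascade, and
#' assemble the mediation diagram with variance explained.
#'
#' @param profile a \code{qmp_profile}.
#' @param cohort per-sample cohort frame.
#' @param wellbeing questionnaire table.
#' @param outcome outcome column name.
#' @param timepoint age in weeks.
#' @param rank rank of the mediator candidates (default genus).
#' @param prevalence candidate prevalence gate.
#' @param alpha significance level for edges and attenuation.
#' @param unit cells/g per count unit for the cascade fits.
#' @param max_terms cap on mediator-model size; default n/10.
#' @param covariates adjustment covariates.
#' @param family outcome model family (\code{"auto"}, \code{"negbin"},
#'   \code{"gaussian"}); see \code{\link{outcome_exposure_model}}.
#' @return a \code{qmp_path} object.
#' @export
path_model <- function(profile, cohort, wellbeing, outcome, timepoint,
                       rank = "genus", prevalence = 0.30, alpha = 0.05,
                       unit = 1e4, max_terms = NULL,
                       covariates = c("breastfeeding", "probiotics"),
                       family = "auto") {
  prof <- if (!identical(rank, profile$rank)) aggregate_rank(profile, rank)
          else profile
  ab <- profile_matrix(prof, "absolute")
  linked <- link_wellbeing(cohort, wellbeing)
  linked <- linked[linked$sample_id %in% rownames(ab), , drop = FALSE]
  em <- outcome_exposure_model(outcome, linked, timepoint,
                               covariates = covariates, family = family)
  dat <- em$data
  absub <- ab[dat$sample_id, , drop = FALSE]
  mm <- select_mediator_taxa(dat$.y, absub, prevalence = prevalence,
                             max_terms = max_terms)
  ed <- exposure_taxon_links(mm$selected, ab, linked, timepoint,
                             alpha = alpha, unit = unit,
                             covariates = covariates)
  assemble_path_diagram(em, mm, ed, ab, outcome, timepoint, alpha = alpha)
}
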