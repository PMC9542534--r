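#' Assign infants to the five birth-exposure study groups
#'
#' The study group is a pure function of birth mode and intrapartum
#' antibiotic: vaginally born unexposed infants form the reference group
#' \code{VD}; cephalosporin exposure (cefuroxime or cephalexin) defines
#' \code{VD-cep} and \code{CS-cep}; penicillin in vaginal delivery defines
#' \code{VD-pen}; any other antibiotic, a combination, an unreported class or
#' penicillin in cesarean delivery defines \code{CS-other}. Elective and
#' emergency cesareans are pooled. Vaginally born infants with an antibiotic
#' outside the enumerated classes are labelled \code{"unclassifiable"} rather
#' than silently dropped, as are cesarean records claiming no antibiotic
#' (all cesarean deliveries involve intrapartum antibiotics).
#'
#' @param birth_mode character vector: \code{"VD"}, \code{"CS"},
#'   \code{"elective CS"} or \code{"emergency CS"}.
#' @param antibiotic character vector: \code{"none"}, \code{"penicillin"},
#'   \code{"cefuroxime"}, \code{"cephalexin"}, \code{"clindamycin"},
#'   \code{"metronidazole"}, \code{"combination"}, \code{"other"} or
#'   \code{"not reported"}.
#' @return character vector of group labels.
#' @examples
#' assign_study_group("emergency CS", "cephalexin")  # "CS-cep"
#' assign_study_group("VD", "none")                  # "VD"
#' @export
assign_study_group <- function(birth_mode, antibiotic) {
  modes <- c("VD", "CS", "elective CS", "emergency CS")
  abx <- c("none", "penicillin", "cefuroxime", "cephalexin", "clindamycin",
           "metronidazole", "combination", "other", "not reported")
  if (!all(birth_mode %in% modes))
    stop("unknown birth mode: ",
         paste(setdiff(birth_mode, modes), collapse = ", "))
  if (!all(antibiotic %in% abx))
    stop("unknown antibiotic class: ",
         paste(setdiff(antibiotic, abx), collapse = ", "))
  cs <- birth_mode != "VD"
  ceph <- antibiotic %in% c("cefuroxime", "cephalexin")
  out <- rep("unclassifiable", length(cs))
  out[!cs & antibiotic == "none"] <- "VD"
  out[!cs & ceph] <- "VD-cep"
  out[!cs & antibiotic == "penicillin"] <- "VD-pen"
  out[cs & ceph] <- "CS-cep"
  out[cs & !ceph & antibiotic != "none"] <- "CS-other"
  out
}

#' Antibiotic-class factor used in the mediation analysis
#'
#' Collapses the antibiotic vocabulary to the exposure classes modelled
#' separately from birth mode: none, penicillin, cephalosporin, other.
#'
#' @param antibiotic character vector as in \code{\link{assign_study_group}}.
#' @return character vector of classes.
#' @export
antibiotic_class <- function(antibiotic) {
  cls <- c("none" = "none", "penicillin" = "penicillin",
           "cefuroxime" = "cephalosporin", "cephalexin" = "cephalosporin",
           "clindamycin" = "other", "metronidazole" = "other",
           "combination" = "other", "other" = "other",
           "not reported" = "other")
  unname(cls[antibiotic])
}

#' Censor samples collected after post-natal antibiotic treatment
#'
#' Samples strictly after an infant's first post-natal antibiotic course are
#' flagged as censored and excluded from all model fits; infants whose first
#' course precedes their first sample are dropped entirely.
#'
#' @param samples per-sample cohort frame with columns \code{infant_id} and
#'   \code{age_weeks}.
#' @param treatments data.frame(infant_id, age_weeks) of post-natal antibiotic
#'   courses (ages in weeks, comparable to sampling ages).
#' @return the cohort frame with a logical \code{censored} column; fully
#'   dropped infants are removed and listed in the \code{dropped_infants}
#'   attribute.
#' @export
censor_postnatal_antibiotics <- function(samples, treatments = NULL) {
  samples$censored <- FALSE
  if (is.null(treatments) || nrow(treatments) == 0) return(samples)
  first_course <- tapply(treatments$age_weeks, treatments$infant_id, min)
  fc <- as.vector(first_course[samples$infant_id])
  samples$censored <- !is.na(fc) & samples$age_weeks > fc
  first_sample <- tapply(samples$age_weeks, samples$infant_id, min)
  drop <- names(first_course)[first_course <
                                first_sample[names(first_course)] &
                                !is.na(first_sample[names(first_course)])]
  out <- samples[!samples$infant_id %in% drop, , drop = FALSE]
  attr(out, "dropped_infants") <- drop
  out
}

#' Build the covariate-adjusted design for one timepoint
#'
#' Returns the model design used by the taxon-wise comparisons: the exposure
#' factor of interest plus the standard adjustments (breastfeeding status,
#' weeks since the introduction of solids, probiotic category, sequencing run
#' and protocol-modification flag). Covariates constant at the timepoint are
#' dropped with a note. Reference levels are fixed at the unexposed vaginally
#' born stratum (group \code{VD}, antibiotic \code{none}, exclusive
#' breastfeeding).
#'
#' @param samples cohort frame (one row per sample) with a \code{censored}
#'   column (censored rows are excluded) or without (all rows used).
#' @param timepoint age in weeks to subset on (column \code{age_weeks}).
#' @param exposure name(s) of the exposure factor(s): \code{"group"} or
#'   \code{c("birth_mode","abx_class")}.
#' @param covariates candidate adjustment columns present in \code{samples}.
#' @return object of class \code{qmp_design}: list with the model
#'   \code{formula}, the subset \code{data}, the exposure term(s), and the
#'   covariates dropped as constant.
#' @export
build_design <- function(samples, timepoint, exposure = "group",
                         covariates = c("breastfeeding", "weeks_since_solids",
                                        "probiotics", "run",
                                        "protocol_modified")) {
  dat <- samples[samples$age_weeks == timepoint, , drop = FALSE]
  if (!nrow(dat)) stop("no samples at timepoint ", timepoint)
  if ("censored" %in% names(dat)) dat <- dat[!dat$censored, , drop = FALSE]
  if ("group" %in% exposure)
    dat$group <- stats::relevel(factor(dat$group), ref = "VD")
  if ("birth_mode" %in% exposure)
    dat$birth_mode <- stats::relevel(
      factor(ifelse(dat$birth_mode == "VD", "VD", "CS")), ref = "VD")
  if ("abx_class" %in% exposure)
    dat$abx_class <- stats::relevel(factor(dat$abx_class), ref = "none")
  if ("breastfeeding" %in% names(dat))
    dat$breastfeeding <- factor(dat$breastfeeding,
                                levels = c("exclusive", "partial", "none"))
  covariates <- intersect(covariates, names(dat))
  dropped <- character(0)
  keep <- character(0)
  for (cv in covariates) {
    v <- dat[[cv]]
    if (length(unique(v[!is.na(v)])) < 2) dropped <- c(dropped, cv)
    else keep <- c(keep, cv)
  }
  for (cv in keep) if (is.character(dat[[cv]]) || is.logical(dat[[cv]]))
    dat[[cv]] <- factor(dat[[cv]])
  rhs <- paste(c(exposure, keep), collapse = " + ")
  structure(list(formula = stats::as.formula(paste("~", rhs)),
                 data = dat, exposure = exposure, covariates = keep,
                 dropped = dropped, timepoint = timepoint),
            class = "qmp_design")
}

#' @export
print.qmp_design <- function(x, ...) {
  cat(sprintf("<qmp_design> week %s: ~ %s (n = %d)\n", x$timepoint,
              paste(deparse(x$formula[[2]]), collapse = ""), nrow(x$data)))
  if (length(x$dropped))
    cat("  dropped constant covariate(s):",
        paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}
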