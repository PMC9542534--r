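#' Principal coordinates analysis on Pearson-correlation distances
#'
#' Log-transforms the abundance matrix (log10 with a pseudo-count), computes
#' between-sample distances d(i, j) = 1 - Pearson r of the transformed
#' abundance vectors, and applies classical scaling. Negative eigenvalues are
#' zeroed and their total magnitude recorded. Samples with constant
#' transformed vectors (undefined correlation) are excluded with a note.
#'
#' @param profile a \code{qmp_profile} or a numeric matrix (samples x taxa).
#' @param scale abundance scale when a profile is given.
#' @param pseudocount pseudo-count of the log transform (default 1).
#' @param k number of axes to return (default all positive-eigenvalue axes,
#'   at least 2).
#' @return object of class \code{qmp_pcoa}: sample coordinates
#'   (\code{points}), eigenvalues, variance-explained proportions, the
#'   distance matrix, excluded samples, and the zeroed negative-eigenvalue
#'   magnitude.
#' @export
pcoa_pearson <- function(profile, scale = "absolute", pseudocount = 1,
                         k = NULL) {
  mat <- if (inherits(profile, "qmp_profile"))
    profile_matrix(profile, scale) else as.matrix(profile)
  if (nrow(mat) < 3) stop("at least 3 samples required")
  if (any(rowSums(mat) == 0)) stop("all-zero sample rows are not allowed")
  x <- log10(mat + pseudocount)
  sds <- apply(x, 1, stats::sd)
  excluded <- rownames(x)[sds == 0]
  if (length(excluded)) {
    message("excluding constant sample vector(s): ",
            paste(excluded, collapse = ", "))
    x <- x[sds > 0, , drop = FALSE]
  }
  d <- 1 - stats::cor(t(x))
  dd <- stats::as.dist(d)
  n <- nrow(x)
  if (is.null(k)) k <- min(n - 1, 10)
  sc <- suppressWarnings(stats::cmdscale(dd, k = min(k, n - 1), eig = TRUE))
  eig <- sc$eig
  neg_mag <- sum(abs(eig[eig < 0]))
  pts <- sc$points
  colnames(pts) <- paste0("PC", seq_len(ncol(pts)))
  var_exp <- pmax(eig, 0) / sum(pmax(eig, 0))
  structure(list(points = pts, eig = eig,
                 var_explained = var_exp[seq_len(ncol(pts))],
                 distance = d, excluded = excluded,
                 negative_eigenvalue_magnitude = neg_mag,
                 scale = scale, pseudocount = pseudocount),
            class = "qmp_pcoa")
}

#' @export
print.qmp_pcoa <- function(x, ...) {
  cat(sprintf("<qmp_pcoa> %d samples, %d axes; PC1 %.1f%%, PC2 %.1f%% of positive inertia\n",
              nrow(x$points), ncol(x$points), 100 * x$var_explained[1],
              100 * x$var_explained[2]))
  if (x$negative_eigenvalue_magnitude > 0)
    cat(sprintf("  zeroed negative eigenvalues, total magnitude %.3g\n",
                x$negative_eigenvalue_magnitude))
  invisible(x)
}

#' Per-timepoint ANOVA of group separation on principal coordinates
#'
#' One-way ANOVA of study group on each of the first two principal
#' coordinates among the samples of one timepoint. Groups with fewer than two
#' samples at the timepoint are excluded with a note. A pooled two-axis test
#' (MANOVA Pillai) is reported alongside the per-axis default.
#'
#' @param ordination a \code{\link{pcoa_pearson}} result.
#' @param cohort per-sample cohort frame with \code{sample_id},
#'   \code{age_weeks}, \code{group}.
#' @param timepoint age in weeks.
#' @param axes axes to test (default 1:2).
#' @return data.frame(axis, F, p) with attributes \code{pooled_p} (MANOVA)
#'   and \code{excluded_groups}.
#' @export
test_group_separation <- function(ordination, cohort, timepoint, axes = 1:2) {
  ids <- intersect(rownames(ordination$points),
                   cohort$sample_id[cohort$age_weeks == timepoint])
  dat <- cohort[match(ids, cohort$sample_id), , drop = FALSE]
  sizes <- table(dat$group)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    ids <- ids[!dat$group %in% small]
    dat <- dat[!dat$group %in% small, , drop = FALSE]
  }
  if (length(unique(dat$group)) < 2)
    stop("fewer than 2 groups with >= 2 samples at timepoint ", timepoint)
  g <- factor(dat$group)
  pts <- ordination$points[ids, axes, drop = FALSE]
  out <- do.call(rbind, lapply(seq_along(axes), function(j) {
    a <- stats::aov(pts[, j] ~ g)
    s <- summary(a)[[1]]
    data.frame(axis = colnames(pts)[j], F = s$`F value`[1],
               p = s$`Pr(>F)`[1], stringsAsFactors = FALSE)
  }))
  pooled <- tryCatch({
    m <- stats::manova(pts ~ g)
    summary(m)$stats[1, "Pr(>F)"]
  }, error = function(e) NA_real_)
  attr(out, "pooled_p") <- pooled
  attr(out, "excluded_groups") <- small
  rownames(out) <- NULL
  out
}

#' Median group trajectories in ordination space
#'
#' Per-group, per-timepoint medians of the principal-coordinate scores, the
#' "large circles" of a trajectory ordination plot.
#'
#' @param ordination a \code{\link{pcoa_pearson}} result.
#' @param cohort per-sample cohort frame.
#' @param axes axes to summarize.
#' @return data.frame(group, age_weeks, axis medians).
#' @export
median_trajectories <- function(ordination, cohort, axes = 1:2) {
  ids <- intersect(rownames(ordination$points), cohort$sample_id)
  dat <- cohort[match(ids, cohort$sample_id), , drop = FALSE]
  pts <- ordination$points[ids, axes, drop = FALSE]
  agg <- stats::aggregate(pts, by = list(group = dat$group,
                                         age_weeks = dat$age_weeks),
                          FUN = stats::median)
  agg[order(agg$group, agg$age_weeks), ]
}

#' Smoothed class-level abundance trajectories
#'
#' Local-regression (loess, degree 1) smooth of log10 abundance against age
#' for each requested taxon/class, evaluated on a fixed age grid restricted
#' to 4-39 weeks, with a pointwise confidence band of the smoothed mean
#' (default level 30\%: mean +/- z(0.65) standard errors).
#'
#' @param profile a \code{qmp_profile} or abundance matrix.
#' @param cohort per-sample cohort frame giving \code{age_weeks} per sample.
#' @param taxa taxa/classes to smooth (columns of the matrix at hand).
#' @param scale abundance scale when a profile is given.
#' @param level band level in (0, 1); default 0.30.
#' @param span loess bandwidth as a fraction of the age range (default 0.5).
#' @param grid age grid; default 40 points over 4-39 weeks.
#' @param pseudocount pseudo-count of the log transform.
#' @return data.frame(taxon, age_weeks, mean, lower, upper, scale) of class
#'   \code{qmp_trajectory}.
#' @export
smooth_class_trajectories <- function(profile, cohort, taxa = NULL,
                                      scale = "absolute", level = 0.30,
                                      span = 0.5,
                                      grid = seq(4, 39, length.out = 40),
                                      pseudocount = 1) {
  mat <- if (inherits(profile, "qmp_profile"))
    profile_matrix(profile, scale) else as.matrix(profile)
  age <- cohort$age_weeks[match(rownames(mat), cohort$sample_id)]
  keep <- !is.na(age) & age >= 4 & age <= 39
  mat <- mat[keep, , drop = FALSE]
  age <- age[keep]
  if (length(unique(age)) < 2) stop("at least 2 distinct ages required")
  grid <- grid[grid >= min(age) & grid <= max(age)]  # no extrapolation
  if (is.null(taxa)) taxa <- colnames(mat)
  z <- stats::qnorm(0.5 + level / 2)
  out <- list()
  for (tx in taxa) {
    if (!tx %in% colnames(mat)) {
      message("taxon '", tx, "' absent; skipped")
      next
    }
    y <- log10(mat[, tx] + pseudocount)
    lo <- stats::loess(y ~ age, span = span, degree = 1,
                       family = "gaussian")
    pr <- stats::predict(lo, newdata = data.frame(age = grid), se = TRUE)
    out[[tx]] <- data.frame(taxon = tx, age_weeks = grid, mean = pr$fit,
                            lower = pr$fit - z * pr$se.fit,
                            upper = pr$fit + z * pr$se.fit,
                            scale = scale, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("qmp_trajectory", "data.frame")
  res
}

#' Age-slope discordance between relative and absolute scales
#'
#' Fits least-squares age slopes of a taxon's log10 abundance on both the
#' copy-number-corrected absolute scale and the relative scale. A taxon whose
#' absolute abundance grows (or stays flat) while the community load grows
#' faster shows a negative relative slope with a non-negative absolute slope:
#' the classic artifact of purely relative profiling.
#'
#' @param profile a \code{qmp_profile}.
#' @param cohort per-sample cohort frame.
#' @param taxon taxon to assess.
#' @param pseudocount pseudo-count; for the relative scale it is applied on
#'   the per-mille scale of the proportions.
#' @return list(slope_absolute, slope_relative, discordant).
#' @export
scale_discordance <- function(profile, cohort, taxon, pseudocount = 1) {
  age <- cohort$age_weeks[match(rownames(profile$corrected),
                                cohort$sample_id)]
  if (!taxon %in% colnames(profile$corrected))
    stop("taxon '", taxon, "' not in the profile")
  slope <- function(y) unname(stats::coef(stats::lm(y ~ age))[2])
  sa <- slope(log10(profile$corrected[, taxon] + pseudocount))
  sr <- slope(log10(profile$relative[, taxon] * 1e6 + pseudocount))
  list(slope_absolute = sa, slope_relative = sr,
       discordant = sign(sa) != sign(sr))
}
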