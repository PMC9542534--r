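#' Prevalence filter
#'
#' Retains taxa observed (nonzero) in strictly more than a given fraction of
#' the analyzed samples; the conventional gate is >30\%.
#'
#' @param mat abundance or count matrix, samples x taxa.
#' @param threshold prevalence fraction in (0, 1).
#' @return character vector of retained taxon names.
#' @export
prevalence_filter <- function(mat, threshold = 0.30) {
  stopifnot(threshold > 0, threshold < 1)
  prev <- colMeans(mat > 0)
  colnames(mat)[prev > threshold]
}

# heteroscedasticity diagnostic: monotone trend of |Pearson residual| vs
# fitted, Spearman-type test; returns the two-sided P of the trend
resid_trend_p <- function(res, fitted) {
  n <- length(res)
  if (n < 8) return(1)
  r <- suppressWarnings(stats::cor(rank(abs(res)), rank(fitted)))
  if (is.na(r) || abs(r) >= 1) return(if (is.na(r)) 1 else 0)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tval), n - 2)
}

#' Fit the count-model cascade for one taxon
#'
#' Attempts, in order, a negative binomial, a Poisson, and a quasi-Poisson
#' log-link regression of the (rounded) abundance on the design, falling back
#' on (a) non-convergence, (b) an invalid or degenerate dispersion estimate,
#' (c) a failed residual diagnostic (a significant monotone trend of absolute
#' standardized residuals against fitted values, the operational
#' heteroscedasticity check, at \code{alpha_diag}), or (d) a failed
#' distribution check: the whole count branch is skipped when a Gaussian
#' model of log abundance clearly outfits the count family (AIC lower by more
#' than 2, likelihoods compared on the count scale via the log-Jacobian). If
#' no count family is admissible, a generalized least-squares fit of
#' \code{log10(y + pseudo)} with group-wise variance weights is used. The
#' first admissible fit is returned with its family label.
#'
#' Count-family fits additionally carry a misspecification guard: the
#' parallel log-scale least-squares coefficient table, whose P values are
#' combined with the robust Wald P values in
#' \code{\link{contrast_groups}} (see there).
#'
#' @param y non-negative abundance vector (rounded to integers for the count
#'   families).
#' @param design a \code{\link{build_design}} object whose \code{data} rows
#'   align with \code{y}.
#' @param alpha_diag level of the residual-trend diagnostic.
#' @param pseudo pseudo-count for the log transforms.
#' @return object of class \code{qmp_fit}: list(fit, family, diagnostics,
#'   guard).
#' @export
fit_cascade <- function(y, design, alpha_diag = 0.05, pseudo = 1) {
  dat <- design$data
  dat$.y <- round(y)
  form <- stats::update(design$formula, .y ~ .)
  diag <- list()
  grab <- function(expr) {
    warns <- character(0)
    fit <- withCallingHandlers(
      tryCatch(expr, error = function(e) e),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    list(fit = fit, warnings = warns)
  }

  ## log-scale reference model: distribution check and contrast guard
  dat$.logy <- log10(dat$.y + pseudo)
  lform <- stats::update(design$formula, .logy ~ .)
  lmfit <- stats::lm(lform, data = dat)
  # AIC of the log-normal model on the count scale (log10 rescaling and
  # Jacobian of the log transform)
  aic_lognormal <- stats::AIC(lmfit) + 2 * sum(dat$.logy) * log(10) +
    2 * nrow(dat) * log(log(10))
  lmco <- stats::coef(summary(lmfit))
  guard <- cbind(estimate = lmco[, 1], p = lmco[, 4])

  ## 1. negative binomial
  nb <- grab(MASS::glm.nb(form, data = dat, x = TRUE,
                          control = stats::glm.control(maxit = 50)))
  count_branch_ok <- TRUE
  if (!inherits(nb$fit, "error")) {
    f <- nb$fit
    aic_nb <- tryCatch(stats::AIC(f), error = function(e) Inf)
    count_branch_ok <- is.finite(aic_nb) && aic_nb < aic_lognormal + 2
    theta_ok <- is.finite(f$theta) && f$theta > 1e-3 && f$theta < 1e4 &&
      !any(grepl("iteration limit", nb$warnings))
    het <- resid_trend_p(stats::residuals(f, type = "pearson"),
                         stats::fitted(f))
    diag$negbin <- list(theta = f$theta, converged = f$converged,
                        het_p = het, aic = aic_nb,
                        aic_lognormal = aic_lognormal)
    if (count_branch_ok && f$converged && theta_ok && het > alpha_diag)
      return(structure(list(fit = f, family = "negbin", diagnostics = diag,
                            guard = guard), class = "qmp_fit"))
  } else diag$negbin <- list(error = conditionMessage(nb$fit))

  if (count_branch_ok) {
    ## 2. Poisson (admissible only when equidispersed)
    po <- grab(stats::glm(form, family = stats::poisson(), data = dat,
                          x = TRUE))
    if (!inherits(po$fit, "error")) {
      f <- po$fit
      disp <- sum(stats::residuals(f, type = "pearson")^2) / f$df.residual
      het <- resid_trend_p(stats::residuals(f, type = "pearson"),
                           stats::fitted(f))
      diag$poisson <- list(dispersion = disp, het_p = het)
      if (f$converged && disp >= 0.5 && disp <= 1.5 && het > alpha_diag)
        return(structure(list(fit = f, family = "poisson",
                              diagnostics = diag, guard = guard),
                         class = "qmp_fit"))
    } else diag$poisson <- list(error = conditionMessage(po$fit))

    ## 3. quasi-Poisson (dispersion free, residual diagnostic still enforced)
    qp <- grab(stats::glm(form, family = stats::quasipoisson(), data = dat,
                          x = TRUE))
    if (!inherits(qp$fit, "error")) {
      f <- qp$fit
      het <- resid_trend_p(stats::residuals(f, type = "pearson"),
                           stats::fitted(f))
      diag$quasipoisson <- list(het_p = het)
      if (f$converged && het > alpha_diag)
        return(structure(list(fit = f, family = "quasipoisson",
                              diagnostics = diag, guard = guard),
                         class = "qmp_fit"))
    } else diag$quasipoisson <- list(error = conditionMessage(qp$fit))
  } else diag$count_branch <- "log-normal model clearly preferred by AIC"

  ## 4. least squares on log abundance with group-wise variance weights
  gvar <- design$exposure[1]
  gls <- grab(fgls_log(stats::model.matrix(lmfit), dat$.logy,
                       dat[[gvar]]))
  if (!inherits(gls$fit, "error")) {
    diag$gls <- list(ok = TRUE, group_sd = gls$fit$group_sd)
    return(structure(list(fit = gls$fit$fit, ctab = gls$fit$ctab,
                          family = "gls-log", diagnostics = diag,
                          pseudo = pseudo), class = "qmp_fit"))
  }
  diag$gls <- list(error = conditionMessage(gls$fit))
  ## last resort: ordinary least squares on the log scale
  lco <- stats::coef(summary(lmfit))
  structure(list(fit = lmfit,
                 ctab = cbind(estimate = lco[, 1], p = lco[, 4]),
                 family = "gls-log", diagnostics = diag,
                 pseudo = pseudo), class = "qmp_fit")
}

# iterated feasible generalized least squares with group-wise variance
# weights: the working implementation behind the cascade's "gls-log" family
# (equivalent to a variance-identity-per-group GLS; implemented directly
# because it is fitted tens of thousands of times in simulation studies)
fgls_log <- function(X, z, g, iter = 2) {
  n <- nrow(X)
  p <- ncol(X)
  g <- as.character(g)
  beta <- stats::lm.fit(X, z)$coefficients
  if (anyNA(beta)) stop("singular design in group-weighted least squares")
  res <- z - as.vector(X %*% beta)
  pooled <- sum(res^2) / max(1, n - p)
  w <- rep(1, n)
  for (it in seq_len(iter)) {
    s2 <- tapply(res^2, g, mean) * n / max(1, n - p)
    s2 <- pmax(s2, 1e-3 * pooled, 1e-12)
    w <- as.vector(1 / s2[g])
    fit <- stats::lm.wfit(X, z, w)
    beta <- fit$coefficients
    res <- z - as.vector(X %*% beta)
  }
  Xw <- X * sqrt(w)
  C <- chol2inv(chol(crossprod(Xw)))
  sigma2 <- sum(w * res^2) / max(1, n - p)
  # coefficient variances as linear combinations of the group variances,
  # with Satterthwaite degrees of freedom per coefficient
  G <- (Xw %*% C)          # rows g_i: beta_hat = t(G) %*% (sqrt(w) z)
  lev <- names(s2)
  cjg <- vapply(lev, function(l) colSums(G[g == l, , drop = FALSE]^2),
                numeric(p))                       # p x groups
  if (p == 1) cjg <- matrix(cjg, nrow = 1, dimnames = list(colnames(X), lev))
  # weights absorb the relative group variances, so each observation
  # contributes sigma2 to Var(beta_hat): V_j = sigma2 * sum_g c_jg, with the
  # group contributions c_jg carrying df_g = n_g - 1 each
  dfg <- as.numeric(pmax(1, table(g)[lev] - 1))
  Vj <- sigma2 * rowSums(cjg)
  dfj <- rowSums(cjg)^2 / as.vector((cjg^2) %*% (1 / dfg))
  se <- sqrt(Vj)
  tv <- beta / se
  pv <- 2 * stats::pt(-abs(tv), df = pmax(1, pmin(dfj, n - p)))
  ctab <- cbind(estimate = beta, p = pv)
  rownames(ctab) <- colnames(X)
  list(fit = structure(list(coefficients = beta, residuals = res,
                            weights = w, df.residual = n - p,
                            group_sd = sqrt(s2)), class = "qmp_fgls"),
       ctab = ctab, group_sd = sqrt(s2))
}

#' @export
print.qmp_fit <- function(x, ...) {
  cat(sprintf("<qmp_fit> family %s\n", x$family))
  invisible(x)
}

# HC3 sandwich covariance of a glm computed from its stored design matrix
# (the per-taxon fit volume makes sandwich::vcovHC's model-frame round trips
# the bottleneck; the formula is identical)
glm_vcov_hc3 <- function(f) {
  X <- if (!is.null(f$x)) f$x else stats::model.matrix(f)
  w <- f$weights
  ok <- w > 0
  Xw <- X[ok, , drop = FALSE] * sqrt(w[ok])
  C <- tryCatch(chol2inv(chol(crossprod(Xw))), error = function(e) NULL)
  if (is.null(C)) return(stats::vcov(f))
  h <- pmin(rowSums((Xw %*% C) * Xw), 1 - 1e-8)
  ef <- X[ok, , drop = FALSE] *
    (w[ok] * stats::residuals(f, type = "working")[ok] / (1 - h))
  V <- C %*% crossprod(ef) %*% C
  dimnames(V) <- list(colnames(X), colnames(X))
  V
}

# coefficient table of a cascade fit: estimate and two-sided P. Count-family
# P values use heteroscedasticity-robust (HC3 sandwich) standard errors with
# residual-df t reference, further guarded against count-model
# misspecification by taking the maximum with the P value of the same term in
# the parallel log-scale least-squares model (an intersection-union
# combination: valid whenever either error model holds). The GLS fit models
# group-wise variances and uses its own t table.
cascade_coef_table <- function(cascade) {
  if (cascade$family == "gls-log") return(cascade$ctab)
  f <- cascade$fit
  co <- stats::coef(f)
  V <- glm_vcov_hc3(f)
  se <- sqrt(diag(V))[names(co)]
  tv <- co / se
  p <- 2 * stats::pt(-abs(tv), df = f$df.residual)
  if (!is.null(cascade$guard)) {
    gp <- cascade$guard[, "p"][names(co)]
    p <- pmax(p, gp, na.rm = TRUE)
  }
  cbind(estimate = co, p = p)
}

#' Extract group-vs-reference contrasts from a cascade fit
#'
#' For log-link count families the fold change is \code{exp(coefficient)};
#' for the log10-scale least-squares fit it is the ratio of back-transformed
#' adjusted means, \code{10^coefficient}. Two-sided P values use
#' heteroscedasticity-robust standard errors for the count families and the
#' GLS t table otherwise. The display value is log10 fold change capped to
#' [-cap, cap].
#'
#' @param cascade a \code{\link{fit_cascade}} result.
#' @param design the design used for the fit.
#' @param cap cap of the display log10 fold change (default 5).
#' @return data.frame(contrast, fold_change, log10_fc, log10_fc_capped, p,
#'   model_family, note).
#' @export
contrast_groups <- function(cascade, design, cap = 5) {
  var <- design$exposure[1]
  lev <- levels(design$data[[var]])
  contrasts <- lev[-1]
  coefs <- cascade_coef_table(cascade)
  out <- lapply(contrasts, function(cl) {
    rn <- paste0(var, cl)
    if (!rn %in% rownames(coefs))
      return(data.frame(contrast = cl, fold_change = NA_real_,
                        log10_fc = NA_real_, log10_fc_capped = NA_real_,
                        p = NA_real_, model_family = cascade$family,
                        note = "non-estimable contrast",
                        stringsAsFactors = FALSE))
    est <- coefs[rn, 1]
    p <- coefs[rn, ncol(coefs)]
    fc <- if (cascade$family == "gls-log") 10^est else exp(est)
    l10 <- log10(fc)
    data.frame(contrast = cl, fold_change = fc, log10_fc = l10,
               log10_fc_capped = pmin(cap, pmax(-cap, l10)), p = p,
               model_family = cascade$family, note = "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Benjamini-Hochberg adjustment within declared families
#'
#' Adds step-up false-discovery-rate q values within each
#' timepoint-and-contrast family and the significance flag used for
#' reporting: \code{p < alpha} and \code{q < fdr} simultaneously.
#'
#' @param results data.frame with columns \code{p} and the \code{by} columns.
#' @param by columns defining the adjustment family.
#' @param alpha pointwise significance level (default 0.05).
#' @param fdr FDR gate (default 0.1).
#' @return \code{results} with \code{q} and \code{significant} columns.
#' @export
fdr_adjust <- function(results, by = c("timepoint", "contrast"),
                       alpha = 0.05, fdr = 0.1) {
  key <- interaction(results[, intersect(by, names(results)), drop = FALSE],
                     drop = TRUE)
  results$q <- NA_real_
  for (k in levels(key)) {
    i <- key == k
    results$q[i] <- stats::p.adjust(results$p[i], method = "BH")
  }
  results$significant <- !is.na(results$p) & results$p < alpha &
    results$q < fdr
  results
}

#' Taxon-wise differential abundance against the reference group
#'
#' Runs the model cascade for every sufficiently prevalent taxon at each
#' timepoint, contrasting each exposure group against the unexposed vaginally
#' born reference with covariate adjustment, and applies Benjamini-Hochberg
#' control within each timepoint-and-contrast family. Absolute abundances
#' (cells/g) are rounded to counts in units of \code{unit} cells/g before the
#' count-model fits; relative profiles are analyzed as counts per million.
#'
#' @param profile a \code{qmp_profile} (see \code{\link{absolute_profile}}).
#' @param cohort per-sample cohort frame (e.g. the simulator's
#'   \code{metadata}) with columns \code{sample_id}, \code{age_weeks},
#'   \code{group} and the adjustment covariates.
#' @param rank taxonomic rank to analyze (aggregated on the fly).
#' @param scale \code{"absolute"} or \code{"relative"}.
#' @param timepoints ages to analyze; default all in the cohort.
#' @param prevalence prevalence threshold (strict, default 0.30).
#' @param unit cells/g per count unit for the absolute scale (default 1e4).
#' @param covariates adjustment covariates passed to
#'   \code{\link{build_design}}.
#' @param alpha,fdr significance gates (defaults 0.05 and 0.1).
#' @param cap display cap of log10 fold changes.
#' @param min_group minimum samples a group needs at a timepoint to enter the
#'   design (default 3).
#' @return object of class \code{qmp_da}: the long-format result table plus
#'   metadata.
#' @export
qmp_da <- function(profile, cohort, rank = "family", scale = "absolute",
                   timepoints = NULL, prevalence = 0.30, unit = 1e4,
                   covariates = c("breastfeeding", "weeks_since_solids",
                                  "probiotics", "run", "protocol_modified"),
                   alpha = 0.05, fdr = 0.1, cap = 5, min_group = 3) {
  prof <- if (!is.null(rank) && !identical(rank, profile$rank))
    aggregate_rank(profile, rank) else profile
  rank_used <- prof$rank
  mat <- profile_matrix(prof, if (scale == "absolute") "absolute"
                        else "relative")
  ymat <- if (scale == "absolute") round(mat / unit) else round(mat * 1e6)
  cohort <- cohort[match(rownames(ymat), cohort$sample_id), , drop = FALSE]
  if (anyNA(cohort$sample_id))
    stop("cohort frame is missing samples present in the profile")
  if (is.null(timepoints)) timepoints <- sort(unique(cohort$age_weeks))
  res <- list()
  for (tp in timepoints) {
    design <- build_design(cohort, tp, exposure = "group",
                           covariates = covariates)
    # enforce minimum group size
    sizes <- table(design$data$group)
    keepg <- names(sizes)[sizes >= min_group]
    if (length(keepg) < 2 || !"VD" %in% keepg) next
    design$data <- droplevels(design$data[design$data$group %in% keepg, ,
                                          drop = FALSE])
    design$data$group <- stats::relevel(design$data$group, ref = "VD")
    ysub <- ymat[design$data$sample_id, , drop = FALSE]
    taxa <- prevalence_filter(ysub, prevalence)
    for (tx in taxa) {
      fit <- tryCatch(fit_cascade(ysub[, tx], design),
                      error = function(e) e)
      if (inherits(fit, "error")) {
        res[[length(res) + 1]] <- data.frame(
          taxon = tx, rank = rank_used, timepoint = tp,
          contrast = setdiff(keepg, "VD"), fold_change = NA_real_,
          log10_fc = NA_real_, log10_fc_capped = NA_real_, p = NA_real_,
          model_family = NA_character_, note = conditionMessage(fit),
          stringsAsFactors = FALSE)
        next
      }
      cc <- contrast_groups(fit, design, cap = cap)
      cc$taxon <- tx
      cc$rank <- rank_used
      cc$timepoint <- tp
      res[[length(res) + 1]] <- cc[, c("taxon", "rank", "timepoint",
                                       "contrast", "fold_change", "log10_fc",
                                       "log10_fc_capped", "p",
                                       "model_family", "note")]
    }
  }
  tab <- if (length(res)) do.call(rbind, res) else
    data.frame(taxon = character(0), rank = character(0),
               timepoint = numeric(0), contrast = character(0),
               fold_change = numeric(0), log10_fc = numeric(0),
               log10_fc_capped = numeric(0), p = numeric(0),
               model_family = character(0), note = character(0))
  tab <- fdr_adjust(tab, alpha = alpha, fdr = fdr)
  rownames(tab) <- NULL
  structure(list(results = tab, scale = scale, rank = rank_used,
                 reference = "VD", alpha = alpha, fdr = fdr, cap = cap,
                 prevalence = prevalence),
            class = "qmp_da")
}

#' @export
print.qmp_da <- function(x, ...) {
  cat(sprintf("<qmp_da> %s-scale, %s level, reference VD: %d tests, %d significant (P < %.2g & FDR < %.2g)\n",
              x$scale, x$rank, nrow(x$results), sum(x$results$significant),
              x$alpha, x$fdr))
  invisible(x)
}

#' @export
summary.qmp_da <- function(object, ...) {
  r <- object$results
  fam <- table(r$model_family[!duplicated(paste(r$taxon, r$timepoint))])
  sig <- r[r$significant, c("taxon", "timepoint", "contrast",
                            "log10_fc_capped", "p", "q", "model_family")]
  out <- list(n_tests = nrow(r), families = fam,
              significant = sig[order(sig$timepoint, sig$p), ])
  class(out) <- "summary.qmp_da"
  out
}

#' @export
print.summary.qmp_da <- function(x, ...) {
  cat(sprintf("%d taxon-wise tests; model families used:\n", x$n_tests))
  print(x$families)
  cat(sprintf("%d significant results:\n", nrow(x$significant)))
  print(x$significant, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Fold-change display matrix
#'
#' Reshapes a \code{\link{qmp_da}} result into a taxa x (timepoint, contrast)
#' matrix of capped log10 fold changes with significance stars, restricted to
#' taxa with at least one significant contrast.
#'
#' @param da a \code{qmp_da} object.
#' @return list with numeric matrix \code{log10_fc} and character matrix
#'   \code{stars}.
#' @export
da_matrix <- function(da) {
  r <- da$results
  keep <- unique(r$taxon[r$significant])
  r <- r[r$taxon %in% keep, , drop = FALSE]
  cols <- unique(paste(r$timepoint, r$contrast, sep = ":"))
  m <- matrix(NA_real_, length(keep), length(cols),
              dimnames = list(keep, cols))
  s <- matrix("", length(keep), length(cols), dimnames = list(keep, cols))
  for (i in seq_len(nrow(r))) {
    cl <- paste(r$timepoint[i], r$contrast[i], sep = ":")
    m[r$taxon[i], cl] <- r$log10_fc_capped[i]
    if (isTRUE(r$significant[i]))
      s[r$taxon[i], cl] <- if (r$p[i] < .001) "***" else
        if (r$p[i] < .01) "**" else "*"
  }
  list(log10_fc = m, stars = s)
}
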