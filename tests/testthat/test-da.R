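test_that("prevalence filter is strict at the threshold", {
  m <- cbind(kept = c(rep(1, 31), rep(0, 69)),
             dropped = c(rep(1, 30), rep(0, 70)))
  expect_equal(prevalence_filter(m, 0.30), "kept")
  # brute-force oracle on a random toy table
  set.seed(2)
  m2 <- matrix(rbinom(200, 1, 0.3), 20, 10,
               dimnames = list(NULL, paste0("t", 1:10)))
  expect_equal(prevalence_filter(m2, 0.30),
               colnames(m2)[colMeans(m2 > 0) > 0.30])
})

test_that("Benjamini-Hochberg adjustment matches the hand computation", {
  res <- data.frame(timepoint = 4, contrast = "CS-cep",
                    p = c(0.01, 0.02, 0.9))
  out <- fdr_adjust(res)
  expect_equal(out$q, c(0.03, 0.03, 0.9))
  # all P = 1: all q = 1, nothing significant
  res1 <- data.frame(timepoint = 4, contrast = "x", p = rep(1, 5))
  out1 <- fdr_adjust(res1)
  expect_equal(out1$q, rep(1, 5))
  expect_false(any(out1$significant))
  # significance needs both P < .05 and q < 0.1
  res2 <- data.frame(timepoint = 4, contrast = "x", p = c(0.04, 0.2))
  expect_equal(fdr_adjust(res2)$significant, c(TRUE, FALSE))
})

test_that("BH is applied within timepoint-and-contrast families", {
  res <- data.frame(timepoint = c(4, 4, 12, 12),
                    contrast = "CS-cep", p = c(0.05, 0.01, 0.05, 0.01))
  out <- fdr_adjust(res)
  expect_equal(out$q, p.adjust(c(0.05, 0.01), "BH")[c(1, 2, 1, 2)])
})

test_that("contrast extraction gives fold change 1 at coefficient zero and caps displays", {
  # noiseless two-group ratio 0.25 recovered through the cascade
  set.seed(8)
  df <- data.frame(group = rep(c("VD", "CS-cep"), each = 12),
                   sample_id = paste0("s", 1:24))
  des <- flat_design(df)
  y <- round(exp(log(2e5) + (des$data$group == "CS-cep") * log(0.25) +
                   rnorm(24, 0, 0.02)))
  fit <- fit_cascade(y, des)
  cc <- contrast_groups(fit, des)
  expect_equal(cc$fold_change, 0.25, tolerance = 0.02)
  expect_equal(cc$log10_fc_capped, log10(0.25), tolerance = 0.02)
  # identical groups: fold change ~ 1
  y0 <- round(exp(log(2e5) + rnorm(24, 0, 0.02)))
  cc0 <- contrast_groups(fit_cascade(y0, des), des)
  expect_equal(cc0$fold_change, 1, tolerance = 0.05)
  # capping at +/- 5 in log10
  res <- data.frame(timepoint = 1, contrast = "x", p = 0.5,
                    log10_fc = c(-8, 8))
  expect_equal(pmin(5, pmax(-5, res$log10_fc)), c(-5, 5))
})

test_that("the cascade selects families that match the data distribution", {
  set.seed(9)
  df <- data.frame(group = rep(c("VD", "CS-cep"), each = 30),
                   sample_id = paste0("s", 1:60))
  des <- flat_design(df)
  # NB data with moderate dispersion: negbin in a clear majority of runs
  fams <- replicate(40, {
    y <- rnbinom(60, mu = 50, size = 2)
    fit_cascade(y, des)$family
  })
  expect_gte(mean(fams == "negbin"), 0.7)
  # equidispersed Poisson data: the NB dispersion estimate degenerates and
  # the cascade falls back rather than erroring; poisson is the usual label
  fams2 <- replicate(40, {
    y <- rpois(60, 40)
    fit_cascade(y, des)$family
  })
  expect_true(all(fams2 %in% c("poisson", "negbin", "gls-log")))
  expect_gte(mean(fams2 == "poisson"), 0.3)
  # heteroscedastic log-normal data failing the count diagnostics: gls-log
  fams3 <- replicate(20, {
    y <- round(exp(rnorm(60, log(1e4) +
                           (des$data$group == "CS-cep") * 0.5,
                         ifelse(des$data$group == "CS-cep", 1.6, 0.5))))
    fit_cascade(y, des)$family
  })
  expect_gte(mean(fams3 == "gls-log"), 0.8)
})

test_that("the cascade is deterministic and never drops a taxon silently", {
  set.seed(10)
  df <- data.frame(group = rep(c("VD", "CS-cep"), each = 10),
                   sample_id = paste0("s", 1:20))
  des <- flat_design(df)
  y <- rnbinom(20, mu = 100, size = 1)
  f1 <- fit_cascade(y, des)
  f2 <- fit_cascade(y, des)
  expect_identical(f1$family, f2$family)
  expect_identical(coef(f1$fit), coef(f2$fit))
})

test_that("a planted large enrichment is estimated within a factor-two band", {
  # 18-fold enrichment, moderate noise, recovered by the full DA chain
  set.seed(12)
  ok <- replicate(10, {
    cfg <- sim_config(
      n_infants_per_group = c(VD = 30, "CS-cep" = 30), timepoints = 4,
      seed = sample.int(1e6, 1),
      group_effects = data.frame(taxon = "Streptococcus", group = "CS-cep",
                                 week_min = 1, week_max = 12,
                                 lfc = log(18)),
      mediation_spec = list(), contaminant_taxa = c())
    sim <- simulate_cohort(cfg)
    prof <- absolute_profile(sim$counts, sim$qpcr, sim$copy_numbers)
    da <- qmp_da(prof, sim$metadata, rank = "genus", timepoints = 4,
                 covariates = character(0))
    fc <- da$results$fold_change[da$results$taxon == "Streptococcus"]
    fc >= 9 && fc <= 36
  })
  expect_gte(mean(ok), 0.9)
})

test_that("differential abundance results carry complete bookkeeping", {
  sim <- small_sim()
  prof <- absolute_profile(sim$counts, sim$qpcr, sim$copy_numbers)
  da <- qmp_da(prof, sim$metadata, rank = "family", timepoints = 4)
  r <- da$results
  expect_true(all(c("taxon", "timepoint", "contrast", "fold_change",
                    "log10_fc_capped", "p", "q", "model_family",
                    "significant") %in% names(r)))
  expect_true(all(r$fold_change > 0, na.rm = TRUE))
  expect_true(all(r$q >= 0 & r$q <= 1, na.rm = TRUE))
  expect_true(all(abs(r$log10_fc_capped) <= 5, na.rm = TRUE))
  expect_true(all(r$model_family %in% c("negbin", "poisson", "quasipoisson",
                                        "gls-log"), na.rm = TRUE))
  # planted depletion of Bacteroidaceae in CS at week 4 is recovered
  hit <- r[r$taxon == "Bacteroidaceae" & r$contrast == "CS-cep", ]
  expect_true(hit$significant)
  expect_lt(hit$fold_change, 1)
  # the display matrix restricts to taxa with a significant contrast
  dm <- da_matrix(da)
  expect_true(all(rownames(dm$log10_fc) %in% unique(r$taxon[r$significant])))
})

test_that("the gls-log stage agrees with nlme::gls under group variance weights", {
  skip_if_not_installed("nlme")
  set.seed(20)
  df <- data.frame(group = rep(c("VD", "CS-cep", "VD-pen"), each = 12),
                   sample_id = paste0("s", 1:36))
  des <- flat_design(df)
  z <- rnorm(36, 5 + 0.5 * (des$data$group == "CS-cep"),
             ifelse(des$data$group == "VD-pen", 2, 0.8))
  X <- model.matrix(des$formula, des$data)
  f <- qmpinfant:::fgls_log(X, z, des$data$group)
  gl <- nlme::gls(z ~ group, data = data.frame(z = z, group = des$data$group),
                  weights = nlme::varIdent(form = ~ 1 | group))
  expect_equal(unname(f$ctab[, "estimate"]), unname(coef(gl)),
               tolerance = 1e-6)
  tt <- summary(gl)$tTable
  # P values agree up to the degrees-of-freedom convention (Satterthwaite
  # here, residual df in gls)
  expect_equal(unname(f$ctab[-1, "p"]), unname(tt[-1, 4]), tolerance = 0.05)
})

test_that("the in-package HC3 covariance matches sandwich::vcovHC", {
  skip_if_not_installed("sandwich")
  set.seed(21)
  df <- data.frame(group = rep(c("VD", "CS-cep"), each = 15),
                   sample_id = paste0("s", 1:30))
  des <- flat_design(df)
  dat <- des$data
  dat$.y <- rpois(30, 20 + 10 * (dat$group == "CS-cep"))
  f <- glm(.y ~ group, family = poisson(), data = dat, x = TRUE)
  expect_equal(qmpinfant:::glm_vcov_hc3(f),
               sandwich::vcovHC(f, type = "HC3"), tolerance = 1e-10)
  fnb <- suppressWarnings(MASS::glm.nb(.y ~ group, data = dat, x = TRUE))
  expect_equal(qmpinfant:::glm_vcov_hc3(fnb),
               sandwich::vcovHC(fnb, type = "HC3"), tolerance = 1e-8)
})
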