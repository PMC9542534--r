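test_that("blank subtraction removes the per-run mean blank count, floored at zero", {
  ct <- toy_counts()
  bl <- toy_blanks()
  out <- suppressWarnings(subtract_blank_contaminants(ct, bl))
  # run1 blank means: A = mean(20, 40) = 30, B = 30, C = 0
  expect_equal(out$counts["s1", "A"], 70)    # 100 - 30
  expect_equal(out$counts["s2", "A"], 30)    # 60 - 30
  expect_equal(out$counts["s1", "B"], 0)     # 10 - 30, floored
  expect_equal(out$counts["s1", "C"], 500)   # untouched taxon
  # run2 has no blank: passed through with a warning
  expect_warning(subtract_blank_contaminants(ct, bl), "no blank control")
  expect_equal(out$counts["s3", ], ct$counts["s3", ])
})

test_that("blank subtraction refuses re-application via provenance", {
  out <- suppressWarnings(subtract_blank_contaminants(toy_counts(),
                                                      toy_blanks()))
  expect_true(out$provenance$blanks_subtracted)
  expect_error(subtract_blank_contaminants(out, toy_blanks()),
               "already subtracted")
})

test_that("depth-proportional blank subtraction scales by sample depth", {
  ct <- toy_counts()
  bl <- toy_blanks()
  out <- suppressWarnings(
    subtract_blank_contaminants(ct, bl, method = "depth_proportional"))
  # run1: mean blank total = mean(50, 70) = 60; s1 total 610 -> scale 610/60
  expect_equal(out$counts["s1", "A"], max(0, round(100 - 610 / 60 * 30)))
})

test_that("rare-read filter zeroes taxa below the per-run total threshold", {
  ct <- toy_counts()
  # run1 totals: A = 160, B = 10, C = 800; run2: A = 80, B = 40, C = 250
  out <- filter_rare_reads(ct, min_count = 50)
  expect_equal(unname(out$counts[, "B"]), c(0, 0, 0))   # 10 < 50 and 40 < 50
  expect_equal(unname(out$counts[c("s1", "s2"), "A"]), c(100, 60))
  # min_count 1 is the identity
  expect_equal(filter_rare_reads(ct, 1)$counts, ct$counts)
  # brute-force oracle: taxon x run survives iff its run total >= threshold
  thr <- 100
  out2 <- filter_rare_reads(ct, thr)
  for (r in unique(ct$samples$run)) {
    in_run <- ct$samples$run == r
    for (tx in colnames(ct$counts)) {
      expected <- if (sum(ct$counts[in_run, tx]) < thr)
        rep(0L, sum(in_run)) else ct$counts[in_run, tx]
      expect_equal(unname(out2$counts[in_run, tx]), unname(expected))
    }
  }
})

test_that("coverage cutoff is inclusive and per cohort", {
  m <- matrix(c(1999L, 2000L, 120L, 119L), 4, 1,
              dimnames = list(paste0("s", 1:4), "A"))
  smp <- data.frame(sample_id = paste0("s", 1:4),
                    run = "run1", cohort = c("HELMi", "HELMi",
                                             "Jorvi", "Jorvi"))
  ct <- count_table(m, samples = smp)
  out <- apply_coverage_cutoff(ct, c(HELMi = 2000, Jorvi = 120))
  expect_setequal(rownames(out$counts), c("s2", "s3"))   # 1999 out, 120 in
  expect_equal(attr(out, "removed")$sample_id, c("s1", "s4"))
  expect_error(apply_coverage_cutoff(ct, c(HELMi = 2000)), "Jorvi")
  # manual tally oracle on a 10-sample toy
  set.seed(1)
  m2 <- matrix(rpois(10, 150), 10, 1,
               dimnames = list(paste0("x", 1:10), "A"))
  ct2 <- count_table(m2, samples = data.frame(
    sample_id = paste0("x", 1:10), run = "run1", cohort = "Jorvi"))
  out2 <- apply_coverage_cutoff(ct2, c(Jorvi = 150))
  expect_equal(nrow(out2$counts), sum(m2[, 1] >= 150))
})

test_that("relative abundance rows sum to one and zero-total samples error", {
  expect_equal(unname(relative_abundance(rbind(s = c(50, 50)))[1, ]),
               c(0.5, 0.5))
  expect_equal(unname(relative_abundance(rbind(s = c(0, 7)))[1, ]), c(0, 1))
  r <- relative_abundance(toy_counts())
  expect_equal(unname(rowSums(r)), rep(1, 3))
  m <- rbind(ok = c(1, 2), bad = c(0, 0))
  expect_error(relative_abundance(m), "bad")
})

test_that("absolute profiles follow the QMP arithmetic with copy-number correction", {
  # one sample, two equal taxa; copy numbers 3.5 and 5.5
  m <- rbind(s1 = c(Bifidobacterium = 500L, Clostridium = 500L))
  lin <- data.frame(taxon = c("Bifidobacterium", "Clostridium"),
                    class = c("Actinobacteria", "Clostridia"),
                    order = c("Bifidobacteriales", "Clostridiales"),
                    family = c("Bifidobacteriaceae", "Clostridiaceae"),
                    genus = c("Bifidobacterium", "Clostridium"))
  ct <- count_table(m, lin)
  qpcr <- data.frame(sample_id = "s1", copies_per_g = 1e10)
  prof <- absolute_profile(ct, qpcr)
  # relative 0.5, load 1e10 -> uncorrected 5e9; /5.5 -> ~9.09e8 cells/g
  expect_equal(unname(prof$uncorrected[1, "Clostridium"]), 5e9)
  expect_equal(unname(prof$corrected[1, "Clostridium"]), 5e9 / 5.5)
  expect_equal(unname(prof$corrected[1, "Bifidobacterium"]), 5e9 / 3.5)
  # equal reads: corrected ratio favors the low-copy taxon by 5.5/3.5
  expect_equal(unname(prof$corrected[1, "Bifidobacterium"] /
                        prof$corrected[1, "Clostridium"]), 5.5 / 3.5)
  # copy number 1 for all taxa: corrected equals uncorrected
  cn1 <- data.frame(name = c("Bifidobacteriaceae", "Clostridiaceae"),
                    rank = "family", mean16S = 1)
  prof1 <- absolute_profile(ct, qpcr, cn1)
  expect_equal(prof1$corrected, prof1$uncorrected)
})

test_that("copy-number resolution falls back genus -> family -> order -> class -> global", {
  lin <- data.frame(taxon = c("g1", "g2", "g3", "g4", "g5"),
                    class = c("C1", "C1", "C1", "C1", "Cx"),
                    order = c("O1", "O1", "O1", "Ox", "Ox"),
                    family = c("F1", "F1", "Fx", "Fx", "Fx"),
                    genus = c("g1", "g2", "g3", "g4", "g5"))
  cn <- data.frame(name = c("g1", "F1", "O1", "C1"),
                   rank = c("genus", "family", "order", "class"),
                   mean16S = c(2, 3, 4, 5))
  res <- resolve_copy_numbers(lin, cn)
  expect_equal(res$copy_number, c(2, 3, 4, 5, mean(c(2, 3, 4, 5))))
  expect_equal(res$source, c("genus", "family", "order", "class",
                             "global-mean"))
})

test_that("per-sample uncorrected abundances conserve the qPCR load", {
  sim <- small_sim()
  prof <- absolute_profile(sim$counts, sim$qpcr, sim$copy_numbers)
  rel_err <- abs(rowSums(prof$uncorrected) - prof$load) / prof$load
  expect_lt(max(rel_err), 1e-9)
})

test_that("samples without qPCR values are excluded with a message", {
  sim <- small_sim()
  qp <- sim$qpcr[-(1:3), ]
  expect_message(prof <- absolute_profile(sim$counts, qp, sim$copy_numbers),
                 "3 sample")
  expect_equal(nrow(prof$corrected), nrow(sim$counts$counts) - 3)
})

test_that("rank aggregation sums lineages and preserves proportion totals", {
  ct <- toy_counts()
  qpcr <- data.frame(sample_id = c("s1", "s2", "s3"),
                     copies_per_g = c(1e9, 2e9, 3e9))
  cn <- data.frame(name = c("Fa", "Fb"), rank = "family", mean16S = c(2, 4))
  prof <- absolute_profile(ct, qpcr, cn)
  fam <- aggregate_rank(prof, "family")
  # two genera of one family: family value = sum
  expect_equal(unname(fam$corrected[, "Fa"]),
               unname(prof$corrected[, "A"] + prof$corrected[, "B"]))
  expect_equal(unname(rowSums(fam$relative)), rep(1, 3))
  # brute-force group-sum oracle at class level
  cl <- aggregate_rank(prof, "class")
  brute <- t(rowsum(t(prof$corrected), prof$lineage$class))
  expect_equal(cl$corrected[, colnames(brute)], brute)
  expect_error(aggregate_rank(prof, "species"))
})

test_that("rank-constant copy numbers preserve within-rank ranking", {
  sim <- small_sim()
  prof <- absolute_profile(sim$counts, sim$qpcr, sim$copy_numbers)
  fams <- unique(prof$lineage$family)
  for (fm in fams[1:5]) {
    taxa <- prof$lineage$taxon[prof$lineage$family == fm]
    if (length(taxa) < 2) next
    ranks_unc <- t(apply(prof$uncorrected[1:20, taxa, drop = FALSE], 1, rank))
    ranks_cor <- t(apply(prof$corrected[1:20, taxa, drop = FALSE], 1, rank))
    # same copy number within the family: correction cannot reorder
    if (length(unique(prof$copy_source$copy_number[
      match(taxa, prof$copy_source$taxon)])) == 1)
      expect_equal(ranks_unc, ranks_cor)
  }
})

test_that("corrected profiles track true cell densities within qPCR noise", {
  sim <- small_sim()
  ct <- suppressWarnings(subtract_blank_contaminants(sim$counts, sim$blanks))
  prof <- absolute_profile(ct, sim$qpcr, sim$copy_numbers)
  truth <- sim$truth$true_cells[rownames(prof$corrected),
                                colnames(prof$corrected)]
  # restrict to well-measured cells to avoid read-sampling dominated ones
  big <- truth > 1e7 & prof$corrected > 0
  rel_err <- abs(prof$corrected[big] - truth[big]) / truth[big]
  expect_lt(median(rel_err), 2 * sim$config$qpcr_cv)
})
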