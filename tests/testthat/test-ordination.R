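test_that("PCoA distances equal the brute-force 1 - Pearson computation", {
  set.seed(13)
  m <- matrix(rexp(40, 1e-6), 5, 8,
              dimnames = list(paste0("s", 1:5), paste0("t", 1:8)))
  ord <- pcoa_pearson(m, pseudocount = 1)
  x <- log10(m + 1)
  brute <- 1 - cor(t(x))
  expect_lt(max(abs(ord$distance - brute)), 1e-12)
  expect_true(all(diff(ord$eig) <= 1e-8))   # eigenvalues non-increasing
})

test_that("duplicated samples sit at distance zero with identical coordinates", {
  set.seed(14)
  m <- matrix(rexp(30, 1e-6), 6, 5,
              dimnames = list(paste0("s", 1:6), paste0("t", 1:5)))
  m[2, ] <- m[1, ]
  ord <- pcoa_pearson(m)
  expect_equal(ord$distance["s1", "s2"], 0)
  # identical on all informative (positive-eigenvalue) axes
  informative <- which(ord$eig[seq_len(ncol(ord$points))] >
                         1e-8 * max(ord$eig))
  expect_equal(ord$points["s1", informative], ord$points["s2", informative],
               tolerance = 1e-8)
})

test_that("orthogonal profile clusters separate on the first axis", {
  set.seed(15)
  base1 <- c(rep(8, 5), rep(0, 5))
  base2 <- c(rep(0, 5), rep(8, 5))
  m <- 10^rbind(t(replicate(6, base1 + rnorm(10, 0, 0.3))),
                t(replicate(6, base2 + rnorm(10, 0, 0.3))))
  rownames(m) <- paste0("s", 1:12)
  colnames(m) <- paste0("t", 1:10)
  ord <- pcoa_pearson(m)
  within <- c(ord$distance[1:6, 1:6][upper.tri(diag(6))],
              ord$distance[7:12, 7:12][upper.tri(diag(6))])
  between <- ord$distance[1:6, 7:12]
  expect_gt(min(between), max(within))
  expect_gt(abs(mean(ord$points[1:6, 1]) - mean(ord$points[7:12, 1])),
            2 * sd(ord$points[, 2]))
})

test_that("constant sample vectors are excluded with a note", {
  m <- matrix(rexp(24, 1e-6), 6, 4,
              dimnames = list(paste0("s", 1:6), paste0("t", 1:4)))
  m[3, ] <- 1e6   # constant log vector: undefined correlation
  expect_message(ord <- pcoa_pearson(m), "s3")
  expect_false("s3" %in% rownames(ord$points))
})

test_that("coordinates reproduce a Euclidean-embeddable distance matrix", {
  set.seed(16)
  # a configuration whose 1-r matrix is fully embeddable has only
  # non-negative eigenvalues; check distance reproduction through the
  # Gram route on such a case
  m <- matrix(rexp(16, 1e-6), 4, 4,
              dimnames = list(paste0("s", 1:4), paste0("t", 1:4)))
  ord <- pcoa_pearson(m, k = 3)
  if (ord$negative_eigenvalue_magnitude < 1e-10) {
    rec <- as.matrix(dist(ord$points))
    expect_lt(max(abs(rec - ord$distance)), 1e-8)
  }
  # and on an exactly Euclidean input: squared distances of points in the
  # plane embed without negative eigenvalues
  pts <- cbind(c(0, 3, 0, 3), c(0, 0, 4, 4))
  d <- as.matrix(dist(pts))
  sc <- cmdscale(as.dist(d), k = 3, eig = TRUE)
  expect_lt(max(abs(as.matrix(dist(sc$points[, 1:2])) - d)), 1e-8)
})

test_that("group separation tests behave at both extremes", {
  set.seed(17)
  # strong separation: two shifted clusters
  m <- 10^rbind(t(replicate(10, c(rep(7, 4), rep(3, 4)) + rnorm(8, 0, 0.2))),
                t(replicate(10, c(rep(3, 4), rep(7, 4)) + rnorm(8, 0, 0.2))))
  rownames(m) <- paste0("s", 1:20)
  colnames(m) <- paste0("t", 1:8)
  cohort <- data.frame(sample_id = paste0("s", 1:20),
                       age_weeks = 4,
                       group = rep(c("VD", "CS-cep"), each = 10))
  ord <- pcoa_pearson(m)
  tst <- test_group_separation(ord, cohort, 4)
  expect_lt(min(tst$p), 0.001)
  # groups with < 2 samples are excluded with a note
  cohort2 <- cohort
  cohort2$group[1] <- "VD-pen"
  tst2 <- test_group_separation(ord, cohort2, 4)
  expect_equal(attr(tst2, "excluded_groups"), "VD-pen")
})

test_that("median trajectories equal brute-force group medians", {
  sim <- small_sim()
  prof <- absolute_profile(sim$counts, sim$qpcr, sim$copy_numbers)
  ord <- pcoa_pearson(prof)
  med <- median_trajectories(ord, sim$metadata)
  pick <- med[med$group == "VD" & med$age_weeks == 4, ]
  ids <- sim$metadata$sample_id[sim$metadata$group == "VD" &
                                  sim$metadata$age_weeks == 4]
  ids <- intersect(ids, rownames(ord$points))
  expect_equal(pick$PC1, median(ord$points[ids, 1]))
  expect_equal(pick$PC2, median(ord$points[ids, 2]))
})

test_that("trajectory smoothing is exact for flat data and bands shrink with level", {
  cohort <- data.frame(sample_id = paste0("s", 1:40),
                       age_weeks = rep(c(4, 8, 16, 32), 10))
  m <- matrix(1e6, 40, 1, dimnames = list(cohort$sample_id, "TaxA"))
  tr <- suppressWarnings(smooth_class_trajectories(m, cohort, "TaxA"))
  expect_equal(tr$mean, rep(log10(1e6 + 1), nrow(tr)), tolerance = 1e-8)
  expect_true(all(tr$lower <= tr$mean & tr$mean <= tr$upper))
  # linear trend in log abundance: smooth stays inside its own band and
  # tracks the generating line
  set.seed(18)
  age <- rep(seq(4, 36, by = 4), each = 6)
  y <- 10^(3 + 0.05 * age + rnorm(length(age), 0, 0.1))
  m2 <- matrix(y, ncol = 1,
               dimnames = list(paste0("x", seq_along(age)), "TaxB"))
  cohort2 <- data.frame(sample_id = rownames(m2), age_weeks = age)
  tr2 <- smooth_class_trajectories(m2, cohort2, "TaxB", level = 0.95)
  line <- 3 + 0.05 * tr2$age_weeks
  expect_true(mean(tr2$lower <= line & line <= tr2$upper) > 0.9)
  # 30% band strictly narrower than 95% band on the same data
  tr30 <- smooth_class_trajectories(m2, cohort2, "TaxB", level = 0.30)
  expect_true(all(tr30$upper - tr30$lower < tr2$upper - tr2$lower))
  # absent taxon: skipped with a note
  expect_message(smooth_class_trajectories(m2, cohort2, c("TaxB", "Nope")),
                 "Nope")
})
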