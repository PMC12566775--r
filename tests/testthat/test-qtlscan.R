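test_that("logistic marker test handles separation and degeneracy", {
  # marker identical to the phenotype: complete separation, tiny p
  g <- rep(c(0L, 2L), each = 59)
  y <- rep(c(0L, 1L), each = 59)
  res <- logistic_marker_test(g, y)
  expect_lt(res$pvalue, 1e-6)
  # factor LRT equals the 2xK G-test of the contingency table
  g2 <- c(rep(0L, 30), rep(1L, 60), rep(2L, 28))
  set.seed(301)
  y2 <- rbinom(118, 1, stats::plogis(0.8 * (g2 - 1)))
  res2 <- logistic_marker_test(g2, y2)
  fit <- stats::glm(y2 ~ factor(g2), family = binomial())
  expect_equal(res2$statistic, fit$null.deviance - fit$deviance,
               tolerance = 1e-8)
  expect_equal(res2$df, 2L)
  # monomorphic marker: missing with reason
  res3 <- logistic_marker_test(rep(1L, 50), rbinom(50, 1, 0.5))
  expect_true(is.na(res3$pvalue))
  expect_match(res3$reason, "monomorphic")
  # additive coding under separation: ridge keeps the statistic finite
  res4 <- logistic_marker_test(g, y, coding = "additive")
  expect_true(res4$ridge_active)
  expect_true(is.finite(res4$statistic))
  expect_lt(res4$pvalue, 1e-6)
})

test_that("null logistic p-values are approximately uniform", {
  set.seed(302)
  n <- 200
  p <- replicate(400, {
    g <- sample(c(0L, 1L, 2L), n, replace = TRUE, prob = c(.25, .5, .25))
    logistic_marker_test(g, rbinom(n, 1, 0.5))$pvalue
  })
  expect_lt(abs(mean(p < 0.1) - 0.1), 3 * sqrt(0.1 * 0.9 / 400))
  expect_lt(abs(mean(p) - 0.5), 3 * sqrt(1 / 12 / 400))
})

test_that("BH selection matches the hand computation", {
  sc <- make_bins(matrix(c(0L, 1L, 2L), 3, 10), pos_cM = c(10, 20, 30))
  scan <- data.frame(chrom = "chr1", pos_bp = 1:3, pos_cM = c(10, 20, 30),
                     pvalue = c(1e-8, 0.5, 0.9), df = 2L, n = 10)
  attr(scan, "statistic") <- "pvalue"
  class(scan) <- c("qtl_scan", "data.frame")
  hit <- fdr_significant(scan, q = 0.01)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$pvalue, 1e-8)
  expect_equal(hit$padj, 3e-8)
  scan$pvalue <- rep(1, 3)
  expect_equal(nrow(fdr_significant(scan, 0.01)), 0)
  expect_equal(nrow(fdr_significant(scan[0, ], 0.01)), 0)
})

test_that("genome scan recovers a strong simulated QTL", {
  set.seed(303)
  n <- 118
  g_qtl <- sample(c(0L, 1L, 2L), n, replace = TRUE, prob = c(.25, .5, .25))
  y <- rbinom(n, 1, stats::plogis(1.5 * (g_qtl - 1)))
  G <- rbind(g_qtl,
             matrix(sample(c(0L, 1L, 2L), n * 20, replace = TRUE), 20, n))
  bmm <- make_bins(G, pos_cM = seq(5, 105, by = 5))
  scan <- genome_scan_logistic(bmm, y)
  expect_s3_class(scan, "qtl_scan")
  expect_equal(nrow(scan), 21)
  expect_equal(which.min(scan$pvalue), 1L)
  # single-bin matrix: scan of length 1
  one <- genome_scan_logistic(make_bins(matrix(g_qtl, 1, n), 10), y)
  expect_equal(nrow(one), 1)
})

test_that("permutation threshold is deterministic and degenerates correctly", {
  set.seed(304)
  G <- matrix(sample(c(0L, 1L, 2L), 30 * 60, replace = TRUE), 30, 60)
  bmm <- make_bins(G, pos_cM = seq(2, 60, by = 2))
  y <- rep(c(0L, 1L), 30)
  t1 <- permutation_threshold(bmm, y, "logistic", n_perm = 100, seed = 42)
  t2 <- permutation_threshold(bmm, y, "logistic", n_perm = 100, seed = 42)
  expect_identical(t1$threshold, t2$threshold)
  # alpha = 1 with min-p extrema: the maximum over permutations
  t3 <- permutation_threshold(bmm, y, "logistic", n_perm = 100, alpha = 1,
                              seed = 43)
  expect_equal(t3$threshold, max(t3$extrema))
  expect_error(permutation_threshold(bmm, y, "logistic", n_perm = 50),
               "at least 100")
})

test_that("interval LOD equals the single-marker LOD at informative markers", {
  set.seed(305)
  gmap <- uniform_genetic_map(1, 60)
  for (rep in 1:10) {
    n <- 80
    G <- matrix(sample(c(0L, 1L, 2L), 5 * n, replace = TRUE), 5, n)
    bmm <- make_bins(G, pos_cM = c(5, 18, 30, 42, 55))
    y <- rbinom(n, 1, stats::plogis(0.9 * (G[3, ] - 1)))
    if (length(unique(y)) < 2) next
    scan <- interval_scan_binary(bmm, gmap, y, step_cM = 5)
    for (m in 1:5) {
      at <- which(scan$pos_cM == bmm$bins$rep_pos_cM[m])
      expect_equal(scan$lod[at], single_marker_lod(G[m, ], y),
                   tolerance = 1e-6)
    }
    # agreement with the 2-df logistic LRT: LOD = LRT / (2 ln 10)
    lg <- genome_scan_logistic(bmm, y)
    lrt <- qchisq(lg$pvalue, lg$df, lower.tail = FALSE)
    at_markers <- match(bmm$bins$rep_pos_cM, scan$pos_cM)
    expect_equal(scan$lod[at_markers], lrt / (2 * log(10)),
                 tolerance = 1e-6)
  }
})

test_that("interval scan is null for constant phenotypes and handles gaps", {
  set.seed(306)
  G <- matrix(sample(c(0L, 1L, 2L), 4 * 40, replace = TRUE), 4, 40)
  gmap <- uniform_genetic_map(1, 100)
  bmm <- make_bins(G, pos_cM = c(20, 30, 70, 80))
  y <- rep(1L, 40)
  suppressWarnings(scan <- interval_scan_binary(bmm, gmap, y, step_cM = 2))
  expect_lt(max(scan$lod), 1e-9)
  # missing flank: positions before the first marker are still scored
  y2 <- rbinom(40, 1, 0.5)
  G2 <- G
  G2[1, 1:20] <- NA
  bmm2 <- make_bins(G2, pos_cM = c(20, 30, 70, 80))
  scan2 <- interval_scan_binary(bmm2, gmap, y2, step_cM = 10)
  expect_true(all(is.finite(scan2$lod)))
  expect_true(all(scan2$lod >= 0))
})

test_that("interval LOD is invariant to relabeling and padding markers", {
  set.seed(307)
  n <- 60
  G <- matrix(sample(c(0L, 1L, 2L), 4 * n, replace = TRUE), 4, n)
  gmap <- uniform_genetic_map(1, 60)
  bmm <- make_bins(G, pos_cM = c(10, 25, 40, 55))
  y <- rbinom(n, 1, 0.5)
  s1 <- interval_scan_binary(bmm, gmap, y, step_cM = 5)
  perm <- sample(n)
  bmm_p <- make_bins(G[, perm], pos_cM = c(10, 25, 40, 55))
  s2 <- interval_scan_binary(bmm_p, gmap, y[perm], step_cM = 5)
  expect_equal(s1$lod, s2$lod, tolerance = 1e-9)
  # an extra monomorphic marker changes nothing at the other positions
  Gm <- rbind(G[1:2, ], rep(2L, n), G[3:4, ])
  bmm_m <- make_bins(Gm, pos_cM = c(10, 25, 32, 40, 55))
  s3 <- interval_scan_binary(bmm_m, gmap, y, step_cM = 5)
  shared <- match(s1$pos_cM, s3$pos_cM)
  expect_equal(s3$lod[shared], s1$lod, tolerance = 1e-6)
})

test_that("peak calling groups, merges and tie-breaks as specified", {
  mk_scan <- function(lod, pos_cM, chrom = "chr1") {
    s <- data.frame(chrom = chrom, pos_bp = pos_cM * 1e6, pos_cM = pos_cM,
                    lod = lod, n = 100)
    attr(s, "statistic") <- "lod"
    class(s) <- c("qtl_scan", "data.frame")
    s
  }
  # flat scan below threshold: nothing
  expect_equal(nrow(find_peaks(mk_scan(rep(1, 50), 1:50), 3)), 0)
  # two bumps 100 cM apart: two peaks
  lod <- rep(0.5, 121)
  lod[c(10, 110)] <- c(5, 6)
  lod[c(9, 11, 109, 111)] <- 4
  pk <- find_peaks(mk_scan(lod, 0:120), 3)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$peak_pos_cM, c(9, 109))
  expect_equal(pk$lod, c(5, 6))
  # plateau of equal LOD: leftmost reported
  lod2 <- rep(0, 30)
  lod2[10:15] <- 4
  pk2 <- find_peaks(mk_scan(lod2, 1:30), 3)
  expect_equal(pk2$peak_pos_cM, 10)
  # peaks closer than min_separation merge keeping the higher
  lod3 <- rep(0, 60)
  lod3[10] <- 4
  lod3[30] <- 5
  pk3 <- find_peaks(mk_scan(lod3, 1:60), 3, min_separation_cM = 30)
  expect_equal(nrow(pk3), 1)
  expect_equal(pk3$peak_pos_cM, 30)
})

test_that("support intervals follow the LOD-drop rule", {
  lod <- c(1, 2, 4, 5.5, 6.9, 5.5, 4.5, 3, 1)
  s <- data.frame(chrom = "chr1", pos_bp = (1:9) * 1e6, pos_cM = (1:9) * 10,
                  lod = lod, n = 100)
  attr(s, "statistic") <- "lod"
  class(s) <- c("qtl_scan", "data.frame")
  pk <- find_peaks(s, 3)
  iv <- lod_support_interval(s, pk[1, ], drop = 1.5)
  # cutoff 5.4: positions 4..6 qualify
  expect_equal(unname(iv), c(4e6, 6e6))
  # drop = 0 degenerates to the peak plateau
  iv0 <- lod_support_interval(s, pk[1, ], drop = 0)
  expect_equal(unname(iv0), c(5e6, 5e6))
  # monotone decrease: first crossings are the endpoints
  iv2 <- lod_support_interval(s, pk[1, ], drop = 3)
  expect_equal(unname(iv2), c(3e6, 7e6))
  sup <- support_intervals(pk, s, 1.5)
  expect_equal(sup$interval_start_bp, 4e6)
})

test_that("variance explained follows the LOD identity", {
  expect_equal(variance_explained(0, 118), 0)
  expect_equal(variance_explained(59, 118), 90)  # n/2 -> 100(1 - 10^-1)
  expect_error(variance_explained(1, 0), "positive")
  # joint fit of a strong marker explains a sizeable fraction
  set.seed(308)
  n <- 118
  g <- sample(c(0L, 1L, 2L), n, replace = TRUE, prob = c(.25, .5, .25))
  y <- rbinom(n, 1, stats::plogis(2 * (g - 1)))
  bmm <- make_bins(rbind(g, sample(g)), pos_cM = c(10, 50))
  pk <- find_peaks(interval_scan_binary(bmm, uniform_genetic_map(1, 60), y,
                                        step_cM = 10), 1)
  joint <- fit_joint_qtl(bmm, y, pk)
  expect_gt(joint$variance_explained_pct, 15)
  expect_lte(joint$variance_explained_pct, 100)
})

test_that("genotype class summaries call favorable allele and dominance", {
  # AB exactly midway: additive
  g <- c(rep(2L, 40), rep(1L, 40), rep(0L, 40))
  y <- c(rep(1L, 32), rep(0L, 8),   # AA: 80% Type II
         rep(1L, 20), rep(0L, 20),  # AB: 50%
         rep(1L, 8), rep(0L, 32))   # BB: 20%
  s <- genotype_class_summary(g, y)
  expect_equal(s$favorable_allele, "A188")
  expect_equal(s$dominance_call, "additive")
  expect_equal(unname(s$props), c(0.8, 0.5, 0.2))
  expect_equal(sum(s$table), 120)
  # AB equal to a homozygote: dominant
  y2 <- c(rep(1L, 32), rep(0L, 8), rep(1L, 32), rep(0L, 8),
          rep(1L, 8), rep(0L, 32))
  expect_equal(genotype_class_summary(g, y2)$dominance_call, "dominant")
  # B73-favorable orientation
  s3 <- genotype_class_summary(g, 1L - y)
  expect_equal(s3$favorable_allele, "B73")
  # empty genotype class: dominance withheld
  g4 <- c(rep(2L, 40), rep(0L, 40))
  y4 <- rep(c(1L, 0L), 40)
  s4 <- genotype_class_summary(g4, y4)
  expect_true(is.na(s4$dominance_call))
  expect_error(genotype_class_summary(rep(1L, 10), rep(0:1, 5)),
               "polymorphic")
})

test_that("scan power is monotone in the effect size", {
  set.seed(309)
  n <- 200
  mean_lrt <- vapply(c(0.3, 0.8, 1.5), function(beta) {
    mean(replicate(60, {
      g <- sample(c(0L, 1L, 2L), n, replace = TRUE, prob = c(.25, .5, .25))
      y <- rbinom(n, 1, stats::plogis(beta * (g - 1)))
      logistic_marker_test(g, y)$statistic
    }))
  }, numeric(1))
  expect_true(all(diff(mean_lrt) > 0))
})
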