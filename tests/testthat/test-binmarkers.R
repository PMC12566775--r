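test_that("segmentation of clean runs is exact", {
  # 100 consecutive AA calls: one AA segment
  gm <- make_gm(matrix(2L, 100, 1))
  seg <- call_segments(gm)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$genotype, "AA")
  expect_equal(seg$n_snps, 100)
  expect_equal(count_recombination_events(seg), 0L)

  # 50 AA then 50 BB: two segments split at the inter-SNP midpoint
  gm2 <- make_gm(matrix(c(rep(2L, 50), rep(0L, 50)), ncol = 1),
                 spacing_bp = 1000)
  seg2 <- call_segments(gm2)
  expect_equal(seg2$genotype, c("AA", "BB"))
  mid <- floor((50 * 1000 + 51 * 1000) / 2)
  expect_equal(seg2$end_bp[1], mid)
  expect_equal(seg2$start_bp[2], mid + 1)
  expect_equal(count_recombination_events(seg2), 1L)
})

test_that("smoothing and absorption remove isolated wrong calls", {
  x <- rep(2L, 50)
  x[25] <- 0L
  seg <- call_segments(make_gm(matrix(x, ncol = 1)),
                       smooth_window = 5, min_snps_per_segment = 3)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$genotype, "AA")
  # a short 2-SNP blip is absorbed even when it survives smoothing
  x2 <- c(rep(2L, 20), rep(0L, 2), rep(2L, 20))
  seg2 <- call_segments(make_gm(matrix(x2, ncol = 1)),
                        smooth_window = 1, min_snps_per_segment = 3)
  expect_equal(seg2$genotype, "AA")
  expect_equal(seg2$n_snps, 42)
})

test_that("missing calls and empty chromosomes are tolerated", {
  x <- c(rep(2L, 10), rep(NA_integer_, 5), rep(2L, 10),
         rep(NA_integer_, 25))
  gm <- make_gm(matrix(x, ncol = 1), chrom = rep(c("chr1", "chr2"), each = 25))
  seg <- call_segments(gm)
  expect_equal(unique(seg$chrom), "chr1")  # chr2 has no calls: no rows
  expect_equal(nrow(seg), 1)
  expect_equal(seg$n_snps, 20)
})

test_that("expected recombination count is 2 x map Morgans", {
  expect_equal(expected_recombination_count(uniform_genetic_map(10, 100)), 20)
  zmap <- genetic_map(data.frame(chrom = "c1", pos_bp = c(1, 10),
                                 pos_cM = c(0, 0)))
  expect_equal(expected_recombination_count(zmap), 0)
  # matches the mean discernible count over error-free simulated F2s
  gmap <- uniform_genetic_map(3, 100)
  cfg <- sim_config(map = gmap, qtls = NULL,
                    n_embryos = 150, n_select_per_class = 40,
                    snp_density = 5, seed = 201)
  sim <- simulate_f2(cfg)
  tg <- truth_genotypes(sim, sim$ids)
  segs <- call_segments_all(tg, smooth_window = 1, min_snps_per_segment = 1)
  counts <- vapply(segs, count_recombination_events, integer(1))
  expd <- expected_recombination_count(gmap)
  se <- sqrt(expd / length(counts))  # Poisson spread
  expect_lt(abs(mean(counts) - expd), 4 * se)
})

test_that("error-free segmentation reproduces the true crossovers", {
  gmap <- uniform_genetic_map(3, 100)
  cfg <- sim_config(map = gmap, qtls = NULL,
                    n_embryos = 80, n_select_per_class = 20,
                    snp_density = 5, seed = 202)
  sim <- simulate_f2(cfg)
  tg <- truth_genotypes(sim, sim$ids[1:30])
  for (id in sim$ids[1:30]) {
    seg <- call_segments(tg, id, smooth_window = 1, min_snps_per_segment = 1)
    expect_equal(count_recombination_events(seg),
                 truth_transition_count(sim, id))
    runs <- truth_runs(tg, id)
    called <- split(seg, seg$chrom)
    for (ch in names(called)) {
      expect_equal(called[[ch]]$genotype,
                   dosage_to_code(runs[[ch]]$values))
      expect_equal(called[[ch]]$n_snps, runs[[ch]]$lengths)
    }
  }
})

test_that("segmentation is idempotent", {
  set.seed(203)
  x <- c(rep(2L, 30), rep(1L, 40), rep(0L, 30))
  x[sample(100, 10)] <- NA_integer_
  gm <- make_gm(matrix(x, ncol = 1))
  seg1 <- call_segments(gm)
  rebuilt <- make_gm(matrix(calls_from_segments(seg1, gm$sites), ncol = 1))
  seg2 <- call_segments(rebuilt)
  expect_equal(seg2$genotype, seg1$genotype)
  expect_equal(count_recombination_events(seg2),
               count_recombination_events(seg1))
})

test_that("recombination count is recovered under mild genotyping error", {
  # <= 1% error at dense SNP coverage: count matches truth in >= 95% of
  # individuals (losses come from true segments spanning < 3 observed SNPs)
  gmap <- uniform_genetic_map(3, 80)
  cfg <- sim_config(map = gmap, qtls = NULL,
                    n_embryos = 130, n_select_per_class = 30,
                    snp_density = 10, seed = 204)
  sim <- simulate_f2(cfg)
  tg <- truth_genotypes(sim, sim$ids[1:60])
  set.seed(205)
  gm <- degrade_to_gbs(tg, missing_rate = 0.05, genotype_error_rate = 0.01,
                       het_undercall_rate = 0)
  hits <- vapply(sim$ids[1:60], function(id) {
    seg <- call_segments(gm, id)
    count_recombination_events(seg) == truth_transition_count(sim, id)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("excess-recombination filtering drops error-inflated individuals", {
  segs <- list(
    a = structure(data.frame(chrom = rep("chr1", 3), start_bp = c(1, 11, 21),
                             end_bp = c(10, 20, 30),
                             genotype = c("AA", "AB", "BB"),
                             n_snps = c(5, 5, 5)),
                  class = c("segment_set", "data.frame")),
    b = structure(data.frame(chrom = "chr1", start_bp = 1, end_bp = 30,
                             genotype = "AA", n_snps = 15),
                  class = c("segment_set", "data.frame")))
  flt <- filter_individuals(segs, expected = 2, multiplier = 2)
  expect_equal(flt$retained, c("a", "b"))  # count 2 == expectation: kept
  flt2 <- filter_individuals(segs, expected = 0.19, multiplier = 2)
  expect_equal(flt2$dropped, "a")
  expect_error(filter_individuals(segs, 2, multiplier = 1), "exceed")
})

test_that("bin harmonization refines boundaries and keeps calls consistent", {
  # two individuals, one offset boundary -> 3 raw bins; the two flanking the
  # offset disagree between individuals, the shared outer parts merge
  seg_a <- structure(data.frame(chrom = "chr1", start_bp = c(1, 501),
                                end_bp = c(500, 1000),
                                genotype = c("AA", "BB"), n_snps = c(5, 5)),
                     class = c("segment_set", "data.frame"))
  seg_b <- structure(data.frame(chrom = "chr1", start_bp = c(1, 701),
                                end_bp = c(700, 1000),
                                genotype = c("AA", "BB"), n_snps = c(6, 4)),
                     class = c("segment_set", "data.frame"))
  gmap <- genetic_map(data.frame(chrom = "chr1", pos_bp = c(1, 1000),
                                 pos_cM = c(0, 1)))
  bmm <- harmonize_bins(list(a = seg_a, b = seg_b), gmap)
  # the only polymorphic stretch is (501..700): a=BB, b=AA
  expect_equal(nrow(bmm$bins), 1)
  expect_equal(bmm$bins$start_bp, 501)
  expect_equal(bmm$bins$end_bp, 700)
  expect_equal(unname(bmm$geno[1, ]), c(0L, 2L))
  expect_error(harmonize_bins(list(a = seg_a), gmap), "at least 2")
})

test_that("bin calls agree with the covering segment for every individual", {
  gmap <- uniform_genetic_map(2, 80)
  cfg <- sim_config(map = gmap, qtls = NULL,
                    n_embryos = 50, n_select_per_class = 12,
                    snp_density = 3, seed = 206)
  sim <- simulate_f2(cfg)
  tg <- truth_genotypes(sim, sim$ids[1:12])
  set.seed(207)
  gm <- degrade_to_gbs(tg, 0.1, 0.01, 0.05)
  segs <- call_segments_all(gm)
  bmm <- harmonize_bins(segs, gmap)
  for (id in sample(colnames(tg$geno), 4)) {
    seg <- segs[[id]]
    for (b in sample(nrow(bmm$bins), 20, replace = TRUE)) {
      s <- seg[seg$chrom == bmm$bins$chrom[b] &
                 seg$start_bp <= bmm$bins$start_bp[b] &
                 seg$end_bp >= bmm$bins$end_bp[b], ]
      expected_call <- if (nrow(s)) code_to_dosage(s$genotype) else NA_integer_
      expect_identical(bmm$geno[b, id], expected_call)
    }
  }
  # bins never invent boundaries: every bin edge is some segment's edge
  seg_edges <- unlist(lapply(segs, function(s)
    paste(s$chrom, c(s$start_bp, s$end_bp + 1))))
  bin_edges <- c(paste(bmm$bins$chrom, bmm$bins$start_bp),
                 paste(bmm$bins$chrom, bmm$bins$end_bp + 1))
  expect_true(all(bin_edges %in% seg_edges))
})
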