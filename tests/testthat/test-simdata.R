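test_that("gamete crossover counts follow Poisson(map Morgans)", {
  set.seed(101)
  gmap <- uniform_genetic_map(1, 100)
  n <- 10000
  counts <- vapply(seq_len(n), function(i)
    length(simulate_gamete(gmap)$xo[[1L]]), integer(1))
  # mean 1 within 3 SE
  expect_lt(abs(mean(counts) - 1), 3 * sqrt(1 / n))
  # goodness of fit against Poisson(1) at alpha = 0.01
  k <- pmin(counts, 4)
  obs <- tabulate(k + 1L, nbins = 5L)
  pr <- c(dpois(0:3, 1), ppois(3, 1, lower.tail = FALSE))
  expect_gt(stats::chisq.test(obs, p = pr)$p.value, 0.01)
  # zero-length chromosome rejected
  zmap <- genetic_map(data.frame(chrom = "c1", pos_bp = c(1, 100),
                                 pos_cM = c(0, 0)))
  expect_error(simulate_gamete(zmap), "zero-length")
})

test_that("recombination fraction matches the Haldane transform", {
  set.seed(102)
  gmap <- uniform_genetic_map(1, 100)
  n <- 20000
  rec <- vapply(seq_len(n), function(i) {
    g <- simulate_gamete(gmap)
    a <- gamete_allele(g, 1L, c(25, 75))
    a[1L] != a[2L]
  }, logical(1))
  r_expected <- haldane_r(50)  # (1 - exp(-1)) / 2 ~ 0.316
  expect_equal(r_expected, (1 - exp(-1)) / 2, tolerance = 1e-12)
  se <- sqrt(r_expected * (1 - r_expected) / n)
  expect_lt(abs(mean(rec) - r_expected), 3 * se)
})

test_that("null F2 has Type II fraction 1/2 and 1:2:1 marker ratios", {
  gmap <- uniform_genetic_map(2, 80)
  cfg <- sim_config(map = gmap, qtls = NULL, mu = 0,
                    n_embryos = 3000, n_select_per_class = 100,
                    snp_density = 0.5, seed = 103)
  sim <- simulate_f2(cfg)
  frac <- mean(sim$phenotype == "TypeII")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 3000))
  # genotype frequencies 1:2:1 before selection
  tg <- truth_genotypes(sim, sim$ids[1:1000])
  for (site in c(10, 40)) {
    obs <- tabulate(tg$geno[site, ] + 1L, nbins = 3L)
    expect_gt(stats::chisq.test(obs, p = c(.25, .5, .25))$p.value, 0.001)
  }
})

test_that("single-QTL penetrance matches the logistic closed form", {
  gmap <- uniform_genetic_map(1, 100)
  cfg <- sim_config(map = gmap, qtls = qtl_spec("chr1", 50, beta = 2),
                    mu = 0, n_embryos = 8000, n_select_per_class = 10,
                    snp_density = 0.2, seed = 104)
  sim <- simulate_f2(cfg)
  aa <- sim$qtl_dosage[, 1L] == 2L
  p_hat <- mean(sim$phenotype[aa] == "TypeII")
  p_true <- stats::plogis(2)  # ~0.881
  expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / sum(aa)))
})

test_that("selection enriches the A188 allele at the chr6 QTL in Type II", {
  cfg <- sim_config(n_embryos = 1200, n_select_per_class = 80,
                    snp_density = 0.5, seed = 105)
  sim <- simulate_f2(cfg)
  q6 <- which(cfg$qtls$chrom == "chr6")
  d2 <- sim$qtl_dosage[match(sim$sel_type2, sim$ids), q6]
  d1 <- sim$qtl_dosage[match(sim$sel_type1, sim$ids), q6]
  expect_gt(mean(d2), mean(d1))
  # and the reverse at a B73-favorable QTL (chr5)
  q5 <- which(cfg$qtls$chrom == "chr5")
  expect_lt(mean(sim$qtl_dosage[match(sim$sel_type2, sim$ids), q5]),
            mean(sim$qtl_dosage[match(sim$sel_type1, sim$ids), q5]))
})

test_that("selection fails loudly when a class is too small", {
  gmap <- uniform_genetic_map(1, 50)
  cfg <- sim_config(map = gmap, qtls = qtl_spec("chr1", 25, 0), mu = 6,
                    n_embryos = 200, n_select_per_class = 80,
                    snp_density = 0.5, seed = 106)
  expect_error(simulate_f2(cfg), "available")
})

test_that("GBS degradation follows the stated per-call model", {
  set.seed(107)
  n <- 10000
  truth <- make_gm(matrix(2L, n, 1, dimnames = list(NULL, "i1")))
  expect_identical(degrade_to_gbs(truth, 0, 0, 0)$geno, truth$geno)
  expect_true(all(is.na(degrade_to_gbs(truth, 1, 0, 0)$geno)))
  # 2% error on 10,000 AA calls: 200 +/- 3 SE miscalls
  g <- degrade_to_gbs(truth, 0, 0.02, 0)$geno
  n_err <- sum(g != 2L)
  expect_lt(abs(n_err - 200), 3 * sqrt(10000 * 0.02 * 0.98))
  # het undercall produces only homozygotes
  het <- make_gm(matrix(1L, n, 1, dimnames = list(NULL, "i1")))
  gh <- degrade_to_gbs(het, 0, 0, 0.5)$geno
  expect_true(all(gh %in% c(0L, 1L, 2L)))
  n_under <- sum(gh != 1L)
  expect_lt(abs(n_under - 5000), 3 * sqrt(10000 * 0.25))
  expect_error(degrade_to_gbs(truth, -0.1, 0, 0), "rates")
})

test_that("bulk read counts are binomial in the bulk allele frequency", {
  gmap <- uniform_genetic_map(1, 60)
  cfg <- sim_config(map = gmap, qtls = qtl_spec("chr1", 30, 0),
                    n_embryos = 300, n_select_per_class = 60,
                    snp_density = 50, bulk_depth_mean = 200, seed = 108)
  sim <- simulate_f2(cfg)
  bc <- simulate_bulk_counts(sim)
  expect_s3_class(bc, "bulk_counts")
  expect_setequal(unique(bc$class), c("XT-I", "XT-II"))
  # per-SNP pooled read fraction is unbiased for the bulk allele frequency
  f_true <- rowMeans(truth_genotypes(sim, sim$sel_type1)$geno) / 2
  sub <- bc[bc$class == "XT-I", ]
  a <- rowsum(sub$a188_reads, sub$pos_bp, reorder = FALSE)[, 1L]
  d <- a + rowsum(sub$b73_reads, sub$pos_bp, reorder = FALSE)[, 1L]
  resid <- a / d - f_true
  expect_lt(abs(mean(resid)), 3 * sqrt(mean(0.25 / d) / length(d)) + 1e-4)
  # SNPs fixed for one parent in a tiny bulk yield only that parent's reads
  bc2 <- simulate_bulk_counts(sim, members_type1 = sim$sel_type1[1],
                              members_type2 = sim$sel_type2[1], n_reps = 1)
  f2_true <- rowMeans(truth_genotypes(sim, sim$sel_type1[1])$geno) / 2
  sub2 <- bc2[bc2$class == "XT-I", ]
  expect_gt(sum(f2_true %in% c(0, 1)), 0)
  expect_true(all(sub2$b73_reads[f2_true == 1] == 0))
  expect_true(all(sub2$a188_reads[f2_true == 0] == 0))
  expect_error(simulate_bulk_counts(sim, members_type1 = character(0)),
               "empty bulk")
})

test_that("bulk allele divergence concentrates at a selected QTL", {
  gmap <- uniform_genetic_map(2, 80)
  cfg <- sim_config(map = gmap, qtls = qtl_spec("chr1", 40, 2.2),
                    n_embryos = 600, n_select_per_class = 100,
                    snp_density = 1, bulk_depth_mean = 300, seed = 109)
  sim <- simulate_f2(cfg)
  bc <- simulate_bulk_counts(sim)
  agg <- function(cls) {
    sub <- bc[bc$class == cls, ]
    rowsum(sub$a188_reads, paste(sub$chrom, sub$pos_bp), reorder = FALSE) /
      rowsum(sub$a188_reads + sub$b73_reads,
             paste(sub$chrom, sub$pos_bp), reorder = FALSE)
  }
  dif <- abs(agg("XT-II") - agg("XT-I"))[, 1L]
  snps <- sim$snps
  near <- snps$chrom == "chr1" & abs(snps$pos_cM - 40) < 5
  far <- snps$chrom == "chr2"
  expect_gt(mean(dif[near]), mean(dif[far]) * 2)
})

test_that("simulation is reproducible given a seed", {
  cfg <- sim_config(n_embryos = 150, n_select_per_class = 30,
                    snp_density = 0.3, seed = 110)
  s1 <- simulate_f2(cfg)
  s2 <- simulate_f2(cfg)
  expect_identical(s1$phenotype, s2$phenotype)
  expect_identical(truth_genotypes(s1)$geno, truth_genotypes(s2)$geno)
  expect_identical(s1$sel_type2, s2$sel_type2)
})

test_that("gene fixture is brute-force checkable", {
  set.seed(111)
  gmap <- uniform_genetic_map(2, 50)
  fx0 <- make_gene_fixture(gmap, 0)
  expect_equal(nrow(fx0$genes), 0)
  fx <- make_gene_fixture(gmap, 200)
  expect_equal(nrow(fx$genes), 200)
  expect_false(any(duplicated(fx$genes$gene_id)))
  expect_true(all(fx$genes$end_bp > fx$genes$start_bp))
  expect_true(all(fx$deg_type$gene_id %in% fx$genes$gene_id))
  expect_true(all(fx$deg_type$direction %in% c("up", "down")))
  expect_equal(rownames(fx$rpm), fx$genes$gene_id)
})
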