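#' QTL specification for the liability simulator
#'
#' Effects act on the log-odds of the Type II phenotype per copy of the A188
#' allele: positive `beta` means the A188 allele favors Type II, negative
#' `beta` means the B73 allele does. `dominance` shifts the heterozygote off
#' the additive midpoint (0 = purely additive, matching the observed
#' non-dominant behaviour of the callus-type loci).
#'
#' @param chrom chromosome id (must exist in the map used for simulation).
#' @param pos_cM genetic position of the QTL.
#' @param beta additive effect (log-odds of Type II per A188 allele copy).
#' @param dominance heterozygote deviation on the log-odds scale.
#' @return A one-row data.frame.
#' @export
qtl_spec <- function(chrom, pos_cM, beta, dominance = 0) {
  stopifnot(is.finite(beta), is.finite(dominance), is.finite(pos_cM))
  data.frame(chrom = as.character(chrom), pos_cM = pos_cM,
             beta = beta, dominance = dominance)
}

#' Five-QTL architecture resembling the mapped callus-type loci
#'
#' QTLs on chromosomes 2, 5, 6, 8 and 9 with the favorable allele from A188 on
#' chromosome 6 and from B73 elsewhere, and the chromosome 5 locus strongest.
#' Positions default to 55% of each chromosome's genetic length. Effect sizes
#' are chosen so the architecture is detectable with roughly 200 selected
#' individuals; the liability-scale truth of the real loci is unknown.
#'
#' @param map a `genetic_map` with at least 9 chromosomes.
#' @return data.frame of QTL specifications (one per locus).
#' @export
demo_qtls <- function(map = default_genetic_map()) {
  chroms <- map_chromosomes(map)
  pick <- paste0("chr", c(2, 5, 6, 8, 9))
  if (!all(pick %in% chroms))
    stop("map must contain chromosomes ", paste(pick, collapse = ", "))
  len <- chrom_lengths_cM(map)[pick]
  betas <- c(-1.9, -2.2, 2.0, -1.9, -1.8)
  do.call(rbind, Map(qtl_spec, pick, 0.55 * len, betas))
}

#' Simulation configuration for a synthetic F2 callus experiment
#'
#' Defaults mirror the design of the mapping experiment: 2194 F2 embryos from
#' which 100 extreme Type I and 100 extreme Type II calli are selected, two
#' 50-callus bulks per phenotype class, and GBS-like genotype degradation
#' (20% missing calls, 2% random genotype error, 10% heterozygote undercall).
#'
#' @param map a `genetic_map` (default: the 10-chromosome maize-like map).
#' @param qtls data.frame of [qtl_spec()] rows (default: [demo_qtls()]).
#' @param mu baseline log-odds of Type II.
#' @param n_embryos number of F2 embryos cultured.
#' @param n_select_per_class extreme calli genotyped per phenotype class.
#' @param snp_density simulated GBS SNPs per cM.
#' @param missing_rate probability a true call is unobserved.
#' @param genotype_error_rate probability a surviving call is replaced by a
#'   uniformly chosen different code.
#' @param het_undercall_rate probability a surviving heterozygous call is
#'   reported as a random homozygote (allele sampling at low GBS depth).
#' @param bulk_size calli pooled per bulk replicate.
#' @param bulk_depth_mean mean sequencing depth per SNP per bulk (Poisson).
#' @param n_bulk_reps bulk replicates per phenotype class.
#' @param seed optional RNG seed applied by [simulate_f2()].
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(map = default_genetic_map(),
                       qtls = demo_qtls(map),
                       mu = 0,
                       n_embryos = 2194,
                       n_select_per_class = 100,
                       snp_density = 5,
                       missing_rate = 0.2,
                       genotype_error_rate = 0.02,
                       het_undercall_rate = 0.1,
                       bulk_size = 50,
                       bulk_depth_mean = 200,
                       n_bulk_reps = 2,
                       seed = NULL) {
  stopifnot(inherits(map, "genetic_map"))
  if (is.null(qtls))
    qtls <- qtl_spec("x", 0, 0)[0, ]
  rates <- c(missing_rate, genotype_error_rate, het_undercall_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (2L * n_select_per_class > n_embryos)
    stop("n_select_per_class x 2 must not exceed n_embryos")
  if (any(chrom_lengths_cM(map) < 0)) stop("invalid map")
  if (nrow(qtls)) {
    if (!all(qtls$chrom %in% map_chromosomes(map)))
      stop("QTL chromosome not in map")
    ok <- qtls$pos_cM >= 0 &
      qtls$pos_cM <= chrom_lengths_cM(map)[qtls$chrom]
    if (!all(ok)) stop("QTL pos_cM outside chromosome map range")
    if (!all(is.finite(qtls$beta))) stop("QTL beta must be finite")
  }
  structure(list(map = map, qtls = qtls, mu = mu, n_embryos = n_embryos,
                 n_select_per_class = n_select_per_class,
                 snp_density = snp_density, missing_rate = missing_rate,
                 genotype_error_rate = genotype_error_rate,
                 het_undercall_rate = het_undercall_rate,
                 bulk_size = bulk_size, bulk_depth_mean = bulk_depth_mean,
                 n_bulk_reps = n_bulk_reps, seed = seed),
            class = "sim_config")
}

#' Simulate one meiotic gamete (Haldane model, no interference)
#'
#' Per chromosome the crossover count is Poisson with mean equal to the
#' chromosome length in Morgans, crossover positions are i.i.d. uniform on
#' the genetic length, and the founder phase of the leftmost segment is
#' Bernoulli(1/2). Uses R's current RNG stream.
#'
#' @param map a `genetic_map`.
#' @return A list with `xo` (per-chromosome sorted crossover positions, cM)
#'   and `phase` (per-chromosome leftmost founder allele, 1 = A188, 0 = B73).
#' @export
simulate_gamete <- function(map) {
  len <- chrom_lengths_cM(map)
  if (any(len <= 0)) stop("zero-length chromosome: rejecting configuration")
  n_xo <- stats::rpois(length(len), len / 100)
  xo <- lapply(seq_along(len), function(i) sort(stats::runif(n_xo[i], 0, len[i])))
  names(xo) <- names(len)
  list(xo = xo, phase = stats::rbinom(length(len), 1L, 0.5))
}

#' Founder allele carried by a gamete at given genetic positions
#'
#' @param gamete a gamete from [simulate_gamete()].
#' @param chrom_index chromosome index into the gamete's map.
#' @param pos_cM sorted or unsorted positions (cM) to query.
#' @return Integer vector of founder alleles (1 = A188, 0 = B73).
#' @export
gamete_allele <- function(gamete, chrom_index, pos_cM) {
  (gamete$phase[chrom_index] +
     findInterval(pos_cM, gamete$xo[[chrom_index]])) %% 2L
}

.sim_snp_sites <- function(map, snp_density) {
  chroms <- map_chromosomes(map)
  len <- chrom_lengths_cM(map)
  out <- lapply(chroms, function(ch) {
    n <- max(2L, round(snp_density * len[[ch]]))
    cm <- sort(stats::runif(n, 0, len[[ch]]))
    bp <- round(map_cM_to_bp(map, ch, cm))
    # enforce strictly increasing bp (collisions from rounding)
    while (any(diff(bp) <= 0)) {
      i <- which(diff(bp) <= 0) + 1L
      bp[i] <- bp[i - 1L] + 1L
    }
    data.frame(chrom = ch, pos_bp = bp, pos_cM = cm)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Simulate an F2 population with a binary liability phenotype
#'
#' Each F2 individual is the union of two independent gametes. The liability
#' is `mu + sum(beta_q * (x_q - 1) + dominance_q * [x_q == 1])` where `x_q` is
#' the A188-allele dosage at QTL `q`; the phenotype is Bernoulli(logistic
#' (liability)) with Type II = 1. Phenotypic extremes are then drawn uniformly
#' at random within each class (the phenotype is binary, so any member of a
#' class is equally "extreme").
#'
#' @param config a [sim_config()].
#' @return An object of class `f2_sim` with elements `config`, `map`, `snps`
#'   (site table), `gametes`, `qtl_dosage` (individuals x QTLs), `liability`,
#'   `phenotype` (factor TypeI/TypeII), `ids`, `sel_type1`, `sel_type2`.
#' @export
simulate_f2 <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  map <- config$map
  chroms <- map_chromosomes(map)
  n <- config$n_embryos
  snps <- .sim_snp_sites(map, config$snp_density)
  gametes <- replicate(n, list(g1 = simulate_gamete(map),
                               g2 = simulate_gamete(map)),
                       simplify = FALSE)
  q <- config$qtls
  qtl_dosage <- matrix(0L, n, nrow(q))
  if (nrow(q)) {
    qi <- match(q$chrom, chroms)
    for (i in seq_len(n)) {
      g <- gametes[[i]]
      qtl_dosage[i, ] <- vapply(seq_len(nrow(q)), function(k) {
        gamete_allele(g$g1, qi[k], q$pos_cM[k]) +
          gamete_allele(g$g2, qi[k], q$pos_cM[k])
      }, integer(1))
    }
  }
  liability <- config$mu
  if (nrow(q)) {
    liability <- config$mu +
      as.vector(qtl_dosage %*% q$beta) - sum(q$beta) +
      as.vector((qtl_dosage == 1L) %*% q$dominance)
  }
  liability <- rep_len(liability, n)
  y <- stats::rbinom(n, 1L, stats::plogis(liability))
  ids <- sprintf("F2_%05d", seq_len(n))
  n_sel <- config$n_select_per_class
  class1 <- which(y == 0L)
  class2 <- which(y == 1L)
  if (length(class1) < n_sel || length(class2) < n_sel)
    stop(sprintf(paste0("cannot select %d per class: ",
                        "%d Type I and %d Type II individuals available"),
                 n_sel, length(class1), length(class2)))
  sel1 <- sort(sample(class1, n_sel))
  sel2 <- sort(sample(class2, n_sel))
  structure(list(config = config, map = map, snps = snps, gametes = gametes,
                 qtl_dosage = qtl_dosage, liability = liability,
                 phenotype = factor(ifelse(y == 1L, "TypeII", "TypeI"),
                                    levels = c("TypeI", "TypeII")),
                 ids = ids, sel_type1 = ids[sel1], sel_type2 = ids[sel2]),
            class = "f2_sim")
}

#' @export
print.f2_sim <- function(x, ...) {
  cat("f2_sim:", length(x$ids), "embryos,",
      sum(x$phenotype == "TypeII"), "Type II;",
      nrow(x$snps), "SNP sites;",
      nrow(x$config$qtls), "QTLs\n")
  invisible(x)
}

#' True (error-free) genotypes of simulated individuals
#'
#' Reconstructs A188-allele dosages at every simulated SNP from the recorded
#' crossover histories; this is the ground truth used by the segmentation and
#' mapping oracles.
#'
#' @param sim an `f2_sim`.
#' @param ids individual ids (default: the selected extremes, Type I then
#'   Type II).
#' @return A `genotype_matrix` of true dosages.
#' @export
truth_genotypes <- function(sim, ids = c(sim$sel_type1, sim$sel_type2)) {
  idx <- match(ids, sim$ids)
  if (anyNA(idx)) stop("unknown individual ids")
  chroms <- map_chromosomes(sim$map)
  pos_by_chr <- split(sim$snps$pos_cM,
                      factor(sim$snps$chrom, levels = chroms))
  geno <- matrix(NA_integer_, nrow(sim$snps), length(ids),
                 dimnames = list(NULL, ids))
  for (j in seq_along(idx)) {
    g <- sim$gametes[[idx[j]]]
    geno[, j] <- unlist(lapply(seq_along(chroms), function(ci) {
      gamete_allele(g$g1, ci, pos_by_chr[[ci]]) +
        gamete_allele(g$g2, ci, pos_by_chr[[ci]])
    }), use.names = FALSE)
  }
  genotype_matrix(sim$snps[, c("chrom", "pos_bp")], geno)
}

#' True number of discernible genotype transitions for one individual
#'
#' Counts the genotype changes along the ordered SNP sites (summed over
#' chromosomes) implied by the recorded crossovers. Crossover pairs falling
#' between the same adjacent SNPs cancel and are, by construction, not
#' discernible.
#'
#' @param sim an `f2_sim`.
#' @param id one individual id.
#' @return Integer transition count.
#' @export
truth_transition_count <- function(sim, id) {
  tg <- truth_genotypes(sim, id)
  sum(vapply(split(tg$geno[, 1L],
                   factor(tg$sites$chrom, levels = map_chromosomes(sim$map))),
             function(v) sum(diff(v) != 0L), integer(1)))
}

#' Degrade true genotypes into GBS-like observations
#'
#' Each call is independently set missing with probability `missing_rate`;
#' each surviving heterozygous call is replaced by a random homozygote with
#' probability `het_undercall_rate` (allele sampling at low depth); each
#' surviving call is then replaced by a uniformly chosen *different* code with
#' probability `genotype_error_rate`.
#'
#' @param truth a `genotype_matrix` of true dosages.
#' @param missing_rate,genotype_error_rate,het_undercall_rate probabilities.
#' @return A degraded `genotype_matrix`.
#' @export
degrade_to_gbs <- function(truth, missing_rate = 0.2,
                           genotype_error_rate = 0.02,
                           het_undercall_rate = 0.1) {
  stopifnot(inherits(truth, "genotype_matrix"))
  rates <- c(missing_rate, genotype_error_rate, het_undercall_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  g <- truth$geno
  nv <- length(g)
  if (missing_rate > 0)
    g[stats::runif(nv) < missing_rate] <- NA_integer_
  if (het_undercall_rate > 0) {
    het <- which(!is.na(g) & g == 1L)
    hit <- het[stats::runif(length(het)) < het_undercall_rate]
    g[hit] <- 2L * stats::rbinom(length(hit), 1L, 0.5)
  }
  if (genotype_error_rate > 0) {
    obs <- which(!is.na(g))
    hit <- obs[stats::runif(length(obs)) < genotype_error_rate]
    # uniform over the two codes different from the current one
    shift <- 1L + stats::rbinom(length(hit), 1L, 0.5)
    g[hit] <- (g[hit] + shift) %% 3L
  }
  genotype_matrix(truth$sites, g)
}

#' Simulate bulk allele read counts at every SNP
#'
#' For each SNP and bulk replicate the A188-allele frequency is the mean A188
#' dosage / 2 over the bulk members, sequencing depth is Poisson, and the
#' A188 read count is Binomial(depth, frequency) — read counts of the two
#' alleles follow a binomial distribution, which is exactly the generative
#' model assumed by the downstream association test.
#'
#' @param sim an `f2_sim`.
#' @param members_type1,members_type2 individual ids pooled into the Type I /
#'   Type II bulks; split sequentially into `n_reps` replicates.
#' @param depth_mean mean depth per SNP per replicate.
#' @param n_reps bulk replicates per class.
#' @return A data.frame (class `bulk_counts`) with columns `chrom`, `pos_bp`,
#'   `class` (XT-I/XT-II), `rep`, `a188_reads`, `b73_reads`.
#' @export
simulate_bulk_counts <- function(sim,
                                 members_type1 = sim$sel_type1,
                                 members_type2 = sim$sel_type2,
                                 depth_mean = sim$config$bulk_depth_mean,
                                 n_reps = sim$config$n_bulk_reps) {
  if (!length(members_type1) || !length(members_type2))
    stop("empty bulk")
  if (depth_mean <= 0) stop("depth_mean must be positive")
  split_reps <- function(ids) {
    split(ids, rep(seq_len(n_reps), length.out = length(ids)))
  }
  classes <- rep(c("XT-I", "XT-II"), each = n_reps)
  reps <- rep(seq_len(n_reps), 2L)
  members <- c(split_reps(members_type1), split_reps(members_type2))
  n_snp <- nrow(sim$snps)
  out <- vector("list", length(members))
  for (k in seq_along(members)) {
    tg <- truth_genotypes(sim, members[[k]])
    f <- rowMeans(tg$geno) / 2
    depth <- stats::rpois(n_snp, depth_mean)
    a <- stats::rbinom(n_snp, depth, f)
    out[[k]] <- data.frame(chrom = sim$snps$chrom, pos_bp = sim$snps$pos_bp,
                           class = classes[k], rep = reps[k],
                           a188_reads = a, b73_reads = depth - a)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("bulk_counts", "data.frame")
  res
}

#' Build a gene annotation and DEG fixture with a computable candidate set
#'
#' Places `n_genes` genes uniformly in bp across the genome and marks random
#' subsets as differentially expressed (up/down) in each of two contrasts
#' (Type II vs Type I; fast- vs slow-growing), so the expected QTL x DEG
#' candidate set can be recomputed by brute force. A fraction `de_overlap` of
#' the second contrast's DEGs is shared with the first (same gene, same
#' direction), emulating the substantial overlap between callus-type and
#' growth-rate expression responses. Also emits a small RPM expression matrix
#' in which DE genes are shifted between sample groups.
#'
#' @param map a `genetic_map`.
#' @param n_genes number of genes.
#' @param de_fraction fraction of genes DE in each contrast.
#' @param de_overlap fraction of contrast-2 DEGs shared (with direction)
#'   with contrast 1.
#' @param gene_width_bp gene length (bp).
#' @param n_samples_per_group samples per group in the RPM fixture.
#' @return A list with `genes` (gene_id, chrom, start_bp, end_bp),
#'   `deg_type` and `deg_growth` (gene_id, direction, padj), and `rpm`
#'   (genes x samples matrix).
#' @export
make_gene_fixture <- function(map, n_genes, de_fraction = 0.2,
                              de_overlap = 0.5, gene_width_bp = 3000,
                              n_samples_per_group = 2) {
  if (n_genes == 0) {
    empty <- data.frame(gene_id = character(), chrom = character(),
                        start_bp = integer(), end_bp = integer())
    return(list(genes = empty,
                deg_type = data.frame(gene_id = character(),
                                      direction = character(),
                                      padj = numeric()),
                deg_growth = data.frame(gene_id = character(),
                                        direction = character(),
                                        padj = numeric()),
                rpm = matrix(numeric(), 0, 2 * n_samples_per_group)))
  }
  len_bp <- chrom_lengths_bp(map)
  chrom <- sample(names(len_bp), n_genes, replace = TRUE,
                  prob = len_bp / sum(len_bp))
  start <- floor(stats::runif(n_genes, 1, pmax(2, len_bp[chrom] - gene_width_bp)))
  genes <- data.frame(gene_id = sprintf("gene%05d", seq_len(n_genes)),
                      chrom = chrom,
                      start_bp = as.integer(start),
                      end_bp = as.integer(start + gene_width_bp - 1))
  genes <- genes[order(match(genes$chrom, names(len_bp)), genes$start_bp), ]
  genes$gene_id <- sprintf("gene%05d", seq_len(n_genes))  # ids in genome order
  rownames(genes) <- NULL
  n_de <- round(de_fraction * n_genes)
  picked1 <- sort(sample(n_genes, n_de))
  deg_type <- data.frame(gene_id = genes$gene_id[picked1],
                         direction = sample(c("up", "down"), n_de,
                                            replace = TRUE),
                         padj = stats::runif(n_de, 0, 0.1))
  n_shared <- round(de_overlap * n_de)
  shared <- sample(n_de, n_shared)
  fresh <- sample(setdiff(seq_len(n_genes), picked1), n_de - n_shared)
  deg_growth <- rbind(
    data.frame(gene_id = deg_type$gene_id[shared],
               direction = deg_type$direction[shared],
               padj = stats::runif(n_shared, 0, 0.1)),
    data.frame(gene_id = genes$gene_id[fresh],
               direction = sample(c("up", "down"), n_de - n_shared,
                                  replace = TRUE),
               padj = stats::runif(n_de - n_shared, 0, 0.1)))
  deg_growth <- deg_growth[order(match(deg_growth$gene_id, genes$gene_id)), ]
  rownames(deg_growth) <- NULL
  groups <- rep(c("grpA", "grpB"), each = n_samples_per_group)
  rpm <- matrix(stats::rlnorm(n_genes * length(groups), 3, 1),
                n_genes, length(groups),
                dimnames = list(genes$gene_id,
                                paste0(groups, seq_along(groups))))
  de1 <- match(deg_type$gene_id, genes$gene_id)
  shift <- ifelse(deg_type$direction == "up", 2, 0.5)
  rpm[de1, groups == "grpB"] <- rpm[de1, groups == "grpB"] * shift
  list(genes = genes, deg_type = deg_type, deg_growth = deg_growth, rpm = rpm)
}
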