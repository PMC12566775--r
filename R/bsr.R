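#' Filter SNP records on allele frequency, quality and depth
#'
#' Applies the variant-selection rule `AF >= af_min && QUAL >= qual_min &&
#' dp_min <= DP < dp_max` to bi-allelic records, with exactly those boundary
#' semantics (all lower bounds inclusive, the depth upper bound strict).
#' Records missing a required field are rejected as `malformed`;
#' multi-allelic records (comma in the ALT allele) as `multiallelic`.
#'
#' @param records data.frame with columns `chrom`, `pos_bp`, `ref`, `alt`,
#'   `qual`, `depth`, `af`.
#' @param af_min,qual_min,dp_min,dp_max thresholds (defaults 0.2, 30, 100,
#'   10000).
#' @return A list: `retained` (data.frame), `tally` (named integer of
#'   rejections per rule), `reasons` (per-record, NA when retained).
#' @export
filter_snp_records <- function(records, af_min = 0.2, qual_min = 30,
                               dp_min = 100, dp_max = 10000) {
  need <- c("chrom", "pos_bp", "ref", "alt", "qual", "depth", "af")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  reason <- rep(NA_character_, nrow(records))
  bad_field <- is.na(records$qual) | is.na(records$depth) | is.na(records$af) |
    is.na(records$ref) | is.na(records$alt)
  reason[bad_field] <- "malformed"
  multi <- !bad_field & (grepl(",", records$alt) | grepl(",", records$ref))
  reason[multi] <- "multiallelic"
  open <- is.na(reason)
  reason[open & records$af < af_min] <- "af"
  open <- is.na(reason)
  reason[open & records$qual < qual_min] <- "qual"
  open <- is.na(reason)
  reason[open & records$depth < dp_min] <- "dp_low"
  open <- is.na(reason)
  reason[open & records$depth >= dp_max] <- "dp_high"
  tally <- table(factor(reason, levels = c("malformed", "multiallelic",
                                           "af", "qual", "dp_low", "dp_high")))
  retained <- records[is.na(reason), , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained,
       tally = stats::setNames(as.integer(tally), names(tally)),
       reasons = reason)
}

#' Filter SNP records for concordance with the parental genotypes
#'
#' A record is retained only when both parents are homozygous for different
#' alleles at the site and the record's REF/ALT pair equals the parental
#' allele pair; anything else (shared parental genotype, a heterozygous
#' parent, mismatching alleles) is the signature of a genotyping error.
#'
#' @param records data.frame with `chrom`, `pos_bp`, `ref`, `alt`.
#' @param parents data.frame with `chrom`, `pos_bp`, `a188_allele`,
#'   `b73_allele` (single bases for homozygous calls; strings like `"A/G"`
#'   or NA mark heterozygous/uncalled parents and cause discard).
#' @return A list: `retained` (data.frame), `tally` (named integer:
#'   `absent`, `parent_not_fixed`, `allele_mismatch`).
#' @export
filter_parental_concordance <- function(records, parents) {
  key_r <- paste(records$chrom, records$pos_bp)
  key_p <- paste(parents$chrom, parents$pos_bp)
  idx <- match(key_r, key_p)
  reason <- rep(NA_character_, nrow(records))
  reason[is.na(idx)] <- "absent"
  ok <- !is.na(idx)
  a <- parents$a188_allele[idx]
  b <- parents$b73_allele[idx]
  single <- function(x) !is.na(x) & nchar(x) == 1L
  fixed_diff <- single(a) & single(b) & a != b
  reason[ok & !fixed_diff] <- "parent_not_fixed"
  open <- is.na(reason)
  pair_match <- open &
    ((records$ref == a & records$alt == b) |
       (records$ref == b & records$alt == a))
  reason[open & !pair_match] <- "allele_mismatch"
  tally <- table(factor(reason, levels = c("absent", "parent_not_fixed",
                                           "allele_mismatch")))
  retained <- records[is.na(reason), , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained,
       tally = stats::setNames(as.integer(tally), names(tally)))
}

#' @keywords internal
#' Vectorized binomial-GLM deviance test of pooled 2x2 allele-count tables.
#' a1, b1: A188/B73 reads in class XT-I; a2, b2: in class XT-II.
#' Equivalent to glm(cbind(a, b) ~ class, binomial) tested by the 1-df LRT.
.binom_glm_lrt <- function(a1, b1, a2, b2) {
  n1 <- a1 + b1
  n2 <- a2 + b2
  a <- a1 + a2
  b <- b1 + b2
  n <- n1 + n2
  2 * (.xlogx(a1) + .xlogx(b1) + .xlogx(a2) + .xlogx(b2) -
         .xlogx(n1) - .xlogx(n2) -
         (.xlogx(a) + .xlogx(b) - .xlogx(n)))
}

#' Binomial GLM association test of bulk allele counts at one SNP
#'
#' Tests whether the A188-allele read proportion differs between the Type I
#' and Type II bulks under a binomial generalized linear model with logit
#' link; the p-value comes from the 1-df likelihood-ratio (deviance) test.
#' Default pooling sums replicate bulks within each class (the closed-form
#' fit); `replicate_term` instead keeps replicates separate and adds the
#' replicate as a nuisance factor via [stats::glm()].
#'
#' @param counts data.frame for one SNP with columns `class` (XT-I/XT-II),
#'   `rep`, `a188_reads`, `b73_reads`.
#' @param pooling `"pool_replicates"` (default) or `"replicate_term"`.
#' @return A list: `pvalue`, `statistic` (deviance), `direction` (class with
#'   the higher A188 proportion), `table` (pooled 2x2), `reason` (NA unless
#'   undefined, e.g. a class with zero reads).
#' @export
bsr_association_test <- function(counts,
                                 pooling = c("pool_replicates",
                                             "replicate_term")) {
  pooling <- match.arg(pooling)
  stopifnot(all(c("class", "rep", "a188_reads", "b73_reads") %in%
                  names(counts)))
  cls <- as.character(counts$class)
  if (!all(cls %in% c("XT-I", "XT-II"))) stop("class must be XT-I or XT-II")
  a1 <- sum(counts$a188_reads[cls == "XT-I"])
  b1 <- sum(counts$b73_reads[cls == "XT-I"])
  a2 <- sum(counts$a188_reads[cls == "XT-II"])
  b2 <- sum(counts$b73_reads[cls == "XT-II"])
  tab <- matrix(c(a1, b1, a2, b2), 2L,
                dimnames = list(c("a188", "b73"), c("XT-I", "XT-II")))
  if (a1 + b1 == 0 || a2 + b2 == 0)
    return(list(pvalue = NA_real_, statistic = NA_real_,
                direction = NA_character_, table = tab,
                reason = "zero reads in a class"))
  if (pooling == "pool_replicates") {
    stat <- .binom_glm_lrt(a1, b1, a2, b2)
  } else {
    dat <- data.frame(a = counts$a188_reads, b = counts$b73_reads,
                      class = factor(cls), rep = factor(counts$rep))
    full <- stats::glm(cbind(a, b) ~ rep + class, family = stats::binomial(),
                       data = dat)
    null <- stats::glm(cbind(a, b) ~ rep, family = stats::binomial(),
                       data = dat)
    stat <- max(null$deviance - full$deviance, 0)
  }
  direction <- if (a2 / (a2 + b2) > a1 / (a1 + b1)) "XT-II" else "XT-I"
  list(pvalue = stats::pchisq(stat, 1L, lower.tail = FALSE),
       statistic = stat, direction = direction, table = tab,
       reason = NA_character_)
}

#' Bonferroni-corrected per-test p-value cutoff
#'
#' @param n_tests number of tests performed (>= 1).
#' @param alpha genome-wide significance level (default 5%).
#' @return `alpha / n_tests`.
#' @export
bonferroni_cutoff <- function(n_tests, alpha = 0.05) {
  if (n_tests < 1) stop("n_tests must be at least 1")
  alpha / n_tests
}

#' Genome-wide BSR association scan
#'
#' Runs the pooled binomial association test at every SNP of a bulk-count
#' table and flags SNPs beating the Bonferroni genome-wide cutoff.
#'
#' @param bulk_counts a `bulk_counts` data.frame (long form; see
#'   [simulate_bulk_counts()]).
#' @param alpha genome-wide significance level.
#' @return A data.frame (class `bsr_result`) with one row per SNP: pooled
#'   counts, `statistic`, `pvalue`, `significant`, `direction`, plus
#'   attributes `cutoff` and `n_tests`.
#' @export
bsr_scan <- function(bulk_counts, alpha = 0.05) {
  key <- paste(bulk_counts$chrom, bulk_counts$pos_bp)
  snp <- !duplicated(key)
  is1 <- bulk_counts$class == "XT-I"
  agg <- function(v, mask) {
    rowsum(ifelse(mask, v, 0), key, reorder = FALSE)[, 1L]
  }
  a1 <- agg(bulk_counts$a188_reads, is1)
  b1 <- agg(bulk_counts$b73_reads, is1)
  a2 <- agg(bulk_counts$a188_reads, !is1)
  b2 <- agg(bulk_counts$b73_reads, !is1)
  testable <- (a1 + b1) > 0 & (a2 + b2) > 0
  stat <- rep(NA_real_, length(a1))
  stat[testable] <- .binom_glm_lrt(a1[testable], b1[testable],
                                   a2[testable], b2[testable])
  pv <- stats::pchisq(stat, 1L, lower.tail = FALSE)
  n_tests <- sum(testable)
  cutoff <- bonferroni_cutoff(max(n_tests, 1L), alpha)
  res <- data.frame(chrom = bulk_counts$chrom[snp],
                    pos_bp = bulk_counts$pos_bp[snp],
                    a188_xt1 = a1, b73_xt1 = b1,
                    a188_xt2 = a2, b73_xt2 = b2,
                    statistic = stat, pvalue = pv,
                    significant = !is.na(pv) & pv <= cutoff,
                    direction = ifelse(a2 / pmax(a2 + b2, 1) >
                                         a1 / pmax(a1 + b1, 1),
                                       "XT-II", "XT-I"))
  rownames(res) <- NULL
  attr(res, "cutoff") <- cutoff
  attr(res, "n_tests") <- n_tests
  class(res) <- c("bsr_result", "data.frame")
  res
}
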