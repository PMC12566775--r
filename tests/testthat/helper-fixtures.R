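# Shared builders for small in-code fixtures.

# Genotype matrix from a dosage matrix with evenly spaced sites on one or
# more chromosomes.
make_gm <- function(dosage, chrom = "chr1", spacing_bp = 1e5) {
  n <- nrow(dosage)
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("ind%02d", seq_len(ncol(dosage)))
  genotype_matrix(data.frame(chrom = rep(chrom, length.out = n),
                             pos_bp = rep(seq_len(n) * spacing_bp,
                                          length.out = n)),
                  dosage)
}

# Bin-marker matrix built directly from a dosage matrix (bins x individuals)
# with explicit cM positions; bp positions proportional to cM.
make_bins <- function(dosage, pos_cM, chrom = "chr1", bp_per_cM = 1e6) {
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("ind%02d", seq_len(ncol(dosage)))
  storage.mode(dosage) <- "integer"
  pos_bp <- round(pos_cM * bp_per_cM)
  bins <- data.frame(chrom = rep(chrom, length.out = nrow(dosage)),
                     start_bp = pos_bp - 1, end_bp = pos_bp + 1,
                     rep_pos_bp = pos_bp, rep_pos_cM = pos_cM)
  rownames(dosage) <- paste(bins$chrom, bins$rep_pos_bp, sep = "_")
  structure(list(bins = bins, geno = dosage), class = "bin_marker_matrix")
}

# Single-marker 2-df binomial-likelihood LOD (independent oracle for the
# complete-data equivalence checks).
single_marker_lod <- function(g, y) {
  keep <- !is.na(g)
  g <- g[keep]
  y <- y[keep]
  ll <- 0
  for (d in unique(g)) {
    yy <- y[g == d]
    p <- mean(yy)
    ll <- ll + sum(yy) * log(max(p, 1e-300)) +
      sum(1 - yy) * log(max(1 - p, 1e-300))
  }
  p0 <- mean(y)
  ll0 <- sum(y) * log(max(p0, 1e-300)) +
    sum(1 - y) * log(max(1 - p0, 1e-300))
  (ll - ll0) / log(10)
}

# Reconstruct per-SNP calls from a segment set (used by the idempotence
# and oracle tests).
calls_from_segments <- function(seg, sites) {
  out <- rep(NA_integer_, nrow(sites))
  for (i in seq_len(nrow(seg))) {
    hit <- sites$chrom == seg$chrom[i] &
      sites$pos_bp >= seg$start_bp[i] & sites$pos_bp <= seg$end_bp[i]
    out[hit] <- code_to_dosage(seg$genotype[i])
  }
  out
}

# RLE of true genotypes per chromosome: the ground-truth segmentation.
truth_runs <- function(gm_truth, id) {
  v <- unname(gm_truth$geno[, id])
  lapply(split(seq_along(v), gm_truth$sites$chrom), function(idx) {
    rle(v[idx])
  })
}
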