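#' Segment profile of a (nearly) inbred line
#'
#' Infers chromosomal segments from a single line's GBS calls with the same
#' segmentation machinery used for F2 individuals, retains residual
#' heterozygous segments, and counts recombination breakpoints (segment
#' transitions summed over chromosomes).
#'
#' @param gm a `genotype_matrix` containing the line.
#' @param line line id (may be omitted for a one-column matrix).
#' @param smooth_window,min_snps_per_segment see [call_segments()].
#' @return An object of class `inbred_profile`: list with `line`, `segments`
#'   (a `segment_set`) and `breakpoint_count`.
#' @export
profile_inbred <- function(gm, line = NULL, smooth_window = 5,
                           min_snps_per_segment = 3) {
  seg <- call_segments(gm, line, smooth_window, min_snps_per_segment)
  structure(list(line = attr(seg, "individual"), segments = seg,
                 breakpoint_count = count_recombination_events(seg)),
            class = "inbred_profile")
}

#' @export
print.inbred_profile <- function(x, ...) {
  cat("inbred_profile:", x$line, "-", nrow(x$segments), "segments,",
      x$breakpoint_count, "recombination breakpoints\n")
  invisible(x)
}

#' Genotype of an inbred profile at each QTL peak
#'
#' Looks up the segment covering each QTL peak position and annotates it
#' against the peak's favorable allele: an `AA` segment where A188 is
#' favorable (or `BB` where B73 is) is `favorable`, the opposite homozygote
#' is `unfavorable`, `AB` is `heterozygous`, and uncovered peaks are NA.
#'
#' @param profile an `inbred_profile`.
#' @param peaks a `qtl_peaks` data.frame with a `favorable_allele` column
#'   (see [annotate_peaks()]).
#' @return data.frame: `qtl`, `chrom`, `peak_pos_bp`, `genotype`,
#'   `favorable_allele`, `status`.
#' @export
allele_at_qtl <- function(profile, peaks) {
  seg <- profile$segments
  geno <- rep(NA_character_, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    s <- seg[seg$chrom == peaks$chrom[i], , drop = FALSE]
    hit <- which(s$start_bp <= peaks$peak_pos_bp[i] &
                   s$end_bp >= peaks$peak_pos_bp[i])
    if (length(hit)) geno[i] <- s$genotype[hit[1L]]
  }
  fav <- if ("favorable_allele" %in% names(peaks)) peaks$favorable_allele
  else rep(NA_character_, nrow(peaks))
  fav_code <- ifelse(fav == "A188", "AA", ifelse(fav == "B73", "BB", NA))
  status <- ifelse(is.na(geno), NA_character_,
                   ifelse(geno == "AB", "heterozygous",
                          ifelse(is.na(fav_code), NA_character_,
                                 ifelse(geno == fav_code, "favorable",
                                        "unfavorable"))))
  data.frame(qtl = peaks$name, chrom = peaks$chrom,
             peak_pos_bp = peaks$peak_pos_bp, genotype = geno,
             favorable_allele = fav, status = status)
}

#' Candidate genes: QTL-interval genes differentially expressed in both
#' contrasts
#'
#' A gene qualifies when it overlaps at least one QTL support interval
#' (any-overlap by default; full containment behind `rule = "within"`), is
#' differentially expressed in both contrasts, and — under the default
#' concordance requirement — with the same direction in both. Genes
#' overlapping several QTL intervals yield one row per QTL.
#'
#' @param intervals data.frame with `qtl`, `chrom`, `start_bp`, `end_bp`
#'   (QTL support intervals, 1-based closed).
#' @param genes data.frame with `gene_id`, `chrom`, `start_bp`, `end_bp`;
#'   duplicate gene ids are an error.
#' @param deg1,deg2 data.frames with `gene_id` and `direction` ("up"/"down")
#'   for the two contrasts (e.g. Type II vs Type I; fast vs slow growing).
#' @param require_concordance require the same direction in both contrasts.
#' @param rule `"any"` (>= 1 bp overlap) or `"within"` (gene fully inside).
#' @return data.frame (class `candidate_table`): `gene_id`, `chrom`,
#'   `start_bp`, `end_bp`, `qtl`, `direction` (contrast-1 direction),
#'   `direction_contrast2`, `concordant`; sorted by (qtl, chrom, start).
#' @export
candidate_genes <- function(intervals, genes, deg1, deg2,
                            require_concordance = TRUE,
                            rule = c("any", "within")) {
  rule <- match.arg(rule)
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup))
    stop("duplicate gene ids: ", paste(unique(dup), collapse = ", "))
  d1 <- deg1$direction[match(genes$gene_id, deg1$gene_id)]
  d2 <- deg2$direction[match(genes$gene_id, deg2$gene_id)]
  de_both <- !is.na(d1) & !is.na(d2)
  if (require_concordance) de_both <- de_both & d1 == d2
  rows <- list()
  for (i in seq_len(nrow(intervals))) {
    same_chr <- genes$chrom == intervals$chrom[i]
    ov <- if (rule == "any") {
      genes$start_bp <= intervals$end_bp[i] &
        genes$end_bp >= intervals$start_bp[i]
    } else {
      genes$start_bp >= intervals$start_bp[i] &
        genes$end_bp <= intervals$end_bp[i]
    }
    hit <- which(same_chr & ov & de_both)
    if (length(hit))
      rows[[length(rows) + 1L]] <-
        data.frame(gene_id = genes$gene_id[hit], chrom = genes$chrom[hit],
                   start_bp = genes$start_bp[hit], end_bp = genes$end_bp[hit],
                   qtl = intervals$qtl[i], direction = d1[hit],
                   direction_contrast2 = d2[hit],
                   concordant = d1[hit] == d2[hit])
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(gene_id = character(), chrom = character(),
                  start_bp = numeric(), end_bp = numeric(),
                  qtl = character(), direction = character(),
                  direction_contrast2 = character(), concordant = logical())
  out <- out[order(out$qtl, out$chrom, out$start_bp), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_table", "data.frame")
  out
}

#' Row-standardize an expression matrix
#'
#' Per gene: subtract the mean across samples and divide by the (sample)
#' standard deviation, the transform used to prepare reads-per-million
#' values for heatmap display. Zero-variance genes are emitted as all-zero
#' rows and flagged rather than divided.
#'
#' @param mat numeric matrix, genes x samples (>= 2 samples).
#' @return The standardized matrix with a logical attribute `zero_variance`
#'   marking constant rows.
#' @export
standardize_expression <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop("need at least 2 samples to standardize")
  m <- rowMeans(mat)
  s <- apply(mat, 1L, stats::sd)
  zero <- s == 0 | is.na(s)
  s[zero] <- 1
  z <- (mat - m) / s
  z[zero, ] <- 0
  attr(z, "zero_variance") <- unname(zero)
  z
}
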