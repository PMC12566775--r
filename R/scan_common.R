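#' Genome-wide significance threshold from phenotype permutations
#'
#' Shuffles the phenotype labels `n_perm` times, records the genome-wide
#' extremum of each permuted scan (minimum p-value for the logistic scan,
#' maximum LOD for interval mapping), and returns the empirical alpha-level
#' threshold: the `alpha` quantile of the min-p distribution or the
#' `1 - alpha` quantile of the max-LOD distribution (type-1 quantiles, so
#' `alpha = 1` with min-p extrema degenerates to the maximum over
#' permutations). Deterministic given `seed`.
#'
#' @param bins a `bin_marker_matrix`.
#' @param y binary phenotype (see [genome_scan_logistic()]).
#' @param method `"logistic"` or `"interval"`.
#' @param map a `genetic_map` (required for `method = "interval"`).
#' @param n_perm number of permutations (>= 100).
#' @param alpha genome-wide significance level.
#' @param step_cM grid step for the interval method.
#' @param seed optional RNG seed.
#' @return A list (class `perm_threshold`): `threshold`, `extrema` (one per
#'   permutation), `alpha`, `n_perm`, `method`, `statistic`.
#' @export
permutation_threshold <- function(bins, y, method = c("logistic", "interval"),
                                  map = NULL, n_perm = 1000, alpha = 0.05,
                                  step_cM = 1, seed = NULL) {
  method <- match.arg(method)
  if (n_perm < 100) stop("n_perm must be at least 100")
  y <- align_phenotype(y, individual_ids(bins))
  if (!is.null(seed)) set.seed(seed)
  Ymat <- vapply(seq_len(n_perm), function(i) sample(y),
                 numeric(length(y)))
  if (method == "logistic") {
    sc <- .logistic_scan_matrix(bins$geno, Ymat)
    pv <- stats::pchisq(sc$stat, sc$df, lower.tail = FALSE)
    extrema <- apply(pv, 2L, min, na.rm = TRUE)
    threshold <- unname(stats::quantile(extrema, alpha, type = 1))
    statistic <- "pvalue"
  } else {
    if (is.null(map)) stop("interval method needs `map`")
    extrema <- .interval_maxlod_perm(bins, Ymat, step_cM = step_cM)
    threshold <- unname(stats::quantile(extrema, 1 - alpha, type = 1))
    statistic <- "lod"
  }
  structure(list(threshold = threshold, extrema = extrema, alpha = alpha,
                 n_perm = n_perm, method = method, statistic = statistic),
            class = "perm_threshold")
}

#' @export
print.perm_threshold <- function(x, ...) {
  cat(sprintf("Permutation threshold (%s, %d permutations, alpha = %g): %g\n",
              x$method, x$n_perm, x$alpha, x$threshold))
  invisible(x)
}

#' @keywords internal
#' Score on a "bigger is stronger" scale: LOD as-is, p-values as -log10 p.
.scan_score <- function(scan) {
  if (identical(attr(scan, "statistic"), "lod")) scan$lod
  else -log10(pmax(scan$pvalue, 1e-300))
}

.threshold_score <- function(scan, threshold) {
  if (identical(attr(scan, "statistic"), "lod")) threshold
  else -log10(max(threshold, 1e-300))
}

#' Call QTL peaks from a genome scan
#'
#' Positions beating the threshold (LOD above it, or p-value below it for a
#' p-value scan) are grouped into contiguous above-threshold runs per
#' chromosome; the maximum-score position of each run is its peak, ties going
#' to the smaller bp. Peaks on the same chromosome closer than
#' `min_separation_cM` are merged, keeping the higher one.
#'
#' @param scan a `qtl_scan`.
#' @param threshold significance threshold on the scan's native scale (a LOD
#'   for LOD scans, a p-value for p-value scans).
#' @param min_separation_cM minimum cM separation between reported peaks.
#' @return A data.frame (class `qtl_peaks`) with columns `name`, `chrom`,
#'   `peak_pos_bp`, `peak_pos_cM`, `lod`, `pvalue`. Empty when nothing beats
#'   the threshold.
#' @export
find_peaks <- function(scan, threshold, min_separation_cM = 30) {
  score <- .scan_score(scan)
  thr <- .threshold_score(scan, threshold)
  is_lod <- identical(attr(scan, "statistic"), "lod")
  above <- !is.na(score) & score >= thr
  peaks <- list()
  for (ch in unique(scan$chrom)) {
    idx <- which(scan$chrom == ch)
    idx <- idx[order(scan$pos_bp[idx])]
    ab <- above[idx]
    if (!any(ab)) next
    run <- cumsum(c(TRUE, diff(ab) != 0))
    for (r in unique(run[ab])) {
      members <- idx[run == r & ab]
      best <- members[which.max(score[members])]  # first max = smaller bp
      peaks[[length(peaks) + 1L]] <-
        data.frame(chrom = ch, peak_pos_bp = scan$pos_bp[best],
                   peak_pos_cM = scan$pos_cM[best], score = score[best])
    }
  }
  if (!length(peaks)) {
    out <- data.frame(name = character(), chrom = character(),
                      peak_pos_bp = numeric(), peak_pos_cM = numeric(),
                      lod = numeric(), pvalue = numeric())
    class(out) <- c("qtl_peaks", "data.frame")
    return(out)
  }
  pk <- do.call(rbind, peaks)
  # merge peaks closer than min_separation_cM, keeping the higher score
  repeat {
    pk <- pk[order(match(pk$chrom, unique(scan$chrom)), pk$peak_pos_cM), ]
    drop <- rep(FALSE, nrow(pk))
    changed <- FALSE
    for (i in seq_len(nrow(pk) - 1L)) {
      j <- i + 1L
      if (pk$chrom[i] == pk$chrom[j] && !drop[i] && !drop[j] &&
          abs(pk$peak_pos_cM[j] - pk$peak_pos_cM[i]) < min_separation_cM) {
        drop[if (pk$score[j] > pk$score[i]) i else j] <- TRUE
        changed <- TRUE
      }
    }
    pk <- pk[!drop, , drop = FALSE]
    if (!changed) break
  }
  out <- data.frame(name = sprintf("q%s_%d", sub("^chr", "", pk$chrom),
                                   stats::ave(seq_len(nrow(pk)), pk$chrom,
                                              FUN = seq_along)),
                    chrom = pk$chrom,
                    peak_pos_bp = pk$peak_pos_bp,
                    peak_pos_cM = pk$peak_pos_cM,
                    lod = if (is_lod) pk$score else NA_real_,
                    pvalue = if (is_lod) NA_real_ else 10^(-pk$score))
  rownames(out) <- NULL
  class(out) <- c("qtl_peaks", "data.frame")
  out
}

#' LOD support interval around a peak
#'
#' The outermost contiguous scan positions around the peak whose score stays
#' within `drop` of the peak score (LOD units for LOD scans, -log10 p units
#' for p-value scans), reported in bp and clipped at the scanned chromosome
#' ends.
#'
#' @param scan the `qtl_scan` the peak came from.
#' @param peak one row of a `qtl_peaks` data.frame (or a list with `chrom`
#'   and `peak_pos_cM`).
#' @param drop score drop defining the interval (default 1.5).
#' @return Numeric `c(start_bp, end_bp)`.
#' @export
lod_support_interval <- function(scan, peak, drop = 1.5) {
  score <- .scan_score(scan)
  idx <- which(scan$chrom == peak$chrom)
  idx <- idx[order(scan$pos_cM[idx])]
  pi_ <- idx[which.min(abs(scan$pos_cM[idx] - peak$peak_pos_cM))]
  cutoff <- score[pi_] - drop
  pos_in_chr <- match(pi_, idx)
  lo <- pos_in_chr
  while (lo > 1L && !is.na(score[idx[lo - 1L]]) &&
         score[idx[lo - 1L]] >= cutoff) lo <- lo - 1L
  hi <- pos_in_chr
  while (hi < length(idx) && !is.na(score[idx[hi + 1L]]) &&
         score[idx[hi + 1L]] >= cutoff) hi <- hi + 1L
  c(start_bp = scan$pos_bp[idx[lo]], end_bp = scan$pos_bp[idx[hi]])
}

#' Add LOD support intervals to a peak table
#'
#' @param peaks a `qtl_peaks` data.frame.
#' @param scan the `qtl_scan` the peaks came from.
#' @param drop score drop (see [lod_support_interval()]).
#' @return `peaks` with `interval_start_bp` and `interval_end_bp` columns.
#' @export
support_intervals <- function(peaks, scan, drop = 1.5) {
  if (!nrow(peaks)) {
    peaks$interval_start_bp <- numeric(0)
    peaks$interval_end_bp <- numeric(0)
    return(peaks)
  }
  iv <- t(vapply(seq_len(nrow(peaks)), function(i)
    lod_support_interval(scan, peaks[i, ], drop), numeric(2)))
  peaks$interval_start_bp <- iv[, 1L]
  peaks$interval_end_bp <- iv[, 2L]
  peaks
}

#' Percent phenotypic variance explained by a joint QTL fit
#'
#' Converts the joint-fit LOD of a model containing all peak markers
#' simultaneously into the classical variance-explained estimate
#' `100 * (1 - 10^(-2 LOD / n))`.
#'
#' @param joint_lod LOD of the joint fit against the null model.
#' @param n number of individuals in the fit.
#' @return Percent of phenotypic variance explained.
#' @export
variance_explained <- function(joint_lod, n) {
  if (n <= 0) stop("n must be positive")
  if (joint_lod < 0) stop("joint_lod must be non-negative")
  100 * (1 - 10^(-2 * joint_lod / n))
}

#' Joint binary-model fit of all QTL peaks
#'
#' Fits the logistic model with every peak's bin genotype as a factor
#' (no epistasis terms) on the individuals with complete genotypes at all
#' peaks, and reports the joint LOD and the variance explained.
#'
#' @param bins a `bin_marker_matrix`.
#' @param y binary phenotype.
#' @param peaks a `qtl_peaks` data.frame.
#' @return A list: `joint_lod`, `n`, `variance_explained_pct`.
#' @export
fit_joint_qtl <- function(bins, y, peaks) {
  y <- align_phenotype(y, individual_ids(bins))
  if (!nrow(peaks))
    return(list(joint_lod = 0, n = length(y), variance_explained_pct = 0))
  bin_idx <- vapply(seq_len(nrow(peaks)), function(i) {
    on_chr <- which(bins$bins$chrom == peaks$chrom[i])
    on_chr[which.min(abs(bins$bins$rep_pos_bp[on_chr] - peaks$peak_pos_bp[i]))]
  }, integer(1))
  G <- t(bins$geno[bin_idx, , drop = FALSE])
  keep <- stats::complete.cases(G)
  G <- G[keep, , drop = FALSE]
  yy <- y[keep]
  dat <- data.frame(y = yy)
  for (k in seq_len(ncol(G))) dat[[paste0("m", k)]] <- factor(G[, k])
  fit <- suppressWarnings(
    stats::glm(y ~ ., data = dat, family = stats::binomial()))
  lod <- max(fit$null.deviance - fit$deviance, 0) / (2 * log(10))
  list(joint_lod = lod, n = length(yy),
       variance_explained_pct = variance_explained(lod, length(yy)))
}

#' Genotype-class phenotype summary, favorable allele and dominance call
#'
#' Tabulates the two phenotype classes against the three genotype classes at
#' one marker. The favorable allele is the parent whose homozygote class has
#' the larger Type II proportion. The dominance call places the heterozygote
#' Type II proportion within the homozygote range: the middle third is
#' `additive`, the sixth nearest either homozygote (or beyond it) is
#' `dominant`, and the bands in between are `partial`.
#'
#' @param g integer dosage calls at the marker (0/1/2, NA allowed).
#' @param y binary phenotype (1 = Type II), same order as `g`.
#' @return A list: `table` (2 x 3 counts, rows TypeI/TypeII, columns
#'   AA/AB/BB), `props` (Type II proportion per genotype), `favorable_allele`
#'   ("A188"/"B73"), `dominance_call` ("additive"/"partial"/"dominant"; NA
#'   when a genotype class is empty).
#' @export
genotype_class_summary <- function(g, y) {
  keep <- !is.na(g) & !is.na(y)
  g <- g[keep]
  y <- y[keep]
  if (length(unique(g)) < 2L) stop("peak bin must be polymorphic")
  counts <- matrix(0L, 2L, 3L,
                   dimnames = list(c("TypeI", "TypeII"), c("AA", "AB", "BB")))
  for (d in 0:2) {
    lbl <- dosage_to_code(d)
    counts["TypeI", lbl] <- sum(g == d & y == 0L)
    counts["TypeII", lbl] <- sum(g == d & y == 1L)
  }
  tot <- colSums(counts)
  props <- ifelse(tot > 0, counts["TypeII", ] / tot, NA_real_)
  favorable <- if (is.na(props["AA"]) || is.na(props["BB"])) NA_character_
  else if (props["AA"] > props["BB"]) "A188"
  else "B73"
  dominance <- NA_character_
  if (!anyNA(props)) {
    p_lo <- min(props["AA"], props["BB"])
    p_hi <- max(props["AA"], props["BB"])
    span <- p_hi - p_lo
    if (span > 0) {
      t_ <- (props["AB"] - p_lo) / span
      t_clip <- min(max(t_, 0), 1)
      dominance <- if (abs(t_clip - 0.5) <= 1 / 6) "additive"
      else if (min(t_clip, 1 - t_clip) <= 1 / 6) "dominant"
      else "partial"
    }
  }
  list(table = counts, props = props, favorable_allele = favorable,
       dominance_call = unname(dominance))
}

#' Annotate peaks with genotype-class summaries at their bins
#'
#' @param peaks a `qtl_peaks` data.frame.
#' @param bins the `bin_marker_matrix` used in the scan.
#' @param y binary phenotype.
#' @return `peaks` with `favorable_allele` and `dominance_call` columns.
#' @export
annotate_peaks <- function(peaks, bins, y) {
  y <- align_phenotype(y, individual_ids(bins))
  fav <- character(nrow(peaks))
  dom <- character(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    on_chr <- which(bins$bins$chrom == peaks$chrom[i])
    bi <- on_chr[which.min(abs(bins$bins$rep_pos_bp[on_chr] -
                                 peaks$peak_pos_bp[i]))]
    s <- genotype_class_summary(bins$geno[bi, ], y)
    fav[i] <- if (is.na(s$favorable_allele)) NA_character_ else s$favorable_allele
    dom[i] <- if (is.na(s$dominance_call)) NA_character_ else s$dominance_call
  }
  peaks$favorable_allele <- fav
  peaks$dominance_call <- dom
  peaks
}

#' Plot a genome scan track
#'
#' Simple base-graphics track of the scan statistic by cumulative genome
#' position, with alternating chromosome shading and an optional threshold
#' line.
#'
#' @param x a `qtl_scan`.
#' @param threshold optional threshold (native scale) drawn as a dashed line.
#' @param ... passed to [plot()].
#' @return Invisibly, `x`.
#' @export
plot.qtl_scan <- function(x, threshold = NULL, ...) {
  score <- .scan_score(x)
  chroms <- unique(x$chrom)
  offsets <- c(0, cumsum(vapply(chroms, function(ch)
    max(x$pos_cM[x$chrom == ch]) + 10, numeric(1))))
  names(offsets) <- c(chroms, "end")
  gx <- x$pos_cM + offsets[x$chrom]
  ylab <- if (identical(attr(x, "statistic"), "lod")) "LOD" else "-log10 p"
  graphics::plot(gx, score, type = "n", xlab = "genome position (cM)",
                 ylab = ylab, ...)
  for (i in seq_along(chroms)) {
    on_chr <- x$chrom == chroms[i]
    graphics::lines(gx[on_chr], score[on_chr],
                    col = if (i %% 2) "grey25" else "steelblue4")
  }
  if (!is.null(threshold))
    graphics::abline(h = .threshold_score(x, threshold), lty = 2, col = "red")
  invisible(x)
}
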