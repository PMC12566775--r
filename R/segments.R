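#' @keywords internal
#' Sliding plurality vote over non-missing calls.
#' Window is centered, truncated at the ends; ties keep the original call.
.plurality_smooth <- function(x, w) {
  n <- length(x)
  if (w <= 1L || n < 2L) return(x)
  h <- (w - 1L) %/% 2L
  counts <- sapply(0:2, function(code) {
    cs <- c(0L, cumsum(x == code))
    lo <- pmax(seq_len(n) - h, 1L)
    hi <- pmin(seq_len(n) + h, n)
    cs[hi + 1L] - cs[lo]
  })
  best <- max.col(counts, ties.method = "first") - 1L
  # strict plurality required: on ties keep the original call
  top <- counts[cbind(seq_len(n), best + 1L)]
  n_at_top <- rowSums(counts == top)
  ifelse(n_at_top > 1L, x, best)
}

#' @keywords internal
#' Absorb runs shorter than min_snps into their flanks.
#' r is an rle-style list(lengths, values); returns the reduced rle.
.absorb_short_runs <- function(r, min_snps) {
  repeat {
    k <- length(r$lengths)
    if (k <= 1L) break
    short <- which(r$lengths < min_snps)
    if (!length(short)) break
    i <- short[which.min(r$lengths[short])]
    if (i > 1L && i < k && r$values[i - 1L] == r$values[i + 1L]) {
      # both flanks agree: merge straight through
      r$lengths[i - 1L] <- sum(r$lengths[(i - 1L):(i + 1L)])
      keep <- setdiff(seq_len(k), c(i, i + 1L))
    } else {
      into <- if (i == 1L) 2L
      else if (i == k) k - 1L
      else if (r$lengths[i + 1L] > r$lengths[i - 1L]) i + 1L else i - 1L
      r$lengths[into] <- r$lengths[into] + r$lengths[i]
      keep <- setdiff(seq_len(k), i)
    }
    r$lengths <- r$lengths[keep]
    r$values <- r$values[keep]
    # re-merge adjacent equal values created by the absorption
    same <- which(diff(r$values) == 0)
    while (length(same)) {
      j <- same[1L]
      r$lengths[j] <- r$lengths[j] + r$lengths[j + 1L]
      r$lengths <- r$lengths[-(j + 1L)]
      r$values <- r$values[-(j + 1L)]
      same <- which(diff(r$values) == 0)
    }
  }
  r
}

#' Infer chromosomal segments for one individual
#'
#' Converts noisy per-SNP calls into chromosomal segments harboring multiple
#' SNPs with the same genotype. Per chromosome: (1) a sliding plurality vote
#' of width `smooth_window` over the non-missing calls replaces each call by
#' the window's plurality code (ties keep the original call); (2) the smoothed
#' calls are run-length encoded into candidate segments; (3) candidates
#' supported by fewer than `min_snps_per_segment` SNPs are absorbed into a
#' flanking segment (merged through when both flanks agree, otherwise into
#' the better-supported flank, ties to the left). Segment boundaries are
#' placed at the bp midpoint between the last SNP of one segment and the
#' first SNP of the next; intervals are 1-based closed.
#'
#' @param gm a `genotype_matrix`.
#' @param individual individual id (may be omitted for a one-column matrix).
#' @param smooth_window odd window width (>= 1) for the plurality vote.
#' @param min_snps_per_segment minimum supporting SNPs per segment.
#' @return A data.frame (class `segment_set`) with columns `chrom`,
#'   `start_bp`, `end_bp`, `genotype` (AA/AB/BB), `n_snps`, and attribute
#'   `individual`. Chromosomes with zero non-missing calls contribute no rows.
#' @export
call_segments <- function(gm, individual = NULL, smooth_window = 5,
                          min_snps_per_segment = 3) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (smooth_window < 1 || smooth_window %% 2 != 1)
    stop("smooth_window must be an odd integer >= 1")
  if (is.null(individual)) {
    if (ncol(gm$geno) != 1L)
      stop("specify `individual` for a multi-individual matrix")
    individual <- colnames(gm$geno)[1L]
  }
  x_all <- gm$geno[, individual]
  chroms <- unique(gm$sites$chrom)
  out <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    on_chr <- gm$sites$chrom == chroms[ci]
    x <- x_all[on_chr]
    pos <- gm$sites$pos_bp[on_chr]
    obs <- which(!is.na(x))
    if (!length(obs)) next
    xx <- .plurality_smooth(x[obs], smooth_window)
    pp <- pos[obs]
    r <- rle(xx)
    r <- .absorb_short_runs(list(lengths = r$lengths, values = r$values),
                            min_snps_per_segment)
    k <- length(r$lengths)
    last_idx <- cumsum(r$lengths)
    first_idx <- c(1L, last_idx[-k] + 1L)
    start <- pp[first_idx]
    end <- pp[last_idx]
    if (k > 1L) {
      mids <- floor((pp[last_idx[-k]] + pp[first_idx[-1L]]) / 2)
      end[-k] <- mids
      start[-1L] <- mids + 1
    }
    out[[ci]] <- data.frame(chrom = chroms[ci], start_bp = start,
                            end_bp = end, genotype = dosage_to_code(r$values),
                            n_snps = r$lengths)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(), start_bp = numeric(),
                      end_bp = numeric(), genotype = character(),
                      n_snps = integer())
  rownames(res) <- NULL
  attr(res, "individual") <- individual
  class(res) <- c("segment_set", "data.frame")
  res
}

#' Infer segments for every individual in a genotype matrix
#'
#' @inheritParams call_segments
#' @return A named list of `segment_set` objects.
#' @export
call_segments_all <- function(gm, smooth_window = 5, min_snps_per_segment = 3) {
  ids <- individual_ids(gm)
  out <- lapply(ids, function(id)
    call_segments(gm, id, smooth_window, min_snps_per_segment))
  names(out) <- ids
  out
}

#' Count discernible recombination events in a segment set
#'
#' The discernible count is the number of segment transitions: the sum over
#' chromosomes of (number of segments - 1). Double crossovers between
#' adjacent SNPs are inherently invisible and are not counted.
#'
#' @param seg a `segment_set`.
#' @return Integer count.
#' @export
count_recombination_events <- function(seg) {
  if (!nrow(seg)) return(0L)
  sum(vapply(split(seg$chrom, seg$chrom), length, integer(1)) - 1L)
}

#' Expected discernible recombination count for an F2 individual
#'
#' An F2 individual is the union of two independent gametes, each with an
#' expected crossover count equal to the map length in Morgans; each crossover
#' creates at most one discernible genotype transition, so the expectation is
#' `2 * total map length in Morgans`.
#'
#' @param map a `genetic_map`.
#' @return Expected count (real).
#' @export
expected_recombination_count <- function(map) {
  2 * total_map_morgans(map)
}

#' Flag individuals with more recombination events than expected
#'
#' An individual is dropped when its observed count exceeds
#' `multiplier x expected`; excess segments are the signature of residual
#' genotyping error rather than real meiotic recombination.
#'
#' @param segsets named list of `segment_set` objects (from
#'   [call_segments_all()]).
#' @param expected expected count, e.g. [expected_recombination_count()].
#' @param multiplier tolerance multiplier (> 1).
#' @return A list with `retained` (ids), `dropped` (ids) and `report`
#'   (data.frame id, n_events, expected, dropped).
#' @export
filter_individuals <- function(segsets, expected, multiplier = 2) {
  if (multiplier <= 1) stop("multiplier must exceed 1")
  counts <- vapply(segsets, count_recombination_events, integer(1))
  drop <- counts > multiplier * expected
  list(retained = names(segsets)[!drop],
       dropped = names(segsets)[drop],
       report = data.frame(id = names(segsets), n_events = unname(counts),
                           expected = expected, dropped = unname(drop)))
}

#' Harmonize per-individual segments into population bin markers
#'
#' Bin boundaries are the union of all individuals' segment boundaries per
#' chromosome; each individual's call in a bin is the genotype of its covering
#' segment (NA where uncovered). Monomorphic bins are removed and adjacent
#' bins with identical call vectors are collapsed. The representative
#' position is the bin midpoint, with its cM position interpolated from the
#' genetic map.
#'
#' @param segsets named list of `segment_set` objects (>= 2 individuals).
#' @param map a `genetic_map`.
#' @return An object of class `bin_marker_matrix`: list with `bins`
#'   (data.frame chrom, start_bp, end_bp, rep_pos_bp, rep_pos_cM) and `geno`
#'   (integer dosage matrix, bins x individuals).
#' @export
harmonize_bins <- function(segsets, map) {
  if (length(segsets) < 2L) stop("need at least 2 retained individuals")
  ids <- names(segsets)
  chroms <- map_chromosomes(map)
  bins_out <- list()
  geno_out <- list()
  for (ch in chroms) {
    per_ind <- lapply(segsets, function(s) s[s$chrom == ch, , drop = FALSE])
    if (!any(vapply(per_ind, nrow, integer(1)) > 0)) next
    # half-open breakpoints: [start, end + 1)
    brk <- sort(unique(unlist(lapply(per_ind, function(s)
      c(s$start_bp, s$end_bp + 1)))))
    if (length(brk) < 2L) next
    b_start <- brk[-length(brk)]
    b_end <- brk[-1L] - 1
    calls <- matrix(NA_integer_, length(b_start), length(ids),
                    dimnames = list(NULL, ids))
    for (j in seq_along(ids)) {
      s <- per_ind[[j]]
      if (!nrow(s)) next
      idx <- findInterval(b_start, s$start_bp)
      cover <- idx >= 1L & b_end <= s$end_bp[pmax(idx, 1L)]
      calls[cover, j] <- code_to_dosage(s$genotype[idx[cover]])
    }
    bins_out[[ch]] <- data.frame(chrom = ch, start_bp = b_start,
                                 end_bp = b_end)
    geno_out[[ch]] <- calls
  }
  if (!length(bins_out)) stop("no segment coverage on any chromosome")
  bins <- do.call(rbind, bins_out)
  geno <- do.call(rbind, geno_out)
  # polymorphic bins only
  n_codes <- apply(geno, 1L, function(v) length(unique(v[!is.na(v)])))
  keep <- n_codes >= 2L
  if (!any(keep))
    stop("no informative overlap between individuals' coverage")
  bins <- bins[keep, , drop = FALSE]
  geno <- geno[keep, , drop = FALSE]
  # collapse physically adjacent bins with identical call vectors; bins that
  # became non-adjacent after the monomorphic drop are never merged across
  key <- paste(bins$chrom, apply(geno, 1L, paste, collapse = ","))
  adjacent <- c(FALSE,
                bins$chrom[-1L] == bins$chrom[-nrow(bins)] &
                  bins$start_bp[-1L] == bins$end_bp[-nrow(bins)] + 1)
  same_key <- c(FALSE, key[-1L] == key[-length(key)])
  run_id <- cumsum(!(adjacent & same_key))
  first <- !duplicated(run_id)
  ends <- tapply(bins$end_bp, run_id, function(v) v[length(v)])
  bins <- bins[first, , drop = FALSE]
  bins$end_bp <- as.numeric(ends)
  geno <- geno[first, , drop = FALSE]
  bins$rep_pos_bp <- floor((bins$start_bp + bins$end_bp) / 2)
  bins$rep_pos_cM <- unlist(lapply(unique(bins$chrom), function(ch)
    map_bp_to_cM(map, ch, bins$rep_pos_bp[bins$chrom == ch])),
    use.names = FALSE)
  rownames(bins) <- NULL
  rownames(geno) <- paste(bins$chrom, bins$rep_pos_bp, sep = "_")
  structure(list(bins = bins, geno = geno), class = "bin_marker_matrix")
}

#' @export
print.bin_marker_matrix <- function(x, ...) {
  cat("bin_marker_matrix:", nrow(x$bins), "bin markers x", ncol(x$geno),
      "individuals on", length(unique(x$bins$chrom)), "chromosomes\n")
  invisible(x)
}

#' Treat each SNP of a genotype matrix as a bin marker
#'
#' Wraps an already-clean (typically dense or error-free) genotype matrix as
#' a `bin_marker_matrix` with one zero-width bin per SNP, bypassing
#' segmentation. Used for scans on data that need no smoothing and for
#' calibration experiments.
#'
#' @param gm a `genotype_matrix`.
#' @param map a `genetic_map` covering the sites.
#' @return A `bin_marker_matrix`.
#' @export
snp_bins <- function(gm, map) {
  stopifnot(inherits(gm, "genotype_matrix"))
  s <- gm$sites
  cm <- unlist(lapply(unique(s$chrom), function(ch)
    map_bp_to_cM(map, ch, s$pos_bp[s$chrom == ch])), use.names = FALSE)
  bins <- data.frame(chrom = s$chrom, start_bp = s$pos_bp,
                     end_bp = s$pos_bp, rep_pos_bp = s$pos_bp,
                     rep_pos_cM = cm)
  structure(list(bins = bins, geno = gm$geno),
            class = "bin_marker_matrix")
}
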