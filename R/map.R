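#' Genetic map linking physical and genetic positions
#'
#' A genetic map is a per-chromosome scaffold of anchor markers with both a
#' physical position (bp) and a genetic position (cM). Positions between
#' anchors are interpolated piecewise linearly; positions outside the anchored
#' range are clamped to the terminal anchors. The map drives crossover
#' simulation, bin-marker cM assignment and interval mapping.
#'
#' @param anchors data.frame with columns `chrom`, `pos_bp` (1-based bp) and
#'   `pos_cM`. Within each chromosome `pos_bp` must be strictly increasing,
#'   `pos_cM` non-decreasing, and the first anchor must sit at 0 cM.
#' @return An object of class `genetic_map` (a data.frame of anchors).
#' @examples
#' gmap <- genetic_map(data.frame(chrom = "chr1",
#'                                pos_bp = c(1, 50e6, 100e6),
#'                                pos_cM = c(0, 60, 100)))
#' map_bp_to_cM(gmap, "chr1", 25e6)
#' @export
genetic_map <- function(anchors) {
  stopifnot(is.data.frame(anchors),
            all(c("chrom", "pos_bp", "pos_cM") %in% names(anchors)))
  anchors <- anchors[, c("chrom", "pos_bp", "pos_cM")]
  anchors$chrom <- as.character(anchors$chrom)
  ord <- order(match(anchors$chrom, unique(anchors$chrom)), anchors$pos_bp)
  anchors <- anchors[ord, , drop = FALSE]
  rownames(anchors) <- NULL
  for (ch in unique(anchors$chrom)) {
    a <- anchors[anchors$chrom == ch, ]
    if (nrow(a) < 2L)
      stop("chromosome '", ch, "' needs at least two anchors")
    if (any(diff(a$pos_bp) <= 0))
      stop("pos_bp must be strictly increasing on chromosome '", ch, "'")
    if (any(diff(a$pos_cM) < 0))
      stop("pos_cM must be non-decreasing on chromosome '", ch, "'")
    if (a$pos_cM[1] != 0)
      stop("first anchor on chromosome '", ch, "' must be at 0 cM")
  }
  class(anchors) <- c("genetic_map", "data.frame")
  anchors
}

#' @export
print.genetic_map <- function(x, ...) {
  len <- chrom_lengths_cM(x)
  cat("Genetic map:", length(len), "chromosomes,",
      sprintf("%.1f cM (%.2f Morgans) total\n", sum(len), sum(len) / 100))
  print(data.frame(chrom = names(len),
                   length_cM = unname(len),
                   length_bp = unname(chrom_lengths_bp(x)),
                   row.names = NULL))
  invisible(x)
}

#' Chromosome names of a genetic map
#' @param map a `genetic_map`.
#' @return Character vector of chromosome identifiers in map order.
#' @export
map_chromosomes <- function(map) unique(map$chrom)

#' Chromosome lengths in centimorgans
#' @param map a `genetic_map`.
#' @return Named numeric vector of terminal-anchor cM positions.
#' @export
chrom_lengths_cM <- function(map) {
  vapply(split(map$pos_cM, factor(map$chrom, levels = map_chromosomes(map))),
         max, numeric(1))
}

#' Chromosome lengths in base pairs
#' @param map a `genetic_map`.
#' @return Named numeric vector of terminal-anchor bp positions.
#' @export
chrom_lengths_bp <- function(map) {
  vapply(split(map$pos_bp, factor(map$chrom, levels = map_chromosomes(map))),
         max, numeric(1))
}

#' Total map length in Morgans
#' @param map a `genetic_map`.
#' @return Total genetic length summed over chromosomes, in Morgans.
#' @export
total_map_morgans <- function(map) sum(chrom_lengths_cM(map)) / 100

.map_anchors <- function(map, chrom) {
  a <- map[map$chrom == chrom, , drop = FALSE]
  if (nrow(a) == 0L) stop("chromosome '", chrom, "' not in map")
  a
}

#' Interpolate genetic position from physical position
#'
#' @param map a `genetic_map`.
#' @param chrom single chromosome id.
#' @param bp numeric vector of physical positions (bp).
#' @return Numeric vector of cM positions (piecewise linear, clamped at
#'   terminal anchors).
#' @export
map_bp_to_cM <- function(map, chrom, bp) {
  a <- .map_anchors(map, chrom)
  stats::approx(a$pos_bp, a$pos_cM, xout = bp, rule = 2, ties = "ordered")$y
}

#' Interpolate physical position from genetic position
#'
#' Flat (0 recombination) stretches of the map are resolved to the left end of
#' the stretch, which keeps the transform deterministic.
#'
#' @param map a `genetic_map`.
#' @param chrom single chromosome id.
#' @param cM numeric vector of genetic positions (cM).
#' @return Numeric vector of bp positions.
#' @export
map_cM_to_bp <- function(map, chrom, cM) {
  a <- .map_anchors(map, chrom)
  keep <- !duplicated(a$pos_cM)
  stats::approx(a$pos_cM[keep], a$pos_bp[keep], xout = cM, rule = 2,
                ties = "ordered")$y
}

#' Default maize-like synthetic genome map
#'
#' Ten chromosomes at reduced scale with genetic lengths between roughly 105
#' and 180 cM (about 14 Morgans in total, close to the shape of the maize
#' genetic map) and a uniform recombination rate of 1 cM per Mb, encoded as
#' two-anchor linear maps.
#'
#' @param n_chrom number of chromosomes (defaults to 10).
#' @param lengths_cM genetic lengths; recycled/truncated to `n_chrom`.
#' @param bp_per_cM physical scale (bp per cM).
#' @return A `genetic_map`.
#' @export
default_genetic_map <- function(n_chrom = 10,
                                lengths_cM = c(180, 170, 160, 150, 145,
                                               140, 130, 120, 110, 105),
                                bp_per_cM = 1e6) {
  lengths_cM <- rep_len(lengths_cM, n_chrom)
  genetic_map(data.frame(
    chrom = rep(paste0("chr", seq_len(n_chrom)), each = 2L),
    pos_bp = as.vector(rbind(1, round(lengths_cM * bp_per_cM))),
    pos_cM = as.vector(rbind(0, lengths_cM))))
}

#' Uniform genome map (equal-length chromosomes)
#'
#' Convenience constructor used throughout the tests: `n_chrom` chromosomes of
#' identical genetic length with a constant bp/cM ratio.
#'
#' @inheritParams default_genetic_map
#' @param length_cM genetic length of every chromosome.
#' @return A `genetic_map`.
#' @export
uniform_genetic_map <- function(n_chrom = 10, length_cM = 120, bp_per_cM = 1e6) {
  default_genetic_map(n_chrom, rep(length_cM, n_chrom), bp_per_cM)
}
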