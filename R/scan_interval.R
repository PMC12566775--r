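#' @keywords internal
#' Drop bins with no segregation: a marker where every non-missing call is
#' identical carries no mapping information (and would otherwise distort the
#' flanking-marker genotype inference).
.drop_monomorphic_bins <- function(bins) {
  keep <- apply(bins$geno, 1L, function(v) length(unique(v[!is.na(v)]))) >= 2L
  if (all(keep)) return(bins)
  structure(list(bins = bins$bins[keep, , drop = FALSE],
                 geno = bins$geno[keep, , drop = FALSE]),
            class = "bin_marker_matrix")
}

#' Haldane map function: cM distance to recombination fraction
#'
#' @param d_cM genetic distance in cM (vectorized).
#' @return Recombination fraction `0.5 * (1 - exp(-2 d / 100))`.
#' @export
haldane_r <- function(d_cM) 0.5 * (1 - exp(-d_cM / 50))

#' @keywords internal
#' F2 genotype transition probability P(to | from) between two linked loci
#' with recombination fraction r; genotypes are A188 dosages 0/1/2. Derived
#' from two independent gamete Markov chains.
.f2_trans <- function(from, to, r) {
  d <- abs(from - to)
  out <- numeric(length(d))
  from_het <- from == 1L
  to_het <- to == 1L
  out[from_het & to_het] <- ((1 - r)^2 + r^2)[from_het & to_het]
  out[from_het & !to_het] <- (r * (1 - r))[from_het & !to_het]
  hom <- !from_het
  out[hom & d == 0] <- ((1 - r)^2)[hom & d == 0]
  out[hom & d == 1] <- (2 * r * (1 - r))[hom & d == 1]
  out[hom & d == 2] <- (r^2)[hom & d == 2]
  out
}

#' @keywords internal
#' Genotype probabilities P(g | flanking informative markers) for every
#' individual at every grid position of one chromosome.
#' mpos_cM: marker cM positions; G: markers x individuals dosage matrix;
#' grid: cM positions. Returns a list of three n_grid x n_ind matrices
#' (weights for g = 0, 1, 2, rows normalized).
.genotype_weights <- function(mpos_cM, G, grid) {
  n_ind <- ncol(G)
  n_grid <- length(grid)
  prior <- c(0.25, 0.5, 0.25)
  W <- lapply(1:3, function(k) matrix(prior[k], n_grid, n_ind))
  for (j in seq_len(n_ind)) {
    obs <- which(!is.na(G[, j]))
    if (!length(obs)) next
    mp <- mpos_cM[obs]
    gg <- G[obs, j]
    li <- findInterval(grid, mp)
    has_l <- li >= 1L
    ri <- li + 1L
    has_r <- ri <= length(mp)
    r1 <- haldane_r(pmax(grid - mp[pmax(li, 1L)], 0))
    r2 <- haldane_r(pmax(mp[pmin(ri, length(mp))] - grid, 0))
    gl <- gg[pmax(li, 1L)]
    gr <- gg[pmin(ri, length(mp))]
    for (g in 0:2) {
      wl <- ifelse(has_l, .f2_trans(gl, rep(g, n_grid), r1), prior[g + 1L])
      wr <- ifelse(has_r, .f2_trans(rep(g, n_grid), gr, r2), 1)
      W[[g + 1L]][, j] <- wl * wr
    }
  }
  tot <- W[[1L]] + W[[2L]] + W[[3L]]
  lapply(W, function(M) M / tot)
}

#' @keywords internal
#' EM fit of the binary penetrance model at one locus, vectorized over
#' phenotype columns. W: n x 3 genotype-probability matrix. Y: n x P matrix
#' of 0/1 phenotypes. Fits p_g = P(y = 1 | g) by EM (E-step: posterior
#' genotype weights; M-step: weighted class means) and returns the LOD of the
#' fitted model against the null with p = column mean of y.
.em_binary <- function(W, Y, tol = 1e-6, maxit = 100) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  P <- ncol(Y)
  W1 <- W[, 1L]; W2 <- W[, 2L]; W3 <- W[, 3L]
  csY <- colSums(Y)
  # complete-data initialization: weighted class means
  p <- rbind(colSums(W1 * Y) / max(sum(W1), 1e-12),
             colSums(W2 * Y) / max(sum(W2), 1e-12),
             colSums(W3 * Y) / max(sum(W3), 1e-12))
  pbar <- csY / n
  sw <- c(sum(W1), sum(W2), sum(W3))
  for (g in 1:3) if (sw[g] < 1e-9) p[g, ] <- pbar
  ll <- rep(-Inf, P)
  for (it in seq_len(maxit)) {
    Pg1 <- matrix(p[1L, ], n, P, byrow = TRUE)
    Pg2 <- matrix(p[2L, ], n, P, byrow = TRUE)
    Pg3 <- matrix(p[3L, ], n, P, byrow = TRUE)
    M1 <- W1 * (Y * Pg1 + (1 - Y) * (1 - Pg1))
    M2 <- W2 * (Y * Pg2 + (1 - Y) * (1 - Pg2))
    M3 <- W3 * (Y * Pg3 + (1 - Y) * (1 - Pg3))
    S <- pmax(M1 + M2 + M3, 1e-300)
    ll <- colSums(log(S))
    A1 <- M1 / S; A2 <- M2 / S; A3 <- M3 / S
    d1 <- pmax(colSums(A1), 1e-12)
    d2 <- pmax(colSums(A2), 1e-12)
    d3 <- pmax(colSums(A3), 1e-12)
    p_new <- rbind(colSums(A1 * Y) / d1,
                   colSums(A2 * Y) / d2,
                   colSums(A3 * Y) / d3)
    delta <- max(abs(p_new - p))
    p <- p_new
    if (delta < tol) break
  }
  # final likelihood at the converged penetrances
  Pg1 <- matrix(p[1L, ], n, P, byrow = TRUE)
  Pg2 <- matrix(p[2L, ], n, P, byrow = TRUE)
  Pg3 <- matrix(p[3L, ], n, P, byrow = TRUE)
  S <- pmax(W1 * (Y * Pg1 + (1 - Y) * (1 - Pg1)) +
              W2 * (Y * Pg2 + (1 - Y) * (1 - Pg2)) +
              W3 * (Y * Pg3 + (1 - Y) * (1 - Pg3)), 1e-300)
  ll <- colSums(log(S))
  ll0 <- .xlogx(csY) + .xlogx(n - csY) - .xlogx(rep(n, P))
  lod <- pmax((ll - ll0) / log(10), 0)
  list(lod = lod, p = p, n_iter = it)
}

#' Binary-model interval mapping by EM
#'
#' Standard interval mapping for a binary trait: at each position of a cM
#' grid (every `step_cM`, plus every marker position), latent F2 QTL genotype
#' probabilities are computed from the nearest informative flanking markers
#' under the Haldane map function with no crossover interference (a missing
#' flank falls back to the marginal 1:2:1 prior on that side), and the
#' penetrances P(Type II | genotype) are fit by EM. The LOD compares the
#' fitted model against the null penetrance equal to the overall Type II
#' frequency. At a fully informative marker the result equals the 2-df
#' single-marker binomial likelihood-ratio LOD.
#'
#' @param bins a `bin_marker_matrix` with cM positions.
#' @param map a `genetic_map` (for the bp coordinates of grid positions).
#' @param y binary phenotype (see [genome_scan_logistic()]).
#' @param step_cM pseudomarker grid step (default 1 cM).
#' @param tol,maxit EM convergence controls.
#' @return A `qtl_scan` data.frame with columns `chrom`, `pos_bp`, `pos_cM`,
#'   `lod`, `n`; attributes `statistic` = "lod", `method` = "interval_em".
#' @export
interval_scan_binary <- function(bins, map, y, step_cM = 1,
                                 tol = 1e-6, maxit = 100) {
  y <- align_phenotype(y, individual_ids(bins))
  Y <- matrix(y, ncol = 1L)
  bins <- .drop_monomorphic_bins(bins)
  chroms <- unique(bins$bins$chrom)
  out <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    on_chr <- bins$bins$chrom == ch
    mpos <- bins$bins$rep_pos_cM[on_chr]
    G <- bins$geno[on_chr, , drop = FALSE]
    grid <- sort(unique(c(seq(min(mpos), max(mpos), by = step_cM), mpos)))
    W <- .genotype_weights(mpos, G, grid)
    lod <- vapply(seq_along(grid), function(i) {
      .em_binary(cbind(W[[1L]][i, ], W[[2L]][i, ], W[[3L]][i, ]), Y,
                 tol = tol, maxit = maxit)$lod
    }, numeric(1))
    out[[ci]] <- data.frame(chrom = ch,
                            pos_bp = round(map_cM_to_bp(map, ch, grid)),
                            pos_cM = grid, lod = lod, n = length(y))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "statistic") <- "lod"
  attr(res, "method") <- "interval_em"
  class(res) <- c("qtl_scan", "data.frame")
  res
}

#' @keywords internal
#' Max LOD per phenotype column over the whole genome (vectorized interval
#' scan used by the permutation threshold).
.interval_maxlod_perm <- function(bins, y_mat, step_cM = 1,
                                  tol = 1e-4, maxit = 100) {
  bins <- .drop_monomorphic_bins(bins)
  chroms <- unique(bins$bins$chrom)
  maxlod <- rep(0, ncol(y_mat))
  for (ch in chroms) {
    on_chr <- bins$bins$chrom == ch
    mpos <- bins$bins$rep_pos_cM[on_chr]
    G <- bins$geno[on_chr, , drop = FALSE]
    grid <- sort(unique(c(seq(min(mpos), max(mpos), by = step_cM), mpos)))
    W <- .genotype_weights(mpos, G, grid)
    for (i in seq_along(grid)) {
      lod <- .em_binary(cbind(W[[1L]][i, ], W[[2L]][i, ], W[[3L]][i, ]),
                        y_mat, tol = tol, maxit = maxit)$lod
      maxlod <- pmax(maxlod, lod)
    }
  }
  maxlod
}
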