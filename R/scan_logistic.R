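#' @keywords internal
#' x * log(x) with the 0 log 0 = 0 convention (elementwise, matrices allowed).
.xlogx <- function(x) {
  out <- x * log(pmax(x, 1))
  pos <- x > 0 & x < 1
  out[pos] <- x[pos] * log(x[pos])
  out
}

#' @keywords internal
#' Likelihood-ratio statistic of a 2 x K contingency table, computed from the
#' per-class totals n_k and per-class successes n1_k (matrices: rows = bins,
#' columns = genotype classes, one statistic per row). This is exactly the
#' deviance difference of the factor-coded logistic fit against the
#' intercept-only model, and stays finite under complete separation.
.lrt_2xk <- function(n1k, nk) {
  n0k <- nk - n1k
  n1 <- rowSums(n1k)
  n <- rowSums(nk)
  n0 <- n - n1
  2 * (rowSums(.xlogx(n1k)) + rowSums(.xlogx(n0k)) - rowSums(.xlogx(nk)) -
         .xlogx(n1) - .xlogx(n0) + .xlogx(n))
}

#' @keywords internal
#' Ridge-penalized logistic regression by IRLS (penalty on non-intercept
#' coefficients). Returns the unpenalized deviance evaluated at the
#' penalized estimate.
.ridge_logistic <- function(X, y, lambda = 1e-4, maxit = 50, tol = 1e-8) {
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1L)), p, p)
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- as.vector(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X, w * X) + pen, crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  mu <- stats::plogis(as.vector(X %*% beta))
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  list(coef = as.vector(beta),
       deviance = -2 * sum(y * log(mu) + (1 - y) * log(1 - mu)))
}

#' Single-marker logistic-regression test for a binary phenotype
#'
#' Likelihood-ratio test of `y ~ genotype` against the intercept-only
#' logistic model. With the default 2-df factor coding (the genotype-
#' frequency comparison between phenotype classes) the maximum-likelihood fit
#' has a closed form through the 2 x 3 contingency table and remains finite
#' under complete separation. The 1-df additive (dosage) coding is fit by
#' `glm`; if the fit diverges (separation) a small ridge penalty (1e-4) on
#' the coefficients stabilizes it and the event is flagged.
#'
#' @param g integer dosage calls at one marker (0/1/2, NA allowed).
#' @param y binary phenotype vector (1 = Type II), same length as `g`.
#' @param coding `"factor"` (2 df) or `"additive"` (1 df).
#' @return A list: `pvalue`, `statistic` (LRT), `df`, `n` (non-missing pairs),
#'   `class_props` (Type II proportion per genotype class), `ridge_active`,
#'   and `reason` (NA unless the test is undefined, e.g. monomorphic marker).
#' @export
logistic_marker_test <- function(g, y, coding = c("factor", "additive")) {
  coding <- match.arg(coding)
  keep <- !is.na(g) & !is.na(y)
  g <- g[keep]
  y <- y[keep]
  n <- length(y)
  props <- c(AA = NA_real_, AB = NA_real_, BB = NA_real_)
  for (d in 0:2) {
    lbl <- dosage_to_code(d)
    if (any(g == d)) props[lbl] <- mean(y[g == d])
  }
  classes <- sort(unique(g))
  if (length(classes) < 2L || length(unique(y)) < 1L || n == 0L)
    return(list(pvalue = NA_real_, statistic = NA_real_, df = NA_integer_,
                n = n, class_props = props, ridge_active = FALSE,
                reason = "monomorphic marker"))
  if (coding == "factor") {
    nk <- t(vapply(classes, function(d) sum(g == d), numeric(1)))
    n1k <- t(vapply(classes, function(d) sum(y[g == d]), numeric(1)))
    stat <- .lrt_2xk(n1k, nk)
    df <- length(classes) - 1L
    ridge <- FALSE
  } else {
    fit <- suppressWarnings(stats::glm(y ~ g, family = stats::binomial()))
    ridge <- !fit$converged || max(abs(stats::coef(fit))) > 15
    if (ridge) {
      X <- cbind(1, g)
      dev1 <- .ridge_logistic(X, y)$deviance
      dev0 <- .ridge_logistic(cbind(rep(1, n)), y)$deviance
      stat <- max(dev0 - dev1, 0)
    } else {
      stat <- max(fit$null.deviance - fit$deviance, 0)
    }
    df <- 1L
  }
  list(pvalue = stats::pchisq(stat, df, lower.tail = FALSE),
       statistic = stat, df = df, n = n, class_props = props,
       ridge_active = ridge, reason = NA_character_)
}

#' @keywords internal
#' Vectorized factor-coded logistic LRT scan over all bins for one or many
#' phenotype vectors. G: bins x individuals dosage matrix. Y: individuals x P
#' matrix of 0/1 phenotypes. Returns list(stat, df, n): stat is bins x P.
.logistic_scan_matrix <- function(G, Y) {
  Y <- as.matrix(Y)
  obs <- !is.na(G)
  n <- rowSums(obs)
  Ik <- lapply(0:2, function(d) {
    M <- (G == d)
    M[!obs] <- FALSE
    storage.mode(M) <- "numeric"
    M
  })
  nk <- vapply(Ik, rowSums, numeric(nrow(G)))          # bins x 3
  if (is.null(dim(nk))) nk <- matrix(nk, nrow = 1L)
  n1k <- lapply(Ik, function(M) M %*% Y)               # each bins x P
  obs_num <- obs
  storage.mode(obs_num) <- "numeric"
  n1 <- obs_num %*% Y                                  # bins x P
  n0 <- n - n1
  term_classes <- Reduce(`+`, lapply(seq_along(Ik), function(k) {
    .xlogx(n1k[[k]]) + .xlogx(nk[, k] - n1k[[k]])
  }))
  stat <- 2 * (term_classes - rowSums(.xlogx(nk)) -
                 .xlogx(n1) - .xlogx(n0) + .xlogx(n))
  df <- rowSums(nk > 0) - 1L
  stat[df < 1L, ] <- NA_real_
  list(stat = stat, df = df, n = n)
}

#' Genome-wide logistic-regression scan over bin markers
#'
#' Applies [logistic_marker_test()] (factor coding, computed in vectorized
#' closed form) to every bin marker.
#'
#' @param bins a `bin_marker_matrix`.
#' @param y binary phenotype vector named by individual id, or a
#'   `phenotype_vector` data.frame (columns id, class).
#' @return A `qtl_scan` data.frame with columns `chrom`, `pos_bp`, `pos_cM`,
#'   `pvalue`, `df`, `n`; attributes `statistic` = "pvalue",
#'   `method` = "logistic".
#' @export
genome_scan_logistic <- function(bins, y) {
  y <- align_phenotype(y, individual_ids(bins))
  sc <- .logistic_scan_matrix(bins$geno, matrix(y, ncol = 1L))
  pv <- stats::pchisq(sc$stat[, 1L], sc$df, lower.tail = FALSE)
  res <- data.frame(chrom = bins$bins$chrom,
                    pos_bp = bins$bins$rep_pos_bp,
                    pos_cM = bins$bins$rep_pos_cM,
                    pvalue = pv, df = sc$df, n = sc$n)
  attr(res, "statistic") <- "pvalue"
  attr(res, "method") <- "logistic"
  class(res) <- c("qtl_scan", "data.frame")
  res
}

#' Benjamini-Hochberg significant bins at a target FDR
#'
#' @param scan a p-value `qtl_scan`.
#' @param q false-discovery-rate level (default 1%).
#' @return The scan rows with BH-adjusted p <= `q`, with a `padj` column.
#' @export
fdr_significant <- function(scan, q = 0.01) {
  if (!nrow(scan)) return(cbind(scan, padj = numeric(0)))
  scan$padj <- stats::p.adjust(scan$pvalue, method = "BH")
  out <- scan[!is.na(scan$padj) & scan$padj <= q, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @keywords internal
#' Coerce a phenotype input to a 0/1 vector aligned with `ids`.
align_phenotype <- function(y, ids) {
  if (is.data.frame(y)) {
    stopifnot(all(c("id", "class") %in% names(y)))
    v <- ifelse(y$class %in% c("TypeII", "XT-II", "1"), 1L, 0L)
    names(v) <- y$id
    y <- v
  }
  if (!is.null(names(y))) {
    if (!all(ids %in% names(y)))
      stop("phenotype missing for some individuals")
    y <- y[ids]
  } else if (length(y) != length(ids)) {
    stop("phenotype length does not match individuals")
  }
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("phenotype must be binary 0/1")
  if (length(unique(y)) < 2L)
    warning("phenotype has a single class; scans will be null")
  unname(y)
}
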