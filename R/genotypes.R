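#' Genotype matrix container
#'
#' Holds SNP genotype observations for a set of individuals. Genotypes are
#' stored internally as the dosage of the A188 allele: 2 = `AA` (A188
#' homozygote), 1 = `AB` (heterozygote), 0 = `BB` (B73 homozygote), `NA` =
#' missing. Sites are sorted by (chrom, pos_bp).
#'
#' @param sites data.frame with columns `chrom` and `pos_bp` (1-based).
#' @param geno integer matrix, sites x individuals, values in {0, 1, 2, NA}.
#'   Column names are individual ids.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, geno) {
  stopifnot(is.data.frame(sites), all(c("chrom", "pos_bp") %in% names(sites)),
            is.matrix(geno), nrow(geno) == nrow(sites))
  if (is.null(colnames(geno))) stop("geno must have individual ids as colnames")
  sites$chrom <- as.character(sites$chrom)
  ord <- order(match(sites$chrom, unique(sites$chrom)), sites$pos_bp)
  sites <- sites[ord, , drop = FALSE]
  geno <- geno[ord, , drop = FALSE]
  bad <- !(geno %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("genotype dosages must be 0, 1, 2 or NA")
  storage.mode(geno) <- "integer"
  rownames(sites) <- NULL
  rownames(geno) <- paste(sites$chrom, sites$pos_bp, sep = "_")
  structure(list(sites = sites, geno = geno), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$geno), "sites x", ncol(x$geno),
      "individuals;", sprintf("%.1f%% missing\n", 100 * mean(is.na(x$geno))))
  invisible(x)
}

#' Individual ids of a genotype container
#' @param x a `genotype_matrix` or `bin_marker_matrix`.
#' @return Character vector of individual ids.
#' @export
individual_ids <- function(x) colnames(x$geno)

#' Convert genotype codes to A188-allele dosage
#'
#' @param codes character vector of `"AA"`, `"AB"`, `"BB"`, `"NA"`/`NA`.
#' @return Integer dosage vector (AA = 2, AB = 1, BB = 0).
#' @export
code_to_dosage <- function(codes) {
  d <- c(AA = 2L, AB = 1L, BB = 0L)[as.character(codes)]
  unname(d)
}

#' Convert A188-allele dosage to genotype codes
#'
#' @param dosage integer vector in {0, 1, 2, NA}.
#' @return Character vector of `"AA"`, `"AB"`, `"BB"` (NA preserved).
#' @export
dosage_to_code <- function(dosage) {
  c("BB", "AB", "AA")[dosage + 1L]
}

#' Subset a genotype matrix by individuals
#' @param x a `genotype_matrix`.
#' @param ids individual ids to keep (order preserved).
#' @return A `genotype_matrix` restricted to `ids`.
#' @export
subset_individuals <- function(x, ids) {
  missing_ids <- setdiff(ids, colnames(x$geno))
  if (length(missing_ids))
    stop("unknown individual ids: ", paste(missing_ids, collapse = ", "))
  genotype_matrix(x$sites, x$geno[, ids, drop = FALSE])
}
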