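#' @keywords internal
#' Write a table with a commented header line stating units/conventions.
.write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a genotype matrix as TSV
#'
#' Rows are SNPs (`chrom`, `pos_bp`, then one column per individual with
#' codes AA/AB/BB/NA; AA = A188 homozygote; positions 1-based bp).
#'
#' @param gm a `genotype_matrix`.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_genotype_tsv <- function(gm, path) {
  codes <- matrix(dosage_to_code(gm$geno), nrow(gm$geno),
                  dimnames = dimnames(gm$geno))
  codes[is.na(codes)] <- "NA"
  df <- cbind(gm$sites[, c("chrom", "pos_bp")], as.data.frame(codes))
  .write_tsv(df, path,
             "genotypes: pos_bp 1-based; AA = A188 hom, BB = B73 hom, AB = het")
}

#' Read a genotype TSV written by [write_genotype_tsv()]
#'
#' @param path input file.
#' @return A `genotype_matrix`.
#' @export
read_genotype_tsv <- function(path) {
  df <- .read_tsv(path)
  ind <- setdiff(names(df), c("chrom", "pos_bp"))
  codes <- as.matrix(df[, ind, drop = FALSE])
  codes[codes == "NA"] <- NA
  geno <- matrix(code_to_dosage(codes), nrow(codes),
                 dimnames = list(NULL, ind))
  genotype_matrix(df[, c("chrom", "pos_bp")], geno)
}

#' Read genotype calls (TSV or minimal VCF)
#'
#' The VCF path parses the fixed fields and GT with `vcfR` and maps calls to
#' A188-allele dosages using a required parental-orientation sidecar giving
#' the A188 allele at each site; sites with non-biallelic GT codes are
#' skipped and tallied (attribute `n_skipped`).
#'
#' @param path genotype file.
#' @param format `"tsv"` or `"vcf"`.
#' @param parents for VCF input, a data.frame with `chrom`, `pos_bp`,
#'   `a188_allele` (the base carried by A188 at the site).
#' @return A `genotype_matrix`.
#' @export
read_genotype_input <- function(path, format = c("tsv", "vcf"),
                                parents = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tsv") return(read_genotype_tsv(path))
  if (is.null(parents))
    stop("VCF input needs a parental-orientation table ",
         "(chrom, pos_bp, a188_allele)")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  chrom <- fix[, "CHROM"]
  pos <- as.numeric(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  gt_clean <- gsub("\\|", "/", gt)
  alt_dosage <- matrix(NA_integer_, nrow(gt), ncol(gt),
                       dimnames = dimnames(gt))
  alt_dosage[gt_clean %in% c("0/0")] <- 0L
  alt_dosage[gt_clean %in% c("0/1", "1/0")] <- 1L
  alt_dosage[gt_clean %in% c("1/1")] <- 2L
  nonbiallelic <- !is.na(gt_clean) & !(gt_clean %in%
                                         c("0/0", "0/1", "1/0", "1/1", "./."))
  bad_site <- rowSums(nonbiallelic) > 0 | grepl(",", alt)
  idx <- match(paste(chrom, pos), paste(parents$chrom, parents$pos_bp))
  if (anyNA(idx))
    stop("parental orientation missing for ",
         sum(is.na(idx)), " VCF site(s)")
  a188 <- parents$a188_allele[idx]
  orient_ok <- a188 == ref | a188 == alt
  keep <- !bad_site & orient_ok
  n_skipped <- sum(!keep)
  # dosage of the A188 allele: flip where A188 carries ALT
  dos <- alt_dosage[keep, , drop = FALSE]
  flip <- a188[keep] == alt[keep]
  dos[!flip, ] <- 2L - dos[!flip, , drop = FALSE]
  gm <- genotype_matrix(data.frame(chrom = chrom[keep], pos_bp = pos[keep]),
                        dos)
  attr(gm, "n_skipped") <- n_skipped
  gm
}

#' Write / read a phenotype table (id, class)
#'
#' @param phenotype data.frame with `id` and `class` (TypeI/TypeII).
#' @param path file path.
#' @return The path (write) or the data.frame (read).
#' @export
write_phenotype_tsv <- function(phenotype, path) {
  .write_tsv(phenotype[, c("id", "class")], path,
             "phenotype classes: TypeI (compact) / TypeII (friable)")
}

#' @rdname write_phenotype_tsv
#' @export
read_phenotype_tsv <- function(path) .read_tsv(path)

#' Write / read a genetic map as TSV (chrom, pos_bp, pos_cM)
#'
#' @param map a `genetic_map`.
#' @param path file path.
#' @return The path (write) or a `genetic_map` (read).
#' @export
write_map_tsv <- function(map, path) {
  .write_tsv(as.data.frame(map), path,
             "genetic map anchors: pos_bp 1-based, pos_cM centimorgans")
}

#' @rdname write_map_tsv
#' @export
read_map_tsv <- function(path) genetic_map(.read_tsv(path))

#' Write segment sets as BED
#'
#' BED convention: 0-based half-open intervals (internal 1-based closed
#' coordinates are shifted on output). Columns: chrom, start, end, genotype,
#' n_snps, individual.
#'
#' @param segsets named list of `segment_set` objects.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_segments_bed <- function(segsets, path) {
  rows <- lapply(names(segsets), function(id) {
    s <- segsets[[id]]
    if (!nrow(s)) return(NULL)
    data.frame(chrom = s$chrom, start = s$start_bp - 1, end = s$end_bp,
               genotype = s$genotype, n_snps = s$n_snps, individual = id)
  })
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# BED: 0-based half-open; genotype AA = A188 hom", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read a bin-marker matrix as TSV
#'
#' @param bins a `bin_marker_matrix`.
#' @param path file path.
#' @return The path (write) or a `bin_marker_matrix` (read).
#' @export
write_bins_tsv <- function(bins, path) {
  codes <- matrix(dosage_to_code(bins$geno), nrow(bins$geno),
                  dimnames = dimnames(bins$geno))
  codes[is.na(codes)] <- "NA"
  df <- cbind(bins$bins, as.data.frame(codes))
  .write_tsv(df, path,
             "bin markers: start/end 1-based closed; AA = A188 hom")
}

#' @rdname write_bins_tsv
#' @export
read_bins_tsv <- function(path) {
  df <- .read_tsv(path)
  meta <- c("chrom", "start_bp", "end_bp", "rep_pos_bp", "rep_pos_cM")
  ind <- setdiff(names(df), meta)
  codes <- as.matrix(df[, ind, drop = FALSE])
  codes[codes == "NA"] <- NA
  geno <- matrix(code_to_dosage(codes), nrow(codes),
                 dimnames = list(paste(df$chrom, df$rep_pos_bp, sep = "_"),
                                 ind))
  structure(list(bins = df[, meta], geno = geno),
            class = "bin_marker_matrix")
}

#' Write a scan result as TSV
#'
#' @param scan a `qtl_scan`.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_scan_tsv <- function(scan, path) {
  .write_tsv(as.data.frame(scan), path,
             paste0("genome scan (", attr(scan, "method"),
                    "): pos_bp 1-based, pos_cM centimorgans"))
}

#' Write a peak table as TSV
#'
#' @param peaks a `qtl_peaks` data.frame.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_peaks_tsv <- function(peaks, path) {
  .write_tsv(as.data.frame(peaks), path, "QTL peaks: positions 1-based bp")
}

#' Write / read bulk allele counts as TSV
#'
#' @param counts a `bulk_counts` data.frame.
#' @param path file path.
#' @return The path (write) or a `bulk_counts` data.frame (read).
#' @export
write_bulk_counts_tsv <- function(counts, path) {
  .write_tsv(counts, path,
             "bulk allele read counts: pos_bp 1-based; class XT-I/XT-II")
}

#' @rdname write_bulk_counts_tsv
#' @export
read_bulk_counts_tsv <- function(path) {
  df <- .read_tsv(path)
  class(df) <- c("bulk_counts", "data.frame")
  df
}

#' Read a DEG list TSV (gene_id, direction, padj)
#'
#' @param path input file.
#' @return data.frame with `gene_id`, `direction`, `padj`.
#' @export
read_deg_tsv <- function(path) .read_tsv(path)

#' Read gene annotations from BED or a TSV with headers
#'
#' BED input (no header, 0-based half-open) is converted to 1-based closed
#' `start_bp`/`end_bp`.
#'
#' @param path input file.
#' @param format `"bed"` or `"tsv"`.
#' @return data.frame with `gene_id`, `chrom`, `start_bp`, `end_bp`.
#' @export
read_genes <- function(path, format = c("bed", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") return(.read_tsv(path))
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  data.frame(gene_id = df[[4L]], chrom = as.character(df[[1L]]),
             start_bp = df[[2L]] + 1L, end_bp = df[[3L]])
}
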