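#' Default pipeline configuration
#'
#' One nested list mirroring the stage surfaces: `simulate` (the simulation
#' design), `segments` (segmentation and recombination QC), `scan` (both
#' mapping methods), `bsr` and `integrate`, plus a global `seed` fanned out
#' to per-stage substreams. Any unknown key in a supplied configuration is
#' rejected.
#'
#' @param seed global RNG seed.
#' @return A nested list of stage blocks (class `pipeline_config`).
#' @export
pipeline_config <- function(seed = 1) {
  structure(list(
    seed = seed,
    simulate = list(
      n_chrom = 10, chrom_length_cM = NULL, mu = 0,
      n_embryos = 2194, n_select_per_class = 100, snp_density = 5,
      missing_rate = 0.2, genotype_error_rate = 0.02,
      het_undercall_rate = 0.1, bulk_size = 50, bulk_depth_mean = 200,
      n_bulk_reps = 2, n_genes = 400, de_fraction = 0.2, de_overlap = 0.5),
    segments = list(smooth_window = 5, min_snps_per_segment = 3,
                    multiplier = 2.0),
    scan = list(n_perm = 200, alpha = 0.05, fdr_q = 0.01, lod_drop = 1.5,
                step_cM = 1, lod_threshold = 3, min_separation_cM = 30),
    bsr = list(alpha = 0.05),
    integrate = list(require_concordance = TRUE, overlap_rule = "any")),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults of [pipeline_config()];
#' unknown keys (at the top level or inside a stage block) are an error.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  bad_top <- setdiff(names(user), names(cfg))
  if (length(bad_top))
    stop("unknown configuration keys: ", paste(bad_top, collapse = ", "))
  for (blk in names(user)) {
    if (blk == "seed") {
      cfg$seed <- user$seed
      next
    }
    bad <- setdiff(names(user[[blk]]), names(cfg[[blk]]))
    if (length(bad))
      stop("unknown keys in block '", blk, "': ",
           paste(bad, collapse = ", "))
    cfg[[blk]][names(user[[blk]])] <- user[[blk]]
  }
  cfg
}

#' @keywords internal
.stage_seed <- function(seed, k) (seed * 97L + k * 1009L) %% 2100000000L

#' @keywords internal
#' QTL architecture for a pipeline run: the five-locus layout when the map
#' carries the usual chromosomes, otherwise a two-locus reduction.
.pipeline_qtls <- function(map) {
  ch <- map_chromosomes(map)
  if (all(paste0("chr", c(2, 5, 6, 8, 9)) %in% ch)) return(demo_qtls(map))
  len <- chrom_lengths_cM(map)
  n <- min(2L, length(ch))
  betas <- c(-1.3, 1.2)[seq_len(n)]
  do.call(rbind, Map(qtl_spec, ch[seq_len(n)], 0.5 * len[seq_len(n)], betas))
}

#' Run the full mapping pipeline on synthetic data
#'
#' Executes simulate -> segments -> bins -> scans -> BSR -> integration and
#' writes every stage's tables plus a manifest (versions, seed, file digests)
#' and a log with per-filter tallies into `outdir`. Rerunning with the same
#' configuration reproduces byte-identical outputs.
#'
#' @param config a `pipeline_config`.
#' @param outdir output directory (created; must not already contain a
#'   manifest unless `overwrite = TRUE`).
#' @param overwrite allow writing into an existing run directory.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list of key results: the simulation, bins, scans,
#'   peaks, BSR result, candidate table, and summary `numbers`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir,
                         overwrite = FALSE, quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (dir.exists(outdir) && file.exists(file.path(outdir, "manifest.json")) &&
      !overwrite)
    stop("run directory already holds a manifest; use overwrite = TRUE")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  say <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  cs <- config$simulate
  map <- if (is.null(cs$chrom_length_cM)) default_genetic_map(cs$n_chrom)
  else uniform_genetic_map(cs$n_chrom, cs$chrom_length_cM)

  # --- stage 1: simulate ---------------------------------------------------
  scfg <- sim_config(map = map, qtls = .pipeline_qtls(map), mu = cs$mu,
                     n_embryos = cs$n_embryos,
                     n_select_per_class = cs$n_select_per_class,
                     snp_density = cs$snp_density,
                     missing_rate = cs$missing_rate,
                     genotype_error_rate = cs$genotype_error_rate,
                     het_undercall_rate = cs$het_undercall_rate,
                     bulk_size = cs$bulk_size,
                     bulk_depth_mean = cs$bulk_depth_mean,
                     n_bulk_reps = cs$n_bulk_reps,
                     seed = .stage_seed(config$seed, 1L))
  sim <- simulate_f2(scfg)
  say("simulate: %d embryos, %d Type II; selected %d + %d",
      length(sim$ids), sum(sim$phenotype == "TypeII"),
      length(sim$sel_type1), length(sim$sel_type2))
  sel <- c(sim$sel_type1, sim$sel_type2)
  truth <- truth_genotypes(sim, sel)
  set.seed(.stage_seed(config$seed, 2L))
  gm <- degrade_to_gbs(truth, cs$missing_rate, cs$genotype_error_rate,
                       cs$het_undercall_rate)
  phen <- data.frame(id = sel,
                     class = as.character(sim$phenotype[match(sel, sim$ids)]))
  set.seed(.stage_seed(config$seed, 3L))
  bulks <- simulate_bulk_counts(sim)
  set.seed(.stage_seed(config$seed, 4L))
  fixture <- make_gene_fixture(map, cs$n_genes, cs$de_fraction,
                               cs$de_overlap)
  write_map_tsv(map, file.path(outdir, "map.tsv"))
  write_genotype_tsv(gm, file.path(outdir, "genotypes.tsv"))
  write_phenotype_tsv(phen, file.path(outdir, "phenotypes.tsv"))
  write_bulk_counts_tsv(bulks, file.path(outdir, "bulk_counts.tsv"))
  .write_tsv(fixture$genes, file.path(outdir, "genes.tsv"),
             "gene annotation: start/end 1-based closed")
  .write_tsv(fixture$deg_type, file.path(outdir, "deg_type.tsv"),
             "DEGs, Type II vs Type I contrast")
  .write_tsv(fixture$deg_growth, file.path(outdir, "deg_growth.tsv"),
             "DEGs, fast vs slow growth contrast")
  jsonlite::write_json(
    list(seed = config$seed,
         qtls = sim$config$qtls,
         n_snps = nrow(sim$snps),
         phenotype = as.character(sim$phenotype)),
    file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA)

  # --- stage 2: segments + recombination QC --------------------------------
  segs <- call_segments_all(gm, config$segments$smooth_window,
                            config$segments$min_snps_per_segment)
  expected <- expected_recombination_count(map)
  flt <- filter_individuals(segs, expected, config$segments$multiplier)
  say("segments: expected %.1f events; dropped %d of %d individuals",
      expected, length(flt$dropped), length(segs))
  write_segments_bed(segs, file.path(outdir, "segments.bed"))
  .write_tsv(flt$report, file.path(outdir, "recombination_qc.tsv"),
             "recombination QC: dropped if n_events > multiplier x expected")

  # --- stage 3: bin markers ------------------------------------------------
  bins <- harmonize_bins(segs[flt$retained], map)
  say("bins: %d bin markers x %d retained individuals",
      nrow(bins$bins), ncol(bins$geno))
  write_bins_tsv(bins, file.path(outdir, "bin_markers.tsv"))

  # --- stage 4: QTL scans --------------------------------------------------
  y <- align_phenotype(stats::setNames(
    ifelse(phen$class == "TypeII", 1L, 0L), phen$id)[flt$retained],
    individual_ids(bins))
  names(y) <- individual_ids(bins)
  csc <- config$scan
  scan_log <- genome_scan_logistic(bins, y)
  fdr_hits <- fdr_significant(scan_log, csc$fdr_q)
  scan_int <- interval_scan_binary(bins, map, y, step_cM = csc$step_cM)
  if (csc$n_perm >= 100) {
    thr_log <- permutation_threshold(bins, y, "logistic",
                                     n_perm = csc$n_perm, alpha = csc$alpha,
                                     seed = .stage_seed(config$seed, 5L))
    p_threshold <- thr_log$threshold
  } else {
    warning("n_perm < 100: permutation threshold skipped, ",
            "statistics emitted without it")
    p_threshold <- NA_real_
  }
  peaks_log <- if (is.na(p_threshold)) find_peaks(scan_log, 1e-4,
                                                  csc$min_separation_cM)
  else find_peaks(scan_log, p_threshold, csc$min_separation_cM)
  peaks_int <- find_peaks(scan_int, csc$lod_threshold, csc$min_separation_cM)
  peaks_int <- support_intervals(peaks_int, scan_int, csc$lod_drop)
  peaks_int <- annotate_peaks(peaks_int, bins, y)
  joint <- fit_joint_qtl(bins, y, peaks_int)
  say("scan: %d FDR-significant bins; %d logistic peaks; %d interval peaks;",
      nrow(fdr_hits), nrow(peaks_log), nrow(peaks_int))
  say("scan: joint LOD %.2f, variance explained %.1f%% (n = %d)",
      joint$joint_lod, joint$variance_explained_pct, joint$n)
  write_scan_tsv(scan_log, file.path(outdir, "scan_logistic.tsv"))
  write_scan_tsv(scan_int, file.path(outdir, "scan_interval.tsv"))
  write_peaks_tsv(peaks_log, file.path(outdir, "peaks_logistic.tsv"))
  write_peaks_tsv(peaks_int, file.path(outdir, "peaks_interval.tsv"))
  if (nrow(peaks_int)) {
    bed <- data.frame(chrom = peaks_int$chrom,
                      start = peaks_int$interval_start_bp - 1,
                      end = peaks_int$interval_end_bp,
                      name = peaks_int$name)
    con <- file(file.path(outdir, "qtl_intervals.bed"), "w")
    writeLines("# LOD support intervals, BED 0-based half-open", con)
    utils::write.table(bed, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    close(con)
  }

  # --- stage 5: BSR --------------------------------------------------------
  bsr <- bsr_scan(bulks, config$bsr$alpha)
  say("bsr: %d SNPs tested, %d significant (Bonferroni cutoff %.3g)",
      attr(bsr, "n_tests"), sum(bsr$significant), attr(bsr, "cutoff"))
  .write_tsv(as.data.frame(bsr), file.path(outdir, "bsr_result.tsv"),
             "BSR association: pooled replicate counts; pos_bp 1-based")

  # --- stage 6: integration ------------------------------------------------
  intervals <- if (nrow(peaks_int))
    data.frame(qtl = peaks_int$name, chrom = peaks_int$chrom,
               start_bp = peaks_int$interval_start_bp,
               end_bp = peaks_int$interval_end_bp)
  else data.frame(qtl = character(), chrom = character(),
                  start_bp = numeric(), end_bp = numeric())
  cand <- candidate_genes(intervals, fixture$genes, fixture$deg_type,
                          fixture$deg_growth,
                          config$integrate$require_concordance,
                          config$integrate$overlap_rule)
  say("integrate: %d candidate gene x QTL pairs", nrow(cand))
  .write_tsv(as.data.frame(cand), file.path(outdir, "candidates.tsv"),
             "candidate genes: QTL-interval DEGs; positions 1-based bp")
  z <- standardize_expression(fixture$rpm)
  .write_tsv(cbind(data.frame(gene_id = rownames(z)), as.data.frame(z)),
             file.path(outdir, "rpm_standardized.tsv"),
             "row-standardized RPM (mean 0, sd 1 per gene)")

  writeLines(log_lines, file.path(outdir, "pipeline.log"))
  files <- sort(setdiff(list.files(outdir), "manifest.json"))
  digests <- as.vector(tools::md5sum(file.path(outdir, files)))
  jsonlite::write_json(
    list(package = "callusmap",
         version = as.character(utils::packageVersion("callusmap")),
         seed = config$seed, config = unclass(config),
         files = stats::setNames(as.list(digests), files)),
    file.path(outdir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  invisible(list(
    sim = sim, bins = bins, scan_logistic = scan_log,
    scan_interval = scan_int, peaks_logistic = peaks_log,
    peaks_interval = peaks_int, joint = joint, bsr = bsr,
    candidates = cand, retained = flt$retained,
    numbers = list(
      n_embryos = length(sim$ids),
      n_type2 = sum(sim$phenotype == "TypeII"),
      n_snps = nrow(sim$snps),
      n_retained = length(flt$retained),
      n_bins = nrow(bins$bins),
      n_fdr_bins = nrow(fdr_hits),
      logistic_p_threshold = p_threshold,
      n_peaks_logistic = nrow(peaks_log),
      n_peaks_interval = nrow(peaks_int),
      max_lod = max(scan_int$lod),
      joint_lod = joint$joint_lod,
      variance_explained_pct = joint$variance_explained_pct,
      n_bsr_tests = attr(bsr, "n_tests"),
      n_bsr_significant = sum(bsr$significant),
      n_candidates = nrow(cand))))
}

#' Scaled-down demonstration configuration
#'
#' A reduced design (4 chromosomes, 400 embryos, 40 + 40 selected calli)
#' that runs the whole pipeline in well under a minute, used by the examples
#' and the determinism checks.
#'
#' @param seed global seed.
#' @return A `pipeline_config`.
#' @export
demo_pipeline_config <- function(seed = 1) {
  cfg <- pipeline_config(seed)
  cfg$simulate$n_chrom <- 4
  cfg$simulate$chrom_length_cM <- 100
  cfg$simulate$n_embryos <- 400
  cfg$simulate$n_select_per_class <- 40
  cfg$simulate$snp_density <- 3
  cfg$simulate$n_genes <- 150
  cfg$scan$n_perm <- 100
  cfg$scan$step_cM <- 2
  cfg
}
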