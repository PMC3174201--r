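# End-to-end orchestration with reproducible seeds and a run manifest.

#' Assemble a pipeline configuration
#'
#' @param sim a [sim_config()] (the pipeline simulates its quartet when no
#'   VCF input is given).
#' @param hmm an [hmm_params()].
#' @param ld_window_bp LD phasing window.
#' @param n_permutations hotspot-test permutations.
#' @param quality_target calibration discordance target among retained
#'   calls. The default 1e-5 aims at the final genotype error scale
#'   family-based error control is expected to reach (1e-6 to 1e-5); the
#'   bare operation's default of 1e-3 cannot bite when the raw
#'   per-genotype error rate is itself ~1e-3.
#' @param out_dir optional output directory for stage TSV reports.
#' @param seed global seed (propagated to the simulator and permutation
#'   test).
#' @export
pipeline_config <- function(sim = sim_config(), hmm = hmm_params(),
                            ld_window_bp = 250000, n_permutations = 1000L,
                            quality_target = 1e-5, out_dir = NULL,
                            seed = 1L) {
  sim$seed <- as.integer(seed)
  structure(list(sim = sim, hmm = hmm, ld_window_bp = ld_window_bp,
                 n_permutations = n_permutations,
                 quality_target = quality_target, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the quartet pipeline end to end on simulated data
#'
#' simulate -> inheritance states -> error flagging + quality calibration
#' -> crossover extraction + hotspot enrichment -> phasing -> summary
#' statistics. Returns all stage outputs plus a manifest recording seed
#' and parameters; reruns with the same config are identical.
#'
#' @param config a [pipeline_config()].
#' @return list of stage outputs with elements `sites`, `truth`, `blocks`,
#'   `flags`, `calibration`, `windows`, `enrichment`, `phased`, `stats`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- simulate_quartet(config$sim)
  sites <- sim$sites
  truth <- sim$truth

  blocks <- decode_states(sites, config$hmm)
  flags <- flag_error_prone_sites(blocks, sites)

  # orthogonal truth subset for quality calibration: the simulator's truth
  # genotypes for all four samples at sites outside flagged error-prone
  # regions (emulating dense array genotyping; flagged regions are removed
  # first, as calibration follows error-region exclusion)
  truth_subset <- quartet_truth_subset(sites, truth, exclude = flags$mask)
  calibration <- calibrate_quality_threshold(sites, truth_subset,
                                             target = config$quality_target)

  windows <- extract_crossovers(blocks, sites)
  hotspots <- config$sim$hotspot_map
  if (is.null(hotspots))
    hotspots <- do.call(rbind, lapply(truth$chrom_names, function(chrom)
      .default_hotspots(chrom, config$sim$chrom_length)))
  callable <- do.call(rbind, lapply(truth$chrom_names, function(chrom)
    intervals(chrom, 0L, config$sim$chrom_length)))
  enrichment <- if (nrow(windows) > 0)
    hotspot_enrichment(windows, hotspots, callable,
                       n_permutations = config$n_permutations,
                       seed = config$seed) else NULL

  ld <- simulate_ld_panel(truth, window_bp = config$ld_window_bp)
  phased <- phase_quartet(sites, blocks, ld, config$hmm,
                          window_bp = config$ld_window_bp)

  stats <- list(mie = mie_rate(sites),
                error_prone_fraction = flags$fraction,
                resolution = if (nrow(windows) > 0)
                  resolution_stats(windows) else NULL)

  manifest <- list(seed = config$seed,
                   n_sites = nrow(sites),
                   chrom_length = config$sim$chrom_length,
                   n_chromosomes = config$sim$n_chromosomes,
                   hmm = unclass(config$hmm),
                   quality_cutoff = calibration$cutoff,
                   n_crossover_windows = nrow(windows))

  out <- list(sites = sites, truth = truth, blocks = blocks, flags = flags,
              calibration = calibration, windows = windows,
              enrichment = enrichment, phased = phased, stats = stats,
              manifest = manifest)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(blocks, file.path(config$out_dir, "state_blocks.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(windows, file.path(config$out_dir, "crossover_windows.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write_phased_vcf(phased, file.path(config$out_dir, "phased.vcf"))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Orthogonal-technology truth subset from simulator ground truth
#'
#' Builds the calibration input for [calibrate_quality_threshold()]: the
#' true genotypes of all four samples at every site not excluded, in the
#' long (chrom, pos, sample, genotype) layout.
#'
#' @param sites a [quartet_sites] table.
#' @param truth the matching `sim_truth`.
#' @param exclude logical mask of sites to drop (e.g. flagged error-prone
#'   regions).
#' @export
quartet_truth_subset <- function(sites, truth, exclude = NULL) {
  keep <- if (is.null(exclude)) seq_len(nrow(sites)) else which(!exclude)
  do.call(rbind, lapply(SAMPLES, function(s) data.frame(
    chrom = sites$chrom[keep], pos = sites$pos[keep], sample = s,
    genotype = truth$true_genotypes[[paste0("g", s)]][keep],
    stringsAsFactors = FALSE)))
}

#' MIE-rate error reduction from error-region flagging plus quality
#' filtering
#'
#' Measures the percent reduction in the MIE-estimated genotype error rate
#' achieved by removing sites in HMM-flagged error-prone regions and sites
#' with any genotype quality below a calibrated cutoff.
#'
#' @param sites a [quartet_sites] table.
#' @param blocks decoded state blocks.
#' @param cutoff genotype-quality cutoff (e.g. from
#'   [calibrate_quality_threshold()]).
#' @return list: `rate_before`, `rate_after` (MIEs per variant),
#'   `reduction_percent`, `n_retained`.
#' @export
mie_error_reduction <- function(sites, blocks, cutoff) {
  before <- mie_rate(sites)
  mask <- flag_error_prone_sites(blocks, sites)$mask
  qmin <- pmin(sites$qF, sites$qM, sites$qC1, sites$qC2, na.rm = TRUE)
  keep <- !mask & !is.na(qmin) & qmin >= cutoff
  after <- mie_rate(sites[keep, , drop = FALSE])
  list(rate_before = before$rate, rate_after = after$rate,
       reduction_percent = 100 * (1 - after$rate / before$rate),
       n_retained = sum(keep))
}
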