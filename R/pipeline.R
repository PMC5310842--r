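#' Run the end-to-end demonstration pipeline
#'
#' Executes the configured stages over a simulated dataset: `simulate`
#' (genome + fragments), `tracks` (end-density and coverage bedGraphs,
#' spike-in normalized), `aggregate` (motif-centered mean end-density
#' profile, footprint width, periodicity), `peaks` (percentile-threshold
#' calls + motif fraction), `solubility` (insolubility log-ratio and
#' centromere median profile) and `contacts` (direct/indirect
#' classification against the truth sites and contact annotation). A
#' JSON run manifest records the config snapshot, output checksums,
#' package version and timestamp; deterministic stages reproduce
#' byte-identical outputs under the same config.
#'
#' @param config a YAML file path or a list. Recognized top-level keys:
#'   `seed`, `stages` (character vector, default all), and `simulate`
#'   (a list of [sim_config()] overrides).
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the manifest and the main in-memory
#'   results.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  all_stages <- c("simulate", "tracks", "aggregate", "peaks",
                  "solubility", "contacts")
  stages <- config$stages %||% all_stages
  unknown <- setdiff(stages, all_stages)
  if (length(unknown))
    stop("unknown stage name(s): ", paste(unknown, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  sim_args <- config$simulate %||% list()
  if (!is.null(config$seed)) sim_args$seed <- config$seed
  cfg <- do.call(sim_config, sim_args)

  results <- list(config = cfg)
  genome <- make_genome(cfg)
  fr <- simulate_fragments(cfg, genome, time_index = 1)
  sites <- genome$truth$sites
  direct <- sites[sites$class == "direct", , drop = FALSE]

  if ("simulate" %in% stages) {
    writeLines(paste0(">", names(genome$sequences), "\n",
                      unlist(genome$sequences)),
               file.path(out_dir, "genome.fa"))
    utils::write.table(
      data.frame(names(genome$chrom_sizes),
                 as.integer(genome$chrom_sizes)),
      file.path(out_dir, "genome.chrom.sizes"),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    write_bed6(direct, file.path(out_dir, "truth_direct_sites.bed"))
    write_fragments_bed(fr$primary, file.path(out_dir, "fragments.bed"))
    utils::write.table(genome$truth$contacts,
                       file.path(out_dir, "truth_contacts.bedpe"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }

  ends_raw <- end_density_track(fr$primary)
  cov_raw <- coverage_track(fr$primary)
  spike_n <- length(fr$spike)
  ends <- normalize_spikein(ends_raw, spike_n)
  covt <- normalize_spikein(cov_raw, spike_n)
  if ("tracks" %in% stages) {
    write_bedgraph(ends, file.path(out_dir, "ends.spikenorm.bedgraph"))
    write_bedgraph(covt, file.path(out_dir, "coverage.spikenorm.bedgraph"))
  }
  results$tracks <- list(ends = ends, coverage = covt,
                         spike_reads = spike_n)

  if ("aggregate" %in% stages) {
    m <- site_matrix(ends, direct, flank = 1000)
    prof <- mean_profile(m, "mean")
    write_profile(prof, file.path(out_dir, "end_density_profile.tsv"))
    results$aggregate <- list(
      profile = prof,
      footprint_width = footprint_width(prof),
      periodicity = periodicity_autocorrelation(prof))
  }

  if ("peaks" %in% stages) {
    # occupancy peaks are called on coverage: per-base end density is
    # 1-bp sparse and its upper percentiles select isolated positions
    pk <- call_peaks(covt)
    write_peaks_bed(pk, file.path(out_dir, "peaks.bed"))
    results$peaks <- list(
      peaks = pk,
      motif_fraction = if (nrow(pk))
        peak_motif_fraction(pk, direct, slop = 100) else NA_real_)
  }

  if ("solubility" %in% stages) {
    fractions <- simulate_fractions(cfg, fr$primary)
    pc <- 1 / (2 * length(fractions$total))
    lr <- insoluble_log_ratio(
      normalize_standard(coverage_track(fractions$total),
                         2 * length(fractions$total)),
      normalize_standard(coverage_track(fractions$soluble),
                         max(2 * length(fractions$soluble), 1)),
      pseudocount = pc)
    write_bedgraph(lr, file.path(out_dir, "insoluble_log2ratio.bedgraph"))
    cenprof <- median_midpoint_profile(lr, genome$truth$centromeres,
                                       flank = 500)
    write_profile(cenprof, file.path(out_dir, "centromere_median.tsv"))
    results$solubility <- list(log_ratio = lr, centromere = cenprof)
  }

  if ("contacts" %in% stages) {
    native <- direct[, c("chrom", "start", "end")]
    pk <- results$peaks$peaks %||% call_peaks(covt)
    cls <- classify_sites(pk, native, slop = 100)
    ann <- anchor_intersect(genome$truth$contacts, cls)
    utils::write.table(ann, file.path(out_dir, "contacts_annotated.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$contacts <- list(classified = cls, annotated = ann)
  }

  manifest <- list(
    tool = "cutrunr",
    version = as.character(utils::packageVersion("cutrunr")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = stages,
    config = cfg[setdiff(names(cfg), "soluble_fraction_by_class")],
    soluble_fraction_by_class =
      as.list(cfg$soluble_fraction_by_class),
    outputs = as.list(tools::md5sum(setdiff(
      list.files(out_dir, full.names = TRUE),
      file.path(out_dir, "manifest.json")))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
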