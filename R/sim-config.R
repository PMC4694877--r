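#' Simulation configuration for matched FF/FFPE pairs
#'
#' Bundles every parameter of the synthetic-data generator: a random genome
#' with tunable GC content and CpG-dinucleotide enrichment, shared germline /
#' somatic / INDEL / copy-number truth, per-position sequencing observations
#' (negative-binomial coverage, per-read sequencing error, per-position
#' mapping quality), FFPE-specific cytosine-deamination artifacts that convert
#' read C bases to T (G to A on the complementary strand) preferentially in
#' CpG context, and low-pass binned read counts with GC bias for copy-number
#' profiling.
#'
#' Deamination rates apply only to FFPE sample kinds; identical configurations
#' (including `seed`) yield bit-identical outputs from every generator
#' function.
#'
#' @param genome_length genome size in bases.
#' @param gc_fraction expected GC content in `[0, 1]`.
#' @param cpg_enrichment multiplier (>= 0) on the iid CG-dinucleotide
#'   frequency; human-like genomes are CpG-depleted (< 1) but artifact studies
#'   need CpG-rich substrate, so values > 1 are common in tests.
#' @param germline_het_rate per-base probability of a heterozygous germline SNV.
#' @param somatic_rate per-base probability of a somatic SNV (tumor kinds only).
#' @param tumor_vaf_mean mean truth variant allele fraction of somatic SNVs.
#' @param indel_rate per-base probability of a germline INDEL event.
#' @param indel_mean_ins,indel_mean_del mean insertion / deletion lengths in
#'   bases (shifted-Poisson size distribution; defaults 6 and 9).
#' @param mean_coverage_ff,mean_coverage_ffpe expected reads per position.
#' @param coverage_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson coverage.
#' @param seq_error_rate per-read-base probability of a uniform miscall.
#' @param deamination_rate_cpg per-C-read probability of an artifactual C>T
#'   flip in FFPE samples when the cytosine is in CpG context.
#' @param deamination_rate_noncpg same, outside CpG context.
#' @param mapq_mean_ff,mapq_mean_ffpe,mapq_sd per-position mapping-quality
#'   truncated-normal parameters (Phred scale, bounded to `[0, 60]`).
#' @param lowpass_mean_coverage expected low-pass reads per base (e.g. 0.2).
#' @param bin_size low-pass bin width in bases (default 15000).
#' @param gc_bias_strength linear GC-bias coefficient for low-pass counts:
#'   expected count is multiplied by `max(1 + gc_bias_strength * (gc - 0.5),
#'   0.1)`.
#' @param cnv_segments `NULL` or a data.frame with columns `start`, `end`,
#'   `copy_state` (1-based inclusive, non-overlapping); applies to tumor kinds.
#' @param seed master integer seed.
#' @return an object of class `ffc_sim_config`.
#' @export
sim_config <- function(genome_length = 1e5,
                       gc_fraction = 0.41,
                       cpg_enrichment = 1,
                       germline_het_rate = 1e-3,
                       somatic_rate = 2e-5,
                       tumor_vaf_mean = 0.4,
                       indel_rate = 5e-5,
                       indel_mean_ins = 6,
                       indel_mean_del = 9,
                       mean_coverage_ff = 60,
                       mean_coverage_ffpe = 45,
                       coverage_dispersion = 0.05,
                       seq_error_rate = 1e-3,
                       deamination_rate_cpg = 0.002,
                       deamination_rate_noncpg = 2e-4,
                       mapq_mean_ff = 55,
                       mapq_mean_ffpe = 50,
                       mapq_sd = 5,
                       lowpass_mean_coverage = 0.2,
                       bin_size = 15000,
                       gc_bias_strength = 0,
                       cnv_segments = NULL,
                       seed = 1L) {
  if (!is.numeric(genome_length) || genome_length < 1)
    stop_config("'genome_length' must be a positive number of bases")
  check_prob(gc_fraction, "gc_fraction")
  if (!is.numeric(cpg_enrichment) || cpg_enrichment < 0)
    stop_config("'cpg_enrichment' must be >= 0")
  check_prob(germline_het_rate, "germline_het_rate")
  check_prob(somatic_rate, "somatic_rate")
  check_prob(indel_rate, "indel_rate")
  if (tumor_vaf_mean <= 0 || tumor_vaf_mean > 1)
    stop_config("'tumor_vaf_mean' must be in (0, 1]")
  check_prob(seq_error_rate, "seq_error_rate")
  check_prob(deamination_rate_cpg, "deamination_rate_cpg")
  check_prob(deamination_rate_noncpg, "deamination_rate_noncpg")
  if (coverage_dispersion < 0) stop_config("'coverage_dispersion' must be >= 0")
  if (mapq_sd < 0) stop_config("'mapq_sd' must be >= 0")
  if (mean_coverage_ff < 0 || mean_coverage_ffpe < 0 ||
      lowpass_mean_coverage < 0)
    stop_config("coverage means must be >= 0")
  if (bin_size < 1) stop_config("'bin_size' must be >= 1")
  if (!is.null(cnv_segments)) {
    cnv_segments <- as.data.frame(cnv_segments)
    need <- c("start", "end", "copy_state")
    if (!all(need %in% names(cnv_segments)))
      stop_config("'cnv_segments' needs columns start, end, copy_state")
    cnv_segments <- cnv_segments[order(cnv_segments$start), , drop = FALSE]
    if (any(cnv_segments$start < 1) || any(cnv_segments$end > genome_length) ||
        any(cnv_segments$start > cnv_segments$end))
      stop_config("'cnv_segments' must lie within [1, genome_length]")
    if (nrow(cnv_segments) > 1 &&
        any(cnv_segments$start[-1] <= cnv_segments$end[-nrow(cnv_segments)]))
      stop_config("'cnv_segments' must be non-overlapping")
    if (any(cnv_segments$copy_state < 0))
      stop_config("copy states must be >= 0")
  }
  structure(list(
    genome_length = as.integer(genome_length),
    gc_fraction = gc_fraction,
    cpg_enrichment = cpg_enrichment,
    germline_het_rate = germline_het_rate,
    somatic_rate = somatic_rate,
    tumor_vaf_mean = tumor_vaf_mean,
    indel_rate = indel_rate,
    indel_mean_ins = indel_mean_ins,
    indel_mean_del = indel_mean_del,
    mean_coverage_ff = mean_coverage_ff,
    mean_coverage_ffpe = mean_coverage_ffpe,
    coverage_dispersion = coverage_dispersion,
    seq_error_rate = seq_error_rate,
    deamination_rate_cpg = deamination_rate_cpg,
    deamination_rate_noncpg = deamination_rate_noncpg,
    mapq_mean_ff = mapq_mean_ff,
    mapq_mean_ffpe = mapq_mean_ffpe,
    mapq_sd = mapq_sd,
    lowpass_mean_coverage = lowpass_mean_coverage,
    bin_size = as.integer(bin_size),
    gc_bias_strength = gc_bias_strength,
    cnv_segments = cnv_segments,
    seed = as.integer(seed)
  ), class = "ffc_sim_config")
}

#' @export
print.ffc_sim_config <- function(x, ...) {
  cat("FF/FFPE simulation configuration\n")
  cat(sprintf("  genome: %d bp, GC %.2f, CpG enrichment %.2f\n",
              x$genome_length, x$gc_fraction, x$cpg_enrichment))
  cat(sprintf("  variants: germline het %.2g, somatic %.2g (VAF %.2f), indel %.2g\n",
              x$germline_het_rate, x$somatic_rate, x$tumor_vaf_mean,
              x$indel_rate))
  cat(sprintf("  coverage: FF %.1fx, FFPE %.1fx (dispersion %.2g); error %.2g\n",
              x$mean_coverage_ff, x$mean_coverage_ffpe,
              x$coverage_dispersion, x$seq_error_rate))
  cat(sprintf("  deamination (FFPE only): CpG %.2g, non-CpG %.2g\n",
              x$deamination_rate_cpg, x$deamination_rate_noncpg))
  cat(sprintf("  low-pass: %.2fx, bin %d bp; CNV segments: %d; seed %d\n",
              x$lowpass_mean_coverage, x$bin_size,
              if (is.null(x$cnv_segments)) 0L else nrow(x$cnv_segments),
              x$seed))
  invisible(x)
}

#' Read a simulation configuration from a key=value text file
#'
#' Lines are `key = value`; `#` starts a comment.  Keys must exactly match
#' [sim_config()] argument names; an unknown key is a hard error so that a
#' misspelled parameter can never fall back silently to a default.
#' `cnv_segments` is given as `start:end:copy_state` triples separated by
#' commas.
#'
#' @param path file path.
#' @return an `ffc_sim_config`.
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L)
      stop_config("malformed config line: '%s'", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(formals(sim_config)))
      stop_config("unknown configuration key '%s'", key)
    if (key == "cnv_segments") {
      trip <- strsplit(strsplit(val, ",")[[1]], ":")
      args[[key]] <- data.frame(
        start = as.integer(vapply(trip, `[`, "", 1L)),
        end = as.integer(vapply(trip, `[`, "", 2L)),
        copy_state = as.numeric(vapply(trip, `[`, "", 3L)))
    } else {
      args[[key]] <- as.numeric(val)
    }
  }
  do.call(sim_config, args)
}
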