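#' Simulate low-pass binned read counts for copy-number profiling
#'
#' Emulates shallow whole-genome sequencing (~0.2x) observed through
#' fixed-width bins: the expected count of bin *b* is
#' `lowpass_mean_coverage * width_b * (copy_state/2 for tumor kinds) *
#' gc_bias(gc_b)`, counts are negative-binomial (Poisson at dispersion 0),
#' and each counted read is assigned a uniform start position within its bin
#' so that binning the returned read starts reproduces the counts exactly.
#'
#' @inheritParams simulate_pileup
#' @return an object of class `ffc_binned`: list with `bins` (data.frame
#'   `chrom, start, end, gc, count`), `bin_size`, and integer vector
#'   `read_starts`.
#' @export
simulate_lowpass_counts <- function(reference, truth, config,
                                    sample_kind = SAMPLE_KINDS,
                                    chrom = "chr1") {
  sample_kind <- match.arg(sample_kind)
  stopifnot(inherits(config, "ffc_sim_config"), inherits(truth, "ffc_truth"))
  L <- nchar(reference)
  bin <- config$bin_size
  if (L < bin) stop_config("genome (%d bp) is shorter than one bin (%d bp)", L, bin)
  is_ffpe <- grepl("^FFPE", sample_kind)
  is_tumor <- grepl("tumor$", sample_kind)

  starts <- seq.int(1L, L, by = bin)
  ends <- pmin(starts + bin - 1L, L)
  width <- ends - starts + 1L
  gc <- bin_gc(reference, starts, ends)

  cnfac <- rep(1, length(starts))
  if (is_tumor && !is.null(truth$cnv_segments)) {
    mid <- (starts + ends) %/% 2L
    full <- cn_factor(L, truth$cnv_segments)
    cnfac <- full[mid]
  }
  bias <- pmax(1 + config$gc_bias_strength * (gc - 0.5), 0.1)
  mu <- config$lowpass_mean_coverage * width * cnfac * bias

  with_substream(config$seed, paste0("lowpass_", sample_kind), {
    counts <- rcoverage(length(mu), mu, config$coverage_dispersion)
    read_starts <- unlist(lapply(seq_along(counts), function(i) {
      if (counts[i] == 0L) integer(0)
      else starts[i] + sample.int(width[i], counts[i], replace = TRUE) - 1L
    }), use.names = FALSE)
    structure(list(
      bins = data.frame(chrom = chrom, start = starts, end = ends, gc = gc,
                        count = as.integer(counts), stringsAsFactors = FALSE),
      bin_size = bin,
      read_starts = sort(read_starts)
    ), class = "ffc_binned")
  })
}

## GC fraction of reference slices, vectorized via Biostrings views
bin_gc <- function(reference, starts, ends) {
  d <- Biostrings::DNAString(reference)
  v <- Biostrings::Views(d, start = starts, end = ends)
  as.numeric(Biostrings::letterFrequency(v, "GC", as.prob = TRUE))
}

#' @export
print.ffc_binned <- function(x, ...) {
  cat(sprintf("Binned read counts: %d bins of %d bp, %d reads total\n",
              nrow(x$bins), x$bin_size, sum(x$bins$count)))
  invisible(x)
}

#' Simulate an entire matched dataset and write it to disk
#'
#' Convenience wrapper over the individual generators: writes the reference
#' (FASTA), germline and somatic truth (VCF), CNV truth segments (BED-like),
#' pileups for the requested sample kinds (TSV), low-pass bin counts for
#' tumor kinds (BED-like), array genotypes (TSV) and a JSON run manifest with
#' content digests.
#'
#' @param config an [sim_config()] object.
#' @param outdir output directory (created if absent).
#' @param kinds sample kinds to simulate pileups for.
#' @param array_error_rate corruption rate for the simulated array.
#' @return invisibly, the manifest list.
#' @export
simulate_dataset <- function(config, outdir,
                             kinds = c("FF_normal", "FFPE_normal"),
                             array_error_rate = 0.01) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  reference <- generate_reference(config)
  truth <- generate_truth(reference, config)

  paths <- list(reference = file.path(outdir, "reference.fa"),
                germline = file.path(outdir, "germline.vcf"),
                somatic = file.path(outdir, "somatic.vcf"),
                segments = file.path(outdir, "cnv_truth.bed"),
                array = file.path(outdir, "array_genotypes.tsv"))
  write_reference_fasta(reference, paths$reference)
  g <- truth$germline
  write_vcf(data.frame(chrom = rep("chr1", nrow(g)), pos = g$pos,
                       ref = g$ref, alt = g$alt, genotype = g$genotype,
                       vaf = rep(0.5, nrow(g)), depth = rep(0L, nrow(g)),
                       mapq = rep(0, nrow(g)), stringsAsFactors = FALSE),
            paths$germline)
  s <- truth$somatic
  write_vcf(data.frame(chrom = rep("chr1", nrow(s)), pos = s$pos,
                       ref = s$ref, alt = s$alt,
                       genotype = rep("het", nrow(s)), vaf = s$vaf,
                       depth = rep(0L, nrow(s)), mapq = rep(0, nrow(s)),
                       stringsAsFactors = FALSE), paths$somatic)
  if (!is.null(truth$cnv_segments))
    write_bed(data.frame(chrom = "chr1", truth$cnv_segments), paths$segments,
              extra_cols = "copy_state")
  arr <- simulate_array_genotypes(truth, array_error_rate, config$seed)
  write_genotype_table(arr, paths$array)

  for (k in kinds) {
    p <- file.path(outdir, paste0("pileup_", k, ".tsv"))
    write_pileup(simulate_pileup(reference, truth, config, k), p)
    paths[[paste0("pileup_", k)]] <- p
    if (grepl("tumor$", k) && nchar(reference) >= config$bin_size) {
      bp <- file.path(outdir, paste0("bins_", k, ".bed"))
      write_binned_counts(simulate_lowpass_counts(reference, truth, config, k), bp)
      paths[[paste0("bins_", k)]] <- bp
    }
  }
  manifest <- write_run_manifest(outdir, "simulate",
                                 config = unclass(config)[setdiff(names(config), "cnv_segments")],
                                 inputs = character(0),
                                 outputs = unlist(paths),
                                 seed = config$seed)
  invisible(manifest)
}
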