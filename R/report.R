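#' Full concordance and artifact report for one matched FF/FFPE pair
#'
#' Runs the standard per-pair analyses — base-level and variant-level
#' concordance, substitution spectra, C·G>T·A rate at disagreeing
#' positions, global mismatch rates — and returns them as one tidy
#' data.frame of metrics plus the underlying objects.
#'
#' @param ff_pileup,ffpe_pileup pileup data.frames of the pair.
#' @param reference reference string.
#' @param filt an [filter_config()].
#' @param regions optional target regions.
#' @return object of class `ffc_pair_report`: list with `metrics`
#'   (data.frame `metric, value`), `base`, `variant` (`ffc_concordance`),
#'   `spectrum_ff`, `spectrum_ffpe`.
#' @export
pair_report <- function(ff_pileup, ffpe_pileup, reference,
                        filt = filter_config(), regions = NULL) {
  base_tab <- classify_base_calls(consensus_base_call(ff_pileup, filt),
                                  consensus_base_call(ffpe_pileup, filt),
                                  regions)
  ff_calls <- call_snv(ff_pileup, filt)
  ffpe_calls <- call_snv(ffpe_pileup, filt)
  ff_var <- variant_calls(ff_calls)
  ffpe_var <- variant_calls(ffpe_calls)
  var_tab <- classify_variants(ff_var, ffpe_var, regions)
  sp_ff <- substitution_spectrum(ff_var, reference)
  sp_fp <- substitution_spectrum(ffpe_var, reference)
  ctr <- discordant_ct_rate(var_tab, reference,
                            classes = c("discordant", "false_positive",
                                        "false_negative"))
  gm_ff <- global_mismatch_rate(ff_pileup, reference, ff_var$pos, filt)
  gm_fp <- global_mismatch_rate(ffpe_pileup, reference, ffpe_var$pos, filt)
  metrics <- data.frame(
    metric = c("base_n_intersect", "base_concordance_rate",
               "variant_n_intersect", "variant_concordance_rate",
               "variant_false_positive", "variant_false_negative",
               "ct_rate_all_ff", "ct_rate_all_ffpe",
               "ct_rate_disagreement_ff", "ct_rate_disagreement_ffpe",
               "global_mismatch_ff", "global_mismatch_ffpe",
               "tstv_ff", "tstv_ffpe"),
    value = c(base_tab$n_intersect, base_tab$concordance_rate,
              var_tab$n_intersect, var_tab$concordance_rate,
              var_tab$n_false_positive, var_tab$n_false_negative,
              sp_ff$ct_rate_all, sp_fp$ct_rate_all,
              ctr$ff_rate, ctr$ffpe_rate,
              gm_ff, gm_fp, sp_ff$tstv, sp_fp$tstv))
  structure(list(metrics = metrics, base = base_tab, variant = var_tab,
                 spectrum_ff = sp_ff, spectrum_ffpe = sp_fp),
            class = "ffc_pair_report")
}

#' @export
print.ffc_pair_report <- function(x, ...) {
  cat("Matched FF/FFPE pair report\n")
  m <- x$metrics
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %-28s %s\n", m$metric[i],
                formatC(m$value[i], digits = 6, format = "g")))
  invisible(x)
}

#' Write a pair report (and manifest) to a directory
#'
#' @param report an `ffc_pair_report`.
#' @param outdir output directory.
#' @param seed seed recorded in the manifest.
#' @return invisibly, the path of the metrics TSV.
#' @export
write_pair_report <- function(report, outdir, seed = NA_integer_) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  mpath <- file.path(outdir, "pair_metrics.tsv")
  write.table(report$metrics, mpath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  ppath <- file.path(outdir, "variant_positions.tsv")
  write.table(report$variant$positions, ppath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_run_manifest(outdir, "report", config = list(),
                     inputs = character(0), outputs = c(mpath, ppath),
                     seed = seed)
  invisible(mpath)
}
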