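#' Sweep coverage and MAPQ thresholds over a matched pair
#'
#' For every value in the coverage grid (then the MAPQ grid) the SNV calls
#' of both samples are recomputed with that threshold substituted — all
#' other filter fields held fixed — and the pairwise variant classification
#' is tabulated.  Raising a threshold can only shrink the call sets, so the
#' intersect sets are nested along each grid.
#'
#' @param ff_pileup,ffpe_pileup pileup data.frames of the matched pair.
#' @param coverage_grid,mapq_grid ascending numeric grids (either may be
#'   `NULL`).
#' @param filt baseline [filter_config()].
#' @param regions optional target regions.
#' @return data.frame with one row per grid value: `threshold_name,
#'   threshold_value, n_intersect, n_concordant, n_discordant,
#'   n_false_positive, n_false_negative`.
#' @export
coverage_mapq_sweep <- function(ff_pileup, ffpe_pileup,
                                coverage_grid = NULL, mapq_grid = NULL,
                                filt = filter_config(), regions = NULL) {
  if (is.null(coverage_grid) && is.null(mapq_grid))
    stop_config("provide at least one of coverage_grid, mapq_grid")
  one <- function(name, value) {
    f <- filt
    if (name == "coverage") f$min_coverage <- max(1L, as.integer(value))
    else f$min_mapq <- value
    tab <- classify_variants(variant_calls(call_snv(ff_pileup, f)),
                             variant_calls(call_snv(ffpe_pileup, f)),
                             regions)
    data.frame(threshold_name = name, threshold_value = value,
               n_intersect = tab$n_intersect,
               n_concordant = tab$n_concordant,
               n_discordant = tab$n_discordant,
               n_false_positive = tab$n_false_positive,
               n_false_negative = tab$n_false_negative,
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (v in coverage_grid) rows[[length(rows) + 1L]] <- one("coverage", v)
  for (v in mapq_grid) rows[[length(rows) + 1L]] <- one("mapq", v)
  do.call(rbind, rows)
}

#' Per-position VAF relationship across a classified matched pair
#'
#' One row per position in the union of the two call sets, carrying both
#' samples' variant allele fractions so that false-positive/false-negative
#' rows show the threshold-induced mechanism (the missing side's VAF is
#' recomputed from that sample's pileup using the called side's alternate
#' allele; 0 when no supporting reads).  Positions absent from both pileups
#' are dropped with a warning.  Each side's read depth at the position is
#' included for coverage-vs-discordance analyses.
#'
#' @param ff_variants,ffpe_variants variant call data.frames (with `vaf`).
#' @param classification `ffc_concordance` from [classify_variants()] on the
#'   same call sets.
#' @param ff_pileup,ffpe_pileup the pair's pileups.
#' @return data.frame `chrom, pos, class, vaf_ff, vaf_ffpe, depth_ff,
#'   depth_ffpe`.
#' @export
vaf_relationship <- function(ff_variants, ffpe_variants, classification,
                             ff_pileup, ffpe_pileup) {
  stopifnot(inherits(classification, "ffc_concordance"))
  p <- classification$positions
  if (nrow(p) == 0)
    return(data.frame(chrom = character(0), pos = integer(0),
                      class = character(0), vaf_ff = numeric(0),
                      vaf_ffpe = numeric(0), depth_ff = numeric(0),
                      depth_ffpe = numeric(0)))
  vaf_from <- function(variants, pos) variants$vaf[match(pos, variants$pos)]
  pileup_vaf <- function(pileup, pos, allele) {
    i <- match(pos, pileup$pos)
    cnt <- numeric(length(pos))
    ok <- !is.na(i) & allele %in% BASES
    col <- match(allele, BASES)
    M <- pileup_matrix(pileup)
    cnt[ok] <- M[cbind(i[ok], col[ok])]
    d <- pileup$depth[i]
    ifelse(is.na(i), NA_real_, ifelse(d > 0, cnt / d, 0))
  }
  vaf_ff <- vaf_from(ff_variants, p$pos)
  vaf_ffpe <- vaf_from(ffpe_variants, p$pos)
  need_ff <- is.na(vaf_ff)
  need_fp <- is.na(vaf_ffpe)
  vaf_ff[need_ff] <- pileup_vaf(ff_pileup, p$pos[need_ff],
                                p$ffpe_alt[need_ff])
  vaf_ffpe[need_fp] <- pileup_vaf(ffpe_pileup, p$pos[need_fp],
                                  p$ff_alt[need_fp])
  depth_ff <- ff_pileup$depth[match(p$pos, ff_pileup$pos)]
  depth_ffpe <- ffpe_pileup$depth[match(p$pos, ffpe_pileup$pos)]
  drop <- is.na(depth_ff) & is.na(depth_ffpe)
  if (any(drop)) {
    warning(sprintf("dropping %d position(s) absent from both pileups",
                    sum(drop)))
  }
  out <- data.frame(chrom = p$chrom, pos = p$pos, class = p$class,
                    vaf_ff = vaf_ff, vaf_ffpe = vaf_ffpe,
                    depth_ff = depth_ff, depth_ffpe = depth_ffpe,
                    stringsAsFactors = FALSE)
  out[!drop, , drop = FALSE]
}
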