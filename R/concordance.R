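new_concordance <- function(level, positions, extra = list()) {
  cls <- positions$class
  n_conc <- sum(cls == "concordant")
  n_disc <- sum(cls == "discordant")
  n_int <- n_conc + n_disc
  out <- c(list(level = level,
                n_intersect = n_int,
                n_concordant = n_conc,
                n_discordant = n_disc,
                concordance_rate = if (n_int > 0) n_conc / n_int else NA_real_),
           extra,
           list(positions = positions))
  structure(out, class = "ffc_concordance")
}

#' @export
print.ffc_concordance <- function(x, ...) {
  cat(sprintf("%s-level FF/FFPE concordance\n", x$level))
  cat(sprintf("  intersect %d: concordant %d, discordant %d (rate %s)\n",
              x$n_intersect, x$n_concordant, x$n_discordant,
              ifelse(is.na(x$concordance_rate), "NA",
                     sprintf("%.4f", x$concordance_rate))))
  if (!is.null(x$n_false_positive))
    cat(sprintf("  false positive (FFPE-only) %d, false negative (FF-only) %d\n",
                x$n_false_positive, x$n_false_negative))
  if (!is.null(x$n_not_assessed))
    cat(sprintf("  not assessed %d\n", x$n_not_assessed))
  invisible(x)
}

restrict_regions <- function(df, regions) {
  if (is.null(regions)) return(df)
  keep <- rep(FALSE, nrow(df))
  for (i in seq_len(nrow(regions))) {
    keep <- keep | (df$chrom == regions$chrom[i] &
                      df$pos >= regions$start[i] & df$pos <= regions$end[i])
  }
  df[keep, , drop = FALSE]
}

check_unique_positions <- function(df, what) {
  k <- pos_key(df$chrom, df$pos)
  if (anyDuplicated(k))
    stop_config("duplicated positions in %s call set", what)
  k
}

#' Base-level concordance between matched FF and FFPE consensus calls
#'
#' The intersect is the set of positions with a non-NO_CALL consensus base in
#' both samples (optionally restricted to target regions); a position is
#' concordant when the two bases agree.  FF is the reference sample by
#' convention.
#'
#' @param ff_calls,ffpe_calls outputs of [consensus_base_call()].
#' @param regions optional data.frame of 1-based inclusive intervals
#'   (`chrom, start, end`).
#' @return an `ffc_concordance` with counts, rate, and a per-position
#'   classification data.frame.
#' @export
classify_base_calls <- function(ff_calls, ffpe_calls, regions = NULL) {
  ff <- restrict_regions(ff_calls, regions)
  fp <- restrict_regions(ffpe_calls, regions)
  kf <- check_unique_positions(ff, "FF")
  kp <- check_unique_positions(fp, "FFPE")
  m <- merge(
    data.frame(key = kf, chrom = ff$chrom, pos = ff$pos, ff = ff$base,
               stringsAsFactors = FALSE),
    data.frame(key = kp, ffpe = fp$base, stringsAsFactors = FALSE),
    by = "key")
  m <- m[!is.na(m$ff) & !is.na(m$ffpe), , drop = FALSE]
  m$class <- ifelse(m$ff == m$ffpe, "concordant", "discordant")
  m <- m[order(m$pos), c("chrom", "pos", "ff", "ffpe", "class")]
  rownames(m) <- NULL
  new_concordance("base", m)
}

#' Variant-level concordance between matched FF and FFPE call sets
#'
#' Positions called variant in both samples are concordant when the
#' alternate alleles agree (genotype class is ignored) and discordant
#' otherwise; positions called only in FFPE are false positives and only in
#' FF false negatives, FF being the reference sample.
#'
#' @param ff_variants,ffpe_variants variant call data.frames (rows with
#'   `chrom, pos, alt`), e.g. [variant_calls()] of [call_snv()] output.
#' @inheritParams classify_base_calls
#' @return an `ffc_concordance` with additional `n_false_positive`,
#'   `n_false_negative` counts; the `positions` element carries `ff_alt`,
#'   `ffpe_alt` and class per position.
#' @export
classify_variants <- function(ff_variants, ffpe_variants, regions = NULL) {
  ff <- restrict_regions(ff_variants, regions)
  fp <- restrict_regions(ffpe_variants, regions)
  kf <- check_unique_positions(ff, "FF")
  kp <- check_unique_positions(fp, "FFPE")
  m <- merge(
    data.frame(key = kf, chrom = ff$chrom, pos = ff$pos, ff_alt = ff$alt,
               stringsAsFactors = FALSE),
    data.frame(key = kp, chrom2 = fp$chrom, pos2 = fp$pos, ffpe_alt = fp$alt,
               stringsAsFactors = FALSE),
    by = "key", all = TRUE)
  m$chrom <- ifelse(is.na(m$chrom), m$chrom2, m$chrom)
  m$pos <- ifelse(is.na(m$pos), m$pos2, m$pos)
  m$class <- ifelse(is.na(m$ff_alt), "false_positive",
                    ifelse(is.na(m$ffpe_alt), "false_negative",
                           ifelse(m$ff_alt == m$ffpe_alt,
                                  "concordant", "discordant")))
  m <- m[order(m$chrom, m$pos), c("chrom", "pos", "ff_alt", "ffpe_alt", "class")]
  rownames(m) <- NULL
  new_concordance("variant", m,
                  extra = list(n_false_positive = sum(m$class == "false_positive"),
                               n_false_negative = sum(m$class == "false_negative")))
}

#' Compare sequencing genotype calls against an orthogonal array
#'
#' At every array site with a filtered sequencing call, the sequencing
#' genotype class (`no_variant` mapped to `ref`, variant calls to `het` /
#' `hom`) is compared with the array class; both reference and alternate
#' alleles are thereby evaluated.  Array sites without a sequencing call are
#' excluded from the denominator and counted in `n_not_assessed`.
#'
#' @param sample_calls output of [call_snv()] (all statuses, not only
#'   variants).
#' @param array_genotypes data.frame with `pos`, `genotype` in
#'   `ref`/`het`/`hom` (see [simulate_array_genotypes()]).
#' @return an `ffc_concordance` with `n_not_assessed`.
#' @export
compare_to_array <- function(sample_calls, array_genotypes) {
  seq_class <- ifelse(sample_calls$status == "variant",
                      ifelse(sample_calls$genotype == "hom_alt", "hom", "het"),
                      ifelse(sample_calls$status == "no_variant", "ref",
                             NA_character_))
  seq_df <- data.frame(pos = sample_calls$pos, seq = seq_class,
                       chrom = sample_calls$chrom, stringsAsFactors = FALSE)
  m <- merge(array_genotypes, seq_df, by = "pos", all.x = TRUE)
  not_assessed <- sum(is.na(m$seq))
  m <- m[!is.na(m$seq), , drop = FALSE]
  pos <- data.frame(chrom = m$chrom, pos = m$pos, array = m$genotype,
                    seq = m$seq,
                    class = ifelse(m$seq == m$genotype, "concordant",
                                   "discordant"),
                    stringsAsFactors = FALSE)
  pos <- pos[order(pos$pos), ]
  rownames(pos) <- NULL
  new_concordance("array", pos, extra = list(n_not_assessed = not_assessed))
}
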