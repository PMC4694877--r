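#' Hard-filter configuration for consensus and variant calling
#'
#' Defaults follow the filters used throughout the matched-pair analyses:
#' coverage >= 13 and per-position mapping quality >= 43 for whole-genome and
#' whole-exome data, a minimum of 20 unique reads in targeted exon sequencing
#' (`mode = "tes"`), and a strict variant-allele-fraction threshold (calls
#' require VAF > 0.2).  The heterozygous/homozygous boundary (VAF >= 0.8 is
#' called hom_alt) is a package default; the threshold analyses upstream do
#' not constrain it.
#'
#' @param mode one of `"wgs"`, `"wxs"`, `"tes"`; sets `min_coverage` to
#'   13/13/20 unless overridden.
#' @param min_coverage minimum read depth for any call.
#' @param min_mapq minimum per-position mapping quality.
#' @param min_vaf variant calls require VAF strictly greater than this.
#' @param het_hom_boundary VAF at or above which a call is `hom_alt`.
#' @return an object of class `ffc_filter`.
#' @export
filter_config <- function(mode = c("wgs", "wxs", "tes"),
                          min_coverage = NULL, min_mapq = 43,
                          min_vaf = 0.2, het_hom_boundary = 0.8) {
  mode <- match.arg(mode)
  if (is.null(min_coverage))
    min_coverage <- if (mode == "tes") 20L else 13L
  if (min_coverage < 1) stop_config("'min_coverage' must be >= 1")
  if (min_vaf < 0 || min_vaf >= het_hom_boundary || het_hom_boundary > 1)
    stop_config("need 0 <= min_vaf < het_hom_boundary <= 1")
  structure(list(mode = mode, min_coverage = as.integer(min_coverage),
                 min_mapq = min_mapq, min_vaf = min_vaf,
                 het_hom_boundary = het_hom_boundary),
            class = "ffc_filter")
}

#' @export
print.ffc_filter <- function(x, ...) {
  cat(sprintf("Hard filter (%s): coverage >= %d, MAPQ >= %g, VAF > %g, hom at >= %g\n",
              x$mode, x$min_coverage, x$min_mapq, x$min_vaf,
              x$het_hom_boundary))
  invisible(x)
}

pileup_matrix <- function(pileup) {
  as.matrix(pileup[, c("nA", "nC", "nG", "nT")])
}

IUPAC2 <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

#' Hard-filtered consensus base calls
#'
#' A position gets no call when its depth is below `min_coverage` or its
#' mapping quality is below `min_mapq`.  In the default (majority) mode the
#' call is the majority base among the A/C/G/T counts, with an exact tie
#' among the top bases yielding no call — fully deterministic.  With
#' `het_aware = TRUE` the consensus is diploid-style, as samtools-era pileup
#' consensus was: when the second-most-frequent base exceeds the `min_vaf`
#' fraction of reads the call is the two-base IUPAC ambiguity code (e.g. `Y`
#' for a C/T heterozygote), which makes consensus at heterozygous sites a
#' deterministic function of the underlying genotype rather than a coin
#' flip between the two alleles.
#'
#' @param pileup pileup data.frame (see [read_pileup()]).
#' @param filt an [filter_config()] object.
#' @param het_aware emit IUPAC two-base codes for heterozygous positions.
#' @return data.frame with `chrom, pos, base`; `base` is `NA` for NO_CALL.
#' @export
consensus_base_call <- function(pileup, filt = filter_config(),
                                het_aware = FALSE) {
  M <- pileup_matrix(pileup)
  n <- nrow(M)
  pass <- pileup$depth >= filt$min_coverage & pileup$mapq >= filt$min_mapq
  top <- max.col(M, ties.method = "first")
  topcount <- M[cbind(seq_len(n), top)]
  base <- BASES[top]
  if (het_aware) {
    M2 <- M
    M2[cbind(seq_len(n), top)] <- -1L
    second <- max.col(M2, ties.method = "first")
    secondcount <- M[cbind(seq_len(n), second)]
    het <- pileup$depth > 0 & secondcount / pileup$depth > filt$min_vaf
    i <- which(het)
    if (length(i)) {
      pair <- ifelse(top[i] < second[i],
                     paste0(BASES[top[i]], BASES[second[i]]),
                     paste0(BASES[second[i]], BASES[top[i]]))
      base[i] <- IUPAC2[pair]
    }
    base[!pass] <- NA_character_
  } else {
    tie <- rowSums(M == topcount) > 1L
    base[tie | !pass] <- NA_character_
  }
  data.frame(chrom = pileup$chrom, pos = pileup$pos, base = base,
             stringsAsFactors = FALSE)
}

#' Threshold-based SNV calling from pileups
#'
#' Positions failing the coverage/MAPQ hard filter get status `no_call`.
#' Otherwise the candidate alternate allele is the non-reference base with
#' the highest count (ties broken by base order A < C < G < T) and
#' `vaf = alt_count / depth`; status is `no_variant` when `vaf <= min_vaf`
#' (the threshold is strict: VAF exactly at the boundary is not called) and
#' `variant` otherwise, with genotype `het` below `het_hom_boundary` and
#' `hom_alt` at or above it.  Positions with reference base `N` are skipped
#' with a warning.
#'
#' @inheritParams consensus_base_call
#' @return data.frame with one row per retained pileup position: `chrom,
#'   pos, ref, status, alt, genotype, vaf, depth, mapq`.
#' @export
call_snv <- function(pileup, filt = filter_config()) {
  isN <- pileup$ref == "N"
  if (any(isN)) {
    warning(sprintf("skipping %d position(s) with reference N", sum(isN)))
    pileup <- pileup[!isN, , drop = FALSE]
  }
  n <- nrow(pileup)
  M <- pileup_matrix(pileup)
  refidx <- match(pileup$ref, BASES)
  M2 <- M
  M2[cbind(seq_len(n), refidx)] <- -1L
  alt_i <- max.col(M2, ties.method = "first")
  alt_count <- M2[cbind(seq_len(n), alt_i)]
  alt_count[alt_count < 0L] <- 0L
  vaf <- ifelse(pileup$depth > 0, alt_count / pileup$depth, 0)
  pass <- pileup$depth >= filt$min_coverage & pileup$mapq >= filt$min_mapq
  status <- ifelse(!pass, "no_call",
                   ifelse(vaf <= filt$min_vaf, "no_variant", "variant"))
  genotype <- ifelse(status == "variant",
                     ifelse(vaf >= filt$het_hom_boundary, "hom_alt", "het"),
                     NA_character_)
  alt <- ifelse(status == "variant", BASES[alt_i], NA_character_)
  data.frame(chrom = pileup$chrom, pos = pileup$pos, ref = pileup$ref,
             status = status, alt = alt, genotype = genotype,
             vaf = vaf, depth = pileup$depth, mapq = pileup$mapq,
             stringsAsFactors = FALSE)
}

#' Threshold-based INDEL calling from pileups
#'
#' Applies the same hard filter and strict VAF threshold as [call_snv()] to
#' the insertion- and deletion-supporting read counts.  When both event
#' types are supported at a position the higher count wins; an exact tie
#' yields no call.  Event alleles use the anchored-base VCF convention and
#' take their sequences from the `ins_seq` / `del_seq` pileup columns when
#' present (symbolic `<INS>` / `<DEL>` otherwise).
#'
#' @inheritParams consensus_base_call
#' @return data.frame with `chrom, pos, status, type, ref, alt, vaf, depth,
#'   mapq`; `type` is `ins` or `del` for variant rows.
#' @export
call_indel <- function(pileup, filt = filter_config()) {
  n <- nrow(pileup)
  pass <- pileup$depth >= filt$min_coverage & pileup$mapq >= filt$min_mapq
  ins <- pileup$n_ins; del <- pileup$n_del
  tie <- ins == del & ins > 0L
  type <- ifelse(ins > del, "ins", ifelse(del > ins, "del", NA_character_))
  count <- pmax(ins, del)
  vaf <- ifelse(pileup$depth > 0, count / pileup$depth, 0)
  status <- ifelse(!pass | tie, "no_call",
                   ifelse(vaf <= filt$min_vaf | is.na(type),
                          "no_variant", "variant"))
  has_ins <- "ins_seq" %in% names(pileup)
  anchor <- pileup$ref
  refall <- altall <- rep(NA_character_, n)
  iv <- which(status == "variant" & type == "ins")
  dv <- which(status == "variant" & type == "del")
  if (length(iv)) {
    seqs <- if (has_ins) pileup$ins_seq[iv] else ""
    refall[iv] <- anchor[iv]
    altall[iv] <- ifelse(nzchar(seqs), paste0(anchor[iv], seqs), "<INS>")
  }
  if (length(dv)) {
    seqs <- if (has_ins) pileup$del_seq[dv] else ""
    refall[dv] <- ifelse(nzchar(seqs), paste0(anchor[dv], seqs), "<DEL>")
    altall[dv] <- anchor[dv]
  }
  data.frame(chrom = pileup$chrom, pos = pileup$pos, status = status,
             type = ifelse(status == "variant", type, NA_character_),
             ref = refall, alt = altall, vaf = vaf, depth = pileup$depth,
             mapq = pileup$mapq, stringsAsFactors = FALSE)
}

#' Extract the variant rows of a [call_snv()] / [call_indel()] result
#' @param calls data.frame with a `status` column.
#' @return the rows with `status == "variant"`.
#' @export
variant_calls <- function(calls) {
  calls[calls$status == "variant", , drop = FALSE]
}
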