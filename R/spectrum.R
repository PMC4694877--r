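SUB_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Collapse an SNV onto the pyrimidine strand and classify it
#'
#' Purine reference sites (A/G) are complemented so every substitution maps
#' to one of the six collapsed classes `C>A, C>G, C>T, T>A, T>C, T>G`; the
#' `C>T` class therefore pools C>T with G>A, the combined C·G>T·A class in
#' which formalin-induced cytosine deamination appears.
#'
#' @param ref,alt character vectors of single reference/alternate bases.
#' @return character vector of collapsed classes.
#' @export
substitution_class <- function(ref, alt) {
  flip <- ref %in% c("A", "G")
  ref[flip] <- complement_bases(ref[flip])
  alt[flip] <- complement_bases(alt[flip])
  cls <- paste0(ref, ">", alt)
  if (any(!cls %in% SUB_CLASSES))
    stop_config("invalid substitution: %s",
                paste(unique(cls[!cls %in% SUB_CLASSES]), collapse = ", "))
  cls
}

#' Substitution-class spectrum, C·G>T·A rate and Ts/Tv of a variant set
#'
#' Each SNV is mapped to one of the six collapsed substitution classes;
#' `ct_rate_all` is the fraction of SNVs in the C·G>T·A class, and `tstv`
#' the transition/transversion ratio (`NA` when there are no transversions
#' or no variants).  Every variant's reference allele is validated against
#' the supplied reference sequence.
#'
#' @param variants variant data.frame (`pos, ref, alt`; single-base alleles).
#' @param reference reference string.
#' @return object of class `ffc_spectrum`: list with `counts` (named vector
#'   over the six classes), `n`, `ct_rate_all`, `tstv`.
#' @export
substitution_spectrum <- function(variants, reference) {
  if (nrow(variants) == 0)
    return(structure(list(counts = setNames(rep(0L, 6L), SUB_CLASSES),
                          n = 0L, ct_rate_all = NA_real_, tstv = NA_real_),
                     class = "ffc_spectrum"))
  refbase <- substring(reference, variants$pos, variants$pos)
  bad <- which(refbase != variants$ref)
  if (length(bad))
    stop_config("variant reference mismatch at position %d (variant says %s, reference %s)",
                variants$pos[bad[1]], variants$ref[bad[1]], refbase[bad[1]])
  cls <- substitution_class(variants$ref, variants$alt)
  counts <- table(factor(cls, levels = SUB_CLASSES))
  counts <- setNames(as.integer(counts), SUB_CLASSES)
  n <- sum(counts)
  ts <- counts["C>T"] + counts["T>C"]
  tv <- n - ts
  structure(list(counts = counts, n = n,
                 ct_rate_all = unname(counts["C>T"] / n),
                 tstv = if (tv > 0) unname(ts / tv) else NA_real_),
            class = "ffc_spectrum")
}

#' @export
print.ffc_spectrum <- function(x, ...) {
  cat("Collapsed substitution spectrum (n =", x$n, ")\n")
  print(x$counts)
  cat(sprintf("  C.G>T.A rate %.4f, Ts/Tv %s\n",
              ifelse(is.na(x$ct_rate_all), NA, x$ct_rate_all),
              ifelse(is.na(x$tstv), "NA", sprintf("%.2f", x$tstv))))
  invisible(x)
}

#' C·G>T·A fraction at discordant (or other disagreement-class) positions
#'
#' Among positions of the selected classes from a variant-level pair
#' classification, computes the fraction whose FFPE-side call is C·G>T·A
#' relative to the reference, and symmetrically for the FF side.  With no
#' qualifying positions the rates are reported missing, not zero.
#'
#' @param classification an `ffc_concordance` from [classify_variants()].
#' @param reference reference string.
#' @param classes which disagreement classes to include (default:
#'   strictly discordant positions, i.e. both samples called a variant).
#' @return list with `ffpe_rate`, `ff_rate`, `n_ffpe`, `n_ff`,
#'   `ffpe_ct`, `ff_ct`.
#' @export
discordant_ct_rate <- function(classification, reference,
                               classes = "discordant") {
  stopifnot(inherits(classification, "ffc_concordance"),
            classification$level == "variant")
  p <- classification$positions
  p <- p[p$class %in% classes, , drop = FALSE]
  if (nrow(p) == 0)
    return(list(ffpe_rate = NA_real_, ff_rate = NA_real_,
                n_ffpe = 0L, n_ff = 0L, ffpe_ct = 0L, ff_ct = 0L))
  refbase <- substring(reference, p$pos, p$pos)
  side_rate <- function(alt) {
    ok <- !is.na(alt)
    if (!any(ok)) return(list(rate = NA_real_, n = 0L, ct = 0L))
    ct <- substitution_class(refbase[ok], alt[ok]) == "C>T"
    list(rate = mean(ct), n = sum(ok), ct = sum(ct))
  }
  fp <- side_rate(p$ffpe_alt)
  ff <- side_rate(p$ff_alt)
  list(ffpe_rate = fp$rate, ff_rate = ff$rate,
       n_ffpe = fp$n, n_ff = ff$n, ffpe_ct = fp$ct, ff_ct = ff$ct)
}

#' Global mismatch rate over filtered positions
#'
#' The fraction of read bases differing from the reference base, summed over
#' positions passing the hard filter and excluding called-variant positions
#' so that true variants do not inflate the mismatch estimate (the exclusion
#' set is configurable through `variant_positions`).
#'
#' @param pileup pileup data.frame.
#' @param reference reference string.
#' @param variant_positions integer vector of positions to exclude
#'   (typically called variants), or `NULL`.
#' @param filt an [filter_config()].
#' @return mismatch proportion (`NA` when no read bases qualify).
#' @export
global_mismatch_rate <- function(pileup, reference, variant_positions = NULL,
                                 filt = filter_config()) {
  keep <- pileup$depth >= filt$min_coverage & pileup$mapq >= filt$min_mapq
  if (!is.null(variant_positions))
    keep <- keep & !(pileup$pos %in% variant_positions)
  p <- pileup[keep, , drop = FALSE]
  if (nrow(p) == 0) return(NA_real_)
  M <- pileup_matrix(p)
  refidx <- match(p$ref, BASES)
  ok <- !is.na(refidx)
  M <- M[ok, , drop = FALSE]; refidx <- refidx[ok]
  total <- sum(M)
  if (total == 0) return(NA_real_)
  match_ref <- sum(M[cbind(seq_len(nrow(M)), refidx)])
  (total - match_ref) / total
}

#' C>T rates stratified by CpN and NpC dinucleotide context
#'
#' Every reference cytosine (and every guanine, complemented onto the
#' pyrimidine strand) is classified by its 3' neighbor into CpA/CpC/CpG/CpT
#' and by its 5' neighbor into ApC/CpC/GpC/TpC; the first and last base of
#' the contig are excluded.  In `call_level` mode the rate per context is
#' the fraction of eligible sites carrying a C>T (G>A) variant call; in
#' `read_level` mode it is the fraction of read bases at eligible sites that
#' support T (A), the direct read-level footprint of cytosine deamination.
#'
#' @param x a variant data.frame (`pos, ref, alt`) in `call_level` mode, or
#'   a pileup data.frame in `read_level` mode.
#' @param reference reference string (length >= 3).
#' @param mode `"call_level"` or `"read_level"`.
#' @return list with named numeric vectors `cpn_rates`, `npc_rates` and the
#'   corresponding numerator/denominator tables `cpn_counts`, `npc_counts`.
#' @export
context_ct_rates <- function(x, reference, mode = c("call_level", "read_level")) {
  mode <- match.arg(mode)
  L <- nchar(reference)
  if (L < 3) stop_config("contig shorter than 3 bases")
  refv <- strsplit(reference, "", fixed = TRUE)[[1]]
  pos <- 2:(L - 1L)
  base <- refv[pos]
  isC <- base == "C"; isG <- base == "G"
  sites <- pos[isC | isG]
  siteC <- refv[sites] == "C"
  # 3' neighbor on the pyrimidine strand
  nxt <- ifelse(siteC, refv[sites + 1L], complement_bases(refv[sites - 1L]))
  # 5' neighbor on the pyrimidine strand
  prv <- ifelse(siteC, refv[sites - 1L], complement_bases(refv[sites + 1L]))
  cpn_lab <- paste0("Cp", nxt)
  npc_lab <- paste0(prv, "pC")
  cpn_lv <- paste0("Cp", BASES)
  npc_lv <- paste0(BASES, "pC")

  if (mode == "call_level") {
    v <- x[x$pos %in% sites, , drop = FALSE]
    is_ct <- logical(length(sites))
    if (nrow(v)) {
      idx <- match(v$pos, sites)
      hit <- (v$ref == "C" & v$alt == "T") | (v$ref == "G" & v$alt == "A")
      is_ct[idx[hit]] <- TRUE
    }
    num_cpn <- tapply(is_ct, factor(cpn_lab, cpn_lv), sum, default = 0)
    den_cpn <- table(factor(cpn_lab, cpn_lv))
    num_npc <- tapply(is_ct, factor(npc_lab, npc_lv), sum, default = 0)
    den_npc <- table(factor(npc_lab, npc_lv))
  } else {
    pi <- x[match(sites, x$pos), , drop = FALSE]
    t_count <- ifelse(siteC, pi$nT, pi$nA)
    depth <- pi$depth
    t_count[is.na(t_count)] <- 0L
    depth[is.na(depth)] <- 0L
    num_cpn <- tapply(t_count, factor(cpn_lab, cpn_lv), sum, default = 0)
    den_cpn <- tapply(depth, factor(cpn_lab, cpn_lv), sum, default = 0)
    num_npc <- tapply(t_count, factor(npc_lab, npc_lv), sum, default = 0)
    den_npc <- tapply(depth, factor(npc_lab, npc_lv), sum, default = 0)
  }
  rate <- function(num, den) {
    r <- as.numeric(num) / as.numeric(den)
    r[as.numeric(den) == 0] <- NA_real_
    setNames(r, names(num))
  }
  list(cpn_rates = rate(num_cpn, den_cpn),
       npc_rates = rate(num_npc, den_npc),
       cpn_counts = data.frame(context = cpn_lv,
                               numerator = as.numeric(num_cpn),
                               denominator = as.numeric(den_cpn)),
       npc_counts = data.frame(context = npc_lv,
                               numerator = as.numeric(num_npc),
                               denominator = as.numeric(den_npc)))
}
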