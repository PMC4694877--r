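SAMPLE_KINDS <- c("FF_normal", "FF_tumor", "FFPE_normal", "FFPE_tumor")

## per-position copy-number factor (copy_state / 2) for tumor kinds
cn_factor <- function(n, cnv_segments) {
  fac <- rep(1, n)
  if (!is.null(cnv_segments)) {
    for (i in seq_len(nrow(cnv_segments))) {
      s <- cnv_segments$start[i]; e <- min(cnv_segments$end[i], n)
      fac[s:e] <- cnv_segments$copy_state[i] / 2
    }
  }
  fac
}

rcoverage <- function(n, mu, dispersion) {
  if (dispersion <= 0) rpois(n, mu) else rnbinom(n, size = 1 / dispersion, mu = mu)
}

rtrunc_norm <- function(n, mean, sd, lo = 0, hi = 60) {
  if (sd <= 0) return(rep(pmin(pmax(mean, lo), hi), n))
  a <- pnorm(lo, mean, sd); b <- pnorm(hi, mean, sd)
  qnorm(runif(n, a, b), mean, sd)
}

#' Simulate a per-position pileup for one sample of a matched pair
#'
#' Coverage is negative-binomial (Poisson when dispersion is 0) with mean
#' `mean_coverage_ff` or `mean_coverage_ffpe`; tumor kinds scale the expected
#' depth by the covering CNV segment's `copy_state / 2`.  Read bases follow
#' the truth allele (sampled by genotype or truth VAF at variant sites), are
#' miscalled to a uniform other base at `seq_error_rate`, and — for FFPE
#' kinds only — read C bases at reference-C positions are flipped to T with
#' probability `deamination_rate_cpg` when the 3' neighbor is G, else
#' `deamination_rate_noncpg` (reference-G positions are handled symmetrically
#' on the complementary strand, G read bases flipping to A).  Per-position
#' mapping quality is truncated-normal on `[0, 60]`.  INDEL events are
#' supported by each read with probability equal to the truth VAF.
#'
#' @param reference reference string.
#' @param truth an `ffc_truth` from [generate_truth()].
#' @param config an [sim_config()] object.
#' @param sample_kind one of `"FF_normal"`, `"FF_tumor"`, `"FFPE_normal"`,
#'   `"FFPE_tumor"`.
#' @param chrom chromosome name used in the output records.
#' @return a pileup data.frame with columns `chrom, pos, ref, depth, nA, nC,
#'   nG, nT, n_ins, n_del, mapq, ins_seq, del_seq`.  The two trailing columns
#'   carry the truth INDEL sequences so that downstream INDEL calls can emit
#'   concrete alleles.
#' @export
simulate_pileup <- function(reference, truth, config,
                            sample_kind = SAMPLE_KINDS, chrom = "chr1") {
  sample_kind <- match.arg(sample_kind)
  stopifnot(inherits(config, "ffc_sim_config"), inherits(truth, "ffc_truth"))
  is_ffpe <- grepl("^FFPE", sample_kind)
  is_tumor <- grepl("tumor$", sample_kind)
  n <- nchar(reference)
  refv <- ref_codes(reference)
  if (anyNA(refv)) stop_config("reference may contain only A/C/G/T")

  with_substream(config$seed, paste0("pileup_", sample_kind), {
    mu <- (if (is_ffpe) config$mean_coverage_ffpe else config$mean_coverage_ff) *
      (if (is_tumor) cn_factor(n, truth$cnv_segments) else rep(1, n))
    depth <- rcoverage(n, mu, config$coverage_dispersion)

    p_alt <- numeric(n)
    alt_idx <- integer(n)
    if (nrow(truth$germline)) {
      p_alt[truth$germline$pos] <- ifelse(truth$germline$genotype == "hom_alt", 1, 0.5)
      alt_idx[truth$germline$pos] <- match(truth$germline$alt, BASES)
    }
    if (is_tumor && nrow(truth$somatic)) {
      p_alt[truth$somatic$pos] <- truth$somatic$vaf
      alt_idx[truth$somatic$pos] <- match(truth$somatic$alt, BASES)
    }
    n_alt <- rbinom(n, depth, p_alt)
    M <- matrix(0L, nrow = n, ncol = 4L)
    M[cbind(seq_len(n), refv)] <- depth - n_alt
    va <- which(alt_idx > 0L)
    if (length(va))
      M[cbind(va, alt_idx[va])] <- M[cbind(va, alt_idx[va])] + n_alt[va]

    err <- config$seq_error_rate
    if (err > 0) {
      for (b in 1:4) {
        e <- rbinom(n, M[, b], err)
        hit <- which(e > 0L)
        if (!length(hit)) next
        M[hit, b] <- M[hit, b] - e[hit]
        parts <- split3(e[hit])
        others <- setdiff(1:4, b)
        for (j in 1:3) M[hit, others[j]] <- M[hit, others[j]] + parts[, j]
      }
    }

    if (is_ffpe &&
        (config$deamination_rate_cpg > 0 || config$deamination_rate_noncpg > 0)) {
      nxt <- c(refv[-1L], NA_integer_)
      prv <- c(NA_integer_, refv[-n])
      isC <- refv == 2L
      isG <- refv == 3L
      rateC <- ifelse(!is.na(nxt) & nxt == 3L,
                      config$deamination_rate_cpg, config$deamination_rate_noncpg)
      rateG <- ifelse(!is.na(prv) & prv == 2L,
                      config$deamination_rate_cpg, config$deamination_rate_noncpg)
      dC <- rbinom(n, ifelse(isC, M[, 2L], 0L), rateC)
      M[, 2L] <- M[, 2L] - dC
      M[, 4L] <- M[, 4L] + dC
      dG <- rbinom(n, ifelse(isG, M[, 3L], 0L), rateG)
      M[, 3L] <- M[, 3L] - dG
      M[, 1L] <- M[, 1L] + dG
    }

    n_ins <- integer(n); n_del <- integer(n)
    ins_seq <- character(n); del_seq <- character(n)
    if (nrow(truth$indels)) {
      ip <- truth$indels$pos
      supp <- rbinom(length(ip), depth[ip], truth$indels$vaf)
      is_ins <- truth$indels$type == "ins"
      n_ins[ip[is_ins]] <- supp[is_ins]
      n_del[ip[!is_ins]] <- supp[!is_ins]
      ins_seq[ip[is_ins]] <- truth$indels$seq[is_ins]
      del_seq[ip[!is_ins]] <- truth$indels$seq[!is_ins]
    }

    mapq <- rtrunc_norm(n,
                        if (is_ffpe) config$mapq_mean_ffpe else config$mapq_mean_ff,
                        config$mapq_sd)

    data.frame(chrom = chrom, pos = seq_len(n), ref = BASES[refv],
               depth = depth, nA = M[, 1L], nC = M[, 2L], nG = M[, 3L],
               nT = M[, 4L], n_ins = n_ins, n_del = n_del,
               mapq = round(mapq, 2), ins_seq = ins_seq, del_seq = del_seq,
               stringsAsFactors = FALSE)
  })
}

#' Simulate matched-pair array genotypes at germline sites
#'
#' Emulates an orthogonal genotyping-array platform: genotypes are emitted at
#' a configurable subset of the germline truth sites and each is corrupted
#' with probability `error_rate` to a uniform draw from the other genotype
#' classes (`ref` / `het` / `hom`).
#'
#' @param truth an `ffc_truth`.
#' @param error_rate per-site corruption probability in `[0, 1]`.
#' @param seed integer seed.
#' @param site_fraction fraction of germline sites placed on the array.
#' @return data.frame with columns `pos`, `genotype`.
#' @export
simulate_array_genotypes <- function(truth, error_rate, seed,
                                     site_fraction = 1) {
  stopifnot(inherits(truth, "ffc_truth"))
  check_prob(error_rate, "error_rate")
  check_prob(site_fraction, "site_fraction")
  classes <- c("ref", "het", "hom")
  with_substream(seed, "array_genotypes", {
    pos <- truth$germline$pos
    if (site_fraction < 1)
      pos <- sort(sample(pos, round(site_fraction * length(pos))))
    geno <- ifelse(truth$germline$genotype[match(pos, truth$germline$pos)] ==
                     "hom_alt", "hom", "het")
    flip <- runif(length(pos)) < error_rate
    if (any(flip))
      geno[flip] <- vapply(geno[flip],
                           function(g) sample(setdiff(classes, g), 1L), "")
    data.frame(pos = pos, genotype = geno, stringsAsFactors = FALSE)
  })
}
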