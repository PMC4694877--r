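#' Generate a random reference sequence
#'
#' Draws an iid nucleotide sequence with the configured GC content, then
#' adjusts the CG-dinucleotide frequency toward
#' `cpg_enrichment * (gc/2)^2` by planting (or destroying) CG dinucleotides.
#' When CpGs are planted, a matched expected number of other C/G bases is
#' flipped to A/T so the overall expected GC content is preserved.
#'
#' @param config an [sim_config()] object.
#' @return a single character string of length `genome_length` over A/C/G/T.
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "ffc_sim_config"))
  L <- config$genome_length
  gc <- config$gc_fraction
  with_substream(config$seed, "reference", {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    x <- sample(BASES, L, replace = TRUE, prob = p)
    enr <- config$cpg_enrichment
    if (enr != 1 && L >= 2 && gc > 0) {
      base_freq <- (gc / 2)^2
      target <- enr * base_freq
      if (target > base_freq) {
        k <- round((target - base_freq) * (L - 1))
        if (k > 0) {
          cand <- sample.int(L - 1L, min(3L * k, L - 1L))
          # avoid overlapping plant sites
          keep <- logical(length(cand))
          used <- logical(L)
          for (i in seq_along(cand)) {
            s <- cand[i]
            if (!used[s] && !used[s + 1L]) {
              keep[i] <- TRUE
              used[s] <- used[s + 1L] <- TRUE
            }
            if (sum(keep) >= k) break
          }
          plant <- cand[keep]
          # GC gained by overwriting two average bases with C,G
          gain <- round(2 * length(plant) * (1 - gc))
          x[plant] <- "C"; x[plant + 1L] <- "G"
          if (gain > 0) {
            gcpos <- which((x == "C" | x == "G") & !used)
            if (length(gcpos) > gain) {
              flip <- sample(gcpos, gain)
              x[flip] <- sample(c("A", "T"), gain, replace = TRUE)
            }
          }
        }
      } else {
        cg <- which(x[-L] == "C" & x[-1L] == "G")
        drop_frac <- if (base_freq > 0) 1 - target / base_freq else 0
        ndrop <- round(drop_frac * length(cg))
        if (ndrop > 0) {
          hit <- sample(cg, ndrop)
          x[hit + 1L] <- "A"
          atpos <- which(x == "A" | x == "T")
          atpos <- setdiff(atpos, hit + 1L)
          if (length(atpos) > ndrop)
            x[sample(atpos, ndrop)] <- "G"
        }
      }
    }
    paste(x, collapse = "")
  })
}

#' Generate the shared truth set for a matched FF/FFPE quad
#'
#' Germline heterozygous SNVs are drawn per base at `germline_het_rate`;
#' somatic SNVs (tumor-only) at `somatic_rate` with truth VAF drawn from a
#' Beta distribution centered on `tumor_vaf_mean`; germline INDELs at
#' `indel_rate` with sizes `1 + Poisson(mean - 1)` (means `indel_mean_ins` /
#' `indel_mean_del`).  Germline, somatic and INDEL position sets are
#' disjoint.  CNV segments are copied from the configuration.
#'
#' @param reference reference string from [generate_reference()].
#' @param config an [sim_config()] object.
#' @return an object of class `ffc_truth`: list with data.frames `germline`
#'   (pos, ref, alt, genotype), `somatic` (pos, ref, alt, vaf), `indels`
#'   (pos, type, length, seq, vaf) and `cnv_segments`.
#' @export
generate_truth <- function(reference, config) {
  stopifnot(inherits(config, "ffc_sim_config"), nzchar(reference))
  L <- nchar(reference)
  refv <- strsplit(reference, "", fixed = TRUE)[[1]]
  with_substream(config$seed, "truth", {
    g_pos <- which(runif(L) < config$germline_het_rate)
    g_alt <- vapply(g_pos, function(p) sample(setdiff(BASES, refv[p]), 1L), "")
    s_pos <- which(runif(L) < config$somatic_rate)
    s_pos <- setdiff(s_pos, g_pos)
    s_alt <- vapply(s_pos, function(p) sample(setdiff(BASES, refv[p]), 1L), "")
    m <- config$tumor_vaf_mean
    conc <- 20
    s_vaf <- if (length(s_pos)) {
      if (m >= 1) rep(1, length(s_pos))
      else pmin(pmax(rbeta(length(s_pos), m * conc, (1 - m) * conc), 0.02), 1)
    } else numeric(0)

    i_pos <- which(runif(L - 1) < config$indel_rate)  # anchor needs pos+1
    i_pos <- setdiff(i_pos, union(g_pos, s_pos))
    n_i <- length(i_pos)
    i_type <- if (n_i) sample(c("ins", "del"), n_i, replace = TRUE) else character(0)
    i_len <- integer(n_i)
    i_seq <- character(n_i)
    for (j in seq_len(n_i)) {
      if (i_type[j] == "ins") {
        len <- 1L + rpois(1L, config$indel_mean_ins - 1)
        i_seq[j] <- paste(sample(BASES, len, replace = TRUE), collapse = "")
      } else {
        len <- 1L + rpois(1L, config$indel_mean_del - 1)
        len <- min(len, L - i_pos[j])
        i_seq[j] <- substr(reference, i_pos[j] + 1L, i_pos[j] + len)
      }
      i_len[j] <- nchar(i_seq[j])
    }
    keep <- i_len > 0
    structure(list(
      germline = data.frame(pos = g_pos, ref = refv[g_pos], alt = g_alt,
                            genotype = rep("het", length(g_pos)),
                            stringsAsFactors = FALSE),
      somatic = data.frame(pos = s_pos, ref = refv[s_pos], alt = s_alt,
                           vaf = s_vaf, stringsAsFactors = FALSE),
      indels = data.frame(pos = i_pos[keep], type = i_type[keep],
                          length = i_len[keep], seq = i_seq[keep],
                          vaf = rep(0.5, sum(keep)),
                          stringsAsFactors = FALSE),
      cnv_segments = config$cnv_segments
    ), class = "ffc_truth")
  })
}

#' @export
print.ffc_truth <- function(x, ...) {
  cat(sprintf("FF/FFPE truth set: %d germline het SNVs, %d somatic SNVs, %d INDELs, %d CNV segments\n",
              nrow(x$germline), nrow(x$somatic), nrow(x$indels),
              if (is.null(x$cnv_segments)) 0L else nrow(x$cnv_segments)))
  invisible(x)
}
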