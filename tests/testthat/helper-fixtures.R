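# Shared fixture builders: everything is generated in code at test time.

make_pileup <- function(pos, ref, counts, depth = NULL, mapq = 50,
                        n_ins = 0L, n_del = 0L, ins_seq = "", del_seq = "",
                        chrom = "chr1") {
  counts <- matrix(counts, ncol = 4, byrow = TRUE)
  n <- nrow(counts)
  if (is.null(depth)) depth <- rowSums(counts)
  data.frame(chrom = chrom, pos = pos, ref = ref, depth = depth,
             nA = counts[, 1], nC = counts[, 2], nG = counts[, 3],
             nT = counts[, 4], n_ins = rep_len(n_ins, n),
             n_del = rep_len(n_del, n), mapq = rep_len(mapq, n),
             ins_seq = rep_len(ins_seq, n), del_seq = rep_len(del_seq, n),
             stringsAsFactors = FALSE)
}

make_variants <- function(pos, ref, alt, vaf = 0.5, chrom = "chr1",
                          genotype = "het", depth = 50L, mapq = 50) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             genotype = rep_len(genotype, length(pos)),
             vaf = rep_len(vaf, length(pos)),
             depth = rep_len(depth, length(pos)),
             mapq = rep_len(mapq, length(pos)), stringsAsFactors = FALSE)
}

make_base_calls <- function(pos, base, chrom = "chr1") {
  data.frame(chrom = chrom, pos = pos, base = base, stringsAsFactors = FALSE)
}

# exhaustive search over all segmentations of y, minimizing
# SSE + k * penalty * log(n) (k = number of breakpoints); the independent
# oracle for the binary-segmentation routine
brute_force_objective <- function(y, penalty) {
  n <- length(y)
  sse <- function(i, j) {
    v <- y[i:j]
    sum((v - mean(v))^2)
  }
  best <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    breaks <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    bounds <- c(0, breaks, n)
    tot <- sum(vapply(seq_len(length(bounds) - 1),
                      function(s) sse(bounds[s] + 1, bounds[s + 1]),
                      numeric(1)))
    obj <- tot + length(breaks) * penalty * log(n)
    if (obj < best) best <- obj
  }
  best
}

seg_objective <- function(y, segments, penalty) {
  tot <- sum(vapply(seq_len(nrow(segments)), function(s) {
    v <- y[segments$start_bin[s]:segments$end_bin[s]]
    sum((v - mean(v))^2)
  }, numeric(1)))
  tot + (nrow(segments) - 1) * penalty * log(length(y))
}

# a somatic call set with a prescribed overlap structure against a partner
overlap_pair <- function(n_shared, n_same_alt, seed = 1) {
  withr::with_seed(seed, {
    pos <- sort(sample.int(1e6, n_shared + 40))
    shared <- pos[seq_len(n_shared)]
    only_ff <- pos[n_shared + 1:20]
    only_fp <- pos[n_shared + 21:40]
    alt_ff <- sample(c("A", "C", "G", "T"), n_shared + 20, replace = TRUE)
    alt_fp <- alt_ff[seq_len(n_shared)]
    if (n_same_alt < n_shared) {
      flip <- seq.int(n_same_alt + 1L, n_shared)
      alt_fp[flip] <- vapply(alt_ff[flip],
                             function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    }
    list(
      ff = data.frame(chrom = "chr1", pos = c(shared, only_ff),
                      alt = alt_ff, stringsAsFactors = FALSE),
      ffpe = data.frame(chrom = "chr1", pos = c(shared, only_fp),
                        alt = c(alt_fp,
                                sample(c("A", "C", "G", "T"), 20, TRUE)),
                        stringsAsFactors = FALSE))
  })
}
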