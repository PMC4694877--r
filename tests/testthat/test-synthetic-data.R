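test_that("reference generation honours length, composition and determinism", {
  cfg <- sim_config(genome_length = 1000, gc_fraction = 0.5, seed = 1)
  ref <- generate_reference(cfg)
  expect_equal(nchar(ref), 1000L)
  expect_true(all(strsplit(ref, "")[[1]] %in% c("A", "C", "G", "T")))
  expect_identical(ref, generate_reference(cfg))
  expect_false(identical(ref, generate_reference(sim_config(
    genome_length = 1000, gc_fraction = 0.5, seed = 2))))

  only_gc <- generate_reference(sim_config(genome_length = 500,
                                           gc_fraction = 1, seed = 3))
  expect_true(all(strsplit(only_gc, "")[[1]] %in% c("G", "C")))

  expect_error(sim_config(genome_length = 0), "genome_length")
  expect_error(sim_config(gc_fraction = 1.2), "gc_fraction")
})

test_that("observed GC content sits within 3 binomial SD of the target", {
  cfg <- sim_config(genome_length = 200000, gc_fraction = 0.41, seed = 7)
  ref <- generate_reference(cfg)
  gc <- mean(strsplit(ref, "")[[1]] %in% c("G", "C"))
  sd3 <- 3 * sqrt(0.41 * 0.59 / 200000)
  expect_lt(abs(gc - 0.41), sd3)
})

test_that("CpG enrichment raises CG-dinucleotide frequency, GC preserved", {
  cpg_freq <- function(ref) {
    v <- strsplit(ref, "")[[1]]
    mean(v[-length(v)] == "C" & v[-1] == "G")
  }
  base <- generate_reference(sim_config(genome_length = 2e5, seed = 11))
  rich_cfg <- sim_config(genome_length = 2e5, cpg_enrichment = 5, seed = 11)
  rich <- generate_reference(rich_cfg)
  expect_gt(cpg_freq(rich), 3 * cpg_freq(base))
  gc <- mean(strsplit(rich, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.41), 4 * sqrt(0.41 * 0.59 / 2e5))

  poor <- generate_reference(sim_config(genome_length = 2e5,
                                        cpg_enrichment = 0.3, seed = 11))
  expect_lt(cpg_freq(poor), 0.6 * cpg_freq(base))
})

test_that("truth generation: empty at zero rates, deterministic, binomial counts", {
  cfg0 <- sim_config(genome_length = 5000, germline_het_rate = 0,
                     somatic_rate = 0, indel_rate = 0, seed = 5)
  ref0 <- generate_reference(cfg0)
  tr0 <- generate_truth(ref0, cfg0)
  expect_equal(nrow(tr0$germline), 0L)
  expect_equal(nrow(tr0$somatic), 0L)

  cfg <- sim_config(genome_length = 1e6, germline_het_rate = 1e-3, seed = 9)
  ref <- generate_reference(cfg)
  tr <- generate_truth(ref, cfg)
  expect_identical(tr, generate_truth(ref, cfg))
  expect_lt(abs(nrow(tr$germline) - 1000), 3 * sqrt(1000 * (1 - 1e-3)))
  # positions in range, sets disjoint, alt differs from ref
  expect_true(all(tr$germline$pos >= 1 & tr$germline$pos <= 1e6))
  expect_length(intersect(tr$germline$pos, tr$somatic$pos), 0)
  expect_true(all(tr$germline$alt != tr$germline$ref))
  expect_true(all(nchar(tr$indels$seq) > 0))
})

test_that("noise-free pileups reproduce the truth exactly", {
  cfg <- sim_config(genome_length = 20000, seq_error_rate = 0,
                    deamination_rate_cpg = 0, deamination_rate_noncpg = 0,
                    germline_het_rate = 2e-3, mean_coverage_ff = 40,
                    coverage_dispersion = 0, seed = 21)
  ref <- generate_reference(cfg)
  tr <- generate_truth(ref, cfg)
  p <- simulate_pileup(ref, tr, cfg, "FF_normal")
  M <- as.matrix(p[, c("nA", "nC", "nG", "nT")])
  refidx <- match(p$ref, c("A", "C", "G", "T"))
  nonref <- p$depth - M[cbind(seq_len(nrow(p)), refidx)]
  hets <- tr$germline$pos
  expect_true(all(nonref[-hets] == 0))
  # at het sites every non-reference read carries the truth alt
  altidx <- match(tr$germline$alt, c("A", "C", "G", "T"))
  expect_equal(unname(nonref[hets]), unname(M[cbind(hets, altidx)]))
})

test_that("deamination is FFPE-specific and absent from FF samples", {
  cfg <- sim_config(genome_length = 20000, seq_error_rate = 0,
                    deamination_rate_cpg = 0.5, deamination_rate_noncpg = 0.5,
                    germline_het_rate = 0, indel_rate = 0,
                    coverage_dispersion = 0, seed = 31)
  ref <- generate_reference(cfg)
  tr <- generate_truth(ref, cfg)
  ff <- simulate_pileup(ref, tr, cfg, "FF_normal")
  fp <- simulate_pileup(ref, tr, cfg, "FFPE_normal")
  expect_equal(sum(ff$nT[ff$ref == "C"]), 0)
  expect_equal(sum(ff$nA[ff$ref == "G"]), 0)
  expect_gt(sum(fp$nT[fp$ref == "C"]), 0)
})

test_that("injected CpG deamination rate is recovered within 3 binomial SD", {
  cfg <- sim_config(genome_length = 1e5, cpg_enrichment = 5,
                    seq_error_rate = 0, deamination_rate_cpg = 0.01,
                    deamination_rate_noncpg = 0.001, germline_het_rate = 0,
                    indel_rate = 0, mean_coverage_ffpe = 30,
                    coverage_dispersion = 0, seed = 41)
  ref <- generate_reference(cfg)
  tr <- generate_truth(ref, cfg)
  fp <- simulate_pileup(ref, tr, cfg, "FFPE_normal")
  v <- strsplit(ref, "")[[1]]
  cpgC <- which(v == "C" & c(v[-1], "") == "G")
  nobs <- sum(fp$depth[cpgC])
  expect_gt(nobs, 1e5)
  rate <- sum(fp$nT[cpgC]) / nobs
  expect_lt(abs(rate - 0.01), 3 * sqrt(0.01 * 0.99 / nobs))
})

test_that("FFPE/FF artifact asymmetry is detectable exactly when rates > 0", {
  run <- function(dc) {
    cfg <- sim_config(genome_length = 5e4, cpg_enrichment = 5,
                      seq_error_rate = 1e-3, deamination_rate_cpg = dc,
                      deamination_rate_noncpg = dc / 10,
                      germline_het_rate = 0, indel_rate = 0,
                      coverage_dispersion = 0, seed = 51)
    ref <- generate_reference(cfg)
    tr <- generate_truth(ref, cfg)
    v <- strsplit(ref, "")[[1]]
    cpgC <- which(v == "C" & c(v[-1], "") == "G")
    ff <- simulate_pileup(ref, tr, cfg, "FF_normal")
    fp <- simulate_pileup(ref, tr, cfg, "FFPE_normal")
    x <- c(sum(fp$nT[cpgC]), sum(ff$nT[cpgC]))
    n <- c(sum(fp$depth[cpgC]), sum(ff$depth[cpgC]))
    stats::prop.test(x, n, alternative = "greater")$p.value
  }
  expect_lt(run(0.02), 0.01)
  expect_gt(run(0), 0.01)
})

test_that("tumor pileup depth scales with copy state and low-pass counts conserve reads", {
  segs <- data.frame(start = 30001, end = 60000, copy_state = 4)
  cfg <- sim_config(genome_length = 90000, cnv_segments = segs,
                    bin_size = 5000, coverage_dispersion = 0,
                    mean_coverage_ff = 30, lowpass_mean_coverage = 0.3,
                    seed = 61)
  ref <- generate_reference(cfg)
  tr <- generate_truth(ref, cfg)
  p <- simulate_pileup(ref, tr, cfg, "FF_tumor")
  ratio <- mean(p$depth[30001:60000]) / mean(p$depth[1:30000])
  expect_lt(abs(ratio - 2), 0.1)

  lp <- simulate_lowpass_counts(ref, tr, cfg, "FF_tumor")
  expect_equal(sum(lp$bins$count), length(lp$read_starts))
  amp <- lp$bins$start >= 30001 & lp$bins$end <= 60000
  expect_gt(mean(lp$bins$count[amp]) / mean(lp$bins$count[!amp]), 1.5)
  # binning the emitted read starts reproduces the counts exactly
  rebinned <- bin_counts(lp$read_starts, cfg$bin_size, ref)
  expect_equal(rebinned$bins$count, lp$bins$count)
  # determinism
  lp2 <- simulate_lowpass_counts(ref, tr, cfg, "FF_tumor")
  expect_identical(lp$bins, lp2$bins)
  expect_error(simulate_lowpass_counts(substr(ref, 1, 100), tr, cfg,
                                       "FF_tumor"), "shorter than one bin")
})

test_that("array genotypes follow the configured corruption rate", {
  cfg <- sim_config(genome_length = 1e5, germline_het_rate = 0.1, seed = 71)
  ref <- generate_reference(cfg)
  tr <- generate_truth(ref, cfg)
  clean <- simulate_array_genotypes(tr, 0, seed = 1)
  expect_true(all(clean$genotype == "het"))
  expect_equal(clean$pos, tr$germline$pos)

  all_bad <- simulate_array_genotypes(tr, 1, seed = 1)
  expect_true(all(all_bad$genotype != "het"))

  some <- simulate_array_genotypes(tr, 0.02, seed = 2)
  n <- nrow(some)
  expect_gt(n, 9000)
  mism <- sum(some$genotype != "het")
  expect_lt(abs(mism - 0.02 * n), 3 * sqrt(0.02 * 0.98 * n))
  expect_identical(some, simulate_array_genotypes(tr, 0.02, seed = 2))
})
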