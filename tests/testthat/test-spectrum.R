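test_that("substitutions collapse onto the pyrimidine strand", {
  expect_equal(substitution_class(c("C", "G", "A"), c("T", "A", "G")),
               c("C>T", "C>T", "T>C"))
  expect_equal(substitution_class("G", "C"), "C>G")
  expect_error(substitution_class("C", "C"), "invalid substitution")
})

test_that("spectrum counts, C.G>T.A rate and Ts/Tv follow the definitions", {
  ref <- "CCGAT"
  v <- data.frame(pos = c(1L, 3L, 4L), ref = c("C", "G", "A"),
                  alt = c("T", "A", "C"), stringsAsFactors = FALSE)
  sp <- substitution_spectrum(v, ref)
  expect_equal(unname(sp$counts["C>T"]), 2L)
  expect_equal(unname(sp$counts["T>G"]), 1L)  # A>C complements to T>G
  expect_equal(sum(sp$counts), 3L)            # conservation
  expect_equal(sp$ct_rate_all, 2 / 3)
  expect_equal(sp$tstv, 2)                    # 2 transitions / 1 transversion

  empty <- substitution_spectrum(v[0, ], ref)
  expect_equal(sum(empty$counts), 0L)
  expect_true(is.na(empty$ct_rate_all))
  expect_true(is.na(empty$tstv))

  bad <- v; bad$ref[1] <- "A"
  expect_error(substitution_spectrum(bad, ref), "position 1")
})

test_that("complementing the reference and all alleles changes nothing", {
  cfg <- sim_config(genome_length = 2e4, germline_het_rate = 5e-3, seed = 3)
  ref <- generate_reference(cfg)
  tr <- generate_truth(ref, cfg)
  v <- data.frame(pos = tr$germline$pos, ref = tr$germline$ref,
                  alt = tr$germline$alt, stringsAsFactors = FALSE)
  sp1 <- substitution_spectrum(v, ref)
  v2 <- v
  v2$ref <- complement_bases(v$ref)
  v2$alt <- complement_bases(v$alt)
  sp2 <- substitution_spectrum(v2, complement_bases(ref))
  expect_equal(sp1$counts, sp2$counts)
  expect_equal(sp1$tstv, sp2$tstv)

  # context classification is invariant under reverse-complementing the
  # genome (true strand symmetry; neighbors swap ends as well)
  L <- nchar(ref)
  rc <- paste(rev(strsplit(complement_bases(ref), "")[[1]]), collapse = "")
  v3 <- data.frame(pos = L + 1L - v$pos, ref = complement_bases(v$ref),
                   alt = complement_bases(v$alt), stringsAsFactors = FALSE)
  cx1 <- context_ct_rates(v, ref, "call_level")
  cx3 <- context_ct_rates(v3, rc, "call_level")
  expect_equal(cx1$cpn_counts$denominator, cx3$cpn_counts$denominator)
  expect_equal(cx1$cpn_rates, cx3$cpn_rates)
  expect_equal(cx1$npc_rates, cx3$npc_rates)
})

test_that("disagreement-side C.G>T.A rates handle empties and toy cases", {
  ff <- make_variants(pos = c(1L, 2L, 3L, 4L), ref = "C",
                      alt = c("G", "G", "G", "G"))
  fp <- make_variants(pos = c(1L, 2L, 3L, 4L), ref = "C",
                      alt = c("T", "T", "T", "A"))
  tab <- classify_variants(ff, fp)
  expect_equal(tab$n_discordant, 4L)
  r <- discordant_ct_rate(tab, strrep("C", 10))
  expect_equal(r$ffpe_rate, 0.75)
  expect_equal(r$ff_rate, 0)

  none <- classify_variants(ff, ff)
  r0 <- discordant_ct_rate(none, strrep("C", 10))
  expect_true(is.na(r0$ffpe_rate))
  expect_equal(r0$n_ffpe, 0L)
})

test_that("global mismatch rate matches the hand-computed definition", {
  p <- make_pileup(pos = 1:2, ref = "A",
                   counts = c(99, 0, 1, 0,
                              50, 0, 0, 0))
  expect_equal(global_mismatch_rate(p, strrep("A", 5)), 1 / 150)
  # variant positions are excluded from the denominator
  expect_equal(global_mismatch_rate(p, strrep("A", 5),
                                    variant_positions = 1L), 0)
  # error-free data has rate zero; all-filtered data is missing
  expect_true(is.na(global_mismatch_rate(p[0, ], strrep("A", 5))))
})

test_that("simulated sequencing error is recovered by the mismatch rate", {
  cfg <- sim_config(genome_length = 3e4, seq_error_rate = 1e-3,
                    deamination_rate_cpg = 0, deamination_rate_noncpg = 0,
                    germline_het_rate = 0, indel_rate = 0,
                    mean_coverage_ff = 40, mean_coverage_ffpe = 40,
                    coverage_dispersion = 0, mapq_sd = 0, seed = 19)
  ref <- generate_reference(cfg)
  tr <- generate_truth(ref, cfg)
  for (kind in c("FF_normal", "FFPE_normal")) {
    p <- simulate_pileup(ref, tr, cfg, kind)
    n <- sum(p$depth)
    r <- global_mismatch_rate(p, ref)
    expect_lt(abs(r - 1e-3), 3 * sqrt(1e-3 * (1 - 1e-3) / n))
  }
})

test_that("CpN and NpC context classification follows the neighbors", {
  # reference ACGT: the C at position 2 is CpG (3' G) and ApC (5' A);
  # the G at position 3 is CpG on the complementary strand as well.
  cx <- context_ct_rates(data.frame(pos = integer(0), ref = character(0),
                                    alt = character(0)), "ACGT", "call_level")
  expect_equal(cx$cpn_counts$denominator[cx$cpn_counts$context == "CpG"], 2)
  # a C>T call at a CpG site registers in the CpG stratum
  v <- data.frame(pos = 2L, ref = "C", alt = "T", stringsAsFactors = FALSE)
  cx2 <- context_ct_rates(v, "ACGT", "call_level")
  expect_equal(unname(cx2$cpn_rates["CpG"]), 0.5)
  # the G at position 3 is also ApC on the complementary strand (5'
  # neighbor = complement of the T at position 4), so the stratum holds
  # both interior sites
  expect_equal(unname(cx2$npc_rates["ApC"]), 0.5)
  expect_error(context_ct_rates(v, "AC", "call_level"), "shorter than 3")
})

test_that("read-level context rates recover the injected deamination ordering", {
  cfg <- sim_config(genome_length = 1e5, cpg_enrichment = 5,
                    seq_error_rate = 0, deamination_rate_cpg = 0.01,
                    deamination_rate_noncpg = 0.001, germline_het_rate = 0,
                    indel_rate = 0, mean_coverage_ffpe = 30,
                    coverage_dispersion = 0, mapq_sd = 0, seed = 29)
  ref <- generate_reference(cfg)
  tr <- generate_truth(ref, cfg)
  fp <- simulate_pileup(ref, tr, cfg, "FFPE_normal")
  cx <- context_ct_rates(fp, ref, "read_level")
  expect_gt(cx$cpn_rates["CpG"], max(cx$cpn_rates[c("CpA", "CpC", "CpT")]))
  expect_lt(abs(cx$cpn_rates["CpG"] - 0.01), 0.1 * 0.01 + 3e-4)
})

test_that("paired t test matches the closed form and its degenerate rules", {
  r <- paired_t_test(c(1, 2, 3), c(2, 3, 5))
  # closed form: d = (1,1,2), t = mean(d)/(sd(d)/sqrt(3))
  d <- c(1, 1, 2)
  expect_equal(r$t, mean(d) / (sd(d) / sqrt(3)))
  expect_equal(r$t, 4)
  expect_equal(r$df, 2)
  expect_equal(r$p, 2 * pt(-4, 2))

  # antisymmetry
  r2 <- paired_t_test(c(2, 3, 5), c(1, 2, 3))
  expect_equal(r2$t, -r$t)
  expect_equal(r2$p, r$p)

  expect_equal(paired_t_test(c(1, 2, 3), c(1, 2, 3)),
               list(t = 0, df = 2L, p = 1))
  expect_error(paired_t_test(c(1, 2), c(2, 3)), "zero variance")
})

test_that("ANOVA F agrees with stats::anova and Dunnett handles degenerate input", {
  g <- list(a = c(1, 2, 3, 2), b = c(2, 3, 4, 3), c = c(5, 6, 5, 7))
  res <- anova_dunnett(g, control_index = 1, seed = 1, ndraws = 2e4)
  y <- unlist(g)
  f <- factor(rep(names(g), lengths(g)))
  ref_F <- anova(lm(y ~ f))[["F value"]][1]
  expect_equal(res$F, ref_F)
  expect_equal(nrow(res$comparisons), 2L)

  const <- anova_dunnett(list(x = c(1, 1, 1), y = c(1, 1, 1)), seed = 1,
                         ndraws = 1e3)
  expect_equal(const$F, 0)
  expect_true(all(const$comparisons$p_adj == 1))
})

test_that("Dunnett with a single comparison reduces to the pooled t test", {
  withr::with_seed(5, {
    a <- rnorm(20); b <- rnorm(20, 0.8)
  })
  res <- anova_dunnett(list(ctrl = a, trt = b), seed = 11, ndraws = 2e5)
  tt <- t.test(b, a, var.equal = TRUE)
  expect_equal(res$comparisons$p_adj, tt$p.value, tolerance = 0.02)
  expect_equal(res$comparisons$t, unname(tt$statistic), tolerance = 1e-8)
})

test_that("Dunnett flags only the truly shifted group", {
  hits <- 0L; false_hits <- 0L
  for (s in 1:10) {
    withr::with_seed(100 + s, {
      g <- list(ctrl = rnorm(50), g1 = rnorm(50), g2 = rnorm(50, 3),
                g3 = rnorm(50))
    })
    res <- anova_dunnett(g, control_index = 1, seed = s, ndraws = 2e4)
    p <- setNames(res$comparisons$p_adj, res$comparisons$group)
    hits <- hits + (p["g2"] < 0.05)
    false_hits <- false_hits + sum(p[c("g1", "g3")] < 0.05)
  }
  expect_gte(hits, 9L)
  expect_lte(false_hits, 2L)
})

test_that("Monte-Carlo Dunnett agrees with the multivariate-t reference", {
  skip_if_not_installed("multcomp")
  withr::with_seed(7, {
    g <- list(ctrl = rnorm(30), a = rnorm(30, 0.5), b = rnorm(30, 1),
              c = rnorm(30))
  })
  res <- anova_dunnett(g, control_index = 1, seed = 3, ndraws = 2e5)
  y <- unlist(g)
  f <- factor(rep(names(g), lengths(g)), levels = names(g))
  fit <- stats::aov(y ~ f)
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(f = "Dunnett"))
  ref <- summary(gl, test = multcomp::adjusted("single-step"))
  expect_equal(res$comparisons$p_adj,
               as.numeric(ref$test$pvalues), tolerance = 0.02)
})
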