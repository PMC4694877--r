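test_that("binning conserves counts and handles the terminal bin", {
  ref <- strrep("ACGT", 31000 / 4)
  b <- bin_counts(c(1L, 2L, 15000L, 15001L, 30000L, 30999L), 15000, ref)
  expect_equal(nrow(b$bins), 3L)
  expect_equal(b$bins$end[3] - b$bins$start[3] + 1L, 1000L)
  expect_equal(sum(b$bins$count), 6L)
  expect_equal(b$bins$count, c(3L, 2L, 1L))
  # GC of a repeated ACGT slice is one half
  expect_equal(b$bins$gc, rep(0.5, 3), tolerance = 1e-6)

  empty <- bin_counts(integer(0), 15000, ref)
  expect_true(all(empty$bins$count == 0))
  expect_error(bin_counts(1:5, 0, ref), "positive")
  expect_error(bin_counts(c(1L, 40000L), 15000, ref), "outside")
})

test_that("GC correction is the identity on homogeneous GC and removes linear bias", {
  bins <- data.frame(chrom = "chr1", start = seq(1, 2000 * 100, 100),
                     end = seq(100, 2000 * 100, 100), gc = 0.5,
                     count = rep(c(100L, 110L), 1000))
  x <- structure(list(bins = bins, bin_size = 100L, read_starts = NULL),
                 class = "ffc_binned")
  same <- gc_correct(x)
  expect_equal(same$bins$count, as.numeric(bins$count))

  withr::with_seed(9, {
    gc <- runif(2000, 0.3, 0.7)
    mu <- 100 * (1 + 0.5 * (gc - 0.5))
    biased <- x
    biased$bins$gc <- gc
    biased$bins$count <- rpois(2000, mu)
  })
  pre <- summary(lm(count ~ gc, data = biased$bins))$coefficients["gc", 4]
  expect_lt(pre, 1e-10)   # bias is very detectable before correction
  corr <- gc_correct(biased)
  post <- summary(lm(corr$bins$count ~ biased$bins$gc))$coefficients[2, 4]
  expect_gt(post, 0.05)
  # overall median preserved
  expect_equal(median(corr$bins$count), median(biased$bins$count),
               tolerance = 0.05)

  zero <- x
  zero$bins$count <- 0L
  expect_error(gc_correct(zero), "zero")
  expect_error(gc_correct(structure(list(bins = bins[1:10, ]),
                                    class = "ffc_binned")), "20 bins")
})

test_that("log2 ratios follow the median convention", {
  counts <- c(50, 100, 200, 100, 100)
  x <- structure(list(bins = data.frame(count = counts)),
                 class = "ffc_binned")
  lr <- log2_ratio(x)
  expect_equal(lr, c(-1, 0, 1, 0, 0))
  expect_true(is.na(log2_ratio(c(0, 10, 10))[1]))
  expect_equal(log2_ratio(c(0, 10, 10), zero_value = -5)[1], -5)
})

test_that("binary segmentation recovers noiseless structure exactly", {
  one <- segment_log2(rep(0.3, 50), penalty = 1)
  expect_equal(nrow(one), 1L)
  expect_equal(one$mean_log2, 0.3)

  step <- segment_log2(c(rep(0, 100), rep(1, 100)), penalty = 1)
  expect_equal(nrow(step), 2L)
  expect_equal(step$end_bin[1], 100L)
  expect_equal(step$start_bin[2], 101L)
  expect_equal(step$mean_log2, c(0, 1))

  # segments partition the bin range even with missing bins
  y <- c(rep(0, 50), NA, rep(1, 49))
  segs <- segment_log2(y, penalty = 1)
  expect_equal(segs$start_bin[1], 1L)
  expect_equal(segs$end_bin[nrow(segs)], 100L)
  expect_equal(sum(segs$n_bins), 100L)

  expect_error(segment_log2(rep(0, 10), penalty = 0), "positive")
})

test_that("segmentation matches the exhaustive-search optimum on short signals", {
  suite <- list(
    rep(0, 8),
    c(rep(0, 4), rep(1, 4)),
    c(rep(0, 4), rep(0.6, 4), rep(-0.4, 4)),
    c(0.1, -0.1, 0.2, 0, 1.1, 0.9, 1, 1.2),
    seq(0, 1, length.out = 10)
  )
  withr::with_seed(31, {
    for (i in 1:6) suite[[length(suite) + 1]] <- rnorm(10, 0, 0.4)
    for (i in 1:4)
      suite[[length(suite) + 1]] <-
        c(rnorm(6, 0, 0.2), rnorm(6, 0.8, 0.2))
  })
  penalty <- 1
  for (y in suite) {
    segs <- segment_log2(y, penalty)
    got <- seg_objective(y, segs, penalty)
    opt <- brute_force_objective(y, penalty)
    expect_lte(got, opt + penalty * log(length(y)) + 1e-9)
  }
})

test_that("noisy breakpoints land within 3 bins of the truth", {
  hits <- 0L
  for (s in 1:30) {
    withr::with_seed(500 + s, {
      y <- c(rnorm(200, 0, 0.2), rnorm(200, 0.58, 0.2))
    })
    segs <- segment_log2(y, penalty = 1)
    hits <- hits + any(abs(segs$end_bin - 200) <= 3)
  }
  expect_gte(hits, 27L)
})

test_that("state calls use inclusive thresholds", {
  segs <- data.frame(start_bin = c(1L, 11L, 21L, 31L),
                     end_bin = c(10L, 20L, 30L, 40L),
                     n_bins = 10L,
                     mean_log2 = c(0, -1, 0.15, -0.15))
  called <- call_states(segs)
  expect_equal(called$call, c("neutral", "loss", "gain", "loss"))
  expect_error(call_states(segs, loss = 0.1, gain = 0.2), "loss < 0")
})

test_that("region harmonization takes the union of breakpoints", {
  mkprof <- function(log2, ends) {
    starts <- c(1L, head(ends, -1) + 1L)
    structure(list(log2 = log2,
                   segments = data.frame(
                     start_bin = starts, end_bin = as.integer(ends),
                     n_bins = as.integer(ends) - starts + 1L,
                     mean_log2 = vapply(seq_along(ends), function(s)
                       mean(log2[starts[s]:ends[s]]), numeric(1)),
                     call = "neutral"),
                   bins = NULL), class = "ffc_cnv_profile")
  }
  a <- mkprof(c(rep(0, 50), rep(1, 50)), c(50, 100))
  b <- mkprof(c(rep(0, 80), rep(-1, 20)), c(80, 100))
  h <- harmonize_regions(list(A = a, B = b))
  expect_equal(h$regions$start_bin, c(1L, 51L, 81L))
  expect_equal(h$regions$end_bin, c(50L, 80L, 100L))
  expect_equal(dim(h$matrix), c(3L, 2L))
  expect_equal(h$matrix[, "A"], c(0, 1, 1))

  solo <- harmonize_regions(list(A = a))
  expect_equal(solo$regions$end_bin, a$segments$end_bin)
  twin <- harmonize_regions(list(A = a, B = a))
  expect_equal(twin$regions$end_bin, a$segments$end_bin)

  short <- mkprof(rep(0, 60), 60)
  expect_error(harmonize_regions(list(a, short)), "bin grids")
})

test_that("clustering pairs identical profiles first; correlations behave", {
  m <- cbind(s1 = c(0, 1, 0, -1, 0.5), s2 = c(0, 1, 0, -1, 0.5),
             s3 = c(1, -1, 0.3, 0, 0))
  cl <- cluster_and_correlate(m)
  expect_equal(sort(cl$hclust$merge[1, ]), c(-2, -1))  # s1+s2 merge first
  expect_equal(diag(cl$correlation), c(s1 = 1, s2 = 1, s3 = 1))
  expect_equal(cl$correlation["s1", "s2"], 1)

  flat <- cbind(m, s4 = rep(2, 5))
  cl2 <- cluster_and_correlate(flat)
  expect_true(is.na(cl2$correlation["s4", "s1"]))
  expect_equal(cl2$correlation["s4", "s4"], 1)
  expect_error(cluster_and_correlate(m[, 1, drop = FALSE]), "at least 2")
})

test_that("the profile pipeline is invariant to count rescaling", {
  cfg <- sim_config(genome_length = 3e5, bin_size = 1000,
                    lowpass_mean_coverage = 0.3, gc_bias_strength = 0.4,
                    cnv_segments = data.frame(start = 100001, end = 200000,
                                              copy_state = 3),
                    coverage_dispersion = 0, seed = 12)
  ref <- generate_reference(cfg)
  tr <- generate_truth(ref, cfg)
  lp <- simulate_lowpass_counts(ref, tr, cfg, "FF_tumor")
  # counts ~300/bin give log2 noise SD ~0.08, so use a matching penalty
  prof1 <- cnv_profile(lp, penalty = 0.2)
  scaled <- lp
  scaled$bins$count <- lp$bins$count * 4
  prof2 <- cnv_profile(scaled, penalty = 0.2)
  expect_equal(prof1$log2, prof2$log2, tolerance = 1e-12)
  expect_equal(prof1$segments, prof2$segments, tolerance = 1e-12)
  # the amplified region is found as a gain near log2(3/2)
  gains <- prof1$segments[prof1$segments$call == "gain", ]
  expect_gte(nrow(gains), 1)
  expect_lt(abs(gains$mean_log2[which.max(gains$n_bins)] - log2(1.5)), 0.15)
})
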