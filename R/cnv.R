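#' Bin read start positions into fixed windows with GC annotation
#'
#' Counts read starts per fixed-width window (terminal window truncated to
#' the genome end) and annotates each window with the GC fraction of the
#' corresponding reference slice.  The total count is conserved.
#'
#' @param read_starts integer vector of 1-based read start positions.
#' @param bin_size window width in bases.
#' @param reference reference string.
#' @param chrom chromosome label.
#' @return an `ffc_binned` object.
#' @export
bin_counts <- function(read_starts, bin_size, reference, chrom = "chr1") {
  if (bin_size <= 0) stop_config("'bin_size' must be positive")
  L <- nchar(reference)
  if (length(read_starts) && (min(read_starts) < 1 || max(read_starts) > L))
    stop_config("read positions outside the reference")
  starts <- seq.int(1L, L, by = as.integer(bin_size))
  ends <- pmin(starts + as.integer(bin_size) - 1L, L)
  idx <- findInterval(read_starts, starts)
  counts <- tabulate(idx, nbins = length(starts))
  structure(list(
    bins = data.frame(chrom = chrom, start = starts, end = ends,
                      gc = bin_gc(reference, starts, ends),
                      count = as.integer(counts), stringsAsFactors = FALSE),
    bin_size = as.integer(bin_size),
    read_starts = sort(read_starts)
  ), class = "ffc_binned")
}

#' GC-bias correction by GC-stratum medians
#'
#' Bins are stratified into GC deciles; each count is divided by its
#' stratum's median count and rescaled so the overall median is unchanged.
#' Strata whose median is zero are flagged and left uncorrected.  Identical
#' GC across all bins makes the correction the identity map.
#'
#' @param binned an `ffc_binned` object with >= 20 bins.
#' @return an `ffc_binned` with corrected (numeric) counts; attribute
#'   `flagged_strata` lists uncorrected deciles.
#' @export
gc_correct <- function(binned) {
  stopifnot(inherits(binned, "ffc_binned"))
  b <- binned$bins
  if (nrow(b) < 20) stop_config("GC correction needs at least 20 bins")
  if (all(b$count == 0)) stop_config("all bin counts are zero")
  br <- unique(quantile(b$gc, probs = seq(0, 1, 0.1), names = FALSE))
  stratum <- if (length(br) > 2) cut(b$gc, br, include.lowest = TRUE)
             else factor(rep(1L, nrow(b)))
  med <- tapply(b$count, stratum, median)
  overall <- median(b$count)
  fac <- med[as.integer(stratum)]
  flagged <- names(med)[med == 0]
  corrected <- ifelse(fac > 0, b$count / fac * overall, b$count)
  out <- binned
  out$bins$count <- as.numeric(corrected)
  attr(out, "flagged_strata") <- flagged
  out
}

#' Per-bin log2 ratios relative to the sample median
#'
#' `log2(count / median(count))`; bins with zero (or missing) counts are
#' masked to `NA` by default, or set to a fixed floor.
#'
#' @param binned an `ffc_binned` (typically GC-corrected).
#' @param zero_value value assigned to zero-count bins (default `NA`).
#' @return numeric vector of per-bin log2 ratios.
#' @export
log2_ratio <- function(binned, zero_value = NA_real_) {
  counts <- if (inherits(binned, "ffc_binned")) binned$bins$count else binned
  med <- median(counts)
  if (!is.finite(med) || med <= 0)
    stop_config("sample median count must be positive")
  out <- ifelse(counts > 0, log2(counts / med), zero_value)
  as.numeric(out)
}

sse_interval <- function(cs, cs2, i, j) {
  s <- cs[j + 1L] - cs[i]
  s2 <- cs2[j + 1L] - cs2[i]
  s2 - s * s / (j - i + 1L)
}

#' Penalized binary segmentation of a log2-ratio profile
#'
#' Greedy recursive binary segmentation minimizing within-segment sum of
#' squared deviations: a split is accepted while the best reduction in SSE
#' exceeds `penalty * log(n)`, after which breakpoints that no longer pay
#' their penalty are pruned (backward elimination), keeping the result close
#' to the exhaustive-search optimum of `SSE + k * penalty * log(n)`.
#' Missing bins are excluded from the fit; each is attached to the segment
#' on its left.  Deterministic.
#'
#' @param log2_values numeric vector (may contain `NA`).
#' @param penalty positive penalty scale; roughly the per-breakpoint SSE
#'   cost in units of the noise variance (default 1, suited to log2 noise
#'   SD around 0.2-0.5).
#' @return data.frame `start_bin, end_bin, n_bins, mean_log2` partitioning
#'   the full bin range.
#' @export
segment_log2 <- function(log2_values, penalty = 1) {
  if (penalty <= 0) stop_config("'penalty' must be positive")
  obs <- which(!is.na(log2_values))
  if (length(obs) < 2) stop_config("need at least 2 non-missing bins")
  y <- log2_values[obs]
  n <- length(y)
  thr <- penalty * log(n)
  cs <- c(0, cumsum(y))
  cs2 <- c(0, cumsum(y * y))

  best_split <- function(i, j) {
    if (j <= i) return(NULL)
    k <- i:(j - 1L)
    nl <- k - i + 1L
    nr <- j - k
    sl <- cs[k + 1L] - cs[i]
    sr <- cs[j + 1L] - cs[k + 1L]
    s2l <- cs2[k + 1L] - cs2[i]
    s2r <- cs2[j + 1L] - cs2[k + 1L]
    sse <- (s2l - sl^2 / nl) + (s2r - sr^2 / nr)
    kbest <- which.min(sse)
    list(k = k[kbest], gain = sse_interval(cs, cs2, i, j) - sse[kbest])
  }

  # grow
  breaks <- integer(0)
  queue <- list(c(1L, n))
  while (length(queue)) {
    iv <- queue[[1L]]; queue <- queue[-1L]
    sp <- best_split(iv[1L], iv[2L])
    if (!is.null(sp) && sp$gain > thr) {
      breaks <- c(breaks, sp$k)
      queue <- c(queue, list(c(iv[1L], sp$k)), list(c(sp$k + 1L, iv[2L])))
    }
  }
  breaks <- sort(breaks)

  # prune: iteratively remove the breakpoint whose removal costs least,
  # while that cost stays within the penalty
  repeat {
    if (!length(breaks)) break
    bounds <- c(0L, breaks, n)
    cost <- vapply(seq_along(breaks), function(b) {
      i <- bounds[b] + 1L; k <- breaks[b]; j <- bounds[b + 2L]
      sse_interval(cs, cs2, i, j) -
        (sse_interval(cs, cs2, i, k) + sse_interval(cs, cs2, k + 1L, j))
    }, numeric(1))
    worst <- which.min(cost)
    if (cost[worst] <= thr) breaks <- breaks[-worst] else break
  }

  bounds <- c(0L, breaks, n)
  nseg <- length(bounds) - 1L
  total_bins <- length(log2_values)
  seg_start <- integer(nseg); seg_end <- integer(nseg)
  means <- numeric(nseg)
  for (s in seq_len(nseg)) {
    i <- bounds[s] + 1L; j <- bounds[s + 1L]
    seg_start[s] <- if (s == 1L) 1L else obs[i]
    seg_end[s] <- if (s == nseg) total_bins else obs[j]
    means[s] <- (cs[j + 1L] - cs[i]) / (j - i + 1L)
  }
  # make ends abut the next start
  if (nseg > 1L) seg_end[-nseg] <- seg_start[-1L] - 1L
  data.frame(start_bin = seg_start, end_bin = seg_end,
             n_bins = seg_end - seg_start + 1L, mean_log2 = means)
}

#' Call copy-number states for segments
#'
#' `mean_log2 <= loss` is a loss, `mean_log2 >= gain` a gain (both
#' boundaries inclusive), anything between is neutral.  The default
#' thresholds of +/-0.15 are package defaults, configurable per analysis.
#'
#' @param segments data.frame from [segment_log2()].
#' @param loss,gain thresholds with `loss < 0 < gain`.
#' @return `segments` with an added `call` column (`loss`/`neutral`/`gain`).
#' @export
call_states <- function(segments, loss = -0.15, gain = 0.15) {
  if (!(loss < 0 && gain > 0)) stop_config("need loss < 0 < gain")
  segments$call <- ifelse(segments$mean_log2 <= loss, "loss",
                          ifelse(segments$mean_log2 >= gain, "gain",
                                 "neutral"))
  segments
}

#' Build a complete copy-number profile from binned counts
#'
#' GC correction, log2 ratios, penalized binary segmentation and state
#' calls in one step.
#'
#' @param binned an `ffc_binned`.
#' @param penalty segmentation penalty (see [segment_log2()]).
#' @param loss,gain state-call thresholds.
#' @return object of class `ffc_cnv_profile`: list with `log2`, `segments`
#'   (including calls), `bins`.
#' @export
cnv_profile <- function(binned, penalty = 1, loss = -0.15, gain = 0.15) {
  corrected <- gc_correct(binned)
  lr <- log2_ratio(corrected)
  segs <- call_states(segment_log2(lr, penalty), loss, gain)
  structure(list(log2 = lr, segments = segs, bins = corrected$bins),
            class = "ffc_cnv_profile")
}

#' Build a copy-number profile directly from log2 ratios
#'
#' For data already on the log2 scale (or externally normalized): runs
#' segmentation and state calling without binning/GC steps.
#'
#' @param log2_values numeric vector of per-bin log2 ratios.
#' @inheritParams cnv_profile
#' @return an `ffc_cnv_profile`.
#' @export
profile_from_log2 <- function(log2_values, penalty = 1, loss = -0.15,
                              gain = 0.15) {
  segs <- call_states(segment_log2(log2_values, penalty), loss, gain)
  structure(list(log2 = log2_values, segments = segs, bins = NULL),
            class = "ffc_cnv_profile")
}

#' @export
print.ffc_cnv_profile <- function(x, ...) {
  cat(sprintf("CNV profile: %d bins, %d segments (%d loss, %d gain)\n",
              length(x$log2), nrow(x$segments),
              sum(x$segments$call == "loss"),
              sum(x$segments$call == "gain")))
  invisible(x)
}

#' Harmonize segment boundaries across samples
#'
#' Imposes the union of all samples' segment breakpoints, yielding a common
#' set of regions, and returns the region-by-sample matrix of mean log2
#' ratios recomputed over each region's bins.  All profiles must share one
#' bin grid.
#'
#' @param profiles named list of `ffc_cnv_profile` objects.
#' @return list with `regions` (data.frame `start_bin, end_bin`) and
#'   `matrix` (regions x samples, mean log2).
#' @export
harmonize_regions <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  nb <- vapply(profiles, function(p) length(p$log2), integer(1))
  if (length(unique(nb)) != 1)
    stop_config("profiles are on different bin grids")
  n <- nb[1]
  ends <- sort(unique(unlist(lapply(profiles, function(p)
    p$segments$end_bin))))
  ends <- unique(c(ends[ends < n], n))
  starts <- c(1L, head(ends, -1L) + 1L)
  if (is.null(names(profiles)))
    names(profiles) <- paste0("sample", seq_along(profiles))
  mat <- vapply(profiles, function(p) {
    vapply(seq_along(starts), function(r) {
      mean(p$log2[starts[r]:ends[r]], na.rm = TRUE)
    }, numeric(1))
  }, numeric(length(starts)))
  mat <- matrix(mat, nrow = length(starts),
                dimnames = list(NULL, names(profiles)))
  list(regions = data.frame(start_bin = starts, end_bin = as.integer(ends)),
       matrix = mat)
}

#' Hierarchical clustering and Pearson correlation of harmonized profiles
#'
#' Agglomerative clustering (Euclidean distance, average linkage) of the
#' samples' region-level log2 vectors, plus the Pearson correlation matrix
#' over regions for every sample pair (unit diagonal; a zero-variance
#' sample's correlations are reported missing).
#'
#' @param region_matrix regions x samples matrix from [harmonize_regions()].
#' @return list with `hclust` (an [stats::hclust] object) and `correlation`.
#' @export
cluster_and_correlate <- function(region_matrix) {
  if (ncol(region_matrix) < 2 || nrow(region_matrix) < 2)
    stop_config("need at least 2 samples and 2 regions")
  sds <- apply(region_matrix, 2, sd, na.rm = TRUE)
  cc <- suppressWarnings(cor(region_matrix,
                             use = "pairwise.complete.obs"))
  cc[sds == 0, ] <- NA_real_
  cc[, sds == 0] <- NA_real_
  diag(cc) <- 1
  hc <- hclust(dist(t(region_matrix)), method = "average")
  list(hclust = hc, correlation = cc)
}
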