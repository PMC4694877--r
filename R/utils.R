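#' @keywords internal
BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Derive a reproducible substream seed for a named stage
#'
#' All randomness in the package flows from a single user-facing seed.  Each
#' simulation or estimation stage draws from its own substream, derived
#' deterministically from the master seed and the stage name, so that adding
#' or reordering stages never perturbs another stage's draws.
#'
#' @param seed master integer seed.
#' @param name character stage name.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 31 + k) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

with_substream <- function(seed, name, code) {
  withr::with_seed(substream_seed(seed, name), code)
}

#' Complement a vector of nucleotide strings
#' @param x character vector of A/C/G/T/N sequences.
#' @return complemented sequences (not reversed).
#' @export
complement_bases <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}

## split a vector of counts uniformly into 3 cells (vectorized multinomial)
split3 <- function(counts) {
  e1 <- rbinom(length(counts), counts, 1 / 3)
  e2 <- rbinom(length(counts), counts - e1, 1 / 2)
  cbind(e1, e2, counts - e1 - e2)
}

## reference string -> integer codes 1..4 (A,C,G,T); N and others -> NA
ref_codes <- function(reference) {
  match(strsplit(reference, "", fixed = TRUE)[[1]], BASES)
}

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_config("'%s' must be a single probability in [0, 1], got %s",
                name, paste(format(x), collapse = ","))
  invisible(x)
}

pos_key <- function(chrom, pos) paste(chrom, pos, sep = ":")
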