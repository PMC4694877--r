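PILEUP_COLS <- c("chrom", "pos", "ref", "depth", "nA", "nC", "nG", "nT",
                 "n_ins", "n_del", "mapq")

#' Read / write the pileup TSV dialect
#'
#' Tab-separated with header `chrom pos ref depth nA nC nG nT n_ins n_del
#' mapq` plus optional trailing `ins_seq` / `del_seq` columns carrying truth
#' INDEL sequences.  Readers validate rather than coerce: malformed rows are
#' rejected with the offending line number, negative counts and base counts
#' that do not sum to depth are errors.  `write_pileup()` followed by
#' [read_pileup()] is the identity on all fields.
#'
#' @param path file path.
#' @return `read_pileup`: a pileup data.frame (see [simulate_pileup()]).
#' @export
read_pileup <- function(path) {
  if (!file.exists(path)) stop_config("pileup file not found: %s", path)
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(hdr) < length(PILEUP_COLS) ||
      !identical(hdr[seq_along(PILEUP_COLS)], PILEUP_COLS))
    stop_config("pileup header does not match the expected dialect")
  has_seq <- length(hdr) >= 13 && identical(hdr[12:13], c("ins_seq", "del_seq"))
  cls <- c("character", "integer", "character", "integer", "integer",
           "integer", "integer", "integer", "integer", "integer", "numeric")
  if (has_seq) cls <- c(cls, "character", "character")
  x <- tryCatch(
    read.table(path, header = TRUE, sep = "\t", colClasses = cls,
               quote = "", comment.char = "", na.strings = NULL,
               stringsAsFactors = FALSE),
    error = function(e) stop_config("malformed pileup file %s: %s", path,
                                    conditionMessage(e)))
  if (!has_seq) { x$ins_seq <- ""; x$del_seq <- "" }
  x$ins_seq[is.na(x$ins_seq)] <- ""
  x$del_seq[is.na(x$del_seq)] <- ""
  num <- c("pos", "depth", "nA", "nC", "nG", "nT", "n_ins", "n_del", "mapq")
  for (cn in num) {
    bad <- which(is.na(x[[cn]]) | x[[cn]] < 0)
    if (length(bad))
      stop_config("invalid %s at line %d of %s", cn, bad[1] + 1L, path)
  }
  bad <- which(x$nA + x$nC + x$nG + x$nT != x$depth)
  if (length(bad))
    stop_config("base counts do not sum to depth at line %d of %s",
                bad[1] + 1L, path)
  if (any(!x$ref %in% c(BASES, "N")))
    stop_config("invalid reference base in %s", path)
  if (any(x$mapq > 60))
    stop_config("mapq above 60 in %s", path)
  x
}

#' @rdname read_pileup
#' @param records pileup data.frame.
#' @export
write_pileup <- function(records, path) {
  stopifnot(all(PILEUP_COLS %in% names(records)))
  cols <- c(PILEUP_COLS,
            intersect(c("ins_seq", "del_seq"), names(records)))
  write.table(records[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read / write single-sample VCF variant calls
#'
#' `write_vcf()` emits a minimal plain-text VCF 4.2 with `DP` and `MQ` in
#' INFO and `GT:AF` in FORMAT; `read_vcf()` parses any single-sample VCF 4.x
#' through \pkg{vcfR}, splits multi-allelic records into biallelic calls
#' (per-allele AF when available), and requires a depth (`DP`) annotation.
#' Positions are 1-based; the pair of functions round-trips all fields in
#' scope.
#'
#' @param path file path.
#' @return `read_vcf`: data.frame with columns `chrom, pos, ref, alt,
#'   genotype, vaf, depth, mapq`.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop_config("VCF not found: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx)))   # single-record files come back as a bare vector
    fx <- matrix(fx, nrow = 1L, dimnames = list(NULL, names(fx)))
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  n <- nrow(fix)
  if (n == 0)
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      genotype = character(0), vaf = numeric(0),
                      depth = integer(0), mapq = numeric(0)))
  dp <- suppressWarnings(as.integer(vcfR::extract.info(v, "DP")))
  mq <- suppressWarnings(as.numeric(vcfR::extract.info(v, "MQ")))
  if (anyNA(dp)) stop_config("VCF %s lacks a DP annotation on some records", path)
  if (is.null(mq) || all(is.na(mq))) mq <- rep(NA_real_, n)
  gt <- af <- NULL
  if (ncol(v@gt) >= 2) {
    gt <- vcfR::extract.gt(v, "GT")[, 1L]
    af <- suppressWarnings(as.character(vcfR::extract.gt(v, "AF")[, 1L]))
  }
  out <- vector("list", n)
  for (i in seq_len(n)) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    afs <- if (!is.null(af) && !is.na(af[i]))
      suppressWarnings(as.numeric(strsplit(af[i], ",", fixed = TRUE)[[1]]))
    else rep(NA_real_, length(alts))
    if (length(afs) == 1L) afs <- rep(afs, length(alts))
    gclass <- if (!is.null(gt) && !is.na(gt[i])) {
      a <- strsplit(gt[i], "[/|]")[[1]]
      if (length(unique(a)) == 1L && a[1] != "0") "hom_alt" else "het"
    } else "het"
    out[[i]] <- data.frame(chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
                           ref = fix$REF[i], alt = alts, genotype = gclass,
                           vaf = afs, depth = dp[i], mapq = mq[i],
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @rdname read_vcf
#' @param calls data.frame of variant calls (`chrom, pos, ref, alt, genotype,
#'   vaf, depth, mapq`).
#' @export
write_vcf <- function(calls, path) {
  need <- c("chrom", "pos", "ref", "alt", "genotype", "vaf", "depth")
  stopifnot(all(need %in% names(calls)))
  mapq <- if ("mapq" %in% names(calls)) calls$mapq else rep(NA_real_, nrow(calls))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=ffpeconcord",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Allele fraction\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "SAMPLE", sep = "\t"))
  gtstr <- ifelse(calls$genotype == "hom_alt", "1/1", "0/1")
  info <- sprintf("DP=%d%s", as.integer(calls$depth),
                  ifelse(is.na(mapq), "", sprintf(";MQ=%.4g", mapq)))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s\tGT:AF\t%s:%.6g",
                  calls$chrom, as.integer(calls$pos), calls$ref, calls$alt,
                  info, gtstr, calls$vaf)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read / write BED-like interval files
#'
#' On disk, intervals are 0-based half-open (the BED standard); internally
#' everything in this package is 1-based inclusive.  These two functions are
#' the only conversion sites.  Extra numeric columns (for example
#' `copy_state`, or `gc` and `count` for bin-count files) are preserved.
#'
#' @param path file path.
#' @param extra_cols names for columns beyond `chrom, start, end`.
#' @return `read_bed`: data.frame with `chrom, start, end` (1-based
#'   inclusive) plus any extra columns.
#' @export
read_bed <- function(path, extra_cols = NULL) {
  if (!file.exists(path)) stop_config("BED file not found: %s", path)
  x <- read.table(path, header = FALSE, sep = "\t", quote = "",
                  comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(x) < 3) stop_config("BED file %s has fewer than 3 columns", path)
  names(x)[1:3] <- c("chrom", "start", "end")
  if (!is.null(extra_cols)) {
    got <- ncol(x) - 3L
    names(x)[3L + seq_len(min(got, length(extra_cols)))] <-
      extra_cols[seq_len(min(got, length(extra_cols)))]
  }
  if (any(x$start < 0)) stop_config("negative start coordinate in %s", path)
  if (any(x$start >= x$end))
    stop_config("start >= end in %s (BED is 0-based half-open)", path)
  x$start <- as.integer(x$start) + 1L   # to 1-based inclusive
  x$end <- as.integer(x$end)
  x
}

#' @rdname read_bed
#' @param intervals data.frame with 1-based inclusive `start`, `end`.
#' @export
write_bed <- function(intervals, path, extra_cols = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  out <- data.frame(chrom = intervals$chrom,
                    start = as.integer(intervals$start) - 1L,  # to 0-based
                    end = as.integer(intervals$end))
  for (cn in extra_cols) out[[cn]] <- intervals[[cn]]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read / write binned low-pass counts (BED-like with gc and count columns)
#' @param path file path.
#' @return `read_binned_counts`: an `ffc_binned` object (without read
#'   starts).
#' @export
read_binned_counts <- function(path) {
  x <- read_bed(path, extra_cols = c("gc", "count"))
  if (!all(c("gc", "count") %in% names(x)))
    stop_config("bin-count file %s needs 5 columns (chrom start end gc count)", path)
  if (any(x$count < 0)) stop_config("negative count in %s", path)
  w <- x$end - x$start + 1L
  structure(list(bins = x[, c("chrom", "start", "end", "gc", "count")],
                 bin_size = as.integer(max(w)), read_starts = NULL),
            class = "ffc_binned")
}

#' @rdname read_binned_counts
#' @param binned an `ffc_binned` object.
#' @export
write_binned_counts <- function(binned, path) {
  write_bed(binned$bins, path, extra_cols = c("gc", "count"))
}

#' Read / write the array genotype table (pos, genotype)
#' @param path file path.
#' @return `read_genotype_table`: data.frame with `pos`, `genotype` in
#'   `ref`/`het`/`hom`.
#' @export
read_genotype_table <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", quote = "",
                  stringsAsFactors = FALSE,
                  colClasses = c("integer", "character"))
  if (!identical(names(x), c("pos", "genotype")))
    stop_config("genotype table %s must have columns pos, genotype", path)
  if (any(!x$genotype %in% c("ref", "het", "hom")))
    stop_config("genotype values must be ref/het/hom in %s", path)
  x
}

#' @rdname read_genotype_table
#' @param genotypes data.frame with `pos`, `genotype`.
#' @export
write_genotype_table <- function(genotypes, path) {
  write.table(genotypes[, c("pos", "genotype")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read / write a reference sequence as FASTA
#' @param path file path.
#' @param name sequence name.
#' @return `read_reference_fasta`: a single character string.
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  as.character(x[[1L]])
}

#' @rdname read_reference_fasta
#' @param reference nucleotide string.
#' @export
write_reference_fasta <- function(reference, path, name = "chr1") {
  x <- Biostrings::DNAStringSet(reference)
  names(x) <- name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a JSON run manifest into an output directory
#'
#' Records the subcommand, configuration snapshot, input/output paths with
#' MD5 content digests, seed, package version and timestamp; reruns with an
#' identical configuration and seed produce identical output digests.
#'
#' @param outdir output directory.
#' @param subcommand name of the stage that ran.
#' @param config configuration list snapshot.
#' @param inputs,outputs character vectors of file paths.
#' @param seed integer seed used.
#' @return invisibly, the manifest list.
#' @export
write_run_manifest <- function(outdir, subcommand, config, inputs, outputs,
                               seed) {
  digest_of <- function(p) unname(tools::md5sum(p[file.exists(p)]))
  manifest <- list(
    subcommand = subcommand,
    config = config,
    inputs = as.list(setNames(digest_of(inputs), basename(inputs[file.exists(inputs)]))),
    outputs = as.list(setNames(digest_of(outputs), basename(outputs[file.exists(outputs)]))),
    seed = seed,
    tool_version = as.character(utils::packageVersion("ffpeconcord")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
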