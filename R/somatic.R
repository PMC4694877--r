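variant_key <- function(v) paste(v$chrom, v$pos, v$alt, sep = ":")

#' Allele-aware germline subtraction
#'
#' Somatic candidates are the tumor variants whose (chrom, pos, alt) triple
#' is absent from the matched normal; a tumor variant at a position the
#' normal carries with a *different* alternate allele is retained.
#'
#' @param tumor_variants,normal_variants variant data.frames
#'   (`chrom, pos, alt`, ...).
#' @return the somatic subset of `tumor_variants`.
#' @export
subtract_germline <- function(tumor_variants, normal_variants) {
  keep <- !(variant_key(tumor_variants) %in% variant_key(normal_variants))
  out <- tumor_variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Normal/tumor overlap accounting for one sample
#'
#' Tabulates the counts behind a somatic-mutation summary row: variants in
#' normal and tumor, positions variant in both, positions with the same
#' alternate allele in both, and the somatic set after allele-aware germline
#' subtraction.
#'
#' @inheritParams subtract_germline
#' @return list with `n_normal, n_tumor, n_same_positions, n_concordant_nt,
#'   n_somatic` and the `somatic` data.frame.
#' @export
somatic_overlap <- function(tumor_variants, normal_variants) {
  kt <- pos_key(tumor_variants$chrom, tumor_variants$pos)
  kn <- pos_key(normal_variants$chrom, normal_variants$pos)
  shared <- intersect(kt, kn)
  conc <- intersect(variant_key(tumor_variants), variant_key(normal_variants))
  som <- subtract_germline(tumor_variants, normal_variants)
  list(n_normal = nrow(normal_variants),
       n_tumor = nrow(tumor_variants),
       n_same_positions = length(shared),
       n_concordant_nt = length(conc),
       n_somatic = nrow(som),
       somatic = som)
}

#' Paired FF/FFPE somatic overlap classification
#'
#' Given the somatic call sets of the two preservation types from one
#' patient, counts positions present in both (`n_overlap_pair`), of which
#' those with identical alternate alleles are concordant and the rest
#' discordant.
#'
#' @param ff_somatic,ffpe_somatic somatic variant data.frames
#'   (`chrom, pos, alt`).
#' @return list with `n_overlap_pair, n_concordant_pair, n_discordant_pair`.
#' @export
paired_somatic_overlap <- function(ff_somatic, ffpe_somatic) {
  kf <- pos_key(ff_somatic$chrom, ff_somatic$pos)
  kp <- pos_key(ffpe_somatic$chrom, ffpe_somatic$pos)
  shared <- intersect(kf, kp)
  n_overlap <- length(shared)
  if (n_overlap == 0)
    return(list(n_overlap_pair = 0L, n_concordant_pair = 0L,
                n_discordant_pair = 0L))
  alt_f <- ff_somatic$alt[match(shared, kf)]
  alt_p <- ffpe_somatic$alt[match(shared, kp)]
  n_conc <- sum(alt_f == alt_p)
  list(n_overlap_pair = n_overlap,
       n_concordant_pair = n_conc,
       n_discordant_pair = n_overlap - n_conc)
}

#' Cross-sample somatic recurrence table with annotation-based filtering
#'
#' Pools somatic variant sets across samples, drops variants lacking an
#' annotation (with a message), removes synonymous variants, variants seen
#' in the supplied panel of normals, and variants present in more than
#' `max_popfreq` of a population reference (strictly greater than; a
#' population frequency exactly at the threshold is kept), then reports
#' variants carried by at least `min_samples` samples, sorted by carrier
#' count (descending) and gene name.
#'
#' @param somatic_sets_by_sample named list of somatic variant data.frames.
#' @param annotation_table data.frame mapping `chrom, pos, alt` to `gene,
#'   consequence, popfreq`.
#' @param normal_variants optional variant data.frame pooled over normal
#'   samples; matching variants are removed.
#' @param min_samples minimum number of carrier samples (default 2).
#' @param max_popfreq population-frequency cutoff (default 0.10).
#' @param drop_synonymous drop `consequence == "synonymous"` rows.
#' @return data.frame `chrom, pos, alt, gene, consequence, popfreq,
#'   n_samples, samples`.
#' @export
recurrence_table <- function(somatic_sets_by_sample, annotation_table,
                             normal_variants = NULL, min_samples = 2L,
                             max_popfreq = 0.10, drop_synonymous = TRUE) {
  need <- c("chrom", "pos", "alt", "gene", "consequence", "popfreq")
  if (!all(need %in% names(annotation_table)))
    stop_config("annotation table needs columns %s", paste(need, collapse = ", "))
  if (is.null(names(somatic_sets_by_sample)))
    names(somatic_sets_by_sample) <- paste0("sample",
                                            seq_along(somatic_sets_by_sample))
  pooled <- do.call(rbind, lapply(names(somatic_sets_by_sample), function(s) {
    v <- somatic_sets_by_sample[[s]]
    if (nrow(v) == 0) return(NULL)
    data.frame(sample = s, chrom = v$chrom, pos = v$pos, alt = v$alt,
               stringsAsFactors = FALSE)
  }))
  if (is.null(pooled) || nrow(pooled) == 0)
    return(data.frame(chrom = character(0), pos = integer(0),
                      alt = character(0), gene = character(0),
                      consequence = character(0), popfreq = numeric(0),
                      n_samples = integer(0), samples = character(0)))
  ak <- variant_key(annotation_table)
  pk <- variant_key(pooled)
  hit <- match(pk, ak)
  n_unann <- sum(is.na(hit))
  if (n_unann > 0)
    message(sprintf("dropping %d call(s) lacking annotation", n_unann))
  pooled <- pooled[!is.na(hit), , drop = FALSE]
  hit <- hit[!is.na(hit)]
  pooled$gene <- annotation_table$gene[hit]
  pooled$consequence <- annotation_table$consequence[hit]
  pooled$popfreq <- annotation_table$popfreq[hit]
  if (drop_synonymous)
    pooled <- pooled[pooled$consequence != "synonymous", , drop = FALSE]
  pooled <- pooled[pooled$popfreq <= max_popfreq, , drop = FALSE]
  if (!is.null(normal_variants) && nrow(normal_variants))
    pooled <- pooled[!(variant_key(pooled) %in% variant_key(normal_variants)),
                     , drop = FALSE]
  if (nrow(pooled) == 0)
    return(data.frame(chrom = character(0), pos = integer(0),
                      alt = character(0), gene = character(0),
                      consequence = character(0), popfreq = numeric(0),
                      n_samples = integer(0), samples = character(0)))
  key <- variant_key(pooled)
  spl <- split(pooled, key)
  rows <- do.call(rbind, lapply(spl, function(d) {
    data.frame(chrom = d$chrom[1], pos = d$pos[1], alt = d$alt[1],
               gene = d$gene[1], consequence = d$consequence[1],
               popfreq = d$popfreq[1],
               n_samples = length(unique(d$sample)),
               samples = paste(sort(unique(d$sample)), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rows <- rows[rows$n_samples >= min_samples, , drop = FALSE]
  rows <- rows[order(-rows$n_samples, rows$gene, rows$pos), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}
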