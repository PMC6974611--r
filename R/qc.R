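#' Per-submission quality metrics
#'
#' The metrics mirror common accreditation guidance: from FASTQ the mean
#' Phred base quality and the fraction of bases at or above Q20/Q30; from the
#' alignment the on/off-target fractions, on-target error rate, coverage at
#' 20x/30x/500x over the ROI, insert-size mean/sd (paired-end) and depth
#' uniformity; from the VCF the Ti/Tv ratio, SNP/indel counts, Het:Hom
#' ratios and mean call quality. Binary BAM decoding is an adapter concern:
#' alignment metrics are computed from a SAM-like tab-delimited summary.
#'
#' @name qc_metrics
NULL

#' FASTQ quality metrics
#'
#' Phred+33 encoding is assumed; if no quality byte below 59 is seen in the
#' first 10,000 reads a Phred+64 warning is attached (no auto-conversion).
#' Records whose sequence and quality lengths differ yield a record-level
#' diagnostic and are skipped.
#'
#' @param path FASTQ file (plain or gzip)
#' @return list with `mean_base_quality`, `frac_q20`, `frac_q30`, `n_reads`,
#'   `n_bases`, `diagnostics`; metrics are `NA` for an empty file
#' @export
fastq_metrics <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  diags <- diag_df()
  n <- length(lines) %/% 4L
  if (length(lines) %% 4L != 0L)
    diags <- add_diag(diags, "warning", NA_integer_,
                      "trailing lines not forming a complete FASTQ record")
  if (n == 0L)
    return(list(mean_base_quality = NA_real_, frac_q20 = NA_real_,
                frac_q30 = NA_real_, n_reads = 0L, n_bases = 0L,
                diagnostics = diags))
  quals <- integer(0)
  all_q <- vector("list", n)
  min_byte <- Inf
  for (i in seq_len(n)) {
    s <- lines[4L * i - 2L]; q <- lines[4L * i]
    if (nchar(s) != nchar(q)) {
      diags <- add_diag(diags, "warning", 4L * i,
                        sprintf("record %d: sequence/quality length mismatch", i))
      all_q[[i]] <- integer(0)
      next
    }
    qi <- utf8ToInt(q)
    if (i <= 10000L && length(qi)) min_byte <- min(min_byte, min(qi))
    all_q[[i]] <- qi - 33L
  }
  if (is.finite(min_byte) && min_byte >= 59L)
    diags <- add_diag(diags, "warning", NA_integer_,
                      "no quality byte < 59 observed: data may be Phred+64 encoded")
  qv <- unlist(all_q)
  if (!length(qv))
    return(list(mean_base_quality = NA_real_, frac_q20 = NA_real_,
                frac_q30 = NA_real_, n_reads = n, n_bases = 0L,
                diagnostics = diags))
  list(mean_base_quality = mean(qv),
       frac_q20 = mean(qv >= 20L), frac_q30 = mean(qv >= 30L),
       n_reads = n, n_bases = length(qv), diagnostics = diags)
}

#' Read a SAM-like alignment summary
#'
#' Tab-delimited with header columns `chrom`, `pos`, `mapq`, `cigar`,
#' `tlen`, `nm`, `flags`: the adapter target for BAM-derived metrics
#' (`pos` 1-based leftmost mapped base, `nm` the edit-distance tag,
#' `flags` the SAM bit flags).
#'
#' @param path summary file path
#' @param chrom_dialect see [canonical_chrom()]
#' @return data.frame of reads
#' @export
read_alignment_summary <- function(path, chrom_dialect = "strip") {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "mapq", "cigar", "tlen", "nm", "flags")
  if (!all(need %in% names(d)))
    stop("alignment summary must have columns: ", paste(need, collapse = ", "))
  d$chrom <- canonical_chrom(as.character(d$chrom), chrom_dialect)
  d
}

cigar_ref_span <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(0L)
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    len <- as.integer(sub("[MIDNSHP=X]", "", ops))
    op <- sub("[0-9]+", "", ops)
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

cigar_aligned_bases <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(0L)
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    len <- as.integer(sub("[MIDNSHP=X]", "", ops))
    op <- sub("[0-9]+", "", ops)
    sum(len[op %in% c("M", "I", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Alignment-derived quality metrics
#'
#' A read is on-target when its reference span overlaps the ROI. Coverage
#' fractions are per-base depth over the ROI; the error rate is the sum of
#' per-read mismatch counts (edit-distance tag) over aligned bases of
#' on-target reads (reference-free by design). Insert statistics use proper
#' pairs only (`flags & 2`, `tlen > 0`, each pair counted once). Uniformity
#' is the fraction of ROI bases with depth within a factor of two of the
#' median ROI depth.
#'
#' @param aln data.frame from [read_alignment_summary()]
#' @param roi a [region_set()]
#' @param thresholds depth thresholds for `coverage_ge` (default 20, 30, 500)
#' @return list of alignment metrics
#' @export
alignment_metrics <- function(aln, roi, thresholds = c(20L, 30L, 500L)) {
  mapped <- aln[bitwAnd(aln$flags, 4L) == 0L & aln$cigar != "*", , drop = FALSE]
  n_mapped <- nrow(mapped)
  if (n_mapped == 0L)
    return(list(frac_on_target = NA_real_, frac_off_target = NA_real_,
                error_rate_on_target = NA_real_,
                coverage_ge = setNames(rep(0, length(thresholds)),
                                       as.character(thresholds)),
                insert_mean = NA_real_, insert_sd = NA_real_,
                uniformity = NA_real_, n_mapped = 0L))
  span <- cigar_ref_span(mapped$cigar)
  read_rs <- data.frame(chrom = mapped$chrom, start = mapped$pos - 1L,
                        end = mapped$pos - 1L + pmax(span, 1L))
  on <- logical(n_mapped)
  roi_by <- as_iranges_by_chrom(roi)
  for (ch in unique(read_rs$chrom)) {
    i <- which(read_rs$chrom == ch)
    if (!ch %in% names(roi_by)) next
    q <- IRanges::IRanges(read_rs$start[i] + 1L, read_rs$end[i])
    on[i] <- IRanges::overlapsAny(q, roi_by[[ch]])
  }
  # per-base depth over ROI
  depth <- integer(0)
  for (ch in unique(roi$chrom)) {
    i <- which(read_rs$chrom == ch)
    cov <- if (length(i))
      IRanges::coverage(IRanges::IRanges(read_rs$start[i] + 1L, read_rs$end[i]))
    else S4Vectors::Rle(0L, 0)
    r <- roi[roi$chrom == ch, , drop = FALSE]
    for (j in seq_len(nrow(r))) {
      n_bases <- r$end[j] - r$start[j]
      dpt <- rep(0L, n_bases)
      lo <- r$start[j] + 1L; hi <- r$end[j]
      if (length(cov) >= lo) {
        hi2 <- min(hi, length(cov))
        dpt[seq_len(hi2 - lo + 1L)] <- as.integer(cov[lo:hi2])
      }
      depth <- c(depth, dpt)
    }
  }
  cov_ge <- vapply(thresholds, function(t) if (length(depth)) mean(depth >= t) else 0,
                   numeric(1))
  aligned <- cigar_aligned_bases(mapped$cigar)
  err <- if (sum(aligned[on]) > 0) sum(mapped$nm[on]) / sum(aligned[on]) else NA_real_
  proper <- bitwAnd(mapped$flags, 2L) != 0L & mapped$tlen > 0L
  ins <- abs(mapped$tlen[proper])
  med <- if (length(depth)) median(depth) else NA_real_
  unif <- if (length(depth) && !is.na(med) && med > 0)
    mean(depth >= med / 2 & depth <= 2 * med) else NA_real_
  list(frac_on_target = mean(on), frac_off_target = mean(!on),
       error_rate_on_target = err,
       coverage_ge = setNames(cov_ge, as.character(thresholds)),
       insert_mean = if (length(ins)) mean(ins) else NA_real_,
       insert_sd = if (length(ins) > 1L) sd(ins) else NA_real_,
       uniformity = unif, n_mapped = n_mapped)
}

#' VCF-derived call-set metrics
#'
#' Transitions are A<->G and C<->T; every other SNP pair is a transversion.
#' Het counts cover the `het`/`het_other` genotype classes, Hom covers
#' `hom_alt`. Mean call quality ignores records with missing QUAL. Ratios
#' with a zero denominator are `NA` (undefined marker).
#'
#' @param v a [variant_tbl()]
#' @return list with `titv`, `snp_count`, `indel_count`, `het_hom_snp`,
#'   `het_hom_indel`, `mean_call_quality`, `call_quality_quartiles`
#' @export
vcf_metrics <- function(v) {
  snp <- v[v$var_class == "snp", , drop = FALSE]
  indel <- v[v$var_class %in% c("insertion", "deletion"), , drop = FALSE]
  is_ti <- (snp$ref == "A" & snp$alt == "G") | (snp$ref == "G" & snp$alt == "A") |
           (snp$ref == "C" & snp$alt == "T") | (snp$ref == "T" & snp$alt == "C")
  n_ti <- sum(is_ti); n_tv <- nrow(snp) - n_ti
  het_hom <- function(d) {
    het <- sum(!is.na(d$gt) & d$gt %in% c("het", "het_other"))
    hom <- sum(!is.na(d$gt) & d$gt == "hom_alt")
    if (hom == 0L) NA_real_ else het / hom
  }
  q <- v$qual[!is.na(v$qual)]
  list(titv = if (n_tv == 0L) NA_real_ else n_ti / n_tv,
       snp_count = nrow(snp), indel_count = nrow(indel),
       het_hom_snp = het_hom(snp), het_hom_indel = het_hom(indel),
       mean_call_quality = if (length(q)) mean(q) else NA_real_,
       call_quality_quartiles = if (length(q))
         quantile(q, c(0.25, 0.5, 0.75), names = FALSE) else rep(NA_real_, 3))
}

#' Benchmark one metric across the cohort
#'
#' Each lab's percentile within the cohort (mean rank on ties; a singleton
#' cohort is 50 by convention) plus a five-number cohort summary, optionally
#' stratified by a metadata key (platform, kit); labs without the key fall
#' in stratum `"unreported"`.
#'
#' @param values named numeric vector: one metric value per participant
#' @param strata optional character vector parallel to `values`
#' @return list with `percentiles` (data.frame participant/stratum/value/
#'   percentile) and `summary` (per-stratum min/q1/median/q3/max/n)
#' @export
cohort_benchmark <- function(values, strata = NULL) {
  stopifnot(length(values) >= 1L)
  ids <- names(values)
  if (is.null(ids)) ids <- as.character(seq_along(values))
  if (is.null(strata)) strata <- rep("all", length(values))
  strata[is.na(strata) | strata == ""] <- "unreported"
  out <- do.call(rbind, lapply(split(seq_along(values), strata), function(i) {
    x <- values[i]
    pct <- if (length(x) == 1L) 50 else (rank(x, ties.method = "average") - 0.5) / length(x) * 100
    data.frame(participant = ids[i], stratum = strata[i][1], value = unname(x),
               percentile = unname(pct), stringsAsFactors = FALSE)
  }))
  out <- out[order(match(out$participant, ids)), , drop = FALSE]
  rownames(out) <- NULL
  summ <- do.call(rbind, lapply(split(values, strata), function(x) {
    qs <- quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, na.rm = TRUE)
    data.frame(min = qs[1], q1 = qs[2], median = qs[3], q3 = qs[4], max = qs[5],
               n = length(x))
  }))
  summ$stratum <- rownames(summ); rownames(summ) <- NULL
  list(percentiles = out, summary = summ)
}
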