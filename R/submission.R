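#' Read a participant submission (VCF + BED)
#'
#' Validates both files, keeps PASS records (FILTER `PASS` or `.`; many
#' callers emit `.` for pass) when `pass_only`, normalizes every record via
#' the variant model, canonicalises the ROI, and reports dropped records.
#' Decomposed alleles whose genotype contains no copy of the ALT
#' (`not_present`) are dropped and counted.
#'
#' @param vcf_path,bed_path submission files
#' @param participant_id opaque lab identifier
#' @param scheme `"germline"` or `"somatic"`
#' @param build `"GRCh37"` or `"GRCh38"`
#' @param pass_only keep only FILTER PASS / "." records
#' @param sequences optional named character vector of reference sequences
#'   used for indel left-alignment
#' @param chrom_dialect see [canonical_chrom()]
#' @param metadata free-form key/value list (platform, kit, pipeline)
#' @return object of class `eqa_submission`: list with `participant_id`,
#'   `scheme`, `build`, `variants` ([variant_tbl()]), `roi` ([region_set()]),
#'   `metadata`, `dropped` (named counts), `diagnostics`
#' @export
read_submission <- function(vcf_path, bed_path, participant_id = basename(vcf_path),
                            scheme = c("germline", "somatic"),
                            build = c("GRCh37", "GRCh38"),
                            pass_only = TRUE, sequences = NULL,
                            chrom_dialect = "strip", metadata = list()) {
  scheme <- match.arg(scheme); build <- match.arg(build)
  diags <- validate_vcf(vcf_path)
  if (any(diags$severity == "error"))
    stop(sprintf("submission %s: VCF failed validation: %s", participant_id,
                 paste(diags$message[diags$severity == "error"], collapse = "; ")))
  roi <- read_bed(bed_path, chrom_dialect)
  recs <- read_vcf_records(vcf_path)
  recs <- recs[!vapply(recs, is.null, logical(1))]
  n_filtered <- 0L; n_rejected <- 0L; n_not_present <- 0L
  vs <- list()
  for (r in recs) {
    if (pass_only && !(is.na(r$filter) || r$filter %in% c("PASS", "."))) {
      n_filtered <- n_filtered + 1L
      next
    }
    nr <- normalize_record(r, sequences = sequences, chrom_dialect = chrom_dialect)
    n_rejected <- n_rejected + nrow(nr$rejected)
    v <- nr$variants
    np <- !is.na(v$gt) & v$gt == "not_present"
    n_not_present <- n_not_present + sum(np)
    v <- v[!np, , drop = FALSE]
    if (nrow(v)) vs[[length(vs) + 1L]] <- v
  }
  variants <- if (length(vs)) do.call(rbind, vs) else variant_tbl()
  class(variants) <- c("variant_tbl", "data.frame")
  variants <- sort_variants(variants)
  dup <- duplicated(call_key(variants, genotype = TRUE))
  if (any(dup)) {
    warning(sprintf("submission %s: %d duplicate record(s) after normalization dropped",
                    participant_id, sum(dup)))
    variants <- variants[!dup, , drop = FALSE]
    rownames(variants) <- NULL
  }
  if (nrow(variants) && nrow(roi) &&
      !any(unique(variants$chrom) %in% unique(roi$chrom)))
    stop(sprintf("submission %s: VCF and BED share no chromosome after canonicalization",
                 participant_id))
  structure(list(participant_id = participant_id, scheme = scheme,
                 build = build, variants = variants, roi = roi,
                 metadata = metadata,
                 dropped = c(filtered = n_filtered, rejected = n_rejected,
                             not_present = n_not_present,
                             duplicates = sum(dup)),
                 diagnostics = diags),
            class = "eqa_submission")
}

#' Construct a submission from in-memory objects
#'
#' Convenience constructor used by the simulator and by tests; applies the
#' same sorting/dedup contract as [read_submission()] but no file I/O or
#' re-normalization.
#'
#' @param participant_id lab identifier
#' @param variants a [variant_tbl()] (already normalized)
#' @param roi a [region_set()]
#' @inheritParams read_submission
#' @return an `eqa_submission`
#' @export
submission <- function(participant_id, variants, roi,
                       scheme = c("germline", "somatic"),
                       build = c("GRCh37", "GRCh38"), metadata = list()) {
  scheme <- match.arg(scheme); build <- match.arg(build)
  variants <- sort_variants(variants)
  variants <- variants[!duplicated(call_key(variants, genotype = TRUE)), , drop = FALSE]
  rownames(variants) <- NULL
  structure(list(participant_id = participant_id, scheme = scheme,
                 build = build, variants = variants, roi = roi,
                 metadata = metadata,
                 dropped = c(filtered = 0L, rejected = 0L, not_present = 0L,
                             duplicates = 0L),
                 diagnostics = diag_df()),
            class = "eqa_submission")
}

#' @export
print.eqa_submission <- function(x, ...) {
  cat(sprintf("eqa_submission '%s' (%s, %s): %d variant(s), ROI %d bp\n",
              x$participant_id, x$scheme, x$build, nrow(x$variants),
              region_width(x$roi)))
  invisible(x)
}

#' Truth sets
#'
#' A truth set couples the expected variants with the assessable region in
#' which they are scored and a provenance tag: `eqa` (pre-established,
#' validated-lab truth), `consensus` (participant vote) or `merged`
#' (EQA truth with strong-consensus override). Consensus variants carry
#' per-variant support counts (`covering_labs`, `agreeing_labs`).
#'
#' @param variants a [variant_tbl()]; consensus/merged sets should carry
#'   `covering_labs` and `agreeing_labs` columns
#' @param assessable a [region_set()] or `NULL` (policy not applied yet)
#' @param provenance `"eqa"`, `"consensus"` or `"merged"`
#' @return object of class `truth_set`
#' @export
truth_set <- function(variants, assessable = NULL,
                      provenance = c("eqa", "consensus", "merged")) {
  provenance <- match.arg(provenance)
  if (!"covering_labs" %in% names(variants))
    variants$covering_labs <- rep(NA_integer_, nrow(variants))
  if (!"agreeing_labs" %in% names(variants))
    variants$agreeing_labs <- rep(NA_integer_, nrow(variants))
  stopifnot(all(is.na(variants$agreeing_labs) |
                variants$agreeing_labs <= variants$covering_labs))
  structure(list(variants = sort_variants(variants), assessable = assessable,
                 provenance = provenance),
            class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("truth_set (%s): %d variant(s), assessable %s bp\n",
              x$provenance, nrow(x$variants),
              if (is.null(x$assessable)) "unset" else region_width(x$assessable)))
  invisible(x)
}

#' Write a truth set as VCF + companion assessable BED
#'
#' The VCF records per-variant supporting-lab count (`SUPPORT`), covering-lab
#' count (`COVER`) and agreement fraction (`AGREE_FRAC`); it round-trips
#' through [validate_vcf()] and [read_truth_vcf()].
#'
#' @param truth a [truth_set()]
#' @param vcf_path output VCF path
#' @param bed_path optional companion BED path for the assessable region
#' @export
write_truth_vcf <- function(truth, vcf_path, bed_path = NULL) {
  v <- truth$variants
  info <- data.frame(SUPPORT = v$agreeing_labs, COVER = v$covering_labs,
                     AGREE_FRAC = ifelse(is.na(v$covering_labs) | v$covering_labs == 0,
                                         NA_real_,
                                         round(v$agreeing_labs / v$covering_labs, 6)))
  write_vcf(v, vcf_path, sample_name = "TRUTH", info = info)
  if (!is.null(bed_path) && !is.null(truth$assessable))
    write_bed(truth$assessable, bed_path)
  invisible(vcf_path)
}

#' Read a truth-set VCF written by [write_truth_vcf()]
#'
#' @param vcf_path truth VCF path
#' @param bed_path optional companion assessable BED
#' @param provenance provenance tag for the loaded set
#' @param chrom_dialect see [canonical_chrom()]
#' @return a [truth_set()]
#' @export
read_truth_vcf <- function(vcf_path, bed_path = NULL, provenance = "eqa",
                           chrom_dialect = "strip") {
  d <- validate_vcf(vcf_path)
  if (any(d$severity == "error"))
    stop(sprintf("truth VCF failed validation: %s",
                 paste(d$message[d$severity == "error"], collapse = "; ")))
  recs <- read_vcf_records(vcf_path)
  recs <- recs[!vapply(recs, is.null, logical(1))]
  rows <- list()
  for (r in recs) {
    info <- r$filter  # unused; support parsed below from raw line
    nr <- normalize_record(r, chrom_dialect = chrom_dialect)
    v <- nr$variants
    if (nrow(v)) rows[[length(rows) + 1L]] <- v
  }
  v <- if (length(rows)) do.call(rbind, rows) else variant_tbl()
  class(v) <- c("variant_tbl", "data.frame")
  # recover support counts from INFO
  lines <- readLines(vcf_path, warn = FALSE)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  sup <- rep(NA_integer_, nrow(v)); cov <- rep(NA_integer_, nrow(v))
  if (length(body) && nrow(v)) {
    f <- strsplit(body, "\t", fixed = TRUE)
    key_file <- vapply(f, function(x) paste(canonical_chrom(x[1], chrom_dialect),
                                            x[2], x[4], x[5], sep = ":"), character(1))
    get_info <- function(s, k) {
      m <- regmatches(s, regexpr(paste0("(?:^|;)", k, "=([0-9.]+)"), s))
      if (!length(m)) NA else as.numeric(sub(paste0(".*", k, "="), "", m))
    }
    kv <- paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
    idx <- match(kv, key_file)
    sup <- vapply(idx, function(i) if (is.na(i)) NA_integer_
                  else as.integer(get_info(f[[i]][8], "SUPPORT")), integer(1))
    cov <- vapply(idx, function(i) if (is.na(i)) NA_integer_
                  else as.integer(get_info(f[[i]][8], "COVER")), integer(1))
  }
  v$agreeing_labs <- sup; v$covering_labs <- cov
  assessable <- if (!is.null(bed_path)) read_bed(bed_path, chrom_dialect) else NULL
  truth_set(v, assessable, provenance)
}
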