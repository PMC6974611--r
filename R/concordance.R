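#' Concordance scoring of a submission against a truth set
#'
#' Variant comparison is performed on SNVs and small indels (< 50 bp) inside
#' the intersection of the assessable region and the submitted ROI. Each
#' comparison result falls in one of four categories: Agree (TP), Disagree
#' (FP, FN), Extra (FP), Missing (FN). Germline matching requires the called
#' genotype class to match; somatic matching requires only the alternate
#' allele.
#'
#' @name concordance
NULL

#' Region in which a submission is scored
#'
#' @param truth a [truth_set()] with an assessable region
#' @param sub an `eqa_submission`
#' @return `truth$assessable` intersected with `sub$roi`
#' @export
comparison_region <- function(truth, sub) {
  if (is.null(truth$assessable)) stop("truth set has no assessable region")
  region_intersect(truth$assessable, sub$roi)
}

eligible_variant <- function(v, indel_max_len) {
  abs(nchar(v$ref) - nchar(v$alt)) < indel_max_len & !v$n_flag
}

#' Classify every call and compute concordance scores
#'
#' Truth variants inside the comparison region are `agree` when a submitted
#' call matches under the matching mode, `disagree` when a submitted call
#' occupies the same normalized site (chrom, start, REF) with a different
#' call, and `missing` otherwise. Submitted calls matching nothing and
#' sharing no site with truth are `extra`. With the default
#' `disagree = "both"` convention a disagreement increments both FP and FN;
#' `disagree = "fn_only"` counts it as FN only (the convention changes
#' precision, so both are provided). Variants failing the indel-size
#' eligibility filter are excluded from all categories and returned in
#' `not_assessed`.
#'
#' @param sub an `eqa_submission`
#' @param truth a [truth_set()] with an assessable region
#' @param mode `"genotype"` (germline) or `"alt_allele"` (somatic)
#' @param params a [consensus_params()] (for `indel_max_len`)
#' @param disagree `"both"` or `"fn_only"`
#' @return object of class `concordance_result`: list with `truth_calls` and
#'   `submitted_calls` (classified data.frames), `counts` (TP/FP/FN),
#'   `scores` (sensitivity/precision/f_score), `comparison_region`,
#'   `matching_mode`, `not_assessed`
#' @export
classify <- function(sub, truth, mode = c("genotype", "alt_allele"),
                     params = consensus_params(),
                     disagree = c("both", "fn_only")) {
  mode <- match.arg(mode); disagree <- match.arg(disagree)
  if ((sub$scheme == "germline") != (mode == "genotype"))
    warning(sprintf("submission scheme '%s' scored with matching mode '%s'",
                    sub$scheme, mode))
  region <- comparison_region(truth, sub)
  gk <- mode == "genotype"

  tv <- as.data.frame(truth$variants)
  sv <- as.data.frame(sub$variants)
  tag_rows <- function(d, src) {
    d <- d[, c("chrom", "pos", "ref", "alt"), drop = FALSE]
    d$source <- rep(src, nrow(d))
    d
  }
  not_assessed <- rbind(
    tag_rows(sv[!eligible_variant(sv, params$indel_max_len), , drop = FALSE], "submitted"),
    tag_rows(tv[!eligible_variant(tv, params$indel_max_len), , drop = FALSE], "truth"))
  tv <- tv[eligible_variant(tv, params$indel_max_len), , drop = FALSE]
  sv <- sv[eligible_variant(sv, params$indel_max_len), , drop = FALSE]
  tv <- tv[region_covers(region, tv$chrom, tv$pos - 1L), , drop = FALSE]
  sv <- sv[region_covers(region, sv$chrom, sv$pos - 1L), , drop = FALSE]

  t_call <- call_key(tv, genotype = gk); t_site <- site_key(tv)
  s_call <- call_key(sv, genotype = gk); s_site <- site_key(sv)

  s_cat <- ifelse(s_call %in% t_call, "agree",
                  ifelse(s_site %in% t_site, "disagree", "extra"))
  t_cat <- ifelse(t_call %in% s_call, "agree",
                  ifelse(t_site %in% s_site, "disagree", "missing"))
  tv$category <- if (nrow(tv)) t_cat else character()
  sv$category <- if (nrow(sv)) s_cat else character()

  tp <- sum(tv$category == "agree")
  fn <- sum(tv$category %in% c("missing", "disagree"))
  fp <- sum(sv$category == "extra") +
    if (disagree == "both") sum(sv$category == "disagree") else 0L
  scores <- compute_scores(tp, fp, fn)
  structure(list(truth_calls = tv, submitted_calls = sv,
                 counts = c(TP = tp, FP = fp, FN = fn),
                 scores = scores, comparison_region = region,
                 matching_mode = mode, disagree_convention = disagree,
                 not_assessed = not_assessed,
                 participant_id = sub$participant_id),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("concordance '%s' (%s): TP=%d FP=%d FN=%d  sens=%.4f prec=%.4f F=%.4f\n",
              x$participant_id, x$matching_mode,
              x$counts["TP"], x$counts["FP"], x$counts["FN"],
              x$scores["sensitivity"], x$scores["precision"], x$scores["f_score"]))
  invisible(x)
}

#' Sensitivity, precision and F-score from confusion counts
#'
#' `sensitivity = TP/(TP+FN)`, `precision = TP/(TP+FP)`,
#' `f_score = 2*precision*sensitivity/(precision+sensitivity)`; any 0/0 is
#' defined as 0.
#'
#' @param tp,fp,fn non-negative counts
#' @return named numeric vector `sensitivity`, `precision`, `f_score`
#' @examples
#' round(compute_scores(21161, 1127, 224) * 100, 1)  # 99.0, 94.9, 96.9
#' @export
compute_scores <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  sens <- if (tp + fn == 0) 0 else tp / (tp + fn)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  f <- if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
  c(sensitivity = sens, precision = prec, f_score = f)
}

#' Sequencing efficiency: raw bases generated per declared variant
#'
#' @param total_bases_sequenced total raw bases (>= 0)
#' @param declared_variants number of declared variants (>= 0)
#' @return bases per variant; `NA` (undefined marker) when no variants were
#'   declared
#' @export
efficiency <- function(total_bases_sequenced, declared_variants) {
  stopifnot(total_bases_sequenced >= 0, declared_variants >= 0)
  if (declared_variants == 0) return(NA_real_)
  total_bases_sequenced / declared_variants
}
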