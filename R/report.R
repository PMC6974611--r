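#' End-to-end EQA run
#'
#' Orchestrates the workflow: ingest and normalize every submission, derive
#' the participant consensus (optionally merged with a pre-established EQA
#' truth set), construct the assessable region under the configured policy,
#' classify every lab, compute scores, and summarise the cohort including
#' F-score band membership (fraction of labs with F > 0.80 and > 0.95).
#'
#' @param config a list (see [eqa_config()]) describing the run
#' @return object of class `eqa_run`: list with `truth`, `per_lab`
#'   (concordance results), `cohort` (per-lab summary data.frame), `bands`,
#'   `params`, `config`
#' @export
run_eqa <- function(config) {
  p <- config$params %||% consensus_params()
  scheme <- match.arg(config$scheme, c("germline", "somatic"))
  policy <- match.arg(config$policy,
                      c("germline_exon2bp", "germline_consensus_exon2bp",
                        "somatic_exact", "somatic_proximity"))
  truth_mode <- match.arg(config$truth_mode %||% "consensus",
                          c("consensus", "eqa_merge"))
  sequences <- config$sequences
  if (is.character(sequences) && length(sequences) == 1L && file.exists(sequences))
    sequences <- read_fasta(sequences)
  exons <- config$exons
  if (is.character(exons) && length(exons) == 1L) exons <- read_bed(exons)

  subs <- config$submissions
  if (length(subs) && !inherits(subs[[1]], "eqa_submission"))
    subs <- lapply(subs, function(s)
      read_submission(s$vcf, s$bed,
                      participant_id = s$participant_id %||% basename(s$vcf),
                      scheme = scheme, sequences = sequences,
                      metadata = s$metadata %||% list()))
  if (!length(subs)) stop("no submissions")

  consensus <- build_consensus(subs, p, scheme)
  truth <- if (truth_mode == "eqa_merge") {
    eqa <- config$eqa_truth
    if (is.list(eqa) && !inherits(eqa, "truth_set"))
      eqa <- read_truth_vcf(eqa$vcf, eqa$bed)
    merge_truth(eqa, consensus, p)
  } else consensus

  per_lab_assessable <- NULL
  if (policy == "somatic_proximity") {
    per_lab_assessable <- lapply(subs, function(s)
      build_assessable("somatic_proximity", variants = s$variants,
                       roi = s$roi, params = p))
  } else {
    truth$assessable <- build_assessable(policy, exons = exons,
                                         variants = truth$variants, params = p)
  }

  mode <- if (scheme == "germline") "genotype" else "alt_allele"
  per_lab <- lapply(seq_along(subs), function(i) {
    t <- truth
    if (!is.null(per_lab_assessable)) t$assessable <- per_lab_assessable[[i]]
    classify(subs[[i]], t, mode = mode, params = p,
             disagree = config$disagree %||% "both")
  })
  cohort <- do.call(rbind, lapply(per_lab, function(r)
    data.frame(participant_id = r$participant_id,
               TP = unname(r$counts["TP"]), FP = unname(r$counts["FP"]),
               FN = unname(r$counts["FN"]),
               sensitivity = unname(r$scores["sensitivity"]),
               precision = unname(r$scores["precision"]),
               f_score = unname(r$scores["f_score"]),
               region_bp = region_width(r$comparison_region),
               stringsAsFactors = FALSE)))
  bands <- c(f_gt_080 = mean(cohort$f_score > 0.80),
             f_gt_095 = mean(cohort$f_score > 0.95))
  structure(list(truth = truth, per_lab = per_lab, cohort = cohort,
                 bands = bands, params = p,
                 config = config[setdiff(names(config), "sequences")]),
            class = "eqa_run")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble a run configuration
#'
#' @param scheme `"germline"` or `"somatic"`
#' @param policy assessable-region policy, see [build_assessable()]
#' @param submissions list of `eqa_submission` objects, or of lists with
#'   `vcf`/`bed`/`participant_id` paths
#' @param exons exon annotation ([region_set()] or BED path; germline)
#' @param sequences reference (named character vector or FASTA path)
#' @param truth_mode `"consensus"` (2017) or `"eqa_merge"` (2016 fall-back
#'   with strong-consensus override)
#' @param eqa_truth a [truth_set()] or list(vcf=, bed=) when `eqa_merge`
#' @param params a [consensus_params()]
#' @param disagree `"both"` or `"fn_only"`, see [classify()]
#' @return config list for [run_eqa()]
#' @export
eqa_config <- function(scheme, policy, submissions, exons = NULL,
                       sequences = NULL, truth_mode = "consensus",
                       eqa_truth = NULL, params = consensus_params(),
                       disagree = "both") {
  list(scheme = scheme, policy = policy, submissions = submissions,
       exons = exons, sequences = sequences, truth_mode = truth_mode,
       eqa_truth = eqa_truth, params = params, disagree = disagree)
}

#' @export
print.eqa_run <- function(x, ...) {
  cat(sprintf("eqa_run: %d lab(s), truth %s with %d variant(s)\n",
              nrow(x$cohort), x$truth$provenance, nrow(x$truth$variants)))
  print.data.frame(x$cohort)
  cat(sprintf("F>0.80: %.0f%%  F>0.95: %.0f%%\n",
              100 * x$bands["f_gt_080"], 100 * x$bands["f_gt_095"]))
  invisible(x)
}

#' Render an EQA run as report files
#'
#' `json` writes the cohort table, bands and per-lab classifications;
#' `tsv` writes the cohort summary table; `markdown` writes a human-readable
#' summary. JSON reports round-trip: reloading gives the same cohort table.
#'
#' @param run an `eqa_run`
#' @param format `"json"`, `"tsv"` or `"markdown"`
#' @param path output file path
#' @return `path`, invisibly
#' @export
render_report <- function(run, format = c("json", "tsv", "markdown"), path) {
  format <- match.arg(format)
  if (format == "json") {
    payload <- list(
      cohort = run$cohort,
      bands = as.list(run$bands),
      params = unclass(run$params)[c("min_participants", "agreement_fraction",
                                     "exon_extension_bp", "somatic_proximity_bp",
                                     "indel_max_len", "consensus_genotype")],
      truth = list(provenance = run$truth$provenance,
                   n_variants = nrow(run$truth$variants)),
      per_lab = lapply(run$per_lab, function(r) list(
        participant_id = r$participant_id,
        counts = as.list(r$counts), scores = as.list(r$scores),
        n_not_assessed = nrow(r$not_assessed))))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  } else if (format == "tsv") {
    utils::write.table(run$cohort, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    lines <- c("# EQA cohort report", "",
               sprintf("- labs: %d", nrow(run$cohort)),
               sprintf("- truth: %s, %d variants", run$truth$provenance,
                       nrow(run$truth$variants)),
               sprintf("- labs with F > 0.80: %.1f%%", 100 * run$bands["f_gt_080"]),
               sprintf("- labs with F > 0.95: %.1f%%", 100 * run$bands["f_gt_095"]),
               "", "| lab | TP | FP | FN | sensitivity | precision | F |",
               "|---|---|---|---|---|---|---|",
               sprintf("| %s | %d | %d | %d | %.4f | %.4f | %.4f |",
                       run$cohort$participant_id, run$cohort$TP, run$cohort$FP,
                       run$cohort$FN, run$cohort$sensitivity,
                       run$cohort$precision, run$cohort$f_score))
    writeLines(lines, path)
  }
  invisible(path)
}
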