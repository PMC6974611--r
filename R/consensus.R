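#' Consensus-truth parameters
#'
#' The voting and region policies are governed by a handful of scheme
#' constants: a site must lie in the ROI of at least `min_participants` labs
#' and at least `agreement_fraction` of those labs must make the identical
#' call; germline assessable regions are exons extended by
#' `exon_extension_bp`; the somatic proximity policy prunes ROI further than
#' `somatic_proximity_bp` from any reported variant; only SNVs and indels
#' shorter than `indel_max_len` are compared.
#'
#' @param min_participants minimum covering labs (default 7)
#' @param agreement_fraction minimum agreeing fraction (default 0.75),
#'   compared with exact rational arithmetic so 6/8 >= 75% holds exactly
#' @param exon_extension_bp exon flank in bp (default 2)
#' @param somatic_proximity_bp proximity pruning distance in bp (default 1000)
#' @param indel_max_len indel size eligibility bound, exclusive (default 50)
#' @param consensus_genotype include the genotype class in germline consensus
#'   call keys (default TRUE)
#' @return list of class `consensus_params`
#' @export
consensus_params <- function(min_participants = 7L, agreement_fraction = 0.75,
                             exon_extension_bp = 2L, somatic_proximity_bp = 1000L,
                             indel_max_len = 50L, consensus_genotype = TRUE) {
  stopifnot(min_participants >= 1L, agreement_fraction > 0,
            agreement_fraction <= 1, exon_extension_bp >= 0,
            somatic_proximity_bp >= 0, indel_max_len >= 0)
  p <- list(min_participants = as.integer(min_participants),
            agreement_fraction = agreement_fraction,
            exon_extension_bp = as.integer(exon_extension_bp),
            somatic_proximity_bp = as.integer(somatic_proximity_bp),
            indel_max_len = as.integer(indel_max_len),
            consensus_genotype = isTRUE(consensus_genotype))
  # rational form of the agreement fraction for exact integer comparison
  den <- 1e6L
  num <- as.integer(round(agreement_fraction * den))
  g <- gcd_int(num, den)
  p$frac_num <- num %/% g; p$frac_den <- den %/% g
  class(p) <- "consensus_params"
  p
}

gcd_int <- function(a, b) if (b == 0L) a else gcd_int(b, a %% b)

# agree/covering >= frac, exact in integers
meets_agreement <- function(agree, covering, params) {
  covering > 0L & (agree * params$frac_den >= params$frac_num * covering)
}

use_genotype_key <- function(scheme, params) {
  scheme == "germline" && isTRUE(params$consensus_genotype)
}

#' Tally calls at one genomic site across the cohort
#'
#' Bookkeeping for the two consensus conditions: `covering_labs` counts the
#' labs whose declared ROI contains the site point; `call_counts` counts,
#' per exact normalized call key, the labs making that call (only labs
#' covering the site vote); `noncalling_labs` are covering labs with no call
#' at the site — they count against every candidate call, so a missed call
#' works against consensus. A lab emitting two different ALTs at one site
#' contributes each call but covers once.
#'
#' @param chrom,pos site (1-based position of the normalized variant start)
#' @param submissions list of `eqa_submission`
#' @param scheme `"germline"` or `"somatic"`
#' @param params a [consensus_params()]
#' @return list with `covering_labs`, `call_counts` (named integer vector),
#'   `noncalling_labs`
#' @export
tally_site <- function(chrom, pos, submissions, scheme = "germline",
                       params = consensus_params()) {
  builds <- unique(vapply(submissions, `[[`, character(1), "build"))
  if (length(builds) > 1L)
    stop("mixed reference builds in one cohort: ", paste(builds, collapse = ", "))
  gk <- use_genotype_key(scheme, params)
  covering <- 0L
  counts <- integer()
  calling <- 0L
  for (s in submissions) {
    if (!region_covers(s$roi, chrom, pos - 1L)) next
    covering <- covering + 1L
    v <- s$variants
    here <- v[v$chrom == chrom & v$pos == pos, , drop = FALSE]
    if (nrow(here) == 0L) next
    calling <- calling + 1L
    for (k in unique(call_key(here, genotype = gk)))
      counts[k] <- (if (k %in% names(counts)) counts[[k]] else 0L) + 1L
  }
  list(covering_labs = covering, call_counts = counts,
       noncalling_labs = covering - calling)
}

#' Build the participant consensus truth set
#'
#' A normalized call enters the consensus iff (a) its site lies in the ROI
#' of at least `min_participants` labs and (b) the labs making that exact
#' call are at least `agreement_fraction` of the covering labs. The
#' denominator is the covering labs, so covering labs that call nothing
#' count as disagreeing. Germline call keys include the genotype class by
#' default. The returned truth set has `provenance = "consensus"` and no
#' assessable region (apply [build_assessable()] next).
#'
#' @param submissions list of `eqa_submission` (same scheme and build)
#' @param params a [consensus_params()]
#' @param scheme `"germline"` or `"somatic"`
#' @return a [truth_set()] with per-variant `covering_labs`/`agreeing_labs`
#' @export
build_consensus <- function(submissions, params = consensus_params(),
                            scheme = c("germline", "somatic")) {
  scheme <- match.arg(scheme)
  stopifnot(length(submissions) >= 1L)
  builds <- unique(vapply(submissions, `[[`, character(1), "build"))
  if (length(builds) > 1L)
    stop("mixed reference builds in one cohort: ", paste(builds, collapse = ", "))
  gk <- use_genotype_key(scheme, params)
  all_v <- do.call(rbind, lapply(seq_along(submissions), function(i) {
    v <- submissions[[i]]$variants
    if (nrow(v) == 0L) return(NULL)
    v$lab <- i
    as.data.frame(v)
  }))
  if (is.null(all_v) || nrow(all_v) == 0L)
    return(truth_set(variant_tbl(), provenance = "consensus"))
  sites <- unique(all_v[, c("chrom", "pos")])
  # covering labs per site: point membership of each site in each lab's ROI
  covering <- integer(nrow(sites))
  for (s in submissions)
    covering <- covering + region_covers(s$roi, sites$chrom, sites$pos - 1L)
  sites$covering <- covering
  sites$skey <- paste(sites$chrom, sites$pos, sep = ":")
  # votes: one per (lab, exact call key), restricted to labs covering the site
  all_v$skey <- paste(all_v$chrom, all_v$pos, sep = ":")
  cov_at <- setNames(sites$covering, sites$skey)
  lab_covers <- matrix(FALSE, nrow(sites), length(submissions))
  for (i in seq_along(submissions))
    lab_covers[, i] <- region_covers(submissions[[i]]$roi, sites$chrom, sites$pos - 1L)
  rownames(lab_covers) <- sites$skey
  voting <- all_v[lab_covers[cbind(match(all_v$skey, sites$skey), all_v$lab)], ,
                  drop = FALSE]
  if (nrow(voting) == 0L)
    return(truth_set(variant_tbl(), provenance = "consensus"))
  voting$ckey <- call_key(voting, genotype = gk)
  voting <- voting[!duplicated(paste(voting$lab, voting$ckey)), , drop = FALSE]
  agree <- table(voting$ckey)
  first <- voting[!duplicated(voting$ckey), , drop = FALSE]
  first$agreeing_labs <- as.integer(agree[first$ckey])
  first$covering_labs <- as.integer(cov_at[first$skey])
  keep <- first$covering_labs >= params$min_participants &
    meets_agreement(first$agreeing_labs, first$covering_labs, params)
  out <- first[keep, , drop = FALSE]
  v <- variant_tbl(out$chrom, out$pos, out$ref, out$alt,
                   gt = if (gk) out$gt else NA_character_)
  v$covering_labs <- out$covering_labs
  v$agreeing_labs <- out$agreeing_labs
  truth_set(v, provenance = "consensus")
}

#' Construct the assessable region under a scheme/year policy
#'
#' Four policies are supported:
#' \describe{
#'   \item{`germline_exon2bp`}{protein-coding exons extended by
#'     `exon_extension_bp` into the introns (the two essential splice bases).}
#'   \item{`germline_consensus_exon2bp`}{only the exons containing at least
#'     one consensus-variant start, extended the same way.}
#'   \item{`somatic_exact`}{the exact REF spans of the truth variants, no
#'     extension.}
#'   \item{`somatic_proximity`}{one submission's ROI with any region further
#'     than `somatic_proximity_bp` from the nearest variant reported by that
#'     lab removed (corrects over-declared ROIs).}
#' }
#'
#' @param policy one of the four policy names
#' @param exons exon annotation [region_set()] (germline policies)
#' @param variants a [variant_tbl()]: consensus variants
#'   (`germline_consensus_exon2bp`), truth variants (`somatic_exact`) or the
#'   lab's own reported variants (`somatic_proximity`)
#' @param roi the lab's declared ROI (`somatic_proximity` only)
#' @param params a [consensus_params()]
#' @return a [region_set()]
#' @export
build_assessable <- function(policy = c("germline_exon2bp",
                                        "germline_consensus_exon2bp",
                                        "somatic_exact", "somatic_proximity"),
                             exons = NULL, variants = NULL, roi = NULL,
                             params = consensus_params()) {
  policy <- match.arg(policy)
  ext <- params$exon_extension_bp
  switch(policy,
    germline_exon2bp = {
      if (is.null(exons)) stop("exon annotation required for germline policies")
      region_extend(exons, ext)
    },
    germline_consensus_exon2bp = {
      if (is.null(exons)) stop("exon annotation required for germline policies")
      if (is.null(variants)) stop("consensus variants required")
      if (nrow(variants) == 0L || nrow(exons) == 0L) return(region_set())
      has <- logical(nrow(exons))
      for (i in seq_len(nrow(exons)))
        has[i] <- any(variants$chrom == exons$chrom[i] &
                      variants$pos - 1L >= exons$start[i] &
                      variants$pos - 1L < exons$end[i])
      sel <- exons[has, , drop = FALSE]
      class(sel) <- c("region_set", "data.frame")
      region_extend(sel, ext)
    },
    somatic_exact = {
      if (is.null(variants)) stop("truth variants required")
      if (nrow(variants) == 0L) return(region_set())
      region_set(variants$chrom, variants$pos - 1L,
                 variants$pos - 1L + nchar(variants$ref))
    },
    somatic_proximity = {
      if (is.null(variants) || is.null(roi))
        stop("reported variants and ROI required")
      if (nrow(variants) == 0L) return(region_set())
      prox <- region_set(variants$chrom,
                         pmax(0L, variants$pos - 1L - params$somatic_proximity_bp),
                         variants$pos - 1L + nchar(variants$ref) +
                           params$somatic_proximity_bp)
      region_intersect(roi, prox)
    })
}

strong_consensus <- function(cov, agr, params) {
  !is.na(cov) & !is.na(agr) & cov >= params$min_participants &
    meets_agreement(agr, cov, params)
}

#' Merge a pre-established EQA truth set with the participant consensus
#'
#' The 2016 rule: variants are primarily compared against the EQA truth set,
#' but where the two sources differ at a site and the consensus is strong
#' (at least `min_participants` covering labs with at least
#' `agreement_fraction` agreement) the consensus call replaces the EQA call.
#' Sites unique to the EQA truth are kept (fall-back); sites unique to the
#' consensus are kept only when strong — weak-consensus-only sites are
#' excluded and listed in the `weak_excluded` attribute. Idempotent.
#'
#' @param eqa a [truth_set()] with provenance `eqa` (or `merged`)
#' @param consensus a [truth_set()] carrying support counts
#' @param params a [consensus_params()]
#' @return a [truth_set()] with provenance `merged`; assessable region taken
#'   from `eqa`
#' @export
merge_truth <- function(eqa, consensus, params = consensus_params()) {
  ev <- eqa$variants; cv <- consensus$variants
  ekey <- paste(ev$chrom, ev$pos, sep = ":")
  ckey <- paste(cv$chrom, cv$pos, sep = ":")
  strong <- strong_consensus(cv$covering_labs, cv$agreeing_labs, params)
  keep_rows <- list()
  weak_rows <- list()
  for (s in unique(c(ekey, ckey))) {
    ei <- which(ekey == s); ci <- which(ckey == s)
    if (length(ei) && length(ci)) {
      same <- setequal(call_key(ev[ei, , drop = FALSE], TRUE),
                       call_key(cv[ci, , drop = FALSE], TRUE))
      if (!same && all(strong[ci])) keep_rows[[s]] <- cv[ci, , drop = FALSE]
      else keep_rows[[s]] <- ev[ei, , drop = FALSE]
    } else if (length(ei)) {
      keep_rows[[s]] <- ev[ei, , drop = FALSE]
    } else {
      if (all(strong[ci])) keep_rows[[s]] <- cv[ci, , drop = FALSE]
      else weak_rows[[s]] <- cv[ci, , drop = FALSE]
    }
  }
  v <- do.call(rbind, keep_rows)
  if (is.null(v)) v <- variant_tbl()
  class(v) <- c("variant_tbl", "data.frame")
  weak_only <- do.call(rbind, weak_rows)
  if (is.null(weak_only)) weak_only <- variant_tbl()
  class(weak_only) <- c("variant_tbl", "data.frame")
  out <- truth_set(v, assessable = eqa$assessable, provenance = "merged")
  attr(out, "weak_excluded") <- weak_only
  out
}
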