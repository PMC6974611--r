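#' Synthetic EQA cohorts
#'
#' Generates a reference genome with engineered repeat tracts, an exon
#' annotation, a planted truth set, and a cohort of lab submissions with
#' controllable false-negative/false-positive behaviour and representation
#' quirks (padded MNPs, right-shifted indels, multi-allelic records), so the
#' consensus, concordance and QC machinery is testable without participant
#' data. All generators are deterministic under a fixed seed.
#'
#' @name synthetic_cohort
NULL

#' Generate a synthetic reference with exon annotation
#'
#' Chromosome sequences are uniform random bases with homopolymer and
#' dinucleotide repeat tracts planted every ~500 bp so that indel
#' left-alignment is genuinely exercised. Exons are `exon_length` windows
#' kept independently with probability `exon_density`, leaving a margin at
#' the chromosome ends.
#'
#' @param seed RNG seed
#' @param n_chrom number of chromosomes (named `"1"`, `"2"`, ...)
#' @param length_per_chrom chromosome length in bp (>= 1000)
#' @param exon_density probability a window becomes an exon
#' @param exon_length exon window size in bp
#' @return list of class `sim_scaffold`: `sequences` (named character),
#'   `exons` ([region_set()]), `seed`
#' @export
generate_reference <- function(seed, n_chrom = 1L, length_per_chrom = 100000L,
                               exon_density = 0.2, exon_length = 150L) {
  stopifnot(length_per_chrom >= 1000L, exon_density >= 0, exon_density <= 1)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  sequences <- character(n_chrom)
  names(sequences) <- as.character(seq_len(n_chrom))
  ex_chrom <- character(); ex_start <- integer(); ex_end <- integer()
  for (ci in seq_len(n_chrom)) {
    s <- sample(bases, length_per_chrom, replace = TRUE)
    # repeat tracts every ~500 bp: homopolymers (6-12) or dinucleotide units (3-8)
    for (anchor in seq(250L, length_per_chrom - 50L, by = 500L)) {
      at <- anchor + sample.int(100L, 1L)
      if (runif(1) < 0.5) {
        len <- sample(6:12, 1L)
        s[at:(at + len - 1L)] <- sample(bases, 1L)
      } else {
        unit <- sample(bases, 2L, replace = FALSE)
        n_units <- sample(3:8, 1L)
        s[at:(at + 2L * n_units - 1L)] <- rep(unit, n_units)
      }
    }
    sequences[ci] <- paste(s, collapse = "")
    margin <- 200L
    starts <- seq(margin, length_per_chrom - margin - exon_length,
                  by = exon_length)
    keep <- runif(length(starts)) < exon_density
    ex_chrom <- c(ex_chrom, rep(names(sequences)[ci], sum(keep)))
    ex_start <- c(ex_start, as.integer(starts[keep]))
    ex_end <- c(ex_end, as.integer(starts[keep] + exon_length))
  }
  exons <- if (length(ex_start)) region_set(ex_chrom, ex_start, ex_end)
           else region_set()
  structure(list(sequences = sequences, exons = exons, seed = seed,
                 exon_length = as.integer(exon_length)),
            class = "sim_scaffold")
}

ref_base_at <- function(sequences, chrom, pos) substr(sequences[[chrom]], pos, pos)

# Skewed indel length sampler: geometric, clamped to the requested range;
# p chosen so the median matches `median_target` (default echoes the 2016
# germline truth-set shape: median 3 bp, maximum 35 bp).
sample_indel_len <- function(n, range = c(1L, 35L), median_target = 3L) {
  p <- 1 - 0.5^(1 / median_target)
  pmin(pmax(rgeom(n, p) + 1L, range[1]), range[2])
}

#' Plant a ground-truth variant set on the scaffold
#'
#' SNPs and indels are placed at exonic starts (indels on a coarse grid, at
#' least 30 bp into their exon so left-alignment cannot shift them out),
#' with no two variants sharing or overlapping starts. Indels are stored
#' left-aligned, i.e. in their canonical truth representation. Germline
#' variants get het/hom-alt genotypes; somatic variants get allele
#' fractions.
#'
#' @param scaffold a `sim_scaffold` from [generate_reference()]
#' @param n_snp,n_indel exact variant counts to plant
#' @param indel_len_range inclusive indel length bounds (default 1-35 bp)
#' @param indel_len_median target median indel length (default 3 bp)
#' @param scheme `"germline"` or `"somatic"`
#' @param seed RNG seed
#' @param het_prob probability a germline variant is heterozygous
#' @return list of class `sim_truth`: scaffold fields plus `variants`
#'   (a [variant_tbl()]) and `scheme`
#' @export
plant_truth_variants <- function(scaffold, n_snp, n_indel,
                                 indel_len_range = c(1L, 35L),
                                 indel_len_median = 3L,
                                 scheme = c("germline", "somatic"),
                                 seed = scaffold$seed + 1L, het_prob = 0.6) {
  scheme <- match.arg(scheme)
  set.seed(seed)
  ex <- scaffold$exons
  if (nrow(ex) == 0L) stop("scaffold has no exons")
  bases <- c("A", "C", "G", "T")
  # 0-based exonic positions per chromosome
  exonic <- do.call(rbind, lapply(seq_len(nrow(ex)), function(i) {
    data.frame(chrom = ex$chrom[i], pos0 = seq(ex$start[i], ex$end[i] - 1L),
               off = seq(ex$start[i], ex$end[i] - 1L) - ex$start[i],
               stringsAsFactors = FALSE)
  }))
  pad <- indel_len_range[2] + 25L
  grid <- exonic[exonic$off >= 30L & exonic$pos0 %% 50L == 0L, , drop = FALSE]
  if (nrow(grid) < n_indel) stop("not enough exonic space for requested indels")
  gi <- grid[sample.int(nrow(grid), n_indel), , drop = FALSE]
  blocked <- rep(FALSE, nrow(exonic))
  ekey <- paste(exonic$chrom, exonic$pos0)
  for (i in seq_len(nrow(gi))) {
    w <- paste(gi$chrom[i], (gi$pos0[i] - pad):(gi$pos0[i] + pad))
    blocked[ekey %in% w] <- TRUE
  }
  snp_pool <- exonic[!blocked & exonic$pos0 %% 2L == 0L, , drop = FALSE]
  if (nrow(snp_pool) < n_snp) stop("not enough exonic space for requested SNPs")
  si <- snp_pool[sample.int(nrow(snp_pool), n_snp), , drop = FALSE]

  rows <- vector("list", n_snp + n_indel)
  for (i in seq_len(n_snp)) {
    pos <- si$pos0[i] + 1L
    refb <- ref_base_at(scaffold$sequences, si$chrom[i], pos)
    altb <- sample(setdiff(bases, refb), 1L)
    rows[[i]] <- list(chrom = si$chrom[i], pos = pos, ref = refb, alt = altb)
  }
  lens <- sample_indel_len(n_indel, indel_len_range, indel_len_median)
  for (i in seq_len(n_indel)) {
    pos <- gi$pos0[i] + 1L
    chrom <- gi$chrom[i]
    anchor <- ref_base_at(scaffold$sequences, chrom, pos)
    if (runif(1) < 0.5) {  # deletion of lens[i] bases after the anchor
      ref <- substr(scaffold$sequences[[chrom]], pos, pos + lens[i])
      la <- left_align_auto(chrom, pos, ref, anchor, scaffold$sequences)
    } else {               # insertion of lens[i] random bases after the anchor
      ins <- paste(sample(bases, lens[i], replace = TRUE), collapse = "")
      la <- left_align_auto(chrom, pos, anchor, paste0(anchor, ins),
                            scaffold$sequences)
    }
    rows[[n_snp + i]] <- list(chrom = chrom, pos = la$pos, ref = la$ref,
                              alt = la$alt)
  }
  v <- variant_tbl(chrom = vapply(rows, `[[`, character(1), "chrom"),
                   pos = vapply(rows, function(r) r$pos, numeric(1)),
                   ref = vapply(rows, `[[`, character(1), "ref"),
                   alt = vapply(rows, `[[`, character(1), "alt"))
  if (scheme == "germline") {
    v$gt <- ifelse(runif(nrow(v)) < het_prob, "het", "hom_alt")
  } else {
    v$gt <- "unknown"
    v$af <- round(runif(nrow(v), 0.05, 1), 3)
  }
  dup <- duplicated(paste(v$chrom, v$pos))
  if (any(dup)) v <- v[!dup, , drop = FALSE]  # left-align collisions (rare)
  v <- sort_variants(v)
  structure(c(scaffold, list(variants = v, scheme = scheme)),
            class = "sim_truth")
}

#' Laboratory error/representation profile
#'
#' @param roi_fraction fraction of exons in this lab's ROI
#' @param fn_rate per-variant miss probability (ignored when `drop_sites`
#'   is given)
#' @param fp_rate expected spurious calls per kb of ROI
#' @param genotype_error_rate probability a kept germline call gets the
#'   wrong genotype class
#' @param quirk_mnp probability a SNP is emitted as a padded MNP record
#' @param quirk_rightshift probability an indel is emitted right-shifted
#'   within its repeat tract
#' @param quirk_multiallelic probability a het SNP record carries an extra
#'   uncalled artifact ALT (GT stays 0/1)
#' @param seed per-lab RNG seed
#' @param drop_sites optional integer indices into the truth variants this
#'   lab misses (deterministic-drop mode, used for exact threshold tests)
#' @param spurious optional [variant_tbl()] of spurious calls to emit
#'   verbatim instead of random ones
#' @return list of class `lab_profile`
#' @export
lab_profile <- function(roi_fraction = 1, fn_rate = 0, fp_rate = 0,
                        genotype_error_rate = 0, quirk_mnp = 0,
                        quirk_rightshift = 0, quirk_multiallelic = 0,
                        seed = 1L, drop_sites = NULL, spurious = NULL) {
  rates <- c(roi_fraction, fn_rate, genotype_error_rate, quirk_mnp,
             quirk_rightshift, quirk_multiallelic)
  stopifnot(all(rates >= 0 & rates <= 1), fp_rate >= 0)
  structure(list(roi_fraction = roi_fraction, fn_rate = fn_rate,
                 fp_rate = fp_rate, genotype_error_rate = genotype_error_rate,
                 quirk_mnp = quirk_mnp, quirk_rightshift = quirk_rightshift,
                 quirk_multiallelic = quirk_multiallelic, seed = as.integer(seed),
                 drop_sites = drop_sites, spurious = spurious),
            class = "lab_profile")
}

# write raw (possibly quirky/multi-allelic) records as a valid VCF
write_raw_vcf <- function(recs, path, germline) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele fraction\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (germline) cols <- c(cols, "FORMAT", "SAMPLE")
  if (length(recs)) {
    ord <- order(vapply(recs, `[[`, character(1), "chrom"),
                 vapply(recs, function(r) r$pos, numeric(1)))
    recs <- recs[ord]
  }
  lines <- vapply(recs, function(r) {
    info <- if (!is.null(r$af) && !is.na(r$af))
      paste0("AF=", paste(format(r$af, digits = 4), collapse = ",")) else "."
    f <- c(r$chrom, r$pos, ".", r$ref, paste(r$alt, collapse = ","),
           if (is.null(r$qual) || is.na(r$qual)) "." else format(r$qual, digits = 6),
           "PASS", info)
    if (germline) f <- c(f, "GT", r$gt)
    paste(f, collapse = "\t")
  }, character(1))
  writeLines(c(hdr, paste(cols, collapse = "\t"), lines), path)
  invisible(path)
}

gt_string <- c(het = "0/1", hom_alt = "1/1", het_other = "0/1",
               hemi_alt = "1", unknown = "./.")

#' Simulate one lab's submission (VCF + BED on disk)
#'
#' The lab's ROI is a random exon subset of the requested fraction plus
#' 2 bp flanks. Kept calls are truth-in-ROI minus drops (Bernoulli
#' `fn_rate`, or the deterministic `drop_sites` list); spurious SNVs are
#' added at `fp_rate` per kb of ROI, uniformly over ROI bases away from
#' truth sites. Representation quirks are applied so that normalization is
#' genuinely exercised; the emitted VCF validates under [validate_vcf()].
#'
#' @param truth a `sim_truth`
#' @param profile a [lab_profile()]
#' @param participant_id lab identifier
#' @param dir output directory (created if needed)
#' @return list with `vcf`, `bed`, `participant_id`, `n_dropped`,
#'   `n_spurious`, `profile`
#' @export
simulate_submission <- function(truth, profile, participant_id, dir) {
  set.seed(profile$seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  germline <- truth$scheme == "germline"
  ex <- truth$exons
  n_take <- max(1L, round(profile$roi_fraction * nrow(ex)))
  sel <- sort(sample.int(nrow(ex), n_take))
  roi <- region_extend(canonicalize_regions(as.data.frame(ex)[sel, , drop = FALSE]), 2L)

  tv <- truth$variants
  in_roi <- which(region_covers(roi, tv$chrom, tv$pos - 1L))
  if (!is.null(profile$drop_sites)) {
    kept_idx <- setdiff(in_roi, profile$drop_sites)
  } else {
    kept_idx <- in_roi[runif(length(in_roi)) >= profile$fn_rate]
  }
  kept <- tv[kept_idx, , drop = FALSE]
  n_dropped <- length(in_roi) - length(kept_idx)

  if (germline && profile$genotype_error_rate > 0 && nrow(kept)) {
    flip <- runif(nrow(kept)) < profile$genotype_error_rate
    kept$gt[flip] <- ifelse(kept$gt[flip] == "het", "hom_alt", "het")
  }

  # spurious calls: uniform over ROI bases excluding truth-site neighbourhoods
  if (!is.null(profile$spurious)) {
    spur <- profile$spurious
  } else {
    n_fp <- rpois(1, profile$fp_rate * region_width(roi) / 1000)
    spur <- variant_tbl()
    if (n_fp > 0) {
      roi_pos <- do.call(rbind, lapply(seq_len(nrow(roi)), function(i)
        data.frame(chrom = roi$chrom[i], pos0 = seq(roi$start[i], roi$end[i] - 1L),
                   stringsAsFactors = FALSE)))
      near_truth <- paste(roi_pos$chrom, roi_pos$pos0) %in%
        unlist(lapply(-40:40, function(d) paste(tv$chrom, tv$pos - 1L + d)))
      pool <- roi_pos[!near_truth, , drop = FALSE]
      pick <- pool[sample.int(nrow(pool), min(n_fp, nrow(pool))), , drop = FALSE]
      pick <- pick[!duplicated(paste(pick$chrom, pick$pos0)), , drop = FALSE]
      refb <- vapply(seq_len(nrow(pick)), function(i)
        ref_base_at(truth$sequences, pick$chrom[i], pick$pos0[i] + 1L), character(1))
      ok <- refb %in% c("A", "C", "G", "T")
      pick <- pick[ok, , drop = FALSE]; refb <- refb[ok]
      altb <- vapply(refb, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                     character(1), USE.NAMES = FALSE)
      spur <- variant_tbl(pick$chrom, pick$pos0 + 1L, refb, altb,
                          gt = if (germline)
                            sample(c("het", "hom_alt"), nrow(pick), TRUE, c(0.7, 0.3))
                          else "unknown",
                          af = if (germline) NA_real_ else round(runif(nrow(pick), 0.05, 0.5), 3))
    }
  }

  emit <- rbind(as.data.frame(kept), as.data.frame(spur))
  recs <- lapply(seq_len(nrow(emit)), function(i) {
    r <- list(chrom = emit$chrom[i], pos = emit$pos[i], ref = emit$ref[i],
              alt = emit$alt[i], gt = gt_string[[emit$gt[i]]],
              qual = round(runif(1, 30, 90), 1),
              af = if (germline) NA_real_ else emit$af[i])
    cls <- classify_alleles(r$ref, r$alt)
    if (cls == "snp") {
      if (germline && !is.na(emit$gt[i]) && emit$gt[i] == "het" &&
          runif(1) < profile$quirk_multiallelic) {
        art <- sample(setdiff(c("A", "C", "G", "T"), c(r$ref, r$alt)), 1L)
        r$alt <- c(r$alt, art)  # uncalled artifact allele, GT stays 0/1
      } else if (runif(1) < profile$quirk_mnp) {
        nb <- ref_base_at(truth$sequences, r$chrom, r$pos + 1L)
        if (nzchar(nb)) { r$ref <- paste0(r$ref, nb); r$alt <- paste0(r$alt, nb) }
      }
    } else if (cls %in% c("insertion", "deletion") &&
               runif(1) < profile$quirk_rightshift) {
      rs <- right_shift_indel(r$pos, r$ref, r$alt, truth$sequences, r$chrom)
      r$pos <- rs$pos; r$ref <- rs$ref; r$alt <- rs$alt
    }
    r
  })
  vcf <- file.path(dir, paste0(participant_id, ".vcf"))
  bed <- file.path(dir, paste0(participant_id, ".bed"))
  write_raw_vcf(recs, vcf, germline)
  write_bed(roi, bed)
  list(vcf = vcf, bed = bed, participant_id = participant_id,
       n_dropped = n_dropped, n_spurious = nrow(spur), profile = profile)
}

#' Simulate a cohort of lab submissions
#'
#' Writes one VCF+BED pair per lab plus a JSON manifest recording every
#' profile, seed and file checksum; the cohort is reproducible from the
#' manifest.
#'
#' @param truth a `sim_truth`
#' @param n_labs number of labs (>= 1)
#' @param profile a [lab_profile()] template; per-lab seeds are derived from
#'   `seed`
#' @param seed cohort seed
#' @param dir output directory
#' @param drop_plan optional list (length `n_labs`) of truth-variant index
#'   vectors: deterministic per-lab drop lists
#' @return manifest list (also written to `dir/manifest.json`)
#' @export
simulate_cohort <- function(truth, n_labs, profile = lab_profile(),
                            seed = truth$seed, dir = tempfile("cohort"),
                            drop_plan = NULL) {
  stopifnot(n_labs >= 1L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labs <- vector("list", n_labs)
  for (i in seq_len(n_labs)) {
    p <- profile
    p$seed <- (seed %% 1000000L) * 1000L + i
    if (!is.null(drop_plan)) p$drop_sites <- drop_plan[[i]]
    labs[[i]] <- simulate_submission(truth, p,
                                     participant_id = sprintf("lab%02d", i),
                                     dir = dir)
  }
  manifest <- list(
    scheme = truth$scheme, seed = seed, n_labs = n_labs,
    labs = lapply(labs, function(l) list(
      participant_id = l$participant_id, vcf = l$vcf, bed = l$bed,
      vcf_md5 = unname(tools::md5sum(l$vcf)),
      bed_md5 = unname(tools::md5sum(l$bed)),
      seed = l$profile$seed, n_dropped = l$n_dropped,
      n_spurious = l$n_spurious)),
    profile = profile[c("roi_fraction", "fn_rate", "fp_rate",
                        "genotype_error_rate", "quirk_mnp",
                        "quirk_rightshift", "quirk_multiallelic")])
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a simulated cohort back as submissions
#'
#' @param manifest manifest list from [simulate_cohort()] (or path to
#'   `manifest.json`)
#' @param sequences reference sequences for normalization
#' @return list of `eqa_submission`
#' @export
read_cohort <- function(manifest, sequences = NULL) {
  if (is.character(manifest))
    manifest <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  lapply(manifest$labs, function(l)
    read_submission(l$vcf, l$bed, participant_id = l$participant_id,
                    scheme = manifest$scheme, sequences = sequences))
}

#' Read and write reference FASTA
#'
#' Thin wrappers over Biostrings keeping the package's internal
#' representation (a named character vector of chromosome sequences).
#'
#' @param sequences named character vector of chromosome sequences
#' @param path FASTA path
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' @rdname write_fasta
#' @param chrom_dialect see [canonical_chrom()]
#' @export
read_fasta <- function(path, chrom_dialect = "strip") {
  x <- Biostrings::readDNAStringSet(path)
  s <- as.character(x)
  names(s) <- canonical_chrom(sub("\\s.*$", "", names(x)), chrom_dialect)
  s
}
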