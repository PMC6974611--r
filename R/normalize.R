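#' Variant normalization
#'
#' Before voting or comparison every submitted record is reduced to a
#' canonical form so that equivalent calls compare equal across pipelines:
#' multi-allelic records are decomposed, MNPs are split into SNPs, alleles
#' are trimmed to their minimal representation, and indels are left-aligned
#' against the reference. `normalize_record()` composes the four steps.
#'
#' @name normalization
NULL

new_raw_record <- function(chrom, pos, ref, alt, gt = NA_character_,
                           qual = NA_real_, filter = NA_character_,
                           af = NA_real_) {
  list(chrom = as.character(chrom), pos = as.integer(pos),
       ref = toupper(as.character(ref)), alt = toupper(as.character(alt)),
       gt = gt, qual = as.numeric(qual), filter = filter, af = as.numeric(af))
}

is_sequence_allele <- function(a) grepl("^[ACGTN]+$", a)

#' Decompose a multi-allelic record into single-ALT records
#'
#' One output record per ALT allele, in ALT order; the genotype is recoded
#' per output via [genotype_class()] (other ALTs become the "other non-ref"
#' marker). Symbolic ALTs (`<DEL>`, breakends, `*`) are rejected with a
#' `non-sequence ALT` diagnostic; the remaining ALTs are still emitted.
#'
#' @param record a raw record as produced by the VCF reader: a list with
#'   `chrom`, `pos`, `ref`, `alt` (character vector, >= 1 allele), optional
#'   `gt`, `qual`, `af`
#' @return list with `records` (list of single-ALT raw records, each with a
#'   `gt_class` field) and `rejected` (data.frame of alt/reason)
#' @export
decompose_multiallelic <- function(record) {
  stopifnot(length(record$alt) >= 1L)
  ok <- is_sequence_allele(record$alt)
  rejected <- if (all(ok)) data.frame(alt = character(), reason = character(),
                                      stringsAsFactors = FALSE)
  else data.frame(alt = record$alt[!ok], reason = "non-sequence ALT",
                  stringsAsFactors = FALSE)
  recs <- lapply(which(ok), function(i) {
    r <- record
    r$alt <- record$alt[i]
    r$gt_class <- genotype_class(if (is.null(record$gt)) NA_character_ else record$gt, i)
    r
  })
  list(records = recs, rejected = rejected)
}

#' Split an MNP into SNPs
#'
#' A same-length multi-base substitution emits one SNP per offset where the
#' REF and ALT bases differ, at `pos + offset`, inheriting the genotype;
#' matching offsets emit nothing.
#'
#' @param chrom,pos,ref,alt the single-ALT variant (`nchar(ref) == nchar(alt)`)
#' @return data.frame with columns `pos`, `ref`, `alt` (one row per SNP)
#' @export
split_mnp <- function(chrom, pos, ref, alt) {
  if (nchar(ref) != nchar(alt)) stop("not an MNP: ref and alt lengths differ")
  rb <- strsplit(ref, "")[[1]]; ab <- strsplit(alt, "")[[1]]
  i <- which(rb != ab)
  data.frame(pos = pos + i - 1L, ref = rb[i], alt = ab[i],
             stringsAsFactors = FALSE)
}

#' Trim an allele pair to minimal representation
#'
#' The shared suffix is trimmed first, then the shared prefix, always keeping
#' at least one base in each allele (the VCF anchor base for indels). The
#' position advances by the number of prefix bases trimmed. Suffix-first
#' order matters for complex alleles and matches the dominant convention, so
#' consensus keys are stable across labs.
#'
#' @param pos,ref,alt the single-ALT variant; `ref != alt` required
#' @return list with `pos`, `ref`, `alt`
#' @export
minimal_representation <- function(pos, ref, alt) {
  if (ref == alt) stop("null variant: ref == alt")
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref)); alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = ref, alt = alt)
}

#' Reference context window
#'
#' A slice of reference sequence covering the shifting window of a variant,
#' used by [left_align()]. `window_start` is 1-based.
#'
#' @param chrom chromosome name
#' @param window_start 1-based start of the slice
#' @param sequence the reference bases of the slice
#' @return list of class `ref_context`
#' @export
ref_context <- function(chrom, window_start, sequence) {
  stopifnot(nchar(sequence) >= 1L, window_start >= 1L)
  structure(list(chrom = chrom, window_start = as.integer(window_start),
                 sequence = toupper(sequence)), class = "ref_context")
}

ctx_base <- function(ctx, pos) {
  i <- pos - ctx$window_start + 1L
  if (i < 1L || i > nchar(ctx$sequence)) return(NA_character_)
  substr(ctx$sequence, i, i)
}

insufficient_context <- function(msg = "insufficient reference context") {
  stop(structure(class = c("insufficient_context", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Left-align an indel against the reference
#'
#' Returns the unique leftmost minimal representation producing an identical
#' alternate haplotype. SNPs and complex substitutions are returned
#' unchanged; the operation is idempotent. If the context window is too
#' small to prove the leftmost placement, an error of class
#' `insufficient_context` is raised (callers typically refetch a doubled
#' window, see [normalize_record()]).
#'
#' @param pos,ref,alt minimally represented single-ALT variant
#' @param ctx a [ref_context()] covering the shift window
#' @return list with `pos`, `ref`, `alt`
#' @export
left_align <- function(pos, ref, alt, ctx) {
  cls <- classify_alleles(ref, alt)
  if (cls %in% c("snp", "complex")) return(list(pos = pos, ref = ref, alt = alt))
  span <- vapply(seq_len(nchar(ref)), function(i) ctx_base(ctx, pos + i - 1L),
                 character(1))
  if (anyNA(span)) insufficient_context("context does not cover the REF span")
  if (paste(span, collapse = "") != ref)
    stop(sprintf("REF '%s' at %s:%d does not match the reference context",
                 ref, ctx$chrom, pos))
  repeat {
    changed <- FALSE
    if (substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
      ref <- substr(ref, 1L, nchar(ref) - 1L)
      alt <- substr(alt, 1L, nchar(alt) - 1L)
      changed <- TRUE
    }
    if (nchar(ref) == 0L || nchar(alt) == 0L) {
      b <- ctx_base(ctx, pos - 1L)
      if (is.na(b)) insufficient_context()
      ref <- paste0(b, ref); alt <- paste0(b, alt)
      pos <- pos - 1L
      changed <- TRUE
    }
    if (!changed) break
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref)); alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = ref, alt = alt)
}

# Fetch context in doubling windows (64 bp, 128, ...) until left_align no
# longer reports an insufficient window; avoids unbounded reads on long
# homopolymers. `sequences` is a named character vector of chromosomes.
left_align_auto <- function(chrom, pos, ref, alt, sequences, start_bp = 64L) {
  if (!chrom %in% names(sequences))
    stop(sprintf("chromosome '%s' absent from reference", chrom))
  seqlen <- nchar(sequences[[chrom]])
  win <- as.integer(start_bp)
  repeat {
    ws <- max(1L, pos - win)
    we <- min(seqlen, pos + nchar(ref) + 1L)
    ctx <- ref_context(chrom, ws, substr(sequences[[chrom]], ws, we))
    res <- tryCatch(left_align(pos, ref, alt, ctx),
                    insufficient_context = function(e) NULL)
    if (!is.null(res)) return(res)
    if (ws == 1L) insufficient_context("shift reached chromosome start")
    win <- win * 2L
  }
}

#' Fully normalize a raw VCF record
#'
#' Composes [decompose_multiallelic()], [minimal_representation()],
#' [split_mnp()] and [left_align()] (when a reference is supplied), returning
#' variants sorted by (chrom, pos, ref, alt) and deduplicated. Applying
#' `normalize_record` to its own output is the identity.
#'
#' @param record raw record (list with `chrom`, `pos`, `ref`, `alt` vector,
#'   optional `gt`, `qual`, `af`)
#' @param sequences optional named character vector of reference chromosome
#'   sequences; when absent, indels are kept as submitted (minimal
#'   representation only) and flagged in the result
#' @param chrom_dialect chromosome-name dialect, see [canonical_chrom()]
#' @return list with `variants` (a [variant_tbl()]) and `rejected`
#'   (data.frame of alt/reason)
#' @export
normalize_record <- function(record, sequences = NULL, chrom_dialect = "strip") {
  record$chrom <- canonical_chrom(record$chrom, chrom_dialect)
  if (!is_sequence_allele(record$ref)) {
    return(list(variants = variant_tbl(),
                rejected = data.frame(alt = paste(record$alt, collapse = ","),
                                      reason = "non-sequence REF",
                                      stringsAsFactors = FALSE)))
  }
  dec <- decompose_multiallelic(record)
  rejected <- dec$rejected
  rows <- list()
  for (r in dec$records) {
    if (r$ref == r$alt) {
      rejected <- rbind(rejected, data.frame(alt = r$alt, reason = "null variant",
                                             stringsAsFactors = FALSE))
      next
    }
    m <- minimal_representation(r$pos, r$ref, r$alt)
    if (nchar(m$ref) == nchar(m$alt) && nchar(m$ref) > 1L) {
      sn <- split_mnp(r$chrom, m$pos, m$ref, m$alt)
      rows[[length(rows) + 1L]] <-
        variant_tbl(r$chrom, sn$pos, sn$ref, sn$alt,
                    gt = r$gt_class, af = r$af, qual = r$qual)
    } else {
      if (!is.null(sequences) && classify_alleles(m$ref, m$alt) %in%
          c("insertion", "deletion")) {
        m <- left_align_auto(r$chrom, m$pos, m$ref, m$alt, sequences)
      }
      rows[[length(rows) + 1L]] <-
        variant_tbl(r$chrom, m$pos, m$ref, m$alt,
                    gt = r$gt_class, af = r$af, qual = r$qual)
    }
  }
  v <- if (length(rows)) do.call(rbind, rows) else variant_tbl()
  class(v) <- c("variant_tbl", "data.frame")
  v <- sort_variants(v)
  v <- v[!duplicated(call_key(v, genotype = TRUE)), , drop = FALSE]
  rownames(v) <- NULL
  list(variants = v, rejected = rejected)
}

# Mirror of left alignment: shift an indel to a (random) non-leftmost
# equivalent placement within its repeat tract. Generator helper used to
# emit the "right-shifted indel" representation quirk.
right_shift_indel <- function(pos, ref, alt, sequences, chrom, max_shift = 30L) {
  cls <- classify_alleles(ref, alt)
  if (!cls %in% c("insertion", "deletion")) return(list(pos = pos, ref = ref, alt = alt))
  seqc <- sequences[[chrom]]
  seqlen <- nchar(seqc)
  # drop the anchor: 'seg' is the inserted/deleted segment starting at pos+1
  seg <- if (cls == "deletion") substr(ref, 2L, nchar(ref)) else substr(alt, 2L, nchar(alt))
  shifted <- 0L
  while (shifted < max_shift) {
    nxt <- pos + 1L + (if (cls == "deletion") nchar(seg) else 0L)
    if (nxt > seqlen) break
    if (substr(seqc, nxt, nxt) != substr(seg, 1L, 1L)) break
    # rotate the segment one base right
    seg <- paste0(substr(seg, 2L, nchar(seg)), substr(seg, 1L, 1L))
    pos <- pos + 1L
    shifted <- shifted + 1L
  }
  anchor <- substr(seqc, pos, pos)
  if (cls == "deletion") list(pos = pos, ref = paste0(anchor, seg), alt = anchor)
  else list(pos = pos, ref = anchor, alt = paste0(anchor, seg))
}
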