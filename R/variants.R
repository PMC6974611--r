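#' Normalized variant tables
#'
#' Variants are carried as plain data.frames with one row per single-ALT,
#' minimally represented call:
#' \describe{
#'   \item{chrom}{chromosome name, canonical dialect}
#'   \item{pos}{1-based position of the first REF base}
#'   \item{ref, alt}{allele strings over A,C,G,T,N}
#'   \item{var_class}{one of `snp`, `insertion`, `deletion`, `complex`}
#'   \item{gt}{genotype class: `het`, `hom_alt`, `het_other`, `hemi_alt`,
#'     `unknown` (somatic calls without GT are `unknown`)}
#'   \item{af}{optional allele fraction in \[0,1\] (`NA` when absent)}
#'   \item{qual}{VCF QUAL (`NA` when missing)}
#'   \item{n_flag}{TRUE when ref or alt contains N (retained but flagged)}
#' }
#'
#' @param chrom,pos,ref,alt,gt,af,qual vectors, recycled to common length
#' @return data.frame with class `variant_tbl`
#' @export
variant_tbl <- function(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        gt = NA_character_, af = NA_real_, qual = NA_real_) {
  n <- max(length(chrom), length(pos), length(ref), length(alt))
  df <- data.frame(chrom = rep_len(as.character(chrom), n),
                   pos = rep_len(as.integer(pos), n),
                   ref = rep_len(toupper(as.character(ref)), n),
                   alt = rep_len(toupper(as.character(alt)), n),
                   gt = rep_len(as.character(gt), n),
                   af = rep_len(as.numeric(af), n),
                   qual = rep_len(as.numeric(qual), n),
                   stringsAsFactors = FALSE)
  if (n == 0L) df$var_class <- character() else
    df$var_class <- classify_alleles(df$ref, df$alt)
  df$n_flag <- grepl("N", df$ref, fixed = TRUE) | grepl("N", df$alt, fixed = TRUE)
  class(df) <- c("variant_tbl", "data.frame")
  df
}

#' Classify a ref/alt allele pair
#'
#' `snp` when both alleles are single differing bases; `insertion`/`deletion`
#' when one allele is the single shared anchor base of the other; `complex`
#' otherwise (length-changing multi-base substitutions are compared as-is).
#'
#' @param ref,alt character vectors of allele strings
#' @return character vector of classes
#' @export
classify_alleles <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  cls <- rep("complex", length(ref))
  cls[nr == 1L & na == 1L & ref != alt] <- "snp"
  ins <- nr == 1L & na > 1L & substr(alt, 1L, 1L) == ref
  del <- na == 1L & nr > 1L & substr(ref, 1L, 1L) == alt
  cls[ins] <- "insertion"
  cls[del] <- "deletion"
  cls
}

#' @export
print.variant_tbl <- function(x, ...) {
  cat(sprintf("variant_tbl: %d variant(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

sort_variants <- function(v) {
  if (nrow(v) == 0L) return(v)
  v <- v[order(v$chrom, v$pos, v$ref, v$alt), , drop = FALSE]
  rownames(v) <- NULL
  v
}

#' Call keys for consensus voting and concordance matching
#'
#' The full normalized call key is `chrom:pos:ref:alt` plus the genotype
#' class when `genotype = TRUE` (germline matching); the site key is
#' `chrom:pos:ref`. Two calls agree exactly when their call keys are equal.
#'
#' @param v a `variant_tbl`
#' @param genotype include the genotype class in the key
#' @return character vector of keys
#' @export
call_key <- function(v, genotype = FALSE) {
  k <- paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
  if (genotype) k <- paste(k, ifelse(is.na(v$gt), "unknown", v$gt), sep = ":")
  k
}

#' @rdname call_key
#' @export
site_key <- function(v) paste(v$chrom, v$pos, v$ref, sep = ":")

#' Genotype class of one ALT allele within a VCF GT string
#'
#' Recodes a (possibly multi-allelic) GT for a single decomposed ALT:
#' phasing is ignored; alleles other than the reference and this ALT become
#' the "other non-ref" marker. A GT containing no copy of this ALT maps to
#' `not_present` (the decomposed record is not a call of this allele and is
#' dropped at ingest); a missing or partially missing GT maps to `unknown`.
#'
#' @param gt GT string, e.g. `"0/1"`, `"1|2"`, `"1"`, `"./."` or `NA`
#' @param alt_index 1-based index of the ALT in the record's ALT list
#' @return one of `het`, `hom_alt`, `het_other`, `hemi_alt`, `not_present`,
#'   `unknown`
#' @export
genotype_class <- function(gt, alt_index = 1L) {
  if (is.na(gt) || gt == "") return("unknown")
  al <- strsplit(gt, "[/|]")[[1]]
  if (any(al == ".") || !all(grepl("^[0-9]+$", al))) return("unknown")
  a <- as.integer(al)
  n_alt <- sum(a == alt_index)
  if (n_alt == 0L) return("not_present")
  if (length(a) == 1L) return("hemi_alt")
  if (n_alt == length(a)) return("hom_alt")
  if (any(a != 0L & a != alt_index)) return("het_other")
  "het"
}

#' Canonicalise chromosome names to one dialect
#'
#' Labs mix `"chr1"` and `"1"`; consensus keys and interval arithmetic need a
#' single dialect. The default strips a leading `"chr"`.
#'
#' @param x character vector of chromosome names
#' @param dialect `"strip"` (default, remove `chr` prefix) or `"chr"` (add it)
#' @return character vector
#' @export
canonical_chrom <- function(x, dialect = c("strip", "chr")) {
  dialect <- match.arg(dialect)
  bare <- sub("^chr", "", x)
  if (dialect == "strip") bare else paste0("chr", bare)
}
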