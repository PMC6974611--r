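#' VCF reading, validation and writing
#'
#' Submissions arrive as VCF 4.1/4.2 text. Validation must give immediate,
#' line-level feedback on possibly malformed files, so the reader is a
#' deliberately tolerant line parser that turns problems into diagnostics
#' rather than exceptions.
#'
#' @name vcf_io
NULL

diag_df <- function(severity = character(), line = integer(), message = character()) {
  data.frame(severity = severity, line = as.integer(line), message = message,
             stringsAsFactors = FALSE)
}

add_diag <- function(d, severity, line, message) {
  rbind(d, diag_df(severity, line, message))
}

#' Validate a VCF file
#'
#' Checks the constraints enforced at submission time: a `##fileformat` line
#' declaring VCF 4.1 or 4.2, a `#CHROM` header with the mandatory columns,
#' per-record column counts, numeric POS, allele alphabet (symbolic ALTs are
#' permitted at this stage; they are rejected at normalization), sorted
#' records (warning) and duplicate records (warning). Never raises on
#' arbitrary bytes: every problem becomes a diagnostic row.
#'
#' @param path path to a VCF file
#' @return data.frame with columns `severity` (`"error"`/`"warning"`),
#'   `line`, `message`; zero rows iff the file is acceptable
#' @export
validate_vcf <- function(path) {
  d <- diag_df()
  lines <- suppressWarnings(tryCatch(readLines(path, warn = FALSE),
                                     error = function(e) NULL))
  if (is.null(lines))
    return(add_diag(d, "error", NA_integer_,
                    sprintf("unreadable file: %s", path)))
  if (!length(lines))
    return(add_diag(d, "error", NA_integer_, "empty file"))
  ff <- grep("^##fileformat=", lines)
  if (!length(ff) || ff[1] != 1L) {
    d <- add_diag(d, "error", 1L, "missing ##fileformat line")
  } else {
    ver <- sub("^##fileformat=", "", lines[ff[1]])
    if (!ver %in% c("VCFv4.1", "VCFv4.2"))
      d <- add_diag(d, "error", ff[1],
                    sprintf("unsupported VCF version '%s' (4.1 or 4.2 required)", ver))
  }
  hdr <- grep("^#CHROM\t", lines)
  if (!length(hdr)) {
    d <- add_diag(d, "error", NA_integer_, "missing #CHROM header line")
    return(d)
  }
  hcols <- strsplit(lines[hdr[1]], "\t", fixed = TRUE)[[1]]
  need <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (length(hcols) < 8L || !identical(hcols[1:8], need))
    d <- add_diag(d, "error", hdr[1], "malformed #CHROM header: first 8 columns must be CHROM POS ID REF ALT QUAL FILTER INFO")
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  prev <- list(chrom = NULL, pos = NULL)
  seen <- character()
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L) {
      d <- add_diag(d, "error", i, sprintf("expected >= 8 columns, found %d", length(f)))
      next
    }
    if (!grepl("^[0-9]+$", f[2])) {
      d <- add_diag(d, "error", i, sprintf("non-numeric POS '%s'", f[2]))
      next
    }
    if (!grepl("^[ACGTNacgtn]+$", f[4]))
      d <- add_diag(d, "error", i, sprintf("invalid REF allele '%s'", f[4]))
    alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
    bad <- !grepl("^([ACGTNacgtn]+|<[^>]+>|\\*|\\.|.*\\[.*|.*\\].*)$", alts)
    if (!length(alts) || any(bad))
      d <- add_diag(d, "error", i, sprintf("invalid ALT allele '%s'", f[5]))
    key <- paste(f[1], f[2], f[4], f[5], sep = ":")
    if (key %in% seen)
      d <- add_diag(d, "warning", i, sprintf("duplicate record %s", key))
    seen <- c(seen, key)
    if (!is.null(prev$chrom) && identical(f[1], prev$chrom) &&
        as.numeric(f[2]) < prev$pos)
      d <- add_diag(d, "warning", i, "unsorted records")
    prev <- list(chrom = f[1], pos = as.numeric(f[2]))
  }
  rownames(d) <- NULL
  d
}

# Parse a VCF body into raw records (list per data line). Assumes the file
# passed validate_vcf; malformed lines are skipped.
read_vcf_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#CHROM\t", lines)[1]
  hcols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  has_fmt <- length(hcols) >= 10L
  body <- lines[seq_along(lines) > hdr & nzchar(lines) & !startsWith(lines, "#")]
  lapply(body, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L || !grepl("^[0-9]+$", f[2])) return(NULL)
    gt <- NA_character_
    if (has_fmt && length(f) >= 10L) {
      keys <- strsplit(f[9], ":", fixed = TRUE)[[1]]
      vals <- strsplit(f[10], ":", fixed = TRUE)[[1]]
      gi <- match("GT", keys)
      if (!is.na(gi) && gi <= length(vals)) gt <- vals[gi]
    }
    af <- NA_real_
    m <- regmatches(f[8], regexpr("(?:^|;)AF=([0-9.eE+-]+)", f[8]))
    if (length(m)) af <- suppressWarnings(as.numeric(sub(".*AF=", "", m)))
    new_raw_record(chrom = f[1], pos = as.integer(f[2]), ref = f[4],
                   alt = strsplit(f[5], ",", fixed = TRUE)[[1]],
                   gt = gt,
                   qual = suppressWarnings(as.numeric(f[6])),
                   filter = f[7], af = af)
  })
}

#' Write a variant table as VCF 4.2
#'
#' Emits one record per variant. Genotype classes are re-encoded as GT values
#' (`het` -> 0/1, `hom_alt` -> 1/1, `hemi_alt` -> 1, `het_other` -> 1/2 with
#' a placeholder second ALT omitted, encoded as 0/1 with an INFO flag,
#' `unknown` -> ./.). Extra INFO key/value columns may be supplied.
#'
#' @param v a [variant_tbl()]
#' @param path output path
#' @param sample_name sample column name when genotypes are present
#' @param info optional data.frame of INFO fields (one row per variant)
#' @param with_genotypes emit FORMAT/GT columns
#' @export
write_vcf <- function(v, path, sample_name = "SAMPLE", info = NULL,
                      with_genotypes = any(!is.na(v$gt) & v$gt != "unknown")) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Labs agreeing on this call\">",
           "##INFO=<ID=COVER,Number=1,Type=Integer,Description=\"Labs whose ROI covers this site\">",
           "##INFO=<ID=AGREE_FRAC,Number=1,Type=Float,Description=\"Agreement fraction among covering labs\">",
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele fraction\">",
           "##INFO=<ID=HETOTHER,Number=0,Type=Flag,Description=\"Genotype class het with other non-ref allele\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (with_genotypes) cols <- c(cols, "FORMAT", sample_name)
  out <- c(hdr, paste(cols, collapse = "\t"))
  if (nrow(v)) {
    v <- sort_variants(v)
    info_str <- vapply(seq_len(nrow(v)), function(i) {
      kv <- character()
      if (!is.null(info)) {
        for (k in names(info)) {
          val <- info[[k]][i]
          if (!is.na(val)) kv <- c(kv, paste0(k, "=", format(val, digits = 10)))
        }
      }
      if (!is.na(v$af[i])) kv <- c(kv, paste0("AF=", format(v$af[i], digits = 6)))
      if (!is.na(v$gt[i]) && v$gt[i] == "het_other") kv <- c(kv, "HETOTHER")
      if (!length(kv)) "." else paste(kv, collapse = ";")
    }, character(1))
    gt_code <- c(het = "0/1", hom_alt = "1/1", hemi_alt = "1",
                 het_other = "0/1", unknown = "./.")
    recs <- vapply(seq_len(nrow(v)), function(i) {
      f <- c(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i],
             ifelse(is.na(v$qual[i]), ".", format(v$qual[i], digits = 6)),
             "PASS", info_str[i])
      if (with_genotypes) {
        g <- v$gt[i]
        f <- c(f, "GT", if (is.na(g)) "./." else gt_code[[g]])
      }
      paste(f, collapse = "\t")
    }, character(1))
    out <- c(out, recs)
  }
  writeLines(out, path)
  invisible(path)
}

#' Read and write BED interval files
#'
#' BED is 0-based half-open with at least three tab-separated columns; extra
#' columns are ignored. Reading canonicalises the intervals (overlaps are
#' merged) and the chromosome dialect.
#'
#' @param path BED file path
#' @param chrom_dialect see [canonical_chrom()]
#' @return a [region_set()]
#' @export
read_bed <- function(path, chrom_dialect = "strip") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                 !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (!length(lines)) return(region_set())
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(f, length, integer(1)) < 3L
  if (any(bad)) stop(sprintf("BED line(s) with fewer than 3 columns: %s",
                             paste(which(bad), collapse = ",")))
  chrom <- canonical_chrom(vapply(f, `[`, character(1), 1L), chrom_dialect)
  start <- as.integer(vapply(f, `[`, character(1), 2L))
  end <- as.integer(vapply(f, `[`, character(1), 3L))
  if (anyNA(start) || anyNA(end)) stop("non-numeric BED coordinates")
  region_set(chrom, start, end)
}

#' @rdname read_bed
#' @param rs a [region_set()] to write
#' @export
write_bed <- function(rs, path) {
  if (nrow(rs) == 0L) writeLines(character(), path)
  else writeLines(paste(rs$chrom, rs$start, rs$end, sep = "\t"), path)
  invisible(path)
}
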