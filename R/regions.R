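#' Genomic region sets
#'
#' A `region_set` is the package's canonical container for genomic intervals
#' (a lab's region of interest, an assessable region, an exon annotation).
#' All internal coordinates are 0-based half-open `[start, end)`; conversion
#' from the 1-based conventions of VCF happens at the I/O boundary only.
#' A canonical region set has, per chromosome, sorted pairwise-disjoint
#' intervals with `start < end`. Interval algebra is delegated to IRanges.
#'
#' @param chrom character vector of chromosome names
#' @param start,end integer vectors, 0-based half-open
#' @return An object of class `region_set`: a data.frame with columns
#'   `chrom`, `start`, `end` in canonical form.
#' @examples
#' rs <- region_set(c("1", "1"), c(10L, 40L), c(50L, 90L))
#' region_width(rs)  # 80, the two overlapping intervals are merged
#' @export
region_set <- function(chrom = character(), start = integer(), end = integer()) {
  stopifnot(length(start) == length(end))
  if (length(chrom) == 1L && length(start) > 1L)
    chrom <- rep(chrom, length(start))
  stopifnot(length(chrom) == length(start))
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   stringsAsFactors = FALSE)
  if (nrow(df) && any(df$start >= df$end))
    stop("region_set: start must be < end (0-based half-open)")
  canonicalize_regions(df)
}

canonicalize_regions <- function(df) {
  if (nrow(df) == 0L) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
    class(out) <- c("region_set", "data.frame")
    return(out)
  }
  parts <- lapply(split(df, df$chrom), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
    data.frame(chrom = d$chrom[1],
               start = IRanges::start(ir) - 1L, end = IRanges::end(ir),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts[order(names(parts))])
  rownames(out) <- NULL
  class(out) <- c("region_set", "data.frame")
  out
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region_set: %d interval(s), %d base(s) on %d chromosome(s)\n",
              nrow(x), region_width(x), length(unique(x$chrom))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

as_iranges_by_chrom <- function(rs) {
  lapply(split(rs, rs$chrom),
         function(d) IRanges::IRanges(d$start + 1L, d$end))
}

binary_region_op <- function(a, b, fun) {
  chroms <- union(unique(a$chrom), unique(b$chrom))
  ia <- as_iranges_by_chrom(a); ib <- as_iranges_by_chrom(b)
  empty <- IRanges::IRanges()
  parts <- lapply(chroms, function(ch) {
    ir <- fun(if (ch %in% names(ia)) ia[[ch]] else empty,
              if (ch %in% names(ib)) ib[[ch]] else empty)
    if (length(ir) == 0L) return(NULL)
    data.frame(chrom = ch, start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (!length(parts)) return(region_set())
  canonicalize_regions(do.call(rbind, parts))
}

#' Region-set algebra
#'
#' Union, intersection and subtraction of canonical region sets. Results are
#' canonical. `region_subtract(a, b)` removes every base of `b` from `a`.
#'
#' @param a,b `region_set` objects
#' @return a `region_set`
#' @export
region_union <- function(a, b) binary_region_op(a, b, IRanges::union)

#' @rdname region_union
#' @export
region_intersect <- function(a, b) binary_region_op(a, b, IRanges::intersect)

#' @rdname region_union
#' @export
region_subtract <- function(a, b) binary_region_op(a, b, IRanges::setdiff)

#' Total width of a region set in bases
#' @param rs a `region_set`
#' @return integer number of bases covered
#' @export
region_width <- function(rs) if (nrow(rs) == 0L) 0L else sum(rs$end - rs$start)

#' Point membership in a region set
#'
#' Tests which 0-based positions fall inside a region set. Vectorised over
#' positions; used for the "site in the ROI" condition of the consensus rules.
#'
#' @param rs a `region_set`
#' @param chrom character vector of chromosome names
#' @param pos0 integer vector of 0-based positions
#' @return logical vector
#' @export
region_covers <- function(rs, chrom, pos0) {
  stopifnot(length(chrom) == length(pos0))
  out <- logical(length(pos0))
  if (!length(pos0) || nrow(rs) == 0L) return(out)
  byc <- as_iranges_by_chrom(rs)
  for (ch in unique(chrom)) {
    if (!ch %in% names(byc)) next
    i <- which(chrom == ch)
    q <- IRanges::IRanges(pos0[i] + 1L, pos0[i] + 1L)
    out[i] <- IRanges::overlapsAny(q, byc[[ch]])
  }
  out
}

#' Extend every interval symmetrically
#'
#' Extends each interval by `bp` bases on both sides (floored at 0) and
#' re-canonicalises. Used for the exon +/- 2 bp assessable-region policies.
#'
#' @param rs a `region_set`
#' @param bp non-negative integer extension
#' @return a `region_set`
#' @export
region_extend <- function(rs, bp) {
  stopifnot(bp >= 0)
  if (nrow(rs) == 0L) return(rs)
  df <- data.frame(chrom = rs$chrom,
                   start = pmax(0L, rs$start - as.integer(bp)),
                   end = rs$end + as.integer(bp), stringsAsFactors = FALSE)
  canonicalize_regions(df)
}

#' Restrict a region of interest by an include or exclude list
#'
#' Laboratories may limit the ROI from their BED file down to named targets
#' via an inclusion (intersection) or exclusion (subtraction) operation.
#'
#' @param roi a `region_set`
#' @param targets a `region_set`
#' @param mode `"include"` (intersection) or `"exclude"` (subtraction)
#' @return a `region_set`; an empty result is permitted
#' @export
restrict_roi <- function(roi, targets, mode = c("include", "exclude")) {
  mode <- match.arg(mode)
  if (mode == "include") region_intersect(roi, targets)
  else region_subtract(roi, targets)
}
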