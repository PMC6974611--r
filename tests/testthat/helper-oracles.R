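# Brute-force oracles, independent of the implementation under test.

# apply a (pos, ref, alt) edit to a reference string by direct surgery
apply_edit <- function(seq, pos, ref, alt) {
  stopifnot(substr(seq, pos, pos + nchar(ref) - 1L) == ref)
  paste0(substr(seq, 1L, pos - 1L), alt,
         substr(seq, pos + nchar(ref), nchar(seq)))
}

# enumerate every anchored placement of an indel of the same size and return
# the leftmost one whose alternate haplotype equals the input's
oracle_leftmost <- function(seq, pos, ref, alt) {
  hap <- apply_edit(seq, pos, ref, alt)
  d <- nchar(ref) - nchar(alt)
  stopifnot(d != 0L)
  n <- nchar(seq)
  for (p in seq_len(n)) {
    if (d > 0L) {                       # deletion of d bases after anchor p
      if (p + d > n) break
      cref <- substr(seq, p, p + d)
      calt <- substr(seq, p, p)
    } else {                            # insertion of -d bases after anchor p
      cref <- substr(seq, p, p)
      calt <- paste0(cref, substr(hap, p + 1L, p - d))
    }
    if (cref == calt) next
    if (apply_edit(seq, p, cref, calt) == hap)
      return(list(pos = p, ref = cref, alt = calt))
  }
  stop("oracle found no equivalent placement")
}

# per-base somatic proximity oracle: keep ROI bases within `bp` of any
# reported variant's REF span (distance 0 inside the span)
oracle_proximity <- function(roi, variants, bp) {
  keep_chrom <- character(); keep_pos <- integer()
  for (i in seq_len(nrow(roi))) {
    ch <- roi$chrom[i]
    v <- variants[variants$chrom == ch, , drop = FALSE]
    if (nrow(v) == 0L) next
    for (b in seq(roi$start[i], roi$end[i] - 1L)) {
      s0 <- v$pos - 1L; e0 <- v$pos - 1L + nchar(v$ref) - 1L
      dist <- pmax(0L, pmax(s0 - b, b - e0))
      if (any(dist <= bp)) { keep_chrom <- c(keep_chrom, ch); keep_pos <- c(keep_pos, b) }
    }
  }
  if (!length(keep_pos)) return(region_set())
  region_set(keep_chrom, keep_pos, keep_pos + 1L)
}

# brute-force Ti/Tv classification of a SNP table
oracle_titv <- function(ref, alt) {
  pair <- paste0(pmin(ref, alt), pmax(ref, alt))
  ti <- sum(pair %in% c("AG", "CT"))
  tv <- length(pair) - ti
  if (tv == 0L) NA_real_ else ti / tv
}

# brute-force per-base pileup depth over a region set from read spans
oracle_depth <- function(reads, roi) {
  depth <- integer(0)
  for (i in seq_len(nrow(roi))) {
    ch <- roi$chrom[i]
    r <- reads[reads$chrom == ch, , drop = FALSE]
    for (b in seq(roi$start[i], roi$end[i] - 1L))
      depth <- c(depth, sum(r$start <= b & b < r$end))
  }
  depth
}
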