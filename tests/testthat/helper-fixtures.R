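# In-code fixtures: tiny VCF/BED writers and in-memory submissions.

write_lines_tmp <- function(lines, ext = ".vcf") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}

minimal_vcf <- function(records = "1\t100\t.\tA\tG\t50\tPASS\t.\tGT\t0/1",
                        fileformat = "VCFv4.2", with_sample = TRUE) {
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (with_sample) cols <- c(cols, "FORMAT", "S1")
  c(paste0("##fileformat=", fileformat),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(cols, collapse = "\t"),
    records)
}

# in-memory submission from compact variant specs
make_sub <- function(id, chrom = character(), pos = integer(),
                     ref = character(), alt = character(), gt = "het",
                     roi = region_set("1", 0L, 100000L),
                     scheme = "germline") {
  submission(id, variant_tbl(chrom, pos, ref, alt, gt = gt), roi,
             scheme = scheme)
}

# cohort of n identical labs all calling `calls` over `roi`
make_cohort <- function(n, chrom, pos, ref, alt, gt = "het",
                        roi = region_set("1", 0L, 100000L),
                        scheme = "germline") {
  lapply(seq_len(n), function(i)
    make_sub(sprintf("lab%02d", i), chrom, pos, ref, alt, gt, roi, scheme))
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
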