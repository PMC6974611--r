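write_fastq <- function(seqs, quals) {
  p <- tempfile(fileext = ".fastq")
  writeLines(unlist(lapply(seq_along(seqs), function(i)
    c(paste0("@r", i), seqs[i], "+", quals[i]))), p)
  p
}
phred33 <- function(q) intToUtf8(q + 33L)

test_that("fastq metrics: means, Q20/Q30 fractions, empty and mismatch cases", {
  f1 <- write_fastq("ACGT", phred33(rep(30L, 4)))
  m1 <- fastq_metrics(f1)
  expect_equal(m1$mean_base_quality, 30)
  expect_equal(m1$frac_q20, 1)
  expect_equal(m1$frac_q30, 1)

  f2 <- write_fastq("AC", phred33(c(10L, 30L)))
  m2 <- fastq_metrics(f2)
  expect_equal(m2$mean_base_quality, 20)
  expect_equal(m2$frac_q20, 0.5)
  expect_equal(m2$frac_q30, 0.5)

  f0 <- tempfile(); file.create(f0)
  expect_true(is.na(fastq_metrics(f0)$mean_base_quality))

  fbad <- write_fastq("ACGT", phred33(c(30L, 30L)))
  mb <- fastq_metrics(fbad)
  expect_true(any(grepl("length mismatch", mb$diagnostics$message)))
  expect_equal(mb$n_bases, 0L)
})

test_that("frac_q30 <= frac_q20 on random quality streams", {
  set.seed(14)
  for (i in 1:10) {
    n <- sample(5:50, 1)
    f <- write_fastq(rand_seq(n), phred33(sample(2:41, n, TRUE)))
    m <- fastq_metrics(f)
    expect_lte(m$frac_q30, m$frac_q20)
  }
})

write_aln <- function(df) {
  p <- tempfile(fileext = ".tsv")
  write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}

test_that("alignment metrics: coverage, on/off target, error rate, uniformity", {
  roi <- region_set("1", 100L, 110L)  # 10 bases
  # 25 reads of 8 bp covering roi bases 100..107; 2 roi bases uncovered
  aln <- data.frame(chrom = "1", pos = 101L, mapq = 60L, cigar = "8M",
                    tlen = 0L, nm = 1L, flags = 0L)[rep(1, 25), ]
  m <- alignment_metrics(read_alignment_summary(write_aln(aln)), roi,
                         thresholds = c(20L, 30L))
  expect_equal(unname(m$coverage_ge["20"]), 0.8)
  expect_equal(unname(m$coverage_ge["30"]), 0)
  expect_equal(m$frac_off_target, 0)
  expect_equal(m$error_rate_on_target, 25 / (25 * 8))
  # constant depth over covered bases is not uniform here (2 zero bases)
  expect_equal(m$uniformity, 0.8)

  # fully uniform depth
  aln2 <- data.frame(chrom = "1", pos = 101L, mapq = 60L, cigar = "10M",
                     tlen = 0L, nm = 0L, flags = 0L)[rep(1, 5), ]
  m2 <- alignment_metrics(read_alignment_summary(write_aln(aln2)), roi)
  expect_equal(m2$uniformity, 1)

  # unmapped-only stream
  aln3 <- data.frame(chrom = "*", pos = 0L, mapq = 0L, cigar = "*",
                     tlen = 0L, nm = 0L, flags = 4L)
  m3 <- alignment_metrics(read_alignment_summary(write_aln(aln3)), roi)
  expect_equal(unname(m3$coverage_ge), c(0, 0, 0))
  expect_true(is.na(m3$insert_mean))
})

test_that("insert statistics use proper pairs only, counted once", {
  roi <- region_set("1", 0L, 1000L)
  aln <- data.frame(chrom = "1", pos = c(1L, 200L, 400L, 500L),
                    mapq = 60L, cigar = "50M",
                    tlen = c(300L, -300L, 410L, 0L),
                    nm = 0L, flags = c(3L, 3L, 3L, 0L))
  m <- alignment_metrics(read_alignment_summary(write_aln(aln)), roi)
  expect_equal(m$insert_mean, mean(c(300, 410)))
  expect_equal(m$insert_sd, sd(c(300, 410)))
})

test_that("depth accounting equals brute-force pileup; coverage_ge monotone", {
  set.seed(27)
  for (rep in 1:10) {
    roi <- region_set("1", 50L, 50L + sample(20:60, 1))
    n <- sample(5:40, 1)
    pos <- sample(20:120, n, TRUE)
    len <- sample(5:20, n, TRUE)
    aln <- data.frame(chrom = "1", pos = pos, mapq = 60L,
                      cigar = paste0(len, "M"), tlen = 0L, nm = 0L, flags = 0L)
    thr <- c(1L, 2L, 4L, 8L)
    m <- alignment_metrics(aln, roi, thresholds = thr)
    depth <- oracle_depth(data.frame(chrom = "1", start = pos - 1L,
                                     end = pos - 1L + len), roi)
    expect_equal(unname(m$coverage_ge),
                 vapply(thr, function(t) mean(depth >= t), numeric(1)))
    expect_true(all(diff(m$coverage_ge) <= 1e-12))
  }
})

test_that("vcf metrics: Ti/Tv, counts, Het:Hom, mean QUAL", {
  v <- variant_tbl("1", 1:6 * 10L,
                   c("A", "G", "C", "T", "A", "G"),
                   c("G", "A", "T", "C", "C", "T"),
                   gt = c("het", "het", "hom_alt", "het", "hom_alt", "het"),
                   qual = c(50, 60, 70, NA, 40, 80))
  m <- vcf_metrics(v)
  expect_equal(m$titv, 2)
  expect_equal(m$snp_count, 6L)
  expect_equal(m$indel_count, 0L)
  expect_equal(m$het_hom_snp, 2)
  expect_true(is.na(m$het_hom_indel))
  expect_equal(m$mean_call_quality, mean(c(50, 60, 70, 40, 80)))

  set.seed(31)
  for (rep in 1:10) {
    n <- sample(5:60, 1)
    ref <- sample(c("A", "C", "G", "T"), n, TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                  character(1), USE.NAMES = FALSE)
    got <- vcf_metrics(variant_tbl("1", seq_len(n) * 3L, ref, alt, gt = "het"))$titv
    want <- oracle_titv(ref, alt)
    if (is.na(want)) expect_true(is.na(got)) else expect_equal(got, want)
  }
})

test_that("cohort benchmarking: percentiles, ties, strata, singleton", {
  b <- cohort_benchmark(c(a = 1, b = 2, c = 3))
  expect_equal(b$percentiles$percentile[b$percentiles$participant == "b"], 50)
  expect_equal(cohort_benchmark(c(only = 7))$percentiles$percentile, 50)
  ties <- cohort_benchmark(c(x = 5, y = 5, z = 5))
  expect_equal(ties$percentiles$percentile, rep(50, 3))
  # reorder invariance
  v <- c(a = 3, b = 1, c = 2, d = 10)
  p1 <- cohort_benchmark(v)$percentiles
  p2 <- cohort_benchmark(v[c(3, 1, 4, 2)])$percentiles
  expect_equal(p1[order(p1$participant), "percentile"],
               p2[order(p2$participant), "percentile"])
  # stratification with unreported group
  s <- cohort_benchmark(c(a = 1, b = 2, c = 3, d = 4),
                        strata = c("ill", "ill", NA, "ion"))
  expect_setequal(unique(s$percentiles$stratum), c("ill", "unreported", "ion"))
})
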