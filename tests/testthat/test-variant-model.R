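test_that("multi-allelic decomposition recodes genotypes per ALT", {
  r <- ngseqa:::new_raw_record("1", 100L, "A", c("G", "T"), gt = "1/2")
  d <- decompose_multiallelic(r)
  expect_length(d$records, 2L)
  expect_equal(vapply(d$records, `[[`, character(1), "alt"), c("G", "T"))
  expect_equal(vapply(d$records, `[[`, character(1), "gt_class"),
               c("het_other", "het_other"))
  # single-alt identity
  one <- decompose_multiallelic(ngseqa:::new_raw_record("1", 100L, "A", "G", gt = "0/1"))
  expect_length(one$records, 1L)
  expect_equal(one$records[[1]]$gt_class, "het")
  # symbolic ALT rejected, sequence ALT kept
  sym <- decompose_multiallelic(ngseqa:::new_raw_record("1", 100L, "A", c("<DEL>", "G")))
  expect_equal(sym$rejected$reason, "non-sequence ALT")
  expect_length(sym$records, 1L)
})

test_that("genotype_class covers the dialects", {
  expect_equal(genotype_class("0/1", 1L), "het")
  expect_equal(genotype_class("1|1", 1L), "hom_alt")
  expect_equal(genotype_class("1", 1L), "hemi_alt")
  expect_equal(genotype_class("1/2", 1L), "het_other")
  expect_equal(genotype_class("0/2", 1L), "not_present")
  expect_equal(genotype_class("./.", 1L), "unknown")
  expect_equal(genotype_class(NA_character_, 1L), "unknown")
})

test_that("split_mnp emits one SNP per mismatching offset", {
  s <- split_mnp("1", 100L, "AG", "CT")
  expect_equal(s$pos, c(100L, 101L))
  expect_equal(s$ref, c("A", "G"))
  expect_equal(s$alt, c("C", "T"))
  expect_equal(split_mnp("1", 100L, "AC", "AT"),
               data.frame(pos = 101L, ref = "C", alt = "T"))
  expect_equal(split_mnp("1", 100L, "A", "C")$pos, 100L)
  expect_error(split_mnp("1", 100L, "AG", "C"), "not an MNP")
  # conservation: SNPs emitted == mismatching bases, random MNPs
  set.seed(7)
  for (i in 1:50) {
    len <- sample(2:8, 1)
    ref <- rand_seq(len)
    alt <- rand_seq(len)
    if (ref == alt) next
    n_mismatch <- sum(strsplit(ref, "")[[1]] != strsplit(alt, "")[[1]])
    expect_equal(nrow(split_mnp("1", 10L, ref, alt)), n_mismatch)
  }
})

test_that("minimal representation trims suffix first, then prefix", {
  m <- minimal_representation(100L, "CTCC", "CCC")
  expect_equal(m, list(pos = 100L, ref = "CT", alt = "C"))
  expect_equal(classify_alleles(m$ref, m$alt), "deletion")
  expect_error(minimal_representation(100L, "A", "A"), "null variant")
  expect_equal(minimal_representation(100L, "G", "T"),
               list(pos = 100L, ref = "G", alt = "T"))
  # MNP-interior SNP: shared flanks trimmed, position advanced
  expect_equal(minimal_representation(100L, "ACG", "ATG"),
               list(pos = 101L, ref = "C", alt = "T"))
})

test_that("left alignment finds the leftmost equivalent placement", {
  # GCATATATG: a 2 bp deletion in the AT tract shifts home to pos 2 (CAT>C)
  ctx <- ref_context("1", 1L, "GCATATATG")
  la <- left_align(4L, "TAT", "T", ctx)
  expect_equal(la, list(pos = 2L, ref = "CAT", alt = "C"))
  expect_equal(apply_edit("GCATATATG", la$pos, la$ref, la$alt),
               apply_edit("GCATATATG", 4L, "TAT", "T"))
  ctx2 <- ref_context("1", 1L, "AAACCC")
  la2 <- left_align(5L, "C", "CC", ctx2)
  expect_equal(la2, list(pos = 3L, ref = "A", alt = "AC"))
  # SNPs cannot shift
  expect_equal(left_align(5L, "A", "G", ctx), list(pos = 5L, ref = "A", alt = "G"))
  # window too small to prove leftmost placement
  expect_error(left_align(3L, "AA", "A", ref_context("1", 3L, "AAAA")),
               class = "insufficient_context")
  # REF inconsistent with the context is refused
  expect_error(left_align(5L, "TAT", "T", ctx), "does not match")
})

test_that("normalize_record composes the pipeline and is idempotent", {
  seqs <- c("1" = "GGGCATATATGCCTAGGACTT")
  # right-shifted 2bp deletion inside the AT tract
  r <- ngseqa:::new_raw_record("1", 8L, "TAT", "T", gt = "0/1")
  nv <- normalize_record(r, seqs)$variants
  expect_equal(nrow(nv), 1L)
  expect_equal(nv$pos, 4L)
  expect_equal(nv$ref, "CAT")
  expect_equal(nv$alt, "C")
  # haplotype preserved
  expect_equal(apply_edit(seqs[["1"]], nv$pos, nv$ref, nv$alt),
               apply_edit(seqs[["1"]], 8L, "TAT", "T"))
  # idempotence
  r2 <- ngseqa:::new_raw_record(nv$chrom, nv$pos, nv$ref, nv$alt, gt = "0/1")
  nv2 <- normalize_record(r2, seqs)$variants
  expect_equal(nv2$pos, nv$pos)
  expect_equal(nv2$ref, nv$ref)
  expect_equal(nv2$alt, nv$alt)
})

test_that("normalize_record handles MNPs and partial symbolic rejection", {
  seqs <- c("1" = rand_seq(200))
  r <- ngseqa:::new_raw_record("1", 100L, "AG", c("CT", "AT"), gt = "1/2")
  # force ref context irrelevant for MNP; build record consistent with seqs not needed
  nv <- normalize_record(r)$variants
  keys <- call_key(nv)
  expect_true(all(c("1:100:A:C", "1:101:G:T") %in% keys))
  expect_equal(sum(keys == "1:101:G:T"), 1L)  # deduplicated per call+genotype
  sym <- normalize_record(ngseqa:::new_raw_record("1", 50L, "A", c("G", "<INS>"), gt = "0/1"))
  expect_equal(sym$rejected$reason, "non-sequence ALT")
  expect_equal(sym$variants$alt, "G")
})

test_that("normalization equals the brute-force leftmost oracle on random repeat-rich windows", {
  set.seed(11)
  n_cases <- 300L
  for (i in seq_len(n_cases)) {
    # repeat-rich window: random bases + a repeated unit tract in the middle
    unit <- rand_seq(sample(1:3, 1))
    win <- paste0(rand_seq(20), strrep(unit, sample(4:8, 1)), rand_seq(20))
    L <- sample(1:6, 1)
    n <- nchar(win)
    pos <- sample(15:(n - L - 15), 1)
    if (runif(1) < 0.5) {
      ref <- substr(win, pos, pos + L); alt <- substr(win, pos, pos)
    } else {
      ref <- substr(win, pos, pos)
      alt <- paste0(ref, rand_seq(L))
    }
    seqs <- setNames(win, "1")
    # emit right-shifted and/or suffix-padded representation
    quirky <- ngseqa:::right_shift_indel(pos, ref, alt, seqs, "1")
    if (runif(1) < 0.5 && quirky$pos + nchar(quirky$ref) <= n) {
      nb <- substr(win, quirky$pos + nchar(quirky$ref), quirky$pos + nchar(quirky$ref))
      quirky$ref <- paste0(quirky$ref, nb); quirky$alt <- paste0(quirky$alt, nb)
    }
    got <- normalize_record(
      ngseqa:::new_raw_record("1", quirky$pos, quirky$ref, quirky$alt, gt = "0/1"),
      seqs)$variants
    exp <- oracle_leftmost(win, pos, ref, alt)
    expect_equal(got$pos, exp$pos)
    expect_equal(got$ref, exp$ref)
    expect_equal(got$alt, exp$alt)
  }
})
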