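p_def <- consensus_params()

test_that("tally_site does the covering/call/noncalling bookkeeping", {
  roi <- region_set("1", 0L, 1000L)
  # 8 labs cover; 6 call A->G het; 2 call nothing
  subs <- c(make_cohort(6, "1", 500L, "A", "G", "het", roi),
            lapply(7:8, function(i) make_sub(paste0("lab", i), roi = roi)))
  t1 <- tally_site("1", 500L, subs, "germline")
  expect_equal(t1$covering_labs, 8L)
  expect_equal(unname(t1$call_counts["1:500:A:G:het"]), 6L)
  expect_equal(t1$noncalling_labs, 2L)

  # genotype splits the call class in germline mode
  subs2 <- c(make_cohort(5, "1", 500L, "A", "G", "het", roi),
             list(make_sub("labH", "1", 500L, "A", "G", "hom_alt", roi)),
             lapply(7:8, function(i) make_sub(paste0("lab", i), roi = roi)))
  t2 <- tally_site("1", 500L, subs2, "germline")
  expect_equal(length(t2$call_counts), 2L)
  expect_equal(unname(t2$call_counts["1:500:A:G:het"]), 5L)
  expect_equal(unname(t2$call_counts["1:500:A:G:hom_alt"]), 1L)

  # no lab covers
  far <- make_sub("labF", roi = region_set("2", 0L, 10L))
  t3 <- tally_site("1", 500L, list(far), "germline")
  expect_equal(t3$covering_labs, 0L)
  expect_length(t3$call_counts, 0L)
})

test_that("consensus boundary is exact: 6/8 in, 5/8 out, 6/6 out (<7 covering)", {
  roi <- region_set("1", 0L, 1000L)
  cohort_68 <- c(make_cohort(6, "1", 500L, "A", "G", "het", roi),
                 lapply(7:8, function(i) make_sub(paste0("lab", i), roi = roi)))
  c68 <- build_consensus(cohort_68, p_def, "germline")
  expect_equal(nrow(c68$variants), 1L)
  expect_equal(c68$variants$covering_labs, 8L)
  expect_equal(c68$variants$agreeing_labs, 6L)

  cohort_58 <- c(make_cohort(5, "1", 500L, "A", "G", "het", roi),
                 lapply(6:8, function(i) make_sub(paste0("lab", i), roi = roi)))
  expect_equal(nrow(build_consensus(cohort_58, p_def, "germline")$variants), 0L)

  cohort_66 <- make_cohort(6, "1", 500L, "A", "G", "het", roi)
  expect_equal(nrow(build_consensus(cohort_66, p_def, "germline")$variants), 0L)
})

test_that("noncalling covering labs count against agreement", {
  roi <- region_set("1", 0L, 1000L)
  # 7 callers agree but 10 cover: 7/10 < 75% -> excluded
  cohort <- c(make_cohort(7, "1", 500L, "A", "G", "het", roi),
              lapply(8:10, function(i) make_sub(paste0("lab", i), roi = roi)))
  expect_equal(nrow(build_consensus(cohort, p_def, "germline")$variants), 0L)
  # 8/10 >= 75% -> included
  cohort2 <- c(make_cohort(8, "1", 500L, "A", "G", "het", roi),
               lapply(9:10, function(i) make_sub(paste0("lab", i), roi = roi)))
  expect_equal(nrow(build_consensus(cohort2, p_def, "germline")$variants), 1L)
})

test_that("genotype classes split the vote in germline mode but not somatic", {
  roi <- region_set("1", 0L, 1000L)
  cohort <- c(make_cohort(5, "1", 500L, "A", "G", "het", roi),
              lapply(6:8, function(i)
                make_sub(paste0("labH", i), "1", 500L, "A", "G", "hom_alt", roi)))
  # germline: neither class reaches 6/8
  expect_equal(nrow(build_consensus(cohort, p_def, "germline")$variants), 0L)
  # genotype off: 8/8 agreement on the alt allele
  p_off <- consensus_params(consensus_genotype = FALSE)
  expect_equal(nrow(build_consensus(cohort, p_off, "germline")$variants), 1L)
  # somatic: genotype never in the key
  som <- lapply(cohort, function(s) { s$scheme <- "somatic"; s })
  expect_equal(nrow(build_consensus(som, p_def, "somatic")$variants), 1L)
})

test_that("threshold monotonicity holds on random small cohorts", {
  set.seed(21)
  roi <- region_set("1", 0L, 2000L)
  for (rep in 1:10) {
    n <- sample(7:12, 1)
    n_call <- sample(0:n, 1)
    cohort <- c(make_cohort(n_call, "1", 700L, "C", "T", "het", roi),
                lapply(seq_len(n - n_call), function(i)
                  make_sub(paste0("nc", i), roi = roi)))
    base <- nrow(build_consensus(cohort, p_def, "germline")$variants)
    # adding an agreeing lab never removes the variant
    more <- c(cohort, list(make_sub("extra", "1", 700L, "C", "T", "het", roi)))
    expect_gte(nrow(build_consensus(more, p_def, "germline")$variants), base)
    # raising the agreement fraction never adds one
    stricter <- consensus_params(agreement_fraction = 0.9)
    expect_lte(nrow(build_consensus(cohort, stricter, "germline")$variants), base)
  }
})

test_that("assessable-region policies match their contracts", {
  exons <- region_set("1", 1000L, 1100L)
  g <- build_assessable("germline_exon2bp", exons = exons)
  expect_equal(g$start, 998L)
  expect_equal(g$end, 1102L)

  # consensus-exon policy keeps only exons containing a consensus variant start
  exons2 <- region_set(c("1", "1"), c(1000L, 5000L), c(1100L, 5100L))
  v <- variant_tbl("1", 1050L, "A", "G", gt = "het")  # 0-based start 1049 in exon 1
  g2 <- build_assessable("germline_consensus_exon2bp", exons = exons2, variants = v)
  expect_equal(nrow(g2), 1L)
  expect_equal(g2$start, 998L)

  s <- build_assessable("somatic_exact", variants = variant_tbl("1", 5000L, "A", "T"))
  expect_equal(s$start, 4999L)
  expect_equal(s$end, 5000L)
  # ref span for deletions
  s2 <- build_assessable("somatic_exact", variants = variant_tbl("1", 5000L, "ATT", "A"))
  expect_equal(s2$end, 5002L)
})

test_that("somatic proximity pruning equals the per-base distance oracle", {
  roi <- region_set("1", 0L, 9000L)
  v <- variant_tbl("1", 5000L, "A", "T")
  got <- build_assessable("somatic_proximity", variants = v, roi = roi)
  expect_equal(got$start, 3999L)
  expect_equal(got$end, 6000L)
  expect_equal(got, oracle_proximity(roi, v, 1000L))

  set.seed(33)
  for (rep in 1:5) {
    roi_r <- region_set("1", sample(0:500, 1), sample(3000:5000, 1))
    n_v <- sample(1:3, 1)
    v_r <- variant_tbl("1", sort(sample(200:4500, n_v)),
                       rep("A", n_v), rep("G", n_v))
    p_small <- consensus_params(somatic_proximity_bp = 300L)
    expect_equal(build_assessable("somatic_proximity", variants = v_r,
                                  roi = roi_r, params = p_small),
                 oracle_proximity(roi_r, v_r, 300L))
  }
})

test_that("merge_truth applies the strong-consensus override and fall-back", {
  eqa <- truth_set(variant_tbl(c("1", "1"), c(100L, 300L), c("A", "C"),
                               c("G", "T"), gt = "het"),
                   assessable = region_set("1", 0L, 1000L), provenance = "eqa")
  cv <- variant_tbl(c("1", "1"), c(100L, 500L), c("A", "G"), c("T", "C"),
                    gt = "het")
  cv$covering_labs <- c(8L, 8L); cv$agreeing_labs <- c(7L, 7L)
  cons <- truth_set(cv, provenance = "consensus")
  m <- merge_truth(eqa, cons)
  keys <- call_key(m$variants, genotype = TRUE)
  expect_true("1:100:A:T:het" %in% keys)      # strong consensus overrides
  expect_false("1:100:A:G:het" %in% keys)
  expect_true("1:300:C:T:het" %in% keys)      # EQA-only site retained
  expect_true("1:500:G:C:het" %in% keys)      # strong consensus-only site kept
  expect_equal(m$provenance, "merged")

  # weak consensus neither overrides nor adds
  cv2 <- cv; cv2$covering_labs <- c(8L, 8L); cv2$agreeing_labs <- c(5L, 5L)
  m2 <- merge_truth(eqa, truth_set(cv2, provenance = "consensus"))
  keys2 <- call_key(m2$variants, genotype = TRUE)
  expect_true("1:100:A:G:het" %in% keys2)
  expect_false("1:500:G:C:het" %in% keys2)
  expect_equal(nrow(attr(m2, "weak_excluded")), 1L)  # the consensus-only site

  # idempotent: identical calls keep the truth unchanged
  same <- truth_set(m$variants, provenance = "consensus")
  m3 <- merge_truth(m, same)
  expect_equal(sort(call_key(m3$variants, TRUE)), sort(keys))
})
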