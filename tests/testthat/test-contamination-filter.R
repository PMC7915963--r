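test_that("count_kmers canonicalizes and skips short or ambiguous windows", {
  sp <- count_kmers(manual_reads("ACGTACG"), k = 7)
  expect_equal(sp$kmer, "ACGTACG")  # canonical vs its revcomp CGTACGT
  expect_equal(sp$count, 1L)

  short <- count_kmers(manual_reads("ACGT"), k = 7)
  expect_equal(length(short$kmer), 0L)

  # windows containing N are skipped entirely
  withN <- count_kmers(manual_reads("ACGTNACGTA"), k = 4)
  expect_false(any(grepl("N", withN$kmer)))
  expect_equal(sum(withN$count), 3L)  # ACGT twice and CGTA once, N windows skipped
})

test_that("count_kmers equals brute-force enumeration on random reads", {
  set.seed(31)
  reads <- vapply(1:100, function(i) oracle_random_dna(sample(20:60, 1)), "")
  got <- count_kmers(manual_reads(reads), k = 9)
  want <- oracle_count_kmers(reads, 9)
  got_df <- data.frame(kmer = got$kmer, count = got$count)
  got_df <- got_df[order(got_df$kmer), ]
  rownames(got_df) <- NULL
  expect_equal(got_df, want[order(want$kmer), , drop = FALSE],
               ignore_attr = TRUE)
})

test_that("flag_kmers applies the inclusive fold rule on focal k-mers only", {
  k <- 8
  km <- "ACGTTGCA"
  focal <- count_kmers(manual_reads(c(km, "GGGGGGGG")), k)
  other <- count_kmers(manual_reads(rep(km, 1000)), k)
  # focal count 1, other count 1000 -> ratio exactly 1000, flagged (inclusive)
  fl <- flag_kmers(focal, other, 1000)
  expect_equal(fl$kmers, canonical_kmer(km))

  focal2 <- count_kmers(manual_reads(c(km, km)), k)
  other2 <- count_kmers(manual_reads(rep(km, 1999)), k)
  # 1999 / 2 = 999.5 < 1000 -> not flagged
  expect_length(flag_kmers(focal2, other2, 1000)$kmers, 0)

  # identical spectra never flag at fold 1000
  expect_length(flag_kmers(focal, focal, 1000)$kmers, 0)

  # k-mers absent from focal are never flagged
  other3 <- count_kmers(manual_reads(rep("TTTTAAAA", 500)), k)
  expect_length(flag_kmers(focal, other3, 2)$kmers, 0)

  expect_error(flag_kmers(focal, count_kmers(manual_reads(km), 6), 10),
               "mismatched k")
})

test_that("flagging is anti-symmetric for fold thresholds above 1", {
  set.seed(7)
  for (rep_i in 1:5) {
    a <- count_kmers(manual_reads(replicate(30, oracle_random_dna(30))), 6)
    b <- count_kmers(manual_reads(replicate(30, oracle_random_dna(30))), 6)
    fab <- flag_kmers(a, b, 2)$kmers
    fba <- flag_kmers(b, a, 2)$kmers
    expect_length(intersect(fab, fba), 0)
  }
})

test_that("filter_reads applies the coverage and length rules per the contract", {
  k <- 57
  base <- oracle_random_dna(150)
  rs <- manual_reads(c(base, oracle_random_dna(74), oracle_random_dna(150)))
  flagged_kmer <- canonical_kmer(substr(base, 10, 10 + k - 1))
  fl <- structure(list(focal_sample = "S", other_sample = "O", k = k,
                       fold_threshold = 1000, kmers = flagged_kmer),
                  class = "FlaggedKmerSet")
  res <- filter_reads(rs, fl, coverage_fraction = 0.25, min_length = 75)
  rep <- res$report
  # one flagged 57-mer covers 57/150 = 0.38 >= 0.25 -> removed
  expect_equal(rep$reason, c("contamination", "too_short", "kept"))
  expect_equal(rep$flagged_frac[1], 57 / 150)
  expect_equal(n_reads(res$kept), 1)
  s <- attr(rep, "summary")
  expect_equal(unname(s["input"]), unname(s["kept"] + s["contamination"] + s["too_short"]))

  # no flagged k-mers anywhere: everything of length >= min_length kept
  none <- filter_reads(rs, list(), 0.25, 75)
  expect_equal(none$report$reason, c("kept", "too_short", "kept"))
})

test_that("filter decisions are invariant to read order", {
  set.seed(19)
  tb <- tiny_batch(seed = 61, n_reads = 500)
  rs <- tb$batch$read_sets$spA
  spA <- count_kmers(rs, 31)
  spB <- count_kmers(tb$batch$read_sets$spB, 31)
  fl <- flag_kmers(spA, spB, 5)
  r1 <- filter_reads(rs, fl, 0.25, 75)$report
  perm <- sample(nrow(rs$reads))
  rs2 <- rs
  rs2$reads <- rs$reads[perm, ]
  r2 <- filter_reads(rs2, fl, 0.25, 75)$report
  m <- match(r1$read_id, r2$read_id)
  expect_equal(r1$kept, r2$kept[m])
  expect_equal(r1$flagged_frac, r2$flagged_frac[m])
})

test_that("flagged-base fractions match the interval-union oracle", {
  set.seed(23)
  k <- 11
  reads <- replicate(30, oracle_random_dna(60))
  flagged <- canonical_kmer(vapply(sample(reads, 10), substr, "", 5, 5 + k - 1))
  fl <- structure(list(focal_sample = "S", other_sample = "O", k = k,
                       fold_threshold = 10, kmers = flagged),
                  class = "FlaggedKmerSet")
  rep <- filter_reads(manual_reads(reads), fl, 0.25, 10)$report
  want <- vapply(reads, oracle_flagged_fraction, 1.0, flagged = flagged, k = k)
  expect_equal(rep$flagged_frac, unname(want))
})

test_that("spike-in sensitivity rises as the fold threshold approaches the
           count ratio implied by the contamination rate", {
  tb <- tiny_batch(seed = 101, n_reads = 4000, rate = 0.02)
  b <- tb$batch
  spA <- count_kmers(b$read_sets$spA, 31)
  spB <- count_kmers(b$read_sets$spB, 31)
  sens_at <- function(fold) {
    fl <- flag_kmers(spA, spB, fold)
    r <- filter_reads(b$read_sets$spA, fl, 0.25, 75)
    score_contamination_filter(r$report, b$read_sets$spA)
  }
  lo <- sens_at(10)
  expect_gt(lo$sensitivity, 0.9)
  expect_lt(lo$false_removal_rate, 0.005)
})
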