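test_that("generate_transcriptome is deterministic and respects its contract", {
  prof <- c("3FTx" = 0.7, PLA2 = 0.3)
  a <- generate_transcriptome(10, prof, mean_length = 600, seed = 7)
  b <- generate_transcriptome(10, prof, mean_length = 600, seed = 7)
  expect_identical(a, b)
  expect_equal(nrow(a$transcripts), 10)
  expect_false(anyDuplicated(a$transcripts$transcript_id) > 0)
  expect_true(all(grepl("^[ACGT]+$", a$transcripts$sequence)))
  expect_gt(sum(a$transcripts$weight), 0)

  one <- generate_transcriptome(1, c("3FTx" = 1), mean_length = 500, seed = 3)
  expect_equal(one$transcripts$family, "3FTx")
  orfs <- find_orfs(with(one$transcripts, setNames(sequence, transcript_id))[1],
                    min_codons = 50)
  expect_gte(nrow(orfs), 1)

  expect_error(generate_transcriptome(5, numeric()), "empty")
  expect_error(generate_transcriptome(5, c(a = 0, b = 0)), "nonnegative")
})

test_that("every generated transcript embeds its designed complete ORF", {
  ts <- generate_transcriptome(15, c("3FTx" = 0.5, kunitz = 0.5),
                               mean_length = 700, seed = 11)
  for (i in seq_len(15)) {
    tr <- ts$transcripts[i, ]
    cds <- substr(tr$sequence, tr$orf_start + 1, tr$orf_end)
    expect_equal(nchar(cds) %% 3, 0)
    expect_equal(substr(cds, 1, 3), "ATG")
    cods <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    expect_true(cods[length(cods)] %in% c("TAA", "TAG", "TGA"))
    expect_false(any(cods[-length(cods)] %in% c("TAA", "TAG", "TGA")))
  }
})

test_that("family assignment frequencies follow the profile (binomial oracle)", {
  n <- 10000
  ts <- generate_transcriptome(n, c("3FTx" = 0.7, PLA2 = 0.3),
                               mean_length = 210, seed = 5)
  f <- mean(ts$transcripts$family == "3FTx")
  sd3 <- 3 * sqrt(0.7 * 0.3 / n)
  expect_lt(abs(f - 0.7), sd3)
})

test_that("simulate_reads honours error model, sources and determinism", {
  ts <- generate_transcriptome(5, c("3FTx" = 1), mean_length = 400, seed = 2)
  expect_identical(simulate_reads(ts, 50, 80, 0.01, seed = 9),
                   simulate_reads(ts, 50, 80, 0.01, seed = 9))
  expect_equal(n_reads(simulate_reads(ts, 0, 80, 0, seed = 1)), 0)
  expect_error(simulate_reads(ts, 10, 10000, 0, seed = 1), "exceeds")

  rs <- simulate_reads(ts, 200, 80, 0, seed = 4)
  hay <- paste(ts$transcripts$sequence, collapse = "#")
  for (s in rs$reads$sequence) {
    expect_true(grepl(s, hay, fixed = TRUE) ||
                  grepl(oracle_revcomp(s), hay, fixed = TRUE))
  }
  expect_true(all(rs$reads$true_source == "sp1"))
  expect_true(all(nchar(rs$reads$quality) == 80))

  one <- generate_transcriptome(1, c("3FTx" = 1), mean_length = 400, seed = 8)
  r1 <- simulate_reads(one, 100, 60, 0, seed = 5)
  expect_true(all(vapply(r1$reads$sequence, function(s) {
    grepl(s, one$transcripts$sequence, fixed = TRUE) ||
      grepl(oracle_revcomp(s), one$transcripts$sequence, fixed = TRUE)
  }, TRUE)))
})

test_that("substitution error rate matches its binomial expectation", {
  ts <- generate_transcriptome(1, c("3FTx" = 1), mean_length = 400, seed = 13)
  txt <- ts$transcripts$sequence
  rl <- 100; n <- 400; rate <- 0.02
  rs <- simulate_reads(ts, n, rl, rate, seed = 21)
  mm <- vapply(rs$reads$sequence, function(s) {
    cand <- c(s, oracle_revcomp(s))
    best <- Inf
    for (q in cand) {
      qv <- strsplit(q, "")[[1]]
      for (o in 0:(nchar(txt) - rl)) {
        cv <- strsplit(substr(txt, o + 1, o + rl), "")[[1]]
        d <- sum(cv != qv)
        if (d < best) best <- d
        if (best == 0) break
      }
    }
    best
  }, 1)
  tot <- sum(mm)
  expected <- n * rl * rate
  expect_lt(abs(tot - expected), 3 * sqrt(n * rl * rate * (1 - rate)) + 1)
})

test_that("spike_contamination preserves genuine reads and spikes verbatim copies", {
  ts1 <- generate_transcriptome(4, c("3FTx" = 1), mean_length = 400, seed = 1)
  ts2 <- generate_transcriptome(4, c("3FTx" = 1), mean_length = 400,
                                seed = 99, species_id = "sp2")
  r1 <- simulate_reads(ts1, 3000, 80, 0.01, seed = 2)
  r2 <- simulate_reads(ts2, 3000, 80, 0.01, seed = 3)

  b0 <- spike_contamination(list(r1, r2), 0, seed = 4)
  expect_identical(b0$read_sets$sp1$reads, r1$reads)
  expect_identical(b0$read_sets$sp2$reads, r2$reads)

  b <- spike_contamination(list(r1, r2), 0.01, seed = 4)
  for (s in c("sp1", "sp2")) {
    reads <- b$read_sets[[s]]$reads
    cont <- startsWith(reads$true_source, "contaminant:")
    expect_lt(abs(sum(cont) - 30), 3 * sqrt(3000 * 0.01 * 0.99) + 1)
    expect_equal(sum(!cont), 3000)                      # genuine untouched
    donor <- if (s == "sp1") r2 else r1
    expect_true(all(reads$sequence[cont] %in% donor$reads$sequence))
  }
  expect_error(spike_contamination(list(r1), 0.01), "single sample")
})

test_that("make_chimera joins prefix and suffix and records the breakpoint", {
  a <- c(ca = strrep("A", 100))
  b <- c(cb = strrep("G", 100))
  ch <- make_chimera(a, b, 50)
  expect_equal(nchar(ch$sequence), 100)
  expect_equal(substr(ch$sequence, 1, 50), strrep("A", 50))
  expect_equal(substr(ch$sequence, 51, 100), strrep("G", 50))
  expect_equal(ch$breakpoint, 50)
  # degenerate join: whole a, empty b-suffix
  full <- make_chimera(a, b, 100, b_from = 101)
  expect_equal(full$sequence, unname(a))
  expect_error(make_chimera(a, b, 0), "breakpoint")
  expect_error(make_chimera(a, b, 101), "breakpoint")
})

test_that("evolve_codon_clade respects zero branch length, stops, determinism", {
  set.seed(1)
  anc <- random_coding_sequence(60)
  a0 <- evolve_codon_clade(anc, n_taxa = 4, branch_length = 0, omega = 1, seed = 2)
  expect_true(all(a0$seqs == anc))
  expect_error(evolve_codon_clade(paste0("ATG", "TAA", "AAA"), 3, 0.1, 1),
               "stop")
  e1 <- evolve_codon_clade(anc, 4, 0.2, 2, seed = 6)
  e2 <- evolve_codon_clade(anc, 4, 0.2, 2, seed = 6)
  expect_identical(e1, e2)
  # stop codons are unreachable
  big <- evolve_codon_clade(anc, 8, 1.5, 2, seed = 7)
  for (s in big$seqs) {
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    expect_false(any(cods %in% c("TAA", "TAG", "TGA")))
  }
})

test_that("estimated omega orders simulated selection regimes", {
  set.seed(2)
  anc <- random_coding_sequence(150)
  lo <- clade_omega(evolve_codon_clade(anc, 8, 0.15, 0.2, seed = 31))$omega
  hi <- clade_omega(evolve_codon_clade(anc, 8, 0.15, 2.4, seed = 31))$omega
  expect_lt(lo, 1)
  expect_gt(hi, 1)
  expect_lt(lo, hi)
})

test_that("synthetic FASTA/FASTQ round-trip losslessly with sidecar truth", {
  ts <- generate_transcriptome(5, c("3FTx" = 1), mean_length = 400, seed = 3)
  fa <- tempfile(fileext = ".fasta")
  seqs <- with(ts$transcripts, setNames(sequence, transcript_id))
  write_fasta(seqs, fa)
  expect_identical(read_fasta(fa), seqs)

  rs <- simulate_reads(ts, 50, 70, 0.01, seed = 5)
  fq <- tempfile(fileext = ".fastq")
  tt <- tempfile(fileext = ".tsv")
  write_fastq(rs, fq, truth_path = tt)
  back <- attach_truth(read_fastq(fq, "sp1"), read_truth_table(tt))
  expect_identical(back$reads, rs$reads)
  # no provenance labels leak into the FASTQ itself
  expect_false(any(grepl("contaminant|true_source", readLines(fq))))
})
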