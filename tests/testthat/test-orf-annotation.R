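test_that("find_orfs handles minimal and incomplete cases", {
  one <- find_orfs(c(x = "ATGTGA"), min_codons = 1)
  expect_equal(nrow(one), 1)
  expect_equal(one$protein, "M")
  expect_equal(one$cds, "ATGTGA")
  expect_equal(c(one$start, one$end), c(0, 6))

  expect_equal(nrow(find_orfs(c(x = "ATGAAA"), min_codons = 1)), 0)  # no stop
  expect_equal(nrow(find_orfs(c(x = "AAATGA"), min_codons = 1)), 0)  # no start
})

test_that("find_orfs equals the brute-force six-frame oracle on random contigs", {
  set.seed(5)
  for (i in 1:120) {
    seq <- oracle_random_dna(300)
    got <- find_orfs(c(ctg = seq), min_codons = 10)
    want <- oracle_orfs(seq, 10)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$strand, want$strand)
    }
  }
})

test_that("reverse-complementing a contig mirrors ORF coordinates and strands", {
  set.seed(8)
  for (i in 1:20) {
    seq <- oracle_random_dna(400)
    L <- nchar(seq)
    fwd <- find_orfs(c(a = seq), min_codons = 15)
    rev <- find_orfs(c(a = oracle_revcomp(seq)), min_codons = 15)
    key <- function(df, flip) {
      if (!nrow(df)) return(character())
      s <- if (flip) ifelse(df$strand == "+", "-", "+") else df$strand
      st <- if (flip) L - df$end else df$start
      en <- if (flip) L - df$start else df$end
      sort(paste(s, st, en))
    }
    expect_equal(key(fwd, FALSE), key(rev, TRUE))
  }
})

test_that("reported ORFs re-translate to their protein", {
  set.seed(9)
  ts <- generate_transcriptome(6, c("3FTx" = 1), mean_length = 600, seed = 14)
  orfs <- do.call(rbind, lapply(seq_len(6), function(i) {
    find_orfs(with(ts$transcripts, setNames(sequence, transcript_id))[i], 30)
  }))
  for (i in seq_len(nrow(orfs))) {
    cds <- orfs$cds[i]
    expect_equal(as.character(translate_cds(substr(cds, 1, nchar(cds) - 3))),
                 orfs$protein[i])
  }
})

test_that("translate_cds follows the standard code and stop conventions", {
  expect_equal(as.character(translate_cds("ATG")), "M")
  expect_equal(as.character(translate_cds("ATGAAATGA")), "MK")
  expect_true(attr(translate_cds("ATGAAATGA"), "valid"))
  lead <- translate_cds("TGAAAATGA")  # leading stop is internal after trim
  expect_equal(as.character(lead), "*K")
  expect_false(attr(lead, "valid"))
  expect_error(translate_cds("ATGA"), "divisible")
})

test_that("similarity_search ranks and scores like a Smith-Waterman oracle", {
  db <- data.frame(
    ref_id = c("r1", "r2", "r3"),
    family = c("3FTx", "PLA2", "kunitz"),
    taxon = c("spA", "spB", "spA"),
    protein = c("MKTLLLTLVV", "CYTTDWGEEC", "RRRGGGWWPP"),
    stringsAsFactors = FALSE
  )
  hits <- similarity_search("MKTLLLTLVV", db, min_score = 5)
  expect_equal(hits$ref_id[1], "r1")
  expect_equal(hits$identity[1], 100)

  data("BLOSUM62", package = "Biostrings", envir = environment())
  set.seed(12)
  aa <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V")
  for (i in 1:12) {
    q <- paste(sample(aa, 10, replace = TRUE), collapse = "")
    s <- paste(sample(aa, 10, replace = TRUE), collapse = "")
    got <- similarity_search(q, data.frame(ref_id = "x", family = "f", taxon = "t",
                                           protein = s, stringsAsFactors = FALSE),
                             min_score = -Inf)
    want <- oracle_sw_score(q, s, BLOSUM62, open = 11, extend = 1)
    expect_equal(got$score, want)
  }
})

test_that("classify_family applies thresholds and deterministic tie-breaks", {
  empty <- similarity_search("MKT", data.frame(ref_id = character(),
                                               family = character(),
                                               taxon = character(),
                                               protein = character(),
                                               stringsAsFactors = FALSE))
  expect_equal(classify_family(empty)$family, "unclassified")

  hits <- data.frame(ref_id = c("a", "b"), family = c("3FTx", "PLA2"),
                     taxon = c("s1", "s2"), score = c(80, 80),
                     identity = c(90, 70), stringsAsFactors = FALSE)
  # ties in score resolve toward the higher identity, already sorted upstream
  expect_equal(classify_family(hits, min_score = 50, min_identity = 30)$family,
               "3FTx")
  expect_equal(classify_family(hits, min_score = 90)$family, "unclassified")
  expect_equal(classify_family(hits, min_score = 50, min_identity = 95)$family,
               "unclassified")
})

test_that("planted families are recovered for uncorrupted ORFs", {
  ts1 <- generate_transcriptome(12, c("3FTx" = 0.5, kunitz = 0.3, PLA2 = 0.2),
                                mean_length = 700, seed = 3, species_id = "spA")
  ts2 <- generate_transcriptome(12, c("3FTx" = 0.5, kunitz = 0.3, PLA2 = 0.2),
                                mean_length = 700, seed = 303, species_id = "spB")
  db <- toxin_reference_db(list(ts1, ts2))
  hitrate <- mean(vapply(seq_len(12), function(i) {
    tr <- ts1$transcripts[i, ]
    cds <- substr(tr$sequence, tr$orf_start + 1, tr$orf_end)
    prot <- translate_cds(substr(cds, 1, nchar(cds) - 3))
    ann <- classify_family(similarity_search(prot, db), min_score = 50,
                           min_identity = 30)
    ann$family == tr$family && ann$taxon == "spA"
  }, TRUE))
  expect_gte(hitrate, 0.99)
})
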