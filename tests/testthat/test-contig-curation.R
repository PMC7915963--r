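test_that("map_reads places exact substrings and rejects foreign reads", {
  set.seed(3)
  ctg <- c(c1 = oracle_random_dna(500), c2 = oracle_random_dna(500))
  rd <- substr(ctg[["c1"]], 101, 160)
  rs <- manual_reads(c(rd, oracle_revcomp(rd), oracle_random_dna(60)))
  aln <- map_reads(rs, ctg, seed_length = 20, max_mismatches = 3)
  p <- aln$placements
  expect_equal(p$contig_id[p$read_id == "r001"], "c1")
  expect_equal(p$start[p$read_id == "r001"], 100)
  expect_equal(p$mismatches[p$read_id == "r001"], 0)
  expect_equal(p$strand[p$read_id == "r002"], "-")
  expect_equal(p$start[p$read_id == "r002"], 100)
  expect_true("r003" %in% aln$unmapped)

  none <- map_reads(rs, character(0))
  expect_equal(sort(none$unmapped), sort(rs$reads$read_id))
})

test_that("map_reads agrees with the exhaustive-alignment oracle", {
  set.seed(4)
  contigs <- setNames(replicate(5, oracle_random_dna(300)), paste0("c", 1:5))
  reads <- character(30)
  for (i in 1:30) {
    src <- sample(5, 1)
    o <- sample(0:(300 - 50), 1)
    r <- substr(contigs[[src]], o + 1, o + 50)
    nmut <- sample(0:2, 1)
    if (nmut > 0) {
      pos <- sample(50, nmut)
      ch <- strsplit(r, "")[[1]]
      for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      r <- paste(ch, collapse = "")
    }
    if (runif(1) < 0.5) r <- oracle_revcomp(r)
    reads[i] <- r
  }
  aln <- map_reads(manual_reads(reads), contigs, seed_length = 12,
                   max_mismatches = 4)
  for (i in 1:30) {
    id <- sprintf("r%03d", i)
    want <- oracle_best_placements(reads[i], contigs)
    got <- aln$placements[aln$placements$read_id == id, ]
    expect_equal(unique(got$mismatches), want$best)
    want_keys <- sort(vapply(want$hits, function(h)
      paste(h$contig, h$start, h$strand), ""))
    got_keys <- sort(paste(got$contig_id, got$start, got$strand))
    expect_equal(got_keys, want_keys)
  }
})

test_that("tied best placements share weight under the fraction policy", {
  ctg <- c(a = strrep("ACGTTGCAGG", 10), b = strrep("ACGTTGCAGG", 10))
  rd <- substr(ctg[["a"]], 1, 40)
  aln <- map_reads(manual_reads(rd), ctg, seed_length = 10, max_mismatches = 0)
  p <- aln$placements
  expect_equal(sum(p$weight), 1)
  expect_true(all(p$weight < 1))
  prim <- map_reads(manual_reads(rd), ctg, seed_length = 10,
                    max_mismatches = 0, policy = "primary")
  expect_equal(nrow(prim$placements), 1)
  expect_equal(prim$placements$weight, 1)
})

test_that("coverage_profile equals the interval-stabbing oracle", {
  set.seed(6)
  L <- 400
  ctg <- c(cc = oracle_random_dna(L))
  n <- 80
  starts <- sample(0:(L - 30), n, replace = TRUE)
  ends <- starts + sample(20:30, n, replace = TRUE)
  pl <- data.frame(read_id = sprintf("r%d", 1:n), contig_id = "cc",
                   start = starts, end = ends, strand = "+",
                   mismatches = 0L, weight = 1, stringsAsFactors = FALSE)
  prof <- coverage_profile(alignment_set(pl), ctg)
  expect_equal(prof$depth, oracle_coverage(starts, ends, L))
  expect_equal(sum(prof$depth), sum(ends - starts))

  one <- coverage_profile(alignment_set(pl[1, ]), ctg)
  expect_equal(sum(one$depth > 0), ends[1] - starts[1])
  zero <- coverage_profile(alignment_set(pl[0, ]), ctg)
  expect_equal(zero$depth, integer(L))
})

test_that("detect_chimera finds constructed steps and respects degenerate input", {
  prof <- structure(list(contig_id = "x",
                         depth = as.integer(c(rep(100, 200), rep(2, 200)))),
                    class = "CoverageProfile")
  call <- detect_chimera(prof, fold_threshold = 10, window = 25, min_depth = 10)
  expect_equal(call$verdict, "chimeric")
  expect_equal(nrow(call$breakpoints), 1)
  expect_lte(abs(call$breakpoints$position - 201), 25)
  expect_gte(call$breakpoints$fold_change, 10)

  flat <- structure(list(contig_id = "y", depth = rep(50L, 400)),
                    class = "CoverageProfile")
  expect_equal(detect_chimera(flat, 10, 25, 10)$verdict, "clean")

  short <- structure(list(contig_id = "z", depth = rep(50L, 30)),
                     class = "CoverageProfile")
  expect_equal(detect_chimera(short, 10, 25, 10)$verdict, "indeterminate")
})

test_that("detect_chimera is translation invariant", {
  mk <- function(at, L = 600) structure(
    list(contig_id = "t", depth = as.integer(c(rep(80, at), rep(4, L - at)))),
    class = "CoverageProfile")
  p1 <- detect_chimera(mk(200), 10, 25, 10)$breakpoints$position
  p2 <- detect_chimera(mk(350), 10, 25, 10)$breakpoints$position
  expect_equal(p2 - p1, 150)
})

test_that("assign_species follows the three-indicator majority rule", {
  ctg <- c(k1 = oracle_random_dna(200))
  ann <- structure(list(orf_id = "k1", family = "3FTx", best_hit = "ref",
                        score = 100, identity = 95, taxon = "spA",
                        hits = NULL), class = "ToxinAnnotation")
  full <- structure(list(contig_id = "k1", depth = rep(20L, 200)),
                    class = "CoverageProfile")
  sparse <- structure(list(contig_id = "k1",
                           depth = c(rep(1L, 30), rep(0L, 170))),
                      class = "CoverageProfile")

  # expression + similarity + coverage all point to spA
  a <- assign_species(ctg, c(spA = 1000, spB = 5), annotation = ann,
                      profiles_by_sample = list(spA = full, spB = sparse))
  expect_equal(a$assigned_species, "spA")
  expect_equal(a$confidence, "3/3")

  # only one sample has reads; similarity agrees
  b <- assign_species(ctg, c(spA = 800, spB = 0), annotation = ann,
                      profiles_by_sample = list(spA = full, spB = NULL))
  expect_equal(b$assigned_species, "spA")

  # expression equivocal, other two split -> ambiguous
  annB <- ann; annB$taxon <- "spB"
  c3 <- assign_species(ctg, c(spA = 100, spB = 80), annotation = annB,
                       profiles_by_sample = list(spA = full, spB = sparse))
  expect_equal(c3$assigned_species, "ambiguous")
  expect_equal(unname(c3$votes["expression"]), "equivocal")

  # a species with no mapped reads is never assigned
  d <- assign_species(ctg, c(spA = 0, spB = 0), annotation = ann,
                      profiles_by_sample = list(spA = sparse, spB = sparse))
  expect_equal(d$assigned_species, "ambiguous")
})

test_that("cluster_isoforms groups by identity with CD-HIT semantics", {
  s <- oracle_random_dna(300)
  mutate_at <- function(x, k) {
    ch <- strsplit(x, "")[[1]]
    pos <- sample(length(ch), k)
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    paste(ch, collapse = "")
  }
  set.seed(10)
  two <- c(a = s, b = s)
  cl <- cluster_isoforms(two, 0.99)
  expect_length(cl, 1)
  expect_setequal(cl[[1]]$members, c("a", "b"))
  # centroid is the longest member, ties broken lexicographically
  expect_equal(cl[[1]]$centroid, "a")

  far <- c(a = s, b = oracle_random_dna(300))
  expect_length(cluster_isoforms(far, 0.99), 2)

  # planted partition: 5 families, intra <= 1%, inter >= 5%
  fams <- lapply(1:5, function(i) oracle_random_dna(400))
  seqs <- character(); ids <- character()
  for (i in 1:5) {
    for (j in 1:sample(2:4, 1)) {
      ids <- c(ids, sprintf("f%d_m%d", i, j))
      # members within 0.5% of the family prototype: pairwise <= 1%
      seqs <- c(seqs, if (j == 1) fams[[i]] else
        mutate_at(fams[[i]], sample(0:2, 1)))
    }
  }
  names(seqs) <- ids
  cl2 <- cluster_isoforms(seqs, 0.99)
  expect_length(cl2, 5)
  for (c_ in cl2) {
    expect_length(unique(sub("_m[0-9]+$", "", c_$members)), 1)
  }
  # partition property
  expect_equal(sum(vapply(cl2, function(x) length(x$members), 1L)),
               length(seqs))
  # clusters sorted by member count descending
  sizes <- vapply(cl2, function(x) length(x$members), 1L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("SAM export and import round-trip an alignment set", {
  set.seed(11)
  ctg <- c(c1 = oracle_random_dna(120))
  rd <- substr(ctg[["c1"]], 11, 60)
  rs <- manual_reads(c(rd, oracle_random_dna(50)))
  aln <- map_reads(rs, ctg, seed_length = 15, max_mismatches = 2)
  sam <- tempfile(fileext = ".sam")
  write_sam(aln, ctg, sam, reads = rs)
  back <- read_sam(sam)
  expect_equal(back$placements$read_id, aln$placements$read_id)
  expect_equal(back$placements$start, aln$placements$start)
  expect_equal(back$placements$end, aln$placements$end)
  expect_equal(back$placements$mismatches, aln$placements$mismatches)
  expect_equal(sort(back$unmapped), sort(aln$unmapped))
})
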