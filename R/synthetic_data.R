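#' Generate a synthetic venom-gland transcript repertoire
#'
#' Builds a species-specific set of toxin-like transcripts with known ground
#' truth. Each toxin family is represented by a random prototype coding
#' sequence; family members are lightly diverged copies of the prototype
#' (mimicking isoform radiations), flanked by random UTRs. Expression
#' weights combine the family weight with a log-normal draw, reproducing the
#' strong skew of venom glands where a few families dominate both expression
#' and contig counts.
#'
#' @param n_transcripts Number of transcripts to generate.
#' @param family_profile Named numeric vector of nonnegative family weights
#'   (e.g. `c("3FTx" = 0.7, PLA2 = 0.3)`); governs both the family assignment
#'   frequencies and the relative expression mass of each family.
#' @param mean_length Mean transcript length in nucleotides.
#' @param seed Integer seed; fixed seeds give byte-identical output.
#' @param species_id Species label carried by the set.
#' @param divergence Per-base divergence of family members from their family
#'   prototype (substitutions only; the designed ORF is preserved).
#' @param weight_sigma Log-scale standard deviation of the per-transcript
#'   expression draw.
#' @return A `TranscriptSet`: list with `species_id`, a `transcripts` data
#'   frame (`transcript_id`, `sequence`, `family`, `weight`, `orf_start`,
#'   `orf_end`, 0-based half-open CDS coordinates), and `prototypes`
#'   (per-family prototype CDS).
#' @export
generate_transcriptome <- function(n_transcripts, family_profile, mean_length = 1500L,
                                   seed = 1L, species_id = "sp1",
                                   divergence = 0.02, weight_sigma = 1.5) {
  stopifnot(n_transcripts >= 1)
  if (length(family_profile) == 0) stop("family_profile must not be empty")
  if (is.null(names(family_profile)) || any(!nzchar(names(family_profile)))) {
    stop("family_profile must be a named vector")
  }
  if (any(family_profile < 0) || sum(family_profile) <= 0) {
    stop("family weights must be nonnegative and not all zero")
  }
  set.seed(seed)
  prob <- family_profile / sum(family_profile)
  fams <- sample(names(prob), n_transcripts, replace = TRUE, prob = prob)

  orf_codons <- max(60L, as.integer(round(mean_length * 0.6 / 3)))
  prototypes <- vapply(sort(unique(fams)), function(f) {
    random_coding_sequence(orf_codons, complete = TRUE)
  }, "")

  rows <- lapply(seq_len(n_transcripts), function(i) {
    fam <- fams[[i]]
    cds <- mutate_orf(prototypes[[fam]], divergence)
    target <- max(nchar(cds) + 40L, as.integer(round(stats::rnorm(1, mean_length, mean_length * 0.1))))
    utr_total <- target - nchar(cds)
    utr5 <- max(10L, as.integer(round(stats::runif(1, 0.2, 0.5) * utr_total)))
    utr3 <- max(10L, utr_total - utr5)
    seq <- paste0(random_dna(utr5), cds, random_dna(utr3))
    w <- unname(prob[fam]) * stats::rlnorm(1, 0, weight_sigma)
    data.frame(
      transcript_id = sprintf("%s_t%04d", species_id, i),
      sequence = seq, family = fam, weight = w,
      orf_start = utr5, orf_end = utr5 + nchar(cds),
      stringsAsFactors = FALSE
    )
  })
  structure(list(species_id = species_id,
                 transcripts = do.call(rbind, rows),
                 prototypes = prototypes),
            class = "TranscriptSet")
}

#' @export
print.TranscriptSet <- function(x, ...) {
  cat(sprintf("TranscriptSet '%s': %d transcripts, families: %s\n", x$species_id,
              nrow(x$transcripts), paste(names(x$prototypes), collapse = ", ")))
  invisible(x)
}

#' Random coding sequence
#'
#' Uniform random codons avoiding stops; optionally a complete ORF
#' (leading ATG, terminal stop).
#'
#' @param n_codons Number of sense codons (excluding the stop).
#' @param complete If `TRUE`, start with ATG and append a stop codon.
#' @return A nucleotide string.
#' @export
random_coding_sequence <- function(n_codons, complete = FALSE) {
  stopifnot(n_codons >= 1)
  sense <- setdiff(all_codons(), STOP_CODONS)
  cods <- sample(sense, n_codons, replace = TRUE)
  if (complete) {
    cods[1] <- "ATG"
    cods <- c(cods, sample(STOP_CODONS, 1))
  }
  paste(cods, collapse = "")
}

random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Substitute bases at rate `rate`, then repair the reading frame so the
# designed ORF stays complete: restore the start codon, replace any internal
# stop created by mutation with a random sense codon, restore the stop.
mutate_orf <- function(cds, rate) {
  if (rate <= 0) return(cds)
  mut <- as.character(cpp_mutate_bases(cds, rate))
  cods <- codon_split(mut)
  n <- length(cods)
  cods[1] <- "ATG"
  internal <- which(cods[-n] %in% STOP_CODONS)
  if (length(internal)) {
    sense <- setdiff(all_codons(), STOP_CODONS)
    cods[internal] <- sample(sense, length(internal), replace = TRUE)
  }
  if (!(cods[n] %in% STOP_CODONS)) cods[n] <- sample(STOP_CODONS, 1)
  paste(cods, collapse = "")
}

#' Build a labelled reference protein database from transcript sets
#'
#' Translates each family prototype of each species into a reference entry
#' with header fields `refid|FAMILY|taxon`, emulating a curated toxin
#' database for annotation and species-assignment tests. The database is
#' synthetic: entries derive from the generator's prototypes, not from any
#' curated archive.
#'
#' @param ts_list A `TranscriptSet` or list of them.
#' @return Data frame with columns `ref_id`, `family`, `taxon`, `protein`.
#' @export
toxin_reference_db <- function(ts_list) {
  if (inherits(ts_list, "TranscriptSet")) ts_list <- list(ts_list)
  rows <- lapply(ts_list, function(ts) {
    data.frame(
      ref_id = sprintf("%s_%s_ref", ts$species_id, names(ts$prototypes)),
      family = names(ts$prototypes),
      taxon = ts$species_id,
      protein = vapply(ts$prototypes, function(cds) translate_cds(strip_stop(cds)), ""),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

strip_stop <- function(cds) {
  cods <- codon_split(cds)
  if (length(cods) && cods[length(cods)] %in% STOP_CODONS) {
    cods <- cods[-length(cods)]
  }
  paste(cods, collapse = "")
}

#' Simulate reads from a transcript set
#'
#' Reads are drawn from transcripts with probability proportional to
#' expression weight times transcript length (so per-base coverage is
#' proportional to expression weight), placed uniformly, assigned to either
#' strand with probability 0.5, and subjected to uniform per-base
#' substitution errors. Quality strings are constant Phred 40 ("I"): quality
#' trimming is outside this pipeline's scope, so quality is cosmetic.
#'
#' @param ts A `TranscriptSet`.
#' @param n_reads Number of reads (0 gives an empty ReadSet).
#' @param read_length Read length in nt; must not exceed the longest
#'   transcript.
#' @param error_rate Per-base substitution error rate in `[0, 1)`.
#' @param seed Integer seed.
#' @return A `ReadSet` whose `true_source` is the species id.
#' @export
simulate_reads <- function(ts, n_reads, read_length = 150L, error_rate = 0.01,
                           seed = 1L) {
  stopifnot(inherits(ts, "TranscriptSet"), error_rate >= 0, error_rate < 1)
  tr <- ts$transcripts
  if (n_reads == 0) return(read_set(ts$species_id))
  len <- nchar(tr$sequence)
  eligible <- which(len >= read_length)
  if (!length(eligible)) stop("read_length exceeds every transcript length")
  set.seed(seed)
  p <- tr$weight[eligible] * len[eligible]
  idx <- eligible[sample.int(length(eligible), n_reads, replace = TRUE, prob = p)]
  start <- floor(stats::runif(n_reads) * (len[idx] - read_length + 1)) + 1L
  seqs <- substring(tr$sequence[idx], start, start + read_length - 1L)
  rev <- stats::runif(n_reads) < 0.5
  if (any(rev)) seqs[rev] <- as.character(cpp_revcomp(seqs[rev]))
  if (error_rate > 0) seqs <- as.character(cpp_mutate_bases(seqs, error_rate))
  read_set(
    sample_id = ts$species_id,
    read_id = sprintf("%s_read%07d", ts$species_id, seq_len(n_reads)),
    sequence = seqs,
    quality = strrep("I", read_length),
    true_source = ts$species_id
  )
}

#' Spike cross-sample contamination into a multiplexed batch
#'
#' Copies reads between samples so that each sample's expected contaminant
#' fraction equals `rate`, emulating the read leakage (index hopping)
#' observed when several libraries share a sequencing run. Spiked reads are
#' verbatim copies carrying `true_source = "contaminant:<origin>"`; genuine
#' reads are untouched.
#'
#' @param read_sets List of at least two `ReadSet` objects with unique
#'   sample ids.
#' @param rate Contamination rate in `[0, 1)`.
#' @param seed Integer seed.
#' @return A `MultiplexBatch`: list with `read_sets` (named list) and
#'   `contamination_rate`.
#' @export
spike_contamination <- function(read_sets, rate, seed = 1L) {
  stopifnot(rate >= 0, rate < 1)
  if (length(read_sets) < 2) stop("contamination is undefined for a single sample")
  ids <- vapply(read_sets, function(r) r$sample_id, "")
  if (anyDuplicated(ids)) stop("sample ids must be unique")
  set.seed(seed)
  out <- read_sets
  for (i in seq_along(read_sets)) {
    n_i <- n_reads(read_sets[[i]])
    m <- stats::rbinom(1, n_i, rate)
    if (m == 0) next
    donor_pool <- do.call(rbind, lapply(read_sets[-i], function(r) {
      data.frame(sequence = r$reads$sequence, quality = r$reads$quality,
                 origin = r$sample_id, stringsAsFactors = FALSE)
    }))
    pick <- sample.int(nrow(donor_pool), m, replace = TRUE)
    spiked <- data.frame(
      read_id = sprintf("%s_ctm%06d", ids[i], seq_len(m)),
      sequence = donor_pool$sequence[pick],
      quality = donor_pool$quality[pick],
      true_source = paste0("contaminant:", donor_pool$origin[pick]),
      stringsAsFactors = FALSE
    )
    out[[i]]$reads <- rbind(read_sets[[i]]$reads, spiked)
  }
  names(out) <- ids
  structure(list(read_sets = out, contamination_rate = rate),
            class = "MultiplexBatch")
}

#' @export
print.MultiplexBatch <- function(x, ...) {
  cat(sprintf("MultiplexBatch: %d samples, contamination rate %g\n",
              length(x$read_sets), x$contamination_rate))
  invisible(x)
}

#' Construct a chimeric contig from two parents
#'
#' Joins the prefix of `a` (up to `breakpoint`) to a suffix of `b`,
#' emulating a mis-assembly that fuses two transcripts. The true breakpoint
#' is recorded on the returned contig for ground-truth scoring.
#'
#' @param a,b Parent contigs (`Contig` objects or single named character
#'   vectors).
#' @param breakpoint Number of leading bases taken from `a`
#'   (`0 < breakpoint <= nchar(a)`).
#' @param b_from 1-based position in `b` where the suffix starts; defaults
#'   to `breakpoint + 1` so that coordinates line up with `a`'s.
#' @return A `Contig` with extra fields `breakpoint`, `parent_a`, `parent_b`.
#' @export
make_chimera <- function(a, b, breakpoint, b_from = breakpoint + 1) {
  a <- as_contig(a); b <- as_contig(b)
  la <- nchar(a$sequence)
  if (breakpoint <= 0 || breakpoint > la) {
    stop("breakpoint must be in (0, length(a)]")
  }
  suffix <- if (b_from > nchar(b$sequence)) "" else substring(b$sequence, b_from)
  out <- contig(paste0(a$contig_id, "x", b$contig_id),
                paste0(substring(a$sequence, 1, breakpoint), suffix))
  out$breakpoint <- breakpoint
  out$parent_a <- a$contig_id
  out$parent_b <- b$contig_id
  out
}

#' Evolve a codon alignment under a known dN/dS ratio
#'
#' Simulates codon evolution from a common ancestor along a star tree (or a
#' supplied tree) under a continuous-time Markov process with an HKY-style
#' nucleotide kernel: single-nucleotide codon changes have rate 1, times
#' `kappa` for transitions, times `omega` when the change is nonsynonymous;
#' changes into stop codons have rate zero, so stops are unreachable. This
#' is an MG94-flavoured approximation adequate for estimator recovery tests,
#' not a fitted substitution model. Rates are scaled so that `branch_length`
#' is the expected number of substitutions per codon site at the ancestral
#' composition.
#'
#' @param ancestor_cds Codon sequence (length divisible by 3, no stop
#'   codons anywhere).
#' @param n_taxa Number of taxa (star tree); ignored when `tree` is given.
#' @param branch_length Expected substitutions per codon from root to tip.
#' @param omega Nonsynonymous/synonymous rate ratio.
#' @param kappa Transition/transversion rate ratio. The default 1 matches
#'   the rate symmetry assumed by the counting estimator this simulator is
#'   used to calibrate.
#' @param seed Integer seed.
#' @param tree Optional `phylo` tree; edge lengths are taken as expected
#'   substitutions per codon site.
#' @return A `CodonAlignment`.
#' @export
evolve_codon_clade <- function(ancestor_cds, n_taxa, branch_length, omega,
                               kappa = 1, seed = 1L, tree = NULL) {
  if (nchar(ancestor_cds) %% 3 != 0) stop("ancestor length must be divisible by 3")
  anc <- codon_split(toupper(ancestor_cds))
  if (any(anc %in% STOP_CODONS)) stop("ancestor contains a stop codon")
  if (is.null(tree) && n_taxa < 2) stop("n_taxa must be >= 2")
  stopifnot(omega > 0, kappa > 0, branch_length >= 0)
  set.seed(seed)
  mach <- codon_machinery()
  # per-codon neighbor rates for this (omega, kappa)
  rates <- mach$base_rate *
    ifelse(mach$is_ts, kappa, 1) *
    ifelse(mach$is_syn, 1, omega)        # 64 x 9 matrix; stops already 0
  total <- rowSums(rates)
  anc_idx <- match(anc, mach$codons)
  mean_rate <- mean(total[anc_idx])
  if (mean_rate <= 0) stop("ancestor admits no substitutions")
  scale <- 1 / mean_rate                  # time unit: expected subs/codon site

  evolve_branch <- function(idx, bl) {
    if (bl <= 0) return(idx)
    for (s in seq_along(idx)) {
      t <- 0
      repeat {
        lam <- total[idx[s]] * scale / 1   # intensity per unit branch length
        if (lam <= 0) break
        t <- t + stats::rexp(1, lam)
        if (t > bl) break
        nb <- mach$neighbor[idx[s], ]
        p <- rates[idx[s], ]
        idx[s] <- nb[sample.int(9L, 1L, prob = p)]
      }
    }
    idx
  }

  if (is.null(tree)) {
    seqs <- vapply(seq_len(n_taxa), function(i) {
      paste(mach$codons[evolve_branch(anc_idx, branch_length)], collapse = "")
    }, "")
    names(seqs) <- sprintf("t%02d", seq_len(n_taxa))
  } else {
    stopifnot(inherits(tree, "phylo"))
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    node_seq <- vector("list", ntip + tree$Nnode)
    node_seq[[root]] <- anc_idx
    ord <- ape::reorder.phylo(tree, "cladewise")
    seqs <- character(ntip)
    for (e in seq_len(nrow(ord$edge))) {
      from <- ord$edge[e, 1]; to <- ord$edge[e, 2]
      node_seq[[to]] <- evolve_branch(node_seq[[from]], ord$edge.length[e])
      if (to <= ntip) seqs[to] <- paste(mach$codons[node_seq[[to]]], collapse = "")
    }
    names(seqs) <- tree$tip.label
  }
  codon_alignment(seqs)
}

#' Build the standard synthetic multiplexed study
#'
#' Bundles the generator calls into the package's reference study
#' conditions: three species-specific transcript repertoires (disjoint
#' sequence space, 20 transcripts each, family profile 3FTx 0.6 / kunitz
#' 0.25 / PLA2 0.1 / CRiSP 0.05), 100,000 reads of 150 nt per sample at 1
#' percent substitution error, 1 percent cross-sample contamination, a
#' contig set equal to the truth transcripts (assembly is an external
#' hand-off) plus optional planted in-frame chimeras, and the matching
#' synthetic reference protein database.
#'
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param n_species,n_transcripts,n_reads,read_length,error_rate,contamination_rate
#'   Study conditions (defaults as above).
#' @param n_chimeras Planted chimeras per species (joined at a codon
#'   boundary between each species' two most expressed transcripts).
#' @param family_profile Family weights used for every species.
#' @return List with `transcript_sets`, `batch` (a `MultiplexBatch`),
#'   `contigs` (named character), `ref_db`, `chimera_truth` (data frame
#'   `contig_id`, `breakpoint`), and `truth_tpm` (per species, the planted
#'   expression in TPM units).
#' @export
synthetic_study <- function(seed = 1L, n_species = 3L, n_transcripts = 20L,
                            n_reads = 100000L, read_length = 150L,
                            error_rate = 0.01, contamination_rate = 0.01,
                            n_chimeras = 2L,
                            family_profile = c("3FTx" = 0.6, kunitz = 0.25,
                                               PLA2 = 0.1, CRiSP = 0.05)) {
  seed <- as.integer(seed) %% 100000L
  species <- sprintf("sp%d", seq_len(n_species))
  tsets <- lapply(seq_len(n_species), function(i) {
    generate_transcriptome(n_transcripts, family_profile, mean_length = 1500L,
                           seed = seed * 31L + i, species_id = species[i])
  })
  names(tsets) <- species
  read_sets <- lapply(seq_len(n_species), function(i) {
    simulate_reads(tsets[[i]], n_reads, read_length, error_rate,
                   seed = seed * 31L + 1000L + i)
  })
  batch <- spike_contamination(read_sets, contamination_rate,
                               seed = seed * 31L + 2000L)
  contigs <- unlist(lapply(tsets, function(ts) {
    stats::setNames(ts$transcripts$sequence, ts$transcripts$transcript_id)
  }))
  names(contigs) <- sub("^sp[0-9]+\\.", "", names(contigs))
  chim_rows <- list()
  if (n_chimeras > 0) {
    set.seed(seed * 31L + 3000L)
    for (ts in tsets) {
      tr <- ts$transcripts[order(-ts$transcripts$weight), ]
      for (ci in seq_len(min(n_chimeras, nrow(tr) %/% 2))) {
        # fuse a dominant transcript with a minor one (typical of coverage
        # step chimeras), joining both CDSs at the same in-frame offset d
        # so the fused ORF stays complete: t1 start, t2 stop, no junction
        # codon; d kept a read length away from the CDS ends
        t1 <- tr[ci, ]; t2 <- tr[min(ci + nrow(tr) %/% 2, nrow(tr)), ]
        d_max <- min(t1$orf_end - t1$orf_start, t2$orf_end - t2$orf_start) - 180L
        if (d_max <= 180L) next
        d <- 3L * sample(seq(60L, d_max %/% 3L), 1L)
        ch <- make_chimera(stats::setNames(t1$sequence, t1$transcript_id),
                           stats::setNames(t2$sequence, t2$transcript_id),
                           breakpoint = t1$orf_start + d,
                           b_from = t2$orf_start + d + 1L)
        chim_rows[[length(chim_rows) + 1L]] <-
          data.frame(contig_id = ch$contig_id, breakpoint = ch$breakpoint,
                     sequence = ch$sequence, stringsAsFactors = FALSE)
      }
    }
  }
  chimera_truth <- if (length(chim_rows)) {
    do.call(rbind, chim_rows)
  } else {
    data.frame(contig_id = character(), breakpoint = integer(),
               sequence = character(), stringsAsFactors = FALSE)
  }
  if (nrow(chimera_truth)) {
    contigs <- c(contigs, stats::setNames(chimera_truth$sequence,
                                          chimera_truth$contig_id))
  }
  truth_tpm <- lapply(tsets, function(ts) {
    w <- ts$transcripts$weight
    stats::setNames(1e6 * w / sum(w), ts$transcripts$transcript_id)
  })
  list(transcript_sets = tsets, batch = batch, contigs = contigs,
       ref_db = toxin_reference_db(tsets),
       chimera_truth = chimera_truth[, c("contig_id", "breakpoint")],
       truth_tpm = truth_tpm)
}

all_codons <- function() {
  b <- c("T", "C", "A", "G")
  g <- expand.grid(p3 = b, p2 = b, p1 = b, stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}

# Precomputed codon neighbor structure shared by the simulator and the
# NG86 estimator: for each codon, its nine single-nucleotide neighbors with
# transition / synonymy / stop flags.
codon_machinery <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    codons <- all_codons()
    gc <- Biostrings::GENETIC_CODE
    aa <- unname(gc[codons])
    n <- length(codons)
    neighbor <- matrix(0L, n, 9)
    is_ts <- matrix(FALSE, n, 9)
    is_syn <- matrix(FALSE, n, 9)
    base_rate <- matrix(1, n, 9)
    nts <- c("A", "C", "G", "T")
    purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
    for (i in seq_len(n)) {
      cod <- strsplit(codons[i], "")[[1]]
      col <- 0L
      for (pos in 1:3) {
        for (alt in setdiff(nts, cod[pos])) {
          col <- col + 1L
          nb <- cod; nb[pos] <- alt
          nbc <- paste(nb, collapse = "")
          j <- match(nbc, codons)
          neighbor[i, col] <- j
          is_ts[i, col] <- purine[[cod[pos]]] == purine[[alt]]
          is_syn[i, col] <- aa[j] == aa[i]
          if (aa[j] == "*" || aa[i] == "*") base_rate[i, col] <- 0
        }
      }
    }
    cache <<- list(codons = codons, aa = aa, neighbor = neighbor,
                   is_ts = is_ts, is_syn = is_syn, base_rate = base_rate)
    cache
  }
})
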