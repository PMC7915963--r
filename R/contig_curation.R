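#' Map reads to contigs with a seed-and-verify aligner
#'
#' Exact `seed_length`-mers anchor candidate placements which are verified
#' by direct mismatch counting on both strands; every placement tied at the
#' minimum mismatch count is reported. Reads whose best placement exceeds
#' `max_mismatches` are unmapped. This is a desk-scale substitution-only
#' mapper; import real alignments with [read_sam()] when indels matter.
#'
#' @param reads A `ReadSet`.
#' @param contigs Named character vector of contig sequences.
#' @param seed_length Exact-match seed length (<= 31).
#' @param max_mismatches Maximum allowed mismatches.
#' @param policy `"fraction"` (weight 1/n over n tied best placements) or
#'   `"primary"` (first placement, weight 1).
#' @return An `AlignmentSet`.
#' @export
map_reads <- function(reads, contigs, seed_length = 31L, max_mismatches = 8L,
                      policy = c("fraction", "primary")) {
  stopifnot(inherits(reads, "ReadSet"))
  policy <- match.arg(policy)
  r <- reads$reads
  empty <- data.frame(read_id = character(), contig_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      mismatches = integer(), weight = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(r) == 0 || length(contigs) == 0) {
    return(alignment_set(empty, unmapped = r$read_id, policy = policy))
  }
  if (is.null(names(contigs))) stop("contigs must be named")
  res <- cpp_map_reads(r$sequence, unname(contigs),
                       as.integer(seed_length), as.integer(max_mismatches))
  if (length(res$read) == 0) {
    return(alignment_set(empty, unmapped = r$read_id, policy = policy))
  }
  pl <- data.frame(
    read_id = r$read_id[res$read],
    contig_id = names(contigs)[res$contig],
    start = res$start,
    end = res$start + nchar(r$sequence)[res$read],
    strand = ifelse(res$strand > 0, "+", "-"),
    mismatches = res$mismatches,
    weight = 1 / res$n_best,
    stringsAsFactors = FALSE
  )
  if (policy == "primary") {
    pl <- pl[!duplicated(pl$read_id), , drop = FALSE]
    pl$weight <- 1
  }
  unmapped <- setdiff(r$read_id, pl$read_id)
  rownames(pl) <- NULL
  alignment_set(pl, unmapped = unmapped, policy = policy)
}

#' Per-base read coverage of a contig
#'
#' `depth[i]` is the number of placements whose interval contains position
#' `i` (1-based in the returned vector; placements use 0-based half-open
#' coordinates).
#'
#' @param aln An `AlignmentSet`.
#' @param x The `Contig` (or single named character) to profile.
#' @return A `CoverageProfile`: list with `contig_id` and integer `depth`
#'   of length `nchar(contig)`.
#' @export
coverage_profile <- function(aln, x) {
  ct <- as_contig(x)
  L <- nchar(ct$sequence)
  p <- aln$placements
  p <- p[p$contig_id == ct$contig_id, , drop = FALSE]
  depth <- integer(L)
  if (nrow(p)) {
    if (any(p$start < 0 | p$end > L | p$start >= p$end)) {
      stop("placement outside contig bounds")
    }
    s <- tabulate(p$start + 1L, nbins = L)
    e <- tabulate(p$end + 1L, nbins = L + 1L)
    depth <- cumsum(s - e[seq_len(L)])
  }
  structure(list(contig_id = ct$contig_id, depth = as.integer(depth)),
            class = "CoverageProfile")
}

#' Screen a coverage profile for chimeric discontinuities
#'
#' Compares the median depth of the `window` bases on either side of every
#' interior position; a position is a breakpoint when the higher/lower
#' median ratio reaches `fold_threshold` and the higher side's median is at
#' least `min_depth`. Windowed medians resist sampling noise that
#' single-base ratios would amplify. Runs of adjacent breakpoint positions
#' are merged, reporting the position of the strongest ratio in each run.
#' A zero low-side median is treated as a floor of 0.5 when forming the
#' reported fold change.
#'
#' With a full-containment mapper, depth necessarily ramps to zero over the
#' last read length at each end of a reference; `margin` excludes those
#' flank positions from breakpoint calling (set it to the read length when
#' the profile comes from [map_reads()]).
#'
#' @param profile A `CoverageProfile`.
#' @param fold_threshold Minimum high/low median ratio (>= 1; default 10).
#' @param window Window half-width in nt (default 25).
#' @param min_depth Minimum median depth on the higher side (default 10).
#' @param margin Flank width (nt) excluded from breakpoint calling at each
#'   end; defaults to `window`.
#' @return A `ChimeraCall`: list with `contig_id`, `breakpoints` data frame
#'   (`position`, `fold_change`), and `verdict` in
#'   `{"clean", "chimeric", "indeterminate"}`.
#' @export
detect_chimera <- function(profile, fold_threshold = 10, window = 25L,
                           min_depth = 10L, margin = window) {
  stopifnot(inherits(profile, "CoverageProfile"), fold_threshold >= 1)
  d <- profile$depth
  L <- length(d)
  lo_pos <- max(window, margin) + 1L
  hi_pos <- L - max(window, margin) + 1L
  empty_bp <- data.frame(position = integer(), fold_change = numeric())
  if (L < 2L * window || lo_pos > hi_pos) {
    return(structure(list(contig_id = profile$contig_id, breakpoints = empty_bp,
                          verdict = "indeterminate"), class = "ChimeraCall"))
  }
  pos <- lo_pos:hi_pos  # boundary between pos-1 and pos
  lm <- running_median(d, window, align = "right")[pos - 1L]
  rm_ <- running_median(d, window, align = "left")[pos]
  hi <- pmax(lm, rm_)
  lo <- pmin(lm, rm_)
  ratio <- hi / pmax(lo, 0.5)
  is_bp <- hi >= min_depth & ratio >= fold_threshold
  bp <- empty_bp
  if (any(is_bp)) {
    runs <- split(which(is_bp), cumsum(c(1L, diff(which(is_bp)) != 1L)))
    bp <- do.call(rbind, lapply(runs, function(ix) {
      best <- ix[which.max(ratio[ix])]
      data.frame(position = pos[best], fold_change = ratio[best])
    }))
    rownames(bp) <- NULL
  }
  structure(list(contig_id = profile$contig_id, breakpoints = bp,
                 verdict = if (nrow(bp)) "chimeric" else "clean"),
            class = "ChimeraCall")
}

# Median of a sliding window of width w; align "right" gives at position i
# the median of d[(i-w+1):i], align "left" the median of d[i:(i+w-1)].
# Positions where the window overruns the vector are NA.
running_median <- function(d, w, align = c("right", "left")) {
  align <- match.arg(align)
  L <- length(d)
  out <- rep(NA_real_, L)
  if (L < w) return(out)
  if (align == "right") {
    for (i in w:L) out[i] <- stats::median(d[(i - w + 1L):i])
  } else {
    for (i in 1L:(L - w + 1L)) out[i] <- stats::median(d[i:(i + w - 1L)])
  }
  out
}

#' @export
print.ChimeraCall <- function(x, ...) {
  cat(sprintf("ChimeraCall %s: %s (%d breakpoint%s)\n", x$contig_id, x$verdict,
              nrow(x$breakpoints), if (nrow(x$breakpoints) == 1) "" else "s"))
  invisible(x)
}

#' Assign a contig's species of origin by three indicators
#'
#' Emulates the curation rule for multiplexed runs: since co-sequenced
#' species are distantly related, reads from several species aligning to
#' one contig indicate contamination, and the contig belongs to the species
#' with clearly higher expression. Three indicators vote:
#' \describe{
#'   \item{expression}{the sample whose TPM exceeds every other sample's by
#'     at least `expression_fold` (else equivocal);}
#'   \item{similarity}{the taxon of the annotation's best hit when it names
#'     a multiplexed sample (else equivocal);}
#'   \item{coverage}{the sample whose profile covers at least
#'     `breadth_high` of the contig while every other sample covers at most
#'     `breadth_low` (else equivocal).}
#' }
#' The contig is assigned when at least two non-equivocal votes agree;
#' otherwise it is `"ambiguous"`. A species with zero mapped coverage and
#' zero expression is never returned.
#'
#' @param x The `Contig` (or single named character).
#' @param tpm_by_sample Named numeric: the contig's TPM in each sample.
#' @param annotation A `ToxinAnnotation` (or `NULL`).
#' @param profiles_by_sample Named list of `CoverageProfile` for this
#'   contig, one per sample (or `NULL` entries).
#' @param expression_fold Minimum TPM fold difference (default 5).
#' @param breadth_high,breadth_low Covered-fraction cutoffs for the
#'   coverage vote.
#' @return A `SpeciesAssignment`: list with `contig_id`, `assigned_species`
#'   (or `"ambiguous"`), `votes` (named character), `confidence`
#'   (`"3/3"`, `"2/3"`, or `"ambiguous"`).
#' @export
assign_species <- function(x, tpm_by_sample, annotation = NULL,
                           profiles_by_sample = NULL, expression_fold = 5,
                           breadth_high = 0.8, breadth_low = 0.5) {
  ct <- as_contig(x)
  stopifnot(!is.null(names(tpm_by_sample)))
  samples <- names(tpm_by_sample)

  expr_vote <- "equivocal"
  if (any(tpm_by_sample > 0)) {
    ord <- order(tpm_by_sample, decreasing = TRUE)
    top <- tpm_by_sample[ord[1]]
    second <- if (length(ord) > 1) tpm_by_sample[ord[2]] else 0
    if (top > 0 && (second == 0 || top / second >= expression_fold)) {
      expr_vote <- samples[ord[1]]
    }
  }

  sim_vote <- "equivocal"
  if (!is.null(annotation) && !is.na(annotation$taxon) &&
      annotation$taxon %in% samples) {
    sim_vote <- annotation$taxon
  }

  cov_vote <- "equivocal"
  breadth <- rep(0, length(samples))
  names(breadth) <- samples
  if (!is.null(profiles_by_sample)) {
    for (s in samples) {
      pr <- profiles_by_sample[[s]]
      if (!is.null(pr)) breadth[s] <- mean(pr$depth > 0)
    }
    full <- breadth >= breadth_high
    if (sum(full) == 1 && all(breadth[!full] <= breadth_low)) {
      cov_vote <- samples[full]
    }
  }

  votes <- c(expression = expr_vote, similarity = sim_vote, coverage = cov_vote)
  nz <- votes[votes != "equivocal"]
  assigned <- "ambiguous"
  confidence <- "ambiguous"
  if (length(nz) >= 2) {
    tab <- sort(table(nz), decreasing = TRUE)
    if (tab[1] >= 2) {
      cand <- names(tab)[1]
      # never assign a species with no read support at all
      if (tpm_by_sample[[cand]] > 0 || breadth[[cand]] > 0) {
        assigned <- cand
        confidence <- if (tab[1] == 3) "3/3" else "2/3"
      }
    }
  }
  structure(list(contig_id = ct$contig_id, assigned_species = assigned,
                 votes = votes, confidence = confidence),
            class = "SpeciesAssignment")
}

#' @export
print.SpeciesAssignment <- function(x, ...) {
  cat(sprintf("SpeciesAssignment %s: %s (%s; votes %s)\n", x$contig_id,
              x$assigned_species, x$confidence,
              paste(names(x$votes), x$votes, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Greedy isoform clustering at an identity threshold
#'
#' Incremental clustering with CD-HIT semantics: sequences are sorted by
#' length (descending; ties by id), each sequence joins the existing
#' centroid of highest identity at or above the threshold (accurate mode),
#' else founds a new cluster, and the final clusters are sorted by member
#' count (descending). Identity is global over the shorter sequence: the
#' shorter sequence is aligned end-to-end within the longer and identity is
#' matches divided by the shorter length. Forward strands only. For
#' thresholds >= 0.95 a shared-8-mer prescreen skips hopeless alignments.
#'
#' @param contigs Named character vector of sequences.
#' @param identity_threshold Fraction in (0, 1]; default 0.99.
#' @return List of `Cluster` objects: `centroid`, `members` (ids, centroid
#'   first), `identity` (per member, vs centroid).
#' @export
cluster_isoforms <- function(contigs, identity_threshold = 0.99) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  if (length(contigs) == 0) return(list())
  if (is.null(names(contigs)) || anyDuplicated(names(contigs))) {
    stop("contigs must have unique names")
  }
  ids <- names(contigs)
  ord <- order(-nchar(contigs), ids)
  ids <- ids[ord]
  seqs <- toupper(unname(contigs[ord]))

  prescreen <- identity_threshold >= 0.95
  kmer_sets <- NULL
  if (prescreen) {
    kmer_sets <- lapply(seqs, function(s) {
      n <- nchar(s)
      if (n < 8) return(character())
      unique(substring(s, 1:(n - 7), 8:n))
    })
  }

  centroid_idx <- integer()
  membership <- integer(length(seqs))
  identity <- numeric(length(seqs))
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                     baseOnly = FALSE)
  for (i in seq_along(seqs)) {
    best_c <- 0L
    best_id <- -1
    for (ci in seq_along(centroid_idx)) {
      j <- centroid_idx[ci]
      if (prescreen) {
        shared <- mean(kmer_sets[[i]] %in% kmer_sets[[j]])
        if (!length(kmer_sets[[i]]) || shared < 0.5) next
      }
      pidv <- pair_identity_shorter(seqs[i], seqs[j], submat)
      if (pidv >= identity_threshold && pidv > best_id) {
        best_id <- pidv
        best_c <- ci
      }
    }
    if (best_c > 0L) {
      membership[i] <- best_c
      identity[i] <- best_id
    } else {
      centroid_idx <- c(centroid_idx, i)
      membership[i] <- length(centroid_idx)
      identity[i] <- 1
    }
  }
  clusters <- lapply(seq_along(centroid_idx), function(ci) {
    mem <- which(membership == ci)
    mem <- mem[order(mem != centroid_idx[ci])]  # centroid first
    structure(list(centroid = ids[centroid_idx[ci]], members = ids[mem],
                   identity = stats::setNames(identity[mem], ids[mem])),
              class = "Cluster")
  })
  sizes <- vapply(clusters, function(cl) length(cl$members), 1L)
  clusters[order(-sizes, vapply(clusters, `[[`, "", "centroid"))]
}

# Identity over the shorter sequence: align the shorter globally within the
# longer (ends-free in the longer) and divide matches by the shorter length.
pair_identity_shorter <- function(a, b, submat) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(a), subject = Biostrings::DNAString(b),
    type = "global-local", substitutionMatrix = submat,
    gapOpening = 5, gapExtension = 2
  )
  Biostrings::nmatch(aln) / nchar(a)
}

#' @export
print.Cluster <- function(x, ...) {
  cat(sprintf("Cluster [%s]: %d members\n", x$centroid, length(x$members)))
  invisible(x)
}

#' Cluster membership as a table
#'
#' @param clusters List of `Cluster` objects.
#' @return Data frame: `cluster_id`, `contig_id`, `is_centroid`, `identity`.
#' @export
cluster_table <- function(clusters) {
  if (!length(clusters)) {
    return(data.frame(cluster_id = integer(), contig_id = character(),
                      is_centroid = logical(), identity = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    data.frame(cluster_id = i, contig_id = cl$members,
               is_centroid = cl$members == cl$centroid,
               identity = unname(cl$identity[cl$members]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
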