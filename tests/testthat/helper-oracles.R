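# Independent brute-force oracles. These deliberately share no code with
# the package internals: string reverse-complement via chartr + rev,
# quadratic scans instead of hashes, and an NG86 re-derivation with its own
# codon table handling.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]), collapse = "")
}

oracle_random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# all canonical k-mer counts by direct window enumeration
oracle_count_kmers <- function(seqs, k) {
  out <- character()
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    for (i in 1:(n - k + 1)) {
      w <- substr(s, i, i + k - 1)
      if (grepl("[^ACGT]", w)) next
      rc <- oracle_revcomp(w)
      out <- c(out, if (w <= rc) w else rc)
    }
  }
  tab <- table(out)
  data.frame(kmer = names(tab), count = as.integer(tab), stringsAsFactors = FALSE)
}

# flagged-base fraction of one read by direct interval union
oracle_flagged_fraction <- function(seq, flagged, k) {
  n <- nchar(seq)
  if (n < k) return(0)
  covered <- rep(FALSE, n)
  for (i in 1:(n - k + 1)) {
    w <- substr(seq, i, i + k - 1)
    if (grepl("[^ACGT]", w)) next
    rc <- oracle_revcomp(w)
    canon <- if (w <= rc) w else rc
    if (canon %in% flagged) covered[i:(i + k - 1)] <- TRUE
  }
  mean(covered)
}

# six-frame complete-ORF scan by direct enumeration of (ATG, first stop)
# pairs; keeps only the longest ORF per (strand, stop) to mirror the
# default rule
oracle_orfs <- function(seq, min_codons) {
  seq <- toupper(seq)
  L <- nchar(seq)
  stops3 <- c("TAA", "TAG", "TGA")
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else oracle_revcomp(seq)
    for (f in 0:2) {
      ncod <- (L - f) %/% 3
      if (ncod < 1) next
      first <- f + seq(1, by = 3, length.out = ncod)
      cods <- substring(s, first, first + 2)
      stop_idx <- which(cods %in% stops3)
      atg_idx <- which(cods == "ATG")
      for (a in atg_idx) {
        pos <- findInterval(a, stop_idx) + 1  # first stop at or after a
        if (pos > length(stop_idx)) next
        stop_at <- stop_idx[pos]
        if (stop_at - a < min_codons) next
        ls <- f + (a - 1) * 3
        le <- f + stop_at * 3
        key <- paste(strand, le)
        cur <- res[[key]]
        if (is.null(cur) || ls < cur$ls) {
          res[[key]] <- list(strand = strand, ls = ls, le = le)
        }
      }
    }
  }
  if (!length(res)) {
    return(data.frame(strand = character(), start = integer(), end = integer()))
  }
  df <- do.call(rbind, lapply(res, function(r) {
    if (r$strand == "+") {
      data.frame(strand = "+", start = r$ls, end = r$le)
    } else {
      data.frame(strand = "-", start = L - r$le, end = L - r$ls)
    }
  }))
  df <- df[order(df$start, df$end, df$strand), ]
  rownames(df) <- NULL
  df
}

# Smith-Waterman local alignment score with affine gaps (open + extend on
# the first gap character), direct three-matrix dynamic program
oracle_sw_score <- function(a, b, mat, open, extend) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)  # gap in b (vertical)
  Y <- matrix(-Inf, n + 1, m + 1)  # gap in a (horizontal)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend)
      Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend)
      sc <- mat[av[i - 1], bv[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1] + sc, X[i, j], Y[i, j])
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

# interval-stabbing coverage
oracle_coverage <- function(starts, ends, L) {
  vapply(seq_len(L), function(i) sum(starts < i & ends >= i), 0L)
}

# independent NG86: own genetic code application, recursive pathway
# enumeration, JC correction
oracle_ng86 <- function(a, b) {
  gcode <- as.list(Biostrings::GENETIC_CODE)
  aa_of <- function(cod) gcode[[cod]]
  split3 <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  ca <- split3(toupper(a)); cb <- split3(toupper(b))
  nts <- c("A", "C", "G", "T")
  syn_per_codon <- function(cod) {
    ch <- strsplit(cod, "")[[1]]
    tot <- 0
    for (p in 1:3) for (x in setdiff(nts, ch[p])) {
      alt <- ch; alt[p] <- x
      altc <- paste(alt, collapse = "")
      if (aa_of(altc) != "*" && aa_of(altc) == aa_of(cod)) tot <- tot + 1
    }
    tot / 3
  }
  paths <- function(from, to) {
    # returns list of step lists; each step c(prev, next)
    pos <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
    if (!length(pos)) return(list(list()))
    out <- list()
    for (p in pos) {
      ch <- strsplit(from, "")[[1]]
      ch[p] <- strsplit(to, "")[[1]][p]
      mid <- paste(ch, collapse = "")
      for (rest in paths(mid, to)) {
        out[[length(out) + 1]] <- c(list(c(from, mid)), rest)
      }
    }
    out
  }
  S_sites <- 0; N_sites <- 0; S_diff <- 0; N_diff <- 0; ncod <- 0
  for (i in seq_along(ca)) {
    if (grepl("[^ACGT]", ca[i]) || grepl("[^ACGT]", cb[i])) next
    ncod <- ncod + 1
    s_i <- (syn_per_codon(ca[i]) + syn_per_codon(cb[i])) / 2
    S_sites <- S_sites + s_i
    N_sites <- N_sites + 3 - s_i
    if (ca[i] != cb[i]) {
      pp <- paths(ca[i], cb[i])
      ok <- Filter(function(path) {
        !any(vapply(path, function(st) aa_of(st[2]) == "*", TRUE))
      }, pp)
      use <- if (length(ok)) ok else pp
      sd <- 0; nd <- 0
      for (path in use) {
        for (st in path) {
          if (aa_of(st[1]) != "*" && aa_of(st[2]) != "*" &&
              aa_of(st[1]) == aa_of(st[2])) sd <- sd + 1 else nd <- nd + 1
        }
      }
      S_diff <- S_diff + sd / length(use)
      N_diff <- N_diff + nd / length(use)
    }
  }
  pS <- if (S_sites > 0) S_diff / S_sites else 0
  pN <- if (N_sites > 0) N_diff / N_sites else 0
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  list(N_sites = N_sites, S_sites = S_sites, N_diff = N_diff, S_diff = S_diff,
       pN = pN, pS = pS, dN = jc(pN), dS = jc(pS))
}

# minimum-Hamming placement of a read over a set of contigs (both strands)
oracle_best_placements <- function(read, contigs) {
  hits <- list()
  best <- Inf
  for (ci in seq_along(contigs)) {
    ctg <- contigs[[ci]]
    cv <- strsplit(ctg, "")[[1]]
    for (strand in c("+", "-")) {
      q <- if (strand == "+") read else oracle_revcomp(read)
      qv <- strsplit(q, "")[[1]]
      L <- length(qv)
      if (length(cv) < L) next
      for (o in 0:(length(cv) - L)) {
        mm <- sum(cv[(o + 1):(o + L)] != qv)
        if (mm < best) { best <- mm; hits <- list() }
        if (mm == best) {
          hits[[length(hits) + 1]] <- list(contig = names(contigs)[ci],
                                           start = o, strand = strand, mm = mm)
        }
      }
    }
  }
  list(best = best, hits = hits)
}

# longest leaf-to-leaf path length by all-pairs distances
oracle_tree_diameter <- function(tree) {
  dm <- ape::cophenetic.phylo(tree)
  max(dm)
}
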