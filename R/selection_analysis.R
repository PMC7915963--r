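#' Newick tree input and output
#'
#' Thin wrappers over ape's Newick reader/writer with a uniform error
#' message for malformed input. `parse_newick()` accepts a Newick string or
#' a file path; `write_newick()` returns the Newick string (and writes it
#' when `path` is given).
#'
#' @param text Newick string, or a path to a file containing one.
#' @return `parse_newick()` returns an ape `phylo` tree.
#' @export
parse_newick <- function(text) {
  tr <- tryCatch({
    if (length(text) == 1 && !grepl("(", text, fixed = TRUE) && file.exists(text)) {
      ape::read.tree(file = text)
    } else {
      ape::read.tree(text = text)
    }
  }, error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("Newick parse error near: ", substr(paste(text, collapse = ""), 1, 60))
  }
  tr
}

#' @rdname parse_newick
#' @param tree An ape `phylo` tree.
#' @param path Optional output file.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree)
  if (!is.null(path)) writeLines(txt, path)
  txt
}

#' Midpoint rooting
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path, so the
#' two maximal root-to-leaf distances are equal -- the standard choice for
#' presenting trees without a reliable outgroup.
#'
#' @param tree An ape `phylo` tree with branch lengths and >= 2 leaves.
#' @return The midpoint-rooted `phylo` tree.
#' @export
midpoint_root <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2) stop("midpoint rooting needs >= 2 leaves")
  if (is.null(tree$edge.length)) stop("midpoint rooting needs branch lengths")
  dm <- ape::cophenetic.phylo(tree)
  if (max(dm) <= 0) stop("degenerate tree: longest leaf-to-leaf path has zero length")
  phangorn::midpoint(tree)
}

#' Root-to-leaf distances of a rooted tree
#'
#' @param tree A rooted `phylo` tree with branch lengths.
#' @return Named numeric vector of distances from the root to each leaf.
#' @export
root_to_leaf_distances <- function(tree) {
  nt <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  stats::setNames(nt, tree$tip.label)
}

#' Extract a monophyletic clade as a subtree
#'
#' Returns the subtree rooted at the most recent common ancestor of the
#' requested leaves; errors if the set is not monophyletic, naming the
#' intruding leaves.
#'
#' @param tree A rooted `phylo` tree.
#' @param leaves Character vector of leaf labels present in the tree.
#' @return The clade as a `phylo` tree.
#' @export
extract_clade <- function(tree, leaves) {
  stopifnot(inherits(tree, "phylo"))
  missing <- setdiff(leaves, tree$tip.label)
  if (length(missing)) {
    stop("leaves not in tree: ", paste(missing, collapse = ", "))
  }
  if (setequal(leaves, tree$tip.label)) return(tree)
  if (length(leaves) < 2) stop("a clade needs >= 2 leaves")
  mrca <- ape::getMRCA(tree, leaves)
  sub <- ape::extract.clade(tree, mrca)
  intruders <- setdiff(sub$tip.label, leaves)
  if (length(intruders)) {
    stop("leaf set is not monophyletic; intruding leaves: ",
         paste(intruders, collapse = ", "))
  }
  sub
}

#' Trim a precursor CDS to the mature protein
#'
#' Removes the first `signal_codons` codons (the signal peptide and any
#' propeptide the caller includes in the count) and a terminal stop codon
#' if present, leaving the codons that translate to the mature protein.
#'
#' @param cds Codon sequence, length divisible by 3.
#' @param signal_codons Number of leading codons to remove.
#' @return The trimmed codon sequence.
#' @export
trim_to_mature <- function(cds, signal_codons) {
  if (nchar(cds) %% 3 != 0) stop("CDS length must be divisible by 3")
  stopifnot(signal_codons >= 0)
  cods <- codon_split(toupper(cds))
  if (length(cods) && cods[length(cods)] %in% STOP_CODONS) {
    cods <- cods[-length(cods)]
  }
  if (signal_codons >= length(cods)) {
    stop("trimming would leave no mature codons")
  }
  paste(cods[(signal_codons + 1):length(cods)], collapse = "")
}

#' Pairwise dN/dS by the Nei-Gojobori (1986) counting method
#'
#' Counts synonymous and nonsynonymous sites (per codon, the expected
#' number of synonymous one-step changes among the three positions;
#' changes into stop codons count as nonsynonymous so sites always sum to
#' three per codon) averaged over both sequences, and synonymous and
#' nonsynonymous differences averaged with equal weight over all minimal
#' mutational pathways between differing codons, excluding pathways that
#' pass through a stop codon. Proportions are corrected for multiple hits
#' with the Jukes-Cantor formula d = -3/4 ln(1 - 4/3 p).
#'
#' Codon columns where either sequence has a gap or an ambiguous base are
#' dropped (pairwise deletion).
#'
#' @param a,b Aligned codon sequences of equal length (divisible by 3),
#'   no internal stop codons.
#' @return A `DnDsEstimate`: list with `N_sites`, `S_sites`, `N_diff`,
#'   `S_diff`, `pN`, `pS`, `dN`, `dS`, `omega`, `codons_compared`, and
#'   `status` (`"ok"`, `"saturated"` when a proportion reaches 3/4 so the
#'   correction is undefined, or `"dS_zero"` when omega is undefined).
#' @export
ng86_pairwise <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) stop("sequences must be aligned to equal length")
  if (nchar(a) %% 3 != 0) stop("length must be divisible by 3")
  ca <- codon_split(a); cb <- codon_split(b)
  usable <- is_plain_codon(ca) & is_plain_codon(cb)
  ca <- ca[usable]; cb <- cb[usable]
  if (any(ca %in% STOP_CODONS) || any(cb %in% STOP_CODONS)) {
    stop("internal stop codon in compared codons")
  }
  n_cod <- length(ca)
  syn_a <- sum(syn_sites(ca)); syn_b <- sum(syn_sites(cb))
  S_sites <- (syn_a + syn_b) / 2
  N_sites <- 3 * n_cod - S_sites
  S_diff <- 0; N_diff <- 0
  for (i in seq_len(n_cod)) {
    if (ca[i] != cb[i]) {
      d <- codon_path_diffs(ca[i], cb[i])
      S_diff <- S_diff + d[["syn"]]
      N_diff <- N_diff + d[["nonsyn"]]
    }
  }
  pN <- if (N_sites > 0) N_diff / N_sites else 0
  pS <- if (S_sites > 0) S_diff / S_sites else 0
  jc <- function(p) if (p < 3 / 4) -3 / 4 * log(1 - 4 / 3 * p) else NA_real_
  dN <- jc(pN); dS <- jc(pS)
  st <- omega_status(dN, dS)
  status <- st$status; omega <- st$omega
  structure(list(N_sites = N_sites, S_sites = S_sites, N_diff = N_diff,
                 S_diff = S_diff, pN = pN, pS = pS, dN = dN, dS = dS,
                 omega = omega, codons_compared = n_cod, status = status),
            class = "DnDsEstimate")
}

#' @export
print.DnDsEstimate <- function(x, ...) {
  cat(sprintf(paste0("DnDsEstimate: %d codons | N sites %.2f, S sites %.2f | ",
                     "N diff %.2f, S diff %.2f | dN %.4f, dS %.4f | omega %s (%s)\n"),
              x$codons_compared, x$N_sites, x$S_sites, x$N_diff, x$S_diff,
              ifelse(is.na(x$dN), NA, x$dN), ifelse(is.na(x$dS), NA, x$dS),
              if (is.na(x$omega)) "undefined" else sprintf("%.3f", x$omega),
              x$status))
  invisible(x)
}

is_plain_codon <- function(cods) !grepl("[^ACGT]", cods)

# omega from corrected distances. A saturated pS (>= 3/4) leaves dS
# undefined but larger than any finite distance, so a zero dN still yields
# omega = 0; any other saturation leaves omega undefined.
omega_status <- function(dN, dS) {
  if (is.na(dN)) return(list(status = "saturated", omega = NA_real_))
  if (is.na(dS)) {
    return(list(status = "saturated",
                omega = if (dN == 0) 0 else NA_real_))
  }
  if (dS == 0) return(list(status = "dS_zero", omega = NA_real_))
  list(status = "ok", omega = dN / dS)
}

# Expected number of synonymous sites per codon: at each position, the
# fraction of the three single-nucleotide changes that are synonymous;
# changes creating a stop codon are nonsynonymous.
syn_sites <- function(cods) {
  mach <- codon_machinery()
  idx <- match(cods, mach$codons)
  if (anyNA(idx)) stop("invalid codon")
  syn_frac <- rowSums(mach$is_syn & mach$base_rate > 0) / 3
  syn_frac[idx]
}

# Average synonymous/nonsynonymous difference counts over all minimal
# mutational pathways between two codons, weighting pathways equally and
# excluding pathways through stop codons. If every pathway is blocked by a
# stop, all pathways are used (flagged nowhere: the endpoints are sense
# codons, so this is a last-resort tie-break for rare codon pairs).
codon_path_diffs <- function(x, y) {
  pos <- which(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  nd <- length(pos)
  if (nd == 0) return(c(syn = 0, nonsyn = 0))
  gc <- Biostrings::GENETIC_CODE
  perms <- list(NULL)
  if (nd == 1) perms <- list(pos)
  if (nd == 2) perms <- list(pos, rev(pos))
  if (nd == 3) {
    perms <- lapply(list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                         c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)),
                    function(o) pos[o])
  }
  walk <- function(order) {
    cur <- strsplit(x, "")[[1]]
    tgt <- strsplit(y, "")[[1]]
    syn <- 0; nonsyn <- 0
    for (p in order) {
      prev <- paste(cur, collapse = "")
      cur[p] <- tgt[p]
      nxt <- paste(cur, collapse = "")
      if (gc[[nxt]] == "*" || gc[[prev]] == "*") return(NULL)
      if (gc[[prev]] == gc[[nxt]]) syn <- syn + 1 else nonsyn <- nonsyn + 1
    }
    c(syn = syn, nonsyn = nonsyn)
  }
  res <- Filter(Negate(is.null), lapply(perms, walk))
  if (!length(res)) {
    # all pathways traverse a stop: fall back to equal weight over all
    res <- lapply(perms, function(order) {
      cur <- strsplit(x, "")[[1]]; tgt <- strsplit(y, "")[[1]]
      syn <- 0; nonsyn <- 0
      for (p in order) {
        prev <- paste(cur, collapse = "")
        cur[p] <- tgt[p]
        nxt <- paste(cur, collapse = "")
        if (gc[[prev]] != "*" && gc[[nxt]] != "*" && gc[[prev]] == gc[[nxt]]) {
          syn <- syn + 1
        } else {
          nonsyn <- nonsyn + 1
        }
      }
      c(syn = syn, nonsyn = nonsyn)
    })
  }
  Reduce(`+`, res) / length(res)
}

#' Pooled clade-level dN/dS
#'
#' Aggregates over all pairwise comparisons of an alignment by pooling
#' site and difference counts (sum of N_diff over sum of N_sites, and
#' likewise for synonymous) before the Jukes-Cantor correction, yielding
#' one overall omega per clade plus the per-pair table.
#'
#' @param aln A `CodonAlignment` with >= 2 taxa.
#' @return A `DnDsEstimate` for the pooled counts, with an extra `pairs`
#'   data frame (`taxon_a`, `taxon_b`, `N_diff`, `S_diff`, `N_sites`,
#'   `S_sites`, `omega`, `status`).
#' @export
clade_omega <- function(aln) {
  stopifnot(inherits(aln, "CodonAlignment"))
  n <- length(aln$taxa)
  if (n < 2) stop("clade_omega needs >= 2 taxa")
  Ns <- Ss <- Nd <- Sd <- 0
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      e <- ng86_pairwise(aln$seqs[i], aln$seqs[j])
      Ns <- Ns + e$N_sites; Ss <- Ss + e$S_sites
      Nd <- Nd + e$N_diff; Sd <- Sd + e$S_diff
      rows[[length(rows) + 1]] <- data.frame(
        taxon_a = aln$taxa[i], taxon_b = aln$taxa[j],
        N_diff = e$N_diff, S_diff = e$S_diff,
        N_sites = e$N_sites, S_sites = e$S_sites,
        omega = e$omega, status = e$status, stringsAsFactors = FALSE
      )
    }
  }
  pN <- if (Ns > 0) Nd / Ns else 0
  pS <- if (Ss > 0) Sd / Ss else 0
  jc <- function(p) if (p < 3 / 4) -3 / 4 * log(1 - 4 / 3 * p) else NA_real_
  dN <- jc(pN); dS <- jc(pS)
  st <- omega_status(dN, dS)
  status <- st$status; omega <- st$omega
  out <- structure(list(N_sites = Ns, S_sites = Ss, N_diff = Nd, S_diff = Sd,
                        pN = pN, pS = pS, dN = dN, dS = dS, omega = omega,
                        codons_compared = NA_integer_, status = status),
                   class = "DnDsEstimate")
  out$pairs <- do.call(rbind, rows)
  out
}

#' Read and write codon alignments as FASTA
#'
#' @param path FASTA path.
#' @return `read_codon_alignment()` returns a `CodonAlignment`.
#' @export
read_codon_alignment <- function(path) {
  codon_alignment(read_fasta(path))
}

#' @rdname read_codon_alignment
#' @param aln A `CodonAlignment`.
#' @export
write_codon_alignment <- function(aln, path) {
  write_fasta(stats::setNames(aln$seqs, aln$taxa), path)
}
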