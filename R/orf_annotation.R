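#' Find complete open reading frames in a contig
#'
#' Scans all six frames for complete ORFs: a leading ATG, an in-frame stop,
#' and no internal stop, with at least `min_codons` sense codons (the stop
#' excluded from the count but included in the reported CDS). Incomplete
#' ORFs (missing start or stop) are never reported. By default only the
#' longest ORF per stop codon is returned; `all_nested = TRUE` emits every
#' qualifying nested start.
#'
#' Coordinates are 0-based half-open on the contig's forward strand,
#' regardless of ORF strand.
#'
#' @param x A `Contig` (or single named character vector).
#' @param min_codons Minimum number of sense codons (default 50, small
#'   enough for short toxin precursors such as three-finger toxins).
#' @param all_nested Report all nested ORFs sharing a stop.
#' @return Data frame of `OrfRecord` rows: `orf_id`, `contig_id`, `strand`,
#'   `frame`, `start`, `end`, `cds`, `protein`, `complete`.
#' @export
find_orfs <- function(x, min_codons = 50L, all_nested = FALSE) {
  ct <- as_contig(x)
  stopifnot(min_codons >= 1)
  seq <- toupper(ct$sequence)
  L <- nchar(seq)
  o_strand <- character(); o_frame <- integer()
  o_start <- integer(); o_end <- integer(); o_cds <- character()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else as.character(cpp_revcomp(seq))
    for (frame in 0:2) {
      ncod <- (L - frame) %/% 3
      if (ncod < min_codons + 1) next
      cods <- substring(s, frame + seq(1L, by = 3L, length.out = ncod),
                        frame + seq(3L, by = 3L, length.out = ncod))
      stops <- which(cods %in% STOP_CODONS)
      starts <- which(cods == "ATG")
      if (!length(stops) || !length(starts)) next
      prev <- 0L
      for (st in stops) {
        cand <- starts[starts > prev & starts <= st - min_codons]
        if (length(cand)) {
          use <- if (all_nested) cand else cand[1]
          for (a in use) {
            # local (frame-strand) nt coords, 0-based half-open, incl. stop
            ls <- frame + (a - 1L) * 3L
            le <- frame + st * 3L
            n <- length(o_strand) + 1L
            o_strand[n] <- strand
            o_frame[n] <- frame
            o_start[n] <- if (strand == "+") ls else L - le
            o_end[n] <- if (strand == "+") le else L - ls
            o_cds[n] <- substring(s, ls + 1L, le)
          }
        }
        prev <- st
      }
    }
  }
  if (!length(o_strand)) {
    return(data.frame(orf_id = character(), contig_id = character(),
                      strand = character(), frame = integer(), start = integer(),
                      end = integer(), cds = character(), protein = character(),
                      complete = logical(), stringsAsFactors = FALSE))
  }
  # complete ORFs have no internal stop, so direct codon-table translation
  # is safe; codons containing N render X
  prot <- vapply(substring(o_cds, 1L, nchar(o_cds) - 3L), fast_translate, "",
                 USE.NAMES = FALSE)
  out <- data.frame(contig_id = ct$contig_id, strand = o_strand,
                    frame = o_frame, start = o_start, end = o_end,
                    cds = o_cds, protein = prot, complete = TRUE,
                    stringsAsFactors = FALSE)
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  out <- cbind(orf_id = sprintf("%s_orf%02d", ct$contig_id, seq_len(nrow(out))),
               out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# table-lookup translation for sequences known to be clean frames
fast_translate <- function(cds) {
  n <- nchar(cds)
  if (n == 0L) return("")
  aa <- Biostrings::GENETIC_CODE[codon_split(cds)]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Translate a coding sequence with the standard genetic code
#'
#' A terminal stop codon is dropped; an internal stop renders `"*"` and
#' marks the translation invalid for annotation (attribute `valid`).
#'
#' @param cds Nucleotide string, length divisible by 3.
#' @return Amino-acid string with attribute `valid` (`FALSE` when an
#'   internal stop is present).
#' @export
translate_cds <- function(cds) {
  if (nchar(cds) %% 3 != 0) stop("CDS length must be divisible by 3")
  if (nchar(cds) == 0) return(structure("", valid = TRUE))
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           if.fuzzy.codon = "X"))
  n <- nchar(aa)
  if (n > 0 && substring(aa, n, n) == "*") aa <- substring(aa, 1L, n - 1L)
  structure(aa, valid = !grepl("*", aa, fixed = TRUE))
}

#' Local-alignment search of a protein against a labelled reference database
#'
#' Smith-Waterman local alignment of the query against every reference
#' sequence (BLOSUM62, affine gaps, open 11 / extend 1 by default --
#' mirroring standard protein-search settings). Hits at or above
#' `min_score` are returned sorted by descending score, ties broken by
#' higher percent identity, then reference id.
#'
#' @param protein Query amino-acid string (nonempty).
#' @param db Reference database data frame (see [read_reference_db()]).
#' @param substitution_matrix Name of a matrix bundled with Biostrings, or
#'   a matrix.
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @param min_score Minimum alignment score to report.
#' @return Data frame of hits: `ref_id`, `family`, `taxon`, `score`,
#'   `identity` (percent).
#' @export
similarity_search <- function(protein, db, substitution_matrix = "BLOSUM62",
                              gap_open = 11, gap_extend = 1, min_score = 0) {
  stopifnot(nchar(protein) > 0)
  empty <- data.frame(ref_id = character(), family = character(),
                      taxon = character(), score = numeric(),
                      identity = numeric(), stringsAsFactors = FALSE)
  if (is.null(db) || nrow(db) == 0) return(empty)
  if (is.character(substitution_matrix)) {
    substitution_matrix <- get(data(list = substitution_matrix,
                                    package = "Biostrings",
                                    envir = environment()))
  }
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(rep(protein, nrow(db))),
    subject = Biostrings::AAStringSet(db$protein),
    type = "local", substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  hits <- data.frame(ref_id = db$ref_id, family = db$family, taxon = db$taxon,
                     score = Biostrings::score(aln),
                     identity = Biostrings::pid(aln, type = "PID1"),
                     stringsAsFactors = FALSE)
  hits <- hits[hits$score >= min_score, , drop = FALSE]
  hits <- hits[order(-hits$score, -hits$identity, hits$ref_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Classify an ORF into a toxin family from its hit list
#'
#' The family of the best hit meeting both thresholds, else
#' `"unclassified"`. The hit list's ordering (score, then identity, then
#' reference id) makes the choice deterministic.
#'
#' @param hits Hit data frame from [similarity_search()].
#' @param min_score Minimum qualifying score.
#' @param min_identity Minimum qualifying percent identity.
#' @param orf_id Optional ORF label carried through.
#' @return A `ToxinAnnotation`: list with `orf_id`, `family`, `best_hit`,
#'   `score`, `identity`, `taxon`, `hits`.
#' @export
classify_family <- function(hits, min_score = 50, min_identity = 30,
                            orf_id = NA_character_) {
  qual <- hits[hits$score >= min_score & hits$identity >= min_identity, , drop = FALSE]
  if (nrow(qual) == 0) {
    ann <- list(orf_id = orf_id, family = "unclassified",
                best_hit = NA_character_, score = NA_real_,
                identity = NA_real_, taxon = NA_character_, hits = hits)
  } else {
    ann <- list(orf_id = orf_id, family = qual$family[1],
                best_hit = qual$ref_id[1], score = qual$score[1],
                identity = qual$identity[1], taxon = qual$taxon[1], hits = hits)
  }
  structure(ann, class = "ToxinAnnotation")
}

#' @export
print.ToxinAnnotation <- function(x, ...) {
  cat(sprintf("ToxinAnnotation %s: family %s (best hit %s, score %.1f, id %.1f%%)\n",
              x$orf_id, x$family,
              if (is.na(x$best_hit)) "-" else x$best_hit,
              if (is.na(x$score)) 0 else x$score,
              if (is.na(x$identity)) 0 else x$identity))
  invisible(x)
}

#' Annotate every ORF of a set against a reference database
#'
#' Convenience wrapper running [similarity_search()] and
#' [classify_family()] over an ORF table. ORFs whose translation is invalid
#' (internal stop) are annotated `"unclassified"` without a search.
#'
#' @param orfs ORF data frame from [find_orfs()].
#' @param db Reference database data frame.
#' @inheritParams classify_family
#' @inheritParams similarity_search
#' @return Named list of `ToxinAnnotation`, one per ORF row.
#' @export
annotate_orfs <- function(orfs, db, min_score = 50, min_identity = 30,
                          substitution_matrix = "BLOSUM62",
                          gap_open = 11, gap_extend = 1) {
  anns <- lapply(seq_len(nrow(orfs)), function(i) {
    p <- orfs$protein[i]
    if (!nzchar(p) || grepl("*", p, fixed = TRUE)) {
      return(classify_family(similarity_search("X", NULL), orf_id = orfs$orf_id[i]))
    }
    hits <- similarity_search(p, db, substitution_matrix = substitution_matrix,
                              gap_open = gap_open, gap_extend = gap_extend)
    classify_family(hits, min_score = min_score, min_identity = min_identity,
                    orf_id = orfs$orf_id[i])
  })
  names(anns) <- orfs$orf_id
  anns
}
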