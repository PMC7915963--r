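#' Read a FASTA file into a named character vector
#'
#' Thin wrapper around [Biostrings::readBStringSet()] returning plain
#' character vectors, which is the sequence representation used throughout
#' the package.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (names are the full headers).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- as.character(x)
  names(out) <- names(x)
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(length(seqs) == 0 || !is.null(names(seqs)))
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a FASTQ file as a ReadSet
#'
#' Ground-truth provenance is never stored in FASTQ; if a sidecar truth
#' table (see [write_truth_table()]) exists it can be joined afterwards with
#' [attach_truth()].
#'
#' @param path Path to a FASTQ file (Phred+33).
#' @param sample_id Sample label for the resulting ReadSet.
#' @return A `ReadSet` object.
#' @export
read_fastq <- function(path, sample_id) {
  # suppress the harmless note about dropped metadata columns
  x <- suppressWarnings(
    Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred"))
  read_set(
    sample_id = sample_id,
    read_id = names(x),
    sequence = as.character(x),
    quality = as.character(Biostrings::quality(x)),
    true_source = NA_character_
  )
}

#' Write a ReadSet to FASTQ (and optionally its truth sidecar)
#'
#' @param rs A `ReadSet`.
#' @param path Output FASTQ path.
#' @param truth_path Optional path for the sidecar table mapping read_id to
#'   true_source; provenance labels are never written into the FASTQ itself.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(rs, path, truth_path = NULL) {
  stopifnot(inherits(rs, "ReadSet"))
  r <- rs$reads
  if (nrow(r) == 0) {
    file.create(path)
  } else {
    # suppress the harmless note about dropped metadata columns
    x <- suppressWarnings(Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(stats::setNames(r$sequence, r$read_id)),
      Biostrings::PhredQuality(r$quality)
    ))
    Biostrings::writeQualityScaledXStringSet(x, path)
  }
  if (!is.null(truth_path)) {
    write_truth_table(data.frame(read_id = r$read_id, true_source = r$true_source,
                                 stringsAsFactors = FALSE), truth_path)
  }
  invisible(path)
}

#' Write / read a ground-truth sidecar table
#'
#' Plain TSV with a header row. Used for read provenance
#' (`read_id`, `true_source`) and chimera truth (`contig_id`, `breakpoint`).
#'
#' @param df A data frame.
#' @param path Path to the TSV file.
#' @return `write_truth_table()` returns `path` invisibly;
#'   `read_truth_table()` returns a data frame.
#' @export
write_truth_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Attach sidecar provenance labels to a ReadSet
#'
#' @param rs A `ReadSet`.
#' @param truth Data frame with columns `read_id`, `true_source`.
#' @return The `ReadSet` with `true_source` filled in.
#' @export
attach_truth <- function(rs, truth) {
  stopifnot(inherits(rs, "ReadSet"))
  idx <- match(rs$reads$read_id, truth$read_id)
  rs$reads$true_source <- truth$true_source[idx]
  rs
}

#' Read a labelled toxin reference database
#'
#' FASTA of protein sequences with headers of the form
#' `refid|FAMILY|taxon`.
#'
#' @param path Path to the reference FASTA.
#' @return Data frame with columns `ref_id`, `family`, `taxon`, `protein`.
#' @export
read_reference_db <- function(path) {
  seqs <- read_fasta(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 2L
  if (any(bad)) {
    stop("reference headers must be 'refid|FAMILY|taxon'; offending: ",
         paste(names(seqs)[bad][seq_len(min(3, sum(bad)))], collapse = ", "))
  }
  data.frame(
    ref_id = vapply(parts, `[`, "", 1L),
    family = vapply(parts, `[`, "", 2L),
    taxon = vapply(parts, function(p) if (length(p) >= 3) p[[3]] else NA_character_, ""),
    protein = unname(seqs),
    stringsAsFactors = FALSE
  )
}

#' @rdname read_reference_db
#' @param db Data frame as returned by `read_reference_db()`.
#' @export
write_reference_db <- function(db, path) {
  hdr <- paste(db$ref_id, db$family, db$taxon, sep = "|")
  write_fasta(stats::setNames(db$protein, hdr), path)
}

#' Minimal SAM text import / export for alignment sets
#'
#' Reads the 11 mandatory columns of an uncompressed SAM file and converts
#' primary alignments into the package's `AlignmentSet` placement table.
#' Mismatch counts are taken from the `NM:i:` tag when present. This is a
#' deliberately small reader for desk-scale data; use dedicated tooling for
#' large BAMs.
#'
#' @param path SAM file path.
#' @return An `AlignmentSet`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  placements <- data.frame(read_id = character(), contig_id = character(),
                           start = integer(), end = integer(),
                           strand = character(), mismatches = integer(),
                           weight = numeric(), stringsAsFactors = FALSE)
  unmapped <- character()
  if (length(lines)) {
    f <- strsplit(lines, "\t", fixed = TRUE)
    qname <- vapply(f, `[`, "", 1L)
    flag <- as.integer(vapply(f, `[`, "", 2L))
    rname <- vapply(f, `[`, "", 3L)
    pos <- as.integer(vapply(f, `[`, "", 4L))
    seqs <- vapply(f, `[`, "", 10L)
    nm <- vapply(f, function(x) {
      tag <- grep("^NM:i:", x[-(1:11)], value = TRUE)
      if (length(tag)) as.integer(sub("^NM:i:", "", tag[[1]])) else NA_integer_
    }, 1L)
    is_unmapped <- bitwAnd(flag, 4L) != 0L
    unmapped <- unique(qname[is_unmapped])
    keep <- !is_unmapped & bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L
    placements <- data.frame(
      read_id = qname[keep], contig_id = rname[keep],
      start = pos[keep] - 1L, end = pos[keep] - 1L + nchar(seqs[keep]),
      strand = ifelse(bitwAnd(flag[keep], 16L) != 0L, "-", "+"),
      mismatches = nm[keep], weight = 1, stringsAsFactors = FALSE
    )
  }
  alignment_set(placements, unmapped, policy = "primary")
}

#' @rdname read_sam
#' @param aln An `AlignmentSet`.
#' @param contigs Named character vector of contig sequences (for the header).
#' @param reads Optional `ReadSet` supplying sequences/qualities.
#' @export
write_sam <- function(aln, contigs, path, reads = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (i in seq_along(contigs)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(contigs)[i], nchar(contigs[[i]])), con)
  }
  p <- aln$placements
  if (nrow(p)) {
    seq_of <- function(id) {
      if (is.null(reads)) return("*")
      r <- reads$reads
      s <- r$sequence[match(id, r$read_id)]
      if (is.na(s)) "*" else s
    }
    for (i in seq_len(nrow(p))) {
      s <- seq_of(p$read_id[i])
      flag <- if (p$strand[i] == "-") 16L else 0L
      cigar <- if (identical(s, "*")) "*" else paste0(nchar(s), "M")
      writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t*\tNM:i:%d",
                         p$read_id[i], flag, p$contig_id[i], p$start[i] + 1L,
                         cigar, s, p$mismatches[i]), con)
    }
  }
  for (id in aln$unmapped) {
    writeLines(sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*", id), con)
  }
  invisible(path)
}
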