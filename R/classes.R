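#' Construct a ReadSet
#'
#' A ReadSet is a sample-labelled collection of sequencing reads. The
#' `true_source` column is the synthetic-data ground-truth channel (species
#' of origin, or `"contaminant:<species>"` for spiked reads); for real data
#' it is `NA`.
#'
#' @param sample_id Sample label.
#' @param read_id,sequence,quality,true_source Per-read vectors (recycled
#'   where length one).
#' @return An object of class `ReadSet`.
#' @export
read_set <- function(sample_id, read_id = character(), sequence = character(),
                     quality = character(), true_source = NA_character_) {
  n <- length(read_id)
  stopifnot(length(sequence) == n)
  if (length(quality) == 1L) quality <- rep(quality, n)
  if (length(true_source) == 1L) true_source <- rep(true_source, n)
  stopifnot(length(quality) == n || n == 0, length(true_source) == n || n == 0)
  if (n > 0 && any(nchar(quality) != nchar(sequence))) {
    stop("quality strings must match sequence lengths")
  }
  structure(list(
    sample_id = sample_id,
    reads = data.frame(read_id = as.character(read_id),
                       sequence = as.character(sequence),
                       quality = if (n) as.character(quality) else character(),
                       true_source = if (n) as.character(true_source) else character(),
                       stringsAsFactors = FALSE)
  ), class = "ReadSet")
}

#' @export
print.ReadSet <- function(x, ...) {
  cat(sprintf("ReadSet '%s': %d reads\n", x$sample_id, nrow(x$reads)))
  invisible(x)
}

#' Number of reads in a ReadSet
#' @param rs A `ReadSet`.
#' @export
n_reads <- function(rs) nrow(rs$reads)

#' Construct an AlignmentSet
#'
#' @param placements Data frame with columns `read_id`, `contig_id`,
#'   `start`, `end` (0-based half-open on the contig forward strand),
#'   `strand`, `mismatches`, `weight` (fractional multi-mapping weight).
#' @param unmapped Character vector of unmapped read ids.
#' @param policy Multi-mapping policy tag (`"fraction"` or `"primary"`).
#' @return An object of class `AlignmentSet`.
#' @export
alignment_set <- function(placements, unmapped = character(), policy = "fraction") {
  structure(list(placements = placements, unmapped = unmapped, policy = policy),
            class = "AlignmentSet")
}

#' @export
print.AlignmentSet <- function(x, ...) {
  cat(sprintf("AlignmentSet: %d placements (%d reads), %d unmapped [policy: %s]\n",
              nrow(x$placements), length(unique(x$placements$read_id)),
              length(x$unmapped), x$policy))
  invisible(x)
}

#' Construct a Contig
#'
#' @param contig_id Label, unique within a set.
#' @param sequence Nucleotide string over \{A,C,G,T,N\}.
#' @param assembly_source Optional provenance label.
#' @return An object of class `Contig`.
#' @export
contig <- function(contig_id, sequence, assembly_source = NA_character_) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) stop("contig sequence must be over {A,C,G,T,N}")
  structure(list(contig_id = contig_id, sequence = sequence,
                 assembly_source = assembly_source), class = "Contig")
}

# Accept a Contig, a single named character, or (id, seq) already split.
as_contig <- function(x) {
  if (inherits(x, "Contig")) return(x)
  if (is.character(x) && length(x) == 1L) {
    id <- names(x)
    if (is.null(id)) id <- "contig"
    return(contig(id, unname(x)))
  }
  stop("cannot interpret object as a Contig")
}

#' @export
print.Contig <- function(x, ...) {
  cat(sprintf("Contig '%s': %d nt\n", x$contig_id, nchar(x$sequence)))
  invisible(x)
}

#' Construct a codon alignment
#'
#' Rows are equal-length nucleotide strings whose length is divisible by
#' three; gaps (`-`) are allowed in whole-codon units. No ungapped row may
#' contain an internal stop codon.
#'
#' @param seqs Named character vector (names are taxa).
#' @return An object of class `CodonAlignment`.
#' @export
codon_alignment <- function(seqs) {
  stopifnot(length(seqs) >= 1, !is.null(names(seqs)))
  w <- unique(nchar(seqs))
  if (length(w) != 1L) stop("all rows must have equal length")
  if (w %% 3 != 0) stop("alignment length must be divisible by 3")
  for (i in seq_along(seqs)) {
    cods <- codon_split(gsub("-", "", seqs[[i]]))
    if (length(cods) > 1 && any(cods[-length(cods)] %in% STOP_CODONS)) {
      stop("internal stop codon in row ", names(seqs)[i])
    }
  }
  structure(list(taxa = names(seqs), seqs = unname(seqs),
                 n_codons = w %/% 3L), class = "CodonAlignment")
}

#' @export
print.CodonAlignment <- function(x, ...) {
  cat(sprintf("CodonAlignment: %d taxa x %d codons\n", length(x$taxa), x$n_codons))
  invisible(x)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

codon_split <- function(s) {
  n <- nchar(s)
  if (n == 0L) return(character())
  stopifnot(n %% 3 == 0)
  substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Reverse complement of nucleotide strings
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) cpp_revcomp(x)
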