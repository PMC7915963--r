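#' Count canonical k-mers of a read set
#'
#' Counts every length-`k` window of every read in canonical (strand-folded)
#' form: a window is stored as the lexicographic minimum of itself and its
#' reverse complement, making counts strand-independent. Windows containing
#' non-ACGT characters are skipped; reads shorter than `k` contribute
#' nothing.
#'
#' @param reads A `ReadSet` or a character vector of sequences.
#' @param k K-mer length (default 57, the cross-contamination screen's
#'   standard; configurable for short synthetic transcripts).
#' @return A `KmerSpectrum`: list with `sample_id`, `k`, and parallel
#'   vectors `kmer` (canonical strings) and `count`.
#' @export
count_kmers <- function(reads, k = 57L) {
  stopifnot(k >= 1)
  if (inherits(reads, "ReadSet")) {
    sample_id <- reads$sample_id
    seqs <- reads$reads$sequence
  } else {
    sample_id <- "sample"
    seqs <- as.character(reads)
  }
  if (k > 63) stop("k must be <= 63")
  res <- cpp_count_kmers(seqs, as.integer(k))
  structure(list(sample_id = sample_id, k = as.integer(k),
                 kmer = as.character(res$kmer), count = as.integer(res$count)),
            class = "KmerSpectrum")
}

#' @export
print.KmerSpectrum <- function(x, ...) {
  cat(sprintf("KmerSpectrum '%s': %d distinct %d-mers (%s windows)\n",
              x$sample_id, length(x$kmer), x$k,
              format(sum(as.numeric(x$count)), big.mark = ",")))
  invisible(x)
}

#' Flag focal k-mers over-represented in another sample
#'
#' A k-mer present in the focal spectrum is flagged when its count in the
#' other sample is at least `fold_threshold` times its focal count
#' (inclusive comparison). K-mers absent from the focal spectrum are never
#' flagged -- they cannot mark any focal read. With `normalize = TRUE` the
#' ratio is computed on per-million-window frequencies to compensate for
#' unequal library depths; the default uses raw counts.
#'
#' @param focal,other `KmerSpectrum` objects with equal `k`.
#' @param fold_threshold Minimum other/focal fold ratio (default 1000).
#' @param normalize Normalize counts per million windows before the ratio.
#' @return A `FlaggedKmerSet`: list with `focal_sample`, `other_sample`,
#'   `k`, `fold_threshold`, and the flagged canonical `kmers`.
#' @export
flag_kmers <- function(focal, other, fold_threshold = 1000, normalize = FALSE) {
  stopifnot(inherits(focal, "KmerSpectrum"), inherits(other, "KmerSpectrum"))
  if (focal$k != other$k) stop("k-mer spectra have mismatched k")
  stopifnot(fold_threshold > 0)
  oc <- other$count[match(focal$kmer, other$kmer)]
  oc[is.na(oc)] <- 0L
  fc <- as.numeric(focal$count)
  onum <- as.numeric(oc)
  if (normalize) {
    ftot <- sum(fc); otot <- sum(as.numeric(other$count))
    if (ftot > 0) fc <- fc / ftot * 1e6
    if (otot > 0) onum <- onum / otot * 1e6
  }
  flagged <- focal$kmer[onum / fc >= fold_threshold]
  structure(list(focal_sample = focal$sample_id, other_sample = other$sample_id,
                 k = focal$k, fold_threshold = fold_threshold, kmers = flagged),
            class = "FlaggedKmerSet")
}

#' @export
print.FlaggedKmerSet <- function(x, ...) {
  cat(sprintf("FlaggedKmerSet %s vs %s: %d k-mers at fold >= %g\n",
              x$focal_sample, x$other_sample, length(x$kmers), x$fold_threshold))
  invisible(x)
}

#' Remove likely cross-contamination and short reads
#'
#' A read is removed as contamination when the fraction of its bases
#' covered by at least one flagged k-mer occurrence reaches
#' `coverage_fraction` (inclusive). In `"union"` mode (default) coverage is
#' computed over the union of flagged positions across all flagged sets; in
#' `"per-sample"` mode the rule fires if any single flagged set alone
#' reaches the fraction. Independently, reads shorter than `min_length` are
#' removed. N positions never match a k-mer but count in the length
#' denominator.
#'
#' @param reads A `ReadSet`.
#' @param flagged A `FlaggedKmerSet` or list of them, all with the same
#'   focal sample and `k`.
#' @param coverage_fraction Minimum flagged-base fraction for removal
#'   (default 0.25).
#' @param min_length Minimum read length in nt (default 75).
#' @param mode `"union"` or `"per-sample"` (see above).
#' @return List with `kept` (a `ReadSet`) and `report` (a `FilterReport`
#'   data frame: `read_id`, `length`, `flagged_frac`, `kept`, `reason`,
#'   with a `summary` attribute of counts).
#' @export
filter_reads <- function(reads, flagged, coverage_fraction = 0.25,
                         min_length = 75L, mode = c("union", "per-sample")) {
  stopifnot(inherits(reads, "ReadSet"),
            coverage_fraction > 0, coverage_fraction <= 1)
  mode <- match.arg(mode)
  if (inherits(flagged, "FlaggedKmerSet")) flagged <- list(flagged)
  ks <- unique(vapply(flagged, function(f) as.integer(f$k), 1L))
  if (length(ks) > 1) stop("flagged k-mer sets have differing k")
  r <- reads$reads
  n <- nrow(r)
  if (n == 0) {
    rep <- data.frame(read_id = character(), length = integer(),
                      flagged_frac = numeric(), kept = logical(),
                      reason = character(), stringsAsFactors = FALSE)
    attr(rep, "summary") <- c(input = 0L, kept = 0L, contamination = 0L, too_short = 0L)
    return(list(kept = reads, report = rep))
  }
  if (length(flagged) == 0 || all(vapply(flagged, function(f) length(f$kmers) == 0, TRUE))) {
    frac <- rep(0, n)
    contaminated <- rep(FALSE, n)
  } else if (mode == "union") {
    all_kmers <- unique(unlist(lapply(flagged, `[[`, "kmers")))
    frac <- as.numeric(cpp_flagged_fraction(r$sequence, all_kmers, ks))
    contaminated <- frac >= coverage_fraction
  } else {
    fracs <- vapply(flagged, function(f) {
      if (length(f$kmers) == 0) return(rep(0, n))
      as.numeric(cpp_flagged_fraction(r$sequence, f$kmers, ks))
    }, numeric(n))
    if (is.null(dim(fracs))) fracs <- matrix(fracs, nrow = n)
    frac <- apply(fracs, 1, max)
    contaminated <- frac >= coverage_fraction
  }
  too_short <- nchar(r$sequence) < min_length
  kept <- !contaminated & !too_short
  reason <- ifelse(contaminated, "contamination",
                   ifelse(too_short, "too_short", "kept"))
  rep <- data.frame(read_id = r$read_id, length = nchar(r$sequence),
                    flagged_frac = frac, kept = kept, reason = reason,
                    stringsAsFactors = FALSE)
  attr(rep, "summary") <- c(input = n, kept = sum(kept),
                            contamination = sum(reason == "contamination"),
                            too_short = sum(reason == "too_short"))
  out <- reads
  out$reads <- r[kept, , drop = FALSE]
  rownames(out$reads) <- NULL
  list(kept = out, report = rep)
}

#' Canonical form of k-mers
#'
#' The lexicographic minimum of each k-mer and its reverse complement.
#'
#' @param kmers Character vector of equal-length DNA strings.
#' @return Character vector of canonical k-mers.
#' @export
canonical_kmer <- function(kmers) {
  rc <- as.character(cpp_revcomp(kmers))
  ifelse(kmers <= rc, kmers, rc)
}
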