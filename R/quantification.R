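#' Transcripts Per Million from mapped-read counts
#'
#' TPM_i = 1e6 * (r_i / l_i) / sum_j (r_j / l_j), where r_i is the
#' (possibly fractional) mapped-read count and l_i the contig length in
#' nucleotides. Effective length is the plain contig length: no
#' fragment-length correction is applied, following venom-transcriptomics
#' convention. All-zero counts give all-zero TPM.
#'
#' @param counts Named numeric vector of mapped-read counts (>= 0).
#' @param lengths Named numeric vector of contig lengths (> 0); every
#'   counted contig must have a length.
#' @return An `ExpressionTable` data frame: `contig_id`, `length`, `count`,
#'   `tpm`. TPM sums to 1e6 (within 1e-6 relative) whenever any count is
#'   positive, and `tpm == 0` iff `count == 0`.
#' @export
compute_tpm <- function(counts, lengths) {
  if (length(counts) == 0) {
    return(data.frame(contig_id = character(), length = numeric(),
                      count = numeric(), tpm = numeric(), stringsAsFactors = FALSE))
  }
  stopifnot(!is.null(names(counts)), !is.null(names(lengths)))
  if (any(counts < 0)) stop("counts must be nonnegative")
  miss <- setdiff(names(counts), names(lengths))
  if (length(miss)) {
    stop("contig with count but no length: ", paste(miss, collapse = ", "))
  }
  len <- lengths[names(counts)]
  if (any(len <= 0)) stop("lengths must be positive")
  rate <- counts / len
  denom <- sum(rate)
  tpm <- if (denom > 0) 1e6 * rate / denom else rep(0, length(counts))
  data.frame(contig_id = names(counts), length = unname(len),
             count = unname(counts), tpm = unname(tpm),
             stringsAsFactors = FALSE)
}

#' Summarize expression by toxin family
#'
#' Aggregates an expression table by the family of each contig's
#' annotation, reporting per-family TPM totals, proportions of the summed
#' TPM, and unique-contig counts (cluster representatives when a clustering
#' is supplied, otherwise table rows). Families whose proportion exceeds
#' `threshold` are listed in descending proportion -- the venom-gland
#' headline statistic ("families above 1 percent of total expression").
#' Proportions are over the toxin-annotated rows present in `table`
#' (include unclassified rows in `table` to change the denominator).
#'
#' @param table An `ExpressionTable` data frame.
#' @param annotations Named list of `ToxinAnnotation` (names = contig ids),
#'   or a named character vector of family labels.
#' @param clusters Optional list of `Cluster` objects; unique-contig counts
#'   then count centroids only.
#' @param threshold Proportion cutoff for the highlighted family list
#'   (default 0.01).
#' @return A `FamilySummary`: data frame (`family`, `total_tpm`,
#'   `proportion`, `n_contigs`) sorted by descending proportion, with
#'   attribute `above_threshold` (character vector of families).
#' @export
summarize_families <- function(table, annotations, clusters = NULL,
                               threshold = 0.01) {
  fam_of <- function(id) {
    if (is.character(annotations)) {
      f <- annotations[[id]]
    } else {
      a <- annotations[[id]]
      f <- if (is.null(a)) NULL else a$family
    }
    if (is.null(f) || is.na(f)) "unclassified" else f
  }
  fams <- vapply(table$contig_id, fam_of, "")
  reps <- table$contig_id
  if (!is.null(clusters) && length(clusters)) {
    reps <- vapply(clusters, `[[`, "", "centroid")
  }
  tot <- tapply(table$tpm, fams, sum)
  cnt <- tapply(table$contig_id %in% reps, fams, sum)
  s <- sum(tot)
  out <- data.frame(family = names(tot), total_tpm = as.numeric(tot),
                    proportion = if (s > 0) as.numeric(tot) / s else 0,
                    n_contigs = as.integer(cnt), stringsAsFactors = FALSE)
  out <- out[order(-out$proportion, out$family), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "above_threshold") <- out$family[out$proportion > threshold]
  class(out) <- c("FamilySummary", "data.frame")
  out
}

#' @export
print.FamilySummary <- function(x, ...) {
  cat("Family summary (proportion of summed TPM):\n")
  print.data.frame(x, digits = 4)
  cat("Above threshold:", paste(attr(x, "above_threshold"), collapse = ", "), "\n")
  invisible(x)
}
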