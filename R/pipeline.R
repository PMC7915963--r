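PIPELINE_DEFAULTS <- list(
  samples = NULL,        # named list/vector: sample_id -> FASTQ path
  contigs = NULL,        # FASTA of assembled contigs
  reference_db = NULL,   # labelled toxin reference FASTA (refid|FAMILY|taxon)
  output_dir = NULL,
  k = 57L,               # contamination screen k-mer length
  fold = 1000,           # cross-sample fold threshold
  frac = 0.25,           # flagged-base fraction for read removal
  min_len = 75L,         # minimum read length
  filter_mode = "union",
  min_codons = 50L,      # minimum ORF length (sense codons)
  min_score = 50,        # annotation score threshold
  min_identity = 30,     # annotation identity threshold (%)
  seed_length = 31L,
  max_mismatches = 8L,
  chimera_fold = 10,
  chimera_window = 25L,
  chimera_min_depth = 10L,
  expression_fold = 5,
  identity = 0.99,       # isoform clustering identity
  tpm_threshold = 0.01,  # family-summary proportion cutoff
  seed = 1L
)

#' Build a validated pipeline configuration
#'
#' Defaults follow the curation workflow's standard settings (k = 57,
#' 1000-fold, 25 percent coverage, 75-bp minimum, 50-codon ORFs, 99 percent
#' isoform identity, 5-fold expression rule, 10-fold/25-nt chimera screen,
#' 1 percent family-summary cutoff). Unknown keys are rejected.
#'
#' @param ... Named overrides of the defaults.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(PIPELINE_DEFAULTS))
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  cfg <- PIPELINE_DEFAULTS
  for (n in names(over)) cfg[n] <- list(over[[n]])  # keeps explicit NULLs
  with(cfg, {
    stopifnot(k >= 1, fold > 0, frac > 0, frac <= 1, min_len >= 1,
              min_codons >= 1, identity > 0, identity <= 1,
              expression_fold >= 1, chimera_fold >= 1, chimera_window >= 1,
              tpm_threshold >= 0, tpm_threshold <= 1,
              filter_mode %in% c("union", "per-sample"))
  })
  structure(cfg, class = "PipelineConfig")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return A `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname read_pipeline_config
#' @param config A `PipelineConfig`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the curation pipeline end-to-end
#'
#' Stages, in order: per-sample length + cross-contamination read filtering;
#' complete-ORF discovery on the supplied contigs (assembly is an external
#' hand-off); toxin-family annotation; mapping of each sample's filtered
#' reads to the annotated ORF catalog with coverage profiling; chimera
#' screening (a contig is removed when every sample with informative depth
#' shows a coverage discontinuity); three-indicator species assignment;
#' per-species isoform clustering; per-species TPM quantification and
#' family summaries.
#'
#' Inputs may be given as file paths in the config or as in-memory objects
#' (`batch`, `contigs`, `ref_db`), which is how the synthetic end-to-end
#' tests drive the pipeline.
#'
#' @param config A `PipelineConfig`.
#' @param batch Optional `MultiplexBatch` or named list of `ReadSet`.
#' @param contigs Optional named character vector of contig sequences.
#' @param ref_db Optional reference database data frame.
#' @param quiet Suppress per-stage messages.
#' @return A `CurationReport` (list) with per-stage counts, per-species
#'   catalogs and family summaries, and provenance (config hash, seed,
#'   package version). Written as JSON to `output_dir` when set.
#' @export
run_pipeline <- function(config, batch = NULL, contigs = NULL, ref_db = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  say <- function(...) if (!quiet) message(sprintf(...))

  # ---- inputs -------------------------------------------------------------
  if (is.null(batch)) {
    if (is.null(config$samples)) stop("no samples: supply config$samples or batch")
    paths <- unlist(config$samples)
    missing <- paths[!file.exists(paths)]
    if (length(missing)) stop("missing input file(s): ", paste(missing, collapse = ", "))
    read_sets <- lapply(names(paths), function(s) read_fastq(paths[[s]], s))
    names(read_sets) <- names(paths)
  } else {
    read_sets <- if (inherits(batch, "MultiplexBatch")) batch$read_sets else batch
    if (is.null(names(read_sets))) {
      names(read_sets) <- vapply(read_sets, function(r) r$sample_id, "")
    }
  }
  if (is.null(contigs)) {
    if (is.null(config$contigs)) stop("no contigs: supply config$contigs or contigs")
    if (!file.exists(config$contigs)) stop("missing input file(s): ", config$contigs)
    contigs <- read_fasta(config$contigs)
  }
  if (is.null(ref_db)) {
    if (is.null(config$reference_db)) stop("no reference db: supply config$reference_db or ref_db")
    if (!file.exists(config$reference_db)) stop("missing input file(s): ", config$reference_db)
    ref_db <- read_reference_db(config$reference_db)
  }
  samples <- names(read_sets)
  outdir <- config$output_dir
  if (!is.null(outdir) && !dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  save_tsv <- function(df, name) {
    if (!is.null(outdir)) write_truth_table(df, file.path(outdir, name))
  }

  # ---- stage 1: contamination + length filtering --------------------------
  say("[filter] counting %d-mers in %d samples", config$k, length(samples))
  spectra <- lapply(read_sets, count_kmers, k = config$k)
  filtered <- list()
  filter_counts <- list()
  for (s in samples) {
    flagged <- lapply(setdiff(samples, s), function(o) {
      flag_kmers(spectra[[s]], spectra[[o]], fold_threshold = config$fold)
    })
    fr <- filter_reads(read_sets[[s]], flagged, coverage_fraction = config$frac,
                       min_length = config$min_len, mode = config$filter_mode)
    filtered[[s]] <- fr$kept
    filter_counts[[s]] <- as.list(attr(fr$report, "summary"))
    save_tsv(fr$report, sprintf("filter_report_%s.tsv", s))
    say("[filter] %s: %d in, %d kept, %d contamination, %d too short", s,
        filter_counts[[s]]$input, filter_counts[[s]]$kept,
        filter_counts[[s]]$contamination, filter_counts[[s]]$too_short)
  }
  spectra <- NULL

  # ---- stage 2: ORF discovery --------------------------------------------
  orfs <- do.call(rbind, lapply(seq_along(contigs), function(i) {
    find_orfs(contigs[i], min_codons = config$min_codons)
  }))
  if (is.null(orfs)) orfs <- find_orfs(c(dummy = "ACGT"), min_codons = 1)
  say("[orf] %d complete ORFs from %d contigs", nrow(orfs), length(contigs))

  # ---- stage 3: annotation ------------------------------------------------
  anns <- annotate_orfs(orfs, ref_db, min_score = config$min_score,
                        min_identity = config$min_identity)
  fams <- vapply(anns, `[[`, "", "family")
  toxin <- orfs[fams[orfs$orf_id] != "unclassified", , drop = FALSE]
  say("[annotate] %d toxin-like ORFs, %d unclassified",
      nrow(toxin), nrow(orfs) - nrow(toxin))
  ann_table <- data.frame(
    orf_id = orfs$orf_id, contig_id = orfs$contig_id,
    family = fams[orfs$orf_id],
    best_hit = vapply(anns[orfs$orf_id], function(a) as.character(a$best_hit), ""),
    stringsAsFactors = FALSE
  )
  save_tsv(ann_table, "annotations.tsv")

  catalog <- stats::setNames(toxin$cds, toxin$orf_id)
  # deduplicate identical CDS picked up from several contigs
  catalog <- catalog[!duplicated(catalog)]
  toxin <- toxin[toxin$orf_id %in% names(catalog), , drop = FALSE]

  # ---- stage 4: mapping + coverage + expression ---------------------------
  alns <- list(); tpm_tables <- list()
  for (s in samples) {
    alns[[s]] <- map_reads(filtered[[s]], catalog,
                           seed_length = config$seed_length,
                           max_mismatches = config$max_mismatches)
    cnt <- stats::setNames(rep(0, length(catalog)), names(catalog))
    if (nrow(alns[[s]]$placements)) {
      agg <- tapply(alns[[s]]$placements$weight, alns[[s]]$placements$contig_id, sum)
      cnt[names(agg)] <- agg
    }
    tpm_tables[[s]] <- compute_tpm(cnt, nchar(catalog))
    say("[map] %s: %d/%d reads mapped", s,
        length(unique(alns[[s]]$placements$read_id)), n_reads(filtered[[s]]))
  }

  # ---- stage 5: chimera screen -------------------------------------------
  profiles <- lapply(names(catalog), function(id) {
    lapply(samples, function(s) coverage_profile(alns[[s]], catalog[id]))
  })
  names(profiles) <- names(catalog)
  for (id in names(catalog)) names(profiles[[id]]) <- samples
  read_len <- vapply(samples, function(s) {
    if (n_reads(filtered[[s]]) == 0) return(0)
    stats::median(nchar(filtered[[s]]$reads$sequence))
  }, 1)
  chim <- vapply(names(catalog), function(id) {
    calls <- vapply(samples, function(s) {
      pr <- profiles[[id]][[s]]
      if (max(pr$depth) < config$chimera_min_depth) return(NA_character_)
      detect_chimera(pr, fold_threshold = config$chimera_fold,
                     window = config$chimera_window,
                     min_depth = config$chimera_min_depth,
                     margin = read_len[[s]])$verdict
    }, "")
    informative <- calls[!is.na(calls) & calls != "indeterminate"]
    length(informative) > 0 && all(informative == "chimeric")
  }, TRUE)
  save_tsv(data.frame(orf_id = names(catalog), chimeric = chim), "chimera_calls.tsv")
  say("[chimera] %d/%d catalog entries flagged chimeric", sum(chim), length(chim))
  kept_ids <- names(catalog)[!chim]

  # ---- stage 6: species assignment ---------------------------------------
  assigns <- lapply(kept_ids, function(id) {
    tpms <- vapply(samples, function(s) {
      t <- tpm_tables[[s]]
      t$tpm[match(id, t$contig_id)]
    }, 1)
    assign_species(catalog[id], tpms, annotation = anns[[id]],
                   profiles_by_sample = profiles[[id]],
                   expression_fold = config$expression_fold)
  })
  names(assigns) <- kept_ids
  assigned_species <- vapply(assigns, `[[`, "", "assigned_species")
  save_tsv(data.frame(orf_id = kept_ids, species = assigned_species,
                      confidence = vapply(assigns, `[[`, "", "confidence")),
           "species_assignments.tsv")
  say("[assign] %d assigned, %d ambiguous",
      sum(assigned_species != "ambiguous"), sum(assigned_species == "ambiguous"))

  # ---- stage 7+8: per-species clustering and quantification ---------------
  per_species <- list()
  for (s in samples) {
    ids <- kept_ids[assigned_species == s]
    if (!length(ids)) {
      per_species[[s]] <- list(catalog = character(), clusters = 0L,
                               expression = compute_tpm(numeric(), numeric()),
                               family_summary = NULL)
      next
    }
    cl <- cluster_isoforms(catalog[ids], identity_threshold = config$identity)
    reps <- vapply(cl, `[[`, "", "centroid")
    cnt <- stats::setNames(rep(0, length(ids)), ids)
    p <- alns[[s]]$placements
    p <- p[p$contig_id %in% ids, , drop = FALSE]
    if (nrow(p)) {
      agg <- tapply(p$weight, p$contig_id, sum)
      cnt[names(agg)] <- agg
    }
    expr <- compute_tpm(cnt, nchar(catalog[ids]))
    fam_vec <- stats::setNames(fams[ids], ids)
    fs <- summarize_families(expr, fam_vec, clusters = cl,
                             threshold = config$tpm_threshold)
    expr$family <- fam_vec[expr$contig_id]
    ct <- cluster_table(cl)
    expr$cluster_id <- ct$cluster_id[match(expr$contig_id, ct$contig_id)]
    save_tsv(expr, sprintf("expression_%s.tsv", s))
    save_tsv(ct, sprintf("clusters_%s.tsv", s))
    if (!is.null(outdir)) {
      write_fasta(catalog[reps], file.path(outdir, sprintf("catalog_%s.fasta", s)))
    }
    per_species[[s]] <- list(catalog = ids, representatives = reps,
                             clusters = length(cl), expression = expr,
                             family_summary = fs)
    say("[species %s] %d contigs, %d clusters, top families: %s", s,
        length(ids), length(cl),
        paste(utils::head(fs$family, 3), collapse = ", "))
  }

  report <- list(
    stages = list(
      reads = filter_counts,
      orfs = list(found = nrow(orfs), toxin = nrow(toxin),
                  unclassified = nrow(orfs) - nrow(toxin)),
      catalog = list(candidates = length(chim), chimeric = sum(chim),
                     assigned = sum(assigned_species != "ambiguous"),
                     ambiguous = sum(assigned_species == "ambiguous"))
    ),
    per_species = lapply(per_species, function(x) {
      list(n_contigs = length(x$catalog), n_clusters = x$clusters,
           families = if (is.null(x$family_summary)) NULL else
             as.list(stats::setNames(x$family_summary$proportion,
                                     x$family_summary$family)))
    }),
    provenance = list(config_hash = rlang::hash(unclass(config)),
                      seed = config$seed,
                      version = as.character(utils::packageVersion("venomtx")))
  )
  out <- structure(list(report = report, per_species = per_species,
                        orfs = orfs, annotations = anns, assignments = assigns,
                        config = config),
                   class = "CurationReport")
  if (!is.null(outdir)) {
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

#' @export
print.CurationReport <- function(x, ...) {
  st <- x$report$stages
  cat("CurationReport\n")
  for (s in names(st$reads)) {
    r <- st$reads[[s]]
    cat(sprintf("  reads %s: %d in, %d kept (%d contamination, %d too short)\n",
                s, r$input, r$kept, r$contamination, r$too_short))
  }
  cat(sprintf("  ORFs: %d found, %d toxin-like\n", st$orfs$found, st$orfs$toxin))
  cat(sprintf("  catalog: %d candidates, %d chimeric, %d assigned, %d ambiguous\n",
              st$catalog$candidates, st$catalog$chimeric,
              st$catalog$assigned, st$catalog$ambiguous))
  for (s in names(x$report$per_species)) {
    p <- x$report$per_species[[s]]
    cat(sprintf("  %s: %d contigs in %d clusters\n", s, p$n_contigs, p$n_clusters))
  }
  invisible(x)
}

#' Score the contamination filter against ground truth
#'
#' Convenience scorer for synthetic batches: sensitivity is the fraction of
#' spiked contaminant reads removed, false-removal rate the fraction of
#' genuine reads removed.
#'
#' @param report A `FilterReport` from [filter_reads()].
#' @param reads The input `ReadSet` with `true_source` labels.
#' @return List with `sensitivity`, `false_removal_rate`, `n_contaminant`,
#'   `n_genuine`.
#' @export
score_contamination_filter <- function(report, reads) {
  truth <- reads$reads$true_source[match(report$read_id, reads$reads$read_id)]
  is_cont <- startsWith(truth, "contaminant:")
  removed <- !report$kept
  list(
    sensitivity = if (any(is_cont)) mean(removed[is_cont]) else NA_real_,
    false_removal_rate = if (any(!is_cont)) mean(removed[!is_cont]) else NA_real_,
    n_contaminant = sum(is_cont),
    n_genuine = sum(!is_cont)
  )
}
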