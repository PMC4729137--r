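#' Run manifest for a cohort of amplicon samples
#'
#' Validates the sample sheet of an end-to-end run: unique sample ids, a
#' patient id and regime per sample, and (when reads come from files) a
#' resolvable SAM/BAM path per sample.
#'
#' @param samples data.frame with columns \code{sample}, \code{patient},
#'   \code{regime} ("native"/"wga2"), and optionally \code{path}.
#' @param reference amplicon reference: a nucleotide string or a FASTA path.
#' @param config a [pipeline_config()]; each sample's regime overrides
#'   \code{config$regime}.
#' @param tcfg optional [transcript_config()] for protein annotation.
#' @param reads named list of in-memory read data.frames keyed by sample id,
#'   used instead of \code{samples$path} when supplied.
#' @return a validated list of class \code{"run_manifest"}.
#' @export
run_manifest <- function(samples, reference, config = pipeline_config(),
                         tcfg = NULL, reads = NULL) {
  if (is.null(samples) || !nrow(samples))
    stop("usage error: empty manifest")
  need <- c("sample", "patient", "regime")
  if (!all(need %in% names(samples)))
    stop("manifest needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(samples$sample))
    stop("duplicate sample ids in manifest")
  if (!all(samples$regime %in% c("native", "wga2")))
    stop("regime must be 'native' or 'wga2'")
  if (is.null(reads)) {
    if (is.null(samples$path))
      stop("manifest needs a 'path' column or in-memory reads")
    missing <- samples$path[!file.exists(samples$path)]
    if (length(missing))
      stop("unresolvable input path(s): ", paste(missing, collapse = ", "))
  } else {
    if (!all(samples$sample %in% names(reads)))
      stop("in-memory reads missing for some samples")
  }
  if (length(reference) == 1L && file.exists(reference) &&
      grepl("\\.(fa|fasta|fna)$", reference, ignore.case = TRUE))
    reference <- read_reference_fasta(reference)
  if (!grepl("^[ACGTacgt]+$", reference))
    stop("reference must be a nucleotide string or FASTA path")
  structure(list(samples = samples, reference = toupper(reference),
                 config = config, tcfg = tcfg, reads = reads),
            class = "run_manifest")
}

sample_config <- function(config, regime) {
  cfg <- unclass(config)
  cfg$regime <- regime
  do.call(pipeline_config, cfg)
}

#' Run the mutation-detection pipeline over a cohort
#'
#' Per sample: quality-filtered pileup, background estimation, candidate
#' calling; then across samples: the cohort recurrent-artifact filter and
#' patient-linked rescue; then per sample: read-backed haplotype tables over
#' the final called variants and (when a transcript configuration is
#' supplied) protein annotation plus a drug-response profile of the detected
#' mutants. All analysis stages are deterministic: identical manifests give
#' identical bundles. A structured log records every threshold applied and
#' every artifact-flagged, rescued and reported call.
#'
#' @param manifest a [run_manifest()].
#' @param out_dir optional directory; when given, per-sample candidate TSVs,
#'   the cohort haplotype TSV and a JSON report are written there.
#' @return a list of class \code{"amplicon_run"}: \code{candidates} (named
#'   list of per-sample candidate tables with final verdict flags),
#'   \code{haplotypes} (named list of [build_haplotype_table()] outputs),
#'   \code{cohort_table} (all haplotype rows with sample/patient columns),
#'   \code{profile} (a [lookup_profile()] result, or NULL without
#'   annotation), \code{log} (character).
#' @export
run_pipeline <- function(manifest, out_dir = NULL) {
  stopifnot(inherits(manifest, "run_manifest"))
  s <- manifest$samples
  ref <- manifest$reference
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  note("pipeline start: %d sample(s), reference %d bp", nrow(s), nchar(ref))
  candidates <- list()
  for (i in seq_len(nrow(s))) {
    id <- s$sample[i]
    cfg <- sample_config(manifest$config, s$regime[i])
    reads <- if (!is.null(manifest$reads)) manifest$reads[[id]]
             else read_sam(s$path[i])
    tab <- build_pileup(reads, ref, cfg)
    bg <- estimate_background(tab, cfg)
    candidates[[id]] <- call_candidates(tab, bg, cfg, sample_id = id,
                                        patient_id = s$patient[i])
    note("sample %s (%s): %d reads, background mean %.4f%% sd %.4f%%, floor %.2f%%, outlier > mean + %g sd",
         id, s$regime[i], nrow(reads), bg$mean, bg$sd, regime_floor(cfg),
         cfg$sd_multiplier)
  }

  if (nrow(s) >= 2L) {
    before <- lapply(candidates, function(x) candidate_key(x)[x$called])
    candidates <- filter_cohort_artifacts(candidates, manifest$config)
    for (id in names(candidates)) {
      dropped <- setdiff(before[[id]],
                         candidate_key(candidates[[id]])[candidates[[id]]$called])
      for (k in dropped)
        note("sample %s: call %s discarded as cohort artifact (recurs in > %.0f%% of samples)",
             id, k, 100 * manifest$config$cohort_artifact_fraction)
    }
  } else {
    note("cohort artifact filter skipped: single-sample manifest")
  }

  grouping <- stats::setNames(s$patient, s$sample)
  candidates <- rescue_patient_linked(candidates, grouping, manifest$config)
  for (id in names(candidates)) {
    x <- candidates[[id]]
    for (k in candidate_key(x)[x$rescued])
      note("sample %s: call %s rescued via a passing call in a matched sample of patient %s (percent > mean + %g sd)",
           id, k, grouping[[id]], manifest$config$rescue_sd_multiplier)
  }

  haplotypes <- list()
  cohort_rows <- list()
  all_labels <- character()
  for (i in seq_len(nrow(s))) {
    id <- s$sample[i]
    cfg <- sample_config(manifest$config, s$regime[i])
    x <- candidates[[id]]
    called <- x[x$called, c("pos", "ref", "alt"), drop = FALSE]
    if (nrow(called) && !is.null(manifest$tcfg)) {
      ann <- annotate_calls(called, ref, manifest$tcfg)
      called$label <- ifelse(is.na(ann$aa_label),
                             paste0(called$pos, called$ref, ">", called$alt),
                             ann$aa_label)
    }
    reads <- if (!is.null(manifest$reads)) manifest$reads[[id]]
             else read_sam(s$path[i])
    pat <- assign_read_patterns(reads, called, cfg)
    ht <- build_haplotype_table(pat, cfg$percent_decimals)
    haplotypes[[id]] <- ht
    for (j in seq_len(nrow(ht)))
      note("sample %s: haplotype %s reported (%d of %d reads, %.2f%%)",
           id, ht$label[j], ht$mutant_reads[j], ht$total_reads[j],
           ht$percent[j])
    if (nrow(ht))
      cohort_rows[[id]] <- cbind(sample = id, patient = s$patient[i],
                                 as.data.frame(ht))
    all_labels <- c(all_labels, ht$label)
  }
  cohort_table <- if (length(cohort_rows)) do.call(rbind, cohort_rows)
                  else NULL
  if (!is.null(cohort_table)) rownames(cohort_table) <- NULL

  profile <- NULL
  if (!is.null(manifest$tcfg) && length(all_labels)) {
    profile <- lookup_profile(sort(unique(all_labels)))
    note("therapy profile: %d mutant(s) queried, retained antagonists: %s",
         length(profile$mutants),
         if (length(profile$retained_antagonists))
           paste(profile$retained_antagonists, collapse = ", ") else "none")
  }

  run <- structure(list(candidates = candidates, haplotypes = haplotypes,
                        cohort_table = cohort_table, profile = profile,
                        log = log),
                   class = "amplicon_run")
  if (!is.null(out_dir)) write_run_bundle(run, out_dir)
  run
}

#' @export
print.amplicon_run <- function(x, ...) {
  n_called <- sum(vapply(x$candidates, function(c) sum(c$called), integer(1)))
  cat(sprintf("Amplicon pipeline run: %d sample(s), %d called variant(s)\n",
              length(x$candidates), n_called))
  if (!is.null(x$cohort_table)) {
    cat("Cohort haplotype table:\n")
    print(x$cohort_table, row.names = FALSE)
  }
  invisible(x)
}

write_run_bundle <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(run$candidates))
    write_candidates_tsv(run$candidates[[id]],
                         file.path(out_dir, paste0(id, ".candidates.tsv")))
  if (!is.null(run$cohort_table))
    utils::write.table(run$cohort_table,
                       file.path(out_dir, "cohort_haplotypes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  report <- list(
    samples = names(run$candidates),
    n_called = vapply(run$candidates, function(c) sum(c$called), integer(1)),
    detected_mutants = if (!is.null(run$profile)) run$profile$mutants
                       else unique(unlist(lapply(run$haplotypes,
                                                 function(h) h$label))),
    retained_antagonists = if (!is.null(run$profile))
      run$profile$retained_antagonists else NULL
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(run$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
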