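#' Estimate the per-sample substitution background
#'
#' The caller's null model: the mean and standard deviation of all
#' non-reference base percentages pooled across amplicon positions within a
#' sample. Observations at or above the regime's calling floor are excluded
#' before estimation so that genuine variants do not inflate the background.
#' The population (n-denominator) standard deviation is used; with thousands
#' of position/alternate-base observations the distinction from the sample
#' estimator is immaterial, and it keeps the constant-vector edge case exact.
#'
#' @param table a [build_pileup()] result covering at least 10 positions.
#' @param config a [pipeline_config()]; its regime selects the floor.
#' @return an object of class \code{"background_model"}: \code{mean} and
#'   \code{sd} (percent), \code{n_observations}, and a construction note.
#' @export
estimate_background <- function(table, config = attr(table, "config")) {
  stopifnot(inherits(table, "base_count_table"),
            inherits(config, "pipeline_config"))
  if (nrow(table) < 10L)
    stop("background estimation requires at least 10 covered positions")
  obs <- nonref_percentages(table)
  floor_pct <- regime_floor(config)
  usable <- obs$percent[obs$percent < floor_pct]
  if (length(usable) < 2L)
    stop("fewer than 2 usable background observations below the ",
         config$regime, " floor (", floor_pct, "%)")
  m <- mean(usable)
  s <- sqrt(mean((usable - m)^2))
  structure(list(mean = m, sd = s, n_observations = length(usable),
                 note = sprintf(
                   "within-sample pooling of per-position non-reference percentages; %d of %d observations below the %s floor (%g%%)",
                   length(usable), nrow(obs), config$regime, floor_pct)),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("Substitution background: mean %.4f%%, sd %.4f%% (n = %d)\n",
              x$mean, x$sd, x$n_observations))
  cat(" ", x$note, "\n")
  invisible(x)
}

#' Call mutation candidates against the background model
#'
#' A non-reference base is called when its percentage strictly exceeds both
#' the one-sided outlier threshold \code{bg$mean + sd_multiplier * bg$sd} and
#' the regime floor (0.1\% native, 1\% WGA2 by default, the latter because of
#' the increased substitution background of amplified libraries). Every
#' non-reference base at every covered position is evaluated and its verdicts
#' recorded, including failures, so downstream cohort filtering and rescue
#' operate on complete evidence.
#'
#' @param table a [build_pileup()] result.
#' @param bg a [estimate_background()] model from the same sample.
#' @param config a [pipeline_config()].
#' @param sample_id,patient_id identifiers attached to each candidate row.
#' @return a data.frame of class \code{"variant_candidates"}: \code{pos},
#'   \code{ref}, \code{alt}, \code{count}, \code{depth}, \code{percent},
#'   \code{bg_mean}, \code{bg_sd}, the verdict flags \code{passed_outlier},
#'   \code{passed_floor}, \code{cohort_artifact}, \code{rescued}, and
#'   \code{called}. At all times
#'   \code{called == (passed_outlier & passed_floor & !cohort_artifact) | rescued}.
#' @export
call_candidates <- function(table, bg, config = attr(table, "config"),
                            sample_id = NA_character_,
                            patient_id = NA_character_) {
  stopifnot(inherits(bg, "background_model"),
            inherits(config, "pipeline_config"))
  obs <- nonref_percentages(table)
  threshold <- bg$mean + config$sd_multiplier * bg$sd
  out <- data.frame(
    sample = sample_id, patient = patient_id,
    obs,
    bg_mean = bg$mean, bg_sd = bg$sd,
    passed_outlier = obs$percent > threshold,
    passed_floor = obs$percent > regime_floor(config),
    cohort_artifact = FALSE, rescued = FALSE,
    stringsAsFactors = FALSE
  )
  out$called <- candidate_verdict(out)
  class(out) <- c("variant_candidates", "data.frame")
  out
}

candidate_verdict <- function(cand) {
  (cand$passed_outlier & cand$passed_floor & !cand$cohort_artifact) |
    cand$rescued
}

candidate_key <- function(cand) {
  paste(cand$pos, cand$ref, cand$alt, sep = ":")
}

#' Flag cohort-recurrent artifacts
#'
#' A (position, ref, alt) key that is a passing call in strictly more than
#' \code{cohort_artifact_fraction} (default 75\%) of the cohort's samples is
#' interpreted as systematic noise: the \code{cohort_artifact} flag is set on
#' that key in every sample and the calls are withdrawn. A key in exactly the
#' threshold fraction (e.g. 3 of 4 samples) is kept. With a single sample the
#' filter is a no-op with a warning.
#'
#' @param calls_by_sample named list of \code{variant_candidates}, one per
#'   sample, keyed identically across samples.
#' @param config a [pipeline_config()].
#' @return the updated list.
#' @export
filter_cohort_artifacts <- function(calls_by_sample, config) {
  n <- length(calls_by_sample)
  if (n < 2L) {
    warning("cohort artifact filter skipped: fewer than 2 samples")
    return(calls_by_sample)
  }
  called_keys <- lapply(calls_by_sample, function(x)
    unique(candidate_key(x)[x$passed_outlier & x$passed_floor]))
  tab <- table(unlist(called_keys, use.names = FALSE))
  artifacts <- names(tab)[tab / n > config$cohort_artifact_fraction]
  lapply(calls_by_sample, function(x) {
    x$cohort_artifact <- candidate_key(x) %in% artifacts
    x$called <- candidate_verdict(x)
    x
  })
}

#' Rescue patient-linked sub-threshold calls
#'
#' Replaces the published manual review of matched-sample scatter plots with
#' a reproducible rule: a candidate that failed the primary thresholds is
#' rescued when the same (position, ref, alt) is a passing call in another
#' sample of the same patient AND its own percentage exceeds
#' \code{bg_mean + rescue_sd_multiplier * bg_sd} (default 2 sd) in its own
#' sample. Rescued candidates are marked, never silently merged. Keys flagged
#' as cohort artifacts are not eligible.
#'
#' @param calls_by_sample named list of \code{variant_candidates}.
#' @param patient_grouping named character vector mapping every sample id to
#'   its patient id.
#' @param config a [pipeline_config()].
#' @return the updated list.
#' @export
rescue_patient_linked <- function(calls_by_sample, patient_grouping, config) {
  samples <- names(calls_by_sample)
  if (is.null(samples) || !all(samples %in% names(patient_grouping)))
    stop("every sample needs a patient id in patient_grouping")
  passing <- lapply(calls_by_sample, function(x)
    unique(candidate_key(x)[x$called & !x$rescued]))
  for (s in samples) {
    mates <- samples[patient_grouping[samples] == patient_grouping[[s]] &
                       samples != s]
    if (!length(mates)) next
    mate_keys <- unique(unlist(passing[mates], use.names = FALSE))
    x <- calls_by_sample[[s]]
    key <- candidate_key(x)
    eligible <- !x$called & !x$cohort_artifact & key %in% mate_keys
    thr <- x$bg_mean + config$rescue_sd_multiplier * x$bg_sd
    x$rescued <- eligible & x$percent > thr
    x$called <- candidate_verdict(x)
    calls_by_sample[[s]] <- x
  }
  calls_by_sample
}

#' Write a candidate table as TSV
#'
#' @param candidates a \code{variant_candidates} data.frame.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_candidates_tsv <- function(candidates, path) {
  utils::write.table(as.data.frame(candidates), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
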