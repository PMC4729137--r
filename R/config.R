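#' Pipeline configuration
#'
#' Bundles every threshold of the mutation-calling pipeline into one validated
#' record. Defaults reproduce the published analysis settings: bases are scored
#' only when their Phred quality exceeds 25 and their read's mapping quality
#' exceeds 18; mutation candidates must lie more than 4 background standard
#' deviations above the background mean AND above a regime-dependent frequency
#' floor (0.1\% for native cfDNA libraries, 1\% for whole-genome-amplified
#' "wga2" libraries, whose amplification chemistry inflates the substitution
#' background); calls recurring in more than 75\% of cohort samples are
#' discarded as systematic artifacts; reads with more than 7 mismatches against
#' the reference are uninformative for haplotype estimation when a sample has
#' multiple calls.
#'
#' All threshold comparisons are strict inequalities (">"), so a base at
#' exactly Phred 25 or a read at mapping quality 18 is excluded, and a call in
#' exactly 75\% of samples is kept.
#'
#' @param base_quality_min minimum Phred base quality (exclusive). Default 25.
#' @param mapping_quality_min minimum mapping quality (exclusive). Default 18.
#' @param sd_multiplier number of background standard deviations a candidate
#'   must exceed. Default 4.
#' @param floor_native frequency floor (percent) for native libraries. Default 0.1.
#' @param floor_wga2 frequency floor (percent) for WGA2 libraries. Default 1.0.
#' @param cohort_artifact_fraction fraction of samples above which a recurrent
#'   call is an artifact (exclusive). Default 0.75.
#' @param mismatch_cap maximum per-read mismatch count for haplotype-informative
#'   reads when multiple variants are called (exclusive). Default 7.
#' @param regime sequencing regime, \code{"native"} or \code{"wga2"}.
#' @param percent_decimals decimal places for reported percentages. Default 2.
#' @param rescue_sd_multiplier background standard deviations required for
#'   patient-linked rescue of a sub-threshold call. Default 2.
#' @return an object of class \code{"pipeline_config"} (a named list).
#' @examples
#' cfg <- pipeline_config(regime = "wga2")
#' regime_floor(cfg)
#' @export
pipeline_config <- function(base_quality_min = 25,
                            mapping_quality_min = 18,
                            sd_multiplier = 4,
                            floor_native = 0.1,
                            floor_wga2 = 1.0,
                            cohort_artifact_fraction = 0.75,
                            mismatch_cap = 7L,
                            regime = c("native", "wga2"),
                            percent_decimals = 2L,
                            rescue_sd_multiplier = 2) {
  regime <- match.arg(regime)
  cfg <- list(
    base_quality_min = as.numeric(base_quality_min),
    mapping_quality_min = as.numeric(mapping_quality_min),
    sd_multiplier = as.numeric(sd_multiplier),
    floor_native = as.numeric(floor_native),
    floor_wga2 = as.numeric(floor_wga2),
    cohort_artifact_fraction = as.numeric(cohort_artifact_fraction),
    mismatch_cap = as.integer(mismatch_cap),
    regime = regime,
    percent_decimals = as.integer(percent_decimals),
    rescue_sd_multiplier = as.numeric(rescue_sd_multiplier)
  )
  with(cfg, {
    stopifnot(
      base_quality_min > 0, mapping_quality_min > 0,
      sd_multiplier > 0, floor_native > 0, floor_wga2 > 0,
      mismatch_cap > 0, percent_decimals >= 0, rescue_sd_multiplier > 0
    )
    if (!(floor_native < floor_wga2))
      stop("floor_native must be smaller than floor_wga2")
    if (!(cohort_artifact_fraction > 0 && cohort_artifact_fraction <= 1))
      stop("cohort_artifact_fraction must lie in (0, 1]")
  })
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Amplicon mutation-calling configuration\n")
  cat(sprintf("  regime: %s (floor %.2f%%)\n", x$regime, regime_floor(x)))
  cat(sprintf("  base quality > %g, mapping quality > %g\n",
              x$base_quality_min, x$mapping_quality_min))
  cat(sprintf("  outlier rule: percent > mean + %g sd; rescue at %g sd\n",
              x$sd_multiplier, x$rescue_sd_multiplier))
  cat(sprintf("  cohort artifact above %.0f%% of samples; mismatch cap %d\n",
              100 * x$cohort_artifact_fraction, x$mismatch_cap))
  invisible(x)
}

#' Regime-specific calling floor
#'
#' @param config a \code{pipeline_config}.
#' @param regime optional regime overriding \code{config$regime}.
#' @return the frequency floor in percent for the regime.
#' @export
regime_floor <- function(config, regime = config$regime) {
  if (regime == "wga2") config$floor_wga2 else config$floor_native
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path path to a YAML or JSON file of \code{pipeline_config} fields.
#' @return a \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown pipeline_config field(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' Transcript-coordinate configuration for an amplicon
#'
#' Maps 1-based amplicon positions to codon numbers and protein residues.
#' The amplicon is assumed to lie inside a coding sequence; \code{cds_start}
#' is the 1-based position of amplicon base 1 within that coding sequence
#' (so \code{(cds_start - 1) \%\% 3} is the reading-frame offset), and
#' \code{aa_offset} shifts codon numbering to protein coordinates (e.g. an
#' amplicon whose first complete codon is residue 860 of the receptor).
#' For minus-strand transcripts (\code{strand = "-"}) the amplicon sequence is
#' reverse-complemented into coding orientation before translation.
#'
#' @param cds_start 1-based coordinate of amplicon base 1 within the CDS.
#' @param aa_offset integer added to the CDS codon number to obtain the
#'   protein residue number. Default 0.
#' @param strand \code{"+"} (amplicon is coding-strand) or \code{"-"}.
#' @return an object of class \code{"transcript_config"}.
#' @export
transcript_config <- function(cds_start = 1L, aa_offset = 0L, strand = c("+", "-")) {
  strand <- match.arg(strand)
  stopifnot(cds_start >= 1, aa_offset == as.integer(aa_offset))
  structure(list(cds_start = as.integer(cds_start),
                 aa_offset = as.integer(aa_offset),
                 strand = strand),
            class = "transcript_config")
}
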