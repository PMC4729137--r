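#' Read-backed haplotype pattern counting
#'
#' Assigns each read to the exclusive substitution pattern it carries across
#' the sample's called variant positions. A read observes a called position
#' only where it covers it with a base passing the base-quality filter. When
#' the sample has calls at more than one position, reads with more than
#' \code{config$mismatch_cap} mismatches against the reference (the SAM NM
#' count) are uninformative and excluded entirely.
#'
#' A read supports pattern p if and only if it observes all of p's positions
#' with p's alternate alleles AND shows the reference allele at every other
#' called position it observes — so a read carrying two linked substitutions
#' counts only toward the double pattern, never toward either single. The
#' denominator of a pattern is coverage-dependent: all informative reads that
#' observe every position of that pattern, which is why different patterns of
#' one sample can have different totals.
#'
#' @param reads a reads data.frame ([simulate_amplicon()] or [read_sam()]).
#' @param variants data.frame of called variants: \code{pos}, \code{ref},
#'   \code{alt}, and optionally \code{label} (defaults to
#'   \code{"<pos><ref>><alt>"}).
#' @param config a [pipeline_config()].
#' @param watch list of patterns (character vectors of variant labels) to
#'   report even with zero supporting reads.
#' @return data.frame: \code{label}, \code{mutant_reads}, \code{total_reads},
#'   \code{watched}; attribute \code{"n_informative"} gives the number of
#'   reads surviving the mismatch cap.
#' @export
assign_read_patterns <- function(reads, variants, config = pipeline_config(),
                                 watch = list()) {
  empty <- data.frame(label = character(), mutant_reads = integer(),
                      total_reads = integer(), watched = logical(),
                      stringsAsFactors = FALSE)
  if (is.null(variants) || !nrow(variants)) return(empty)
  if (is.null(variants$label))
    variants$label <- paste0(variants$pos, variants$ref, ">", variants$alt)
  ord <- order(variants$pos, variants$alt)
  variants <- variants[ord, , drop = FALSE]
  nv <- nrow(variants)

  multi <- length(unique(variants$pos)) > 1L
  if (multi) reads <- reads[reads$nm <= config$mismatch_cap, , drop = FALSE]
  n <- nrow(reads)

  # state per read x variant: 2 = alternate, 1 = reference, 0 = other base,
  # NA = not observed (uncovered or below base quality)
  state <- matrix(NA_integer_, nrow = n, ncol = nv)
  if (n) {
    for (v in seq_len(nv)) {
      p <- variants$pos[v]
      covered <- reads$start <= p & reads$end >= p
      off <- p - reads$start + 1L
      b <- substr(reads$seq, off, off)
      qchar <- substr(reads$qual, off, off)
      q <- rep(NA_integer_, n)
      nz <- covered & nzchar(qchar)
      if (any(nz))
        q[nz] <- utf8ToInt(paste(qchar[nz], collapse = "")) - 33L
      obs <- covered & !is.na(q) & q > config$base_quality_min
      st <- rep(NA_integer_, n)
      st[obs & b == variants$alt[v]] <- 2L
      st[obs & b == variants$ref[v]] <- 1L
      st[obs & b != variants$alt[v] & b != variants$ref[v]] <- 0L
      state[, v] <- st
    }
  }

  has_alt <- !is.na(state) & state == 2L
  has_other <- !is.na(state) & state == 0L
  supports <- rowSums(has_alt) >= 1L & rowSums(has_other) == 0L
  sig <- apply(has_alt, 1L, function(z) paste(which(z), collapse = ","))

  observed <- sort(unique(sig[supports]))
  watch_sigs <- vapply(watch, function(w) {
    idx <- match(w, variants$label)
    if (anyNA(idx)) stop("watch pattern refers to an unknown variant label")
    paste(sort(idx), collapse = ",")
  }, character(1))
  all_sigs <- union(observed, watch_sigs)
  if (!length(all_sigs)) {
    attr(empty, "n_informative") <- n
    return(empty)
  }

  rows <- lapply(all_sigs, function(s) {
    idx <- as.integer(strsplit(s, ",")[[1]])
    covers_all <- rowSums(!is.na(state[, idx, drop = FALSE])) == length(idx)
    data.frame(
      label = paste(variants$label[idx], collapse = "/"),
      mutant_reads = sum(supports & sig == s),
      total_reads = sum(covers_all),
      watched = s %in% watch_sigs,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "n_informative") <- n
  out
}

#' Build the per-sample haplotype frequency table
#'
#' One row per observed non-reference pattern, mirroring the published
#' haplotype tables: mutant, wild-type and total read counts plus the percent
#' mutant (half-up rounding). Wild-type reads are the pattern's informative
#' total minus its supporting reads. Rows are sorted by descending mutant
#' count; patterns with zero supporting reads appear only when explicitly
#' watch-listed.
#'
#' @param patterns output of [assign_read_patterns()].
#' @param decimals decimal places for the percent column. Default 2.
#' @return a data.frame of class \code{"haplotype_table"}: \code{label},
#'   \code{mutant_reads}, \code{wildtype_reads}, \code{total_reads},
#'   \code{percent}.
#' @export
build_haplotype_table <- function(patterns, decimals = 2L) {
  keep <- patterns$mutant_reads > 0L | patterns$watched
  x <- patterns[keep, , drop = FALSE]
  x <- x[order(-x$mutant_reads, x$label), , drop = FALSE]
  pct <- rep(NA_real_, nrow(x))
  nz <- x$total_reads > 0L
  pct[nz] <- percent_mutant(x$mutant_reads[nz], x$total_reads[nz], decimals)
  out <- data.frame(
    label = x$label,
    mutant_reads = as.integer(x$mutant_reads),
    wildtype_reads = as.integer(x$total_reads - x$mutant_reads),
    total_reads = as.integer(x$total_reads),
    percent = pct,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("haplotype_table", "data.frame")
  out
}
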