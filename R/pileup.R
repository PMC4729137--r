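#' Convert an allele count to a percentage of depth
#'
#' The pipeline's percentage arithmetic: \code{100 * count / depth}, rounded
#' half-up to \code{decimals} places — the convention that reproduces the
#' published per-haplotype "percent mutant" values (e.g. 1,270 of 7,255 reads
#' is 17.51\%).
#'
#' @param count non-negative allele (or haplotype) read count.
#' @param depth positive total read count at the position. Zero depth is an
#'   error: the percentage is undefined.
#' @param decimals decimal places (half-up rounding). Default 2.
#' @return the percentage, vectorized over \code{count}/\code{depth}.
#' @examples
#' percent_mutant(1270, 7255)   # 17.51
#' percent_mutant(251, 13270)   # 1.89
#' @export
percent_mutant <- function(count, depth, decimals = 2L) {
  if (any(depth == 0))
    stop("percent undefined at zero depth")
  if (any(count < 0) || any(count > depth))
    stop("count must lie in [0, depth]")
  round_half_up(100 * count / depth, decimals)
}

round_half_up <- function(x, decimals) {
  # the 1e-9 guard keeps exact-rational .5 boundaries (100*count/depth) from
  # rounding down due to binary representation
  p <- 10^decimals
  floor(x * p + 0.5 + 1e-9) / p
}

#' Quality-filtered per-position base counts for an amplicon
#'
#' Re-implements the read-count quantification step of the pipeline: a read
#' base contributes to position p if and only if the read's mapping quality
#' strictly exceeds \code{config$mapping_quality_min}, the base's own Phred
#' quality strictly exceeds \code{config$base_quality_min}, and the read
#' covers p. Counts of A/C/G/T and the filtered depth are reported for every
#' reference position; ambiguity codes (N) never count toward depth. Raw
#' counts are converted to percentages of the filtered depth at the position.
#'
#' @param reads a reads data.frame ([simulate_amplicon()] or [read_sam()]).
#' @param reference the amplicon reference string.
#' @param config a [pipeline_config()].
#' @return a data.frame of class \code{"base_count_table"} with columns
#'   \code{pos}, \code{ref}, \code{depth}, \code{A}, \code{C}, \code{G},
#'   \code{T}, \code{pct_A} ... \code{pct_T} (percent of filtered depth;
#'   \code{NA} where depth is 0). The configuration is attached as attribute
#'   \code{"config"}.
#' @export
build_pileup <- function(reads, reference, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  reference <- toupper(reference)
  L <- nchar(reference)
  if (!nrow(reads)) stop("empty read set")
  if (any(reads$start < 1L) || any(reads$end > L))
    stop("read extends beyond the reference bounds")
  if (any(is.na(reads$qual)) || any(!nzchar(reads$qual)) ||
      any(nchar(reads$qual) != nchar(reads$seq)))
    stop("missing or malformed base qualities")

  keep <- reads$mapq > config$mapping_quality_min
  counts <- matrix(0L, nrow = L, ncol = 4L,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  if (any(keep)) {
    r <- reads[keep, , drop = FALSE]
    len <- nchar(r$seq)
    pos <- unlist(lapply(seq_len(nrow(r)),
                         function(i) seq.int(r$start[i], length.out = len[i])),
                  use.names = FALSE)
    base <- unlist(lapply(r$seq, utf8ToInt), use.names = FALSE)
    qual <- unlist(lapply(r$qual, utf8ToInt), use.names = FALSE) - 33L
    code <- match(base, utf8ToInt("ACGT"))
    ok <- !is.na(code) & qual > config$base_quality_min
    if (any(ok)) {
      tab <- tabulate((pos[ok] - 1L) * 4L + code[ok], nbins = 4L * L)
      counts <- matrix(tab, nrow = L, ncol = 4L, byrow = TRUE,
                       dimnames = list(NULL, c("A", "C", "G", "T")))
    }
  }
  depth <- as.integer(rowSums(counts))
  pct <- matrix(NA_real_, nrow = L, ncol = 4L)
  nz <- depth > 0L
  if (any(nz))
    pct[nz, ] <- round_half_up(100 * counts[nz, , drop = FALSE] / depth[nz],
                               config$percent_decimals)
  out <- data.frame(pos = seq_len(L),
                    ref = strsplit(reference, "")[[1]],
                    depth = depth,
                    counts,
                    pct_A = pct[, 1], pct_C = pct[, 2],
                    pct_G = pct[, 3], pct_T = pct[, 4],
                    stringsAsFactors = FALSE)
  attr(out, "config") <- config
  class(out) <- c("base_count_table", "data.frame")
  out
}

#' Write a base-count table as TSV
#'
#' @param table a \code{base_count_table}.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_pileup_tsv <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Non-reference percentage observations of a base-count table
#'
#' Returns the long form used by the background model: one row per
#' (position, alternate base) with its percentage of filtered depth.
#' Zero-depth positions are dropped.
#'
#' @param table a \code{base_count_table}.
#' @return data.frame with \code{pos}, \code{ref}, \code{alt}, \code{count},
#'   \code{depth}, \code{percent}.
#' @export
nonref_percentages <- function(table) {
  bases <- c("A", "C", "G", "T")
  out <- do.call(rbind, lapply(bases, function(b) {
    sel <- table$ref != b & table$depth > 0L
    data.frame(pos = table$pos[sel], ref = table$ref[sel],
               alt = rep(b, sum(sel)),
               count = table[[b]][sel], depth = table$depth[sel],
               percent = table[[paste0("pct_", b)]][sel],
               stringsAsFactors = FALSE)
  }))
  out[order(out$pos, out$alt), , drop = FALSE]
}
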