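#' Write simulated reads as SAM (single contig, gapless)
#'
#' Emits one \code{flag 0} record per read with a \code{<len>M} CIGAR and the
#' mismatch count in the \code{NM} tag. The header carries the single
#' amplicon contig.
#'
#' @param reads a reads data.frame as produced by [simulate_amplicon()].
#' @param reference the amplicon reference string (for the \code{@SQ} length).
#' @param path output SAM path.
#' @param contig contig name. Default \code{"amplicon"}.
#' @return the path, invisibly.
#' @export
write_sam <- function(reads, reference, path, contig = "amplicon") {
  stopifnot(all(c("id", "start", "seq", "qual", "mapq", "nm") %in% names(reads)))
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", contig, nchar(reference)))
  body <- sprintf("%s\t0\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s\tNM:i:%d",
                  reads$id, contig, reads$start, reads$mapq,
                  nchar(reads$seq), reads$seq, reads$qual, reads$nm)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a gapless single-contig SAM/BAM file into the pipeline's read table
#'
#' Parsing is delegated to Rsamtools (SAM input is converted to BAM in a
#' temporary directory first). Only gapless alignments (CIGAR \code{<n>M})
#' on a single contig are supported; anything else is rejected, since the
#' pipeline operates in single-amplicon space.
#'
#' @param path SAM or BAM path.
#' @return a reads data.frame (\code{id}, \code{start}, \code{end},
#'   \code{seq}, \code{qual}, \code{mapq}, \code{nm}).
#' @export
read_sam <- function(path) {
  bam <- if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    path
  } else {
    Rsamtools::asBam(path, file.path(tempdir(), paste0("ampvar_", basename(path))),
                     overwrite = TRUE, indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "mapq", "cigar", "seq", "qual"),
    tag = "NM")
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  if (!length(x$qname)) stop("no alignments in ", path)
  if (length(unique(as.character(x$rname[!is.na(x$pos)]))) > 1L)
    stop("multiple reference contigs in ", path, "; single-amplicon input required")
  if (!all(grepl("^[0-9]+M$", x$cigar)))
    stop("non-gapless alignment (CIGAR with indels/clips) in ", path)
  qual <- as.character(x$qual)
  if (any(!nzchar(qual)) || any(qual == "*"))
    stop("missing base qualities in ", path)
  nm <- x$tag$NM
  if (is.null(nm)) stop("NM tag absent in ", path)
  data.frame(id = x$qname,
             start = as.integer(x$pos),
             end = as.integer(x$pos) + nchar(as.character(x$seq)) - 1L,
             seq = as.character(x$seq),
             qual = qual,
             mapq = as.integer(x$mapq),
             nm = as.integer(nm),
             stringsAsFactors = FALSE)
}

#' Amplicon reference FASTA I/O
#'
#' Thin wrappers over Biostrings for the single-sequence amplicon reference.
#'
#' @param path FASTA path.
#' @param reference nucleotide string.
#' @param name sequence name.
#' @return \code{read_reference_fasta}: the reference string;
#'   \code{write_reference_fasta}: the path, invisibly.
#' @export
read_reference_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  if (length(s) != 1L)
    stop("expected exactly one reference sequence in ", path)
  as.character(s[[1]])
}

#' @rdname read_reference_fasta
#' @export
write_reference_fasta <- function(reference, path, name = "amplicon") {
  s <- Biostrings::DNAStringSet(reference)
  names(s) <- name
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

#' Write reads as FASTQ
#'
#' @param reads a reads data.frame.
#' @param path output FASTQ path.
#' @return the path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  lines <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", reads$qual))
  writeLines(lines, path)
  invisible(path)
}
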