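revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[toupper(codon)]]
  if (is.null(aa)) stop("untranslatable codon: ", codon)
  aa
}

#' Annotate a nucleotide substitution with its protein consequence
#'
#' Reconstructs the codon containing the substituted amplicon position from
#' the reference sequence and the transcript-coordinate configuration,
#' applies the substitution, and translates both codons with the standard
#' genetic code. For minus-strand transcripts the amplicon is taken in
#' reverse-complement (coding) orientation before the codon arithmetic.
#'
#' The label follows the field convention \code{<refAA><residue><altAA>}
#' (e.g. \code{T878A}); silent changes render as \code{<AA><residue><AA>} and
#' stop gains use \code{*}. A substitution falling in a codon truncated by
#' the amplicon boundary signals an "untranslatable" error.
#'
#' @param pos 1-based amplicon position of the substitution.
#' @param ref_base reference base at \code{pos} (amplicon orientation).
#' @param alt_base alternate base (amplicon orientation).
#' @param reference the amplicon reference string.
#' @param tcfg a [transcript_config()].
#' @return an object of class \code{"protein_annotation"}: \code{codon_number},
#'   \code{ref_aa}, \code{alt_aa}, \code{label}, and \code{class} (one of
#'   \code{"silent"}, \code{"missense"}, \code{"nonsense"}).
#' @examples
#' tcfg <- transcript_config(cds_start = 1)
#' annotate_variant(3, "G", "A", "ATGCTGTGGAAACCCGGGTTTACGTAGGCTAGCTAGGCTAGCTAGGCTAGCTAGGCTAGCTAGGCTAGCTAGGCTAGCTAGGCTAGCTAGGCTAGCTAGG", tcfg)
#' @export
annotate_variant <- function(pos, ref_base, alt_base, reference, tcfg) {
  stopifnot(inherits(tcfg, "transcript_config"))
  reference <- toupper(reference)
  L <- nchar(reference)
  if (pos < 1L || pos > L) stop("position outside the amplicon")
  ref_base <- toupper(ref_base); alt_base <- toupper(alt_base)
  if (substr(reference, pos, pos) != ref_base)
    stop("ref_base does not match the reference at position ", pos)
  if (ref_base == alt_base) stop("not a substitution")

  if (tcfg$strand == "-") {
    coding <- revcomp(reference)
    cpos <- L - pos + 1L
    c_ref <- revcomp(ref_base)
    c_alt <- revcomp(alt_base)
  } else {
    coding <- reference
    cpos <- pos
    c_ref <- ref_base
    c_alt <- alt_base
  }
  cds_pos <- tcfg$cds_start + cpos - 1L
  within <- (cds_pos - 1L) %% 3L         # 0-based offset within the codon
  codon_start <- cpos - within
  if (codon_start < 1L || codon_start + 2L > L)
    stop("untranslatable: substitution in an incomplete boundary codon")
  ref_codon <- substr(coding, codon_start, codon_start + 2L)
  alt_codon <- ref_codon
  substr(alt_codon, within + 1L, within + 1L) <- c_alt
  stopifnot(substr(ref_codon, within + 1L, within + 1L) == c_ref)

  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  codon_number <- (cds_pos - 1L) %/% 3L + 1L + tcfg$aa_offset
  cls <- if (ref_aa == alt_aa) "silent"
         else if (alt_aa == "*") "nonsense"
         else "missense"
  structure(list(codon_number = codon_number,
                 ref_aa = ref_aa, alt_aa = alt_aa,
                 label = paste0(ref_aa, codon_number, alt_aa),
                 class = cls),
            class = "protein_annotation")
}

#' @export
print.protein_annotation <- function(x, ...) {
  cat(sprintf("%s (%s, codon %d: %s -> %s)\n", x$label, x$class,
              x$codon_number, x$ref_aa, x$alt_aa))
  invisible(x)
}

#' Append protein annotations to a candidate table
#'
#' Vectorized [annotate_variant()] over the rows of a candidate (or any
#' pos/ref/alt) data.frame. Untranslatable rows (boundary codons) get
#' \code{NA} annotation columns and class \code{"untranslatable"} instead of
#' an error, so whole-sample annotation never aborts a run.
#'
#' @param calls data.frame with \code{pos}, \code{ref}, \code{alt}.
#' @param reference the amplicon reference string.
#' @param tcfg a [transcript_config()].
#' @return \code{calls} with added \code{codon_number}, \code{ref_aa},
#'   \code{alt_aa}, \code{aa_label}, \code{aa_class}.
#' @export
annotate_calls <- function(calls, reference, tcfg) {
  ann <- lapply(seq_len(nrow(calls)), function(i) {
    tryCatch(annotate_variant(calls$pos[i], calls$ref[i], calls$alt[i],
                              reference, tcfg),
             error = function(e) {
               if (grepl("untranslatable", conditionMessage(e)))
                 list(codon_number = NA_integer_, ref_aa = NA_character_,
                      alt_aa = NA_character_, label = NA_character_,
                      class = "untranslatable")
               else stop(e)
             })
  })
  calls$codon_number <- vapply(ann, function(a) as.integer(a$codon_number),
                               integer(1))
  calls$ref_aa <- vapply(ann, function(a) a$ref_aa, character(1))
  calls$alt_aa <- vapply(ann, function(a) a$alt_aa, character(1))
  calls$aa_label <- vapply(ann, function(a) a$label, character(1))
  calls$aa_class <- vapply(ann, function(a) a$class, character(1))
  calls
}

#' Translate the full in-frame portion of an amplicon
#'
#' Used by the silent-change invariant check: translates every complete codon
#' of the amplicon in transcript orientation.
#'
#' @param reference the amplicon reference string.
#' @param tcfg a [transcript_config()].
#' @return a single amino-acid string.
#' @export
translate_amplicon <- function(reference, tcfg) {
  coding <- if (tcfg$strand == "-") revcomp(toupper(reference))
            else toupper(reference)
  lead <- (3L - (tcfg$cds_start - 1L) %% 3L) %% 3L  # bases before first full codon
  usable <- nchar(coding) - lead
  n_codons <- usable %/% 3L
  if (n_codons < 1L) return("")
  s <- substr(coding, lead + 1L, lead + 3L * n_codons)
  # the amplicon is an internal CDS fragment: never initiator-translate
  as.character(Biostrings::translate(Biostrings::DNAString(s),
                                     no.init.codon = TRUE))
}
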