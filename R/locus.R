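#' Amplicon locus with reading frame
#'
#' A locus is a sequenced amplicon (typically ~1 kb of a TLR exon) carrying
#' a reference sequence and the reading-frame offset of its first base.
#' `frame_offset` is the 0-based position within a codon of base 1: offset 0
#' means base 1 opens a codon, offset 1 means base 1 is the second base of a
#' codon whose first base lies upstream of the amplicon, and so on.
#' A trailing incomplete codon is allowed; sites inside it cannot be
#' translated and are rejected by [classify_substitution()].
#'
#' @param name locus label, e.g. `"TLR4"`.
#' @param reference_seq reference nucleotide sequence (single string, A/C/G/T).
#' @param frame_offset integer 0, 1 or 2.
#' @return an object of class `tlr_locus`.
#' @export
new_locus <- function(name, reference_seq, frame_offset = 0L) {
  reference_seq <- toupper(as.character(reference_seq))
  stopifnot(length(name) == 1L, length(reference_seq) == 1L)
  if (grepl("[^ACGT]", reference_seq)) {
    stop("reference sequence of '", name, "' contains non-ACGT characters")
  }
  frame_offset <- as.integer(frame_offset)
  if (!frame_offset %in% 0:2) stop("frame_offset must be 0, 1 or 2")
  structure(
    list(name = as.character(name),
         reference_seq = reference_seq,
         frame_offset = frame_offset,
         length_bp = nchar(reference_seq)),
    class = "tlr_locus")
}

#' @export
print.tlr_locus <- function(x, ...) {
  cat(sprintf("<tlr_locus> %s: %d bp, frame offset %d\n",
              x$name, x$length_bp, x$frame_offset))
  invisible(x)
}

# 1-based index of the codon containing `position`, and the position of the
# site within that codon (1..3). Codons are counted within the amplicon:
# codon 0 is the incomplete leading codon when frame_offset > 0.
codon_index <- function(locus, position) {
  shifted <- position - 1L + locus$frame_offset
  list(codon = shifted %/% 3L, within = shifted %% 3L + 1L)
}

# extract the 3 amplicon coordinates of the codon containing `position`;
# NULL when the codon is incomplete (runs off either end of the amplicon)
codon_span <- function(locus, position) {
  ci <- codon_index(locus, position)
  start <- ci$codon * 3L + 1L - locus$frame_offset
  span <- start:(start + 2L)
  if (span[1] < 1L || span[3] > locus$length_bp) return(NULL)
  span
}

#' Translate a codon with the standard genetic code
#'
#' @param codon character vector of 3-base strings.
#' @return character vector of one-letter residues (`*` for stop).
#' @export
translate_codon <- function(codon) {
  codon <- toupper(as.character(codon))
  aa <- Biostrings::GENETIC_CODE[codon]
  if (anyNA(aa)) stop("invalid codon: ",
                      paste(unique(codon[is.na(aa)]), collapse = ", "))
  unname(aa)
}
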