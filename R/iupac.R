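#' IUPAC consensus encoding of unordered diploid base calls
#'
#' Sanger sequencing of a diploid PCR product reports a heterozygous site as
#' a double peak, conventionally recorded as the two-base IUPAC ambiguity
#' code. `iupac_encode()` maps an unordered pair of nucleotides to that
#' consensus code; `iupac_decode()` inverts it.
#'
#' @param a,b character vectors of single bases (`A`, `C`, `G` or `T`).
#'   Recycled to a common length.
#' @return `iupac_encode()`: a character vector of consensus codes (the base
#'   itself for homozygous pairs). `iupac_decode()`: a two-column character
#'   matrix with the alleles of each code in alphabetical order.
#' @examples
#' iupac_encode("C", "T")        # "Y"
#' iupac_decode("R")             # c("A", "G")
#' @export
iupac_encode <- function(a, b) {
  a <- toupper(as.character(a))
  b <- toupper(as.character(b))
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  bad <- !(a %in% DNA_BASES) | !(b %in% DNA_BASES)
  if (any(bad)) {
    stop("non-nucleotide symbol in genotype pair: ",
         paste(unique(c(a[bad], b[bad])), collapse = ", "))
  }
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  unname(IUPAC_FROM_PAIR[paste0(lo, hi)])
}

#' @param code character vector of one- or two-base IUPAC codes.
#' @rdname iupac_encode
#' @export
iupac_decode <- function(code) {
  code <- toupper(as.character(code))
  expand <- Biostrings::IUPAC_CODE_MAP[code]
  if (anyNA(expand) || any(nchar(expand) > 2)) {
    bad <- code[is.na(expand) | nchar(Biostrings::IUPAC_CODE_MAP[code]) > 2]
    stop("not a diploid consensus code: ", paste(unique(bad), collapse = ", "))
  }
  # homozygous codes expand to one base; duplicate it
  expand[nchar(expand) == 1L] <- paste0(expand[nchar(expand) == 1L],
                                        expand[nchar(expand) == 1L])
  m <- matrix(c(substr(expand, 1L, 1L), substr(expand, 2L, 2L)),
              ncol = 2L, dimnames = list(NULL, c("a1", "a2")))
  m
}

#' Is a consensus code heterozygous?
#'
#' @param code character vector of IUPAC consensus codes.
#' @return logical vector: `TRUE` for two-base ambiguity codes.
#' @export
is_het_code <- function(code) {
  nchar(Biostrings::IUPAC_CODE_MAP[toupper(as.character(code))]) == 2L
}

DNA_BASES <- c("A", "C", "G", "T")

# reverse lookup built from Biostrings' IUPAC map at load time
IUPAC_FROM_PAIR <- local({
  map <- Biostrings::IUPAC_CODE_MAP
  two <- map[nchar(map) <= 2]
  keys <- ifelse(nchar(two) == 1L, paste0(two, two), two)
  stats::setNames(names(two), keys)
})
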