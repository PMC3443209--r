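#' Classify a nucleotide substitution as synonymous or non-synonymous
#'
#' Translates the codon containing `position` under each allele with the
#' standard genetic code and compares the encoded residues. A variant that
#' creates a stop codon is never dropped silently: it is classified like any
#' other residue change and flagged via `stop_codon`.
#'
#' @param locus a [new_locus()] object.
#' @param position 1-based site position within the amplicon.
#' @param allele_a,allele_b the two nucleotides to compare (order
#'   irrelevant; the classification is symmetric).
#' @return a list with elements `class` (`"synonymous"` or
#'   `"nonsynonymous"`), `residues` (one-letter residues under each allele),
#'   `codons` and `stop_codon` (logical).
#' @export
classify_substitution <- function(locus, position, allele_a, allele_b) {
  stopifnot(inherits(locus, "tlr_locus"))
  position <- as.integer(position)
  if (position < 1L || position > locus$length_bp) {
    stop("position ", position, " outside amplicon [1, ", locus$length_bp, "]")
  }
  for (al in c(allele_a, allele_b)) {
    if (!al %in% DNA_BASES) stop("invalid allele: ", al)
  }
  span <- codon_span(locus, position)
  if (is.null(span)) {
    stop("untranslatable: site ", position, " of ", locus$name,
         " falls in an incomplete terminal codon")
  }
  within <- codon_index(locus, position)$within
  base_codon <- substr(locus$reference_seq, span[1], span[3])
  make_codon <- function(al) {
    s <- strsplit(base_codon, "")[[1]]
    s[within] <- al
    paste(s, collapse = "")
  }
  codons <- c(make_codon(allele_a), make_codon(allele_b))
  residues <- translate_codon(codons)
  list(class = if (residues[1] == residues[2]) "synonymous" else "nonsynonymous",
       residues = residues,
       codons = codons,
       stop_codon = any(residues == "*"))
}

#' Classify a SNP site (2 or 3 alleles) at codon level
#'
#' A site is non-synonymous if any pair of its alleles encodes different
#' residues. This matches the convention of counting a triallelic site as a
#' single SNP.
#'
#' @inheritParams classify_substitution
#' @param alleles character vector of 2-3 nucleotides observed at the site.
#' @return list with `class`, `residues` (one per allele, in allele order)
#'   and `stop_codon`.
#' @export
classify_site <- function(locus, position, alleles) {
  stopifnot(length(alleles) >= 2L, length(alleles) <= 3L)
  res <- vapply(alleles, function(al) {
    classify_substitution(locus, position, al, al)$residues[1]
  }, character(1))
  list(class = if (length(unique(res)) > 1L) "nonsynonymous" else "synonymous",
       residues = unname(res),
       stop_codon = any(res == "*"))
}

PURINES <- c("A", "G")

is_transition <- function(a, b) {
  (a %in% PURINES) == (b %in% PURINES)
}

#' Tally transitions and transversions over a set of SNP sites
#'
#' A diallelic site contributes one classification. A triallelic site is
#' decomposed into exactly two changes by the minimal-transversion rule: the
#' pivot allele is the one minimising the number of transversions among its
#' changes to the other two alleles, ties broken toward the reference
#' allele (taken as the first allele listed unless a `ref` column is given).
#'
#' @param sites a data frame with a column `alleles` of slash-separated
#'   allele strings (e.g. `"C/T"`, `"A/C/T"`) and optionally a column `ref`
#'   naming the reference allele of each site.
#' @return named integer vector `c(transitions = , transversions = )`.
#' @export
ti_tv_tally <- function(sites) {
  alleles <- strsplit(as.character(sites$alleles), "/", fixed = TRUE)
  ref <- if ("ref" %in% names(sites)) as.character(sites$ref) else
    vapply(alleles, `[`, character(1), 1L)
  ti <- 0L
  tv <- 0L
  for (k in seq_along(alleles)) {
    al <- alleles[[k]]
    if (!length(al) %in% 2:3) stop("site must have 2 or 3 alleles, got: ",
                                   sites$alleles[k])
    if (length(al) == 2L) {
      if (is_transition(al[1], al[2])) ti <- ti + 1L else tv <- tv + 1L
    } else {
      # decompose around the pivot minimising transversions
      ntv <- vapply(al, function(p) {
        sum(!vapply(setdiff(al, p), is_transition, logical(1), a = p))
      }, numeric(1))
      best <- al[ntv == min(ntv)]
      pivot <- if (ref[k] %in% best) ref[k] else best[1]
      for (o in setdiff(al, pivot)) {
        if (is_transition(pivot, o)) ti <- ti + 1L else tv <- tv + 1L
      }
    }
  }
  c(transitions = ti, transversions = tv)
}

AA_CATEGORY <- c(
  A = "nonpolar", V = "nonpolar", L = "nonpolar", I = "nonpolar",
  P = "nonpolar", F = "nonpolar", M = "nonpolar", W = "nonpolar",
  G = "nonpolar",
  S = "polar", T = "polar", C = "polar", Y = "polar", N = "polar",
  Q = "polar",
  K = "positive", R = "positive", H = "positive",
  D = "negative", E = "negative")

AA_THREE_TO_ONE <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V")

as_one_letter <- function(res) {
  res <- as.character(res)
  out <- ifelse(nchar(res) == 1L, toupper(res),
                AA_THREE_TO_ONE[paste0(toupper(substr(res, 1, 1)),
                                       tolower(substr(res, 2, 3)))])
  if (anyNA(out) || !all(out %in% names(AA_CATEGORY))) {
    stop("unknown residue: ", paste(res[is.na(out) |
      !out %in% names(AA_CATEGORY)], collapse = ", "))
  }
  unname(out)
}

#' Physicochemical class of an amino-acid change
#'
#' Residues are grouped as nonpolar (A V L I P F M W G), polar uncharged
#' (S T C Y N Q), positively charged (K R H) and negatively charged (D E).
#' A change within a group is conservative; across groups, non-conservative.
#'
#' @param res_a,res_b residues, one-letter (`"N"`) or three-letter (`"Asn"`).
#' @return `"identical"`, `"conservative"` or `"non-conservative"`.
#' @export
aa_change_class <- function(res_a, res_b) {
  a <- as_one_letter(res_a)
  b <- as_one_letter(res_b)
  ifelse(a == b, "identical",
         ifelse(AA_CATEGORY[a] == AA_CATEGORY[b],
                "conservative", "non-conservative"))
}

#' Extract the SNP table of a set of aligned haplotypes
#'
#' Scans an alignment of gap-free, equal-length haplotype sequences of one
#' locus and returns every polymorphic column with its 1-based position and
#' allele set, together with the per-haplotype allele vectors. Monomorphic
#' loci yield an empty site list.
#'
#' @param haps named character vector of haplotype sequences (equal length,
#'   A/C/G/T only).
#' @return list with `sites` (data frame: `position`, `alleles` as
#'   slash-separated string, `ref` = allele of the first haplotype) and
#'   `allele_matrix` (haplotypes x sites character matrix).
#' @export
haplotypes_to_snp_table <- function(haps) {
  haps <- toupper(as.character(haps))
  if (length(unique(nchar(haps))) != 1L) {
    stop("haplotype sequences have unequal lengths; alignment required")
  }
  if (any(grepl("[^ACGT]", haps))) stop("haplotypes must be gap-free A/C/G/T")
  m <- do.call(rbind, strsplit(haps, ""))
  poly <- which(apply(m, 2, function(col) length(unique(col)) > 1L))
  sites <- data.frame(
    position = as.integer(poly),
    alleles = vapply(poly, function(j) {
      paste(sort(unique(m[, j])), collapse = "/")
    }, character(1)),
    ref = if (length(poly)) m[1, poly] else character(0),
    stringsAsFactors = FALSE)
  list(sites = sites,
       allele_matrix = m[, poly, drop = FALSE])
}
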