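#' Published TLR SNP panel of the bottlenecked robin founder population
#'
#' The per-locus SNP survey of the motivating study system: nine TLR
#' amplicons genotyped across the 12 genetic founders of a reintroduced
#' New Zealand robin island population, with one row per SNP site
#' (position, alleles and the residues segregating at the site).
#' `TLR7` rows are the three Mendelian-segregating sites of that locus
#' (its eight non-Mendelian universal-heterozygote sites are inter-paralog
#' differences and are excluded, as in the survey).
#'
#' @return data frame with columns `locus`, `position`, `alleles`
#'   (slash-separated, reference allele first) and `residues`
#'   (slash-separated three-letter codes; a single residue marks a
#'   synonymous site).
#' @export
robin_snp_panel <- function() {
  tab <- c(
    "TLR1LA,172,C/T,Arg/Trp",
    "TLR1LA,291,G/A,Ser",
    "TLR1LB,154,C/T,Leu",
    "TLR1LB,185,C/T,Ala/Val",
    "TLR1LB,369,G/A,Val",
    "TLR2A,891,C/T,Gly",
    "TLR2B,108,G/A,Glu",
    "TLR2B,324,C/T,Asn",
    "TLR2B,632,C/T,Thr/Met",
    "TLR2B,645,C/T,Asn",
    "TLR2B,846,G/A,Arg",
    "TLR4,94,A/C/T,Ile/Leu/Phe",
    "TLR4,142,C/T,Leu/Phe",
    "TLR4,220,A/T,Thr/Ser",
    "TLR4,520,G/A,Asp/Asn",
    "TLR5,371,G/A,Arg/Gln",
    "TLR5,817,G/T,Asp/Tyr",
    "TLR7,162,G/A,Asn/Asp",
    "TLR7,672,C/T,Pro/Ser",
    "TLR7,723,G/A,Ser/Gly",
    "TLR15,997,G/A,Asp/Asn",
    "TLR21,118,G/A,Asn/Asp",
    "TLR21,169,C/T,Arg/Trp",
    "TLR21,300,G/A,Pro")
  df <- utils::read.csv(text = paste(tab, collapse = "\n"), header = FALSE,
                        stringsAsFactors = FALSE)
  names(df) <- c("locus", "position", "alleles", "residues")
  df$ref <- vapply(strsplit(df$alleles, "/"), `[`, character(1), 1L)
  df
}

#' Per-locus summary of the published TLR survey
#'
#' Fragment lengths, observed haplotype counts and amino-acid variant
#' counts of the nine genotyped amplicons (the `TLR7` length is that of
#' the cloned product; its direct-sequence length, used for the paralog
#' scan fraction, was 947 bp).
#'
#' @return data frame with columns `locus`, `length_bp`, `n_haplotypes`,
#'   `n_aa_variants`.
#' @export
robin_locus_table <- function() {
  data.frame(
    locus = c("TLR1LA", "TLR1LB", "TLR2A", "TLR2B", "TLR3", "TLR4",
              "TLR5", "TLR7", "TLR15", "TLR21"),
    length_bp = c(1166L, 971L, 1034L, 1021L, 1087L, 649L, 1229L, 1010L,
                  1279L, 618L),
    n_haplotypes = c(2L, 2L, 2L, 3L, 1L, 5L, 3L, 2L, 2L, 4L),
    n_aa_variants = c(2L, 2L, 2L, 2L, 1L, 5L, 3L, NA_integer_, 2L, 3L),
    stringsAsFactors = FALSE)
}

#' Synthetic reference amplicons realising the published SNP panel
#'
#' The survey prints, for every SNP, its position, alleles and the
#' residues they encode, but not the surrounding sequence. This
#' constructor builds one synthetic reference amplicon per locus whose
#' codon at each SNP position encodes exactly the printed residues under
#' the printed alleles, so codon-level classification of the panel can be
#' exercised end to end. For each locus the reading-frame offset is the
#' smallest one under which every printed residue pair is realisable
#' (offset 1 for `TLR7`, 0 elsewhere); filler codons are alanine (`GCA`).
#' These references are synthetic stand-ins, not the deposited sequences.
#'
#' @return named list of [new_locus()] objects for the loci carrying SNPs.
#' @export
robin_reference_loci <- function() {
  panel <- robin_snp_panel()
  lens <- robin_locus_table()
  out <- list()
  for (loc in unique(panel$locus)) {
    snps <- panel[panel$locus == loc, , drop = FALSE]
    L <- lens$length_bp[lens$locus == loc]
    built <- NULL
    for (f in 0:2) {
      built <- try(build_reference(L, f, snps), silent = TRUE)
      if (!inherits(built, "try-error")) break
    }
    if (inherits(built, "try-error")) {
      stop("no codon context realises the printed residues for ", loc)
    }
    out[[loc]] <- new_locus(loc, built, frame_offset = f)
  }
  out
}

# build a reference of length L at frame offset f whose codons realise the
# printed residues of every SNP row; errors if any SNP is unrealisable
build_reference <- function(L, f, snps) {
  # alanine filler aligned to the frame: every complete codon reads GCA
  fill <- c("G", "C", "A")
  s <- fill[(seq_len(L) - 1L + f) %% 3L + 1L]
  used_codons <- integer(0)
  for (r in seq_len(nrow(snps))) {
    pos <- snps$position[r]
    alleles <- strsplit(snps$alleles[r], "/")[[1]]
    residues <- as_one_letter(strsplit(snps$residues[r], "/")[[1]])
    shifted <- pos - 1L + f
    codon_no <- shifted %/% 3L
    within <- shifted %% 3L + 1L
    start <- codon_no * 3L + 1L - f
    if (start < 1L || start + 2L > L) stop("SNP in incomplete codon")
    if (codon_no %in% used_codons) stop("two SNPs share a codon")
    used_codons <- c(used_codons, codon_no)
    ctx <- solve_codon_context(within, alleles, residues)
    if (is.null(ctx)) stop("unrealisable residue set at position ", pos)
    s[start:(start + 2L)] <- ctx
  }
  paste(s, collapse = "")
}

# find bases for the two non-SNP codon positions such that the SNP alleles
# encode exactly the printed residue set (all alleles -> the single residue
# for synonymous sites); first solution in a fixed scan order wins
solve_codon_context <- function(within, alleles, residues) {
  others <- setdiff(1:3, within)
  for (b1 in DNA_BASES) {
    for (b2 in DNA_BASES) {
      cod <- character(3)
      cod[others] <- c(b1, b2)
      res <- vapply(alleles, function(al) {
        cod[within] <- al
        translate_codon(paste(cod, collapse = ""))
      }, character(1))
      if (any(res == "*")) next
      ok <- if (length(residues) == 1L) {
        all(res == residues)
      } else {
        length(unique(res)) == length(res) && setequal(res, residues)
      }
      if (ok) {
        cod[within] <- alleles[1]   # reference carries the first allele
        return(cod)
      }
    }
  }
  NULL
}

#' Founder genotype configurations of the published diversity table
#'
#' The survey prints, per polymorphic locus, the number of variants and
#' the observed/expected heterozygosity of the 12 founders. Those printed
#' values determine the underlying integer genotype configurations
#' (e.g. TLR1LA: 4 + 5 + 3 individuals with allele counts 11:13), which
#' this constructor materialises as deterministic variant-pair matrices.
#' `TLR2B` is the one locus whose printed gene diversity (0.591) is not
#' attainable from two variants at n = 12; its configuration is built at
#' the three-SNP-haplotype level (counts 12:10:2), the closest consistent
#' reconstruction.
#'
#' @return named list of 12 x 2 character matrices of variant labels
#'   (`V1`, `V2`, ...), rownames `F01`..`F12`.
#' @export
robin_founder_genotypes <- function() {
  mk <- function(...) {
    rows <- list(...)
    g <- do.call(rbind, lapply(rows, function(r) {
      matrix(rep(r$g, r$n), ncol = 2, byrow = TRUE)
    }))
    rownames(g) <- sprintf("F%02d", seq_len(nrow(g)))
    g
  }
  gt <- function(n, a, b) list(n = n, g = c(a, b))
  list(
    TLR1LA = mk(gt(4, "V1", "V1"), gt(5, "V1", "V2"), gt(3, "V2", "V2")),
    TLR1LB = mk(gt(5, "V1", "V1"), gt(3, "V1", "V2"), gt(4, "V2", "V2")),
    TLR2B  = mk(gt(3, "V1", "V1"), gt(4, "V1", "V2"), gt(2, "V1", "V3"),
                gt(3, "V2", "V2")),
    TLR4   = mk(gt(3, "V1", "V1"), gt(2, "V1", "V2"), gt(2, "V1", "V3"),
                gt(1, "V1", "V4"), gt(1, "V2", "V2"), gt(1, "V2", "V3"),
                gt(1, "V3", "V4"), gt(1, "V4", "V5")),
    TLR5   = mk(gt(5, "V1", "V1"), gt(5, "V1", "V2"), gt(1, "V1", "V3"),
                gt(1, "V2", "V2")),
    TLR15  = mk(gt(11, "V1", "V1"), gt(1, "V1", "V2")),
    TLR21  = mk(gt(6, "V1", "V1"), gt(5, "V1", "V2"), gt(1, "V1", "V3")))
}
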