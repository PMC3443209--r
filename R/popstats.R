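#' Observed heterozygosity
#'
#' Fraction of individuals whose two variants (alleles, haplotypes or
#' amino-acid variants) differ.
#'
#' @param genotypes two-column matrix or data frame: one row per
#'   individual, the two variant labels carried.
#' @return proportion in \[0, 1\].
#' @export
observed_heterozygosity <- function(genotypes) {
  g <- as.matrix(genotypes)
  if (!nrow(g)) stop("at least one individual is required")
  stopifnot(ncol(g) == 2L)
  mean(g[, 1] != g[, 2])
}

#' Nei's unbiased gene diversity
#'
#' \deqn{H_E = \frac{2n}{2n-1}\left(1 - \sum_i p_i^2\right)}
#' with allele frequencies \eqn{p_i} estimated from `2n` gene copies. The
#' small-sample correction matters at founder-cohort sizes: at n = 12
#' diploids it inflates the plug-in estimate by 24/23.
#'
#' @param allele_counts integer vector of allele (variant) copy counts.
#' @return unbiased expected heterozygosity in \[0, 1\].
#' @export
unbiased_gene_diversity <- function(allele_counts) {
  cnt <- as.numeric(allele_counts)
  if (any(cnt < 0)) stop("allele counts must be >= 0")
  tot <- sum(cnt)
  if (tot < 2) stop("need at least 2 gene copies")
  p <- cnt / tot
  tot / (tot - 1) * (1 - sum(p^2))
}

#' Nucleotide diversity with standard error
#'
#' Mean pairwise nucleotide differences per site among the sampled gene
#' copies, with the small-sample correction:
#' \deqn{\pi = \frac{2n}{2n-1} \sum_{i<j} 2 p_i p_j d_{ij} / L}
#' where \eqn{d_{ij}} is the number of differences between haplotypes i and
#' j and \eqn{L} the sequence length. The standard error is the square root
#' of Nei's (1987, eq. 10.7) / Tajima's stochastic variance
#' \deqn{V(\pi) = \frac{m+1}{3(m-1)L}\pi + \frac{2(m^2+m+3)}{9m(m-1)}\pi^2}
#' with \eqn{m = 2n} sequences.
#'
#' @param haplotypes character vector of equal-length haplotype sequences.
#' @param counts integer vector: gene copies sampled per haplotype
#'   (sums to 2n).
#' @param scale multiply `pi` and `se` by this factor for reporting
#'   (default 1; use `1e4` to match per-10-kb conventions).
#' @return list with `pi`, `se`, `n_copies` and `length_bp`.
#' @export
nucleotide_diversity <- function(haplotypes, counts, scale = 1) {
  haplotypes <- toupper(as.character(haplotypes))
  if (length(unique(nchar(haplotypes))) != 1L) {
    stop("haplotypes must be aligned to equal length")
  }
  counts <- as.numeric(counts)
  stopifnot(length(counts) == length(haplotypes), all(counts >= 0))
  L <- nchar(haplotypes[1])
  m <- sum(counts)                       # gene copies (2n)
  if (m < 2) stop("need at least 2 gene copies")
  p <- counts / m
  k <- length(haplotypes)
  pi <- 0
  if (k > 1) {
    chars <- do.call(rbind, strsplit(haplotypes, ""))
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        d <- sum(chars[i, ] != chars[j, ])
        pi <- pi + 2 * p[i] * p[j] * d
      }
    }
  }
  pi <- m / (m - 1) * pi / L
  v <- (m + 1) / (3 * (m - 1) * L) * pi +
    2 * (m^2 + m + 3) / (9 * m * (m - 1)) * pi^2
  list(pi = pi * scale, se = sqrt(v) * scale, n_copies = m, length_bp = L)
}

#' Multilocus heterozygosity per individual
#'
#' @param is_het logical matrix: rows = individuals, columns = loci; `TRUE`
#'   where the individual is heterozygous.
#' @return list with `per_individual` (named counts), `mean` and `sd`
#'   (n - 1 denominator).
#' @export
multilocus_heterozygosity <- function(is_het) {
  m <- as.matrix(is_het)
  counts <- rowSums(m)
  list(per_individual = counts,
       mean = mean(counts),
       sd = if (length(counts) > 1) stats::sd(counts) else 0)
}

#' Per-locus diversity summary
#'
#' Assembles allele counts, observed heterozygosity, Nei's unbiased gene
#' diversity, the exact Hardy-Weinberg p-value and (when haplotype
#' sequences are supplied) nucleotide diversity into one record. For a
#' monomorphic locus Ho = He = 0 and the Hardy-Weinberg p-value is
#' undefined (reported `NA`, rendered `-`).
#'
#' @param locus locus name.
#' @param genotypes two-column matrix of variant labels, one row per
#'   individual (amino-acid variants for protein-level summaries,
#'   haplotype labels for sequence-level ones).
#' @param haplotype_seqs optional named character vector of haplotype
#'   sequences (names = variant labels) for nucleotide diversity.
#' @param pi_scale scaling for reported `pi` and `se` (default 1e4).
#' @return object of class `locus_diversity`.
#' @export
locus_summary <- function(locus, genotypes, haplotype_seqs = NULL,
                          pi_scale = 1e4) {
  g <- as.matrix(genotypes)
  stopifnot(ncol(g) == 2L)
  n <- nrow(g)
  variants <- sort(unique(as.vector(g)))
  counts <- stats::setNames(
    vapply(variants, function(v) sum(g == v), numeric(1)), variants)
  mono <- length(variants) < 2L
  ho <- observed_heterozygosity(g)
  he <- if (mono) 0 else unbiased_gene_diversity(counts)
  hwe_p <- if (mono) NA_real_ else {
    k <- length(variants)
    tab <- matrix(0L, k, k, dimnames = list(variants, variants))
    for (r in seq_len(n)) {
      a <- sort(g[r, ])
      tab[a[2], a[1]] <- tab[a[2], a[1]] + 1L
    }
    hwe_exact_test(tab)$p.value
  }
  pi <- se <- NA_real_
  if (!is.null(haplotype_seqs)) {
    if (!all(variants %in% names(haplotype_seqs))) {
      stop("haplotype_seqs must cover every variant label")
    }
    nd <- nucleotide_diversity(haplotype_seqs[variants], counts,
                               scale = pi_scale)
    pi <- nd$pi; se <- nd$se
  }
  structure(list(locus = as.character(locus),
                 n_individuals = n,
                 n_variants = length(variants),
                 allele_counts = counts,
                 Ho = ho, He = he, hwe_p = hwe_p,
                 pi = pi, pi_se = se, pi_scale = pi_scale),
            class = "locus_diversity")
}

#' @export
print.locus_diversity <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "-" else sprintf("%.3f", round3(v))
  cat(sprintf("<locus_diversity> %s: n = %d, %d variant(s) (%s)\n",
              x$locus, x$n_individuals, x$n_variants,
              paste(x$allele_counts, collapse = ":")))
  cat(sprintf("  Ho = %s  He = %s  HWE p = %s\n",
              fmt(x$Ho), fmt(x$He), fmt(x$hwe_p)))
  if (!is.na(x$pi)) {
    cat(sprintf("  pi = %.2f (+/- %.2f) x 1/%g per site\n",
                x$pi, x$pi_se, x$pi_scale))
  }
  invisible(x)
}

# round half-up to `digits` decimals (table-style rounding, not banker's)
round3 <- function(x, digits = 3) {
  floor(abs(x) * 10^digits + 0.5) / 10^digits * sign(x)
}
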