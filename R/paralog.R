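#' Scan a genotype matrix for universally heterozygous sites
#'
#' Coamplification of diverged gene duplicates makes every individual
#' appear heterozygous at each fixed inter-copy difference. The scan
#' returns the sites whose call-level heterozygosity reaches `threshold`
#' (default 1, i.e. 100\% of individuals), and separately the sites with
#' intermediate heterozygosity (het in some but not all individuals),
#' which under coamplification point at polymorphism within one of the
#' copies. Chromatogram peak heights are not available from genotype
#' calls, so the scan keys on call-level heterozygosity only.
#'
#' @param geno character matrix of IUPAC consensus codes (rows =
#'   individuals, columns = sites; column names taken as positions when
#'   present, otherwise column indices).
#' @param threshold fraction of individuals that must be heterozygous for a
#'   site to be flagged constant-het (default 1).
#' @return list with `constant_het` (integer positions), `variable_het`
#'   (positions het in >0 but < threshold of individuals), `het_fraction`
#'   (per-site fraction) and `fraction_of_length` = length(constant_het) /
#'   ncol(geno).
#' @export
constant_het_scan <- function(geno, threshold = 1) {
  stopifnot(is.matrix(geno), nrow(geno) >= 2L)
  het <- apply(geno, 2, function(col) mean(is_het_code(col)))
  pos <- if (!is.null(colnames(geno))) as.integer(colnames(geno)) else
    seq_len(ncol(geno))
  list(constant_het = pos[het >= threshold],
       variable_het = pos[het > 0 & het < threshold],
       het_fraction = stats::setNames(het, pos),
       fraction_of_length = sum(het >= threshold) / ncol(geno))
}

#' Mendelian null probability of all-heterozygous trios
#'
#' At a diallelic site, two heterozygous parents produce a heterozygous
#' offspring with probability 1/2. Observing heterozygous offspring in all
#' `n_trios` independent trios therefore has probability \eqn{(1/2)^n}
#' under single-locus Mendelian inheritance; a tiny value is evidence that
#' the "site" is a fixed difference between coamplifying duplicates.
#'
#' @param n_trios integer >= 0.
#' @return \eqn{(1/2)^{n}}.
#' @export
all_het_trio_probability <- function(n_trios) {
  n_trios <- as.integer(n_trios)
  if (any(n_trios < 0)) stop("n_trios must be >= 0")
  0.5^n_trios
}

#' Probability that n clones cover every haplotype at least once
#'
#' Exact inclusion-exclusion over the haplotype set: with haplotype
#' frequencies \eqn{f_i}, \eqn{P = \sum_S (-1)^{|S|} (1 - \sum_{i \in S}
#' f_i)^n}. For four equifrequent haplotypes (two heterozygous gene
#' copies), 24 clones give 99.6\% coverage.
#'
#' @param n_clones number of clones sequenced (>= 0).
#' @param haplotype_freqs positive frequencies summing to 1.
#' @return coverage probability in \[0, 1\].
#' @export
clone_coverage_probability <- function(n_clones, haplotype_freqs) {
  f <- as.numeric(haplotype_freqs)
  if (any(f <= 0)) stop("haplotype frequencies must be > 0")
  if (abs(sum(f) - 1) > 1e-9) stop("haplotype frequencies must sum to 1")
  n_clones <- as.integer(n_clones)
  if (n_clones < 0) stop("n_clones must be >= 0")
  k <- length(f)
  p <- 0
  for (mask in 0:(2^k - 1)) {
    s <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    p <- p + (-1)^length(s) * (1 - sum(f[s]))^n_clones
  }
  min(max(p, 0), 1)
}

#' Smallest clone count reaching a target coverage probability
#'
#' Design targets are conventionally quoted at 0.1\% precision (e.g.
#' "99.6\%"), so a coverage within `tol` below the nominal target is
#' treated as attaining it; with the default `tol = 5e-4`, 24 clones
#' attain 99.6\% for four equifrequent haplotypes (exact coverage
#' 0.99599). Set `tol = 0` for a strict bound.
#'
#' @param haplotype_freqs positive frequencies summing to 1.
#' @param target required coverage probability, 0 < target < 1.
#' @param tol slack on the target (default 5e-4, half the last quoted
#'   digit of a 3-decimal target).
#' @return smallest n with [clone_coverage_probability()] >= target - tol.
#' @export
min_clones_for <- function(haplotype_freqs, target, tol = 5e-4) {
  if (!is.numeric(target) || target <= 0 || target >= 1) {
    stop("target must lie strictly between 0 and 1")
  }
  n <- length(haplotype_freqs)  # need at least one clone per haplotype
  while (clone_coverage_probability(n, haplotype_freqs) < target - tol) {
    n <- n + 1L
    if (n > 1e6) stop("target coverage unreachable")
  }
  n
}

#' Clone-read experiment for one individual x locus
#'
#' @param individual,locus labels.
#' @param reads data frame with columns `sequence`, `replicate` (PCR
#'   replicate label) and optionally `count` (default 1).
#' @return object of class `clone_experiment`.
#' @export
clone_experiment <- function(individual, locus, reads) {
  stopifnot(all(c("sequence", "replicate") %in% names(reads)))
  if (!"count" %in% names(reads)) reads$count <- 1L
  if (any(reads$count < 1)) stop("clone counts must be >= 1")
  if (length(unique(nchar(reads$sequence))) > 1L) {
    stop("clone sequences must be of equal length")
  }
  structure(list(individual = as.character(individual),
                 locus = as.character(locus),
                 reads = reads),
            class = "clone_experiment")
}

#' Haplotypes supported by independent PCR replicates
#'
#' PCR chimeras and polymerase errors arise independently in each
#' amplification, so a true haplotype should recur across replicates while
#' artefacts are overwhelmingly replicate-private. Distinct clone sequences
#' seen in two or more independent PCR replicates are reported as
#' supported; the rest are chimera/error candidates.
#'
#' @param exp a [clone_experiment()].
#' @return list with `supported` and `candidates` (character vectors of
#'   sequences), `n_replicates`, and `copy_number_lower_bound` from the
#'   supported count.
#' @export
replicate_supported_haplotypes <- function(exp) {
  stopifnot(inherits(exp, "clone_experiment"))
  reps_per_seq <- tapply(exp$reads$replicate, exp$reads$sequence,
                         function(r) length(unique(r)))
  supported <- names(reps_per_seq)[reps_per_seq >= 2L]
  candidates <- names(reps_per_seq)[reps_per_seq < 2L]
  list(supported = supported,
       candidates = candidates,
       n_replicates = length(unique(exp$reads$replicate)),
       copy_number_lower_bound = copy_number_bound(length(supported)))
}

#' Minimum diploid gene-copy number consistent with n haplotypes
#'
#' Each diploid gene copy contributes at most two haplotypes to one
#' individual, so n distinct haplotypes require at least `ceiling(n/2)`
#' coamplifying copies (five haplotypes imply three copies).
#'
#' @param n_supported_haplotypes integer >= 0.
#' @return integer lower bound on copy number.
#' @export
copy_number_bound <- function(n_supported_haplotypes) {
  n <- as.integer(n_supported_haplotypes)
  if (any(n < 0)) stop("haplotype count must be >= 0")
  as.integer(ceiling(n / 2))
}

#' Assemble a paralog coamplification report
#'
#' Combines the universal-heterozygosity scan of a genotype matrix, the
#' all-heterozygous-trio Mendelian null probability, and (optionally) the
#' replicate-support analysis of a clone experiment into one report.
#'
#' @param geno IUPAC genotype matrix (see [constant_het_scan()]).
#' @param n_all_het_trios number of parent/offspring trios in which all
#'   three members are heterozygous at the scanned sites.
#' @param clone_exp optional [clone_experiment()].
#' @param threshold passed to [constant_het_scan()].
#' @return object of class `paralog_report`.
#' @export
paralog_report <- function(geno, n_all_het_trios = 0L, clone_exp = NULL,
                           threshold = 1) {
  scan <- constant_het_scan(geno, threshold = threshold)
  rep <- list(
    constant_het_sites = scan$constant_het,
    variable_het_sites = scan$variable_het,
    fraction_of_length = scan$fraction_of_length,
    n_all_het_trios = as.integer(n_all_het_trios),
    mendel_null_prob = all_het_trio_probability(n_all_het_trios),
    supported_haplotypes = character(0),
    chimera_candidates = character(0),
    copy_number_lower_bound = NA_integer_)
  if (!is.null(clone_exp)) {
    supp <- replicate_supported_haplotypes(clone_exp)
    rep$supported_haplotypes <- supp$supported
    rep$chimera_candidates <- supp$candidates
    rep$copy_number_lower_bound <- supp$copy_number_lower_bound
  }
  structure(rep, class = "paralog_report")
}

#' @export
print.paralog_report <- function(x, ...) {
  cat("<paralog_report>\n")
  cat(sprintf("  constant-het sites: %d (%.1f%% of scanned length)\n",
              length(x$constant_het_sites), 100 * x$fraction_of_length))
  if (length(x$constant_het_sites)) {
    cat("   ", paste(x$constant_het_sites, collapse = ", "), "\n")
  }
  cat(sprintf("  variable-het sites: %d\n", length(x$variable_het_sites)))
  cat(sprintf("  all-het trios: %d (Mendelian null p = %.3g)\n",
              x$n_all_het_trios, x$mendel_null_prob))
  if (length(x$supported_haplotypes)) {
    cat(sprintf("  replicate-supported haplotypes: %d -> >= %d gene copies\n",
                length(x$supported_haplotypes), x$copy_number_lower_bound))
    cat(sprintf("  chimera/error candidates: %d\n",
                length(x$chimera_candidates)))
  }
  invisible(x)
}
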