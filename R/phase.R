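#' Pedigree-assisted haplotype phasing of one locus
#'
#' Resolves each individual's unordered genotype at the SNP sites of a
#' locus into an (unordered) pair of haplotypes. Phase is first propagated
#' through the pedigree: homozygous sites anchor phase, and every sampled
#' parent-offspring link forces co-transmission of one allele per site.
#' Individuals whose candidate set is reduced to a single pair are flagged
#' `certain`. Residual ambiguity is resolved by expectation-maximisation
#' over locus haplotype frequencies (uniform initialisation, convergence
#' when the largest frequency change is below `tol`, at most `max_iter`
#' iterations, ties broken lexicographically); such calls are flagged
#' `uncertain`. A pedigree-genotype contradiction is flagged
#' `inconsistent` for the individual, never auto-corrected.
#'
#' @param geno character matrix of IUPAC consensus codes: rows are
#'   individuals (rownames = ids), columns are SNP sites of the locus.
#' @param ped a [new_pedigree()] object covering (at least) the genotyped
#'   individuals.
#' @param tol,max_iter EM convergence controls.
#' @return data frame with columns `id`, `hap_a`, `hap_b` (allele strings
#'   over the locus sites, `hap_a <= hap_b`), `certainty` (`certain`,
#'   `uncertain` or `inconsistent`); the EM haplotype frequency estimates
#'   are attached as attribute `"freqs"`.
#' @export
phase_by_pedigree <- function(geno, ped, tol = 1e-6, max_iter = 500L) {
  stopifnot(is.matrix(geno), !is.null(rownames(geno)))
  ids <- rownames(geno)
  n_sites <- ncol(geno)

  cand <- lapply(ids, function(i) candidate_pairs(geno[i, , drop = TRUE]))
  names(cand) <- ids

  # parent-offspring links where both ends are genotyped (or child is)
  pd <- as.data.frame(ped)
  pd <- pd[pd$id %in% ids, , drop = FALSE]

  pair_has <- function(pp, hap) hap %in% pp
  parent_can_give <- function(parent, hap) {
    # TRUE if `parent` (id or NA) could transmit haplotype `hap`; an
    # individual already proven inconsistent is treated as uninformative
    # so one contradiction cannot cascade through the pedigree
    if (is.na(parent) || !parent %in% ids) return(TRUE)
    if (!length(cand[[parent]])) return(TRUE)
    any(vapply(cand[[parent]], pair_has, logical(1), hap = hap))
  }

  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (r in seq_len(nrow(pd))) {
      child <- pd$id[r]; dam <- pd$dam[r]; sire <- pd$sire[r]
      if (is.na(dam) && is.na(sire)) next
      if (!length(cand[[child]])) next
      keep <- vapply(cand[[child]], function(cp) {
        (parent_can_give(dam, cp[1]) && parent_can_give(sire, cp[2])) ||
          (parent_can_give(dam, cp[2]) && parent_can_give(sire, cp[1]))
      }, logical(1))
      if (!all(keep)) { cand[[child]] <- cand[[child]][keep]; changed <- TRUE }
      # prune each sampled parent against this child (skip if the child
      # itself is inconsistent)
      if (!length(cand[[child]])) next
      for (side in c("dam", "sire")) {
        p <- pd[[side]][r]
        if (is.na(p) || !p %in% ids) next
        co <- pd[[if (side == "dam") "sire" else "dam"]][r]
        keep <- vapply(cand[[p]], function(pp) {
          any(vapply(cand[[child]], function(cp) {
            (pair_has(pp, cp[1]) && parent_can_give(co, cp[2])) ||
              (pair_has(pp, cp[2]) && parent_can_give(co, cp[1]))
          }, logical(1)))
        }, logical(1))
        if (length(keep) && !all(keep)) {
          cand[[p]] <- cand[[p]][keep]; changed <- TRUE
        }
      }
    }
  }

  certainty <- vapply(ids, function(i) {
    k <- length(cand[[i]])
    if (k == 0L) "inconsistent" else if (k == 1L) "certain" else "uncertain"
  }, character(1))

  # EM over haplotype frequencies for the residual ambiguity
  universe <- sort(unique(unlist(lapply(cand, function(ps) {
    unlist(ps, use.names = FALSE)
  }))))
  freqs <- stats::setNames(rep(1 / length(universe), length(universe)),
                           universe)
  live <- ids[lengths(cand) > 0L]
  if (length(universe) && length(live)) {
    for (iter in seq_len(max_iter)) {
      counts <- stats::setNames(numeric(length(universe)), universe)
      for (i in live) {
        w <- vapply(cand[[i]], function(p) {
          freqs[p[1]] * freqs[p[2]] * (if (p[1] == p[2]) 1 else 2)
        }, numeric(1))
        if (sum(w) == 0) w <- rep(1, length(w))
        w <- w / sum(w)
        for (k in seq_along(cand[[i]])) {
          p <- cand[[i]][[k]]
          counts[p[1]] <- counts[p[1]] + w[k]
          counts[p[2]] <- counts[p[2]] + w[k]
        }
      }
      new_freqs <- counts / sum(counts)
      delta <- max(abs(new_freqs - freqs))
      freqs <- new_freqs
      if (delta < tol) break
    }
  }

  pick <- function(i) {
    ps <- cand[[i]]
    if (!length(ps)) return(c(NA_character_, NA_character_))
    if (length(ps) == 1L) return(ps[[1]])
    w <- vapply(ps, function(p) {
      freqs[p[1]] * freqs[p[2]] * (if (p[1] == p[2]) 1 else 2)
    }, numeric(1))
    ps[[which.max(w)]]  # candidates are lexicographic; first max wins ties
  }
  haps <- t(vapply(ids, pick, character(2)))
  out <- data.frame(id = ids, hap_a = haps[, 1], hap_b = haps[, 2],
                    certainty = unname(certainty),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "freqs") <- freqs
  out
}

# all unordered haplotype pairs consistent with one individual's IUPAC
# genotype vector, in lexicographic order (hap_a <= hap_b)
candidate_pairs <- function(codes) {
  alleles <- iupac_decode(codes)          # n_sites x 2, sorted per site
  het <- which(alleles[, 1] != alleles[, 2])
  base <- alleles[, 1]
  if (!length(het)) {
    h <- paste(base, collapse = "")
    return(list(c(h, h)))
  }
  if (length(het) > 16L) stop("too many heterozygous sites to enumerate")
  # fix the first het site's assignment to halve the enumeration
  free <- het[-1]
  k <- length(free)
  pairs <- vector("list", 2^k)
  for (mask in 0:(2^k - 1)) {
    a <- base; b <- base
    a[het[1]] <- alleles[het[1], 1]; b[het[1]] <- alleles[het[1], 2]
    if (k) {
      bits <- bitwAnd(mask, 2^(seq_len(k) - 1)) > 0
      a[free] <- alleles[cbind(free, ifelse(bits, 2L, 1L))]
      b[free] <- alleles[cbind(free, ifelse(bits, 1L, 2L))]
    }
    h <- sort(c(paste(a, collapse = ""), paste(b, collapse = "")))
    pairs[[mask + 1L]] <- h
  }
  pairs[order(vapply(pairs, paste, character(1), collapse = " "))]
}
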