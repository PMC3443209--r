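#' Classify aligned sites for a McDonald-Kreitman contrast
#'
#' Scans a codon-aligned pair of species haplotype sets and classifies each
#' site as `polymorphic` (variable within either species), `fixed`
#' (invariant within each species but different between them) or
#' `monomorphic` (shared invariant), and each change as synonymous or
#' non-synonymous by translating the codon context. A site polymorphic in
#' both species is counted once, as polymorphic. Sites with more than two
#' states are decomposed into single changes around the pivot allele that
#' minimises transversions (the same rule used for transition/transversion
#' tallies), each change classified separately.
#'
#' @param species_a,species_b character vectors of equal-length, gap-free
#'   haplotype sequences, codon-aligned across species.
#' @param frame_offset reading-frame offset of base 1 (see [new_locus()]).
#' @return data frame with one row per change: `position`, `status`
#'   (`fixed`/`polymorphic`), `class` (`synonymous`/`nonsynonymous`),
#'   `alleles`.
#' @export
classify_sites <- function(species_a, species_b, frame_offset = 0L) {
  a <- toupper(as.character(species_a))
  b <- toupper(as.character(species_b))
  lens <- unique(nchar(c(a, b)))
  if (length(lens) != 1L) stop("alignment error: unequal sequence lengths")
  ma <- do.call(rbind, strsplit(a, ""))
  mb <- do.call(rbind, strsplit(b, ""))
  # codon context from the consensus of species A's first haplotype
  ctx <- new_locus("mk_context", a[1], frame_offset)
  out <- list()
  for (pos in seq_len(lens)) {
    aa <- unique(ma[, pos])
    ab <- unique(mb[, pos])
    states <- unique(c(aa, ab))
    if (length(states) == 1L) next
    status <- if (length(aa) > 1L || length(ab) > 1L) "polymorphic" else "fixed"
    changes <- decompose_changes(states, ref = ma[1, pos])
    for (ch in changes) {
      cls <- classify_substitution(ctx, pos, ch[1], ch[2])
      out[[length(out) + 1L]] <- data.frame(
        position = pos, status = status, class = cls$class,
        alleles = paste(ch, collapse = "/"), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(position = integer(0), status = character(0),
                      class = character(0), alleles = character(0)))
  }
  do.call(rbind, out)
}

# decompose a 2- or 3-state site into pivot->other changes (minimal
# transversions, ties toward `ref`)
decompose_changes <- function(states, ref) {
  states <- sort(states)
  if (length(states) == 2L) return(list(states))
  if (length(states) != 3L) stop("sites with >3 states are not supported")
  ntv <- vapply(states, function(p) {
    sum(!vapply(setdiff(states, p), is_transition, logical(1), a = p))
  }, numeric(1))
  best <- states[ntv == min(ntv)]
  pivot <- if (ref %in% best) ref else best[1]
  lapply(setdiff(states, pivot), function(o) c(pivot, o))
}

#' Log-likelihood-ratio (G) test of a 2x2 contingency table
#'
#' \eqn{G = 2 \sum O \ln(O/E)} over the four cells, with expectations from
#' the margins and the convention \eqn{0 \ln 0 = 0}; the p-value is from
#' the chi-square distribution with 1 df. The Williams continuity
#' correction divides G by
#' \eqn{q = 1 + \frac{(n/r_1 + n/r_2 - 1)(n/c_1 + n/c_2 - 1)}{6n}}.
#'
#' @param table 2x2 numeric matrix of counts.
#' @param williams apply the Williams correction (default `FALSE`).
#' @return list with `G`, `p.value` and `williams`.
#' @export
g_test <- function(table, williams = FALSE) {
  tab <- as.matrix(table)
  stopifnot(all(dim(tab) == c(2L, 2L)))
  if (any(tab < 0)) stop("counts must be >= 0")
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (any(rs == 0) || any(cs == 0)) {
    stop("undefined test: a margin of the 2x2 table is zero")
  }
  e <- outer(rs, cs) / n
  terms <- ifelse(tab > 0, tab * log(tab / e), 0)
  g <- 2 * sum(terms)
  g <- max(g, 0)
  if (williams) {
    q <- 1 + (n / rs[1] + n / rs[2] - 1) * (n / cs[1] + n / cs[2] - 1) / (6 * n)
    g <- g / q
  }
  list(G = unname(g),
       p.value = stats::pchisq(unname(g), df = 1, lower.tail = FALSE),
       williams = williams)
}

#' McDonald-Kreitman test of two species' haplotype sets
#'
#' Builds the 2x2 table of fixed/polymorphic x synonymous/non-synonymous
#' changes from [classify_sites()] and tests the association with the G
#' test (Fisher's exact p-value is reported alongside). The neutrality
#' index \eqn{NI = (P_n/P_s)/(D_n/D_s)} is undefined when any required
#' margin is zero. An excess of non-synonymous fixed differences
#' (non-synonymous fraction among fixed sites above that among polymorphic
#' sites) is flagged as consistent with directional selection.
#'
#' @inheritParams classify_sites
#' @param locus label for the report.
#' @param williams use Williams-corrected G for the reported p-value.
#' @return object of class `mk_table` with elements `counts` (2x2: rows
#'   fixed/polymorphic, columns synonymous/nonsynonymous), `G`, `p_g`,
#'   `p_fisher`, `neutrality_index`, `prop_nonsyn_fixed`,
#'   `prop_nonsyn_poly` and `directional_flag`.
#' @export
mk_report <- function(species_a, species_b, frame_offset = 0L,
                      locus = "locus", williams = FALSE) {
  sites <- classify_sites(species_a, species_b, frame_offset)
  mk_report_from_sites(sites, locus = locus, williams = williams)
}

#' @param sites a site classification as returned by [classify_sites()]
#'   (or any data frame with `status` and `class` columns).
#' @rdname mk_report
#' @export
mk_report_from_sites <- function(sites, locus = "locus", williams = FALSE) {
  counts <- matrix(0L, 2, 2,
                   dimnames = list(c("fixed", "polymorphic"),
                                   c("synonymous", "nonsynonymous")))
  for (st in rownames(counts)) {
    for (cl in colnames(counts)) {
      counts[st, cl] <- sum(sites$status == st & sites$class == cl)
    }
  }
  rs <- rowSums(counts)
  prop_fixed <- if (rs["fixed"] > 0) counts["fixed", "nonsynonymous"] /
    rs["fixed"] else NA_real_
  prop_poly <- if (rs["polymorphic"] > 0) counts["polymorphic",
    "nonsynonymous"] / rs["polymorphic"] else NA_real_
  gt <- tryCatch(g_test(counts, williams = williams), error = function(e) NULL)
  pf <- if (!is.null(gt)) stats::fisher.test(counts)$p.value else NA_real_
  ni <- if (all(counts[, "synonymous"] > 0) &&
            counts["fixed", "nonsynonymous"] > 0) {
    (counts["polymorphic", "nonsynonymous"] /
       counts["polymorphic", "synonymous"]) /
      (counts["fixed", "nonsynonymous"] / counts["fixed", "synonymous"])
  } else NA_real_
  flag <- !is.null(gt) && !is.na(prop_fixed) && !is.na(prop_poly) &&
    prop_fixed > prop_poly && gt$p.value < 0.05
  structure(list(locus = locus,
                 counts = counts,
                 G = if (is.null(gt)) NA_real_ else gt$G,
                 p_g = if (is.null(gt)) NA_real_ else gt$p.value,
                 p_fisher = pf,
                 neutrality_index = unname(ni),
                 prop_nonsyn_fixed = unname(prop_fixed),
                 prop_nonsyn_poly = unname(prop_poly),
                 directional_flag = flag,
                 williams = williams),
            class = "mk_table")
}

#' @export
print.mk_table <- function(x, ...) {
  cat(sprintf("<mk_table> %s\n", x$locus))
  print(x$counts)
  fmt <- function(v) if (is.na(v)) "-" else sprintf("%.3g", v)
  cat(sprintf("  G = %s, p(G) = %s, p(Fisher) = %s, NI = %s\n",
              fmt(x$G), fmt(x$p_g), fmt(x$p_fisher),
              fmt(x$neutrality_index)))
  cat(sprintf("  nonsyn fraction: fixed %s vs polymorphic %s%s\n",
              fmt(x$prop_nonsyn_fixed), fmt(x$prop_nonsyn_poly),
              if (isTRUE(x$directional_flag))
                "  [excess nonsyn fixed: consistent with directional selection]"
              else ""))
  invisible(x)
}
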