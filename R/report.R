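#' Read and write FASTA sequence sets
#'
#' Thin wrappers over Biostrings keeping the package's canonical types
#' (named character vectors, 70-column FASTA).
#'
#' @param path file path.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @param seqs named character vector of sequences.
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path, width = 70L)
  invisible(path)
}

#' Read / write clone-read FASTA
#'
#' Clone reads use the header grammar `>individual|locus|replicate|cloneN`.
#'
#' @param path file path.
#' @return a list of [clone_experiment()] objects, one per
#'   individual x locus.
#' @export
read_clone_fasta <- function(path) {
  seqs <- read_fasta(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  bad <- lengths(parts) != 4L
  if (any(bad)) {
    stop("malformed clone header (expected individual|locus|replicate|cloneN): ",
         names(seqs)[bad][1])
  }
  meta <- data.frame(individual = vapply(parts, `[`, character(1), 1L),
                     locus = vapply(parts, `[`, character(1), 2L),
                     replicate = vapply(parts, `[`, character(1), 3L),
                     sequence = unname(seqs), stringsAsFactors = FALSE)
  out <- list()
  for (key in unique(paste(meta$individual, meta$locus, sep = "|"))) {
    sub <- meta[paste(meta$individual, meta$locus, sep = "|") == key, ]
    out[[key]] <- clone_experiment(sub$individual[1], sub$locus[1],
                                   sub[c("sequence", "replicate")])
  }
  out
}

#' @param exp a [clone_experiment()].
#' @rdname read_clone_fasta
#' @export
write_clone_fasta <- function(exp, path) {
  stopifnot(inherits(exp, "clone_experiment"))
  reads <- exp$reads
  seqs <- rep(reads$sequence, reads$count)
  reps <- rep(reads$replicate, reads$count)
  names(seqs) <- sprintf("%s|%s|%s|clone%d", exp$individual, exp$locus,
                         reps, seq_along(seqs))
  write_fasta(seqs, path)
}

#' Read / write an IUPAC genotype matrix TSV
#'
#' Rows are individuals (first column `id`), remaining columns are sites
#' named `locus:position`; cells are IUPAC consensus codes. Lines starting
#' `#` are comments.
#'
#' @param path file path.
#' @return character matrix with rownames = individual ids.
#' @export
read_genotype_matrix <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character")
  if (names(df)[1] != "id") stop("first column of a genotype TSV must be 'id'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  m
}

#' @param geno character matrix of IUPAC codes (rownames = ids).
#' @rdname read_genotype_matrix
#' @export
write_genotype_matrix <- function(geno, path) {
  df <- data.frame(id = rownames(geno), geno, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-locus diversity report
#'
#' Runs [locus_summary()] for each locus and assembles the survey-style
#' report: variants, observed and unbiased expected heterozygosity, exact
#' Hardy-Weinberg p-value, plus a mean row. Undefined statistics
#' (monomorphic loci) render as `-` in the written TSV.
#'
#' @param genotypes named list of two-column variant matrices, one per
#'   locus (see [locus_summary()]).
#' @param haplotype_seqs optional named list (per locus) of named
#'   haplotype sequence vectors for nucleotide diversity.
#' @param pi_scale scaling for pi (default 1e4).
#' @return data frame of class `diversity_report` with one row per locus
#'   and a final `Mean` row; unrounded summaries are attached as
#'   attribute `"summaries"`.
#' @export
run_diversity <- function(genotypes, haplotype_seqs = NULL, pi_scale = 1e4) {
  stopifnot(is.list(genotypes), length(names(genotypes)) == length(genotypes))
  sums <- lapply(names(genotypes), function(loc) {
    locus_summary(loc, genotypes[[loc]],
                  haplotype_seqs = haplotype_seqs[[loc]],
                  pi_scale = pi_scale)
  })
  names(sums) <- names(genotypes)
  df <- data.frame(
    locus = names(sums),
    n = vapply(sums, function(s) s$n_individuals, numeric(1)),
    variants = vapply(sums, function(s) s$n_variants, numeric(1)),
    Ho = round3(vapply(sums, function(s) s$Ho, numeric(1))),
    He = round3(vapply(sums, function(s) s$He, numeric(1))),
    hwe_p = round3(vapply(sums, function(s) s$hwe_p, numeric(1))),
    pi = round3(vapply(sums, function(s) s$pi, numeric(1)), 2),
    pi_se = round3(vapply(sums, function(s) s$pi_se, numeric(1)), 2),
    stringsAsFactors = FALSE, row.names = NULL)
  mean_row <- data.frame(
    locus = "Mean", n = mean(df$n),
    variants = round3(mean(df$variants), 1),
    Ho = round3(mean(vapply(sums, function(s) s$Ho, numeric(1)))),
    He = round3(mean(vapply(sums, function(s) s$He, numeric(1)))),
    hwe_p = NA_real_, pi = NA_real_, pi_se = NA_real_,
    stringsAsFactors = FALSE)
  out <- rbind(df, mean_row)
  attr(out, "summaries") <- sums
  class(out) <- c("diversity_report", "data.frame")
  out
}

#' @param report a `diversity_report`.
#' @rdname run_diversity
#' @export
write_diversity_report <- function(report, path) {
  out <- as.data.frame(report)
  for (col in names(out)) {
    v <- out[[col]]
    if (is.numeric(v)) {
      v <- as.character(v)
      v[is.na(v)] <- "-"
      out[[col]] <- v
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Infer an unsampled parent's genotypes across the sites of a locus
#'
#' For a pedigree containing an ungenotyped parent, runs
#' [infer_missing_parent()] at every site of a genotype matrix, using the
#' target's genotyped offspring and their genotyped other parents.
#'
#' @param geno IUPAC genotype matrix (rows = genotyped individuals).
#' @param ped a [new_pedigree()].
#' @param target id of the ungenotyped parent to infer.
#' @return data frame: `site`, `status`, `genotypes` (slash-separated
#'   consistent genotype calls), `n_offspring`, `nondetection_prob`.
#' @export
run_founder_inference <- function(geno, ped, target) {
  pd <- as.data.frame(ped)
  if (target %in% rownames(geno)) {
    stop("'", target, "' is already genotyped; nothing to infer")
  }
  kids <- pd$id[(!is.na(pd$dam) & pd$dam == target) |
                (!is.na(pd$sire) & pd$sire == target)]
  kids <- kids[kids %in% rownames(geno)]
  if (!length(kids)) stop("no genotyped offspring of '", target, "'")
  co <- unique(unlist(pd[pd$id %in% kids, c("dam", "sire")]))
  co <- setdiff(co[!is.na(co)], target)
  co <- co[co %in% rownames(geno)]
  out <- lapply(colnames(geno), function(site) {
    offspring <- lapply(kids, function(k) iupac_decode(geno[k, site])[1, ])
    # candidate alleles: everything segregating at the site population-wide
    alleles <- unique(as.vector(iupac_decode(geno[, site])))
    known <- if (length(co) == 1L) iupac_decode(geno[co, site])[1, ] else NULL
    inf <- infer_missing_parent(alleles, known, offspring)
    gstr <- if (is.null(known)) {
      vapply(inf$consistent, function(p)
        paste0(iupac_encode(p$dam[1], p$dam[2]), "+",
               iupac_encode(p$sire[1], p$sire[2])), character(1))
    } else {
      vapply(inf$consistent, function(g) iupac_encode(g[1], g[2]),
             character(1))
    }
    data.frame(site = site, status = inf$status,
               genotypes = paste(gstr, collapse = "/"),
               n_offspring = inf$n_offspring_used,
               nondetection_prob = inf$nondetection_prob,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Clone-sampling design
#'
#' How many clones must be sequenced to observe every haplotype of a
#' coamplified product with a target probability.
#'
#' @param haplotype_freqs haplotype frequencies (sum to 1).
#' @param target required coverage probability.
#' @return list with `n_clones` and the achieved `coverage`.
#' @export
clone_design <- function(haplotype_freqs, target = 0.996) {
  n <- min_clones_for(haplotype_freqs, target)
  list(n_clones = n,
       coverage = clone_coverage_probability(n, haplotype_freqs))
}
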