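#' Pedigree of a pedigreed study population
#'
#' A pedigree is a table of individuals with optional dam and sire links.
#' Founders carry no recorded parents. Unknown parents are encoded `NA`
#' (written as `UNKNOWN` in the TSV interchange format).
#'
#' @param df data frame with columns `id`, `dam`, `sire`, and optionally
#'   `sex` and `founder` (0/1). `dam`/`sire` may be `NA` or `"UNKNOWN"`.
#' @return an object of class `tlr_pedigree` (a validated data frame).
#' @export
new_pedigree <- function(df) {
  stopifnot(all(c("id", "dam", "sire") %in% names(df)))
  df$id <- as.character(df$id)
  for (col in c("dam", "sire")) {
    v <- as.character(df[[col]])
    v[v %in% c("", "UNKNOWN", "0")] <- NA_character_
    df[[col]] <- v
  }
  if (anyDuplicated(df$id)) stop("duplicated individual ids in pedigree")
  if (!"founder" %in% names(df)) {
    df$founder <- as.integer(is.na(df$dam) & is.na(df$sire))
  }
  if (any(df$founder == 1 & (!is.na(df$dam) | !is.na(df$sire)))) {
    stop("founders must have no recorded parents")
  }
  # acyclicity: repeatedly strip individuals whose parents are all stripped
  live <- rep(TRUE, nrow(df))
  repeat {
    in_live <- function(p) !is.na(p) & p %in% df$id[live]
    strippable <- live & !in_live(df$dam) & !in_live(df$sire)
    if (!any(strippable)) break
    live <- live & !strippable
  }
  if (any(live)) {
    stop("pedigree contains a cycle involving: ",
         paste(df$id[live], collapse = ", "))
  }
  structure(df, class = c("tlr_pedigree", "data.frame"))
}

#' @export
print.tlr_pedigree <- function(x, ...) {
  cat(sprintf("<tlr_pedigree> %d individuals (%d founders)\n",
              nrow(x), sum(x$founder == 1)))
  NextMethod()
}

#' Read / write a pedigree TSV
#'
#' Columns `id`, `dam`, `sire`, `sex`, `founder`; `UNKNOWN` marks a missing
#' parent; lines starting `#` are comments.
#'
#' @param path file path.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  if ("founder" %in% names(df)) df$founder <- as.integer(df$founder)
  new_pedigree(df)
}

#' @param ped a `tlr_pedigree`.
#' @rdname read_pedigree
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)
  for (col in c("dam", "sire")) out[[col]][is.na(out[[col]])] <- "UNKNOWN"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Mendelian consistency of a parent-offspring trio at one site
#'
#' @param offspring,dam,sire length-2 character vectors: the unordered
#'   allele pair of each individual at the same site.
#' @return `TRUE` iff the offspring pair can be formed by taking one allele
#'   from the dam and one from the sire.
#' @export
trio_consistent <- function(offspring, dam, sire) {
  o <- as.character(offspring)
  (o[1] %in% dam && o[2] %in% sire) || (o[2] %in% dam && o[1] %in% sire)
}

# all unordered genotype pairs over an allele set, lexicographic
genotype_candidates <- function(alleles) {
  alleles <- sort(unique(as.character(alleles)))
  out <- list()
  for (i in seq_along(alleles)) {
    for (j in i:length(alleles)) {
      out[[length(out) + 1L]] <- c(alleles[i], alleles[j])
    }
  }
  out
}

#' Probability of failing to detect an allele of an unsampled parent
#'
#' A heterozygous unsampled parent transmits the same one of its two alleles
#' to every one of `n_offspring` independently sampled offspring with
#' probability \eqn{(1/2)^n}; its second allele then stays hidden. Five
#' offspring bound this nondetection probability below 3.5\%.
#'
#' @param n_offspring integer >= 0.
#' @return the probability \eqn{(1/2)^{n}}.
#' @export
nondetection_probability <- function(n_offspring) {
  n_offspring <- as.integer(n_offspring)
  if (any(n_offspring < 0)) stop("n_offspring must be >= 0")
  0.5^n_offspring
}

#' Smallest number of offspring bounding nondetection below alpha
#'
#' @param alpha target probability, 0 < alpha < 1.
#' @return smallest integer n with \eqn{(1/2)^n < \alpha}.
#' @export
min_offspring_for <- function(alpha) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly between 0 and 1")
  }
  n <- 0L
  while (0.5^n >= alpha) n <- n + 1L
  n
}

#' Infer the genotype of an unsampled parent from its offspring
#'
#' Filters every possible genotype of the missing parent through Mendelian
#' consistency with all sampled offspring, given the sampled co-parent.
#' When both parents are unsampled (`known_parent = NULL`) the inference is
#' joint and the result enumerates consistent genotype pairs.
#' An empty consistent set is flagged `"inconsistent"` (a genotyping-error
#' or paralog signal), never raised as an error.
#'
#' @param site_alleles character vector: the alleles segregating at the site.
#' @param known_parent length-2 character vector (the sampled co-parent's
#'   genotype), or `NULL` if both parents are unsampled.
#' @param offspring list of length-2 character vectors, one per offspring.
#' @return list with `consistent` (list of genotypes, or of genotype pairs
#'   `list(dam =, sire =)` for joint inference), `status` (`"unique"`,
#'   `"ambiguous"` or `"inconsistent"`), `n_offspring_used` and
#'   `nondetection_prob`.
#' @export
infer_missing_parent <- function(site_alleles, known_parent, offspring) {
  if (!length(offspring)) stop("at least one offspring genotype is required")
  cands <- genotype_candidates(site_alleles)
  if (!is.null(known_parent)) {
    keep <- vapply(cands, function(g) {
      all(vapply(offspring, trio_consistent, logical(1),
                 dam = known_parent, sire = g))
    }, logical(1))
    consistent <- cands[keep]
  } else {
    consistent <- list()
    for (gi in cands) {
      for (gj in cands) {
        ok <- all(vapply(offspring, trio_consistent, logical(1),
                         dam = gi, sire = gj))
        if (ok) consistent[[length(consistent) + 1L]] <-
            list(dam = gi, sire = gj)
      }
    }
  }
  status <- if (!length(consistent)) "inconsistent"
            else if (length(consistent) == 1L) "unique" else "ambiguous"
  list(consistent = consistent,
       status = status,
       n_offspring_used = length(offspring),
       nondetection_prob = nondetection_probability(length(offspring)))
}
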