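# Independent oracles used across test files.

# --- Hardy-Weinberg oracle -------------------------------------------------
# Distribution of genotype configurations conditional on allele counts,
# derived by sequentially pairing gene copies uniformly at random (always
# consume one copy of the smallest-indexed remaining allele, pair it with a
# uniformly chosen remaining copy). This derivation never touches the
# closed-form n!2^h... weight used by the implementation.
#
# Configurations are keyed by the cell counts of the lower-triangular
# genotype table in (1,1),(2,1),(2,2),(3,1),... order.

.pairing_memo <- new.env(parent = emptyenv())

cell_order <- function(k) {
  cells <- list()
  for (j in seq_len(k)) for (i in j:k) cells[[length(cells) + 1L]] <- c(i, j)
  cells
}

pairing_dist <- function(counts) {
  key <- paste(counts, collapse = ",")
  if (!is.null(.pairing_memo[[key]])) return(.pairing_memo[[key]])
  k <- length(counts)
  cells <- cell_order(k)
  zero_key <- paste(rep(0L, length(cells)), collapse = ",")
  if (all(counts == 0)) {
    res <- stats::setNames(1, zero_key)
    .pairing_memo[[key]] <- res
    return(res)
  }
  a <- min(which(counts > 0))
  rem <- counts
  rem[a] <- rem[a] - 1L
  total <- sum(rem)
  acc <- new.env(parent = emptyenv())
  for (b in which(rem > 0)) {
    p <- rem[b] / total
    rem2 <- rem
    rem2[b] <- rem2[b] - 1L
    sub <- pairing_dist(rem2)
    cell <- which(vapply(cells, function(c2) {
      all(c2 == c(max(a, b), min(a, b)))
    }, logical(1)))
    for (s in seq_along(sub)) {
      v <- as.integer(strsplit(names(sub)[s], ",")[[1]])
      v[cell] <- v[cell] + 1L
      nk <- paste(v, collapse = ",")
      acc[[nk]] <- (if (is.null(acc[[nk]])) 0 else acc[[nk]]) + p * sub[[s]]
    }
  }
  res <- unlist(as.list(acc))
  .pairing_memo[[key]] <- res
  res
}

# two-sided probability-ordering p-value from the pairing oracle
hwe_oracle_p <- function(g) {
  g <- as.matrix(g)
  g[upper.tri(g)] <- t(g)[upper.tri(g)]   # counts live in the lower triangle
  k <- nrow(g)
  counts <- as.integer(vapply(seq_len(k), function(a) {
    2 * g[a, a] + sum(g[a, -a])
  }, numeric(1)))
  cells <- cell_order(k)
  obs <- paste(as.integer(vapply(cells, function(c2) g[c2[1], c2[2]],
                                 numeric(1))), collapse = ",")
  dist <- pairing_dist(counts)
  p_obs <- dist[[obs]]
  sum(dist[dist <= p_obs * (1 + 1e-9)])
}

# all compositions of n into m nonnegative parts
compositions <- function(n, m) {
  if (m == 1L) return(matrix(n, 1, 1))
  out <- list()
  for (first in 0:n) {
    rest <- compositions(n - first, m - 1L)
    out[[length(out) + 1L]] <- cbind(first, rest)
  }
  do.call(rbind, out)
}

# --- small utilities -------------------------------------------------------

random_coding <- function(n_codons) {
  gc <- Biostrings::GENETIC_CODE
  paste(sample(names(gc)[gc != "*"], n_codons, replace = TRUE),
        collapse = "")
}

expect_round3 <- function(x, target) {
  expect_equal(floor(abs(x) * 1000 + 0.5) / 1000 * sign(x), target)
}
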