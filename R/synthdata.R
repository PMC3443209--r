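#' Configuration for the synthetic study-population generator
#'
#' The defaults emulate the study design the pipeline targets: a
#' 12-founder (5 female, 7 male) bottlenecked island population genotyped
#' at ~1 kb TLR amplicons carrying 2-5 haplotypes per locus, up to 7
#' offspring genotyped per breeding pair, coamplifying paralog pairs
#' diverged at 8 of 947 bp, and clone experiments of 24 reads across 3
#' independent PCR amplifications with a low chimera rate.
#'
#' @param seed integer master seed; every generator forks a named stream
#'   from it, so outputs are byte-reproducible and adding a generator never
#'   perturbs existing ones.
#' @param n_loci number of simulated loci.
#' @param length_bp amplicon length per locus.
#' @param n_founders,n_female_founders founder cohort composition.
#' @param haplotypes_per_locus integer vector (recycled) of haplotype
#'   counts per locus, each in 2..5, or `NULL` to sample from 2:5.
#' @param hap_freq_alpha symmetric-Dirichlet concentration for haplotype
#'   frequencies (1 = uniform over the simplex).
#' @param offspring_per_pair offspring genotyped per breeding pair (<= 7).
#' @param paralog_length_bp,paralog_divergence_sites coamplification
#'   overlay: amplicon length and number of fixed inter-copy differences.
#' @param clone_draws,replicate_count,chimera_rate clone experiment:
#'   total clones per individual, independent PCR replicates, probability
#'   that a read is a PCR chimera.
#' @param mk_length_bp,divergence_subs,within_species_theta,n_haps_per_species,selection_factor
#'   two-species divergence scenario: coding length, fixed differences,
#'   expected segregating sites per species, haplotypes sampled per
#'   species, and the non-synonymous enrichment factor on the fixed branch
#'   (1 = neutral).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_loci = 7L,
                       length_bp = 1006L,
                       n_founders = 12L,
                       n_female_founders = 5L,
                       haplotypes_per_locus = NULL,
                       hap_freq_alpha = 1,
                       offspring_per_pair = 5L,
                       paralog_length_bp = 947L,
                       paralog_divergence_sites = 8L,
                       clone_draws = 24L,
                       replicate_count = 3L,
                       chimera_rate = 0.05,
                       mk_length_bp = 600L,
                       divergence_subs = 50L,
                       within_species_theta = 25,
                       n_haps_per_species = 8L,
                       selection_factor = 1) {
  cfg <- list(seed = as.integer(seed), n_loci = as.integer(n_loci),
              length_bp = as.integer(length_bp),
              n_founders = as.integer(n_founders),
              n_female_founders = as.integer(n_female_founders),
              haplotypes_per_locus = haplotypes_per_locus,
              hap_freq_alpha = hap_freq_alpha,
              offspring_per_pair = as.integer(offspring_per_pair),
              paralog_length_bp = as.integer(paralog_length_bp),
              paralog_divergence_sites = as.integer(paralog_divergence_sites),
              clone_draws = as.integer(clone_draws),
              replicate_count = as.integer(replicate_count),
              chimera_rate = chimera_rate,
              mk_length_bp = as.integer(mk_length_bp),
              divergence_subs = as.integer(divergence_subs),
              within_species_theta = within_species_theta,
              n_haps_per_species = as.integer(n_haps_per_species),
              selection_factor = selection_factor)
  with(cfg, {
    if (n_loci < 1 || length_bp < 3 || n_founders < 2) {
      stop("impossible configuration: need >= 1 locus, >= 3 bp, >= 2 founders")
    }
    if (n_female_founders < 1 || n_female_founders >= n_founders) {
      stop("founder cohort needs at least one founder of each sex")
    }
    if (offspring_per_pair < 1 || offspring_per_pair > 7) {
      stop("offspring_per_pair must be in 1..7")
    }
    if (chimera_rate < 0 || chimera_rate > 1) {
      stop("chimera_rate must be a probability")
    }
    if (!is.null(haplotypes_per_locus) &&
        any(haplotypes_per_locus < 1 | haplotypes_per_locus > 5)) {
      stop("haplotypes_per_locus entries must be in 1..5")
    }
    if (selection_factor <= 0) stop("selection_factor must be > 0")
  })
  structure(cfg, class = "sim_config")
}

# fork a deterministic sub-seed (< 2^31) from the master seed and a stream
# name, so independent generators never share a random stream
stream_seed <- function(seed, stream) {
  h <- as.double(seed) %% 2147483647
  for (c in utf8ToInt(stream)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

with_stream <- function(cfg, stream, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(cfg$seed, stream))
  force(expr)
}

rdirichlet1 <- function(k, alpha) {
  x <- stats::rgamma(k, shape = alpha)
  x / sum(x)
}

NONSTOP_CODONS <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
})

random_coding_seq <- function(n_codons) {
  paste(sample(NONSTOP_CODONS, n_codons, replace = TRUE), collapse = "")
}

#' Simulate a pedigreed founder population with Mendelian transmission
#'
#' Draws per-locus haplotype pools and frequencies, assigns founder
#' genotypes by random union of gametes, mates founders into female-male
#' pairs, and transmits alleles fairly (each parent passes one of its two
#' haplotypes with probability 1/2, independently per offspring).
#' Genotypes are emitted as IUPAC consensus matrices, exactly as Sanger
#' sequencing of a diploid PCR product would report them.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_population`: `geno` (per-locus IUPAC
#'   matrices, rows = individuals, columns = SNP positions), `pedigree`,
#'   `loci` (per-locus reference, SNP sites, haplotype allele strings and
#'   frequencies), `truth` (per-locus matrix of each individual's two true
#'   haplotype allele strings, plus transmission records) and `config`.
#' @export
simulate_population <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  n_pairs <- min(cfg$n_female_founders, cfg$n_founders - cfg$n_female_founders)
  founders <- sprintf("F%02d", seq_len(cfg$n_founders))
  sex <- rep(c("F", "M"), c(cfg$n_female_founders,
                            cfg$n_founders - cfg$n_female_founders))
  pair_idx <- rep(seq_len(n_pairs), each = cfg$offspring_per_pair)
  kid_no <- rep(seq_len(cfg$offspring_per_pair), times = n_pairs)
  offspring <- sprintf("O%02d_%02d", pair_idx, kid_no)
  kid_dam <- founders[sex == "F"][pair_idx]
  kid_sire <- founders[sex == "M"][pair_idx]
  ped <- rbind(
    data.frame(id = founders, dam = NA_character_, sire = NA_character_,
               sex = sex, founder = 1L, stringsAsFactors = FALSE),
    data.frame(id = offspring, dam = kid_dam, sire = kid_sire,
               sex = rep_len(c("F", "M"), length(offspring)), founder = 0L,
               stringsAsFactors = FALSE))
  ids <- c(founders, offspring)

  hap_counts <- with_stream(cfg, "locus_architecture", {
    if (is.null(cfg$haplotypes_per_locus)) {
      sample(2:5, cfg$n_loci, replace = TRUE)
    } else rep_len(as.integer(cfg$haplotypes_per_locus), cfg$n_loci)
  })

  loci <- vector("list", cfg$n_loci)
  geno <- vector("list", cfg$n_loci)
  truth <- vector("list", cfg$n_loci)
  names(loci) <- names(geno) <- names(truth) <-
    sprintf("L%02d", seq_len(cfg$n_loci))

  for (l in seq_len(cfg$n_loci)) {
    lab <- names(loci)[l]
    loci[[l]] <- with_stream(cfg, paste0("locus_", lab), {
      h <- hap_counts[l]
      ref <- random_coding_seq(cfg$length_bp %/% 3L)
      L <- nchar(ref)
      n_sites <- max(1L, h - 1L)
      positions <- sort(sample.int(L, n_sites))
      refb <- substring(ref, positions, positions)
      altb <- vapply(refb, function(b) sample(setdiff(DNA_BASES, b), 1),
                     character(1))
      # haplotype j (j >= 2) carries the alternate allele at site j-1 only
      haps <- matrix(rep(refb, each = h), nrow = h)
      if (h > 1) for (j in 2:h) haps[j, j - 1L] <- altb[j - 1L]
      hap_str <- apply(haps, 1, paste, collapse = "")
      freqs <- rdirichlet1(h, cfg$hap_freq_alpha)
      list(name = lab, reference_seq = ref, length_bp = L,
           sites = data.frame(position = positions,
                              ref = unname(refb), alt = unname(altb),
                              stringsAsFactors = FALSE),
           haplotypes = hap_str, freqs = freqs)
    })
  }

  for (l in seq_len(cfg$n_loci)) {
    lab <- names(loci)[l]
    lc <- loci[[l]]
    h <- length(lc$haplotypes)
    tr <- with_stream(cfg, paste0("genotypes_", lab), {
      fhap <- matrix(sample.int(h, 2 * cfg$n_founders, replace = TRUE,
                                prob = lc$freqs),
                     ncol = 2, dimnames = list(founders, NULL))
      gd <- sample.int(2L, length(offspring), replace = TRUE)
      gs <- sample.int(2L, length(offspring), replace = TRUE)
      ohap <- cbind(fhap[cbind(match(kid_dam, founders), gd)],
                    fhap[cbind(match(kid_sire, founders), gs)])
      rownames(ohap) <- offspring
      trans <- cbind(dam = gd, sire = gs)
      rownames(trans) <- offspring
      list(hap = rbind(fhap, ohap), trans = trans)
    })
    hm <- tr$hap[ids, , drop = FALSE]
    a1 <- do.call(rbind, strsplit(lc$haplotypes[hm[, 1]], ""))
    a2 <- do.call(rbind, strsplit(lc$haplotypes[hm[, 2]], ""))
    g <- matrix(iupac_encode(a1, a2), nrow = length(ids),
                dimnames = list(ids, lc$sites$position))
    geno[[l]] <- g
    truth[[l]] <- list(
      hap_index = hm,
      hap_strings = matrix(lc$haplotypes[hm], ncol = 2,
                           dimnames = list(ids, NULL)),
      transmissions = tr$trans)
  }

  structure(list(geno = geno, pedigree = new_pedigree(ped),
                 loci = loci, truth = truth, config = cfg),
            class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf("<sim_population> %d individuals (%d founders), %d loci\n",
              nrow(x$pedigree), sum(x$pedigree$founder == 1),
              length(x$geno)))
  invisible(x)
}

#' Censor founders from a simulated population
#'
#' Emulates founders that died before sampling: removes `k` founder
#' genotype records (by default one of each sex, preferring founders with
#' offspring) and retains at most `offspring_kept` genotyped offspring per
#' hidden founder, so the missing-parent inference machinery can be tested
#' against the recorded truth.
#'
#' @param pop a [simulate_population()] result.
#' @param k number of founders to hide (default 2).
#' @param offspring_kept offspring retained per hidden founder (<= 7).
#' @return list with `geno` (censored matrices), `pedigree`, `hidden`
#'   (ids), `truth` (the hidden founders' true IUPAC genotypes) and
#'   `offspring_used` per hidden founder.
#' @export
hide_founders <- function(pop, k = 2L, offspring_kept = 5L) {
  stopifnot(inherits(pop, "sim_population"))
  ped <- as.data.frame(pop$pedigree)
  founders <- ped$id[ped$founder == 1]
  if (k > length(founders)) stop("cannot hide more founders than exist")
  if (k == 0L) {
    return(list(geno = pop$geno, pedigree = pop$pedigree,
                hidden = character(0), truth = list(),
                offspring_used = integer(0)))
  }
  has_kids <- founders[founders %in% c(ped$dam, ped$sire)]
  mate_of <- function(f) {
    kids <- ped[(!is.na(ped$dam) & ped$dam == f) |
                (!is.na(ped$sire) & ped$sire == f), ]
    setdiff(unique(unlist(kids[c("dam", "sire")])), f)
  }
  by_sex <- split(has_kids, ped$sex[match(has_kids, ped$id)])
  hidden <- character(0)
  for (s in names(by_sex)) {   # one per sex, from different broods so each
    pool <- by_sex[[s]]        # hidden founder keeps a sampled co-parent
    pool2 <- pool[!pool %in% unlist(lapply(hidden, mate_of))]
    if (length(hidden) < k && length(c(pool2, pool))) {
      hidden <- c(hidden, c(pool2, pool)[1])
    }
  }
  hidden <- c(hidden, setdiff(has_kids, hidden))[seq_len(k)]

  drop <- hidden
  for (f in hidden) {
    kids <- ped$id[!is.na(ped$dam) & ped$dam == f |
                   !is.na(ped$sire) & ped$sire == f]
    if (length(kids) > offspring_kept) {
      drop <- c(drop, kids[-seq_len(offspring_kept)])
    }
  }
  geno <- lapply(pop$geno, function(g) g[!rownames(g) %in% drop, ,
                                         drop = FALSE])
  truth <- lapply(pop$geno, function(g) g[hidden, , drop = FALSE])
  list(geno = geno, pedigree = pop$pedigree, hidden = hidden,
       truth = truth,
       offspring_used = stats::setNames(rep(offspring_kept, k), hidden))
}

#' Merge two coamplifying gene copies into pseudo-genotypes
#'
#' Pools each individual's four gene copies (two per paralog) and emits,
#' per site, the IUPAC consensus over all alleles present -- what Sanger
#' sequencing of the coamplified PCR product would show. Fixed inter-copy
#' differences become universally heterozygous sites; within-copy
#' polymorphism shows as variable heterozygosity.
#'
#' @param pairs_a,pairs_b n x 2 character matrices of full-length
#'   haplotype sequences (rows = individuals, equal lengths).
#' @return IUPAC character matrix (rows = individuals, columns = 1..L).
#' @export
overlay_paralogs <- function(pairs_a, pairs_b) {
  stopifnot(is.matrix(pairs_a), is.matrix(pairs_b),
            nrow(pairs_a) == nrow(pairs_b))
  lens <- unique(nchar(c(pairs_a, pairs_b)))
  if (length(lens) != 1L) stop("paralog copies must have equal length")
  n <- nrow(pairs_a)
  out <- matrix(NA_character_, n, lens,
                dimnames = list(rownames(pairs_a), seq_len(lens)))
  code_of <- stats::setNames(names(Biostrings::IUPAC_CODE_MAP),
                             Biostrings::IUPAC_CODE_MAP)
  for (i in seq_len(n)) {
    chars <- rbind(strsplit(pairs_a[i, 1], "")[[1]],
                   strsplit(pairs_a[i, 2], "")[[1]],
                   strsplit(pairs_b[i, 1], "")[[1]],
                   strsplit(pairs_b[i, 2], "")[[1]])
    out[i, ] <- apply(chars, 2, function(col) {
      code_of[[paste(sort(unique(col)), collapse = "")]]
    })
  }
  out
}

#' Simulate a coamplifying paralog pair
#'
#' Copy A segregates a small number of within-copy SNPs; copy B is fixed
#' and differs from copy A's reference at `cfg$paralog_divergence_sites`
#' positions. The merged pseudo-genotypes are returned together with the
#' planted divergent-site set.
#'
#' @param cfg a [sim_config()].
#' @param n_individuals number of individuals to emit.
#' @param n_copy_a_snps within-copy-A polymorphic sites (default 3).
#' @return list with `geno` (merged IUPAC matrix), `divergent_sites`
#'   (planted truth), `copy_a_snps` and `length_bp`.
#' @export
simulate_coamplification <- function(cfg = sim_config(), n_individuals = 20L,
                                     n_copy_a_snps = 3L) {
  stopifnot(inherits(cfg, "sim_config"))
  with_stream(cfg, "coamplification", {
    L <- cfg$paralog_length_bp
    ref <- paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
    all_pos <- sample.int(L, cfg$paralog_divergence_sites + n_copy_a_snps)
    div_pos <- sort(all_pos[seq_len(cfg$paralog_divergence_sites)])
    snp_pos <- sort(all_pos[-seq_len(cfg$paralog_divergence_sites)])
    mutate_at <- function(seq, pos) {
      s <- strsplit(seq, "")[[1]]
      s[pos] <- vapply(s[pos], function(b) sample(setdiff(DNA_BASES, b), 1),
                       character(1))
      paste(s, collapse = "")
    }
    ref_b <- mutate_at(ref, div_pos)
    # copy A: two haplotypes per SNP structure; individuals draw freely
    hapA <- c(ref, vapply(snp_pos, function(p) mutate_at(ref, p),
                          character(1)))
    pa <- matrix(sample(hapA, 2 * n_individuals, replace = TRUE),
                 ncol = 2,
                 dimnames = list(sprintf("I%02d", seq_len(n_individuals)),
                                 NULL))
    pb <- matrix(ref_b, nrow = n_individuals, ncol = 2,
                 dimnames = dimnames(pa))
    list(geno = overlay_paralogs(pa, pb),
         divergent_sites = div_pos,
         copy_a_snps = snp_pos,
         length_bp = L)
  })
}

#' Simulate a clone-sequencing experiment for one individual
#'
#' Multinomial draws over the individual's true haplotypes, split across
#' independent PCR replicates; with probability `cfg$chimera_rate` a read
#' is replaced by a recombinant of two distinct templates joined at a
#' uniformly chosen breakpoint (a single-crossover PCR chimera). Every
#' read is truth-labelled.
#'
#' @param hap_seqs character vector of the individual's true haplotype
#'   sequences (equal lengths).
#' @param cfg a [sim_config()].
#' @param freqs template frequencies (default equifrequent).
#' @param stream random-stream label (vary per individual).
#' @return list with `experiment` (a [clone_experiment()]) and `truth`
#'   (data frame: `replicate`, `sequence`, `is_chimera`, `templates`).
#' @export
simulate_clones <- function(hap_seqs, cfg = sim_config(), freqs = NULL,
                            stream = "clones") {
  stopifnot(length(hap_seqs) >= 1L)
  hap_seqs <- as.character(hap_seqs)
  L <- unique(nchar(hap_seqs))
  if (length(L) != 1L) stop("haplotypes must have equal length")
  k <- length(hap_seqs)
  if (is.null(freqs)) freqs <- rep(1 / k, k)
  with_stream(cfg, stream, {
    per_rep <- diff(round(seq(0, cfg$clone_draws,
                              length.out = cfg$replicate_count + 1)))
    rows <- list()
    for (r in seq_len(cfg$replicate_count)) {
      for (d in seq_len(per_rep[r])) {
        tmpl <- sample.int(k, 1, prob = freqs)
        if (k >= 2 && stats::runif(1) < cfg$chimera_rate) {
          other <- sample(setdiff(seq_len(k), tmpl), 1)
          bp <- sample.int(L - 1L, 1)
          seq <- paste0(substr(hap_seqs[tmpl], 1, bp),
                        substr(hap_seqs[other], bp + 1L, L))
          rows[[length(rows) + 1L]] <- data.frame(
            replicate = r, sequence = seq, is_chimera = TRUE,
            templates = paste(tmpl, other, sep = "+"),
            stringsAsFactors = FALSE)
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            replicate = r, sequence = hap_seqs[tmpl], is_chimera = FALSE,
            templates = as.character(tmpl), stringsAsFactors = FALSE)
        }
      }
    }
    truth <- do.call(rbind, rows)
    list(experiment = clone_experiment("sim", "sim_locus",
                                       truth[c("sequence", "replicate")]),
         truth = truth)
  })
}

#' Simulate two-species divergence with labelled changes
#'
#' Evolves an ancestral coding sequence along two branches: fixed
#' differences are placed in distinct codons (one change per codon, stops
#' rejected) and split between the branches; within-species polymorphism
#' adds a Poisson(`within_species_theta`) number of segregating sites per
#' species, each with the derived allele on a random proper subset of that
#' species' haplotypes. `selection_factor` > 1 enriches non-synonymous
#' changes among the fixed differences (synonymous proposals are accepted
#' with probability 1/factor), emulating directional selection.
#'
#' @param cfg a [sim_config()].
#' @param stream random-stream label.
#' @return list with `species_a`, `species_b` (haplotype vectors) and
#'   `truth` (data frame: `position`, `status`, `class`, `species`).
#' @export
simulate_divergence <- function(cfg = sim_config(), stream = "divergence") {
  stopifnot(inherits(cfg, "sim_config"))
  with_stream(cfg, stream, {
    n_codons <- cfg$mk_length_bp %/% 3L
    anc <- random_coding_seq(n_codons)
    n_poly_a <- stats::rpois(1, cfg$within_species_theta)
    n_poly_b <- stats::rpois(1, cfg$within_species_theta)
    need <- cfg$divergence_subs + n_poly_a + n_poly_b
    if (need > n_codons) {
      stop("mk_length_bp too short for the requested number of changes")
    }
    codons <- sample.int(n_codons, need)     # one change per codon
    take <- function(n) {
      out <- codons[seq_len(n)]; codons <<- codons[-seq_len(n)]; out
    }

    propose_change <- function(seq, codon_idx, sel = 1) {
      repeat {
        within <- sample.int(3L, 1)
        pos <- (codon_idx - 1L) * 3L + within
        old <- substr(seq, pos, pos)
        new <- sample(setdiff(DNA_BASES, old), 1)
        cod <- substr(seq, (codon_idx - 1L) * 3L + 1L, codon_idx * 3L)
        mut <- cod
        substr(mut, within, within) <- new
        if (Biostrings::GENETIC_CODE[mut] == "*") next
        cls <- if (Biostrings::GENETIC_CODE[mut] ==
                   Biostrings::GENETIC_CODE[cod]) "synonymous"
               else "nonsynonymous"
        # enrichment: thin synonymous proposals when sel > 1
        if (sel > 1 && cls == "synonymous" && stats::runif(1) > 1 / sel) next
        return(list(pos = pos, new = new, class = cls))
      }
    }

    seq_a <- anc; seq_b <- anc
    truth <- list()
    fixed_codons <- take(cfg$divergence_subs)
    on_a <- stats::runif(cfg$divergence_subs) < 0.5
    for (i in seq_along(fixed_codons)) {
      target <- if (on_a[i]) "a" else "b"
      ch <- propose_change(if (on_a[i]) seq_a else seq_b, fixed_codons[i],
                           sel = cfg$selection_factor)
      if (on_a[i]) substr(seq_a, ch$pos, ch$pos) <- ch$new
      else substr(seq_b, ch$pos, ch$pos) <- ch$new
      truth[[length(truth) + 1L]] <- data.frame(
        position = ch$pos, status = "fixed", class = ch$class,
        species = target, stringsAsFactors = FALSE)
    }

    make_species <- function(seq, n_poly, label) {
      haps <- rep(seq, cfg$n_haps_per_species)
      for (cd in take(n_poly)) {
        ch <- propose_change(seq, cd)
        carriers <- sample.int(cfg$n_haps_per_species,
                               sample.int(cfg$n_haps_per_species - 1L, 1))
        for (cix in carriers) substr(haps[cix], ch$pos, ch$pos) <- ch$new
        truth[[length(truth) + 1L]] <<- data.frame(
          position = ch$pos, status = "polymorphic", class = ch$class,
          species = label, stringsAsFactors = FALSE)
      }
      haps
    }
    haps_a <- make_species(seq_a, n_poly_a, "a")
    haps_b <- make_species(seq_b, n_poly_b, "b")
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(position = integer(0), status = character(0),
                 class = character(0), species = character(0))
    list(species_a = haps_a, species_b = haps_b,
         truth = truth[order(truth$position), , drop = FALSE])
  })
}
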