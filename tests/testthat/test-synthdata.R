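test_that("generators are deterministic under the master seed", {
  cfg <- sim_config(seed = 5, n_loci = 2)
  p1 <- simulate_population(cfg)
  p2 <- simulate_population(cfg)
  expect_identical(p1$geno, p2$geno)
  expect_identical(p1$truth, p2$truth)
  c1 <- simulate_clones(c("AAAA", "TTTT"), cfg)
  c2 <- simulate_clones(c("AAAA", "TTTT"), cfg)
  expect_identical(c1, c2)
  d1 <- simulate_divergence(cfg)
  d2 <- simulate_divergence(cfg)
  expect_identical(d1, d2)
  # different seeds decouple
  expect_false(identical(simulate_population(sim_config(seed = 6,
    n_loci = 2))$geno, p1$geno))
})

test_that("emitted genotypes are re-derivable from the truth haplotypes", {
  pop <- simulate_population(sim_config(seed = 17, n_loci = 3))
  for (l in seq_along(pop$geno)) {
    tr <- pop$truth[[l]]$hap_strings
    rebuilt <- do.call(rbind, lapply(rownames(pop$geno[[l]]), function(id) {
      iupac_encode(strsplit(tr[id, 1], "")[[1]],
                   strsplit(tr[id, 2], "")[[1]])
    }))
    dimnames(rebuilt) <- dimnames(pop$geno[[l]])
    expect_identical(rebuilt, pop$geno[[l]])
  }
})

test_that("offspring genotypes obey Mendelian transmission from parents", {
  pop <- simulate_population(sim_config(seed = 29, n_loci = 2,
                                        offspring_per_pair = 7))
  ped <- as.data.frame(pop$pedigree)
  kids <- ped[ped$founder == 0, ]
  for (l in seq_along(pop$geno)) {
    tr <- pop$truth[[l]]$hap_strings
    for (r in seq_len(nrow(kids))) {
      kid <- kids$id[r]
      expect_true(tr[kid, 1] %in% tr[kids$dam[r], ] ||
                  tr[kid, 2] %in% tr[kids$dam[r], ])
      expect_true(tr[kid, 1] %in% tr[kids$sire[r], ] ||
                  tr[kid, 2] %in% tr[kids$sire[r], ])
    }
  }
})

test_that("founder heterozygosity matches expectation at large n", {
  cfg <- sim_config(seed = 41, n_loci = 1, haplotypes_per_locus = 2,
                    n_founders = 10000, n_female_founders = 5000,
                    offspring_per_pair = 1)
  pop <- simulate_population(cfg)
  ped <- as.data.frame(pop$pedigree)
  founders <- ped$id[ped$founder == 1]
  tr <- pop$truth[[1]]$hap_strings[founders, ]
  ho <- mean(tr[, 1] != tr[, 2])
  f <- pop$loci[[1]]$freqs
  expected <- 2 * f[1] * f[2]
  se <- sqrt(expected * (1 - expected) / length(founders))
  expect_lt(abs(ho - expected), 3 * se)
})

test_that("haplotype frequencies are recovered within sampling error", {
  cfg <- sim_config(seed = 43, n_loci = 1, haplotypes_per_locus = 3,
                    n_founders = 5000, n_female_founders = 2500,
                    offspring_per_pair = 1)
  pop <- simulate_population(cfg)
  ped <- as.data.frame(pop$pedigree)
  founders <- ped$id[ped$founder == 1]
  idx <- pop$truth[[1]]$hap_index[founders, ]
  f <- pop$loci[[1]]$freqs
  for (h in seq_along(f)) {
    emp <- mean(idx == h)
    se <- sqrt(f[h] * (1 - f[h]) / (2 * length(founders)))
    expect_lt(abs(emp - f[h]), 3 * se)
  }
})

test_that("hiding founders censors genotypes but keeps the truth", {
  pop <- simulate_population(sim_config(seed = 53, n_loci = 2))
  un <- hide_founders(pop, k = 0)
  expect_identical(un$geno, pop$geno)
  hid <- hide_founders(pop, k = 2, offspring_kept = 5)
  expect_length(hid$hidden, 2L)
  # hidden founders come from different broods: each keeps a sampled mate
  ped <- as.data.frame(pop$pedigree)
  mates <- vapply(hid$hidden, function(f) {
    kids <- ped[(!is.na(ped$dam) & ped$dam == f) |
                (!is.na(ped$sire) & ped$sire == f), ]
    setdiff(unique(unlist(kids[c("dam", "sire")])), f)[1]
  }, character(1))
  expect_false(any(mates %in% hid$hidden))
  for (l in seq_along(hid$geno)) {
    expect_false(any(hid$hidden %in% rownames(hid$geno[[l]])))
    expect_identical(hid$truth[[l]], pop$geno[[l]][hid$hidden, ,
                                                   drop = FALSE])
  }
})

test_that("missing-founder inference recovers forced genotypes from truth", {
  hits <- 0; total <- 0
  for (seed in 1:10) {
    pop <- simulate_population(sim_config(seed = seed, n_loci = 1,
                                          haplotypes_per_locus = 2,
                                          offspring_per_pair = 5))
    hid <- hide_founders(pop)
    for (f in hid$hidden) {
      inf <- run_founder_inference(hid$geno[[1]], hid$pedigree, f)
      for (r in seq_len(nrow(inf))) {
        expect_false(inf$status[r] == "inconsistent")
        truth_code <- hid$truth[[1]][f, inf$site[r]]
        cands <- strsplit(inf$genotypes[r], "/", fixed = TRUE)[[1]]
        total <- total + 1
        if (truth_code %in% cands) {
          if (inf$status[r] == "unique") hits <- hits + 1
        } else {
          # nondetection: a true allele can stay hidden when no relative
          # carries it -- but the deduced call must share the transmitted
          # allele with the truth
          tru <- iupac_decode(truth_code)[1, ]
          expect_true(all(vapply(cands, function(cc) {
            any(iupac_decode(cc)[1, ] %in% tru)
          }, logical(1))))
        }
      }
    }
  }
  expect_gt(hits, 0)    # deduction is forced at least somewhere
})

test_that("paralog overlay with zero divergence flags nothing", {
  co <- simulate_coamplification(sim_config(seed = 3,
                                            paralog_divergence_sites = 0),
                                 n_individuals = 15)
  expect_length(constant_het_scan(co$geno)$constant_het, 0L)
})

test_that("clone simulation respects the chimera rate contract", {
  haps <- c(paste(rep("A", 30), collapse = ""),
            paste(rep("C", 30), collapse = ""))
  cl0 <- simulate_clones(haps, sim_config(seed = 61, chimera_rate = 0))
  expect_true(all(cl0$truth$sequence %in% haps))
  expect_false(any(cl0$truth$is_chimera))
  expect_equal(nrow(cl0$truth), 24L)
  expect_equal(length(unique(cl0$truth$replicate)), 3L)
  cl <- simulate_clones(haps, sim_config(seed = 61, chimera_rate = 1))
  expect_true(all(cl$truth$is_chimera))
})

test_that("clone coverage simulation recovers the closed-form 99.6%", {
  set.seed(71)
  reps <- 1e5
  covered <- stats::rmultinom(reps, 24, rep(0.25, 4))
  emp <- mean(colSums(covered > 0) == 4L)
  p <- clone_coverage_probability(24, rep(0.25, 4))
  se <- sqrt(p * (1 - p) / reps)
  expect_lt(abs(emp - p), 3 * se)
  expect_round3(p, 0.996)
})

test_that("neutral divergence yields an empty table only in the degenerate case", {
  dv <- simulate_divergence(sim_config(seed = 81, divergence_subs = 0,
                                       within_species_theta = 0))
  expect_equal(nrow(dv$truth), 0L)
  expect_identical(dv$species_a[1], dv$species_b[1])
  rep <- mk_report(dv$species_a, dv$species_b)
  expect_equal(sum(rep$counts), 0)
  expect_true(is.na(rep$G))       # the association test is undefined
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_founders = 0), "impossible|each sex")
  expect_error(sim_config(offspring_per_pair = 9), "1..7")
  expect_error(sim_config(chimera_rate = 2), "probability")
  expect_error(sim_config(selection_factor = 0), "> 0")
})
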