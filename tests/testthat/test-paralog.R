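test_that("universal-heterozygosity scan recovers planted divergent sites", {
  for (seed in c(1, 7, 13)) {
    co <- simulate_coamplification(sim_config(seed = seed),
                                   n_individuals = 20)
    scan <- constant_het_scan(co$geno)
    expect_equal(sort(scan$constant_het), co$divergent_sites)
    # within-copy SNPs show up as variable, never constant, heterozygosity
    expect_true(!any(co$copy_a_snps %in% scan$constant_het))
  }
  # the 8-of-947 fraction reported for a coamplified amplicon
  co <- simulate_coamplification(sim_config(seed = 1), n_individuals = 20)
  scan <- constant_het_scan(co$geno)
  expect_equal(round(100 * scan$fraction_of_length, 1), 0.8)
})

test_that("single-copy loci in HWE never trigger the scan", {
  for (seed in 1:5) {
    pop <- simulate_population(sim_config(
      seed = seed, n_loci = 1, haplotypes_per_locus = 3,
      n_founders = 20, n_female_founders = 10, offspring_per_pair = 1))
    scan <- constant_het_scan(pop$geno[[1]])
    expect_length(scan$constant_het, 0L)
  }
})

test_that("all-heterozygous-trio probability matches per-trio enumeration", {
  # enumerate the 4x4 gamete grid of two A/T heterozygotes: 8 of 16
  # offspring outcomes are heterozygous, so one trio contributes exactly 1/2
  gametes <- expand.grid(d = c("A", "T"), s = c("A", "T"),
                         stringsAsFactors = FALSE)
  p_het <- mean(gametes$d != gametes$s)
  expect_equal(p_het, 0.5)
  expect_equal(all_het_trio_probability(15), p_het^15)
  expect_equal(signif(all_het_trio_probability(15), 1), 3e-5)
  expect_equal(all_het_trio_probability(0), 1.0)
  expect_error(all_het_trio_probability(-2), ">= 0")
})

test_that("clone coverage probability is exact and well-behaved", {
  expect_round3(clone_coverage_probability(24, rep(0.25, 4)), 0.996)
  expect_equal(clone_coverage_probability(1, 1.0), 1.0)
  expect_error(clone_coverage_probability(10, c(0.5, 0.4)), "sum to 1")
  # k = 2 closed form 1 - 2 (1/2)^n
  for (n in c(2, 5, 11)) {
    expect_equal(clone_coverage_probability(n, c(0.5, 0.5)),
                 1 - 2 * 0.5^n)
  }
  # nondecreasing in n, bounded in [0, 1] over random simplex draws
  set.seed(5)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    f <- stats::rgamma(k, 1)
    f <- f / sum(f)
    p_prev <- 0
    for (n in seq(k, 40, by = 4)) {
      p <- clone_coverage_probability(n, f)
      expect_gte(p, p_prev - 1e-12)
      expect_gte(p, 0); expect_lte(p, 1)
      p_prev <- p
    }
  }
})

test_that("clone coverage agrees with a Monte-Carlo oracle", {
  set.seed(31)
  f <- c(0.5, 0.3, 0.2)
  reps <- 1e6
  draws <- stats::rmultinom(reps, 10, f)
  emp <- mean(colSums(draws > 0) == 3L)
  p <- clone_coverage_probability(10, f)
  se <- sqrt(p * (1 - p) / reps)
  expect_lt(abs(emp - p), 3 * se)
})

test_that("clone-design inverse finds the published 24-clone depth", {
  expect_equal(min_clones_for(rep(0.25, 4), 0.996), 24L)
  expect_equal(min_clones_for(1.0, 0.9), 1L)
  expect_equal(min_clones_for(c(0.5, 0.5), 0.999), 11L)
  expect_error(min_clones_for(rep(0.25, 4), 1.2), "between 0 and 1")
  d <- clone_design(rep(0.25, 4))
  expect_equal(d$n_clones, 24L)
  expect_round3(d$coverage, 0.996)
})

test_that("replicate support separates haplotypes from artefact candidates", {
  reads <- data.frame(
    sequence = c("AAA", "AAA", "CCC", "GGG", "GGG"),
    replicate = c("1", "2", "1", "2", "3"))
  exp <- clone_experiment("RU152", "TLR7", reads)
  supp <- replicate_supported_haplotypes(exp)
  expect_setequal(supp$supported, c("AAA", "GGG"))
  expect_equal(supp$candidates, "CCC")
  # five supported haplotypes imply at least three gene copies
  expect_equal(copy_number_bound(5), 3L)
  expect_equal(copy_number_bound(4), 2L)
  expect_equal(copy_number_bound(1), 1L)
})

test_that("chimeras are overwhelmingly replicate-private at a low rate", {
  haps <- c(paste(rep("A", 40), collapse = ""),
            paste(rep(c("A", "C"), 20), collapse = ""),
            paste(rep("G", 40), collapse = ""),
            paste(rep(c("G", "T"), 20), collapse = ""))
  hit_true <- 0; n_chim <- 0; chim_unsupported <- 0
  # 33 clones (top of the 24-33 sequencing range): at 24 the chance that
  # some haplotype lands in fewer than 2 of the 3 replicates is ~11%
  for (seed in 1:200) {
    cl <- simulate_clones(haps, sim_config(seed = seed, chimera_rate = 0.05,
                                           clone_draws = 33))
    supp <- replicate_supported_haplotypes(cl$experiment)
    if (all(haps %in% supp$supported)) hit_true <- hit_true + 1
    chim <- unique(cl$truth$sequence[cl$truth$is_chimera])
    chim <- setdiff(chim, haps)      # a chimera can coincide with a template
    n_chim <- n_chim + length(chim)
    chim_unsupported <- chim_unsupported + sum(chim %in% supp$candidates)
  }
  expect_gte(hit_true / 200, 0.95)
  expect_gte(chim_unsupported / n_chim, 0.90)
})

test_that("the paralog report assembles scan, trios and clone support", {
  co <- simulate_coamplification(sim_config(seed = 2), n_individuals = 20)
  reads <- data.frame(sequence = c("AA", "AA", "CC"),
                      replicate = c("r1", "r2", "r1"))
  rep <- paralog_report(co$geno, n_all_het_trios = 15,
                        clone_exp = clone_experiment("i", "l", reads))
  expect_equal(sort(rep$constant_het_sites), co$divergent_sites)
  expect_equal(rep$mendel_null_prob, 0.5^15)
  expect_equal(rep$supported_haplotypes, "AA")
  expect_equal(rep$copy_number_lower_bound, 1L)
  expect_output(print(rep), "constant-het sites")
})
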