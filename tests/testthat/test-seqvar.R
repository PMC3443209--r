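test_that("IUPAC consensus codes round-trip all unordered base pairs", {
  pairs <- t(combn(c("A", "C", "G", "T"), 2))
  pairs <- rbind(pairs, cbind(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  for (r in seq_len(nrow(pairs))) {
    code <- iupac_encode(pairs[r, 1], pairs[r, 2])
    expect_equal(sort(unname(iupac_decode(code)[1, ])), sort(pairs[r, ]))
  }
  expect_equal(iupac_encode("C", "T"), "Y")
  expect_equal(iupac_encode("T", "C"), "Y")  # order-free
  expect_equal(iupac_encode("A", "A"), "A")
  expect_equal(iupac_encode("G", "A"), "R")
  expect_error(iupac_encode("A", "N"), "non-nucleotide")
  expect_error(iupac_decode("B"), "not a diploid")
})

test_that("substitutions are classified by codon translation", {
  loc <- new_locus("toy", "ATTTCGGCA", frame_offset = 0)
  hit <- classify_substitution(loc, 1, "A", "C")      # ATT -> CTT
  expect_equal(hit$class, "nonsynonymous")
  expect_setequal(hit$residues, c("I", "L"))
  syn <- classify_substitution(loc, 6, "G", "A")      # TCG -> TCA
  expect_equal(syn$class, "synonymous")
  expect_equal(unique(syn$residues), "S")
  # symmetry in the two alleles
  expect_equal(classify_substitution(loc, 1, "C", "A")$class, hit$class)
  # stop codons are flagged, not dropped
  stop_loc <- new_locus("stop", "TACGCA")
  got <- classify_substitution(stop_loc, 3, "C", "A") # TAC -> TAA
  expect_true(got$stop_codon)
  expect_equal(got$class, "nonsynonymous")
})

test_that("classification errors are explicit", {
  loc <- new_locus("frame", "GCAGCAGC", frame_offset = 0)  # 8 bp: last codon incomplete
  expect_error(classify_substitution(loc, 8, "C", "T"), "untranslatable")
  expect_error(classify_substitution(loc, 40, "C", "T"), "outside")
  expect_error(classify_substitution(loc, 1, "X", "T"), "invalid allele")
  off <- new_locus("off", "CAGCA", frame_offset = 1)       # base 1 mid-codon
  expect_error(classify_substitution(off, 1, "C", "T"), "untranslatable")
})

test_that("classification agrees with brute-force full-sequence translation", {
  set.seed(42)
  for (rep in 1:5) {
    ref <- random_coding(30)
    loc <- new_locus("rnd", ref)
    for (m in 1:9) {
      pos <- sample.int(90, 1)
      old <- substr(ref, pos, pos)
      new <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
      got <- classify_substitution(loc, pos, old, new)$class
      mut <- ref
      substr(mut, pos, pos) <- new
      aa_ref <- as.character(Biostrings::translate(
        Biostrings::DNAString(ref), no.init.codon = TRUE))
      aa_mut <- as.character(Biostrings::translate(
        Biostrings::DNAString(mut), no.init.codon = TRUE))
      expect_equal(got,
                   if (aa_ref == aa_mut) "synonymous" else "nonsynonymous")
    }
  }
})

test_that("transition/transversion tallies decompose triallelic sites minimally", {
  expect_equal(unname(ti_tv_tally(data.frame(alleles = "A/G"))), c(1L, 0L))
  expect_equal(unname(ti_tv_tally(data.frame(alleles = "A/T"))), c(0L, 1L))
  # A/C/T: pivot C or T gives 1 ti + 1 tv; pivot A would give 2 tv
  expect_equal(unname(ti_tv_tally(data.frame(alleles = "A/C/T", ref = "A"))),
               c(1L, 1L))
  # invariant: classifications = diallelic + 2 * triallelic
  set.seed(7)
  sites <- data.frame(alleles = replicate(50, paste(
    sample(c("A", "C", "G", "T"), sample(2:3, 1)), collapse = "/")))
  tally <- ti_tv_tally(sites)
  n_tri <- sum(lengths(strsplit(sites$alleles, "/")) == 3)
  expect_equal(sum(tally), (nrow(sites) - n_tri) + 2L * n_tri)
})

test_that("diallelic ti/tv equals a per-site purine/pyrimidine check", {
  set.seed(11)
  alleles <- replicate(200, paste(sample(c("A", "C", "G", "T"), 2),
                                  collapse = "/"))
  tally <- ti_tv_tally(data.frame(alleles = alleles))
  pur <- c("A", "G")
  is_ti <- vapply(strsplit(alleles, "/"), function(p) {
    (p[1] %in% pur) == (p[2] %in% pur)
  }, logical(1))
  expect_equal(unname(tally), c(sum(is_ti), sum(!is_ti)))
})

test_that("amino-acid changes are classed by physicochemical category", {
  expect_equal(aa_change_class("Asn", "Asp"), "non-conservative")
  expect_equal(aa_change_class("Ile", "Leu"), "conservative")
  expect_equal(aa_change_class("Gly", "Gly"), "identical")
  expect_equal(aa_change_class("N", "D"), "non-conservative")
  expect_error(aa_change_class("Xyz", "Asp"), "unknown residue")
})

test_that("SNP tables are extracted from aligned haplotypes", {
  base <- strsplit(paste(rep("ACGT", 250), collapse = ""), "")[[1]][1:971]
  h1 <- paste(base, collapse = "")
  b2 <- base
  b2[154] <- "T"; b2[185] <- "T"; b2[369] <- "G"
  h2 <- paste(b2, collapse = "")
  tab <- haplotypes_to_snp_table(c(a = h1, b = h2))
  expect_equal(tab$sites$position, c(154L, 185L, 369L))
  # monomorphic alignment: empty site list
  expect_equal(nrow(haplotypes_to_snp_table(c(h1, h1))$sites), 0L)
  expect_error(haplotypes_to_snp_table(c("ACGT", "ACG")), "unequal")
  # random mutant set vs a brute-force column scan
  set.seed(3)
  seqs <- c(h1, vapply(1:4, function(i) {
    b <- base
    idx <- sample.int(971, 5)
    b[idx] <- vapply(b[idx], function(x) {
      sample(setdiff(c("A", "C", "G", "T"), x), 1)
    }, character(1))
    paste(b, collapse = "")
  }, character(1)))
  tab2 <- haplotypes_to_snp_table(seqs)
  m <- do.call(rbind, strsplit(seqs, ""))
  oracle <- which(apply(m, 2, function(col) length(unique(col)) > 1))
  expect_equal(tab2$sites$position, as.integer(oracle))
})

test_that("amino-acid variants never outnumber haplotypes", {
  set.seed(19)
  for (rep in 1:10) {
    ref <- random_coding(40)
    loc <- new_locus("rnd", ref)
    haps <- c(ref, vapply(1:3, function(i) {
      mut <- ref
      pos <- sample.int(120, 2)
      for (p in pos) {
        substr(mut, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                            substr(mut, p, p)), 1)
      }
      mut
    }, character(1)))
    aa <- vapply(haps, function(h) {
      as.character(Biostrings::translate(Biostrings::DNAString(h),
                                         no.init.codon = TRUE))
    }, character(1))
    expect_lte(length(unique(aa)), length(unique(haps)))
  }
})
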