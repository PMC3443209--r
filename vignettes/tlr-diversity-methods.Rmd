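---
title: "Methods: TLR SNP diversity analysis in small pedigreed populations"
author: "tlrpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TLR SNP diversity analysis in small pedigreed populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tlrpop)
```

## The problem

Severely bottlenecked wildlife populations -- here the motivating case is a
New Zealand robin population re-founded from 12 genetic contributors --
retain little neutral variation, and the question is whether functionally
important immune genes such as the Toll-like receptors (TLRs) still
segregate useful diversity. Answering it from Sanger amplicon sequencing of
a founder cohort raises a cluster of small-sample statistical problems that
this package solves as one pipeline:

* classifying each SNP as synonymous or non-synonymous from its codon
  context, and tallying transitions against transversions;
* deducing the genotypes of founders that died before sampling, from their
  genotyped mates and offspring, with explicit control of the probability
  that an allele goes undetected;
* phasing unordered Sanger genotypes into haplotypes using the pedigree;
* recognising when a primer pair coamplifies duplicated gene copies
  (paralogs), which masquerade as universal heterozygosity, and designing
  clone-sequencing experiments to dissect such loci;
* estimating heterozygosity, gene diversity, Hardy--Weinberg conformance
  and nucleotide diversity at n = 12 diploids, where asymptotic tests are
  meaningless; and
* testing for historical directional selection with the McDonald--Kreitman
  (MK) contrast against a second species.

Every generator needed to exercise the pipeline ships in the package
(`simulate_population()` and friends), with full ground truth, so each
method is validated against data whose answer is known.

## Sequence and variant model

A locus (`new_locus()`) is an amplicon with a reference sequence and a
reading-frame offset (0--2): the 0-based position within a codon of base 1.
Coordinates are 1-based within the amplicon, matching how SNP positions are
reported in amplicon surveys. Genotypes are unordered allele pairs,
represented exactly as a Sanger chromatogram reports them: the base itself
when homozygous, the two-base IUPAC ambiguity code when heterozygous
(`iupac_encode()` / `iupac_decode()`).

`classify_substitution()` translates the codon containing a site under each
allele with the standard genetic code and compares residues. A variant
producing a stop codon is flagged (`stop_codon = TRUE`) but still
classified -- silently dropping it would bias non-synonymous counts. Sites
in an incomplete terminal codon raise an explicit error rather than
guessing a frame.

Transition/transversion tallies (`ti_tv_tally()`) count one classification
per diallelic site. A triallelic site is decomposed into exactly two
changes around a pivot allele. The pivot is chosen to minimise the number
of transversions, with ties broken toward the reference allele. This is a
genuine convention choice: surveys typically count a triallelic site as
*one* SNP but classify *two* changes, and the minimal-transversion pivot is
the only decomposition consistent with treating the transition as the
more probable mutational route. For an A/C/T site it yields one transition
(C--T) plus one transversion, never two transversions.

Amino-acid changes are graded conservative/non-conservative by fixed
physicochemical categories: nonpolar {A V L I P F M W G}, polar uncharged
{S T C Y N Q}, positive {K R H}, negative {D E}. These categories follow
the common usage in which Asn is "polar" and Asp "negatively charged", so
Asn/Asp is non-conservative.

### The published SNP panel and its synthetic references

`robin_snp_panel()` carries the 24 SNPs of the motivating survey (position,
alleles, residues per locus). The survey does not print the surrounding
sequence, so `robin_reference_loci()` *constructs* synthetic reference
amplicons whose codon at each SNP position encodes exactly the printed
residues under the printed alleles. The constructor searches, per locus,
for the smallest frame offset under which every printed residue pair is
realisable (offset 1 for TLR7 -- its Ser/Gly site is only realisable at a
first codon position -- and 0 elsewhere), and for each SNP solves for the
two non-SNP bases of the codon; the printed residue order is treated as an
unordered set because surveys do not always list residues in allele order.
These references are explicitly synthetic stand-ins: they reproduce the
panel's codon-level behaviour, not the deposited sequences.

## Pedigree inference

`trio_consistent()` is the elementary predicate: an offspring genotype is
Mendelian-consistent with a parental pair if it can be assembled from one
allele of each parent. `infer_missing_parent()` filters every possible
genotype of an unsampled parent through this predicate against all sampled
offspring (jointly over both parents when neither is sampled). The result
is a consistent set flagged `unique`, `ambiguous` or `inconsistent`; an
empty set is a data-quality signal (genotyping error or paralog
coamplification) and is reported, never "corrected".

The design arithmetic is deliberately simple. A heterozygous unsampled
parent hides its second allele from k offspring with probability
$(1/2)^k$ (`nondetection_probability()`), so five offspring bound
nondetection below 3.5% ($2^{-5} = 0.03125$), and `min_offspring_for()`
inverts the bound. `run_founder_inference()` orchestrates the per-site
inference across a genotype matrix, taking the candidate alleles of a site
from everything segregating in the genotyped population (not just the
brood), which is how a survey in practice knows a site's allele set.

## Pedigree-assisted phasing

`phase_by_pedigree()` resolves unordered genotypes into haplotype pairs in
two stages:

1. **Constraint propagation.** Each individual starts with every haplotype
   pair consistent with its genotype (homozygous sites anchor phase, so an
   individual with h heterozygous sites has $2^{h-1}$ candidates). Each
   parent--offspring link then requires that the offspring's two
   haplotypes be transmissible, one from each parental side; candidate
   pairs violating every assignment are pruned, iterating to a fixpoint.
   Individuals reduced to a single pair are flagged `certain` --
   such calls are forced by Mendelian logic alone and are exact whenever
   transmission is faithful.
2. **EM over haplotype frequencies.** Residual ambiguity is resolved by
   maximum likelihood under random union of gametes: frequencies start
   uniform, expectations weight each surviving pair by $f_a f_b$ (doubled
   for heterozygous pairs), and iteration stops when the largest frequency
   change falls below $10^{-6}$ or after 500 iterations. Ties are broken
   lexicographically so results are deterministic. These calls are flagged
   `uncertain`.

A coalescent-based phasing model is intentionally out of scope: at the 2--5
haplotypes per locus typical of bottlenecked cohorts, the pedigree plus EM
resolves phase adequately and deterministically. A contradiction between
pedigree and genotypes flags the individual `inconsistent`; the
contradiction is contained (an inconsistent individual is treated as
uninformative for its relatives) rather than propagated.

## Paralog detection and clone design

When one primer pair amplifies two diverged gene copies, every fixed
inter-copy difference appears heterozygous in every individual.
`constant_het_scan()` flags sites whose call-level heterozygosity reaches a
threshold (default 1.0, i.e. all individuals); sites heterozygous in some
but not all individuals are reported separately as candidates for
within-copy polymorphism. Chromatogram peak heights, which wet-lab
workflows also use here, are not recoverable from genotype calls, so the
scan keys on call-level heterozygosity alone -- the threshold is
configurable for noisy data.

The pedigree gives an orthogonal signal: at a true diallelic locus, two
heterozygous parents produce heterozygous offspring half the time, so
observing all-heterozygous parent/offspring trios n times has Mendelian
null probability $(1/2)^n$ (`all_het_trio_probability()`; $3 \times
10^{-5}$ at n = 15).

Clone experiments dissect a coamplified locus. The number of clones needed
is a multinomial coverage problem solved exactly by inclusion--exclusion
(`clone_coverage_probability()`): for haplotype frequencies $f_i$,
$P(\text{all seen}) = \sum_S (-1)^{|S|} (1 - \sum_{i \in S} f_i)^n$.
Twenty-four clones cover four equifrequent haplotypes (two heterozygous
gene copies) with probability 0.99599, conventionally quoted as 99.6%;
`min_clones_for()` inverts the formula and, because such targets are quoted
at 0.1% precision, treats coverage within `tol = 5e-4` of the target as
attaining it (set `tol = 0` for a strict bound). Exactness is preferred
over simulation at these desk scales (k ≤ 8); simulation is retained only
as a test oracle.

PCR chimeras are guarded by replicate support
(`replicate_supported_haplotypes()`): artefacts arise independently per
amplification, so sequences seen in ≥ 2 independent PCR replicates are
accepted and the rest listed as chimera/error candidates. Clone sequences
are compared by exact string match -- no clustering -- so a polymerase
error surfaces as an unsupported singleton rather than being absorbed.
`copy_number_bound()` converts n supported haplotypes into the minimal
copy number $\lceil n/2 \rceil$ (five haplotypes imply at least three
coamplifying copies). Distinguishing "three copies" from "two copies plus
in vitro recombination" is explicitly not attempted; the data cannot
decide it.

## Diversity statistics at founder-cohort sizes

All estimators carry small-sample corrections appropriate to n ≈ 12
diploids:

* **Observed heterozygosity** is the fraction of heterozygous individuals.
* **Gene diversity** uses Nei's unbiased estimator
  $H_E = \frac{2n}{2n-1}(1 - \sum_i p_i^2)$. At n = 12 this 24/23
  correction is what reconciles integer allele counts with published
  three-decimal values (e.g. counts 11:13 give 0.518).
* **Hardy--Weinberg conformance** uses a fully enumerated exact test
  (`hwe_exact_test()`): conditional on allele counts, a configuration with
  h heterozygotes has probability $n!\,2^h \prod_a n_a! \,/\,
  (\prod_g n_g!\,(2n)!)$, and the two-sided p-value sums all
  configurations no more probable than the observed one (probability
  ordering). Enumeration is preferred over the usual Markov-chain
  approximation because at these sizes it is instant and exact --
  configuration probabilities are verified to sum to 1 inside every call
  -- whereas chain estimates wobble in the third decimal. The enumeration
  is meant for desk scale (tens of diploids, a handful of alleles);
  configuration counts explode beyond that.
* **Nucleotide diversity** is sample-corrected mean pairwise difference
  per site, $\pi = \frac{2n}{2n-1}\sum_{i<j} 2 p_i p_j d_{ij} / L$, with a
  standard error from the Nei (1987, eq. 10.7)/Tajima stochastic variance
  $V(\pi) = \frac{m+1}{3(m-1)L}\pi + \frac{2(m^2+m+3)}{9m(m-1)}\pi^2$
  (m = gene copies). Published surveys rarely state which variance formula
  they used, so the reported SE should be compared across studies with
  care.
* **Reporting** rounds half-up to 3 decimals (table convention, not
  banker's rounding) and scales π by $10^4$; undefined statistics at
  monomorphic loci render as `-`.

Statistics can be computed at the amino-acid-variant level or the
haplotype/nucleotide level; the level is simply the labelling of the
variant matrix passed to `locus_summary()`.

### Known discrepancies in the reference survey

The package reproduces the motivating survey's tables from reconstructed
integer genotype configurations (`robin_founder_genotypes()`), with three
documented exceptions it deliberately does not force:

* the survey's TLR1LB exact-test p-value prints as 0.104 where full
  enumeration gives 0.103 (third-decimal wobble of a chain-based
  estimate);
* the survey's TLR2B gene diversity (0.591) is unattainable from two
  variants at n = 12 (maximum 0.522) and no three-count integer
  configuration gives exactly 0.591 either; the fixture uses the closest
  consistent three-haplotype reconstruction (counts 12:10:2, $H_E$ =
  0.594), so the reproduced mean $H_E$ is 0.478 against the printed 0.477;
* the survey reports mean multilocus heterozygosity 2.83 of 7 loci while
  its own per-locus heterozygote counts sum to 35/12 ≈ 2.92;
  `multilocus_heterozygosity()` reports what the data imply and the
  discrepancy is surfaced rather than matched.

## McDonald--Kreitman tests

`classify_sites()` walks a codon-aligned pair of species haplotype sets
and assigns each varying site to polymorphic (variable within either
species) or fixed (invariant within each, different between), and each
change to synonymous/non-synonymous via the codon context. A site
polymorphic in both species is counted once, as polymorphic; sites with
three states are decomposed by the same minimal-transversion pivot rule as
the ti/tv tally. Alignments are inputs: codon alignment construction is
out of scope.

`mk_report()` assembles the 2×2 table and tests association with the G
test, $G = 2\sum O \ln(O/E)$ with 1 df ($0\ln 0 = 0$; Williams-corrected G
available via `williams = TRUE`), reporting Fisher's exact p alongside,
the neutrality index $NI = (P_n/P_s)/(D_n/D_s)$ (undefined on zero
margins), and the non-synonymous fractions among fixed and among
polymorphic sites. An excess non-synonymous fraction among fixed
differences with p < 0.05 is flagged as consistent with directional
selection. The survey's own significant locus (TLR1LB: 51% non-synonymous
among fixed vs 24% among polymorphic, G = 6.62, p = 0.010) requires the
second species' deposited alignments, which the package does not download;
the machinery is validated instead on simulated divergence with labelled
truth, where the neutral type-I error of the α = 0.05 G test is checked to
be nominal over 2,000 replicates and the directional scenario to be
flagged.

## The synthetic-data generator

`sim_config()` fixes the study conditions; its defaults are the
motivating design, not tuning knobs: 12 founders (5 female, 7 male),
~1 kb amplicons (1,006 bp), 2--5 haplotypes per locus with
symmetric-Dirichlet frequencies, up to 7 (default 5) genotyped offspring
per breeding pair, a 947 bp coamplified paralog pair diverged at 8 sites,
clone experiments of 24 reads (the study sequenced 24--33) across 3
independent PCR replicates with a 5% chimera rate, and a two-species
divergence scenario sized so fixed differences outnumber polymorphic sites
(600 bp, 50 fixed changes, Poisson(25) segregating sites per species).

Randomness derives from one master seed forked into named streams (one
per generator and locus), so adding a generator never perturbs existing
output, and every emitted observable is byte-reproducible from the
configuration. Truth bundles record haplotypes, transmissions, planted
divergent sites, chimera provenance and per-site MK cells; tests verify
that re-deriving the observables from truth reproduces them exactly.

What the generator emulates -- fair Mendelian transmission, random union
of gametes, multinomial clone sampling, single-crossover chimeras, one
substitution per codon in the divergence scenario -- is what the methods
assume. What it does not emulate matters for interpreting green tests:
there is no genotyping error (beyond chimeras), no recombination within
amplicons, no allele dropout, no missing data, and mutation is placed
uniformly without rate heterogeneity. Passing tests therefore show the
machinery is correct under its stated model, not that real chromatograms
are this clean.

## Validation scale and numerical choices

The shipped test-suite checks run at the following sizes, chosen to keep
three-standard-error bands tight while remaining desk-scale: full HWE
enumeration against an independent random-pairing oracle for *every*
genotype table with up to 8 diploids and 3 alleles; 10^5 simulated broods
per offspring count for the allele-nondetection curve; 10^6 multinomial
draws for clone coverage; 2,000 neutral MK replicates; the paralog scan on
50 seeds and phasing truth-match on 100 seeded pedigrees. Replicate
support of clone haplotypes is checked at 33 clones, the top of the
study's sequencing range, where the probability that some true haplotype
lands in fewer than two of three replicates is ~2% (at 24 clones it is
~11% by the same exact computation -- a design observation, not a
failure).

Numerical conventions: probability comparisons in the exact test use a
relative tolerance of 10^-9 to absorb floating-point ties; EM convergence
is 10^-6 with a 500-iteration cap and lexicographic tie-breaks; reported
tables round half-up to 3 decimals. Degenerate inputs (monomorphic loci,
empty MK tables, zero-offspring broods, negative counts) error or render
`-` explicitly rather than returning silent zeros.

## Limitations

The exact HWE enumeration and the inclusion--exclusion coverage formula
are exponential in allele/haplotype count and are intended for the small
cohorts this package targets. Phasing assumes the pedigree is correct;
parentage assignment is out of scope. The paralog scan cannot see peak
heights and so approximates "uniform double peaks" by call-level
universality. The MK implementation takes codon alignments as given and
implements the classical contrast only (no HKA, no dN/dS estimation).
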