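---
title: "Methods: methylome inheritance and allelic expression in F1 trios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylome inheritance and allelic expression in F1 trios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its models, the choices made
where conventions were genuinely open, and what the synthetic-data tests
do and do not establish.

## Data model

All coordinates are 1-based inclusive in memory; BED is converted to
0-based half-open only at the file boundary. A methylation call record is
one cytosine on one strand: a plus- and a minus-strand record at a CG
dyad are distinct and never pooled, and a cytosine's context (CG, CHG,
CHH; H = A/C/T) is read 5′→3′ on its own strand. The methylation level of
a covered site is mC/C = `mc_count / total_count`; zero-coverage sites
are carried in the tables (they arise naturally under Poisson coverage)
and excluded by each consumer's coverage filter (default `min_cov = 4`).

## Methylated-site calling and the conversion rate

Bisulfite conversion is imperfect: an unmethylated cytosine reads as
methylated with probability `fail_rate`. The conversion rate is estimated
as 1 − pooled mC/C on the unmethylated lambda spike-in, and a site is
called methylated when a one-sided binomial test of `mc_count` out of
`total_count` against `fail_rate` rejects at `alpha = 0.05`. At ~15×
coverage a raw "≥ 1 methylated read" rule would be dominated by
conversion noise (P ≈ 0.058 of ≥ 1 false methylated read per site at
fail 0.006), which is why the statistical call is also used for PSMS
rule (v) below. BH correction across sites is available behind a flag
and off by default, since the genome-wide tally is the quantity of
interest rather than per-site error control.

## DMRs

Window geometry is not fixed by any single convention; we default to
1 kb windows with a 100 bp step, requiring ≥ 5 sites of the context
covered ≥ 4× in *both* samples (windows are defined on the two samples
being compared; F1 coverage is not required for parental windows). The
test statistic is a two-sided Fisher exact p on the window's pooled
methylated/unmethylated read counts, and the effect criterion is a
pooled-level fold change ≥ 2, computed as `(level_a + ε)/(level_b + ε)`
with ε = 0.001 so that fully unmethylated windows do not divide by zero.
Significant same-direction windows that overlap or are book-ended merge;
the merged region reports recomputed pooled levels and the minimum
window p, and is re-checked against all three thresholds so that every
emitted DMR satisfies them (a merged extent can in principle dilute the
fold change below 2; such regions are dropped rather than reported
inconsistently).

Parental-DMR inheritance is operationalised purely by interval overlap,
mirroring a three-set Venn construction: a parental DMR is LIKE_FATHER
iff it overlaps (≥ 1 bp) an F1-vs-mother DMR whose direction matches the
parental difference and overlaps no F1-vs-father DMR; LIKE_MOTHER
symmetrically; otherwise UNRESOLVED. No secondary equivalence test is
applied. The Venn table reports, for each source set, counts by overlap
pattern with the other two sets (overlap counts between interval sets
are not symmetric, so per-source patterns are the faithful summary).

## DMSs and the eight-way classification

Per-site two-sided Fisher exact tests are computed for the three sample
pairs at sites covered ≥ `min_cov` in all three samples; a site is a DMS
when any pairwise p < 0.01 (raw, uncorrected — BH is available behind a
flag). The eight-way classification is driven by the significance
pattern plus level ordering; the published taxonomy names the classes
but not an algorithm, so the branch structure here is this package's
operationalisation, chosen so each prose definition maps to exactly one
branch and the classes partition all DMS inputs:

* parents differ (p_ab < α): ADDITIVE iff the F1 differs from both
  parents and lies strictly between them; LOW_PARENT / HIGH_PARENT iff
  the F1 is indistinguishable from that parent and distinguishable from
  the other; ABOVE_HIGH_PARENT / BELOW_LOW_PARENT iff the F1 differs
  from both and lies outside the parental range; else AMBIGUOUS.
* parents equal (p_ab ≥ α): ABOVE_PARENT / BELOW_PARENT iff the F1
  differs significantly from both parents in the same direction; else
  AMBIGUOUS.

Sites under-covered in any sample are *excluded*, not labelled
AMBIGUOUS: "untestable" and "unclassifiable" are different states, and
only the latter belongs in the Ambiguous class. Whether the published
Ambiguous fraction includes low-coverage sites is unstated; our
convention is documented, not attributed.

The Fisher implementation vectorises the standard two-sided
minimum-likelihood rule over `stats::dhyper`, computing each distinct
2×2 table once; tests verify exact agreement with both
`stats::fisher.test` and a from-first-principles hypergeometric
enumeration oracle for totals ≤ 200.

## Allelic expression

PSNPs are biallelic SNPs with homozygous-different parents and a
heterozygous F1. Per-gene allele counts are the *mean* over the gene's
covered PSNPs of per-SNP allele reads (a sum would confound bias calls
with PSNP density; sums are available behind a flag), rounded to
integers because the exact test's support is integer.

TMM factors follow the doubly-trimmed (30% on M, 5% on A),
inverse-variance-weighted mean of log-ratios against a reference
library. The reported factor folds the library-size ratio in (identical
libraries → factors 1; an exact 2× library → factors (1/√2, √2) after
rescaling to geometric mean 1), so dividing counts by the factor makes
libraries directly comparable; the edgeR convention separates the
library size from its norm factor, and the test suite checks our factors
against `edgeR::calcNormFactors` after converting conventions.

The bias test is an exact conditional test: for two independent
negative-binomial counts with equal means and common dispersion d, the
first count given the pair total is beta-binomial with both shapes 1/d
(binomial at d = 0). Two-sided p-values sum conditional probabilities of
outcomes no more likely than observed. The common dispersion is
estimated by the method of moments on the conditional variance
(E[(x1−x2)²/n] = 1 + (n−1)·d/(d+2)), floored at 0. A gene is called
biased only when p < 0.05 *and* the normalised fold reaches 1.5; the
published method states the distribution and the fold threshold but not
α, which we set to 0.05 and expose. The fold is computed on normalised
counts (also unstated in the source; documented here).

## PSMS identification

The five conjunctive rules: (i) parents homozygous-different at a
C↔non-C SNP; (ii) F1 heterozygous with exactly the two parental alleles;
(iii) genotype–WGBS consistency; (iv) zero methylation support on the
non-cytosine allele (taken literally, no tolerance); (v) the F1 cytosine
is methylated. Two rules need operationalisation. Rule (iii): bisulfite
reads cannot genotype a C→T variant directly (conversion mimics the
variant), so consistency is checked as presence/absence concordance of
methylome records — the cytosine-carrying parent must have a record at
the position and strand, the other parent must not. Rule (v): the
binomial-vs-conversion-failure call at α = 0.05 rather than
"≥ 1 methylated read", for the noise reason given above. The
allele-resolved F1 methylation table is a required input (the simulator
emits it; producing it from alignments is out of scope), and its absence
is an error because rule (iv) is otherwise unevaluable.

Origin attribution is structural: the origin parent is the one whose
genotype carries the cytosine. On error-free genotypes the rules are
sound by construction (precision 1 in the recovery tests); recall is
limited by coverage through rule (v).

## The synthetic data generator

The generator's defaults state the world the analysis assumes: 2
chromosomes × 250 kb, SNP rate 0.005/bp with half the SNPs exchanging a
cytosine for A/T in exactly one parent (the remainder are A↔T swaps,
the only substitution class that cannot create or destroy a cytosine on
either strand), Poisson coverage with mean 15, conversion failure 0.006,
Beta-distributed per-site methylation propensities per context
(CG ~ Beta(4,1), mean 0.8; CHG ~ Beta(3.5,1.5), mean 0.7;
CHH ~ Beta(1,4), mean 0.2), and 300 genes of 500–1200 bp (gene length is
not externally constrained; at the stated 300 genes per 500 kb, genes
longer than ~1.5 kb cannot be placed without overlap, so the default is
set below that bound).

Two region-level processes (10 kb grid) create the structure the
downstream stages detect. *Inheritance modes* are drawn per region from
{additive 0.6, maternal-like 0.15, paternal-like 0.15, above-parent
0.05, below-parent 0.05}: additive regions pass both parental
propensities to the F1 alleles unchanged; parental-like regions copy one
parent onto both alleles; transgressive regions shift both alleles
beyond the parental range by 0.3. *Regional parental divergence*
(rate 0.2, one parent shifted strongly up and the other down) is what
makes the two parents differ at the window scale: without it, iid
per-site propensity draws average out within 1 kb windows and the
parental DMR set is empty, which is not the world a two-species
comparison assumes. F1 reads choose an allele by a fair coin; at
C↔non-C SNPs the non-cytosine allele contributes coverage but never
methylation support, and the parent lacking the cytosine emits no
record.

Allelic RNA counts: each gene's latent expression is Gamma-distributed
so per-SNP totals are negative-binomial (mean 300, dispersion 0.1), and
reads split between alleles binomially — fair for unbiased genes, at
odds fold:(1) for the 10% of genes with a true 3-fold bias. The split
is binomial rather than two independent NB draws because
allele-specific counts from a single RNA library arise by assigning
reads of one pool to alleles; gene-level dispersion then lives in the
totals, and the between-allele overdispersion that the dispersion
estimator measures is near zero under the null. (The estimator is still
validated against independently drawn NB pairs, where it recovers the
true dispersion.)

What a green recovery test establishes: the pipeline's rules are
internally consistent with the generative model (PSMS precision 1,
allelic-bias sensitivity ≥ 0.8 at the stated effect size, conversion
rate within binomial error). What it does not establish: robustness to
mapping bias, genotyping error, non-independent coverage, repeat-driven
multi-mapping, or the real effect-size spectrum of diverged species —
none of which the generator emulates. Note also that regional parental
divergence induces *genuine* allele-specific methylation at PSMSs inside
divergent regions (the cytosine-carrying allele inherits the shifted
parental propensity), so the allelic-methylation rank-sum test rejects
above its nominal rate on default simulations; calibration is tested on
configurations with divergence disabled.

## Integration

Per-allele methylation for a gene is the mean F1 cytosine-allele level
over PSMSs of that origin. The allelic methylation test compares the two
origins' per-PSMS level lists: the rank-sum test (unpaired, since the
two alleles' PSMS sets are different positions) uses full enumeration
with mid-ranks for small groups and the tie-corrected normal
approximation otherwise; Welch's t-test is run on the subset of genes
whose per-allele levels pass a Shapiro normality screen (p > 0.05 both
alleles). The published analysis applied the two tests "sequentially"
with cohort sizes that are not derivable from its text; we run both and
report both rather than invent the gating.

## Numerical and degenerate-input conventions

* Fisher two-sided p: sum of table probabilities ≤ observed × (1+1e−7),
  the same floating-point tie guard `fisher.test` uses; p capped at 1.
* Fold changes: ε = 0.001 pseudo-level (DMR); +0.5 pseudo-count on
  log2 allelic fold for volcano output; exact-test fold uses raw
  normalised counts (Inf when one allele is 0, NONE when both are 0).
* Ties in inheritance classification (F1 exactly at a parental level)
  fall through to AMBIGUOUS rather than being forced into a class.
* `estimate_dispersion` needs ≥ 20 genes, uses pairs with total ≥ 2,
  and floors at 0; degenerate all-equal input returns 0.
* Identical lists in the rank-sum test return p = 1; constant unequal
  lists in the t-test return p = 0 (the limit of the Welch statistic).
* All randomness flows from one integer seed; stage generators use
  fixed small offsets (seed, seed+1, seed+2), keeping every derived
  seed well below 2³¹.

## Known limitations

DMR window geometry, the mC-calling rule, the bias-test α and the
Wilcoxon/t gating are all unstated in the source method descriptions;
each choice here is explicit, tested and configurable, but none is
claimed to reproduce the original pipeline bit-for-bit. Genome-scale
published counts (tens of thousands of DMRs, 236k PSNPs, 122k PSMSs)
require the original sequencing data and are out of desk-scale reach;
the package instead verifies every published *proportion* from its
printed numerator/denominator pairs and all statistical machinery
against independent oracles.
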