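---
title: "Dissecting a trait into a QTL-allele system: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting a trait into a QTL-allele system: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtlallele)
```

## The problem

Breeding against a leaf-feeding pest such as the common cutworm
(*Spodoptera litura*) needs more than a handful of major resistance genes:
in a germplasm population the trait -- antixenosis, measured as the damaged
leaf percentage (DLP, 0--100%) at the seedling stage -- is typically
governed by many loci, each segregating for several haplotype alleles.
Bi-parental linkage mapping sees at most two alleles per locus, and
standard single-locus SNP GWAS sees exactly two. This package implements
the alternative the restricted two-stage multi-locus (RTM) approach takes:
group SNPs into linkage-disequilibrium blocks whose haplotypes act as the
multiple alleles of one marker, fit all loci jointly by stepwise selection
under a heritability budget, and then use the resulting loci-by-accessions
*QTL-allele matrix* as the substrate for breeding design -- cross
prediction, group differentiation, and candidate-gene annotation.

## Phenotype model

A plot's DLP is scored several times as damage progresses. The plot value
is a weighted average that up-weights the observation times at which the
population spreads out most:

$$P_i = \frac{CV_i}{\sum_j CV_j}, \qquad PM = \sum_i P_i\,Y_i,$$

where $CV_i$ is the coefficient of variation of the observed values across
accessions at time $i$. We compute the $CV_i$ within each environment:
cross-accession dispersion at a given time is the only CV that
distinguishes observation times, and damage trajectories differ between
environments. Weights are non-negative and sum to one, so $PM$ is always
bounded by the observed range.

Variance components come from the expected mean squares of the balanced
genotype $\times$ environment ANOVA with replication ($a$ genotypes, $n$
environments, $r$ replicates):

$$h^2 = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_{ge}/n + \sigma^2_e/(nr)}$$

(single environment: $h^2 = \sigma^2_g/(\sigma^2_g + \sigma^2_e/r)$), with
$GCV = \sigma_g/\mu$. Genotype is tested against the G$\times$E mean
square, G$\times$E against the residual. Method-of-moments estimates can
go negative in finite samples; we truncate at zero and flag the component,
which is the standard EMS practice. For balanced layouts the closed-form
sums of squares are used directly (they agree with `aov()` to machine
precision and avoid building a several-thousand-column design matrix);
unbalanced tables are accepted with a warning and treated by cell means.
Multiple-comparison letters for group means use Duncan's new multiple
range test, computed from studentized-range quantiles at protection level
$1-(1-\alpha)^{p-1}$; Tukey HSD is available as an alternative.

## SNPLDB markers

Input genotypes are from fully inbred (selfing) accessions, so residual
heterozygous calls (already filtered to $\le 20\%$ per SNP, together with
missing rate $\le 20\%$ and MAF $\ge 1\%$) are set to missing and
haplotypes are read directly off the homozygotes -- no statistical phasing
is needed. Remaining missing calls are filled by the per-SNP mode before
block construction so every accession has a complete haplotype.

Blocks are grown greedily left to right along each chromosome: the next
SNP joins the current block iff its $D'$ with *every* SNP already in the
block exceeds 0.7 and the block span stays within a cap (default 200 kb).
The all-pairs criterion makes the guarantee "within-block $D' > 0.7$" hold
by construction; the span cap is our addition -- greedy merging with a
pairwise criterion can otherwise chain drifted haplotypes into
chromosome-scale blocks. Unmerged SNPs stay as biallelic singleton
markers, so the partition covers every SNP exactly once.

Each block's haplotype strings become the alleles of one multi-allelic
marker. Haplotypes rarer than 1% (mirroring the MAF filter) are pooled
into a single `rare` allele, which keeps the allele count per marker
interpretable and the design matrix well-conditioned; markers left with a
single allele are dropped. Population structure is summarised by the
accession-by-accession proportion of SNPLDB alleles shared
identical-in-state; the top eigenvectors (default 10 -- the number is a
free parameter, as similarity-matrix structure correction does not
prescribe one) enter the scan as fixed covariates. Note the leading
eigenvector of an uncentered similarity matrix is close to constant and is
absorbed by the intercept; subpopulation contrasts appear from the second
axis on.

## The two-stage multi-locus scan

Stage 1 fits each marker singly in a fixed-effect model with environment
and structure covariates and keeps markers whose allele-term F-test
reaches an unadjusted 0.05. This is deliberately liberal: its only job is
to shrink the candidate set for the multi-locus stage. Because the
accession-by-environment rows of one accession share its genotypic value,
the single-marker test is anti-conservative as a test -- another reason
its threshold is treated as a screen, not an inference.

Stage 2 builds the multi-locus model by forward selection and backward
deletion over the preselected markers. A forward step adds the candidate
with the smallest partial-F p-value if

1. it reaches the entry threshold, and
2. the cumulative genetic $R^2$ of the model stays within the
   *heritability cap* -- the trait's own $h^2$ estimate. A QTL system
   cannot explain more variance than is genetic, and the cap is what keeps
   stepwise accretion from absorbing noise once the true signal is
   exhausted.

Backward steps delete any included marker whose partial-F p-value exceeds
the retention threshold; the loop runs to convergence with ties broken by
smaller p-value, then smaller chromosome/position. After the main-effect
model stabilises, marker-by-environment (QEI) terms are scanned the same
way with the main effects held fixed, so a locus can carry a main effect,
a QEI effect, or both.

In the default `bonferroni` mode the entry/retention alphas are divided by
the **total** number of markers scanned in stage 1, not by the preselected
count. Preselection conditions on small p-values, so correcting only over
the survivors would not control the family-wise rate (with \~5% retention
the null family-wise error would be \~60%, not 5%); dividing by the full
scan size restores it, which our null simulations confirm (about 1 run in
20 admits a spurious locus). An `"unadjusted"` mode (`correction =
"none"`) mirrors a plain p = 0.05 threshold.

Per-locus summaries are Type-III: each term's partial sum of squares over
the total phenotypic sum of squares, in percent. Allele effects are the
least-squares estimates under an unweighted sum-to-zero constraint per
locus; negative effects lower DLP, i.e. increase resistance. Loci are
named `q-DLP-<chromosome>-<rank>` with the rank assigned by physical
position, and classified LC (large contribution, $R^2 \ge 1\%$, boundary
inclusive) or SC.

## QTL-allele matrix and cross prediction

The detected main-effect loci and their allele effects are assembled into
the loci $\times$ accessions matrix; each cell is the effect of the allele
that accession carries, and the fitted grand mean $\mu$ is stored so that
$\mu$ + column sum predicts an accession's genotypic value. Rare-collapsed
alleles carry their estimated joint effect, keeping the matrix complete.

For every unordered parent pair we simulate fully homozygous recombinant
inbred progenies directly: per chromosome, parental origin follows a
Markov chain over the loci -- the first locus comes from either parent
with probability 1/2, and each later locus switches origin with
probability $R$ (linkage model) or 1/2 (independent assortment). For
selfed inbred lines the appropriate two-locus recombination fraction is
$R = 2r/(1+2r)$; simulating the terminal inbred directly (one recombinant
gamete, doubled) is valid because the percentile statistics only need the
F$_\infty$ marginal distribution, and the $R$ transform already encodes
the extra effective recombination of repeated selfing. No genetic map
accompanies the marker set, so physical positions are converted at a
configurable 1 cM/Mb and mapped to $r$ by the Haldane function; this is a
documented stand-in, not an estimate of the real recombination landscape,
which is why published cross-value tables are not expected to reproduce
numerically. Progeny values are pure genotypic values ($\mu$ plus summed
allele effects, no residual noise), matching the notion of a *predicted
genotypic* cross value.

Each cross is summarised by type-7 (linear interpolation) percentiles; the
25th percentile is the predicted cross value -- a deliberately moderate
selection intensity. Crosses whose P25 falls below the observed population
minimum are the transgressive, "optimal" crosses, and the population's
recombination potential is reported as mean, maximum improvement
(population mean minus best P25) and maximum transgression (population
minimum minus best P25). Per-cross child seeds derive from the sorted
parent indices and the master seed, so results are independent of
execution order.

## Group differentiation and candidate genes

Accessions are ranked by DLP and split 20/60/20 into susceptible (SV,
highest DLP), moderately resistant (MRV) and resistant (RV, lowest DLP)
groups, tails of size $\lfloor 0.2N \rfloor$ and ties broken by accession
id. Allele frequencies are computed per group, and an allele's change
between groups is classified by a presence/absence rule: *increased* iff
absent in the reference group and present in the derived one, *decreased*
for the reverse, *inherent* otherwise. Frequency shifts that do not cross
zero are inherent -- this strict rule is the one whose counts reproduce
the published group-change tables exactly, which is the package's core
regression test for this module. The union comparison ("MRV and RV
compared to SV") unions the two pairwise classifications. Gene
annotations are joined by locus, since genes are annotated from QTLs
rather than mapped directly.

Candidate genes are sought within a closed 50-kb window flanking the
SNPLDB span (not its midpoint); a gene qualifies when the most significant
contingency chi-square (no continuity correction) between the marker's
haplotype alleles and any SNP inside the gene reaches p = 0.05, with no
multiple-testing correction across genes by default (a Bonferroni switch
exists). Low expected cell counts are flagged. The eight GO
biological-process categories (I--VIII) are input labels carried through
to the tallies, not derived from the GO graph.

## The synthetic-data generator

Nothing in the original study's raw data is deposited, so the generator is
a first-class module that emulates the study design: 370 inbred
accessions, 20 chromosomes, 3 environments $\times$ 3 replicates, a
population mean DLP of 44.5% and a target broad-sense heritability of
0.77, with marker density reduced to 100 SNPs on 3 Mb per chromosome so
the full pipeline runs in seconds.

* **LD** comes from a block-copy model: chromosomes are cut into segments
  with exponential lengths (mean 100 kb); each segment carries 2--4
  founder haplotypes built by single-mutation descent (every SNP mutates
  on exactly one edge of a founder tree), so any within-block SNP pair
  shows at most three gametes and has $D' = 1$, while blocks assort
  independently. This gives the block builder a sharp, known truth.
* **QTLs** are designated blocks; their haplotypes are the true alleles
  (2--6 per locus). Effect vectors are drawn normal and standardised to a
  common spread (default 3 DLP points), so every planted locus is a
  well-defined signal while realised contributions still vary through
  allele frequencies.
* **Noise** is solved, not tuned: given the realised genotypic variance,
  $\sigma^2_{ge}$ is a configured fraction of $\sigma^2_g$ (default 0.2)
  and $\sigma^2_e$ is set from the $h^2$ formula so the realised
  heritability matches the target; an unreachable combination is a
  configuration error, not a silent rescale.
* **Repeated observations** are an affine transform of the standardised
  plot values with time-varying spread, constructed so the CV-weighted
  average returns the plot value *exactly* -- the round trip through the
  phenotype module is a machine-precision test, not a statistical one.
  The CV profile argument is relative: only its ratios matter.
* **Seeds**: one master seed; each component draws from a child seed
  derived as `(48271 * master + 9973 * stream) mod (2^31 - 1)`, so any
  module can be regenerated independently and reruns are byte-identical.

What the generator does *not* emulate: admixed population structure beyond
independent block founders, LD decay calibrated to real soybean (the
block-span default is a free parameter, not a claim about the species),
sequencing error, or genotype imputation uncertainty. Passing tests
therefore demonstrate correctness of the machinery under the stated
model, not robustness to every artefact of real RAD-seq data.

## Numerical choices and degenerate inputs

* Perfect model fits (zero residual) are reported as $p = 0$ rather than
  undefined, so noise-free constructions behave sensibly.
* The heritability cap is compared with a $10^{-9}$ tolerance; an exact
  100% fit must not be rejected by floating-point rounding.
* All-zero CVs fall back to equal weights with a warning; a constant
  phenotype yields all-zero variance components with F and $h^2$ reported
  as undefined.
* Duplicate (collinear) markers contribute zero extra rank; the nested
  F-test then returns NA and the duplicate can never enter the model.
* Quantiles are type-7 everywhere, stated explicitly because percentile
  conventions differ across software.
* Coordinates are 1-based inclusive; window intersection uses closed
  intervals, so a gene at exactly 50 kb is a candidate.

## Problem sizes used in the validation suite

The packaged tests run the full machinery at reduced scale, chosen so the
suite completes in about a minute: a shared 80-accession, 4-chromosome
population for unit tests; twenty 400-accession, 10-QTL, $h^2 = 0.75$
replicates for scan recovery (detection and allele-effect correlation);
twenty 150-accession null replicates for family-wise error; and 2000
progenies per simulated cross, the same number the cross-prediction
defaults use. The acceptance script recomputes the published tables'
derived counts from the packaged reference data and reruns the recovery
study from scratch.

## Known limitations

* Variance components are method-of-moments, not REML; with severe
  unbalance prefer a mixed model.
* The scan is fixed-effect with eigenvector structure correction; no
  kinship random effect is fitted, so subtle relatedness beyond the top
  axes can inflate small contributions.
* Cross prediction ignores dominance, epistasis and residual variation --
  progeny values are additive genotypic values by design.
* The 1 cM/Mb map stand-in makes linkage-model outputs qualitatively,
  not numerically, comparable to analyses with a real map.
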