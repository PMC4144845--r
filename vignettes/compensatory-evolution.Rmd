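---
title: "Quantifying compensatory evolution after gene loss: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying compensatory evolution after gene loss: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compscape)
```

## The problem

When a non-essential gene is deleted, the resulting fitness defect is not
necessarily permanent: laboratory populations founded from slow-growing
deletion genotypes can recover fitness by accumulating mutations elsewhere
in the genome.  `compscape` implements the quantitative machinery needed to
measure this process in a large evolution experiment in which many deletion
genotypes, each represented by several independently evolving replicate
lines, are propagated alongside isogenic wild-type control lineages, and to
characterize the genomic, transcriptomic and environmental signatures of
the compensatory mutations.

The central difficulty is separating *compensation* (adaptation specific to
the deleted gene's defect) from *general adaptation* to the growth medium,
which the wild-type controls also experience.  Every statistic in the
package is therefore defined against the evolving-control null.

## Fitness from growth curves

Fitness is the maximum specific growth rate, estimated from plate-reader
OD time series as the maximum slope of `ln(OD - blank)` over a sliding
window (default 5 consecutive readings, `estimate_growth_rate()`).  This is
the standard estimator for microbial growth assays; during exponential
growth the slope equals the rate exactly, and the window makes it robust to
single-reading glitches.  Three normalization layers remove technical
structure:

1. division by the median rate of neighboring reference wells
   (`normalize_by_neighbors()`; default neighborhood: the four orthogonally
   adjacent wells of an interleaved reference layout, configurable radius),
   cancelling smooth within-plate gradients;
2. division by the median rate of the wild-type controls at the same
   timepoint (`relative_fitness()`), giving dimensionless relative fitness;
3. the median over at least four technical replicates, which is insensitive
   to any single outlying replicate.

At day 0 the replicates of all lines of a genotype are pooled, since the
lines have no independent evolutionary history before the experiment
starts.  A genotype enters the panel as a *slow grower* only with a fitness
drop of at least 10% that is also statistically supported (one-tailed
Wilcoxon rank-sum against the wild-type replicates, Benjamini–Hochberg FDR
0.05; `classify_slow_growers()`).

*Blank handling.*  The blank is taken from a supplied per-well blank column
when available and falls back to the first reading otherwise.  The fallback
is biased — it absorbs the inoculum — so simulated tables always carry the
true blank, and real users should provide medium-only readings when they
have them.

## Calling compensation

For one line with initial fitness $\Delta_{start}$ and evolved fitness
$\Delta_{end}$, the relative fitness improvement is

$$\mathrm{RFI} = \Delta_{end}/\Delta_{start} - 1,$$

and the relative compensation index, measured against the evolving
wild-type controls' end fitness $WT_{end}$, is

$$\mathrm{RC} = \frac{\Delta_{end} - \Delta_{start}}{WT_{end} - \Delta_{start}},$$

the unique linear index that is 0 for no improvement and 1 when the line
reaches the controls' evolved fitness.  (Forms that also adjust for the
controls' starting fitness exist; this one is fixed by those two anchor
properties.)

A line is called *compensated* when two criteria hold
(`call_compensation()`):

* its improvement is significant: one-tailed Wilcoxon rank-sum of end
  versus start replicate fitness, BH-corrected across lines at FDR 0.05
  (exact tails for small samples, mid-rank normal approximation with ties —
  the behavior of `stats::wilcox.test`);
* its RFI exceeds the control cutoff: a normal distribution is fitted by
  maximum likelihood (sample mean, ML standard deviation) to the control
  lineages' RFIs, and the cutoff is the upper $\alpha = 0.05$ quantile
  $\hat\mu + z_{0.95}\hat\sigma$ (`control_improvement_cutoff()`).

A genotype shows evidence of compensatory evolution when at least one of
its lines is compensated.  Downstream structure is quantified by a
Cochran–Armitage trend test across initial-fitness bins (equally spaced
scores; bin edges are a user input because sensible binning depends on the
panel), a one-way ANOVA of fitness gains by genotype, a
category-randomization test for genotype specificity (`none`/`mixed`/`all`
categories versus 1000 shuffles of the call matrix), and a final-interval
depletion test for trajectory saturation (among lines with exactly one
significant per-interval improvement, a 1-df chi-squared test of the
final-interval count against the uniform expectation $n/4$).

## Mutation statistics

*Nonsynonymous excess.*  For each observed coding SNP the package computes
the probability that its substitution type (e.g. `G→A`) would change an
amino acid had it occurred at a random coding position carrying that base
(`ns_site_probability()`, exact codon-table enumeration; stop-gains count
as nonsynonymous).  The probability of observing at least the actual
number of nonsynonymous SNPs is then the upper tail of a Poisson-binomial
distribution over those per-SNP probabilities, computed exactly by dynamic
programming (`poisson_binomial_tail()`).  A small tail indicates selection
on protein sequence.  The test treats observed SNPs as independent given
their substitution types.

*Parallelism.*  Pairs of lines are compared by the Jaccard share of their
de novo mutated gene sets; the mean within-genotype share against the mean
between-genotype share measures genotype-specific parallel evolution.  The
denominator convention is not universal, so intersection-over-smaller-set
is available as an option.

*Functional relatedness.*  The permutation test
(`functional_relatedness_test()`) asks whether mutations preferentially hit
genes functionally related to the deleted gene under four measures:
co-complex and co-category membership (binary) and genetic-interaction
profile similarity or co-expression (continuous).  The null reassigns the
whole per-line mutated-gene lists to knock-out genotypes uniformly at
random, preserving each line's mutational burden — the unit of exchange is
the line, not the mutation, because mutation counts per line vary.
P-values use the add-one permutation estimator and are therefore
conservative by construction.

*Promoter enrichment* is a two-sided exact binomial test of the
promoter-mutation count against the merged promoter fraction of the genome
(500 bp upstream windows by default, merged with `IRanges`).  *Paralog
pairs* require all of: E-value < 1e-8, alignment > 100 residues, similarity
> 30%, and no transposon membership.

## Expression restoration

Differential expression between two strains requires both a 1.7-fold mean
change and t-test p < 0.05 on biological replicates (technical replicates
are averaged first; with 2 biological x 2 technical replicates the test has
2 degrees of freedom, so the fold-change gate does most of the work — this
mirrors platform practice for dual-channel arrays).  The geometry of a
wild-type/ancestor/evolved triplet is summarized by Euclidean distances
between mean profiles over the union of genes DE in any pairwise
comparison, normalized to the ancestor–wild-type distance
(`distance_triangle()`), with replicate-noise radii from the two
biological-replicate means.  A gene counts as *restored* only when it is DE
in the evolved line versus the ancestor with sign opposite to the ancestral
change — a full significant reversion, not a mere sign flip
(`restoration_fractions()`).  `robustness_filter()` re-runs everything
without CNV-amplified, aneuploidy-responsive, growth-rate-correlated or
stochastically varying genes.

## Colony profiling across environments

Colony sizes on 768-position arrays are corrected for spatial bias by
additive row/column median polish on log sizes fitted to reference
colonies, then scaled so the median reference colony is 1
(`normalize_colony_sizes()`).  Median polish is used instead of a
parametric surface because it is robust to failed colonies and exact for
additive (log-multiplicative) gradients.  Per line and environment,
evolved versus ancestral replicate sizes are compared by a two-sided
Wilcoxon test, BH-corrected within each environment, and called
improved/equal/declined; "equal" means only non-significant (no
equivalence test).  Dispersion of evolved fitness across a genotype's
replicate lines is measured by the coefficient of variation per
environment; the selection medium is compared with the mean of the other
media by a Wilcoxon test across genotypes, by a large-sample Z-test on log
CVs with delta-method variance $(0.5 + CV^2)/n$, and by the Spearman
correlation of per-genotype fitness gain with off-target CV.  Calls
require at least 3 replicate colonies (the experimental design pins 4; 3
is the declared floor for partial plates).

## Suppression and epistasis

In a genetic-interaction map, deletion of B suppresses deletion of A when
$F_A < F_B$ and $F_{AB} > F_A + \sigma_A$ (`find_suppressors()`).  The
per-gene suppressor fraction supports both denominators — all partners
tested, or only the gene's genetic interactions — and is correlated with
single-deletion fitness by Spearman rank correlation with quartile-binned
medians.  Epistasis between two reconstructed mutations uses the
multiplicative null $\varepsilon = F_{ab} - F_a F_b$ (the standard null
for fitness); sign epistasis is a sign change of one mutation's effect
across backgrounds, reciprocal sign epistasis a change of both.
Significance for sign epistasis is offered two ways: a bootstrap
percentile interval over replicate measurements and a Wilcoxon test of the
double mutant against the background single.

## The synthetic-data generators

Every input shape the pipeline consumes can be generated with embedded
ground truth, so the whole chain is validated by parameter recovery rather
than by fixtures.  Defaults encode the emulated study conditions: 187
deletion genotypes x 4 lines plus 22 evolving wild-type controls, days
0/26/52/78/104, 6 technical replicates, initial fitness uniform on
[0.5, 0.9], mean control improvement 5%, compensation effects with mean
0.22 and SD 0.08 (chosen so the panel-wide mean RFI of deletion lines is
about 23% when 68% of genotypes are compensable), ~6 point mutations and
~0.5 indels per evolved clone, 1.7-fold expression effects, 768-position
colony plates across 14 environments, and a 3880-gene interaction map.

Design choices where the emulated experiment leaves the model open:

* **Lineage-level drift.**  The medium-adaptation gain is drawn once per
  genotype (and per control lineage) and shared by the genotype's replicate
  lines, with a small per-line jitter.  Two reasons: compensation propensity
  is strongly genotype-specific in such experiments (the all-or-none
  signature the specificity randomization detects), and it makes a null
  genotype exchangeable with a single control lineage, so the
  control-derived cutoff keeps its nominal error rate at the genotype level
  (the genotype call takes a maximum over 4 lines; with independent
  per-line draws that maximum would be anti-conservative by construction).
  Drift is a *fractional* improvement — its absolute gain scales with the
  line's current fitness — whereas the compensation effect is an absolute
  recovery, matching how the two indices are defined.
* **Saturating trajectories.**  True fitness approaches its final value as
  $1 - e^{-3t/T}$, normalized so the full gain is reached exactly at the
  final day; the time constant $T/3$ puts ~53% of the gain in the first
  quarter of the experiment, a saturating but not degenerate shape.
* **Growth curves** are logistic with carrying capacity 1.5 OD, blank 0.05
  and inoculum 0.005 OD.  The inoculum is deliberately small relative to
  the capacity so that several sampling windows lie in the effectively
  exponential phase, which the sliding-window estimator needs for sub-1%
  recovery of the true rate; real inocula are often denser, and the
  estimator then carries a bias of order `od0/K` (visible in the tests,
  which pin it below 3% at `od0/K = 2%`).
* **Mutation counts** are Poisson with the stated means; synthetic ORFs are
  uniform random non-stop codons, adequate for codon-effect bookkeeping but
  without codon-usage or transition/transversion structure.
  `functional_bias` is the *excess* probability that a coding mutation
  targets a gene sharing a complex or category with the deleted gene; the
  complement falls uniformly on all other genes, so bias 0 is exactly the
  uniform null the permutation test must be calibrated against.
* **The GI map** plants suppression directly: each (A, B) pair is a
  suppressor with probability `suppression_link(F_A)`, and fitness values
  are then constructed to satisfy or violate the rule exactly (suppressor
  partners are drawn among genes fitter than A; non-suppressor doubles are
  multiplicative, truncated below the noise threshold).  The planted flag
  therefore *is* the rule's output, and the link function is the ground
  truth that the fitness–suppression correlation must recover.
* **Colony plates** place the reference strain on a diagonal grid covering
  every row and every column (every fourth position), because a row/column
  bias model is only identifiable when references span both margins.

## Calibration and problem sizes

The acceptance suite validates, at fixed seeds: the caller's genotype-level
false-call rate on a 500-genotype null panel (within the 95% binomial
interval of the nominal 5%); recovery of a 68% compensable fraction to
within 0.05 on a 1000-genotype panel; exact agreement of
`ns_site_probability()` with per-site enumeration on a 10 kb ORF set;
agreement of the Poisson-binomial tail with a $10^6$-draw Monte-Carlo
oracle within 3 Monte-Carlo SEs across 20 configurations; recovery of
restoration fractions 0, 0.2 and 1.0 to within 0.05; recovery of the
link-implied fitness–suppression Spearman correlation to within 0.1 at map
scale (n = 3880, 400 partners per gene); and stochastic dominance of
uniform by the permutation p-values over 200 null runs.  The calibration
panels use technical noise well below lineage drift: the decision rule
does not model measurement error in the genotype-level maximum (the
experimental design it follows does not either), so calibration is a
property of the lineage-level null, and the test isolates exactly that.

## Limitations

Passing recovery tests on these generators shows the statistics are
implemented correctly and calibrated under the stated models; it does not
show the models capture everything in real data.  Known gaps: no
mutation-spectrum or codon-usage structure; no correlation between a
genotype's initial fitness and its compensable status unless
`compensable_link` is supplied; expression noise is i.i.d. (no
array/batch structure beyond the biological/technical split); colony noise
is lognormal without pinning artifacts; technical replicate noise on
fitness is Gaussian with a configurable SD because replicate-level noise
magnitudes are assumptions, not measurements.  The DE test is a plain
two-sample t-test standing in for platform-specific pipelines, so DE calls
on real array data will differ near the significance boundary.
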