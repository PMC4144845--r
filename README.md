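# compscape

Quantifying compensatory evolution after gene loss in laboratory evolution
experiments.

## What problem this solves

Deleting a non-essential gene usually costs fitness — but the cost can be
undone. When replicate populations founded from slow-growing deletion
genotypes evolve in the lab alongside isogenic wild-type control lineages,
some lines recover fitness through *compensatory* mutations elsewhere in
the genome, over and above the general adaptation to the medium that the
controls also show. `compscape` is an R package for analysts of such
experiments. It covers the full quantitative chain:

* **Fitness from growth curves** — maximum specific growth rate as the max
  sliding-window slope of `ln(OD − blank)`, normalized by neighboring
  reference wells and by the wild-type control median; slow-grower panel
  selection (≥10% fitness drop, one-tailed Wilcoxon, BH FDR 0.05).
* **Compensation calling** — per line,
  `RFI = Δ_end/Δ_start − 1` and
  `RC = (Δ_end − Δ_start)/(WT_end − Δ_start)` (RC = 1 means the knock-out
  reached the evolving controls' fitness). A line is *compensated* when its
  improvement is significant (one-tailed Wilcoxon, BH FDR 0.05) **and**
  its RFI exceeds the upper-5% quantile of a normal fit to the control
  lineages' RFIs. A genotype is compensated when ≥1 of its lines is.
  Structure tests: Cochran–Armitage trend across initial-fitness bins,
  genotype ANOVA, all-or-none specificity randomization, final-interval
  depletion (trajectory saturation).
* **Mutation statistics** — de-novo/ancestral variant classification;
  nonsynonymous-excess test (per-substitution site probabilities from exact
  codon enumeration, Poisson-binomial upper tail by dynamic programming);
  Jaccard parallelism of mutated-gene sets; permutation test for
  functional relatedness of mutated genes to the deleted gene (co-complex,
  co-category, GI-profile similarity, co-expression); promoter binomial
  test; paralog filter (E < 1e-8, >100 residues, >30% similarity,
  non-transposon).
* **Expression restoration** — DE at fold-change ≥ 1.7 and p < 0.05;
  WT/ancestor/evolved distance triangles normalized to the ancestor–WT
  distance; restored-gene fractions; robustness filtering.
* **Environmental profiling** — colony-size spatial normalization by
  median polish on reference colonies; improved/equal/declined calls per
  line × environment; coefficient-of-variation pleiotropy analysis.
* **Suppression & epistasis** — the suppression rule
  `F_A < F_B and F_AB > F_A + σ_A`, fitness–suppression Spearman
  correlation; multiplicative-null epistasis `ε = F_ab − F_a·F_b` with
  sign / reciprocal-sign classification.
* **Synthetic data** — generators for every input shape with embedded
  ground truth (`simulate_*`), so the whole pipeline is validated by
  parameter recovery.

## Worked example

Simulate a 50-genotype × 4-line experiment with 22 evolving wild-type
controls, build the fitness tables, and call compensation:

```r
library(compscape)

params <- evolution_sim_params(n_genotypes = 50, n_controls = 22, seed = 42)
sim    <- simulate_evolution_experiment(params)
tabs   <- sim_fitness_tables(sim)
calls  <- compensation_analysis(tabs$fitness, tabs$control)

round(calls$cutoff, 4)
#> [1] 0.0962
round(100 * mean(calls$control_rfis), 1)     # controls improved ~5%
#> [1] 5.7
round(100 * mean(calls$calls$rfi), 1)        # deletion lines improved much more
#> [1] 23.6
round(100 * mean(calls$genotypes$compensated), 1)  # % genotypes compensated
#> [1] 74
head(calls$calls[, c("genotype", "line", "start", "end", "rfi", "q",
                     "compensated", "rc")], 4)
#>   genotype line    start       end       rfi            q compensated        rc
#> 1    g0001   l1 0.872996 1.1860628 0.3586119 2.245519e-06        TRUE 1.7542088
#> 2    g0001   l2 0.872996 1.1700643 0.3402859 2.245519e-06        TRUE 1.6645642
#> 3    g0001   l3 0.872996 0.9843199 0.1275194 2.245519e-06        TRUE 0.6237819
#> 4    g0001   l4 0.872996 1.2235720 0.4015779 2.245519e-06        TRUE 1.9643842
```

The cutoff (0.0962) is the improvement an evolving control would exceed
with probability 0.05; lines are compensated only when their RFI beats it
*and* the improvement is significant. RC values near 1 mean the line
reached the evolved controls' fitness (values > 1 overshoot it).

The nonsynonymous-excess test on a set of observed coding SNPs:

```r
snps <- data.frame(ref = c("G", "G", "C"), alt = c("A", "T", "T"),
                   effect = c("nonsynonymous", "nonsynonymous", "synonymous"))
orfs <- simulate_mutation_tables(n_lines = 1, n_orfs = 20,
                                 orf_length = 600, seed = 1)$orfs
ns <- ns_excess_test(snps, orfs)
round(c(ns_fraction = ns$ns_fraction, expected = ns$expected_ns / ns$n,
        p = ns$p), 3)
#> ns_fraction    expected           p
#>       0.667       0.727       0.821
```

Here 2 of 3 SNPs are nonsynonymous while random placement of these
substitution types would make ~73% nonsynonymous, so there is no excess
(p = 0.82); in a genuinely adaptive mutation set the observed fraction
exceeds the expectation and the Poisson-binomial tail becomes small.

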