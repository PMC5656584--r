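---
title: "Predicting stress resistance from transcriptome changes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting stress resistance from transcriptome changes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossres)
```

## The problem

When bacterial populations are evolved under a stressful condition —
salts, acids, alcohols, oxidative or membrane stressors — the resistant
strains that emerge usually change their fitness under *other* stresses
too: **cross-resistance** (a growth-rate gain under a stress the strain
never saw) or **collateral sensitivity** (a loss).  A typical design
evolves several parallel lines under each of a panel of stress
conditions (here: 11 stresses × 5 lines = 55 resistant strains plus the
shared parent), then measures each strain's specific growth rate (1/h)
under *every* stress and its genome-wide expression profile.

`crossres` implements the analysis chain that connects the two data
layers: can the panel of growth-rate changes be predicted from a small
number of expression changes?

## The model

For stress $k$ and resistant strain $j$, the change in specific growth
rate relative to the parent is modelled as a linear combination of
standardized log10 expression changes over a *shared* set of $N$ genes:

$$\Delta g_j^k = \sum_{i=1}^{N} \alpha_i^k\, X_{ij} + \beta^k$$

where $X_{ij}$ is the log10 expression change of gene $i$ in strain
$j$ (vs the parent under the strain's own evolution stress),
standardized per gene to zero mean and unit variance across strains.
Nonlinear and interaction terms are deliberately omitted.  Each stress
has its own coefficients $\alpha_i^k$ and intercept $\beta^k$, but all
stresses share the gene set — the object of the selection problem.

Estimation is ordinary least squares via the SVD.  When $N + 1$ exceeds
the number of training strains the system is underdetermined and we
return the **minimum-norm** solution rather than a regularized one: the
overfitting regime at large $N$ is part of the phenomenon under study
(held-out accuracy collapses there) and must not be masked.

## Preprocessing

The fixed stage order, `preprocess_expression()`:

1. **Quantile normalization** of all samples (backed by limma); ties
   within a sample receive the mean of the reference values across
   their rank span.
2. **Low-expression filter**: genes below 100 a.u. in *every* sample
   are unquantifiable and removed (a gene is kept as soon as one sample
   reaches the floor).
3. **Expression change**: per resistant strain, the ratio of its
   replicate-averaged intensity to the parent's, both assayed under the
   strain's evolution stress.  Replicates are averaged arithmetically on
   the intensity scale before the ratio.
4. **Operon representatives**: operon members are co-regulated, so one
   gene per operon — the one with the highest mean expression over all
   samples — represents it; ties break to the smallest gene id.
5. **Variance filter**: genes whose log10 change has variance below a
   threshold (default 0.01 squared log10 units) across the resistant
   strains plus the parent (whose change is 0 by definition) carry
   mostly measurement error and are removed.
6. **Standardization** per gene to zero mean, unit population variance
   across resistant strains.

Two points were genuinely open and are resolved as follows.  The
variance filter includes the parent's zero change (its stated purpose
is to catch genes that barely move relative to the parent), while the
standardization statistics use the resistant strains only, since those
are the observations entering the model.  Second, each strain
contributes one column of $X$, computed under its own evolution stress;
assay profiles of every strain under every stress are not required.

## Gene-set selection

Candidate gene sets of size $N$ are scored by the **pooled Pearson
correlation** between fitted and observed growth changes over all
training (strain, stress) cells.  Pooling (rather than averaging
per-stress correlations) gives the single scalar fitness the search
needs, and has a useful property: with a shared training set and
per-stress intercepts the pooled correlation equals
$\sqrt{\mathrm{var}(\hat y)/\mathrm{var}(y)}$, which is provably
non-decreasing when a gene is added — the nested-model monotonicity the
test suite asserts.

The search is a **genetic algorithm without crossover**
(`ga_select()`): a population of random $N$-gene sets (default 1000);
each cycle keeps the top 5% by fitness as parents, carries them
unchanged into the next generation (elitism, so the best-so-far trace
is non-decreasing by construction), and fills the remaining slots with
mutants of uniformly chosen parents, each formed by replacing one
uniformly chosen member gene with a uniformly chosen non-member; 300
cycles by default.  The refill bookkeeping (how many mutants per
parent, constant population size) is not fully pinned down by the
protocol we follow; the choices above are the simplest that keep the
population size constant and the reported optimum monotone.
`exhaustive_select()` provides the enumeration oracle for small pools.

Generalization is assessed by **5-fold cross-validation with repeated
random partitioning** (`cv_partition()`, `evaluate_partition()`,
`sweep_gene_count()`): strains are partitioned into five near-equal
folds; the GA and the refit see only the four training folds, and
held-out strains are predicted from coefficients they never influenced.
Stratifying the partition by evolution stress is the default (it keeps
the held-out panel balanced); plain random partitioning is available by
flag.  Repeating the selection over many random partitions yields the
**selection frequency** of each gene (`selection_frequency()`, one
training set per partition) and per-cell prediction error bars
(`prediction_with_uncertainty()`).  The protocol value of 10,000
repetitions is the package default for frequency runs; examples and
tests use 10–50, which already separate planted from background genes
cleanly.

## The synthetic-data generator

Real microarray studies are not reproducible at desk scale, so the
package ships a generator (`simulate_dataset()`) that emulates the
statistical structure the analysis assumes, with full ground truth:

* **Design**: 11 stresses × 5 lines + parent; the parent is assayed
  under all stresses, each strain under its own, in 3 biological
  replicates (`simulation_design()`).
* **Intensities** are positive, log10-normal: per-gene baselines in
  $10^{[2.3, 4.5]}$ a.u.; 40% of genes sit below the 100 a.u. floor in
  every sample (the filter then retains 60%, matching the reported
  retention of quantifiable genes).
* **Replicate noise**: a per-operon-per-sample latent (sd 0.02 log10)
  shared by operon members plus independent per-gene noise (sd 0.02
  log10).  These defaults calibrate replicate reproducibility so that
  ≥99% of replicate expression ratios fall within 1.3-fold, the
  reproducibility criterion the analysis assumes.  A latent residual as
  large as 0.05 log10 would break that calibration, so the smaller
  value is used.
* **Operons**: sizes drawn from a distribution with mean just under 2
  genes (55% singletons), consecutive genes grouped.
* **Planted signal**: 5 planted genes (sampled from expressed singleton
  operons, so the operon-representative step provably retains them)
  receive stress-level shifts (sd 0.3 log10) plus strain-level
  variation (sd 0.1); all other expressed genes receive diffuse
  stress-level (sd 0.1) plus strain-level (sd 0.05) shifts, which make
  selection a real discrimination problem and make strains cluster by
  evolution stress, as real resistant strains do.
* **Growth changes** are generated *from the realized standardized
  matrix* via the planted linear model with Gaussian noise; the planted
  coefficients (sd 0.07 per gene) span growth changes of roughly ±0.3
  1/h, the scale seen in stress-evolution growth panels.  Noise can be
  set absolutely or as a fraction of the signal sd.

What the generator does **not** emulate: probe-level effects, array
batch structure, intensity-dependent noise, condition-specific global
expression responses (which cancel in strain/parent ratios), and any
direct effect of mutations on growth.  Passing tests therefore
demonstrate correctness of the machinery and recoverability of planted
linear structure — not that real transcriptomes satisfy the linear
model.

## Numerical choices

* Rank decisions in the SVD use the standard
  `max(dim) * eps * max(singular value)` tolerance; the C++ fitness
  kernel and the R fitting path use the same rule and agree to 1e-10
  (asserted in tests).
* Undefined fitness (zero variance in fitted or observed values) scores
  $-\infty$, so such sets lose every comparison.
* Ties: operon representatives and exhaustive search break ties to the
  lexicographically smallest gene id; quantile normalization averages
  tied ranks.
* Missing growth cells are skipped by both fitting and correlation;
  a stress with no training observation is an explicit error.
* All randomness flows from one master seed through derived substreams
  (partitioning, GA initialization/mutation, noise draws), so every
  pipeline product is bit-reproducible under a fixed seed.

## Validation design and problem sizes

The test suite validates properties, at sizes chosen to keep a full run
in minutes: OLS against a normal-equations oracle (100 random
instances); exact recovery and pooled $R = 1$ in the noiseless limit;
GA against exhaustive enumeration on a 10-gene pool with a planted
pair (100 seeded trials, ≥95% agreement, never exceeding the
enumeration optimum); the held-out accuracy curve over
$N \in \{1, 2, 5, 10, 25, 50\}$ on the study-scale regime (55 strains,
~430 candidate genes, 5 planted genes, growth noise at 25% of signal
sd, 50 repeated partitions, reduced GA settings of population 100 / 50
cycles), which peaks near the planted count and declines at $N = 50$;
selection-frequency dominance of planted genes across 10 seeded
experiments; and clustering of strains by evolution stress (adjusted
Rand index > 0.8 over 10 seeds).

One null-model subtlety deserves a note.  To show that held-out
accuracy is honest (no leakage), growth labels are destroyed and the
mean held-out correlation is checked against $\pm 3/\sqrt{n}$.  That
band assumes exchangeable cells, so the null permutes the *cells* of
the growth table.  Permuting whole strain rows instead leaves real,
learnable structure behind — per-stress means survive row permutation,
and same-stress strains have correlated expression changes, whose
group means anti-correlate with held-out values under
without-replacement permutation — and the measured mean correlation is
then visibly negative, not zero.  Both behaviours are properties of the
statistics, not leakage; the cell-permutation null is the one that
matches the band's assumptions.

## Limitations

* The linear model ignores mutation effects on growth and any
  nonlinearity; on real data the pooled correlation bounds how much of
  the resistance profile expression changes can explain, not a causal
  decomposition.
* Selection frequencies are descriptive; no multiplicity-corrected
  inference is attached to them.
* The GA is a stochastic heuristic: on large pools it may return
  near-optimal sets; only on enumerable pools is optimality asserted.
* The clustering and correlation summaries use 1 − Pearson distance
  with average linkage and permutation p-values by default; both are
  conventional, configurable, and not the only defensible choices.
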