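---
title: "Pooled double-barcode fitness inference: models and methods"
author: "ppiseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled double-barcode fitness inference: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppiseq)
```

## The measurement problem

A pooled protein-fragment complementation screen couples each bait-prey
genotype pair to a set of double DNA barcodes and competes thousands of such
lineages in one culture under methotrexate selection. Interaction strength
is read out as growth rate: reconstituted mDHFR confers a per-generation
fitness advantage over reporter-free control strains. The raw data are
time-series read counts per double barcode across serial 1:8 dilutions
(about three generations per transfer), sequenced at generations 0, 3, 6, 9
and 12.

A single end-point frequency is not a usable score: how far a lineage rises
or falls depends on the changing composition of the pool, because every
frequency is measured against the current population mean fitness. The
package therefore fits trajectories, not end points.

## Frequency model and likelihood

Lineage $l$ has initial frequency $f_l$ and relative fitness $s_l$ (per
generation, natural-log scale). Its expected frequency at generation $t$ is

$$\varphi_l(t) = f_l\, e^{s_l t - \bar x(t)},$$

where $\bar x(t)$ is the cumulative mean-fitness integral of the pool,
defined by the normalization $\sum_l \varphi_l(t) = 1$ at every sequenced
time point, with the gauge $\bar x(0)=0$. It is this term that makes the
trajectories of fit lineages bend downward as the pool's mean fitness
rises.

Reads are modelled as Poisson counts, $R_{l,t} \sim
\mathrm{Pois}(D_t\,\varphi_l(t))$, with $D_t$ the sample depth. The
per-lineage log-likelihood is maximized over $(f_l, s_l)$; given $s_l$ the
initial frequency has the closed form $\hat f_l = \sum_t R_{l,t} / \sum_t
D_t e^{s_l t - \bar x(t)}$, so the optimization is a one-dimensional
profile-likelihood Newton iteration in $s_l$, run vectorized across all
lineages. Lineage fits alternate with the fixed-point update
$\bar x(t) \leftarrow \bar x(t) + \log \sum_l \hat\varphi_l(t)$ until
$\max_t |\Delta \bar x| < 10^{-4}$ (cap 100 outer iterations; in practice
the fixed point converges in well under ten). Standard errors come from the
observed information, $\mathrm{se}(\hat s_l) = (I_{ss} -
I_{sf}^2/I_{ff})^{-1/2}$ with $I = \sum_t \mu_{l,t}\,(1, t)^{\otimes 2}$.

Poisson counting noise is the committed error model: replicate scatter in
this assay class is consistent with finite read depth, and the Poisson
likelihood handles zero counts natively, so extinct trajectories keep a
defined likelihood. Fitness is bounded to $s \in [-2, 2]$ per generation;
trajectories that are all-zero after $t=0$ ride the lower bound and are
reported with `converged = FALSE`.

### Gauge fixing and control zeroing

The model has a gauge freedom: adding $c\,t$ to $\bar x(t)$ shifts every
$s_l$ by $c$. The biologically meaningful scale is fixed by the
reporter-free (mDHFR-negative) control lineages: after fitting, every
fitness in a pool is shifted so the mean fitness of used control lineages
is exactly zero. Scores are then comparable across replicates, pools and
environments.

### Trajectory quality

Each trajectory's goodness-of-fit score is the mean per-time-point
log-likelihood of the fitted model minus that of the saturated model (0 is
a perfect fit). Trajectories below a threshold are excluded from control
zeroing and interaction scoring. The default threshold of $-1.5$ was
calibrated once on the experiment-scale simulation: it flags about 0.3% of
well-behaved trajectories (far below the 5% design ceiling) while a single
time point corrupted to 100x its expectation scores below $-40$ and is
always removed.

## PCR chimera correction

A chimeric amplicon joins barcode halves from two templates. Under random
re-pairing, the expected chimeric count for pair $(i,j)$ in a sample is
$\varepsilon\, R_{i\cdot} R_{\cdot j} / R_{\cdot\cdot}$, built from the
half-marginals; corrected counts subtract this expectation, floor at zero
and round to integers so the Poisson likelihood stays well defined. The
rate $\varepsilon$ is estimated from pairs whose halves are each known to
the library but whose combination was never designed - such pairs can only
arise through chimerism. When the designed library is a *complete cross* of
its barcode halves (as in a fully pairwise-mated pool), no off-target pair
exists and $\varepsilon$ must come from external calibration; the package
signals this explicitly rather than guessing. The default rate used in the
examples, 0.002, is the regime reported for this assay class.

## The generative simulator

`simulate_pool()` is the package's ground-truth engine and test fixture
generator. Per replicate culture it draws a starting bottleneck of
`bottleneck_size` cells (multinomial over lineages), grows deterministically
- cells multiply by $e^{g(\ln 2 + s)}$ per cycle of $g$ generations -
re-bottlenecks by multinomial sampling at each transfer, and sequences each
time point multinomially at the configured depth, with a binomial fraction
$\varepsilon$ of reads re-paired at random between the half-marginals.

Default configuration, chosen once to mirror the bench experiment: 10 x 10
genotype pairs (one slot each reserved for the control), 25 barcode pairs
per genotype (5 x 5 halves, a complete cross), triplicate cultures, 1:8
dilutions for 4 cycles (generations 0/3/6/9/12), 67 reads per barcode per
sample, $\varepsilon = 0.002$. True fitness of genuine bait x prey pairs is
evenly spaced over $[0, 0.4]$, the observed range of the assay; pairs
involving a control half sit at 0. The bottleneck defaults to $10^6$ cells,
the protocol arithmetic of a 70 ul transfer from a minimal-media culture at
roughly $10^7$ cells/ml.

Deliberate simplifications: growth between bottlenecks is noiseless (the
transfer multinomial dominates drift at these population sizes), there is
no mutation or adaptation within lineages, no plate or media covariates,
and chimera formation is a single rate with no position structure. Passing
tests on simulated data therefore demonstrate correctness of the inference
under counting and transfer noise; they do not probe biological artefacts
such as the adaptive mutations that real screens occasionally carry.

### What recovery accuracy to expect

At 67 reads per barcode, the Fisher information of five Poisson-sampled
time points bounds the per-culture fitness standard error near 0.018; the
estimator attains this bound (root-mean-square error matches the
likelihood-based standard errors). With true fitness spread over
$[0, 0.4]$, the per-culture correlation between truth and estimate is
therefore capped near 0.985, and averaging the three replicate cultures of
a lineage - the level at which the assay itself aggregates - yields
$r \approx 0.995$. The acceptance script reports this per-lineage
correlation over 2,500 lineages, averaged across five seeds.

```{r recovery}
sim <- simulate_pool(default_experiment_config(seed = 7))
traj <- correct_counts(as_trajectory_table(sim), rate = sim$config$chimera_rate)
fit <- fit_pool_fitness(traj)
e <- fit$estimates[fit$estimates$used, ]
per_lineage <- tapply(e$fitness, e$barcode_pair, mean)
truth <- sim$truth$s_true[match(names(per_lineage), sim$truth$entry_id)]
cor(truth, per_lineage)
```

## Read processing choices

Barcode regions (38 bp each) are cut from fixed offsets of the amplicon;
the layout (`default_read_layout()`) is configuration, since amplicon
geometry varies by library preparation. Three filters apply, in order:
mean region quality strictly greater than 30; a structural match of region
1 (4-bp flank with one error allowed, two `AA` spacers and one `TT` spacer
between random fill of 4-7 bases, or the fixed alternate flank
`GTACTAACGGCTAATTTGGTGCCCA` carried by a subset of constructs); and the
corresponding structural match of region 2. Parsed pairs are assigned to
the designed library by unique-best Hamming distance with a budget of 2
mismatches over the 76-bp concatenation - barcodes are fixed-length, so
substitutions are the error model and indels are out of scope - and ties
at the minimal distance are deliberately left unmatched rather than
assigned arbitrarily.

## Interaction calling

Used fitness estimates are aggregated per genotype pair and environment
(about 75 estimates: 25 barcode pairs x 3 replicates) and tested against
the pooled control estimates with a one-sided Welch $t$-test, Bonferroni
multiplied by 500 - the convention of this assay's published score tables,
kept fixed rather than tied to the number of rows. Welch is the default
because group sizes differ; a pooled-variance option exists for exact
replication attempts. Environment dependence is tested per pair against
the permissive (DMSO) environment with a two-sided test multiplied by 400.
The dynamic summary defines "detected" as significant against the control
in at least one environment, which is the denominator the assay's headline
fractions use. A pair suspected of artefact (e.g. an adaptive mutation in
a parent strain) is removed via an explicit blacklist argument, never
hard-coded.

Two orthogonal bench validations are included as small calculators:
isolated-growth OD curves scored by area under the curve before
saturation, with relative fitness
$(\mathrm{AUC}_t - \mathrm{AUC}_c)_{cond} / (\mathrm{AUC}_t -
\mathrm{AUC}_c)_{DMSO}$, and luciferase complementation response as the
condition/DMSO luminescence ratio.

## Scalability calculators

`predicted_complexity()` is the pooled-mating bound: cells per plate x
mating efficiency x recombination efficiency x plates; at the measured
lower-bound efficiencies (8.1% and 2.7%, the precise values rather than
their rounded 8%/2% forms) a $10^{10}$-cell plate yields $2.187 \times
10^7$ unique double barcodes, and ~50 plates exceed $10^9$.
`detection_fraction()` gives the expected fraction of barcodes at $\ge k$
reads under Poisson sampling, exact in the many-barcodes small-frequency
regime the assay operates in.

## Numerical notes and limitations

* Newton steps in $s$ are damped to $\pm 0.5$ per iteration and bounded to
  $[-2, 2]$; initial values are the end-to-start log-frequency slope with
  half-count pseudocounts.
* Corrected counts are rounded to integers; for rates near 0.2% this
  changes individual pairs by at most a read.
* Lineages with zero reads everywhere carry `NA` fitness and are never
  used; lineages extinct after $t=0$ keep a defined (boundary) estimate.
* The likelihood assumes independent Poisson counts; overdispersion from
  PCR jackpots or plate effects is not modelled and will inflate the
  goodness-of-fit flag rate before it biases fitness.
* Replicate concordance on simulated triplicates exceeds 0.97, comfortably
  above the 0.91 floor observed on real data - real cultures carry
  biological variance the simulator does not emulate.

## Problem sizes used in the test suite

The packaged tests run the full 2,500-lineage configuration where the
check concerns the experiment scale (recovery correlation, replicate
concordance), and reduced pools (16-625 lineages, depths of a few thousand
reads) for property checks where scale adds nothing. The family-wise error
check uses ten seeded all-neutral pools at 9 barcode pairs per genotype;
the power check uses five seeded pools with one pair at $s = 0.10$ under
full 25-barcode, triplicate replication.
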