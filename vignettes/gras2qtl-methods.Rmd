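---
title: "Co-dominant genotyping from amplicon read depths and F2 QTL mapping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-dominant genotyping from amplicon read depths and F2 QTL mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gras2qtl)
```

## The problem

Genotyping by random amplicon sequencing (GRAS-Di) produces thousands of
anonymous amplicon markers without needing a contiguous reference genome, but
each marker is natively *dominant*: it reports presence or absence of one
parent's allele. In an F2 intercross, however, the read-depth count at a
locus carries more information than presence/absence. An individual carrying
zero, one or two copies of the amplicon-bearing allele is expected to show
background-level, intermediate and high counts respectively, so the depth
distribution across a segregating population is trimodal with mixing weights
near the Mendelian 1:2:1. This package recovers full *co-dominant* genotype
calls (AA / AB / BB) from those depths, then carries them through the
standard downstream analyses of an F2 mapping study: marker quality control,
linkage-map construction, interval and composite interval mapping of
quantitative traits, and marker-trait association summaries. A synthetic-data
generator reproduces the statistical structure of such a study so that every
stage is testable without sequencing data.

## Per-locus mixture model

At each marker, counts across the population are modelled as a
three-component mixture, under either a gamma or a normal family:

$$f(x) = \sum_{k=1}^{3} \pi_k \, f_k(x \mid \theta_k)$$

fitted by EM. Initialization encodes the F2 design:

* mixing proportions start at exactly $(0.25, 0.50, 0.25)$;
* normal family: component means start at $0$, the 50% quantile and the 75%
  quantile of the counts, with a common starting sd equal to the sd of the
  counts;
* gamma family: *pre-initial* shape/scale are moment-matched
  ($\alpha = m^2/s^2$, $\theta = s^2/m$) to target means $(0, q_{50}, q_{75})$
  and target sds $(\mathrm{sd}/3, \mathrm{sd}/2, \mathrm{sd}/2)$; the
  zero-mean component's pre-initials are 0, the only self-consistent reading
  of a zero target mean. Offsets of $+1.0$ (shape) and $+0.5$ (scale) give
  the initial values, so the first component starts at $(1.0, 0.5)$.

Iteration stops when the relative log-likelihood change drops below $10^{-8}$
or after 5000 iterations; non-converged loci are removed rather than called.
Genotypes are assigned by maximum posterior probability, with the components
ordered by fitted mean: lowest mean = homozygote lacking the source parent's
allele, middle = heterozygote, highest = homozygote carrying two copies.

Numerical choices worth knowing:

* **Zero counts under the gamma family.** The gamma density is degenerate at
  zero, so counts are shifted by $+0.5$ before gamma fitting. Calls depend
  only on posteriors, so the shift is never undone; reported component means
  subtract it again.
* **Component collapse.** If any mixing proportion falls below $1/(10n)$ or a
  normal component's variance underflows, the locus is declared non-converged
  instead of letting the likelihood diverge. Numerical failures never escape
  the per-marker loop.
* **Posterior ties** are called missing, not broken arbitrarily: an invented
  call at a tie would inject a phantom recombination into the map, which is
  worse than a missing value.
* The gamma M-step uses the exact weighted maximum-likelihood update (Newton
  iteration on $\log\alpha - \psi(\alpha)$), so every EM step increases the
  log-likelihood; the tests assert this trace monotonicity on every fitted
  locus.

## Calibration against the default caller

The proprietary caller that accompanies the assay emits dominant calls for
all loci and co-dominant calls for a small minority. Its behaviour is
*emulated* by the generator (a presence threshold on counts plus a corrupted
copy of truth for a configurable fraction of loci); its internals are not
reverse-engineered. Mixture calls are scored against it two ways: co-dominant
agreement on the default co-dominant subset, and dominant agreement after
collapsing the heterozygote into the source parent's presence class. Markers
are retained only when dominant consensus is *strictly* greater than 95% and
both parents are called as the expected opposite homozygotes by the same
per-locus fit. The consensus filter runs before the parental filter (the
order is exposed in `run_pipeline()`); redundant markers called by several
systems are merged with the fixed priority default > gamma > normal.

## Map construction

Pairwise recombination fractions are maximum-likelihood estimates under the
F2 intercross model, computed on an exact category likelihood that handles
the ambiguous double-heterozygote class and dominant observations ("C" = not
AA, "D" = not BB) uniformly; the 1-D likelihood is maximized numerically and
clipped to $[0, 0.5]$, with linkage LOD taken against $r = 0.5$. Grouping is
single-linkage closure over pairs with $r \le 0.35$ and LOD $\ge 3$ (both
exposed; the upstream tool the field uses does not document its criteria, so
these are package defaults, not claims). Ordering minimizes the sum of
adjacent recombination fractions by greedy nearest-neighbour seriation plus
2-opt refinement with 50 restarts by default — an ant-colony optimizer would
chase the same objective; the testable contract is order recovery, which the
suite checks against simulated truth up to reversal. Positions are cumulative
Kosambi distances, $d = 25\ln\frac{1+2r}{1-2r}$ cM. Adjacent gaps larger than
20 cM trigger removal of the gap-side marker in the smaller block, iterated
to a fixed point; because positions are cumulative, removing a marker merges
its two gaps by summation (an upper bound on the direct distance —
conservative, and it keeps the filter deterministic without re-estimation).
The reported average marker distance divides total length by the marker
count $N$ (not $N-1$), matching the arithmetic of the summary tables this
output format follows.

## QTL mapping

Scanning uses Haley–Knott regression on expected genotype scores: at each
grid position (1 cM by default) the phenotype is regressed on
$x = P(\mathrm{AA}) - P(\mathrm{BB})$ and $z = P(\mathrm{AB})$, with
$\mathrm{LOD} = \frac{n}{2}\log_{10}(\mathrm{RSS}_0/\mathrm{RSS}_1)$. The
class probabilities condition on the nearest informative flanking markers
under the no-interference model with Kosambi-inverse recombination fractions;
at observed markers they are degenerate, so interval mapping reduces exactly
to single-marker regression there (asserted at $10^{-9}$ against a direct
`lm()` oracle). Composite interval mapping adds forward-selected marker
cofactors (default 5, each contributing additive and dominance columns,
missing calls mean-imputed), excluding cofactors within 10 cM of the test
position. These defaults mirror common CIM practice and are configurable;
the exact-EM mixture likelihood used by some CIM software is deliberately
out of scope — Haley–Knott has the same asymptotic surface and its parameter
recovery is what the tests exercise.

Significance thresholds come from permutation: phenotype labels are permuted
(1000 times at $\alpha = 0.05$ by default), each permutation's genome-wide
maximum LOD is recorded, and the threshold is the
$\lceil(1-\alpha)n_\mathrm{perm}\rceil$-th order statistic. For CIM the
cofactors are selected once on the observed phenotype and held fixed across
permutations. Effects at a peak are read off the regression:
$a = (\mu_{AA} - \mu_{BB})/2$ (negative when the seed-parent allele
decreases the trait), $d = \mu_{AB} - (\mu_{AA}+\mu_{BB})/2$, and
$R^2 = 100(\mathrm{RSS}_0 - \mathrm{RSS}_1)/\mathrm{RSS}_0$. Support
intervals are 1-LOD drops by default — the tables this mimics do not state
their interval construction, so the choice is flagged here rather than
claimed.

Right-censored individuals (plants that never matured before the experiment
ended) are kept in the scan at the truncated end-day value by default and
can be excluded; when nobody is censored the two policies are identical, a
property the tests assert. A survival-model treatment of censoring is a
non-goal.

## Association statistics

Genotype-class summaries report $n$, mean and sample sd (n−1 denominator)
per class with Tukey–Kramer adjusted pairwise P values. The statistic
depends on the data only through $(n_k, \bar y_k)$ and the pooled
within-group variance $\mathrm{MSW}$, so the function accepts either raw
observations or printed summary triplets and the two entry points agree to
machine precision — this identity is what licenses checking published
class-mean tables from their one-decimal summaries (agreement to roughly two
significant figures; the rounding of the inputs, not the distribution
function, limits the precision). Studentized-range tail probabilities come
from `stats::ptukey`, R's numerical integration of that distribution; the
test suite cross-checks against `TukeyHSD()` on raw data as an independent
code path.

## The synthetic generator: what it emulates, what it does not

The generator reproduces the statistical skeleton of a two-parent F2
phenology study:

* **Genome and population.** 8 linkage groups (the buckwheat chromosome
  number), 20 markers per group at 5 cM, 150 individuals — the regime of the
  study design this package targets (populations of 120–150). Gametes are
  Markov chains with adjacent recombination from the Kosambi inverse and no
  interference between intervals; downstream estimators only see pairwise
  recombination, so exact interference modelling would not change what is
  testable.
* **Depths.** Counts are gamma-mixed Poisson (negative binomial), mean
  proportional to allele dosage times a lognormal per-marker scale. Defaults
  `mu = (2, 50, 100)` reads, dispersion 0.02, scale sd 0.25 describe the
  deep-coverage regime in which a depth-based caller can reach the ~95%
  co-dominant accuracy that makes the method worthwhile; both mixture
  families are deliberately mis-specified against this generator, as they
  are against real data.
* **Phenotypes.** Maturity = baseline + QTL effects ($+a$ / $d$ / $-a$ for
  AA/AB/BB) + Gaussian noise scaled so the QTLs explain the configured
  heritability (default 0.21, one major QTL with $a=-7.19$, $d=-3.28$ days
  after sowing — an early-maturity allele from the seed parent). Maturity
  past the experiment end (105 DAS) is right-censored. Flowering time is
  generated the same way from its own QTL, genetically independent of
  maturity by default.
* **Parents** are fully homozygous and contrasting at every marker; residual
  within-cultivar heterozygosity of an outcrossing crop is out of scope.
* **Morphological marker.** A single dominant floral-morph locus (carrier
  classes segregating 3:1) can be appended and mapped as a dominant marker;
  it passes through the distortion filter under its 3:1 expectation.

What passing tests on this generator do *not* show: robustness to
per-individual library-size variation (a normalization hook exists but raw
counts are the default), to within-cultivar parental heterozygosity, to
missing-data patterns correlated with genotype, or to the marker-discovery
step of the proprietary pipeline, none of which are simulated.

One emergent behaviour is worth highlighting: maps built from *called*
genotypes are longer than the generating truth (≈40% at the default ~2.5%
call error rate), because every call error looks like a double
recombination. This inflation is a well-known property of error-containing
genetic maps, and it is why the acceptance check on map-length recovery uses
true genotypes while the pipeline reports its own inflated length honestly.

## Problem sizes in the test suite

The stochastic suites run at the study's population size (n = 150) but trim
replication and grid resolution to what the properties need: 500-marker
calling accuracy at one seed; map recovery on the full 8-group genome with
10 ordering restarts; QTL recovery over 100 replicates and null calibration
over 200 replicates at a 2 cM scan step with 200 permutations each. The
acceptance script runs the full pipeline once at the default 1 cM step with
1000 permutations and 50 ordering restarts.

## Known limitations

* Three components only; polyploid dosage models are out of scope.
* Haley–Knott regression, not the exact mixture likelihood, under CIM.
* Grouping thresholds and the default-caller emulation parameters are
  package choices where the upstream tools are undocumented; both are
  exposed in the configuration.
* Censored maturity is truncated, not modelled; correlations and class means
  exclude censored plants by default.
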