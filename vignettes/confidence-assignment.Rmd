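---
title: "Replicate-derived FDR confidence for somatic mutation calls"
author: "somaticFDR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replicate-derived FDR confidence for somatic mutation calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(somaticFDR))
```

## The problem

Somatic mutation discovery compares a tumor genome against the matched
normal genome. The calls that come out of this comparison are a mixture of
real mutations and artifacts of the whole measurement chain - library
preparation, amplification, sequencing chemistry, alignment, and the
calling algorithm itself. Different callers agree on fewer than half of
their calls, and callers emit several per-call quality metrics (base
quality, depth, mapping quality, genotype or somatic scores) with no
obvious way to combine or threshold them. A researcher choosing mutations
for validation, therapy-target selection or follow-up needs one number per
mutation that says how likely the call is to be wrong.

`somaticFDR` produces that number: an empirical per-mutation false
discovery rate. The key device is a **same-versus-same comparison**:
profile the *same* (normal) sample twice and run the identical calling
pipeline on the replicate pair. Any "mutation" found between two profiles
of the same genome is a false positive by construction, so the
same-vs-same call set is a direct sample from the artifact process,
collected under exactly the lab and analysis conditions of the real
experiment.

## From quality vectors to one score Q

Each caller attaches a fixed tuple of quality properties
$S = (s_1, \dots, s_n)$ to each call (a `CallerConfig` fixes the list and
its VCF field mapping per caller; models are trained separately per caller
because the property sets differ). Call $S$ *superior* to $T$ iff
$s_i > t_i$ for every $i$ - a deliberately rigorous partial order under
which many pairs are incomparable. For any point $S$ in quality space
define the **intermediate FDR**

$$\mathrm{IFDR}(S) \;=\;
  \frac{\#\{T \in \mathrm{ss} : T \ge S\}/C_{ss}}
       {\#\{T \in \mathrm{tn} : T \ge S\}/C_{tn}},$$

clamped to $[0,1]$, where "$\ge$" is componentwise at-or-above (so a call
always counts itself in its own denominator), $\mathrm{ss}$ and
$\mathrm{tn}$ are the same-vs-same and tumor-vs-normal quality pools, and
$C_{ss}$, $C_{tn}$ are the **common coverages** of the two comparisons:
the number of reference bases covered at depth $\ge 1$ in *both* members
of a comparison. Dividing by the common coverage makes counts from
comparisons with different searchable space commensurable; the depth
threshold is fixed at 1 (not configurable) so the FDR semantics stay
fixed.

The partial order leaves too many pairs undecided to rank mutations
directly, so the IFDR is generalized by regression
(`trainQualityModel()`):

1. For each property, take its observed range in the tumor pool and place
   up to $p$ uniformly spaced values across it (the observed value set is
   used verbatim when it has fewer than $p$ distinct values); form the
   Cartesian product, at most $p^n$ grid points. The built-in configs use
   $p = 20$ for four-property callers and $p = 12$ for the five-property
   one, keeping grid sizes comparable ($20^4 \approx 12^5$).
2. Draw a uniform random subset of the grid - nominally 1% of it, with a
   floor of 1,000 points (capped at the grid size). The floor keeps small
   grids from under-training; on the default $20^4$ grid the 1% fraction
   is what binds. Sampling is without replacement.
3. Compute each sampled point's IFDR against the full pools and fit a
   random forest regression (500 trees, package defaults otherwise; the
   forest is a smoother here, and the fit is insensitive to these
   choices). Training is seeded and bit-reproducible.

The **generalized quality score** is $Q = 1 - \widehat{\mathrm{IFDR}}$,
clamped to $[0,1]$. The regression only ever fixes Q up to orientation and
scale - what matters is the total order it induces - and this choice makes
higher Q mean higher confidence, so "a score of Q or better" is simply
$Q' \ge Q$.

## From Q to a per-mutation FDR

With every call of both comparisons scored, the empirical FDR function
(`buildFdrFunction()`) is the one-dimensional analogue of the IFDR on the
Q axis:

$$\mathrm{FDR}(q) \;=\;
  \frac{\#\{x \in Q_{ss} : x \ge q\}/C_{ss}}
       {\#\{y \in Q_{tn} : y \ge q\}/C_{tn}},$$

clamped to $[0,1]$. `assignFdr()` evaluates it at each tumor call's Q and
returns the set sorted by FDR - the prioritization order.

Numerical and degenerate-case choices, all shared between `ifdr()` and
`evaluateFdr()`:

* Ratios above 1 are clamped: an FDR is a rate, and the raw ratio can
  exceed 1 when coverage-scaled null counts exceed tumor counts.
* If no tumor call scores $q$ or better, the value is 0 when no null call
  does either, else 1. Tumor calls themselves never hit this branch
  (their own denominator is at least 1), but sampled grid points and
  user-supplied probes can.
* Zero common coverage is a hard error, not a silent NaN.
* The raw ratio is reported without monotone (q-value-style) smoothing by
  default: per-mutation FDRs are what get reported and the ROC estimator
  below sorts by FDR, which tolerates local non-monotonicity. A
  `smooth = TRUE` flag enforces a running maximum for users who want
  q-value behavior.

Because the null side is a property of the platform and caller rather
than of the tumor sample, `reuseReference()` swaps a new tumor
comparison's scores into an existing FDR function: the same-vs-same
profiling needs to be done only once per platform, provided the same
caller (hence comparable Q) is used.

## Label-free ROC estimation

To compare callers, coverages, read layouts or replicate designs without
ground truth, each mutation contributes fractionally to both axes of an
ROC curve: its FDR to the false-positive sum and $1-\mathrm{FDR}$ to the
true-positive sum. These are the unique per-mutation contributions
satisfying $\mathrm{FDR} = \mathrm{FPR}/(\mathrm{FPR}+\mathrm{TPR})$ with
$\mathrm{FPR}+\mathrm{TPR} = 1$. Mutations are sorted by FDR, cumulative
sums are normalized by the grand totals, $(0,0)$ is prepended, and the
AUC is the trapezoid integral (`rocFromFdrs()`). Two consequences worth
stating:

* A constant-FDR list - in particular all-0.5, "no information" - yields
  exactly the diagonal and AUC 0.5.
* Equal-FDR mutations are merged into a single curve step (their
  contributions summed), so the curve is independent of tie order; the
  AUC is invariant under duplicating the FDR list.

`meanRoc()` summarizes the stability of FDR assignment when the
same-vs-same reference is exchanged: member curves are aligned on the
cumulative rank fraction of the FDR-sorted list (each mutation advances
that axis by exactly one combined contribution unit - the natural common
parameter, since member sets may differ in size), linearly interpolated
at uniform positions, and averaged with a normal-approximation 95%
interval for the mean ($\pm 1.96\,\mathrm{SEM}$) in both dimensions.
Where validation labels exist, `rocFromLabels()` builds the classical
curve with $1-\mathrm{FDR}$ as the score (inconclusive labels excluded),
`thresholdSweep()` tabulates sensitivity/specificity over FDR cutoffs
$0, 0.05, \dots, 1$ (thresholds rounded to kill float drift so a call at
exactly the cutoff is accepted), and `resampledAuc()` guards against
imbalanced validation group sizes by averaging the AUC over seeded
balanced redraws.

## The synthetic generator: what it emulates and what it does not

`generateExperiment()` produces the statistical structure the method
relies on, with known labels: a tumor-vs-normal set that is a
$\pi : (1-\pi)$ mixture of true mutations and artifacts, and a
same-vs-same set drawn from the artifact distribution only. Defaults are
chosen once to represent a realistic exome experiment:

* Four samtools-style properties, each an independent truncated Gaussian
  for artifacts; true calls draw from the same Gaussian shifted up by
  0.75 standard deviations per property - a moderate, partially
  overlapping separation (a `shiftScale` multiplier gives the
  zero-separation and high-separation variants used in comparative
  tests).
* $n_{tn} = 5{,}000$ calls, $\pi = 0.5$, common coverages
  $C_{ss} = C_{tn} = 4.5\times10^7$ bases (a ~50 Mb capture design at
  near-complete breadth).
* The same-vs-same size defaults to $(C_{ss}/C_{tn})(1-\pi)\,n_{tn}$, so
  the artifact rate *per covered base* matches between comparisons and
  assigned FDRs are directly interpretable in calibration checks.
* Loci are uniform without collision on a virtual contig; generation is
  seed-deterministic down to the emitted bytes (quality values are
  rounded to four decimals so VCF round-trips are exact).

`replicateTumorNormal()` emulates a technical replicate: true mutations
keep their loci and alleles but their quality vectors are redrawn;
artifacts are redrawn entirely, because sequencing artifacts do not
reproduce across replicates. Intersecting replicate call sets
(`intersectPairings()`) therefore enriches for true mutations - the
qualitative replicate-design effect.

What the generator deliberately does **not** emulate: read-level error
processes, alignment context, correlated quality properties, non-Gaussian
tails, locus-dependent artifact rates, or shared artifacts between
replicates. Passing tests on this generator show that the machinery -
dominance counting, regression, coverage normalization, the ROC algebra -
does what it claims under the model's assumptions; they do not certify
performance on any particular real platform, which is exactly why the
same-vs-same replicate exists as an experimental (not simulated) control
in real use.

`writeFixtures()` emits the five pipeline inputs (two VCFs, two per-base
depth TSVs, a label TSV) and refuses coverage totals above 2 Mb: a
per-base depth dump at exome scale would be hundreds of megabytes, so
file emission is intended for compact scenarios while exome-scale
experiments stay in memory (coverage then enters as a base count).

## What "calibrated" means here - a known limitation

The assigned FDR is a **tail** quantity: the FDR of a call estimates the
false-discovery proportion of the whole set accepted at that call's
score. Empirically (and by construction) the realized FDP of
$\{ \mathrm{fdr} \le t \}$ matches the *boundary* - the largest assigned
FDR in the subset - and the test suite asserts exactly that. It is *not*
a local (per-call posterior) error probability: the *mean* assigned FDR
of a subset is systematically below that subset's realized FDP whenever
the mixture is separated, because the low-FDR members of the subset pull
the mean down while the FDP is set at the boundary. The gap grows with
separation and vanishes only for uninformative data. Users who want
"average the FDRs of my selection to predict its error rate" semantics
should use `smooth = TRUE` and still read the result as a bound at the
selection boundary, not as a per-call posterior.

Other limitations worth knowing:

* Quality reconciliation across callers is out of scope: models and FDR
  functions are strictly per caller, and merged multi-caller lists are
  ranked by their per-caller FDRs.
* The FDR function defaults to the supplied tumor set's own scores in the
  denominator; pooling tumor comparisons across pairings is reachable by
  concatenating score vectors before `buildFdrFunction()`.
* Common coverage may be computed genome-wide or restricted to a target
  design (`restrict` in `commonCoverage()`); restriction is off by
  default and the choice must match how the call sets were filtered.
* Indels are excluded at ingestion; the framework scores single-base
  substitutions only.

## Problem sizes in the test suite

The shipped tests run the full pipeline at $n_{tn}$ between 1,200 and
5,000 calls with 1-3 seeds per property (about 10 s per trained pipeline
on one core), oracle checks on hundreds of randomized small instances,
and byte-level reproducibility on compact fixture configurations
(coverage $10^4$ bases). These sizes were chosen to exercise every code
path at stable Monte-Carlo error, and the whole suite completes in a few
minutes.

## A compact end-to-end run

```{r pipeline, eval = FALSE}
library(somaticFDR)

cfg <- syntheticConfig(nTnCalls = 2000, seed = 1)
exp <- generateExperiment(cfg)

model <- trainQualityModel(exp@sameSame, exp@tumorNormal,
                           exp@cSS, exp@cTN, samtoolsConfig(), seed = 1)
fn <- buildFdrFunction(scoreQuality(model, exp@sameSame),
                       scoreQuality(model, exp@tumorNormal),
                       exp@cSS, exp@cTN)

tn <- exp@tumorNormal
S4Vectors::mcols(tn@ranges)$Q <- scoreQuality(model, tn)
scored <- assignFdr(fn, tn)
head(as.data.frame(scored))

curve <- rocFromFdrs(S4Vectors::mcols(scored@ranges)$FDR)
auc(curve)
plotRoc(curve)
```

The same run is available from a shell through the config-driven driver:
`simulate`, `train`, `assign`, `roc`, `sweep` and `compare` subcommands
of `inst/cli/somaticfdr.R`, each of which logs config hash, seed, package
version and per-filter record counts to `run.log`.
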