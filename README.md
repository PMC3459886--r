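# somaticFDR

Per-mutation confidence values for somatic variant calls, derived from a
replicate "same versus same" null.

## The problem

Calling somatic mutations from tumor/normal sequencing is error-prone:
different callers agree on fewer than half of their calls, and each caller
emits several per-call quality metrics (base quality, depth, mapping
quality, consensus/somatic scores) with no principled way to rank or
threshold mutations across them. Researchers selecting mutations for
validation or clinical follow-up need a single per-mutation statistic.

`somaticFDR` assigns each mutation an empirical **false discovery rate**.
The empirical null comes from profiling the *same* (normal) sample twice
and running the identical calling pipeline on the pair: every call in that
same-vs-same comparison is a false positive by construction, so it samples
the artifact process under the experiment's exact lab and analysis
conditions.

## The method

For a caller's quality tuple *S* = (s₁, …, sₙ), *S* is superior to *T* iff
sᵢ > tᵢ for all *i*. The dominance-order **intermediate FDR** of a point in
quality space is the coverage-normalized tail ratio

    IFDR(S) = [ #{T ∈ ss : T ≥ S} / C_ss ] / [ #{T ∈ tn : T ≥ S} / C_tn ]

clamped to [0, 1], where *C_ss* and *C_tn* are the **common coverages** of
the two comparisons (bases covered at depth ≥ 1 in both members), which
make call counts from different searchable spaces commensurable. A random
forest regression trained on a uniform grid over the observed quality
space (up to *p* values per property; a random subset of grid points with
their IFDRs as response) generalizes this partial order to a total one:
the **generalized quality score Q = 1 − predicted IFDR**. The per-mutation
FDR is then the same tail ratio on the Q axis:

    FDR(q) = [ #{x ∈ Q_ss : x ≥ q} / C_ss ] / [ #{y ∈ Q_tn : y ≥ q} / C_tn ]

Calls are reported sorted by FDR. Because the null side characterizes the
platform rather than the tumor, the FDR(Q) reference can be reused across
experiments that share platform and caller.

For benchmarking without ground truth, each mutation contributes FDR to
the false-positive axis and 1 − FDR to the true-positive axis of an
**estimated ROC curve** (the unique split with FPR + TPR = 1 and
FDR = FPR/(FPR+TPR)); curves and trapezoid AUCs compare callers,
coverages, read layouts and replicate designs. With validation labels,
classical ROC curves, threshold sweeps and resampled AUCs are available.

## Worked example

A compact synthetic experiment with known labels (2,000 tumor-vs-normal
calls, half of them true mutations, quality shift 0.75 sd per property):

```r
library(somaticFDR)

cfg   <- syntheticConfig(nTnCalls = 2000, seed = 1)
exp   <- generateExperiment(cfg)
model <- trainQualityModel(exp@sameSame, exp@tumorNormal,
                           exp@cSS, exp@cTN, samtoolsConfig(), seed = 1)
fn    <- buildFdrFunction(scoreQuality(model, exp@sameSame),
                          scoreQuality(model, exp@tumorNormal),
                          exp@cSS, exp@cTN)

tn <- exp@tumorNormal
S4Vectors::mcols(tn@ranges)$Q <- scoreQuality(model, tn)
scored <- assignFdr(fn, tn)
head(as.data.frame(scored)[, c("chrom", "pos", "ref", "alt", "Q", "FDR")], 5)
#>   chrom     pos ref alt     Q FDR
#> 1  chrS   21060   T   G 1.000   0
#> 2  chrS 2813206   T   G 0.998   0
#> 3  chrS 4249388   T   G 0.998   0
#> 4  chrS 7200852   A   G 0.998   0
#> 5  chrS 8583593   G   C 1.000   0
```

The table is the prioritization order: the top rows are the calls whose
quality vectors are essentially never reached by same-vs-same artifacts
(FDR 0). Summary statistics from the same run:

```r
fdr <- S4Vectors::mcols(scored@ranges)$FDR
mean(fdr <= 0.05)                 # 0.104  - share of calls at high confidence
auc(rocFromFdrs(fdr))             # 0.724  - label-free estimated ROC AUC
lab <- syntheticLabels(exp)[somaticFDR:::.callKeys(scored)]
auc(rocFromLabels(fdr, unname(lab)))   # 0.83 - classical AUC vs truth

thresholdSweep(fdr, unname(lab), step = 0.05)[c(2, 5, 11), 1:3]
#>  threshold sensitivity specificity
#>       0.05       0.196       0.989
#>       0.20       0.635       0.839
#>       0.50       1.000       0.000
```

Reading the sweep: accepting calls at FDR ≤ 0.05 keeps specificity at 0.99
while recovering 20% of the true mutations; FDR ≤ 0.2 trades specificity
0.84 for sensitivity 0.64. The full pipeline is also drivable from a shell
via the config-based subcommands (`simulate`, `train`, `assign`, `roc`,
`sweep`, `compare`) in `inst/cli/somaticfdr.R`.

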