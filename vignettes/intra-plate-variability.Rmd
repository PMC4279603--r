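---
title: "Quantifying intra-plate variability of qPCR-based GMO measurements"
author: "qpcrPlateVar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intra-plate variability of qPCR-based GMO measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpcrPlateVar)
```

## The statistical model

A GMO quantification plate measures one material in many replicate wells:
per gene (transgene, reference) a 5-point standard curve in triplicate, a
no-template control, and 32 sample wells split over two DNA isolations of
16. A routine analysis averages everything into one number. This package
instead treats the plate as supporting a *population* of plausible
results: for a replicate setting $k$, any $k$-subset of each isolation's
wells, per gene, could have been the laboratory's replicate set. Drawing
$N$ such combinations at random and quantifying each one yields the
frequency distribution of results the plate could have produced.

Each combination is quantified by the standard-curve method. Per gene and
per baseline/threshold setting an ordinary least-squares line
$C_q = a + b\,\log_{10}(\text{copies})$ is fitted to the standard wells
(replicates as individual points), and sample Cq values are inverted
through it. One combination's GMO percentage is the **ratio of means**

$$\text{GMO\%} \;=\; f \cdot
  \frac{\overline{\text{copies}}_{\,\text{transgene}}}
       {\overline{\text{copies}}_{\,\text{reference}}} \cdot 100,$$

each mean taken over the $2k$ selected wells of that gene. Ratio of means
(not mean of per-well ratios) is used because transgene and reference
wells are unpaired on this plate design, and because it makes the
$k = 16$ case collapse to a single value — at full replication there is
nothing left to resample, so the population variance is exactly zero. The
factor $f$ (default 1) absorbs the material-specific zygosity /
copy-ratio-to-mass-fraction approximation; it is user knowledge about the
certified material, not computable from the plate, so it lives in the
configuration.

### The population statistics panel

The $N$ values of a (setting, $k$) cell are a complete population, not a
sample from something larger — every statistic therefore uses the
population convention with divisor $n$: $s = \sqrt{\tfrac1n\sum(x_i -
\bar x)^2}$, RSD $= 100\,s/\bar x$, and the empirical skewness

$$\upsilon = \frac1n \sum_{i=1}^{n}
  \left(\frac{x_i - \bar x}{s}\right)^{3}.$$

Trueness is measured as $100\,|\bar x - \text{nominal}|/\text{nominal}$.

Values are binned into equal-width classes spanning $[\min, \max]$,
labelled by their upper limits, intervals $(\text{lower},
\text{upper}]$ with the first class closed on its lower edge. The fit to a
Gaussian is tested by a deliberately *simplified* $\chi^2$: observed class
counts $n_i$ against expected $m_i$, $\chi^2 = \sum (n_i - m_i)^2 / m_i$,
**without** merging marginal classes when an expectation falls below 10 —
the construction stays simple enough to replicate cell by cell in a
spreadsheet, which is the audience this statistic serves. The result is
reported as the upper-tail probability (CHIDIST convention), displayed as
a percentage.

The $\ge 95\,\%$ cut-off summarises where the bulk of the distribution
sits: the largest count threshold $c$ such that classes with occupancy
$\ge c$ jointly hold at least 95 % of all values (ties at the line are
included), reported as middle class $\pm$ half range of the included
upper limits.

## Numerical and design choices

**Expected $\chi^2$ counts.** Expected counts use exact Gaussian interval
masses (CDF differences) with the first class's lower edge extended to
$-\infty$ and the last upper edge to $+\infty$. Midpoint-density
approximations lose tail mass systematically; open tails guarantee the
masses sum to 1. If an expected count is exactly zero the test refuses and
advises fewer classes, rather than returning an infinite statistic.

**Degrees of freedom.** With mean and SD estimated from the same
population, the default is $df = n_\text{classes} - 3$;
$n_\text{classes} - 1$ is available for comparison with one-constraint
spreadsheet implementations. The choice shifts the displayed probability
but not the $\chi^2$ value itself.

**Number of classes.** Default 20, user-adjustable. At $N = 5000$ this
resolves the histogram shape without starving the $\chi^2$ expectations.

**Binning range.** $[\min, \max]$ of each population, so class labels
drift with the data when the same plate is re-analysed under another
setting; no anchoring of the class containing the nominal value is
attempted.

**Degenerate populations.** All-identical values (the $k = 16$ case) have
no natural class width; binning falls back to a nominal width with a
warning, one occupied class results, skewness and $\chi^2$ are undefined
and reported as `NA`, and the RSD is 0.

**The resampling plan.** Combinations are drawn uniformly, without
replacement *within* each (gene, isolation) pool, independently across
pools and across combinations — so the same tuple may recur among the
5000. Exhaustive enumeration is impossible anyway at intermediate $k$
($\binom{16}{8}^4 \approx 2.8\times10^{16}$). The plan is a pure function
of (seed, pool sizes, ks, $N$); each $k$ uses the derived substream seed
$(\text{seed} + 10007\,k) \bmod (2^{31}-1)$, so one $k$ can be regenerated
without replaying the others. The *same* plan is applied to every
baseline/threshold setting — this is what makes setting comparisons
meaningful — and can be exported/imported as a text table for exact
re-runs.

**Undetermined Cq.** Wells without amplification are kept as an explicit
missing marker at parse time; policy is applied downstream. Default
`exclude`: a well undetermined in *any* setting leaves its pool for *all*
settings (preserving the shared plan), with a warning. The alternative
`zero_copies` counts such wells as 0 copies for detection-aware studies
near the limit of quantification.

**Calibration.** Regression of Cq on $\log_{10}$(copies), matching
instrument-software convention, replicate standards as individual points.
For balanced designs level-means fitting gives the same slope; only $R^2$
differs. NTC wells are validated (undetermined, or beyond a configurable
late-cycle cut) and never enter fits.

## The synthetic-plate generator

`simulatePlate()` emulates the canonical plate with known ground truth.
Its defaults *are* the study conditions of interest, chosen once:

* `trueGmoPercent = 0.1` — the regulatory minimum performance level,
  where quantification is hardest;
* `refCopiesPerReaction = 20000` — a realistic template load (~60 ng of a
  mid-sized plant genome), putting the transgene at ~20 copies/reaction;
* `slopes = -3.3219`, `intercepts = 37` — 100 % amplification efficiency,
  Cq values in the usual 20–35 range;
* `cqNoiseSd = 0.2` cycles of well-to-well noise;
* `isolationEffectSd = 0.1` cycles: one shift per DNA isolation, shared
  by both genes. Both genes are measured from the same extract, so an
  isolation-level template-amount difference moves every well of that
  isolation together and largely cancels in the copy ratio — which is the
  point of the dual-target design. The simulator reproduces that
  structure rather than inventing gene-specific extraction biases;
* `poissonTemplate = TRUE`: per-well template copies are Poisson draws
  around the nominal mean. This is the mechanism behind the right-skewed
  low-copy distributions — at ~20 transgene copies per well the relative
  Poisson spread is ~22 %, and Gaussian Cq noise alone cannot produce the
  observed asymmetry. A draw of 0 copies yields an undetermined Cq,
  exercising the missing-Cq policy;
* `nPseudoSettings = 5`, `settingJitterSd = 0.05` cycles: re-analysis
  under different baseline/threshold settings is emulated as small
  independent perturbations of the *same* wells' Cq values — one run
  re-read several ways, not several plates. The true inter-setting shift
  structure of real instruments is unknown; the jitter magnitude is a
  free parameter, not an estimate.

What the generator does **not** emulate: amplification-curve
(fluorescence-level) detail, inhibitors, pipetting gradients or
position effects across the plate, and any systematic (non-random)
dependence of Cq on the baseline/threshold choice. Passing tests on
synthetic plates therefore demonstrate the *statistical machinery* —
calibration, resampling, distribution statistics — under a realistic
noise model, not instrument-specific behaviour of real exports.

```{r example, eval = FALSE}
pe <- simulatePlate(simulationConfig(seed = 42))
report <- runAnalysis(pe, seed = 42, ks = 2:16, nCombinations = 5000)
head(report$summary)
plotRsdSweep(report$sweep)
```

## Problem sizes

The shipped test-suite and the acceptance script scale the analyses so a
full run stays comfortable on one CPU: the exhaustive-enumeration checks
use 3-well pools at $k = 2$ (81 enumerable tuples against 5000 draws); the
replicate-number trend checks use 50 simulated plates at the full 5000
combinations over $k \in \{2, 4, 8, 16\}$ (at 1000 combinations the
Monte-Carlo error on the skewness, roughly $\sqrt{15/N} \approx 0.12$,
would blur the $k$ trend); the acceptance script analyses one full plate
at the complete 2×2…2×16 ladder with 5000 combinations per cell, plus a
20-plate ensemble. These sizes keep the Monte-Carlo standard errors far
below the effects being demonstrated.

## Known limitations

* Real vendor exports must first be adapted to the canonical table schema
  (`Well, Target, Task, Cq, Quantity`); no instrument dialects are built
  in.
* The $\chi^2$ degrees-of-freedom convention in historical spreadsheet
  implementations varies; exact numerical agreement with any particular
  sheet may require setting `chiDf` accordingly.
* The package quantifies variability *within* one plate. Between-run and
  between-laboratory components, and regulatory interpretation, are out
  of scope.
* No confidence intervals are attached to the panel statistics: the
  population convention treats the $N$ combination values as exhaustive,
  and the residual Monte-Carlo error at $N = 5000$ is negligible relative
  to the effects of interest.
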