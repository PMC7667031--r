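---
title: "Methods: absolute multi-omics calibration, process allocation, and NGAM estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: absolute multi-omics calibration, process allocation, and NGAM estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omniflux)
```

omniflux implements a complete analysis chain for resource-allocation studies
of recombinant-protein-producing yeast grown in chemostats: absolute
quantification of both omics layers from spike-in standards, allocation of
the absolute layers to biological-process gene sets, cross-layer comparison,
steady-state physiology, and enzyme-constrained flux balance analysis (FBA)
with a maintenance-energy objective. Every stage can be exercised on
synthetic data with recorded ground truth, which is how the package tests
itself. This vignette explains the models, the tunable parameters, and the
design decisions, in that order of importance.

## The measurement model and absolute calibration

Both omics layers arrive as signals: FPKM-like values for mRNA, iBAQ values
(summed peptide intensity divided by the count of theoretically observable
peptides) for protein. Absolute scales are anchored by spike-in standards of
known concentration — an external mRNA mix covering the dynamic range
(36 standards by default) and a UPS2-style protein dynamic-range standard
(48 proteins over five orders of magnitude). The calibration model is
log-linear:

$$\log_{10}(\text{concentration}) = a \cdot \log_{10}(\text{signal}) + b,$$

fitted by ordinary least squares in log10–log10 space. The log-space choice
is deliberate: both axes span orders of magnitude, and a linear-space fit
would be dominated by the few largest standards. Protein standards detected
with fewer than two unique peptides are discarded before fitting
(`filter_standards()`, threshold `min_unique_peptides = 2`), the
conventional detection-quality rule for dynamic-range standards.

Per-sample absolute proteomes are obtained by calibrating the pooled
reference (iBAQ + standards) and multiplying through the TMT
sample/reference ratios; proteins absent from the reference stay absent.
Zero or missing signal is treated as missing data everywhere, never as a
zero concentration — log-space calibration is undefined at zero, and
inventing absolute values for undetected features would bias downstream
fractions.

## Allocation to bioprocess gene sets

Absolute layers are allocated to process gene sets (a 99-term GO-Slim-like
vocabulary by default, or custom GMT collections such as secretory-pathway
subsystems). The molar fraction of process $p$ in sample $s$ is

$$f_{p,s} = \frac{\sum_{g \in p} a_{g,s}}{\sum_{g} a_{g,s}},$$

with the mass (g/g) variant weighting each gene by its molecular weight.
Two conventions matter and are fixed by design: a gene belonging to several
processes contributes fully to each (the GO mapping is many-to-many), while
the denominator always covers all quantified genes — so fractions across an
overlapping ontology may sum above 1, and on a partition ontology they sum
to exactly 1 (a conservation property the tests enforce at 1e-9).

Differential expression between strains at a matched dilution rate uses a
two-tailed pooled-variance Student's t-test per process (or gene) on
replicate fraction values, with `log2FC = log2(mean_test / mean_reference)`
and the reference strain as baseline. P-values are reported raw by default
(the conventional `P < 0.05` call for this analysis); Benjamini–Hochberg
adjustment is available via `adjust = "BH"`. The test runs on fractions
rather than absolute sums because fractions are what the allocation figures
compare; `diff_units()` accepts any matrix, so the alternative is one call
away.

## Cross-layer comparison

Gene-level protein–mRNA correlation is the squared Pearson correlation of
log10 absolute abundances over the genes quantified in both layers
("protein–transcript pairs"); for abundances spanning orders of magnitude
only the log-space correlation is meaningful. Process-level correlation
compares untransformed fraction values across processes. Translation
propensity is the elementwise ratio P/T of absolute protein to absolute
mRNA; `compare_propensity()` reports its percent change between strains.

## Chemostat physiology

At steady state the growth rate equals the dilution rate $D$, and rates are
plain mass balances: uptake $q = D(c_{feed} - c_{residual})/X$, secretion
$q = D\,c_{residual}/X$, yield $= \text{titer}/X$, productivity
$= \text{yield} \times D$, with $X$ the biomass dry weight concentration.
Dilution of intracellular product and evaporation are ignored, the standard
steady-state assumptions.

## Enzyme-constrained FBA and the NGAM objective

The metabolic model is a GECKO-style linear program. Variables are reaction
fluxes $v$ and enzyme usages $e$ (mmol/gDCW); constraints are steady state
($S v = 0$ over internal metabolites), flux bounds, kcat coupling
($v_j \le k_{cat,j} e_j$, reversible enzymatic reactions split into coupled
forward/backward halves), and the shared enzyme pool

$$\sum_i MW_i \, e_i \le P_{total} \cdot f \cdot \sigma,$$

with $P_{total}$ the total protein content (g/gDCW, default 0.46), $f$ the
mass fraction of the proteome available to metabolic enzymes (default 0.5,
the conventional choice when the pool is constrained), and $\sigma$ the
average enzyme saturation (default 0.5). Measured absolute proteomics
tightens per-enzyme upper bounds ($e_i \le$ measured abundance); the unit
chain from molar cellular abundances is
mmol/gDCW = molecules/cell × cells/gDCW / (6.022e20), exposed as
`protein_to_usage_units()`. Measured exchange fluxes are boxed inside a
flexibility window $[m/\text{flex},\ m \cdot \text{flex}]$ (default flex
1.03, two-sided; a one-sided variant keeps the measurement as the lower
edge) so the LP is not overconstrained by measurement error.

For the maintenance-energy question the biomass flux is pinned to the
dilution rate — chemostat steady state forces growth = D — and the LP
**maximizes** the flux through the ATP-hydrolysis maintenance reaction
(NGAM). The optimization sense is a design decision worth stating
prominently: with growth fixed and catabolic inputs boxed by measurements,
maximizing NGAM measures the surplus ATP the measured physiology can
sustain beyond growth — the accessory energy available for protein
production, stress response and futile cycling. Because NGAM is a small
difference between large ATP flows, its optimum is sensitive to the
flexibility window: at flex = 1 and truth-implied proteomics bounds the toy
model recovers the configured NGAM to machine precision, while flex = 1.03
admits visibly higher optima (a few tens of percent on the toy network).
The objective value is the contract; the flux vector may be degenerate.

### The LP engine

The solver is a hand-written dense two-phase primal simplex with Bland's
anti-cycling rule (`solve_lp()`), written for auditability on toy-scale
problems. Enzyme columns are internally rescaled to capacity units
($k_{cat} e$) and every inequality row normalized to unit maximum
coefficient, which keeps the tableau well-conditioned despite kcats spanning
10^3–10^5 per hour against enzyme usages of 1e-5 mmol/gDCW. Feasibility
tolerance is 1e-8; the test suite checks the solver against exhaustive
vertex enumeration (every basis of the slack-augmented standard form) on
networks small enough to enumerate, at 1e-7. "Unbounded" is reported when
the optimum rides the conventional default flux cap of 1000 mmol/gDCW/h on
a bound the user never set.

## What the synthetic generator emulates — and what it does not

The generator reproduces the statistical structure the analysis assumes:
three strains (a reference and two evolved producers) × two dilution rates
(0.1/h, 0.2/h) × biological duplicates; ~2,800 protein–transcript pairs over
a 99-process ontology; 36 mRNA calibration standards chosen by stratified
quantiles of the dynamic range; 48 UPS2-like standards of which 5 are
emitted below the two-peptide detection threshold (so 43 survive the
filter); log-normal noise on all signal layers, the standard model for
RNA-seq and MS intensities and the one consistent with log-space
calibration.

Ground-truth abundances are log-normal with base log10 mRNA SD 0.5
(molecules/cell; about two orders of magnitude of dynamic range, a
realistic spread for yeast mRNA). Protein equals mRNA × a gene-specific
translation propensity × strain effects × replicate noise; the propensity
dispersion is set from the target coupling as
$Var(\log prop) = Var(\log mRNA)(1-R^2)/R^2$, so a configured protein–mRNA
$R^2$ of 0.5 is recovered by direct correlation of the truth layers.
Shipped strain effects are qualitative analogues of the biology the
pipeline is meant to resolve: the first ontology process plays "protein
folding" (up 1.5× in strain 2, 2.0× in strain 3, at both the transcript
and protein level), the second plays "storage-sugar metabolism" (up only in
strain 2). The toy metabolic network configures true NGAM directly per
strain × rate — strain 2 wastes the most maintenance energy, strain 3 the
least at equal product output — and solves glucose uptake from the ATP
balance, so the recorded exchange measurements are exactly consistent with
the configured NGAM. That construction is what makes exact NGAM recovery a
meaningful test rather than a coincidence.

Features of real data the generator does **not** emulate: peptide-level
identification artifacts, TMT channel interference and normalization,
between-process covariance structure (each gene's abundance is drawn
independently, so process-level protein–mRNA correlations are much weaker
than in real data, where shared regulation aligns whole processes), growth
rate-dependent global expression remodeling, and carbon limitation in the
chemostat records (biomass concentration is a fixed setting, not solved
from the feed). Passing tests therefore certify the analysis machinery and
its contracts, not biological realism of any particular number.

## Statistical power and the recovery benchmark

With biological duplicates, the differential t-test has two degrees of
freedom and a 0.05 critical value of 4.30 — recovery of a planted effect
needs a large effect-to-noise ratio. Process-level replicate noise is the
gene-level noise shrunk by the effective number of genes per process, and
that effective number is governed by the abundance distribution's tail: for
log-normal abundances the largest gene can dominate a process sum. On the
protein layer, whose log10 spread is $\sqrt{0.5^2+0.5^2} \approx 0.71$,
single-gene-dominated processes are common enough that duplicate-based
process tests miss even 2-fold planted effects at a noticeable rate — a
real limitation of duplicated designs that the package documents rather
than hides (and an echo of how much sparser significant calls are on
proteome fractions than transcriptome fractions in this kind of study). The
recovery benchmark in the test suite therefore plants transcriptional
effects (which propagate to both layers) and asserts significance on
transcriptome molar fractions, using a partition ontology of 50 blocks over
2,800 genes (~56 genes per block, comparable to real GO-Slim set sizes),
where the design has ample power; proteome calls are checked for direction.

## Numerical choices

* Calibration refuses to fit with fewer than two usable standards or
  zero signal variance; applying a curve to zero signal yields missing.
* Fractions error on an all-zero sample rather than dividing by zero.
* A nonpositive group mean leaves log2FC missing (flagged, not invented);
  the t-test is still reported.
* LP: feasibility 1e-8, oracle comparison 1e-7, Bland's rule for
  degeneracy; ties among degenerate optima are resolved by reporting the
  objective value only.
* All generators take an explicit seed and restore the caller's RNG state;
  identical (config, seed) gives byte-identical output files.

## Problem sizes

The shipped defaults — 2,800 genes, 99 processes, 12 samples, a ~20-reaction
toy network — run the full pipeline in about two seconds. The test suite's
simulation studies use 15–50 seeds per property and vertex-enumeration
oracles on networks of at most 6 reactions, sizes chosen so the whole suite
completes in under a minute while keeping every Monte-Carlo band at three
standard errors or better.

## Known limitations

* One enzyme per reaction: isoenzymes and complexes are out of scope; the
  model form, not genome-scale annotation, is the point.
* The dense simplex is for toy-scale models; genome-scale work needs a
  sparse industrial solver.
* The NGAM optimum inherits the flexibility window's slack; comparisons
  across strains are meaningful at a fixed flex, absolute values are not
  calibrated quantities.
* No multiple-testing correction by default (the conventional raw
  `P < 0.05` call); switch on BH adjustment for exploratory scans across
  many contrasts.
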