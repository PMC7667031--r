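# omniflux

Multi-omics resource-allocation analysis for recombinant-protein-producing
yeast grown in steady-state chemostats. The package is aimed at systems
biologists who have gene × sample signal matrices (FPKM for mRNA, iBAQ/TMT
intensities for protein), spike-in standard tables, chemostat measurements,
and a small enzyme-constrained metabolic model — and who want absolute
abundances, process-level allocation with differential calls, protein–mRNA
comparison, physiological rates, and maintenance-energy (NGAM) estimates out
the other end, reproducibly.

## What it computes

* **Absolute quantification.** Spike-in calibration by OLS in
  log10–log10 space, `log10(conc) = a·log10(signal) + b`: external mRNA
  standards calibrate FPKM; UPS2-style dynamic-range standards (filtered to
  ≥ 2 unique peptides) calibrate iBAQ
  (`iBAQ = Σ peptide intensities / #theoretical peptides`) for a pooled
  reference, which is propagated to all samples through TMT ratios.
* **Allocation.** Process fractions `f_p = Σ_{g∈p} a_g / Σ_g a_g` in
  mol/mol or g/g; two-tailed pooled-variance Student's t-tests between
  strains at matched dilution rates with log2 fold changes versus the
  reference strain.
* **Cross-layer comparison.** Gene-level R² of log10 absolute abundances
  over protein–transcript pairs; process-level R² of fractions; translation
  propensity P/T = protein/mRNA and its percent changes.
* **Chemostat physiology.** Steady-state balances: uptake
  `q = D(c_feed − c_residual)/X`, yield = titer/X, productivity = yield·D.
* **Enzyme-constrained FBA.** GECKO-form LP — fluxes plus enzyme usages,
  kcat coupling `v ≤ kcat·e`, pool constraint `Σ MW_i e_i ≤ P_total·f·σ`
  (f = 0.5, σ = 0.5 by default), proteomics as per-enzyme upper bounds,
  measured exchange fluxes boxed in a flexibility window (flex = 1.03),
  growth pinned to the dilution rate, and the ATP-hydrolysis maintenance
  reaction (NGAM) maximized as the accessory-energy readout. The LP engine
  is a dense two-phase simplex with Bland's rule, validated against
  exhaustive vertex enumeration.
* **Synthetic data with ground truth.** Generators for annotation, truth
  layers with configurable strain effects and protein–mRNA coupling, both
  assays with their standards, chemostat records, and a toy ec-network whose
  true NGAM is configured directly — so every stage is testable end to end.

## Worked example

```r
library(omniflux)
rep <- run_pipeline(pipeline_config(seed = 1))

rep$quant$mrna_curve
#> CalibrationCurve (log10-log10): slope=0.8613 intercept=1.9425 R2=0.960 n=36
rep$quant$protein_curve
#> CalibrationCurve (log10-log10): slope=0.9640 intercept=0.7675 R2=0.995 n=43
```

The mRNA curve is fitted from 36 standards spanning the dynamic range (the
configured truth is slope 0.9; attenuation from signal noise accounts for
the difference), the protein curve from the 43 of 48 UPS2-like standards
that survive the two-peptide filter.

```r
subset(rep$correlations, sample == "B184_0.2_1")
#>        sample   gene_r2 gene_n_pairs process_r2 process_n_pairs
#> 11 B184_0.2_1 0.4926734         2800  0.1869214              99
```

Gene-level protein–mRNA R² of 0.49 over 2,800 pairs recovers the
generator's configured coupling target of 0.5.

```r
rep$ngam[, c("condition", "ngam", "true_ngam")]
#>   condition      ngam true_ngam
#> 1   AAC_0.1 1.1844076      0.91
#> 2   AAC_0.2 2.2598949      1.30
#> 3  MH34_0.1 1.1573923      0.98
#> 4  MH34_0.2 1.9013995      1.40
#> 5  B184_0.1 0.8100397      0.70
#> 6  B184_0.2 1.6865704      1.00
```

Solved NGAM (mmol ATP/gDCW/h) at flex 1.03 sits above the configured truth
— the window admits surplus catabolism — but preserves the strain contrast:
the B184-like strain spends the least maintenance energy at both dilution
rates. At flex = 1 the solver returns the true NGAM to machine precision.

```r
d <- rep$diff[["mrna_B184_vs_AAC_0.1"]]
head(d[order(d$p_value), ], 3)
#>    unit_id log2_fold_change t_statistic      p_value significant
#> 98   bp098       0.03652227    36.66202 0.0007431609        TRUE
#> 1    bp001       0.95881814    20.89726 0.0022820905        TRUE
#> 73   bp073       0.22798769    18.02694 0.0030630696        TRUE
```

The planted folding-process upregulation (`bp001`, 2× in the B184-like
strain) is recovered with log2FC ≈ 0.96 and P < 0.05.

## Layout

* `R/` — implementation; `tests/testthat/` — unit, property and
  acceptance suites (oracle-first: closed forms, vertex enumeration,
  generator round trips).
* `vignettes/omniflux-methods.Rmd` — the methods vignette: models,
  parameters, generator design, numerical choices, limitations.
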