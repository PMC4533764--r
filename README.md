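# stressomics

Integrative proteome–transcriptome analysis of metabolite stress in bacteria.

Solventogenic clostridia such as *Clostridium acetobutylicum* are stressed by
their own fermentation products (butanol, butyrate). Transcriptome studies
alone miss a large layer of regulation: a substantial fraction of the
detectable stress proteome moves in the *opposite* direction from its mRNA,
or is present despite unchanged, well-expressed transcripts — the signature
of post-transcriptional regulation. `stressomics` packages the analysis
workflow needed to find and characterise those genes from iTRAQ quantitative
proteomics plus RNAseq/microarray transcriptomics, and ships a synthetic
multi-omic generator with planted ground truth so every screen can be
validated end to end.

## What it computes

* **iTRAQ differential proteome.** Ratios to a pooled reference are
  log2-transformed and median-centred, then tested per stress level with a
  SAM-style moderated statistic `d = (x̄_stress − x̄_control)/(s + s0)` with
  permutation-based FDR control via a δ threshold (δ = smallest value with
  estimated FDR ≤ 5 %). Proteins are classified five ways: `up` / `down`
  (FDR pass and linear fold ≥ 2.0 / ≤ 0.5), `nonsig`, and the
  exclusive-detection categories `stress_only` / `control_only`, which get
  the fixed heat-map sentinels **+6.0** and **−5.0** (fold changes cannot be
  computed when one condition is below the detection limit).
* **Transcript layer.** Median-of-ratios size factors, pseudocounted log2
  fold changes, a permutation DE stand-in (designed to be replaceable by an
  external DE table), and 0–100 percentile abundance ranks ("blue plots":
  least abundant feature → 0, most abundant → 100, per time point then
  averaged).
* **TSS / 5′UTR / leaderless annotation.** A TSS caller on strand-specific
  TEX± coverage (coverage step plus TEX+/TEX− enrichment filters), 5′UTR
  lengths, leaderless flags (TSS at the translational start), and
  condition-dependent leaderless switches.
* **RBS strength.** Exhaustive Shine–Dalgarno motif × spacer search over the
  21 nt upstream window against a calibrated score table spanning −18.92
  (no RBS) to 12.87 (perfect AGGAGG at optimal spacer).
* **Integration screens.** Discordance calling (opposite protein/mRNA
  patterns, or exclusive detection despite good mRNA ranks), hypothesis
  screens H1–H3 (constitutive translational inefficiency; stress-blocked
  translation; translational up-regulation with long-5′UTR / strong-RBS
  annotation), revised abundance-percentile screens (mRNA rank < 60 with
  protein rank > 80, and mirrored), per-category Pearson correlations, and
  COG enrichment (one-sided Fisher, BH).

## Worked example

```r
library(stressomics)

v <- simulate_and_validate(generator_config(n_genes = 300, seed = 1),
                           outdir = "readme_run")
print(v$run)
#> stressomics integrative run: readme_run/run
#>   BuOH: 288 proteins detected, discordant 17.7%, H3 hits 22
#>   BA: 288 proteins detected, discordant 18.8%, H3 hits 22
#>   union of detected sets: 289
#>   TSS records: 286, median control 5'UTR 33 nt

v$confusion
#>               called
#> planted        control_only down nonsig stress_only  up
#>   control_only           48    0      0           0   0
#>   down                    0   78      0           0   0
#>   nonsig                  0    0    288           8   0
#>   stress_only             0    0      0          46   0
#>   up                      0    0      0           0 108
round(v$category_accuracy, 3)
#> [1] 0.986
```

Reading this: 288 of 300 simulated genes were quantified in at least one
condition per stressor (the rest fall below the iTRAQ detection limit
everywhere); ~18 % of detected proteins are called discordant, matching the
planted discordant mass; the 22 H3 hits are the genes planted with an 8×
translation boost on flat mRNA; the planted-vs-called confusion matrix is
nearly diagonal (98.6 % accuracy), with the only confusions being
borderline-abundance `nonsig` genes drifting across the detection limit.
The run directory contains per-stage TSVs (`proteome_de_*.tsv`,
`integration_*.tsv`, `tss_records.tsv`, `rbs_scores.tsv`, ...), a
`summary.yaml` whose every number is recomputable from those TSVs, and a
`run.log` recording each threshold.

A thin CLI over the same functions lives at
`inst/scripts/stressomics-cli.R` (`simulate`, `run-all`, `validate`).

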