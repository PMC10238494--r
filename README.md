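# mrmpanel

Targeted-proteomics (MRM/SRM) biomarker panels fail most often in the gap
between discovery and validation: candidates found by deep, long-gradient
profiling do not survive re-measurement on the fast triple-quadrupole assays
used clinically. `mrmpanel` implements the alternative strategy of building a
library of *quantifiable surrogate peptides* up front — peptides already
shown to be measurable in neat serum/plasma on a short (10 min) MRM gradient
— and then running discovery and validation in that same assay setting. The
package covers the whole workflow for computational method development:

1. **Library construction** — in-silico tryptic digestion (zero missed
   cleavages, no cleavage before proline), candidate scoring against
   detectability rules (preferred length 6–16 aa; Kyte–Doolittle GRAVY
   bounds; Cys/Met and N-terminal Trp instability; N-X-[S/T] glycosylation
   sequons; ragged C-terminal basic pairs RR/KK/RK/KR), seeded per-protein
   surrogate selection, and monoisotopic precursor/y-ion m/z computation
   with heavy labels (Lys +8.01420 Da, Arg +10.00827 Da).
2. **Quantifiability screening** — Gaussian-smoothed peak detection with a
   robust baseline (median / 1.4826·MAD); a peptide is quantifiable when
   SNR > 3 (high confidence above 10), retention times of standard, sample
   and spiked-in standard agree, and the top-3 product-ion ratio vectors
   match (cosine ≥ 0.95).
3. **Two-stage discovery/validation cascade** — stage 1 keeps peptides with
   case/control fold change ≥ 1.2 in either direction *and* two-sided
   Wilcoxon rank-sum p < 0.05; stage 2 re-applies the fold-change filter,
   same direction, on an independent validation cohort.
4. **Analytical QC** — calibration linearity (OLS, R²) with the 5-of-6
   accuracy rule (fitted/measured within ±20%), intra-/inter-day precision
   (CV of 5 replicates), 7-day storage stability, and internal-standard
   quantification `conc = (analyte area / IS area) · IS amount`; a marker
   validates only if every component passes.
5. **Hold-out classifier evaluation** — stratified 70/30 splits over
   repeated random states (replicates never straddle the split), ridge
   logistic regression on standardized log10 abundances, rank-statistic AUC
   (`AUC = U/(n₁n₀)`), and sensitivity/specificity at a Youden threshold
   frozen on training data.

A first-class simulation module generates every input — blood-like
proteomes, MRM chromatograms with planted SNR, case/control cohorts with
planted fold changes, calibration and precision series — with recorded
ground truth, so each stage is testable without instrument data.

## Worked example

Digest a protein, score the candidates, and compute transitions:

```r
library(mrmpanel)
cands <- score_candidate(digest_tryptic("TPDVSSALDKAVIDDAFARK", "P1"))
cands[, c("sequence", "length", "gravy", "n_flags", "priority_tier")]
#>     sequence length gravy n_flags priority_tier
#> 1 TPDVSSALDK     10  -0.5       0             1
#> 2  AVIDDAFAR      9   0.6       0             1
#> 3          K      1  -3.9       2             3

compute_mz("AVIDDAFAR", charge = 2)
#> transition_set AVIDDAFAR (light, 2+): precursor m/z 489.2562
#>   y8^1+  906.4680
#>   y7^1+  807.3995
#>   y6^1+  694.3155
```

The first two peptides are clean tier-1 surrogates; the C-terminal `K`
fragment is too short and too hydrophilic, so it drops two tiers. The
doubly charged precursor of AVIDDAFAR sits at m/z 489.2562 with its three
longest y-ions as transitions.

Simulate paired cohorts (50/50 discovery, 96/95 validation, fold change 1.5
planted on 10 of 100 peptides) and run the cascade:

```r
disc <- generate_cohort(cohort_spec(50, 50, 100, 10, planted_fc = 1.5, seed = 42))
vali <- generate_cohort(cohort_spec(96, 95, 100, 10, planted_fc = 1.5, seed = 43),
                        differential_ids = disc$truth$differential_peptide_ids)
res <- run_cascade(disc$quant, vali$quant)
res
#> marker_results: 100 peptides; 10 passed discovery; 10 passed validation
sum(res$passed_validation & res$peptide_id %in% disc$truth$differential_peptide_ids)
#> [1] 10
```

All ten planted markers survive both stages and no null peptide is called.

The whole workflow, from proteome simulation to the hold-out metrics table,
runs from one config:

```r
res <- run_pipeline(system.file("extdata", "demo_config.json",
                                package = "mrmpanel"),
                    out_dir = "demo_run", seed = 1)
#> [proteome] in=40 out=40
#> [library] in=785 out=40 candidates -> surrogates
#> [screening] in=40 out=20 quantifiable peptides
#> [cascade] in=20 out=8 (stage1=8)
#> [qc] in=8 out=5
#> [evaluate] in=5 out=5 random states
```

The run log is the auditable funnel: 785 tryptic candidates → 40 surrogates
(one per protein) → 20 quantifiable → 8 cascade survivors → 5 QC-validated
markers, which the classifier stage then evaluates over five random states
(`metrics.csv` holds per-state specificity/sensitivity/AUC/accuracy plus
their average). A thin shell wrapper is installed at
`inst/scripts/mrmpanel.R` (`run-all --config ... --seed ... --out ...`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the packaged demo pipeline end-to-end from the installed package
(writing its outputs under `results/`) and emits the acceptance JSON.

## Vignette

`vignettes/mrmpanel-methods.Rmd` documents the models and assumptions: the
scoring-tier construction, the SNR definition, the noise models behind the
simulators and what they deliberately leave out, numerical conventions
(inclusive thresholds, tie handling, degenerate inputs), and known
limitations.
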