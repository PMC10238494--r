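---
title: "Methods: surrogate-peptide libraries and MRM panel validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surrogate-peptide libraries and MRM panel validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmpanel)
```

# The workflow and its assumptions

`mrmpanel` models the quantifiable-peptide-library strategy for blood
biomarker work: instead of discovering candidates on deep profiling runs and
losing most of them when they are re-assayed on a fast targeted instrument,
one first builds a library of surrogate peptides already proven quantifiable
in the validation setting (neat serum or plasma, 10-minute MRM gradient),
then runs discovery *and* validation against that library. The package
implements each stage as a testable unit and ships simulators that generate
every input with known ground truth.

# Library construction

**Digestion.** Fully tryptic, zero missed cleavages: cut after every K or R
except before proline. The zero-missed-cleavage choice is the minimal
reading of "R or K at both ends"; surrogate peptides for quantification are
conventionally fully tryptic because partially cleaved forms quantify
unreliably. The protein's N-terminal fragment is a valid candidate (its
left boundary is the protein start); the C-terminal fragment qualifies only
if it itself ends in K/R. Coordinates are 0-based half-open, and the
concatenation of all fragments reconstructs the protein — an invariant the
test suite checks against a brute-force substring oracle.

**Scoring.** Each candidate receives independent boolean flags:

| flag | rule | rationale |
|---|---|---|
| `length_out_of_range` | length outside [6, 16] | detection rates drop outside this range on short gradients |
| `hydrophobicity_extreme` | GRAVY outside [−2, 2] | extreme peptides have irreproducible retention times |
| `has_cys`, `has_met` | any C / any M | oxidation-prone, chemically unstable |
| `nterm_trp` | W at position 1 | unstable N-terminal tryptophan |
| `glyco_sequon` | N-X-[S/T], X ≠ P | occupancy makes the unmodified form unreliable |
| `ragged_end` | C-terminal dipeptide in {RR, KK, RK, KR} | variable digestion at basic pairs |

The priority tier is ordinal: `1 + number of triggered flags`. The
selection rules only rank candidates as higher or lower priority; a count
of violated criteria is the simplest order that is monotone in the criteria
(adding a flag never improves a candidate), which the tests verify. The GRAVY scale is
Kyte–Doolittle with cutoffs ±2.0; no scale or cutoff is dictated by the
workflow, so both are config-exposed (`selection_config()`). The six listed
trypsin-resistant pairs decompose into two mechanisms: KP/RP suppress
cleavage (applied during digestion), while RR/KK/RK/KR mark a ragged
C-terminus (applied during scoring). Digestion-rule lists often conflate the two
mechanisms; the decomposition makes each testable. Under
zero missed cleavages a digestion product can rarely end in a basic pair,
so the ragged flag matters mainly when scoring externally supplied peptide
lists.

**Selection.** One surrogate per protein (configurable) from the best
available tier, ties broken by a seeded random draw; proteins whose best
candidates are low-tier still get one (a weak surrogate beats none), and
proteins with no tryptic candidate are reported.

**Masses.** Monoisotopic residue masses, water 18.0105646 Da, proton
1.00727646 Da. Heavy labels sit on the C-terminal residue
(Lys ¹³C₆,¹⁵N₂ = +8.01420 Da; Arg ¹³C₆,¹⁵N₄ = +10.00827 Da), so the
precursor and every y-ion shift together. Without measured spectra the
"top three" product ions are taken deterministically as the three longest
y-ions; real method development would re-rank them by observed intensity.

# Quantifiability screening

Instrument software reports peaks without publishing a formula, so the SNR
definition is fixed here: apex of the 5-point-moving-average-smoothed trace
minus a robust baseline (median of samples more than 0.5 min from the
apex), divided by the robust noise SD (1.4826·MAD of those samples). A
constant trace yields zero noise and the SNR is reported as an `Inf`
sentinel with a warning, never an error. Peak area integrates the
baseline-subtracted trace (floored at 0) over apex ± 3σ, with σ from the
smoothed peak's FWHM/2.3548.

A peptide is quantifiable when all three gates pass: best-transition
SNR > 3 (high confidence above 10); max pairwise retention-time difference
between standard, endogenous and spiked runs ≤ 0.2 min (inclusive, with a
1 ns floating-point guard); cosine similarity of the top-3 transition area
vectors ≥ 0.95. The RT tolerance, ratio threshold and baseline exclusion
half-width are package choices, config-exposed in `screening_config()`.
Every failure carries a machine-readable reason (`low_snr`, `rt_mismatch`,
`ratio_mismatch`, `missing_peak`).

# Discovery/validation cascade

Technical replicates are collapsed to their mean first. Stage 1 keeps
peptides with linear-scale fold change (ratio of group means; median
optional) at least 1.2 in either direction — both boundaries inclusive —
and two-sided Wilcoxon rank-sum p < 0.05. Stage 2 re-applies only the
fold-change criterion on the validation cohort, restricted to stage-1
survivors, and additionally requires the same direction of change
(direction consistency is this package's addition; without it a marker
could "validate" by flipping sign). No multiple-testing correction is
applied by default (raw p-values are this workflow's deliberate choice); a
Benjamini–Hochberg option exists (`discovery_config(adjust_p = TRUE)`).
Missing values are dropped per peptide, not imputed — MRM missingness is
informative. The rank-sum backend is exact enumeration for small untied
groups and the tie/continuity-corrected normal approximation otherwise;
all-identical input returns p = 1 rather than a division-by-zero.

# Analytical QC

Calibration uses unweighted OLS over ≥ 6 concentrations (1/x weighting
optional) and reports R² plus per-point accuracy defined as the value
estimated from the fitted line divided by the measured value, in percent.
A curve is acceptable when at least n−1 of n points (5 of 6) fall within
100 ± 20%. Precision is the CV of five replicates: intra-day is the worst
day's CV, inter-day the CV of daily means; stability is 7-day recovery
(deep-freeze and 4 °C conditions — the temperature labels are metadata)
within 100 ± 20%. The 20% CV and stability tolerances are bioanalytical
convention, not dictated by the workflow, and are config-exposed
(`qc_config()`). A marker validates only if every component passes; the
gate is monotone in the tolerances (relaxing one never de-validates), and
missing component results reject with `incomplete_qc`.

# Classifier evaluation

Deep learning, logistic regression, random forest and gradient boosting
tend to perform near-identically on small marker panels of this kind, so
the package defines a pluggable classifier contract (any
`fit`/`predict` pair emitting probabilities) with ridge logistic regression
(glmnet, fixed small λ, standardized log10 features) as the reference
implementation. Evaluation is a stratified 70/30 hold-out repeated over
random states; technical replicates never straddle the split (they are
aggregated at the biological-sample level before splitting). The operating
threshold is Youden-optimal on training scores and frozen before the test
block is scored. AUC uses the midrank Mann–Whitney identity, which equals
trapezoidal integration with ties counted half — tested to 1e-12 against a
pair-counting oracle. Samples outside the case/control labels (e.g. an
other-cancer group) are excluded from training and metrics but scored by
every state's model, giving the per-group probability distributions used
for generalisation checks. Stratification is enforced by default although
it is a package choice; an unstratified mode exists.

# Synthetic data: what it emulates and what it does not

* **Proteomes** are i.i.d. draws over the 20 residues (uniform by default —
  no composition was specified); real sequences have domain structure and
  biased composition, so library-size fractions observed on synthetic
  proteomes do not transfer to real FASTA inputs.
* **Chromatograms** are Gaussian peaks over additive Gaussian baseline
  noise in a 10-minute window (default σ = 0.05 min ≈ 7 s FWHM, 2 Hz
  sampling — typical for short-gradient MRM). No tailing, drift,
  interference or co-elution is simulated; instrument vendors do not
  publish baseline noise models, so Gaussian baseline noise is a package
  choice,
  flagged as such. The screening panel plants its ground-truth SNR on the
  best transition, the quantity the screening stage estimates.
* **Cohorts** draw per-peptide base abundances log10-uniform over [3, 8]
  (the observed MRM intensity dynamic range in blood), multiply the
  differential subset by the planted fold change in cases, and apply
  mean-one multiplicative log-normal noise for biological (CV 0.2 default)
  and technical (CV 0.2, two replicates) variation. Peptides are
  independent — no correlation structure, batch drift or missingness is
  simulated — so a green cascade test establishes correctness of the
  filters, not robustness to correlated real-world serum data.
* **Calibration/precision series** apply multiplicative CV errors to an
  exact line; with all noise at zero, every estimator (fold change, R²,
  accuracy, CV, IS quantification, peak height/RT) returns its planted
  value exactly, which the acceptance tests assert. The zero-noise SNR is
  `Inf` by construction of the definition, so the noiseless-identity check
  asserts the sentinel rather than a finite value.

The screening-mixture table (`screening_mixture_default()`) records the
composition used to pool screening samples: 40 breast + 20 pancreatic +
20 thyroid + 20 ovarian + 18 lung + 20 colorectal = 138 cancer samples,
plus 30 disease-free.

# Numerical conventions

* All thresholds are inclusive where the rule says "at least" (fold change
  1.2, RT tolerance, 5-of-6 accuracy).
* All generators and selectors draw from a locally seeded RNG and restore
  the global seed; identical seeds give bit-identical outputs, including
  across the pipeline driver, whose stage seeds derive from the global seed
  via a fixed linear map kept below 2³¹.
* Ties: midranks in the AUC and rank-sum statistics; seeded uniform draw in
  surrogate selection; `which.max` (first maximum) at chromatogram apexes.
* Degenerate inputs fail loudly (`stop()`) when a precondition is violated
  (empty sequence, invalid residue, charge 0, IS area 0, < 6 calibration
  points) and fail *softly* with a reason code when they are legitimate
  screening outcomes (missing peak, nonpositive group center, zero SD).

# Design choices on open points

* The pipeline config is JSON (`jsonlite`), one structured text file with
  schema validation (unknown sections/keys rejected); the resolved config
  is written next to the outputs of every run.
* The demo pipeline engineers a fixed number of stability failures among
  cascade survivors so the QC gate's attrition is visible in the funnel;
  the count is config-exposed (`qc.n_fail_qc`).
* Per-point calibration accuracy follows the response-scale definition
  (fitted/measured). The alternative back-calculated-concentration reading
  amplifies leverage at low concentrations and cannot satisfy the
  documented 5-of-6 behaviour for a single perturbed point.

# Known limitations

* No mzML/raw parsing, ionization physics or LC chemistry; inputs are
  text-format traces and tables.
* The "top three" product ions are index-ranked, not intensity-ranked.
* Collision energies are carried as opaque metadata in transition lists,
  never computed.
* The funnel proportions on synthetic data (e.g. 785 → 40 → 20 → 8 → 5 in
  the demo) illustrate mechanics only; real-cohort headline numbers depend
  on instrument data this package does not model.
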