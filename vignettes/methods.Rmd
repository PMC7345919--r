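---
title: "Methods: synthetic serum NMR fingerprinting with OPLS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic serum NMR fingerprinting with OPLS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model, the synthetic-data
generator, the numerical choices behind `nmrfp`, and their limitations.
Code chunks are illustrative and not evaluated when the vignette is
built; the full default study takes about six minutes on one CPU.

## 1. Problem and estimator

Serum ¹H NMR spectra of early-lactation dairy cows are regressed on two
energy-balance biomarkers, β-hydroxybutyrate (BHBA) and non-esterified
fatty acids (NEFA). Each spectrum is a row of intensities on a shared
chemical-shift axis; the scientific deliverable is (a) a calibrated
predictive model per biomarker and (b) the *fingerprint*: which
metabolites' resonances are significantly associated with each
biomarker, and in which direction.

The estimator is single-response OPLS (orthogonal projections to latent
structures). Given column-centered `X` (n × K) and centered `y`:

1. predictive weight `w = X'y / y'y`, normalized to unit length;
2. for each of `n_orth` orthogonal components: score `t = X w`, loading
   `p = X't / t't`, orthogonal weight `w_o ∝ p − (w'p) w` normalized,
   orthogonal score `t_o = X w_o`, loading `p_o`, and deflation
   `X ← X − t_o p_oᵀ`;
3. one predictive component `t_p = X w`, `q = y't_p / t_pᵀt_p` from the
   filtered matrix.

Prediction applies the stored orthogonal filter and then scores, which
collapses to a single regression vector `b`, so
`ŷ = X_new b + ȳ_train`. With `n_orth = 0` the model is exactly NIPALS
PLS1 with one component; the test suite asserts this equivalence to
1e-10 against an independently coded PLS1, whose coefficients are in
turn checked against a SIMPLS implementation.

Two sign conventions make results reproducible across platforms:
`cor(t_p, y) ≥ 0` (larger predictive scores mean higher concentration),
and each orthogonal loading's largest-magnitude element is positive.

**VIP.** With a unit-norm predictive weight and a single predictive
component, the usual variable-importance-in-projection formula collapses
to `VIP_j = √K |w_j|`, so `mean(VIP²) = 1` identically and the
conventional VIP > 1 cutoff marks bins carrying more than an average
share of the predictive direction. VIP is computed on the predictive
component only.

**Model complexity.** The number of orthogonal components is chosen by
venetian-blind cross-validation: the smallest `n_orth` whose RMSECV is
within 2 % of the curve minimum (parsimony rule). On the default study
both biomarkers select two orthogonal components.

## 2. Preprocessing

The chain applies, in order: (1) water-region deletion (4.68–5.00 ppm),
(2) correlation optimized warping, (3) total-area normalization
(rows sum to 1), (4) deletion of methanol (3.32–3.36 ppm), the internal
standard region (0.40–0.60 ppm) and everything above 9.00 ppm,
(5) asymmetric least squares baseline correction, (6) mean centering.

Choices worth stating:

- **Step order is kept literal** even though normalizing *before* the
  second deletion means post-deletion rows no longer sum to exactly 1;
  a `renormalize_after_deletion` flag (default off) is provided.
- **COW** uses segment length 80 bins, slack 5, and the mean calibration
  spectrum as reference. The warp is a dynamic program over integer
  boundary displacements maximizing the summed per-segment Pearson
  correlation with the reference, endpoints fixed, ties broken toward
  zero shift, warped intensities by linear interpolation. On tiny
  instances the DP is verified against exhaustive enumeration of all
  feasible boundary placements.
- **Baseline**: "automatic weighted least squares" is implemented as
  asymmetric least squares with a second-difference penalty
  (λ = 1e5 on unit-area rows, p = 0.001, 10 iterations); non-convergence
  produces a warning and uses the last iterate. The sparse banded system
  is solved with the Matrix package.
- **Deletion intervals are closed** on both ends, ppm comparisons at
  tolerance 1e-9.
- **Provenance**: `run_preprocess()` returns a state object (step log,
  COW reference, retained axis, calibration column means) and
  `replay_preprocess()` reproduces the processed calibration matrix
  bit-for-bit and pushes validation spectra through the *stored* state —
  the calibration reference and means, never their own.

Cross-validation re-estimates the centering means per fold but keeps
the full-calibration COW reference; re-warping each training fold is
cost-prohibitive and warp leakage is negligible. A strict variant
(`run_config(strict_cv = TRUE)` or `cross_validate_strict()`) re-runs
the entire chain per fold; with preprocessing disabled the two paths
agree exactly, which the tests assert.

## 3. Validation and effect analysis

- **Venetian blinds**: sample `i` (input order) goes to fold
  `(i − 1) mod 10`.
- **Metrics**: R² = 1 − SSE/SST (SST about the full-sample mean for CV,
  the validation-set mean for external validation), RMSE, and NRMSE =
  RMSE divided by the interquartile interval of the observed response
  (type-7 linear-interpolation quartiles).
- **Permutation testing**: the response is permuted 50 times, the full
  CV re-run each time; both a one-sided Wilcoxon signed-rank p on
  (observed − permuted) and the assumption-free empirical
  `p = (1 + #{permuted ≥ observed}) / 51` are reported, because the
  customary "Wilcoxon significance of a permutation test" is ambiguous
  and the two readings are both defensible.
- **PCA screening**: SVD-based PCA with Hotelling
  `T² = Σ t²_a / λ_a` on PC1–PC2 against the F-distribution ellipse
  limit `[2(n−1)(n+1)/(n(n−2))] F₂,ₙ₋₂(α)`. Flags are advisory;
  removal requires an explicit `exclude` list in the run configuration,
  mirroring a manual-review step rather than automating it.
- **ASCA**: main effects only. Each factor's effect matrix replaces
  every row by its factor-level mean; its share is
  `100‖X_f‖²_F / ‖X‖²_F`; significance by permuting that factor's
  labels (add-one rule, so p is never exactly 0). Days in milk is split
  at 16 d (median of the 4–30 d range), age into {2, 3, ≥4 years}; the
  residual is defined as total minus the sum of effects, which absorbs
  the non-orthogonality of unbalanced designs.

## 4. The synthetic generator

The generator's goal is statistical, not physical, realism: spectra on
which the pipeline behaves like it does on real serum data, with ground
truth to test against.

**Biomarkers.** BHBA and NEFA are bivariate lognormal, moment-matched on
the natural scale (means 0.55/0.75, SDs 0.21/0.32 mmol/L, Pearson
correlation 0.45). Lognormality enforces positivity and right skew; the
log-scale correlation is solved from the natural-scale target.

**Metabolite concentrations.** Each metabolite's log concentration is
linear in the standardized log biomarkers plus noise, parameterized by
planted *marginal correlations* `(r_bhba, r_nefa)`. The planted sign
pattern defines the ground-truth fingerprint: glucose, lactate, alanine
and valine negative for both biomarkers; glycine, phosphocholine, LDL,
VLDL and N-acetyl glycoprotein positive for both; acetate and creatine
positive-BHBA/negative-NEFA; betaine (+) and dimethyl sulfone (−) for
BHBA only; isoleucine (+), leucine (−) and hippurate (−) for NEFA only;
formate is a planted null. Three design choices matter:

- *Equalized line heights.* Median concentrations are set so the tallest
  resonance of every metabolite sits on a comparable intensity scale, as
  in protein-depleted serum; without this, VIP normalization is
  dominated by a few tall peaks.
- *Unassigned background.* 800 extra singlets ("clutter"), at fixed
  positions kept ≥ 0.035 ppm clear of annotated lines, each with a
  small random biomarker coupling (SD ≈ 0.3–0.4, clamped at ±0.45).
  Real serum spectra carry hundreds of such resonances; they give the
  spectral covariance a dense bulk, which is what makes the VIP > 1
  cutoff discriminate. With sparse peaks only, the cutoff corresponds to
  a trivially low correlation and planted nulls pass on sampling noise.
  The background library is deterministic in its own seed: it is
  chemistry shared by both cohorts, not a cohort draw.
- *In-sample orthogonalization of nuisance.* The biological residuals of
  the concentration model, and the per-sample shift-field coefficients,
  are projected against the realized biomarker scores within each
  cohort. Planted couplings — including the nulls — are then the
  cohort's exact ground truth rather than holding only in expectation,
  so recovery tests measure the pipeline, not seed luck. This removes
  only sampling correlation between nuisance and response; the nuisance
  variance itself is untouched.

**Rendering.** Multiplets are area-normalized Lorentzians (HWHM
0.0015 ppm ≈ 1 Hz at 700 MHz) with binomial line intensities for
doublet/triplet/quartet patterns, on a default axis of 8192 bins over
0.20–9.00 ppm. Per-sample peak movement is a global shift
(SD 0.002 ppm) plus a smooth local shift field of three random-phase
cosines (SD 0.004 ppm, within COW's slack), each cosine a
`a·cos + b·sin` quadrature pair so the field is linear in its Gaussian
coefficients. A broad macromolecular hump, residual water and methanol
artifact peaks (so region deletion has something to delete), a random
quadratic baseline and iid Gaussian noise complete the spectrum.
Rendering is seeded separately from the cohort draw, so spectra are
bit-reproducible.

**Effect magnitudes are a calibration.** The planted correlation
magnitudes were tuned once so that the full default pipeline reaches
external R² ≈ 0.8–0.9 for BHBA (and somewhat less for the noisier
NEFA), which is the regime the pipeline is meant to operate in. They are
not measurements; only the signs and the class structure are treated as
ground truth by the tests.

## 5. Numerical choices

- Deterministic seeding throughout: every stochastic stage derives its
  seed from the run seed; `with_seed()` restores the caller's RNG state.
- JSON artifacts are written with full numeric precision; the run
  configuration encodes its axis as shortest-exact decimal strings so
  the config round-trips bit-identically.
- The COW dynamic program scores segments with a correlation that
  defines all-constant segments as 0, avoiding NaN on flat regions.
- OPLS deflation stops with an informative error when the orthogonal
  weight norm falls below 1e-12 (degenerate deflation).
- The artifact manifest records seeds and md5 hashes of every file, and
  identical configurations reproduce identical hashes.

## 6. Limitations

- The generator renders singlet "clutter" and Lorentzian lineshapes
  only: no J-coupling fine structure beyond first-order multiplets, no
  phase or shimming artifacts, no field-dependent chemical-shift drift
  (pH-dependent citrate-type shifts are not modeled even though COW
  would handle them).
- Fixed-effect structure (days in milk, age, herd) is planted only
  implicitly (it is independent of the spectra), so ASCA on the default
  study quantifies a near-null partition; the ASCA machinery itself is
  validated on constructed fixtures with known effect percentages.
- The four-way classification depends on annotation windows
  (± 0.01 ppm around library lines); in crowded regions overlapping
  windows are reported, not resolved, and LDL/VLDL/glycoprotein
  envelopes are treated as annotatable regions like any metabolite.
- External validation uses a synthetic cohort drawn from the same
  generative distribution; it measures generalization across sampling,
  not across instruments, laboratories or populations.
- Cross-validated and external R² on synthetic data should not be read
  as claims about any real herd; they demonstrate that the pipeline
  recovers a signal of the planted magnitude at the planted noise.
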