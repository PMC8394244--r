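---
title: "A panel-based EEG biomarker framework for Alzheimer's disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A panel-based EEG biomarker framework for Alzheimer's disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Resting-state EEG changes in Alzheimer's disease (AD) along three axes:
the spectrum *slows* (power shifts from alpha toward theta and delta),
the signal becomes *less complex* (entropy- and dimension-type measures
fall), and *functional connectivity* between cortical regions weakens
(inter-channel coherence falls). No single scalar derived from one
channel and one band is a reliable marker on its own. The framework in
`adeeg` therefore treats marker discovery as a search problem: compute a
large, systematic space of candidate biomarkers, screen them
statistically, and let classifiers find the combination — the *panel* —
that separates AD patients from normal elderly controls (Nold).

The candidate space is the cross product of

* **eight analysis families** — band power (`DPS`), per-second amplitude
  change rate (`DEEGA`, µV/s), mean zero-crossing interval (`ZCI`, s),
  Tsallis entropy (`TSEN`), Higuchi fractal dimension (`HFD`),
  Lempel–Ziv complexity (`LZC`), approximate entropy (`APEN`), and
  magnitude-squared coherence (`COH`);
* **25 band specifications** — the five classical bands (delta 0–4,
  theta 4–8, alpha 8–12, beta 12–30, gamma 30–45 Hz) plus all 20
  *ordered* ratios (theta/alpha and alpha/theta are distinct features,
  because the direction of a ratio carries the direction of the disease
  effect);
* **locations** — the 19 channels of the 10–20 montage for the seven
  single-channel families, and the 171 unordered channel pairs for
  coherence.

A full montage therefore yields 7·25·19 + 25·171 = 3325 + 4275 = **7600
features** per subject; with `C` channels present the column count is
`7·25·C + 25·C(C−1)/2`, which the test suite checks as an invariant.

The pipeline then proceeds in the order a clinician-facing tool would
use:

1. **Screen** every feature with a two-sample test (AD vs Nold). The
   operative rule is raw `p ≤ 0.001`; Bonferroni-corrected values and
   the `0.05/N` critical value are reported alongside but do not gate
   the selection (both appear in the output so a reader can apply either
   convention). Features and channels are then ranked by their
   *probability distribution ratio* — each one's share of all
   significant tests — and the shortest prefix reaching a cumulative 80%
   is selected. Coherence pairs are kept whenever at least one of their
   biomarkers passes the `p` rule.
2. **Enumerate Stage-1 panels**: one selected band-spec feature crossed
   with every combination (sizes 1–10) of the selected locations,
   homogeneous per family. With 11 features, 12 channels and 10 pairs
   this is 44,902 panels per single-channel family and 325,567 in total
   — the package reproduces these counts exactly in closed form and by
   streaming enumeration.
3. **Rate each panel** with a linear SVM under stratified 10-fold
   cross-validation on the 60% training split; panels with pooled
   out-of-fold sensitivity *and* specificity ≥ 80% survive.
4. **Fuse** the survivors' biomarkers with linear discriminant analysis
   and evaluate once on the held-out 40%.
5. **Optimise**: search all panels of up to four biomarkers drawn from
   the surviving pool (919,310 panels for the reference pool of 69) for
   the smallest compliant panel, smallest sizes first.

`ad_fit()` wraps steps 1–4 and returns a classed model object with
`print`, `summary`, `coef`, `predict` and `validate` support;
`optimize_min_subset()` is step 5.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| Tsallis `k_states`, `q` | 2200, 0.5 | – | amplitude quantisation states and entropic order of the reference analysis |
| ApEn `m`, `r` | 2, 0.15·SD | – , µV | standard physiologic practice; `r` proportional to SD makes ApEn scale-invariant |
| Higuchi `kmax` | 8 | – | common choice for 128 Hz EEG; curve-length scaling saturates beyond it |
| Welch segments | 2 s Hann, 50% overlap | – | 0.5 Hz resolution resolves the 4 Hz-wide bands with ≥ 8 averages even on 60 s records |
| selection `p` rule | 0.001 | – | the screening threshold the count tables are built on |
| cumulative ratio | 80% | – | prefix-selection threshold for features and channels |
| panel thresholds | Sen, Spec ≥ 80% | % | survival rule for the SVM screen |
| split / folds | 0.6 / 10 | – | development/holdout split and CV folds (folds shrink with a warning when a class is smaller) |
| SVM | linear, cost 1 | – | small-n tabular screening; per-fold standardisation, no kernel tuning |

## Filtering

Bands are isolated with zero-phase Chebyshev type-II filtering: an
order-8 highpass with stopband edge at 0.85·lo cascaded with an order-8
lowpass with stopband edge at 1.18·hi, 40 dB stopband attenuation each,
applied forward–backward with reflection padding. Each filter is
realised as a cascade of second-order sections rather than one order-8
polynomial — at the small normalised frequencies of the delta band the
direct form loses stopband accuracy to coefficient rounding, while
biquads do not. This design keeps a mid-band sinusoid within 1 dB,
attenuates probes one octave outside each band by far more than 40 dB
(the forward–backward pass doubles the dB), and leaves the five-band
sum holding ≥ 90% of the 0.5–45 Hz variance of broadband noise — a
single order-8 bandpass cannot satisfy the last property because its
transition skirts notch out the band boundaries. The delta low edge is
clamped to 0.5 Hz: DC drift carries no neural signal. These response
figures are asserted in the test suite by steady-state sinusoid probes
through the filter exactly as applied.

## Conventions and numerical choices

* Samples are 0-based in time arithmetic; intervals are half-open
  `[start, end)`. The default artefact trim is 61–240 s; shorter records
  are analysed whole, with a warning, because one of the reference
  recording sites only provides 60 s.
* Zero crossings require strictly `x_t > 0` and `x_{t+1} < 0`; exact
  zeros never open or close a crossing. Fewer than two crossings yields
  a non-finite sentinel that is excluded downstream with a logged
  reason, as is any ratio with a |denominator| < 1e−12.
* The amplitude change rate closes each one-second block on the next
  block's opening sample, so the signed differences telescope over the
  block and a sinusoid over whole cycles scores ≈ 0; a summed (rather
  than mean) definition of the zero-crossing statistic would equal the
  total spanned time and carry no information, so the mean interval is
  used.
* The Higuchi dimension is the negative slope of `log L(k)` vs `log k`
  (the canonical curve-fitting estimator); a literal mean-of-curve-
  lengths variant is available as `variant = "curve-mean"` for
  comparison, but it is a curve-length summary, not a dimension.
* Band power is the mean of `|FFT|²/N` over the positive-frequency bins
  in `[lo, hi)`, DC excluded; mean (not sum) keeps ratios comparable
  across bands of different widths.
* Coherence ratios divide band-averaged coherences rather than
  averaging a ratio spectrum; with Welch averaging the former is the
  stable quantity.
* Ratio features apply the same family's biomarker to the two
  band-filtered signals — the only construction that makes sense of
  names like `TSEN theta/alpha` uniformly across all eight families.
* Ties at the cumulative-80% boundary include the tying item, and tied
  ratios are broken by total count, then lexicographically. The bundled
  worked-example count tables accumulate ratios rounded to three
  decimals, so their cumulative column can differ from exact arithmetic
  in the third decimal (81.343 printed vs 81.3449 exact for the
  12-channel selection); the package computes exactly and the tests
  compare at 0.01.
* The channel ranking uses the seven single-channel families only
  (coherence lives on pairs, not channels), which is why its total is
  461 rather than 475 in the worked example; a few tabulated rows also
  disagree with their own cell sums by one, and the package always
  recomputes totals from cells.
* LDA fusion standardises on the training set and falls back to a
  shrunken (diagonal-blended, ridged) Fisher discriminant when the
  within-class covariance is singular — routine with tens of features
  and tens of subjects — with a logged message.
* Panels are enumerated lazily in deterministic size-then-lexicographic
  order, so capped screens always rate the smallest panels first and
  identical seeds give bit-identical outputs; the 919,310-panel Stage-2
  stream is generated without materialisation.

## The synthetic cohort generator

No public EEG of the reference cohorts exists, so the package ships a
generator (`cohort_spec()`, `generate_cohort()`) that is deliberately
the *minimal* construction moving the three biomarker axes
independently:

* each channel is a weighted sum of five band-limited Gaussian noise
  sources (weights = the group's band profile) plus one band-limited
  source shared by all channels, then an AR(1) smoother and white
  measurement noise;
* **slowing**: AD moves a fraction (default 0.3) of the alpha weight
  into theta/delta;
* **complexity**: AD raises the AR(1) coefficient by 0.15, lowering
  LZC/ApEn/HFD;
* **connectivity**: AD cuts the shared-source weight by 40%. The Nold
  shared weight (1.0) was chosen so that parieto-parietal alpha
  coherence sits near 0.25–0.4, the range seen in eyes-closed resting
  recordings; a weaker source leaves the planted contrast inside the
  coherence estimator's noise floor.

Defaults are 20 + 20 subjects, 128 Hz, 180 s, all 19 channels, with a
Nold band-weight profile peaking at alpha. With all three effects at
zero the two groups are draws from one distribution, which the test
suite uses for its type-I and exchangeability checks. One master seed
derives an independent stream per (group, subject), so enlarging a
cohort never reshuffles existing subjects.

What the generator does **not** emulate: 1/f background structure,
ocular/muscle artefacts, age and sex covariates, non-stationarity,
volume conduction and reference-montage effects, or realistic spatial
covariance beyond a single global source. Passing tests on these
cohorts therefore demonstrate that the pipeline's statistics and
machinery behave as designed — planted effects are recovered in the
planted direction, null cohorts stay null, separable cohorts separate —
not that the framework attains any particular clinical accuracy.

## Problem sizes used by the tests and the acceptance script

The combinatorial and worked-example checks are exact and instantaneous.
For the signal-level and pipeline checks the package uses sizes chosen
to keep a full run on one CPU comfortable: unit-level oracle checks use
sequences of 30–10,000 samples; planted-effect recovery pools 24 + 24
subjects of 10 s across seeds, or one 20 + 20 cohort of 60 s; the
end-to-end run extracts the fast families (DPS, DEEGA, ZCI, LZC, COH)
from 20 + 20 subjects at 60 s and validates on an independently seeded
cohort of the same shape. ApEn, TsEn and HFD — whose cost is quadratic
or filter-bound — are exercised by their oracles and in the full
7600-column extraction audit on 8 s records. The minimal-subset
recovery experiment plants a jointly informative feature pair among 69
candidates, where neither feature alone clears the 80/80 rule but the
pair does, and checks that the smallest-first search returns (at most
one feature more than) the planted pair.

## Known limitations

* The SVM screen's hyperparameters are fixed (linear, cost 1), not
  tuned; the screen ranks panels, it does not certify generalisation.
* With tiny held-out sets the reported percentages are coarse-grained
  (one subject is 10 points at n = 10); the acceptance run uses 16
  held-out subjects.
* The Stage-1 screen caps the number of SVM-rated panels
  (`screen_cap`); the audit always reports the full closed-form counts,
  and the cap rates panels in deterministic smallest-first order.
* Coherence is computed on the channels as given; no surface-Laplacian
  or re-referencing correction for volume conduction is applied, so
  absolute coherence levels depend on the recording montage.
* EDF support covers the continuous core layout (EDF/EDF+C, int16
  records); annotations and discontinuous files are out of scope.
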