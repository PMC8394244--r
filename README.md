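# adeeg — quantitative EEG biomarker panels for Alzheimer's disease

Resting-state EEG changes in Alzheimer's disease (AD) in three
well-replicated ways: the spectrum **slows** (power moves from alpha into
theta/delta), the signal loses **complexity** (entropy- and
dimension-type measures fall), and inter-channel **coherence** drops. No
single channel/band scalar is a dependable marker, so `adeeg` implements
a panel-based discovery framework for researchers working with
19-channel 10–20 recordings of AD patients and normal elderly controls
(Nold):

1. band-filter each channel into delta/theta/alpha/beta/gamma
   (zero-phase Chebyshev II);
2. compute eight biomarker families per band and per *ordered* band
   ratio — band power ΔPS, amplitude change rate ΔEEG_A (µV/s),
   zero-crossing interval ZCI (s), Tsallis entropy
   `TsEn = (Σ P_i − P_i^q)/(q − 1)` (k = 2200 states, q = 0.5), Higuchi
   fractal dimension (slope of log L(k) vs log k), Lempel–Ziv complexity
   `C(N) = c(N)/(N/log₂N)` on the median-binarised signal, approximate
   entropy `ApEn = φ^m(r) − φ^{m+1}(r)` (m = 2, r = 0.15·SD), and Welch
   magnitude-squared coherence `|P_ab|²/(P_aa·P_bb)` per channel pair —
   7600 features on the full montage (25 band specs × [7 × 19 channels +
   171 pairs]);
3. screen features with two-sample tests (raw p ≤ 0.001; Bonferroni
   columns reported), rank by probability distribution ratio
   `P_i = x_i/Σx`, and keep the cumulative-80% prefix;
4. enumerate biomarker panels exhaustively (one feature × channel
   combinations of sizes 1–10; 325,567 panels in the reference
   configuration), rate each with a 10-fold cross-validated linear SVM,
   and keep panels with sensitivity and specificity ≥ 80%;
5. fuse survivors with LDA into one diagnostic model, evaluate on a
   held-out split, and search all ≤ 4-biomarker subsets (919,310 for a
   69-biomarker pool) for the smallest compliant panel.

Because no public data of this kind exists, the package ships a
synthetic cohort generator with independently controllable slowing,
complexity-reduction and coherence-loss effects; every stage is tested
against it and against closed-form oracles.

## Worked example

```r
library(adeeg)

spec   <- cohort_spec(n_ad = 10, n_nold = 10, duration = 30, seed = 42)
cohort <- generate_cohort(spec)
cohort$records[[1]]
#> <eeg_record> nold01 [NOLD]: 19 channels x 3840 samples @ 128 Hz (30.0 s)

tab <- extract_features(cohort$records,
                        methods = c("DPS", "ZCI", "LZC", "COH"))
tab
#> <biomarker_table> 20 subjects x 5700 features (10 AD / 10 Nold)

model <- ad_fit(tab, seed = 42, screen_cap = 100)
model
#> <ad_model> panel-fused LDA diagnostic model
#>   biomarkers: 55 from 55 panel(s)
#>   held-out: Sen 100.00%  Spec 100.00%  Acc 100.00%  MCC 1.00

model$selection
#> <selection_report> 5700 features screened (p <= 0.001 rule)
#>   significant: 1192 | selected band specs: 12 | channels: 15 | pairs: 171

head(model$selection$feature_ranking, 3)
#>      id count     ratio cumulative
#> 1 alpha   189 15.855705   15.85570
#> 2  beta   179 15.016779   30.87248
#> 3 delta   118  9.899329   40.77181
```

Reading the output: 5700 candidate biomarkers were computed (four of the
eight families on 19 channels / 171 pairs), 1192 of them separate the
groups at p ≤ 0.001 — the planted AD effects are strong here — and the
band specs covering 80% of those hits span 12 specifications led by
alpha (15.5% of all significant tests). One hundred of the smallest
panels were rated by the cross-validated SVM, 55 survived the 80/80
rule, and their LDA fusion classifies the eight held-out subjects
perfectly. `predict(model, newtable)` applies the frozen model to new
cohorts; `optimize_min_subset()` then hunts for the smallest panel that
keeps the performance.

The per-family extractors are ordinary functions
(`tsallis_entropy()`, `higuchi_fd()`, `lempel_ziv_complexity()`,
`approximate_entropy()`, `zero_crossing_interval()`,
`amplitude_change_rate()`, `band_power()`, `msc_coherence()`), and
`read_edf()` / `read_matrix()` ingest clinical recordings. A thin CLI
(`inst/cli/adeeg`) exposes the stages as subcommands
(`simulate … validate`, `all`) for shell use.

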