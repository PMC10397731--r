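---
title: "Brain rhythm codes: method, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain rhythm codes: method, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythmcode)
```

## The problem and the model

EEG-based emotion recognition usually feeds large multichannel feature sets
into a classifier. `rhythmcode` implements the opposite philosophy: find the
*single* channel-specific feature that classifies trials best, so that a
practical brain-computer interface needs one electrode.

The pipeline has four stages.

1. **Time-frequency analysis.** Each single-channel trial segment $x(t)$ is
   transformed with the reassigned smoothed pseudo-Wigner-Ville distribution
   (RSPWVD). The Wigner-Ville distribution

   $$W_x(t,\omega)=\int x\!\left(t+\tfrac{\tau}{2}\right)
     x^*\!\left(t-\tfrac{\tau}{2}\right)e^{-j\omega\tau}\,d\tau$$

   offers the sharpest time-frequency localisation of the quadratic class
   but suffers oscillatory cross-terms between signal components. Separable
   smoothing with a time window $g$ and a lag window $h$ gives the SPWVD;
   reassignment then moves each smoothed value to the local centre of
   gravity of the energy, $(\hat t,\hat\omega)$, computed from the ratios of
   the $\tau g$- and $D_h$-kernel transforms to the plain SPWVD. The
   reassigned plane keeps the smoothed cross-term suppression while
   restoring near-WVD concentration, and relocation conserves total plane
   energy exactly (a property the test suite asserts to $10^{-6}$ relative).

2. **Sequencing.** The frequency axis is cut into the five canonical bands
   (delta 0-4, theta 4-8, alpha 8-13, beta 13-30, gamma 30-50 Hz) and the
   time axis into 0.2 s timestamps, the average neuronal reaction time. The
   power in each band x timestamp box is averaged and the band with maximal
   mean power becomes that timestamp's symbol, giving a string over
   `{D,T,A,B,G}` (150 symbols for a 30 s segment).

3. **Code features.** By analogy with triplet codons over a 4-letter
   genetic alphabet, every window of three consecutive symbols (step one) is
   a *rhythm code*; there are $5^3 = 125$ possible codes, and a length-$L$
   sequence contributes exactly $L-2$ windows. A 32-channel recording thus
   yields $32 \times 125 = 4000$ counting features per subject; 62 channels
   yield 7750.

4. **Evaluation and selection.** Every (channel, code) count is scored by
   leave-one-trial-out cross-validation (LOTO-CV) under four classical
   classifiers (k-NN, RBF-SVM, LDA, multinomial logistic regression).
   Selection is two-phase: best code per channel, then best channel
   overall. A one-way ANOVA screen on each selected feature is *reported*
   (flagged at $p \le 0.05$), never used to remove features. An
   all-features majority-vote baseline is provided for comparison.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| timestamp interval | 0.2 s | average neuronal reaction time; fixed by the method |
| analysis window | last 30 s of each trial | equalises sequence lengths so counts are comparable; the trailing period is the steadier emotional state |
| band edges | 0, 4, 8, 13, 30, 50 Hz | canonical EEG bands; half-open intervals, gamma closed at 50, membership by bin centre |
| processing block | 2 s | bounds the quadratic transform cost; 0.2 s-aligned so no timestamp straddles a block edge |
| time window $g$ | Hamming, ~block/10 (odd) | conventional SPWVD default |
| lag window $h$ | Hamming, ~block/4 (odd), capped at one timestamp | see below |
| SVM | RBF kernel, $C=1$, $\gamma = 1/\mathrm{var}$ on standardised values | the source method names only the kernel; these are the common defaults |
| k-NN | $k \approx \sqrt{n_{\text{train}}}$, odd: 5 for 40/45-trial designs, 3 for 20 | stated rule of thumb |
| ANOVA screen | $\alpha = 0.05$ | conventional significance level |

**Why the lag-window cap.** The instantaneous autocorrelation
$z(t+\tau)z^*(t-\tau)$ reaches $\pm\tau_{\max}$ samples around $t$, where
$\tau_{\max}$ is half the lag-window length. If that reach exceeds one
timestamp (25.6 samples at 128 Hz), a quadratic *bridge* auto-term forms
between two same-band timestamps flanking a different one — delta energy
appears squarely inside a gamma timestamp — and the dominant-band argmax is
corrupted in a way no amount of averaging removes. Capping $h$ at one
timestamp (25 samples at 128 Hz) removes this artifact class entirely while
leaving ordinary tone/chirp localisation intact; the 0.25 Hz bin spacing of
a 2 s block is unaffected because reassignment, not the lag window,
determines the final frequency concentration.

## Numerical choices

- The transforms run on the analytic signal (mean removed, negative
  frequencies zeroed) so positive/negative-frequency interference never
  enters the plane. Frequency bins tile $[0, f_s/2)$ with one bin per block
  sample (half-sample lag steps).
- Reassignment ratios divide by the SPWVD; grid points with
  $|SPW| < 10^{-12}\max|SPW|$ are left in place. Reassigned coordinates are
  clamped to the block, so energy conservation is exact by construction.
- SPWVD/RSPWVD values are signed; they are clipped to zero only at the
  band-power averaging step, where the plane is read as instantaneous
  power.
- Ties: dominant band goes to the lower-frequency band; best-code ties to
  the lower base-5 code index (D<T<A<B<G); best-channel ties to the earlier
  channel in recording order; classifier vote ties to the lowest class
  index. All ties are measure-zero on real data but make the pipeline fully
  deterministic.
- Degenerate LOTO folds (zero-variance feature, single-class training set)
  predict the training-fold majority label and are counted in
  `n_degenerate`.
- The RBF-SVM is a deterministic sequential-minimal-optimisation solver
  (systematic pair selection, tolerance $10^{-3}$); logistic regression is
  Newton with tolerance $10^{-8}$, at most 1000 iterations. Repeated runs
  on identical inputs are bit-identical.

## What the synthetic generator emulates — and what it does not

`synth_dataset()` states a fully known world: per 0.2 s timestamp, the
scheduled band's carrier sinusoid (delta 2, theta 6, alpha 10, beta 20,
gamma 40 Hz) plays at 10 uV while the other four carriers play at 2 uV,
phase-continuous across timestamps, plus white Gaussian noise (1 uV
default). One designated channel carries a 3-symbol code motif inserted
into its schedule at a class-conditional per-timestamp rate
($r_0 = 0.05$, $r_1 = 0.35$).

Two generator choices deserve justification:

- **Dwell times.** Schedules are rhythm *bouts* (minimum two timestamps,
  geometric mean three), not i.i.d. symbols. Real EEG rhythms persist for
  hundreds of milliseconds; more fundamentally, a 0.2 s delta epoch holds
  less than half a cycle of a 2 Hz carrier, so the time-bandwidth product
  makes single-timestamp dominance physically unidentifiable at the
  sequencing resolution. With bouts, the zero-noise round trip
  (schedule -> signal -> sequence) is exact.
- **Motif insertion.** An insertion overwrites three consecutive timestamps
  and the left-to-right scan resumes *after* it, so motifs never
  interleave. If later insertions could overwrite earlier tails, the dense
  class-1 rate would plant interleaved shadow patterns (TGT, TTG, ...) as
  strongly as the motif itself, and no selector could prefer the nominal
  motif over its shadows; with disjoint insertion the planted (channel,
  code) is the unique strongest feature, which is the property the
  generator exists to provide.

A green planted-recovery test therefore establishes that the pipeline
recovers a known, well-posed band-dominance signal and its class-coupled
code — it does not establish performance on real EEG, which has 1/f
background, broadband transients, volume conduction, artifacts, and no
ground-truth schedule.

## Known limitations and honest caveats

- **LOTO pessimism under the null.** Leaving one trial out makes the
  held-out class the training minority (e.g. 19 vs 20). For an
  uninformative feature, classifiers that lean on class frequencies (LDA
  and logistic regression via empirical priors, k-NN via neighbour counts)
  therefore sit systematically *below* chance on permuted labels — measured
  means at $n=20$: LDA $\approx 0.30$, logistic regression $\approx 0.36$,
  k-NN $\approx 0.44$, SVM $\approx 0.46$. This is a well-known property of
  leave-one-out designs, not an implementation defect; the suite asserts
  the one-sided property (no spurious skill above chance) and the
  two-sided "indistinguishable from chance" acceptance check is left
  failing with this analysis on record. The same mechanism drives the
  all-features majority vote to very low accuracy on balanced designs:
  thousands of uninformative features vote anti-majority in unison.
- **No multiple-testing correction** is applied across the 4000-feature
  scan; the ANOVA screen is post-hoc verification of an accuracy-based
  selection, mirroring the source method.
- **Selection is subject-dependent.** The optimal feature varies across
  subjects; the package deliberately offers no cross-subject transfer.
- Scalp-region mapping uses a declared prefix table (FP/AF/F frontal, FC/C
  central, CP/P parietal, FT/TP/T temporal, PO/O occipital, midline Z
  ignored); published work rarely states its exact table, so regional
  percentages depend mildly on this choice.
- EDF input is not implemented (no EDF reader among the declared
  dependencies); the delimited-matrix + JSON-sidecar dialect is the
  interchange format, and the generator writes it so synthetic and real
  data are interchangeable downstream.

## A minimal worked run

```{r example, eval = FALSE}
cfg <- synth_config(channels = c("FP1", "O1"), duration_s = 10,
                    noise_sd = 0.5)
ds <- synth_dataset(cfg, n_per_class = 5, seed = 21)
res <- run_pipeline(ds, pipeline_config(window_s = NULL,
                                        classifiers = "svm_rbf", seed = 21))
res$report$optimal       # the planted FP1:TGB feature, LOTO accuracy 1.0
res$majority$accuracy    # the all-features baseline, far lower
```
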