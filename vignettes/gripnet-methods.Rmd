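---
title: "Decoding graded hand-clenching from EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding graded hand-clenching from EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(gripnet)
```

gripnet implements a single-trial EEG decoding pipeline for graded motor
tasks: three levels of hand-clenching force (or speed), executed or
imagined, recorded over nine sensorimotor electrodes (FC3, FCz, FC4, C3,
Cz, C4, CP3, Pz, CP4). This vignette explains the models behind each stage,
the parameters that matter, what the synthetic data generator does and does
not emulate, and the numerical choices made where the design was open.

## Preprocessing

Raw multichannel EEG (1000 Hz) passes through four steps:

1. **Common average reference** — subtract the instantaneous mean across
   electrodes. Idempotent; afterwards the data are exactly rank-deficient
   by one (channels sum to zero at every sample), which matters for the
   autoregressive fits below.
2. **Zero-phase FIR band-limiting, 0.05–48 Hz** — a linear-phase windowed
   FIR applied forward–backward so no phase distortion is introduced. A
   0.05 Hz cutoff corresponds to a 20 s period; no FIR short enough to run
   on trial-length segments can realize it, so below the filter's
   resolution the high-pass is implemented exactly as per-channel mean and
   linear-trend removal. The contract is the same: DC is annihilated,
   mid-band tones pass at unit gain with zero lag, and a 60 Hz tone is
   attenuated by more than 20 dB. The two-pass filtering is evaluated by
   FFT convolution with odd-reflection edge padding, which is the same
   operator as direct-form `filtfilt` but much faster on long records.
3. **Decimation to 125 Hz** — an anti-alias low-pass at 80% of the target
   Nyquist, then every 8th sample. Event indices rescale with floor
   rounding.
4. **Epoching and artifact rejection** — each trial event yields a task
   window of exactly 3 s (375 samples) spanning `[event, event + 3 s)` and
   a 1 s baseline `[event − 1 s, event)`; intervals are half-open with
   0-based sample indexing. Epochs exceeding ±100 µV on any channel are
   dropped. This amplitude screen is a deliberate, configurable stand-in
   for component-based artifact removal (ICA), which is out of scope here.

No additional band-limit is applied before microstate analysis; the
microstate stage sees the same 0.05–48 Hz signal as every other feature
family.

## Microstate analysis

The topographic state of the array at time $t$ is summarized by the global
field power,
$$\mathrm{GFP}(t) = \sqrt{\tfrac{1}{k}\sum_{i=1}^{k}
  \bigl(V_i(t) - \bar V(t)\bigr)^2},$$
the spatial standard deviation over the $k = 9$ electrodes. Local GFP
maxima are moments of high topographic signal-to-noise; the maps at those
peaks are clustered by a modified k-means in which similarity is the
spatial Pearson correlation. In the default *polarity-invariant* mode the
absolute correlation is used (a map and its sign-flip belong to one state,
standard practice for spontaneous EEG) and each template is re-estimated
as the first principal direction of its assigned maps; a
*polarity-sensitive* mode (signed correlation, normalized mean update) is
first-class because evoked, time-locked paradigms can carry meaningful
polarity.

The number of templates $q$ is chosen by a predictive residual criterion,
$$\mathrm{CV}(q) = \hat\sigma^2_q\left(\frac{k-1}{k-1-q}\right)^{2},
\qquad
\hat\sigma^2_q = \frac{1}{n(k-1)}\sum_t \left(v_t^\top v_t -
  (a_{L(t)}^\top v_t)^2\right),$$
with $v_t$ the (channel-centered) peak maps and $a_{L(t)}$ their assigned
unit templates. The criterion is computed for every candidate $q$ and the
minimizer returned, together with the whole curve. On structureless input
the selection is flagged: rather than testing curve flatness (with $k = 9$
the penalty term makes the curve rise steeply in $q$ even for pure noise),
the package warns when the selected model explains less than half the
variance, which is the operational symptom of clustering noise.

Backfitting assigns each GFP peak to its best-correlated template (ties go
to the lower template index) and extends each peak's label to the midpoints
toward its neighboring peaks; epoch edges belong to the nearest peak. From
the resulting segmentation come the four microstate parameters per
template: **duration** (mean contiguous-run length, ms), **occurrence**
(runs per second), **coverage** (fraction of samples) and **amplitude**
(mean GFP over the template's samples). Coverages sum to one whenever every
sample is labeled, and duration × occurrence ≈ coverage up to one-sample
discretization per run — both are enforced as invariants in the tests.

Template naming (A, B, C) follows first occurrence in time, so labels are
reproducible across runs. Peaks closer than 10 ms are pruned (keeping the
larger); no temporal smoothing or minimum-duration merging is applied by
default, though the segmentation machinery would accommodate one.

For classification, each trial's own templates are matched against
*typical* maps by greedy descending correlation, each trial template used
at most once, with a match threshold of 0.55 for the force task and 0.45
for the speed task. Matched typical templates contribute the trial's four
parameters; unmatched ones contribute zeros, giving the fixed 3 × 4 = 12
block. Two open designs were resolved as follows: typical maps are fit on
the **training partition of each cross-validation fold only** (never on
test subjects), and they are fit **class-agnostically** — pooled over all
levels — so the microstate block has the documented dimensionality, does
not depend on labels, and cannot leak class information through the
matching stage.

## Directed connectivity and networks

Each 3 s epoch gets its own multivariate autoregressive (MVAR) model,
$$x(t) = \sum_{r=1}^{p} C_r\, x(t-r) + \varepsilon(t),$$
fit by least squares on stacked lagged regressors. Because
average-referenced EEG is exactly rank-one deficient, the normal equations
are singular by construction; a tiny scale-relative ridge
($\lambda = 10^{-10}\,\overline{\mathrm{diag}(X^\top X)}$) selects the
minimum-norm solution deterministically. The order is either fixed
(default 8 in the pipeline) or chosen by AIC over 1–20. Stability is
checked via the companion-matrix spectral radius and logged.

Partial directed coherence follows from
$\bar A(f) = I - \sum_r C_r e^{-\mathrm{i}2\pi f r/f_s}$:
$$\mathrm{PDC}_{j \to k}(f) =
  \frac{|\bar a_{k,j}(f)|}{\sqrt{\sum_i |\bar a_{i,j}(f)|^2}},$$
the fraction of channel $j$'s outflow reaching $k$; squares sum to one over
sinks for every source and frequency, which the tests assert to $10^{-8}$
and cross-check against a brute-force complex-matrix evaluation to
$10^{-10}$. PDC is evaluated on a 1 Hz grid (1–45 Hz) and averaged over
theta (4–8 Hz), alpha (8–13 Hz) and beta (13–30 Hz), bands half-open
$[lo, hi)$.

Each band matrix becomes an undirected binary graph: symmetrize by the mean
of the two directions, zero the diagonal, keep the strongest
$\lceil 0.3 \cdot N(N-1)/2 \rceil$ edges (density 0.3 by default — the
conversion from weighted PDC to an unweighted graph is not dictated by the
metrics themselves, so both the rule and the density are exposed). Two
metrics per band: the mean clustering coefficient
$C = \tfrac{1}{N}\sum_i 2e_i / (k_i(k_i-1))$ with $C_i = 0$ where the
degree is below two (the formula is undefined there), and the
characteristic path length — BFS hop counts averaged over unordered
*connected* pairs, with disconnected pairs excluded and counted rather than
imputed. Both are implemented directly from their definitions and verified
against igraph by exhaustive enumeration of every graph on up to six nodes.

## Classic features

- **ERD/ERS energy**: relative change
  $E_n(\%) = (e_n - e_c)/e_c \times 100$ of each 1 s task window's mean
  squared amplitude against the 1 s baseline, per channel (3 × 9). Computed
  broadband by default; an 8–30 Hz option exists because the
  desynchronization phenomenon is mu/beta-specific.
- **AR spectrum**: per channel and 1 s window, a Burg AR(10) fit evaluated
  as $P(\omega) = \sigma^2/|1 - \sum_i \phi_i e^{-\mathrm{i}\omega i}|^2$
  on a 125-point grid over $[0, f_s)$, normalized to unit total mass
  (3 × 9 × 125). The normalized values are the features — scale invariance
  is the point of normalizing. The mu+beta band ratio (mass with aliased
  frequency in $[8, 30)$ Hz, both spectral half-axes) is exposed as a
  per-window scalar; for white noise it sits at $22/62.5 \approx 0.35$,
  which the tests verify.
- **Wavelet packets**: a three-level decomposition with the orthonormal
  db4 (8-tap) pair, symmetric boundary extension, nodes in frequency
  (sequency) order so node $m$ spans $\approx [m, m+1) \cdot 7.8$ Hz at
  125 Hz. Features are the **node energies** (sum of squared coefficients)
  of nodes 1–4 (~7.8–39 Hz, alpha through beta), 4 × 9 values — raw
  coefficients would not have a fixed 4 × 9 dimensionality, so the energy
  aggregate is the only reading consistent with the stated feature count.
  Coefficients are centrally aligned and trimmed so the transform neither
  grows nor double-counts boundary energy; total level-3 energy matches
  signal energy within a few percent (Parseval, up to boundary effects).

Blocks concatenate in the fixed order microstate (12), network (6), energy
(27), AR (3375), wavelet (36) — 3456 combined.

## Classification protocol

Three classifiers sit behind one fit/predict contract. The **extreme
learning machine** is implemented here: input weights and biases drawn
from a seeded uniform(−1, 1), sigmoid hidden layer (200 units by default),
output weights by pseudoinverse against one-hot targets; deterministic
given its seed, ties at prediction resolve to the lowest class index.
**SVM** (RBF) delegates to e1071; **LDA** delegates to MASS when $n > 2p$
and otherwise uses a shrinkage variant (pooled covariance shrunk halfway
toward its average diagonal) because 3456-dimensional features make the
pooled covariance singular.

Two protocols: **leave-one-subject-out** (one fold per subject; with 20
subjects × 90 trials each fold trains on 1710 and tests on 90) and
**per-subject session rotation** (each session held out once). Features
are standardized with training-fold statistics only, and — as noted above
— typical microstate maps are refit per training fold. An adversarial test
plants class signal only in the held-out subject and checks that accuracy
stays at chance, guarding the whole feature path against leakage.

Chance levels come from a permutation test: labels shuffled within subject
(respecting the grouping), the cross-validation rerun, 200 permutations by
default. For the ELM under LOSO the hidden activations and their
pseudoinverse do not depend on labels, so they are computed once per fold
and only the output weights are refit per permutation — numerically
identical to refitting with the fold's hidden layer held fixed, and the
reason 200 permutations on 3456-dimensional features are affordable.

## The synthetic data generator

No public recordings exist for this paradigm, so the generator produces
datasets with the statistical structure the pipeline assumes, at the
study's layout: 20 subjects × 3 sessions × 30 trials (10 per level),
generated at 1000 Hz and pushed through the *real* preprocessing chain.
Each trial superimposes:

- a **microstate-like component**: a cycling A→B→C template sequence
  (orthonormal, average-referenced maps) with gamma-jittered segment
  durations around class-dependent means, amplitude-modulated at ~10 Hz so
  GFP peaks every ~49 ms. For force, map C's duration (80/110/140 ms) and
  amplitude rise with level; for speed, map A's duration rises while C's
  falls. States blend through a short (24 ms) linear crossfade: hard
  switches would inject broadband transients at a class-dependent rate,
  bleeding microstate class structure into the beta band and confounding
  the network features.
- a **coupled beta-band MVAR component**: AR(2) oscillators resonant at
  20 Hz (pole modulus 0.8 at the pipeline rate) with lag-1 directed
  coupling on feed-forward graphs. The generator designs these dynamics at
  125 Hz — where a 20 Hz resonance leaves a wide stability margin — and
  upsamples band-limitedly to 1000 Hz; acyclic coupling keeps the poles at
  the oscillator modulus for any gain. Force levels 1 and 2 couple along a
  triangle-free chain at gains 0.4 and 0.6; level 3 couples a 5-clique
  with a spoke from every outer node at gain 2.0 (an acyclic clique
  necessarily has high out-degree sources, and PDC's outflow normalization
  dilutes their edges, so expressing the clique takes a disproportionate
  gain). Estimated beta networks then grade from sparse and elongated to
  compact and clustered — clustering up, path length down with force
  level — and the speed task reverses the assignment. Structures touch
  all nine nodes (isolated nodes would be attached at random distances by
  estimation-noise edges), and the clique carries more candidate edges
  (14) than the density-0.3 binarization keeps (11), so noise edges
  cannot dilute its compactness.
- **1/f plus white noise** everywhere, with the 1 s baseline noise-only.
  The SNR parameter (default 5) is the microstate-component RMS over the
  noise RMS; the MVAR component is scaled relative to the microstate
  component (2.2 by default) and is deliberately *not* counted in that
  ratio, being structured signal rather than noise. The large default is
  load-bearing: the microstate component's switching modulation leaves
  sidebands in the beta band whose spatial pattern depends on the drawn
  templates, so the coupled network must dominate that band for the
  network trends to be template-geometry-robust. The flip side, stated
  plainly: under the combined default the per-trial topography clustering
  recovers the generating maps only approximately, so the microstate
  feature block is a weak (though honest) class signal there; clean
  microstate recovery is demonstrated with the network component switched
  off, which is also how the recovery tolerances are verified.

Subject-level random effects — a small template rotation and a
multiplicative SNR jitter — make leave-one-subject-out validation
non-trivial. Effect sizes are calibrated so the default pipeline reaches
high leave-one-subject-out accuracy; this calibrates a test bench and
claims nothing about how real recordings look.

What passing tests show, and what they do not: recovery and
effect-direction results demonstrate that the implementation detects the
structure it was designed to detect, at realistic epoch lengths and
sampling rates, through the full preprocessing chain. They do not
demonstrate performance on real EEG, where volume conduction, non-
stationarity, true artifact topographies and inter-subject variability are
all richer than this generator. In particular the generator contains no
biophysical forward model.

## Numerical choices and degenerate inputs

- Sample indexing is 0-based with half-open time intervals; a 3 s epoch at
  125 Hz is exactly 375 task and 125 baseline samples.
- GFP peak ties (equal adjacent maxima) keep the earlier sample; template
  correlation ties keep the lower template index; binarization ties keep
  the smaller node-index pair — all deterministic.
- Clustering restarts default to 10 (5 at trial level); an empty cluster
  is reseeded with the worst-fit map; near-duplicate templates trigger a
  degeneracy warning.
- Constant channels are rejected before MVAR fitting with the channel
  named; exact duplicates likewise. Burg fits are checked for stability
  per window and channel.
- `reject_artifacts` erases everything only with an explicit empty-set
  error, never silently.
- Problem sizes used by the validation suite: the full 20 × 3 × 30 design
  (1800 trials) for the end-to-end and force-trend checks, 100 trials per
  level for the speed trend, 30 epochs at SNR 5 for microstate recovery,
  50 seeded runs for template-count selection, 200 permutations for chance
  levels, and every graph on up to six nodes for the metric oracles —
  sizes chosen to make sampling error negligible relative to the margins
  being asserted.

## Known limitations

- The EDF writer/reader covers plain continuous 16-bit EDF, not EDF+
  annotations; events travel in a sidecar table.
- Weighted or directed graph metrics, generalized PDC variants,
  time-varying MVAR and microstate syntax analysis are out of scope.
- The LDA shrinkage intensity is fixed (0.5) rather than estimated; LDA is
  a comparison baseline here, not the recommended classifier.
- Mean beta PDC averaged over *all* channel pairs is not monotone in the
  coupling grade (PDC's column normalization concentrates mass when few
  sources couple); the generator's coupling grade is asserted on the
  coupled entries.
```
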