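---
title: "Decoding auditory attention from EEG microstate and recurrence dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding auditory attention from EEG microstate and recurrence dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msrqa)
```

## The problem

In a two-speaker "cocktail party", a listener's EEG carries a signature of
*which* speaker they attend, even without access to the speech signals.
`msrqa` decodes that signature from the **dynamics** of the EEG alone: the
scalp topography of spontaneous EEG is quasi-stable for ~80–120 ms at a time
(*microstates*), and attentional state modulates how quickly and in what
pattern those states succeed one another. The package turns each short
analysis window into a vector of dynamic features — microstate parameters and
recurrence-quantification (RQA) measures of derived scalar series — and trains
a bank of classifiers, including a GRU–CNN deep Q-learning agent (GCQL), to
label each window `SPK1` or `SPK2`.

## The model, stage by stage

### Preprocessing

Recordings are resampled to 256 Hz, band-passed 0.5–70 Hz, and re-referenced
to the average of TP7 and TP8. The band-pass is a zero-phase windowed-sinc
FIR (applied forward and backward), with the order derived from the low
transition edge (about 3.3 cycles of the low cutoff; the order actually used
is recorded in `attr(, "fir_order")`). A zero-phase FIR was chosen because
linear-phase filtering preserves the relative timing that microstate
segmentation depends on; IIR designs of comparable sharpness distort it.
Artifact handling is a deliberate non-feature: an optional amplitude
threshold can reject windows, but it is off by default so the pipeline stays
deterministic.

### Microstate analysis

Global field power (GFP) is the spatial standard deviation over the $N$
electrodes at each sample,

$$\mathrm{GFP}(t) = \sqrt{\tfrac1N \sum_{i=1}^{N} (x_i(t) - \bar x(t))^2},$$

computed with the population convention (divide by $N$). Topographies at GFP
peaks — moments of maximal signal-to-noise — are clustered into $K$ prototype
maps. Four clustering routes are provided: a modified **k-means** that is
polarity-invariant (a map and its negation are one state) and maximises the
GFP²-weighted squared spatial correlation; **AAHC** (atomize-and-agglomerate
hierarchical clustering); **PCA** loadings; and **FastICA** mixing columns.
PCA and ICA do not natively produce cluster labels, so their component
loadings over the peak-map ensemble are read directly as prototypes — the
only interpretation under which they are comparable with the clustering
routes.

Model adequacy is measured by global explained variance,

$$\mathrm{GEV} = \frac{\sum_t \mathrm{GFP}(t)^2 \,
  \mathrm{corr}^2\!\big(x(t), a_{\ell(t)}\big)}{\sum_t \mathrm{GFP}(t)^2},$$

with `corr` the spatial Pearson correlation and $\ell(t)$ the assigned state.
The number of states is configurable (default 4, the canonical A–D maps);
`scan_n_states()` scans $K = 2..10$. For the scan, GEV is evaluated on the
GFP-peak topographies (the model-selection convention) and the k-means route
warm-starts each $K$ from the previous solution, which makes the GEV curve
non-decreasing in $K$ by construction; the elbow (the collapse of the
incremental gain) then identifies the planted order on synthetic data.
Evaluation on the full data via backfitting is also available
(`on = "data"`).

Backfitting labels every sample with the prototype of largest absolute
spatial correlation; polarity is the sign of that correlation; ties go to
the lowest state index; zero-variance samples inherit their left neighbour's
label. Four parameters summarise a segmentation per state: mean GFP (µV),
occurrence (runs/s), duration (mean run length, ms) and coverage (fraction
of samples). Coverages sum to 1 exactly, and
$\text{coverage} = \text{occurrence} \times \text{duration}$ holds exactly
when no run touches a window edge. Optional minimum-duration smoothing
reassigns short runs to the better-correlated neighbour; it is off by
default because the synthetic ground truth contains genuinely short runs.

### Recurrence quantification

A scalar series (the GFP sequence of a window, or a per-state microstate
parameter recomputed over 0.25 s sub-windows) is delay-embedded
($m = 1, \tau = 1$ by default — these series are short and already
state-space-like) and thresholded into a binary recurrence plot
$R_{ij} = \Theta(\varepsilon - \|x_i - x_j\|_\infty)$ with $\Theta(0) = 1$.
Eight features are computed: RR, DET, L\_MEAN, L\_MAX, ENTR (diagonal-line
statistics), TT, V\_max (vertical-line statistics) and RPDE (normalised
recurrence-time entropy, $H/\ln T_{\max} \in [0,1]$).

Conventions, each configurable:

* **RR** is normalised by $N^2$ over the full matrix, so the line of
  identity (LOI) is included.
* Diagonal-line statistics exclude the LOI and a Theiler band of width 1,
  since otherwise DET is trivially inflated by temporal adjacency.
* Vertical statistics use the full matrix (the standard laminarity
  convention).
* $l_{\min} = v_{\min} = 2$; ENTR normalises over lines of length
  $\ge l_{\min}$.
* Degenerate cases return 0 (no qualifying diagonals → DET, L\_MEAN,
  ENTR = 0; no qualifying verticals → TT = 0; $T_{\max} \le 1$ → RPDE = 0).

**Threshold choice.** The default is $\varepsilon = 0.2\,\mathrm{sd}$ of the
series (`std_fraction`). An alternative calibrates $\varepsilon$ to a target
recurrence rate (`target_rr`); that is useful when comparing line-structure
features at matched recurrence density, but it *pins RR itself to the
target*, destroying the very feature this pipeline found most informative —
with `target_rr`, RR of the GFP series is constant across windows by
construction and attention decoding from it collapses to chance. The
sd-fraction default keeps RR meaningful while still normalising away
amplitude differences between windows.

Series longer than `max_points` (default 2048) are decimated before the
$N \times N$ matrix is built. This only affects windows longer than 8 s at
256 Hz and bounds the memory of the window-length sweep.

### Feature assembly and screening

Three modes mirror the experimental design: `ms_only` (4 parameters × K
states), `rqa_only` (8 RQA features of the window's GFP series) and
`multivariate` (8 RQA features of every microstate parameter series: the GFP
series plus occurrence/duration/coverage per state — with K = 4 that is
8 × 13 = 104 columns, including the optimal `rr(gfp)`). The per-state series
are formed by recomputing each parameter on consecutive non-overlapping
0.25 s sub-windows; occurrence, duration and coverage are window-level
summaries, so some such aggregation scale is unavoidable and 0.25 s gives
four points per 1 s window — the minimum recurrence analysis tolerates.

Screening per feature: a Lilliefors (KS with estimated parameters) normality
p-value, then a two-sided Mann–Whitney U test between classes; significance
at raw $p < 0.05$ with optional Benjamini–Hochberg adjustment (off by
default, matching the raw-p reporting convention of screening tables in this
literature).

### Classification

Five decoders share one interface, all fed z-scored features
(training-split statistics only):

* **KNN** — one neighbour, Euclidean; implemented in-package so that
  equidistant ties resolve deterministically toward the lowest class index
  (library implementations break ties randomly, which makes reruns of the
  pipeline non-reproducible on quantised features such as RR, whose values
  lie on a $1/N^2$ lattice).
* **SVM** — Gaussian kernel, box constraint 1 (`e1071`).
* **LSTM** (5 stacked layers) and **Bi-LSTM** (3 bidirectional layers), with
  a max-pool over time, one dense layer, softmax, dropout 0.2, batch 512,
  Adam. Layers are hand-implemented with analytically derived
  backpropagation; the gradients are verified against central finite
  differences in the test suite.
* **GCQL** — a Q-learning agent whose action-value function is a GRU stage
  (64 units) over the feature sequence, a 1-D convolution stage (32 filters,
  kernel 3) over the GRU outputs, a global max-pool, and a dense head with
  two action values (predict SPK1 / predict SPK2). Each window is a
  single-step episode: reward +1 for matching the label, −1 otherwise;
  ε-greedy behaviour decaying linearly 1.0 → 0.05; experience replay of
  10 000 transitions; squared TD error on the taken action. Because episodes
  are terminal, the discount defaults to γ = 0 and the TD target reduces to
  the immediate reward — the MDP degenerates to cost-sensitive
  classification. This is one admissible reading of a reinforcement-learning
  formulation over independent windows; with γ = 0 the greedy policy
  provably matches a reward-regression baseline, and the test suite checks
  that equivalence empirically.

Sequence construction for the recurrent models groups consecutive windows of
a trial (default length 1; longer sequences pad history at trial starts by
repeating the earliest window).

Evaluation uses SPK1 as the positive class:
$\mathrm{ACC} = (TP+TN)/(TP+TN+FP+FN)$, $\mathrm{TPR} = TP/(TP+FN)$,
$\mathrm{TNR} = TN/(TN+FP)$. Splits are at **trial** granularity (70/30 by
default, stratified by class), so windows of one trial never leak across the
split. `window_sweep()` repeats the whole pipeline per window length from
0.02 s up to the trial limit.

## The synthetic generator

`simulate_eeg()` is the package's test bed. Each trial is a semi-Markov
chain over K orthonormal topographies; dwell times are uniform around a
class-specific mean — **100 ms when attending speaker 1 versus 60 ms for
speaker 2** by default, both inside the empirical 80–120 ms microstate band
(the SPK2 mean sits at its faster edge, the kind of dwell-time contraction
attention shifts produce). The class signal therefore lives entirely in the
*dynamics*, not the maps, matching the premise that attention modulates
state succession rather than topography. Within a run the active template is
amplitude-modulated by a half-sine envelope so GFP peaks occur mid-state
(where the topography is cleanest), and Gaussian sensor noise is added at a
linear RMS SNR of 10. Defaults: 64 channels, 256 Hz, K = 4, 20 trials per
class of 50 s.

What the generator does **not** emulate: volume-conducted 1/f background,
ocular/muscle artifacts, non-orthogonal canonical topographies, inter-subject
map variability, or any coupling to actual speech envelopes. Passing tests
on this generator therefore demonstrates that the pipeline recovers planted
microstate dynamics and converts dwell-time differences into decodable
features — not that real cocktail-party EEG is decodable at these accuracies.

## Numerical choices and degenerate inputs

* All randomness flows through explicit seeds; a single root seed is fanned
  out per stage by a deterministic hash, and every fit is reproducible
  bit-for-bit under a fixed seed.
* Eigenvector prototypes fix their sign by making the largest-magnitude
  loading positive, so restarts are comparable.
* Constant feature columns get screening p = 1 and a `degenerate` flag;
  constant series get a valid all-ones recurrence plot (RR = 1, RPDE = 0);
  all-zero windows make GEV error out rather than return 0/0.
* `auto_epsilon("target_rr")` resolves the threshold as an exact order
  statistic of the pairwise distances rather than by bisection.
* Dead k-means clusters are reseeded with the worst-explained map.

## Problem sizes used in the checks

The bundled tests and the acceptance script run scaled-down versions of the
study conditions so the whole suite completes on a laptop-class single core:
microstate recovery uses 4 trials/class of 10 s (64 channels, SNR 10, K = 4);
the end-to-end decoding run uses 20 trials/class of 10 s with 1 s windows;
the classifier benchmark uses 500–1000 rows per class; the screening
calibration uses 1000 null draws at n = 30 per group. Generator *defaults*
remain the full study conditions (20 × 50 s trials per class).

## Known limitations

* Group-level (multi-subject) two-stage clustering is out of scope; maps are
  fitted per recording.
* FIF containers are not read; supported formats are EDF, BDF and the
  package's JSON bundle.
* The GCQL agent's reinforcement-learning framing is degenerate by design
  (single-step episodes); sequences longer than one window are supported but
  untuned.
* RQA is $O(N^2)$ in window length; very long windows are decimated (see
  `max_points`).
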