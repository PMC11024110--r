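# msrqa

Auditory attention decoding (AAD) from multichannel EEG via **microstate**
and **recurrence quantification** analysis.

In a two-speaker listening task, the listener's EEG alone — without access to
the speech audio — carries a decodable trace of which speaker is attended.
`msrqa` extracts that trace from the *dynamics* of the signal and classifies
short analysis windows as "attending speaker 1" (`SPK1`) or "attending
speaker 2" (`SPK2`).

The pipeline:

1. **Preprocess** — resample to 256 Hz, zero-phase FIR band-pass 0.5–70 Hz,
   re-reference to the TP7/TP8 average.
2. **Microstates** — global field power
   `GFP(t) = sqrt(Σᵢ (xᵢ(t) − x̄(t))² / N)`; topographies at GFP peaks are
   clustered (polarity-invariant modified k-means, AAHC, PCA or ICA) into K
   prototype maps, scored by global explained variance (GEV), and backfitted
   so every sample gets a state label. Per state: mean GFP, occurrence,
   duration, coverage.
3. **Recurrence analysis** — scalar series derived from each window (the GFP
   sequence, or per-state parameter series) are thresholded into a
   recurrence plot `R_ij = Θ(ε − ‖x_i − x_j‖∞)` and summarised by eight
   features: RR, DET, L_MEAN, L_MAX, ENTR, TT, V_max, RPDE.
4. **Screening** — Lilliefors normality check, then Mann–Whitney U between
   classes per feature (p < 0.05).
5. **Classification** — KNN, SVM, LSTM, Bi-LSTM, and GCQL, a GRU–CNN deep
   Q-learning agent (GRU over the feature sequence → 1-D convolution →
   dense head with two action values; ε-greedy exploration, experience
   replay, TD learning). Evaluation by ACC/TPR/TNR with trial-granular
   70/30 splits, across window lengths from 0.02 s upward.

A synthetic EEG generator with planted microstate dynamics (class-dependent
dwell times: 100 ms vs 60 ms) makes the whole pipeline testable with no
external data.

## Worked example

```r
library(msrqa)

sim <- simulate_eeg(synthetic_spec(n_channels = 32, K = 4, snr = 10,
                                   n_trials_per_class = 6, trial_length_s = 10,
                                   seed = 42))
rec <- preprocess(sim$recording)

gfp   <- compute_gfp(rec$data, rec$sfreq)
peaks <- find_gfp_peaks(gfp, 10, rec$sfreq)
proto <- fit_prototypes(t(rec$data[, peaks]), K = 4, method = "kmeans",
                        n_init = 10, seed = 42)
proto
#> <microstate_prototypes> K = 4 (kmeans), GEV = 0.963
```

Four prototype maps explain 96.3 % of the GFP-weighted topographic variance
of the peak maps — the planted state structure is recovered. Featurise 1 s
windows with the eight recurrence features of their GFP series and screen
them:

```r
w  <- segment_windows(rec, length_s = 1)
fm <- build_features(w, proto, mode = "rqa_only")
fm[1:3, 1:6]
#> # A tibble: 3 x 6
#>   window_id trial_id label `rr(gfp)` `det(gfp)` `l_mean(gfp)`
#> 1         1        1 SPK1      0.124      0.631          3.43
#> 2         2        1 SPK1      0.124      0.596          3.40
#> 3         3        1 SPK1      0.134      0.682          3.36

dplyr::arrange(screen_features(fm), group_p)[1:3, ]
#> # A tibble: 3 x 5
#>   feature    normality_p  group_p significant degenerate
#> 1 v_max(gfp)    1.31e-27 4.92e-23 TRUE        FALSE
#> 2 det(gfp)      2.43e- 2 6.80e-19 TRUE        FALSE
#> 3 tt(gfp)       1.29e- 4 2.09e-11 TRUE        FALSE
```

The vertical-line and determinism features separate the classes strongly:
faster state switching under `SPK2` (60 ms dwell) shortens the laminar
structures of the GFP recurrence plot. Train the GCQL agent and evaluate on
held-out trials:

```r
sp     <- split_trials(fm, 0.7, seed = 42)
model  <- train_gcql(sp$train, gcql_config(epochs = 30), seed = 42)
evaluate_aad(model, sp$test)
#> # A tibble: 1 x 8
#>      tp    tn    fp    fn   acc   tpr   tnr window_length_s
#> 1    20    20     0     0     1     1     1               1
```

All 40 held-out windows are classified correctly (ACC = TPR = TNR = 1): at
this SNR the planted dwell-time difference is fully decodable from 1 s
windows. `window_sweep()` repeats the run per window length, and
`autoplot()` methods exist for recurrence plots, GFP series, segmentations
and sweep results.

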