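# boxfd

Complexity analysis of physiological recordings via the box-counting
fractal dimension of the signal graph, for within-subject studies that
compare flat (2D) with stereoscopic (3D) viewing of the same content.

EEG and facial EMG traces are irregular, self-affine signals; their
complexity can be summarized by the fractal dimension (FD) of the graph
drawn by the signal in the time–amplitude plane.  A smooth trace has FD
near 1, a rough, information-dense trace approaches 2, and a rise in FD
under a stimulus is read as stronger engagement.  `boxfd` implements:

- **Box-counting FD** (`box_count`, `estimate_fd`, `record_fd`): the
  graph is normalized into the unit square, covered with grids of side
  ε = 1/2, 1/4, 1/8, …, and D is the OLS slope of ln N(ε) versus
  ln (1/ε), where N(ε) counts grid cells the polyline intersects.  An
  exhaustive all-cells reference scan (`box_count_naive`) uses the same
  grid convention and agrees exactly — it serves as the estimator's
  built-in oracle.
- **Generalized (Renyi) dimensions** (`occupancy_histogram`,
  `renyi_entropy`, `generalized_dimension`): D_c = H_c / ln(1/ε) from
  the Renyi entropy of the time the amplitude spends in each of m equal
  value intervals (ε = 1/m).
- **Preprocessing** (`butterworth_bandpass`, `truncate_record`,
  `exclude_channels`): zero-phase Butterworth band-pass (1–40 Hz EEG,
  25–125 Hz EMG), truncation to the first 118.2 s, channel exclusion.
- **A synthetic study generator** (`gen_fbm`, `gen_study`): fractional
  Brownian motion signals whose graph dimension is exactly 2 − H, in the
  full study layout (9 subjects × 6 stimuli in three 2D/3D pairs ×
  2 sessions, 12 EEG + 5 EMG channels), plus Bernoulli questionnaire
  answers — analytic ground truth for every downstream stage.
- **Inference and reporting** (`rm_anova`, `paired_t`, `run_study`):
  one-way repeated-measures ANOVA across stimuli, paired Student t tests
  for the content-matched pairs, Shapiro–Wilk screening, questionnaire
  learning rates, and a deterministic JSON/text study report.

## Worked example

Estimate the dimension of one synthetic signal with known truth
(H = 0.3, so the graph dimension is 2 − 0.3 = 1.7):

```r
library(boxfd)
fd <- record_fd(gen_fbm(H = 0.3, n = 2^14, seed = 1))
fd
#> <fd_estimate> D = 1.6620 (R^2 = 0.9995, 8 scales)
```

The estimate sits a little under the true 1.7 — the box-counting
estimator compresses toward the center of [1, 2] at finite length (see
the methods vignette).  Now a reduced synthetic study with a rougher-3D
effect injected (ΔH = 0.05) and the full pipeline — filter, truncate,
per-channel FD, aggregation, repeated-measures tests, questionnaire
scoring:

```r
cfg <- study_config(n_subjects = 5, sessions = 2, duration_s = 16,
                    n_channels_eeg = 4, n_channels_emg = 2,
                    h_eeg_2d = 0.35, h_eeg_3d = 0.30, seed = 2026)
report <- run_study(gen_study(cfg), analysis_config(analysis_duration_s = 15.5))
report
#> Mean fractal dimension (EEG):
#>   first   (2D)  1.7064
#>   second  (3D)  1.7127
#>   third   (2D)  1.7087
#>   fourth  (3D)  1.7151
#>   fifth   (2D)  1.7031
#>   sixth   (3D)  1.7144
#>   ANOVA (stimulus): F(5, 20) = 4.6036, p = 0.005881
#> Mean fractal dimension (EMG):
#>   first   (2D)  1.8443
#>   second  (3D)  1.8440
#>   third   (2D)  1.8480
#>   fourth  (3D)  1.8472
#>   fifth   (2D)  1.8500
#>   sixth   (3D)  1.8494
#>   ANOVA (stimulus): F(5, 20) = 1.0284, p = 0.4278
#> Learning rate: 2D 75.56%, 3D 97.78%
```

Each even-numbered (3D) stimulus shows a higher mean EEG dimension than
its 2D partner, and the stimulus ANOVA picks the effect up.  The EMG
table is flat: its 25–125 Hz band-pass removes the low-frequency
structure through which the surrogate signal carries the effect — the
methods vignette discusses why that is a property of the fBm surrogate,
not of real muscle signals.  The learning rates are the percent of
correct questionnaire answers per condition.  `write_report_json()`
serializes the full report; re-running the same configuration yields a
byte-identical file.

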