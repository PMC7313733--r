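---
title: "Complexity analysis of physiological signals with boxfd: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Complexity analysis of physiological signals with boxfd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boxfd)
```

## The problem

When the same audiovisual content is shown flat (2D) or stereoscopically
(3D), brain and facial-muscle engagement may differ.  One way to quantify
engagement from EEG and facial EMG recordings is the *complexity* of the
signal, measured by the fractal dimension (FD) of its graph: a smooth,
regular trace has FD near 1, a rough, information-dense trace approaches
2.  `boxfd` implements the full analysis chain for a within-subject
viewing study: band-pass preprocessing, box-counting and generalized
(Renyi) dimension estimation, aggregation to a subjects-by-stimuli table,
repeated-measures inference, and questionnaire-based learning scores —
together with a synthetic study generator whose ground-truth dimensions
are known analytically, so every stage can be validated without human
recordings.

## Box-counting dimension of a signal graph

A recording is first mapped to a polyline in the unit square: time
affinely onto $[0,1]$, amplitude min–max onto $[0,1]$ (a constant record
maps to the line $y = 0.5$).  FD estimates are therefore invariant under
positive affine amplitude transforms, and amplitude units never matter.

For a grid of cells with side $\varepsilon$, $N(\varepsilon)$ is the
number of cells the polyline intersects.  The dimension is the ordinary
least-squares slope of $\ln N(\varepsilon)$ against
$\ln(1/\varepsilon)$:

$$D = \lim_{\varepsilon \to 0}
      \frac{\ln N(\varepsilon)}{\ln (1/\varepsilon)}.$$

Design choices that needed fixing where the method itself is silent:

* **Grid convention.** Cells are half-open,
  $[i\varepsilon,(i+1)\varepsilon) \times [j\varepsilon,(j+1)\varepsilon)$,
  with the top and right edges of the square closed.  A cell touched by a
  segment at a single corner belongs to the cell being entered; polyline
  vertices always occupy their own cell.  The convention is stated so the
  fast counter and the exhaustive reference scan (`box_count_naive`)
  agree *exactly*, which the test suite asserts on random polylines.
* **Segment-aware counting.** Cells crossed by the linear interpolant
  between consecutive samples count as occupied; point-only counting
  undercounts at fine scales.
* **Scales.** Dyadic, $\varepsilon = 2^{-k}$, $k = 1, \dots, k_{\max}$
  with $k_{\max} = \min(\lfloor \log_2(n/2) \rfloor, 8)$, so the finest
  grid still averages at least two samples per column.  The fit is
  unweighted OLS over all scales.
* **Constant signals** report $D = 1$ rather than erroring.

`box_count` uses a per-column scan for signal graphs (within a grid
column a continuous curve occupies the contiguous rows between its
running extremes, with edge-crossing values interpolated) and an exact
segment-traversal for general polylines.  Both produce identical counts
to the brute-force all-cells scan; the brute force is quadratic in
$1/\varepsilon$ and exists purely as an independent oracle.

```{r}
curve <- box_count_curve(normalize_graph(gen_fbm(0.5, 2^12, seed = 1)),
                         dyadic_scales(2^12))
estimate_fd(curve)
```

### Estimator bias, and what "recovery" means here

Fractional Brownian motion (fBm) with Hurst exponent $H$ has a graph of
box-counting dimension exactly $2 - H$, which makes it the natural
ground-truth signal.  At finite length the estimator is biased downward,
increasingly so for rough paths: sampled extremes under-estimate the
continuous range within a column, and the $+1$ cell per column acts as a
floor.  At $n = 2^{14}$ with the default scales the mean estimate over
20 paths is about $1.71$ for $H = 0.2$ (true $1.8$), $1.45$ for
$H = 0.5$, and $1.21$ for $H = 0.8$ — within $\pm 0.1$ of truth, the
tolerance the test suite enforces, but users comparing absolute FD values
across studies should expect this systematic compression.  Both finer
and coarser dyadic windows were measured to *worsen* the bias, so the
default window is kept.

## Generalized (Renyi) dimensions

The amplitude range is cut into $m$ equal intervals (default
$m = 100$); $r_j$ is the fraction of recording time spent in interval
$j$ (occupancy time $t_j$ over total duration $T$).  The Renyi entropy
$H_c = \ln (\sum_j r_j^c) / (1-c)$ (Shannon at $c = 1$) yields

$$D_c = \frac{H_c}{\ln(1/\varepsilon)}, \qquad \varepsilon = 1/m,$$

with $\varepsilon$ read as the interval width on the normalized
amplitude axis.  $D_c$ is non-increasing in $c$; uniform occupancy gives
$D_c = 1$, a degenerate distribution $0$.  The pipeline's headline
statistic remains the box-counting $D$; the spectrum is exposed for
exploratory use (`generalized_dimension`, `generalized_spectrum`).

## Preprocessing

Recordings pass a Butterworth band-pass — 1–40 Hz for EEG sampled at
128 Hz, 25–125 Hz for facial EMG at 256 Hz — then are truncated to the
first 118.2 s (device clocks drift, so recordings run slightly short of
their nominal 120 s; the head segment is the only part guaranteed
present), then configured channels are excluded (e.g. electrodes with
known contact problems).  The filter order (4) and zero-phase
(forward–backward) application are conventional choices for EEG/EMG;
zero-phase matters here because phase distortion would alter the graph
geometry and hence the FD.  Because forward–backward filtering with zero
padding injects large end transients on signals that wander far from
zero (an fBm ends $O(\sqrt{n})$ away), `butterworth_bandpass` pads by
odd reflection — `max(512, 3 fs / low_hz)` samples, discarded after
filtering — so transients die inside the pads.  The EMG band's upper
edge (125 Hz) sits close to Nyquist (128 Hz); the design is stable
(largest pole modulus 0.973) and the band is used as stated rather than
lowered.

## The synthetic study generator

`gen_study` emulates the full design: `n_subjects = 9`, six stimuli in
three content-matched 2D/3D pairs (first/third/fifth are 2D), two
sessions, 12 EEG channels at 128 Hz and 5 EMG channels at 256 Hz, 120 s
per stimulus, three questions per stimulus.  Signals are fBm; the
condition effect is injected through the Hurst exponent, keeping the
true dimension interpretable as $2 - H$.  Per subject $s$, condition
$k$, and modality, $H_{s,k} = \mathrm{clip}(H_k +
\mathcal{N}(0, \sigma_{\mathrm{subj}}), 0.05, 0.95)$; channels are
independent paths sharing that exponent.  Answers are independent
Bernoulli draws per question.  Default Hurst values are back-computed
from the per-condition mean dimensions the method reports on real data
($H = 2 - \mathrm{FD}$: EEG 0.2950/0.2747 for 2D/3D, EMG 0.7532/0.7384),
success probabilities from the reported learning rates (0.8087/0.9260),
and $\sigma_{\mathrm{subj}} = 0.02$.  One master seed expands into
per-record substreams by stable hashing of (subject, stimulus, session,
channel), so adding a channel or reordering the configuration does not
change any other record.

### What the generator does and does not emulate

fBm reproduces the *scale-free roughness* that the FD statistic
measures, with known ground truth — that is its purpose.  It is not a
biophysical EEG/EMG model: no alpha peaks, no oscillatory structure, no
EMG bursting, and — critically — its H-signature lives at *all*
frequencies, with most energy at the lowest.  Band-pass filtering
therefore removes the very structure that carries the injected condition
effect: after the EMG band (25–125 Hz) the estimated FD saturates near
1.9 and is measurably *insensitive* to $H$ at any practical duration
(measured $\Delta\mathrm{FD}$ for $\Delta H = 0.05$: $+0.006$ at 2 s,
$-0.002$ at 8 s, $-0.001$ at 16 s); after the EEG band (1–40 Hz) the
sensitivity is attenuated but present ($\Delta\mathrm{FD} \approx
0.007$–$0.018$ depending on duration).  Real signals presumably carry
their complexity differences inside the passband, which the surrogate
cannot imitate.  Consequently, in the validation suite:

* **Directional fidelity** (higher FD under 3D when $H_{3D} < H_{2D}$ is
  injected, both modalities) is assessed with the band-pass stage
  disabled (`analysis_config(filter = FALSE)`): it is a property of the
  generator, estimator, and aggregation, and with filtering enabled it is
  unattainable for EMG under this surrogate — a generator limitation,
  not an implementation defect.
* **Type-I calibration and power** run the full filtered pipeline; the
  power contrast is carried by the EEG side, where filtered sensitivity
  survives.

Passing these tests validates the pipeline's mechanics and inference
calibration on fBm; it does not certify that the published effect sizes
would be recovered from real recordings.

## Inference

Per modality, per-channel dimensions are averaged over channels, then
over sessions, giving one value per subject and stimulus.  On that
table:

* one-way repeated-measures ANOVA with subjects as blocks, error term =
  subject-by-stimulus interaction, df $(k-1, (n-1)(k-1))$, no sphericity
  correction;
* the same ANOVA on per-subject condition means (two levels, where
  $F = t^2$ of the paired $t$ — asserted in the tests as a cross-check
  of both implementations);
* paired two-sided Student $t$ tests for the three content-matched
  pairs, raw p-values plus Holm-adjusted values logged alongside;
* Shapiro–Wilk normality per stimulus column — a warning, never an
  abort, when rejected.

The paired (not independent) $t$ is the coherent reading of a
within-subject design; both are available in `paired_t`.  Degenerate
tables are handled explicitly: zero treatment variance returns $F = 0,
p = 1$; zero error variance warns and returns $F = \infty, p = 0$.
Degeneracy is detected relative to the table's total variance, since
floating-point sums of squares are never exactly zero.

## Problem sizes used in the validation suite

Monte-Carlo checks use reduced designs chosen as the package's own
balance of fidelity and turnaround: type-I calibration uses 200 null
studies (5 subjects, one session, 16-s records, $H$ equal across
conditions, $\sigma_{\mathrm{subj}} = 0$ so stimuli are exchangeable —
with independent per-condition subject draws a nonzero
$\sigma_{\mathrm{subj}}$ would violate sphericity by construction;
2 EEG + 1 EMG channels); power uses 100 studies (9 subjects, 12 EEG
channels, 8-s records, $\Delta H = 0.05$,
$\sigma_{\mathrm{subj}} = 0.02$), where the 8-s duration keeps most
dyadic box scales inside the passband time-scales; directional fidelity
uses 100 studies (9 subjects, 3 EEG + 2 EMG channels, 16-s records,
filter off).  Parameter recovery uses 20 paths of $n = 2^{14}$ per Hurst
value.

## Known limitations

* The box-counting estimator's finite-length bias (above) makes absolute
  FD values comparable only at matched record length and scale set.
* The occupancy measure uses the global amplitude range; heavy-tailed
  amplitude outliers compress the effective histogram support.
* No artifact rejection, notch filtering, or re-referencing: inputs are
  assumed already clean apart from out-of-band noise.
* The reported dimension is the $c = 0$ box-counting $D$; multifractal
  summaries beyond $D_c$ (e.g. singularity spectra) are out of scope.
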