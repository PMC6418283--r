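---
title: "Retinotopic and topographic mapping of gaze-restricted SSVEPs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retinotopic and topographic mapping of gaze-restricted SSVEPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssvepmap)
```

## The problem

A flickering visual stimulus drives a steady-state visual evoked potential
(SSVEP): a periodic EEG response at the flicker frequency and its harmonics,
generated mainly in primary visual cortex. How strongly a flicker drives the
response depends on where it falls in the visual field, and the answer
matters for any design that arranges many flickers on a screen — notably
SSVEP brain-computer interfaces, where nearby "competing" flickers can be
mistaken for the attended one.

Measuring that dependence cleanly requires *gaze restriction*: if the eyes
wander toward a peripheral flicker, its retinal eccentricity changes and the
map is contaminated. The protocol modelled here therefore keeps the
participant fixating a central point inside a 1.5° ring monitored by an eye
tracker, while one of 46 flickers at eccentricities of 0-10° is presented
for 4 s; a trial in which any gaze sample leaves the ring is discarded and
repeated until every (run, stimulus) pair has one clean trial.

`ssvepmap` implements the complete analysis of such an experiment — and a
forward simulator of it — so that every stage is testable without access to
recordings.

## Response scoring

An epoch is scored by canonical correlation analysis (CCA) against a
harmonic reference bank. For stimulation frequency $f$, $M$ harmonics,
sampling rate $S$ and $N$ samples, the reference is

$$Y_f = \begin{bmatrix}
\sin(2\pi f t)\\ \cos(2\pi f t)\\ \vdots\\
\sin(2\pi M f t)\\ \cos(2\pi M f t)
\end{bmatrix},\qquad
t = \tfrac{1}{S}, \tfrac{2}{S}, \ldots, \tfrac{N}{S},$$

and the SSVEP response is
$R = \max_{W_x,W_y}\ \mathrm{corr}(X^T W_x,\, Y^T W_y)$, the largest
canonical correlation between the multichannel epoch $X$ and the reference
span. $R \in [0,1]$, is invariant to per-channel affine rescaling and
channel permutation, and never decreases when a channel is added. The
retinotopic analyses score $R$ over the 11 occipito-parietal channels
(P7, P3, Pz, P4, P8, PO3, POz, PO4, O1, Oz, O2); topographic analyses use
all 31.

Numerically, $R$ is obtained from the singular values of the whitened
cross-covariance. Whitening uses an eigen-decomposition truncated at a
relative tolerance of $10^{-10}$ rather than a fixed ridge: a noise-free
epoch is rank-deficient, and truncation keeps $R = 1$ exact to machine
precision while remaining stable for collinear or zero-variance channels
(which warn and are excluded by the truncation). Weight-vector signs are
fixed by making the first nonzero component of $W_x$ positive; $R$ itself
is sign-invariant.

Per-trial epochs are scored individually and averaged over the 12 valid
runs of each stimulus. CCA on run-averaged signals is the other defensible
reading of the protocol; per-trial scoring was chosen because it keeps
every downstream statistic (error rates, rank tests) defined at the run
level, where the protocol's granularity lives.

## Preprocessing

Epochs pass through a 50 Hz notch, then a 4–35 Hz band-pass. No filter
shapes beyond the corner frequencies are part of the protocol, so the
package uses conventional choices and documents them:

* band-pass realized as a Butterworth high-pass (4 Hz) and low-pass
  (35 Hz) cascade, order 4 each;
* notch as a constrained-gain biquad with quality factor $Q = 30$
  (≈1.7 Hz bandwidth) — the notch bandwidth is unstated in the protocol
  and is exposed as `notch_q`;
* every filter applied forward–backward (zero phase) with odd-reflection
  padding of 0.5 s, so sinusoid peaks are not shifted and CCA phase
  relations are untouched. Attenuation at 50 Hz and 1 Hz exceeds 20 dB and
  the 15 Hz passband is preserved within 5%; the test suite measures all
  three on the implemented filters.

Trial gating is independent of filtering: a trial is valid iff every gaze
sample satisfies $\sqrt{x^2+y^2} \le 1.5°$. The boundary is inclusive —
"beyond the ring" is read as strictly outside.

## The synthetic world

The simulator generates what the analysis assumes the brain does, with
every effect size explicit in `sim_params()`:

* **Eccentricity falloff.** Evoked amplitude
  $A(x,y) = A_0 \exp(-e^2/2\sigma_r^2)(1+\beta[y<0])$ with
  $\sigma_r = 4°$: the response surface is a Gaussian bump centered on
  fixation, falling to half by ≈4.7°. The width is not reported by the
  modelled study (which published only correlation-scale responses), so it
  was set once to place the steep decline within the first three layers.
* **Lower-field boost** $\beta = 0.3$: positions below the horizontal
  midline respond 1.3× their mirror images.
* **Scalp projection.** Channel weights form a Gaussian bump over the
  occipital pole (width 0.6 head-radii), and channels contralateral to the
  stimulated hemifield are scaled by $1+\gamma$ with $\gamma = 0.5$.
  Weights are normalized to max 1, so mirror pairs are equal for on-axis
  stimuli and frontal channels never exceed occipital ones.
* **Signal.** Three harmonics of 15 Hz with amplitudes $1/m$ and zero
  phases, on the same $t = k/S$ time base as the reference bank, so a
  noise-free epoch lies exactly in the reference span.
* **Noise.** Independent $1/f$ background per channel with standard
  deviation $1/\mathrm{snr}$ signal units (deliberately independent of
  $A_0$, so $A_0=0$ yields pure noise), plus a common 50 Hz line component.
  The default $\mathrm{snr}=0.5$ puts the single-trial central-stimulus $R$
  near 0.5 and the 11-channel noise floor near 0.15 — typical magnitudes
  for 4-s epochs — rather than the saturated $R \to 1$ regime where layer
  differences vanish.
* **Gaze.** Fixation jitter as iid zero-mean Gaussian samples with
  $\sigma = 0.3°$. (A larger jitter is inconsistent with this iid model:
  at 0.5° roughly 93% of 240-sample trials would spontaneously cross the
  ring and the repeat-until-success protocol could not finish; real
  fixational drift is temporally correlated, which the model does not
  represent.) With probability `p_excursion` (default 0.1) one contiguous
  excursion ramps out to a peak of 1.8–3°, guaranteeing a ring violation.

The simulator does **not** emulate saccade dynamics, EOG/EMG artifacts,
electrode drift, spatially correlated noise (available as nothing — noise
is independent across channels), inter-participant amplitude variability
beyond the seed, or any attention effect. A green simulation-based test
therefore establishes that the *analysis* recovers the structure the
forward model put in — not that the physiological effect sizes are
realistic.

## The statistics

**Error rate (competitive effect).** For visual angle $d$ the error rate is
the percentage of runs in which the best layer-$d$ stimulus out-responds
the central stimulus. The run-wise definition is chosen because the
published per-participant values lie on a lattice of twelfths (and one
eleventh, i.e. one dropped run), which a run-level event count reproduces
exactly; a pooled per-(stimulus, run) variant is available via
`method = "pooled"`. Significance uses Welch's two-sample, two-sided
t-test between per-run central and pooled layer-$d$ responses; when both
groups are degenerate (zero variance) the convention $p=1$ for equal
means, $p\to 0$ otherwise, is applied with a warning.

**Layer averages and surfaces.** Responses are averaged per stimulus over
valid runs, per layer over stimuli, then over participants. The response
surface is a piecewise-linear interpolation over the triangulated stimulus
positions (exact at the nodes, undefined outside the convex hull). The
concentric layout is co-circular, which makes the Delaunay step fall back
to internal jitter; the resulting node error is ~$10^{-6}$ and the
associated warning is muffled.

**Single-channel contributions.** The printed definition of the
contribution sums CCA outcomes over channel index sets, which cancels
algebraically; following its prose meaning, the package computes
$r_i = (R_{\text{all}} - R_{-i})/R_{\text{all}}$ — the normalized drop in
the 31-channel $R$ when channel $i$ is left out. By CCA nesting
$r_i \le 1$; a duplicated channel contributes exactly 0. Note the null is
not exactly zero-mean: on pure noise, removing a channel lowers the
overfitted $R$ slightly, so null contributions carry a small positive
bias; the test suite checks the measured null against that predicted bias
rather than against zero.

**Contralateral scores.** For mirror pair $p$, stimulus side $s$ and angle
$d$,
$$E_{s,d,p} = \frac{\overline{r_{s,k,p_\mathrm{left}}}}{r_{0,0,p_\mathrm{left}}}
            - \frac{\overline{r_{s,k,p_\mathrm{right}}}}{r_{0,0,p_\mathrm{right}}},$$
with $r$ the per-stimulus single-channel responses averaged over valid
runs and $r_{0,0,\cdot}$ the central-stimulus references that absorb
static hemisphere differences. "Within $d$" is read cumulatively (all side-$s$
stimuli with eccentricity $\le d$), matching the wording "total stimuli
within certain degrees"; `within = "layer"` gives the single-ring variant.
Swapping the pair negates $E$ exactly. Significance uses the
Kruskal–Wallis rank test between the two channels' normalized per-stimulus
responses (pooled over participants) at $\alpha = 0.05$, because the
normalized scores are not normally distributed; with a single participant
at $d = 2°$ a side can have fewer than two stimuli, and the flag is then
reported as missing rather than computed from a degenerate test.

## Degenerate inputs and tie-breaks

* All-zero epochs: $R$ defined as 0, with a warning.
* Stimuli with no valid trial: missing position mean, with a warning.
* Zero usable runs at an angle: error (the statistic is undefined).
* Zero central reference in $E$: error, since the normalization is
  undefined.
* All-tied Kruskal–Wallis samples: $H = 0$, $p = 1$.
* Unfinishable sessions (retry cap exceeded): error naming run and
  stimulus; the cap (20) exists only to guarantee termination — the
  physical protocol has none.

## Layout geometry

The 46 stimuli sit on six layers: a central flicker plus rings of 3, 6, 9,
12 and 15 at 2°-spaced eccentricities. The per-ring counts are not stated
in the modelled protocol text (only the total and the spacing); these
defaults give every ring the same ~4.19° arc length between neighbours and
respect the within-ring non-overlap constraint, and they are configurable.
Because flickers are presented one at a time, discs on *different* rings
may legitimately sit closer than one diameter (the center-to-ring-2
distance of 2° is smaller than the 3° disc); overlap is only forbidden
within a ring. Ring offsets default to half the arc step, halved until no
stimulus sits on a meridian, so hemifield and vertical-field labels are
always defined.

## Known limitations

* EDF/BDF input is not implemented (no reader available in the supported
  dependency set); recordings exchange through the delimited formats of
  `read_eeg()`/`write_session()`.
* The error-rate t-test's peripheral pooling (per layer, not per stimulus)
  is one of several readings of the protocol; published per-participant
  p-values are not reproducible either way and are not treated as a
  reference surface.
* Simulated effect sizes are calibrated to qualitative structure only; no
  published amplitude or SNR figures exist for the modelled recordings.
* $\sigma_r$ recovery from CCA responses relies on the
  $R/\sqrt{1-R^2}$ amplitude index, which is exactly proportional to
  signal-to-noise amplitude only for a single matched-filter channel; with
  multichannel CCA it is approximate, and the recovery tolerance (20%)
  reflects that.
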