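---
title: "Methods: PAD preference scoring and ERP feature extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PAD preference scoring and ERP feature extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(padpref)
```

# Scope and model

`padpref` implements a two-track analysis of affective preference for visual
stimuli (in the motivating application, decorative oil paintings shown in
different interior environments):

1. a **subjective track**: semantic-differential emotion ratings scored into
   the Pleasure-Arousal-Dominance (PAD) space, typed into sign-octant
   emotion categories, matched against normative emotion profiles by
   Euclidean proximity, and summarized with a variance-free effect size and
   pleasure-band preference classes; and
2. an **objective track**: an event-related-potential (ERP) chain that takes
   multichannel EEG epochs to late-positive-potential (LPP) peak amplitudes
   and a frontal-asymmetry valence classification.

A synthetic-data module generates rater panels and lateralized evoked
epochs with the statistical structure the analysis assumes, so the whole
pipeline is testable without recorded data.

# The subjective track

## Scoring

Each response consists of twelve bipolar adjective items on a 9-point scale
from $-4$ to $+4$. The three dimensions are linear contrasts of four items
each:

$$P = (V_1 - V_4 + V_7 - V_{10})/4, \quad
  A = (-V_2 + V_5 - V_8 + V_{11})/4, \quad
  D = (V_3 - V_6 + V_9 - V_{12})/4.$$

Scoring is total on valid input and rejects (never imputes) missing or
out-of-range items, naming the offending cell. Because each dimension
averages four items, a rater noise of sd $\sigma$ per item yields a
per-dimension sd of $\sigma/2$.

## Octant typing and the two vocabularies

The sign triple of $(P, A, D)$ selects one of eight emotion categories
(`pad_octants()`): `+++` Joyful, `++-` Dependent, `+-+` Relaxed, `+--`
Mild, `---` Boring, `--+` Contempt, `-+-` Anxiety, `-++` Disgust. An
exactly-zero component has no sign; the package counts it as negative by
default and raises `zero_flag`. This choice is unobservable on the
published group means (none is exactly zero) but makes the function total
and deterministic; the opposite policy is available as an argument.

The *normative* inventory (`pad_norms()`) is a different vocabulary: eight
labeled points in PAD space (Joyful, Relaxed, Surprise, Dependent, Boring,
Fear, Contempt, Disgust) from the standardized Chinese PAD instrument. The
two vocabularies overlap but are not identical (the octant set has Mild and
Anxiety where the normative set has Surprise and Fear), and the source
material defines no cross-mapping. `padpref` deliberately keeps them as two
disjoint label sets and never converts between them.

## Preference by proximity

Emotional preference is nearest-centroid classification: the proximity of a
measured PAD mean to a normative point is the Euclidean distance
$L_i = \sqrt{(P-P_N)^2 + (A-A_N)^2 + (D-D_N)^2}$, and the preferred
emotion is the norm with minimal $L_i$. Exact ties are broken by
norm-table order and flagged; ties have measure zero on real data, so the
rule only matters for reproducibility of constructed cases.

## Effect size without variances

Group comparisons use a variance-free standardized mean difference
$\mathrm{SMD} = (M_1 - M_2)/(|M_1| + |M_2|)$, bounded in $[-1, 1]$, with
$|\mathrm{SMD}| = 1$ exactly when the two means have opposite signs or one
is zero. The printed rendering of this formula in the source material is
typographically corrupted; the reading implemented here is the unique one
consistent with all five effect sizes printed alongside their input means
(1.00, 0.24, 0.12, 0.42, 1.00), which the acceptance suite recomputes. The
measure is undefined at $M_1 = M_2 = 0$ and the package raises an error
there rather than returning 0.

## Pleasure bands

Pleasure means are classified into Unpleased / General / Pleased bands
between four nodes: $-1.25, -0.25, 0.25, 1.25$ for the painting scheme and
$-1.5, -0.2, 0.5, 1.5$ for the interior scheme. Adjacent bands share their
boundary node; a value exactly on a shared node is assigned to the band
*farther from zero*. That tie rule is forced by the published
classification itself: the Contemporary-art mean sits exactly on the
$-0.25$ node and is listed Unpleased. Values outside the outer nodes are
flagged `out_of_range` and assigned to the nearest band.

## Aggregation

Group means are unweighted arithmetic means of per-record PAD vectors
within group $\times$ stimulus; each participant contributes one response
per stimulus. Subgroups are non-exclusive (young-man and young-woman are
subsets of young), so records carry a cohort label plus sex and membership
is derived at aggregation time. Whether the published group means averaged
the three images of a style per participant first or pooled all records is
not stated in the source; both groupings are exposed
(`stimulus_map` + `participant_first`), they coincide for balanced panels,
and the participant-first variant is the default because it weights
participants equally under dropout.

# The objective track

The ERP chain applies a fixed stage order: low-pass, notch, segmentation,
baseline correction, mastoid re-referencing, artifact rejection,
averaging, peak extraction. Filtering precedes segmentation (edge
transients stay in the continuous record); baseline correction precedes
re-referencing (the removed constant is then independent of reference
noise); rejection operates on the fully preprocessed single trials that
enter the average.

## Filters

No DSP dependency is assumed: the package designs its own filters and
applies them forward-backward (zero phase, squared magnitude response).

* **Low-pass**: digital Butterworth (bilinear transform with pre-warping),
  default 4th order, 30 Hz cutoff. The single-pass design was verified
  against an independent reference implementation to coefficient-level
  agreement; the tests assert behavior, not coefficients: DC preserved,
  a 5 Hz sinusoid attenuated < 5%, a 45 Hz sinusoid attenuated > 90%
  (at 500 Hz sampling).
* **Notch**: biquad band-reject at 50 Hz, quality factor 30 (bandwidth
  about 1.7 Hz): > 95% suppression at 50 Hz with < 5% change at 40 and
  10 Hz.
* **Edge handling**: odd-reflection padding whose length adapts to the
  filter's slowest pole (about six decay time constants), with
  steady-state ("step-matched") initial conditions so constant signals
  pass through exactly. A high-Q notch still rings near segment edges —
  an inherent property of zero-phase notching, shared by standard
  implementations — so attenuation is asserted on the steady-state
  interior of long signals, and pipelines should notch continuous
  recordings rather than short epochs.

## Segmentation and windows

Epochs span $-200$ to $800$ ms around each onset with a half-open boundary
convention: the sample at the event time belongs to the post-stimulus side,
so a 1000 ms window at $f_s$ Hz yields exactly $f_s$ samples. Sample
indices derive from ms by round-half-up; all interfaces speak ms.
Events whose window exceeds the recording are dropped and logged, never
silently truncated. Baseline correction subtracts the per-trial,
per-channel mean of $[-200, 0]$ ms (endpoints inclusive); the corrected
baseline mean is zero to $10^{-9}$ by construction.

## Rejection, peaks, asymmetry

Artifact rejection removes any trial with $|v| > 100\ \mu V$ on any
analysis (non-mastoid) channel — the conventional amplitude-threshold
reading of the corrupted unit annotation in the source ("-100 to 100 Hz"),
and the only physically sensible one. Ocular ICA is out of scope.

The LPP feature is the **signed extremum**: within the inclusive
250-600 ms window, the value at the sample of maximal $|v|$, sign
preserved, ties to the earliest latency. The signed reading is required
because the source reports negative "maximum amplitudes" (e.g., frontal
values near $-4\ \mu V$). Peaks are extracted from condition-averaged
waveforms (matching the source's average-then-extract description);
per-participant extraction is available by running the pipeline per
subject.

The frontal-asymmetry index is mean(Fp1, F3) $-$ mean(Fp2, F4) of the peak
table; under the valence hypothesis an index above $+\varepsilon$
classifies `like`, below $-\varepsilon$ `dislike`, else `neutral`. The
neutrality half-width $\varepsilon$ is not specified in the source; the
API default is $0.5\ \mu V$ (a conservative small band), and cohort-level
tests use $\varepsilon = 2\ \mu V$, appropriate to their known index scale
of $5\ \mu V$ (see below).

# The synthetic world

The generators' defaults state the simulated world once; tests never tune
them toward outcomes.

* **Raters** (`generate_ratings`): item means are the exact inverse of the
  scoring contrasts, plus iid Gaussian item noise (default sd 0.5 on the
  9-point scale — about half a scale step, a plausible panel disagreement
  level), clipped to $[-4, 4]$; default panel size 45 matches the
  reference study (35 students + 10 professionals). Clipping biases
  recovered means toward zero for $|{\rm target}| \gtrsim 3.5$; tests stay
  below that regime. The model has no per-rater bias or cross-stimulus
  covariance: a green recovery test establishes correct plumbing and
  sampling behavior, not robustness to structured rater effects.
* **EEG** (`generate_epochs`): white Gaussian background (default
  $5\ \mu V$ per sample — single-trial LPP-window EEG scale) plus a
  Gaussian bump (default peak 400 ms, sd 80 ms, $5\ \mu V$ for
  like/dislike, $3\ \mu V$ for neutral) on scalp channels; mastoids carry
  noise only. Lateralization multiplies the frontal bump by $1 \pm
  \lambda$ (left/right for `like`, mirrored for `dislike`; default
  $\lambda = 0.5$), so the noiseless asymmetry index is exactly
  $2\lambda A$. The sampling rate is not stated in the source; 500 Hz is
  the package default. White noise is the simplest spectrum that
  exercises every stage; an LPP bump plus white noise does not emulate
  real EEG morphology (alpha rhythm, 1/f background, blinks), so green
  pipeline tests certify signal-processing correctness, not field
  performance.

With 40 trials/condition the averaged-waveform noise is
$5/\sqrt{40} \approx 0.79\ \mu V$ per channel and the asymmetry index has
sd $\approx 0.79\ \mu V$; against a $5\ \mu V$ index and
$\varepsilon = 2\ \mu V$ this predicts $\ge 95\%$ valence recovery, which
the acceptance suite measures on a 30-subject cohort at fixed seeds.

# Numerical conventions and limitations

* Proximities and PAD means print at 4 decimals, SMD at 2; table
  comparisons in tests allow $\pm 0.0002$ (last-digit rounding slack).
* One column of the published interior proximity table (Relaxed) is
  systematically inconsistent with the distance formula applied to its own
  inputs; it is shipped in the fixture but excluded from oracle tests, as
  documented in `?pad_extdata`. It is never a row minimum, so preference
  conclusions are unaffected.
* The published per-style ERP amplitudes come from recordings that are not
  publicly deposited and are not reproducible here; the ERP suite is
  property-based (injected-signal recovery, sign symmetries, attenuation
  bounds, synthetic-cohort accuracy) by design.
* Exact-zero PAD components and exact proximity ties are resolved by
  documented deterministic policies (`zero_policy`, norm-table order) and
  flagged, never silent.
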