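---
title: "Discovering latent directed network structures in trial-based recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering latent directed network structures in trial-based recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ercnet)
```

## The problem

Multichannel cortical recordings during a structured task contain many
concurrent directed interactions: bottom-up sensory flows, mnemonic
re-activations, top-down modulation. `ercnet` implements a complete
chain for extracting such *latent network structures* from
trial-segmented multichannel data:

1. **Trial screening** — gaze traces classify each trial by whether the
   context stimulus was visually perceived (`Cplus` iff the eye
   position is on screen strictly more than 80% of the first 0.5 s of
   the Context period; invalid gaze counts as off screen).
2. **Artifact-trial rejection** — robust z on band-averaged log
   spectral power.
3. **Source separation** — PCA-whitened fixed-point ICA with restart
   aggregation; the model order is the smallest eigencount explaining
   90% of channel variance; artifactual components are screened by
   extreme values and abnormal spectra.
4. **Spectral effective connectivity** — sliding-window multitrial VAR
   (AIC order, KPSS/whiteness/consistency validation) and the direct
   directed transfer function (dDTF), the full-frequency DTF weighted
   by partial coherence so that influences mediated by third sources
   are suppressed.
5. **Event-related causality (ERC)** — dDTF in decibels relative to the
   median of a within-Waiting baseline period, per frequency.
6. **Condition contrasts** — nine ordered scenario comparisons in each
   perception condition (18 in all), each cell bootstrap-tested over
   trials and Benjamini–Hochberg corrected, yielding ternary maps in
   {-1, 0, +1}.
7. **Tensor decomposition** — the maps are pooled into a 3-way tensor
   (comparison-condition x time-frequency x connection-subject) and
   factorized by PARAFAC with nonnegative time-frequency and
   connection modes; the component number is chosen where the core
   consistency diagnostic collapses.
8. **Structure-level statistics and inference** — per-subject directed
   graphs, causal density/outflow, area-level maximum flow, top-
   connection overlap, temporal/spectral profiles, trial-shuffle
   significance of the comparison loadings, activation-level
   reconstruction, and inter-structure correlations.

A synthetic-data generator with planted, condition-dependent couplings
stands in for animal recordings, so every stage is testable
end to end.

## The generator

Sources are damped AR(2) resonators: a source with resonance $f_r$ and
bandwidth $b$ at sampling rate $f_s$ has poles $\rho e^{\pm i 2\pi
f_r/f_s}$ with $\rho = e^{-\pi b/f_s}$, and its innovation SD is set so
the uncoupled stationary variance is exactly 1 (this keeps the channel
eigenspectrum balanced, so the 90%-variance ICA order rule recovers the
true source count). A scheduled coupling adds a lag-1 coefficient from
a driver to a sink during a trial-relative interval with a gain per
trial type; because the driver resonates at the coupling band, the
transferred power is band limited, and the exact time-varying VAR
coefficients are available in closed form (`planted_var()`) as the
analytic oracle for every spectral quantity.

Innovations are amplitude-modulated by slow log-normal envelopes (unit
mean square, knots at 4 Hz, log-SD 0.6). This makes the oscillations
bursty — as cortical band power is — and it makes the source marginals
super-Gaussian, which fixed-point ICA requires for identifiability: a
stationary Gaussian VAR is unidentifiable from marginal statistics
alone. The envelopes are independent of the VAR state, so the
coefficient oracle is untouched.

The default schedule plants five structures: a context-graded beta
coupling in early Context (Cm > Ch > Cw, halved under `Cminus`), an
Rf-only high-gamma coupling early in Response, a generalized-context
beta coupling in late Context (Ch = Cm > Cw), its Rf- and
Cplus-gated re-activation in mid-Response on the same pair, and a
top-down alpha/low-beta coupling late in Response that reverses the
first structure's pair. Two deliberate design choices:

* **No coupling cycle is ever simultaneously active.** The two
  directions of the reused pair occupy disjoint intervals, and the
  three Response-period couplings activate sequentially. Each
  piecewise-constant segment's coupling graph is therefore acyclic and
  stability follows from the resonator poles (still verified segment
  by segment; unstable requests are rejected with a report).
* **Effect sizes are development choices, not measurements.** The
  study design this emulates does not fix coupling magnitudes; the
  defaults (base strength 0.35, sensor noise SD 0.2) were chosen once
  so that the planted effects are comfortably detectable at the
  desk-scale sizes used throughout the tests, and they are exposed in
  the configuration.

What the generator does *not* emulate: volume conduction and cortical
geometry, non-stationary artifacts beyond broadband bursts, genuine
oscillatory cross-frequency coupling, inter-subject anatomical
variability. Passing tests therefore demonstrate the pipeline's
correctness and calibration on data satisfying its assumptions, not
performance on real recordings.

## Numerical choices that matter

* **Windows**: 250 ms length / 50 ms step by default; milliseconds are
  converted to samples by round-half-up (250 ms at 250 Hz is 63
  samples), the realized durations are recorded, and window timestamps
  are window centers.
* **Sample budget**: a window must satisfy `w * n * k >= 10 * k^2 * p`
  (parameters at most 10% of scalar samples). The one-line form
  `w >= 10 k^2 p / n` is also evaluated and disagreement flagged; at
  realistic trial counts the one-line form is unsatisfiable for
  windows shorter than a second, while the adopted reading matches the
  published operating point (63-sample windows at k = 33, p = 9,
  n = 122).
* **VAR order**: multivariate AIC with `N_eff` the pooled regression
  rows, all candidate orders evaluated on a common observation range;
  ties go to the smaller order.
* **Stationarization order**: detrend, per-trial z-score, ensemble
  normalization are applied to the *retained source series* before the
  VAR stage. Applying them to channels before ICA would make the
  mixing time-varying; on synthetic data this measurably degrades
  source recovery.
* **ERC epsilon policy**: baseline medians (and map values) are floored
  at 1e-12 before the dB ratio, with a warning, since the ratio is
  undefined at zero.
* **Contrast testing**: per cell, the two-sided percentile bootstrap
  p-value is `2 min(#{d* > 0}, #{d* < 0}) / B`; Benjamini–Hochberg runs
  across all cells of one comparison within a subject (the widest
  defensible family). Lowering the level can only remove cells.
* **PARAFAC**: alternating least squares; the unconstrained comparison
  mode carries all scale, the nonnegative modes are updated column-wise
  (HALS — a closed-form clipped update; an active-set solver per row
  would be equivalent but far slower in interpreted code) and returned
  with unit-norm columns. Convergence is a relative change in the
  residual sum of squares below 1e-6, capped at 2000 iterations.
  Random-orthogonal restarts are screened for 40 iterations and the
  best continued to convergence; the direct-trilinear start is
  generalized rank annihilation on two random slab aggregates.
* **Component number**: the scan fits both initializations at every
  `r`; the restart-based consistency curve drives the sharp-drop rule
  (the largest `r` holding the threshold while `r + 1` falls below
  it). A single direct-trilinear solution can land on a degenerate
  high-consistency optimum when over-factored, which is why it does
  not drive selection.
* **Shuffle inference**: trial-type labels are permuted within each
  perception condition (the conservative choice; the alternative of
  permuting across conditions is configuration-exposed), the full
  contrast pipeline is recomputed, and only the comparison mode is
  refitted against the fixed time-frequency and connection modes. The
  observed loadings are always the refit of the unshuffled tensor —
  at the ALS optimum this equals the model's own loadings. With 50
  shuffles the achievable two-sided level is 2/51, about 0.039, which
  is recorded on the result.

## Small-source-count phenomena

Two genuine properties of the directed measures dominate at desk scale
(a handful of sources) and are worth knowing about before interpreting
results on small systems:

* **Suppression side lobes.** The full-frequency DTF normalizes each
  sink's inflows over sources and frequencies, and partial coherence
  conditions every pair on all other sources. When a strong coupling
  switches on, the measured dDTF of *other* connections into the same
  sink drops. The ternary tensor therefore contains, for each planted
  coupling, a focal positive pattern and a diffuse negative one with
  the same comparison signature. Under the nonnegativity constraints
  these must occupy separate components, so decompositions of
  small-system tensors need spare components beyond the planted count
  (the end-to-end recovery study uses 7 for 5 planted structures). At
  realistic source counts (tens of components) each sink has many
  inflows and the side lobes are correspondingly diluted.
* **Post-selection optimism of the shuffle test.** With the
  time-frequency and connection modes fixed from the same tensor being
  tested, the observed comparison loadings inherit the fit's optimism;
  on sparse null tensors this inflates the empirical size well above
  the nominal level, while at the standard FDR level a null tensor is
  empty and every loading ties at zero. The calibration experiment in
  the test suite therefore fixes the modes from an independent null
  realization and uses a permissive contrast threshold, isolating the
  permutation test's intrinsic size (2/51 with 50 shuffles).

## Problem sizes used in the tests

The suite runs the full pipeline on one synthetic subject with 8
channels, 6 sources, 36 trials per trial type at 200 Hz, 7 s trials,
contiguous 0.7 s windows, the generative VAR order (p = 2), 8 frequency bins spanning 5–90 Hz, and 7 PARAFAC
components; the core-consistency scan uses 18 x 60 x 80 tensors over 20 seeds
with 20 restarts per fit (the smallest size at which the consistency
collapse beyond the planted component number is reliably resolved); calibration studies use 3-source null generators. These
sizes were chosen as the smallest at which every stage operates in its
intended regime (the sample-budget rule holds, ICA is overdetermined,
the planted spectral peaks are resolvable on the bin grid).

## Known limitations

* The restart-aggregation ICA replaces a published multi-run bootstrap
  tool with average-linkage clustering on absolute source
  correlations; stability indices are comparable in spirit but not
  numerically identical to that tool's.
* The artifact-trial and artifact-component screens are documented
  robust-z rules, not reproductions of the published toolbox
  heuristics they stand in for.
* Line noise removal is a zero-phase IIR notch (Q = 35), not multitaper
  regression.
* The activation-level solver (anchored least squares over significant
  differences) is the minimal-assumption reconstruction; the source
  publication does not define one.
* Per-subject PARAFAC refits are not implemented; one model is fitted
  to the pooled-subject tensor.
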