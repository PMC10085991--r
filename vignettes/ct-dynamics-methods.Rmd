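---
title: "Models and methods behind ctdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ctdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdyn)
```

## The problem

The carboxyl terminus (CT) of several Gs-coupled GPCRs is intrinsically
disordered yet functionally engaged: it docks onto the cytoplasmic surface
of the transmembrane core and competes with the G protein. Four data
modalities quantify this equilibrium: smFRET between a core reference label
and a CT label (high FRET ≈ CT engaged, low FRET ≈ CT displaced),
concentration-response titrations of binders that displace the CT, NMR
chemical-shift and intensity perturbations along the CT backbone, and
adaptively seeded MD campaigns that sample the CT conformational ensemble.
`ctdyn` implements the analysis for all four, plus generators that produce
each input with known ground truth.

## Synthetic smFRET traces

Traces follow a discrete-time two-state Markov chain at the camera frame
time (default 100 ms). Exit rates `k_high_to_low`, `k_low_to_high`
(s⁻¹) convert to per-frame switching probabilities `p = k Δt` (checked
`≤ 1`), so simulated dwell lengths are exactly geometric with mean
`1/(k Δt)` frames — the property the dwell-time oracle tests assert.

Each state carries a fixed mean total intensity split between donor and
acceptor channels by its mean efficiency. Noise enters in two places:

* `efficiency_sd` jitters the per-frame donor/acceptor partition, so the
  apparent per-frame FRET efficiency has exactly that standard deviation
  (before clamping to `[0, 1]`). This is the natural parameter when peak
  widths are stated in efficiency units, and it is how the recovery
  studies set the generative peak width (e.g. sd 0.068 gives
  FWHM `2√(2 ln 2) × 0.068 ≈ 0.16`).
* `channel_noise_sd` adds independent Gaussian read noise per channel,
  the regime of an EMCCD whose readout dominates. A Poisson channel model
  was considered and left out: at the hundreds-of-counts-per-frame level
  used here the Gaussian approximation is indistinguishable, and the
  efficiency-level parameterization is what the downstream checks need.

Donor photobleaching is an absorbing event with exponential waiting time
(`photobleach_rate`); after it both channels emit background only. Only
donor bleaching is modelled, matching the dominant failure mode in
two-color TIRF traces. No blinking, spectral crosstalk or gamma correction
is modelled; the FRET values are apparent efficiencies throughout,
consistent with the ratio formula used for the real data.

Confocal bursts are exponential-duration transits (default mean 5 ms,
recorded in 1000 µs bins) with per-channel Poisson photon counts at the
stated signal and background rates.

## From intensities to histograms

Per-frame efficiency is `I_A / (I_A + I_D)`, clamped to `[0, 1]`; frames
with nonpositive total intensity are flagged invalid, never divided.
Photobleach truncation uses a least-squares single change point on total
intensity: the split minimizing within-segment variance is a bleach when
the post-drop mean falls below half the pre-drop mean (configurable) for
at least 5 frames. The real experiments truncated traces manually; a
deterministic detector makes the pipeline reproducible, and the exhaustive
change-point oracle in the tests pins its behavior. Histograms use 100
fixed bins of width 0.01 on `[0, 1]` (half-open, last bin closed) and are
normalized by total frame count.

Burst analysis applies the ≥ 40 raw-photon threshold before background
correction, then computes the corrected-count efficiency. Out-of-range
values (one corrected channel negative) clamp to the nearest boundary;
bursts with both corrected channels ≤ 0 are discarded. Whether the
original analyses clamped or discarded such bursts is not documented;
clamping keeps the histogram mass budget intact, and the choice only
touches a thin tail of bursts at realistic backgrounds.

## State identification and dwell times

`fit_hmm()` is a Gaussian-emission Baum–Welch fit: k-means initialization
on the pooled efficiencies, 5 seeded restarts (best likelihood kept),
convergence at relative log-likelihood change `< 1e-6` or 500 iterations,
with the forward/backward and Viterbi recursions compiled. The state count
defaults to 2 — the two-state behavior the FRET histograms justify — and
the free-state-count search of HaMMy-style tools is deliberately not
reproduced. A fit is flagged `degenerate` when two state means are closer
than 1.5 × the sum of their emission sds: such states cannot be resolved
on these emissions and usually mean one population was split in half.

Dwells are maximal constant runs of the Viterbi path. The first and last
run of every trace are truncated by the observation window and flagged
censored; summary means use uncensored dwells only. Note a second,
subtler truncation effect: interior dwells must fit inside the window, so
when the window is not much longer than the mean dwell the interior mean
is biased slightly short. The generator test therefore uses windows ~300×
the mean dwell; at the 60 s traces and ~2 s dwells of the recovery study
the bias is ~2%, well inside the ±20% recovery tolerance.

Occupancies come from a weighted least-squares double-Gaussian fit to the
histogram (weights `1/max(height, 1/N)`, stabilizing empty bins). The
occupancy of a component is its **area fraction** `a σ / Σ a σ`, not its
peak amplitude — areas are the probability masses. When conditions with
weak low-FRET signal are fitted, the low center can be held fixed (the
real analyses used 0.38 below 10 nM Gs). `occupancy_curve()` assigns
components to the low/high side at 0.55 efficiency (midway between the
canonical ~0.4 displaced and ~0.7 engaged peaks), which also resolves the
one-population case where the two-component model splits a single peak
arbitrarily.

## Dose-response fitting

`fit_4pl()` fits `R(c) = bottom + (top − bottom)/(1 + 10^{h(log₁₀EC50 −
log₁₀ c)})` by bounded Levenberg–Marquardt on the log-concentration axis.
The Hill slope is free by default with bounds `[0.3, 5]` (a
four-parameter sigmoid implies a free slope; whether the original smFRET
EC50s fixed it is unstated, and at Hill ≈ 1 truth both choices recover
the EC50 within tolerance). Starting values take bottom/top from the
extreme-concentration means and EC50 from the half-maximal crossing.
Replicates are fitted jointly rather than as means, preserving the error
structure. Flat responses raise a no-signal error instead of returning a
meaningless EC50. The cell-assay arithmetic (fold change over a baseline
window, vehicle normalization, expression-normalized slopes and %WT,
ΔpEC50 and relative Emax) is plain, unit-tested algebra.

## NMR perturbation profiles

CSP uses the standard weighted amide combination
`Δδ_av = √(Δδ_H² + (Δδ_N/5)²)`; peaks are matched by assigned residue
number and residues absent from either list propagate as explicit gaps
(`NA` + `missing` flag), never as zeros. Intensity ratios and PRE
`I_para/I_dia` default to per-replicate ratios averaged with s.e.m.
(matching sequential-measurement replication); a merged mode averages
intensities first. Replicate counts are configurable since different
experiments used two or three sequential measurements. No peak picking,
assignment, or PRE-to-distance conversion is attempted.

## Adaptive sampling

Frames are scored `P ∝ W1 (1 − |D_target − D|) + W2 / P_obs` with
`W1 = W2 = 1` by default. Two quantities in that rule are underspecified
in words and fixed here as follows:

* The exploit term is dimensionally ambiguous if `D` is in Ångström, so
  `D` is min-max rescaled to `[0, 1]` over the accumulated frame pool
  (bounds refreshed at each scoring call, or fixed via `d_bounds`). This
  keeps the exploit and explore components commensurate, which is the
  point of balancing them equally.
* `P_obs` is the fraction of pool frames in the frame's descriptor bin
  (default bin width 2 Å on the scalar descriptor). A frame's own
  observation counts, so `P_obs ≥ 1/n` and `1/P_obs` is always finite.

Seeds are drawn **without replacement** proportionally to score
(replacement policy is otherwise unspecified; without replacement avoids
duplicate starts within an epoch). Epoch 1 starts every trajectory from
the initial conformation; later epochs restart the engine from the
selected frames. The engine interface is a plain closure, and the shipped
engine is the toy overdamped-Langevin integrator: Euler–Maruyama on a
sum-of-Gaussian-wells potential, `dx = (D/kT) F(x) dt + √(2 D dt) ξ`,
with soft harmonic walls outside 25–75 Å. `thermal_energy = 0` is the
deterministic gradient-descent limit (noise off, mobility taken
numerically equal to the diffusion coefficient). The default landscape is
a double well with minima near 40 and 60 Å, depth 3 kT, width 4 Å and
D = 2 Ų/ns — an energy scale that makes well hopping rare on one
trajectory but reachable, which is the regime where adaptive seeding
demonstrably beats naive restarts. Campaigns default to 5 epochs × 10
trajectories; the test and acceptance campaigns use 400-step, 0.5 ns
trajectories emitted every 4 steps (100 frames ≙ 200 ns each), enough to
separate adaptive from naive enrichment in every seeded repeat without
atomistic cost.

Trajectory descriptors are intentionally simple: minimum pairwise
distance between two labelled point sets, positional RMSD versus the
starting frame or the trajectory average (no superposition — inputs are
assumed pre-aligned or internal), centered running averages, and contact
frequency as the fraction of frames with minimum inter-residue distance
within 3.5 Å.

## Problem sizes and tolerances

The recovery studies run at desk scale, sized so each completes in
seconds while leaving comfortable statistical margins: 300 traces × 200
frames for peak-center recovery (±0.01), 3 replicates on half-log
concentration grids for EC50 recovery (±25%), 200 traces × 600 frames for
dwell recovery (±20%), 10⁵ frames for mixture-weight recovery (±0.03 on
weights, ±0.02 on the low center). Statistical acceptance bands use 3
standard errors with autocorrelation-corrected effective sample sizes
where the data are Markov chains.

## Limitations

* The generators emulate the statistical structure of the real data, not
  their physics: no camera PSF fitting, no diffusion-limited burst shapes,
  no chemical-shift prediction, no atomistic forces. Passing recovery
  tests shows the analysis is correct and well-calibrated on data
  matching its assumptions; it does not validate those assumptions
  against any particular instrument.
* The HMM assumes frame-wise conditional independence of emissions;
  blinking or slow drift would violate it.
* The double-Gaussian occupancy model is exactly two components; more
  heterogeneous ensembles need a different mixture order.
* The toy dynamics are one-dimensional by construction; the descriptor
  binning for `P_obs` is one admissible reading of "conformation" and a
  clustering-based definition would need a different implementation of
  the same interface.
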