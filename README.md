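# ctdyn

Quantitative analysis of GPCR C-terminal (CT) dynamics from single-molecule
FRET, concentration-response, solution-NMR and adaptive-sampling data.

The disordered carboxyl terminus of receptors such as the β2-adrenergic
receptor competes with the G protein for the cytoplasmic surface of the
transmembrane core. The experiments that expose this — TIRF smFRET traces of
labelled receptors, confocal photon bursts, Gs/nanobody titrations, amide
chemical-shift-perturbation and PRE profiles, and adaptively seeded MD
campaigns — share a common quantitative toolchain, which this package
implements end-to-end with a synthetic-data module so that every stage can
be validated against known ground truth.

## What it computes

* **Per-frame FRET**: `E = I_A / (I_A + I_D)` with photobleach truncation
  (least-squares change point on total intensity), pooled into normalized
  100-bin histograms at bin width 0.01.
* **Per-burst FRET**: `(f_A − b_A) / ((f_A − b_A) + (f_D − b_D))` with the
  ≥ 40-photon burst threshold applied to raw counts.
* **State kinetics**: maximum-likelihood Gaussian-emission HMM (Baum–Welch,
  k-means initialization, seeded restarts), Viterbi idealization, dwell
  extraction with first/last-dwell censoring, and double-Gaussian occupancy
  fits (`fwhm = 2√(2 ln 2) σ`; occupancy = component area fraction; the
  low-FRET center can be held at a fixed value such as 0.38).
* **Dose-response**: four-parameter logistic fits on the log10-concentration
  axis, `R(c) = bottom + (top − bottom) / (1 + (EC50/c)^h)`, with
  `pEC50 = −log10 EC50`, ΔpEC50 and relative Emax comparisons, fold-change
  and expression-slope normalizations for cell assays.
* **NMR profiles**: `Δδ_av = √(Δδ_H² + (Δδ_N/5)²)` per residue, intensity
  ratios and PRE `I_para/I_dia` with replicate s.e.m.
* **Adaptive sampling**: the explore/exploit seeding rule
  `P(frame) ∝ W1 (1 − |D_target − D|) + W2 / P_obs` over epochs of
  trajectories, with a toy overdamped-Langevin engine on a double-well
  landscape standing in for atomistic MD, plus trajectory descriptors
  (minimum label-site distance, RMSD versus start/mean, running averages,
  contact frequencies at a 3.5 Å cutoff).

## Worked example

```r
library(ctdyn)

# an apo-like receptor: one FRET population at 0.72 with per-frame sd 0.068
em  <- emission_model(mean_donor = 280, mean_acceptor = 720, efficiency_sd = 0.068)
kin <- two_state_kinetics(1e-12, 1e-12, p_high0 = 1)
tr  <- simulate_traces(kin, em, n_traces = 100, duration = 20, seed = 1)
effs <- lapply(split(tr$traces, tr$traces$trace_id), compute_fret)
fit  <- fit_single_gaussian(build_histogram(effs))
cat(sprintf("peak center %.3f, FWHM %.3f\n", fit$centers, fit$fwhm))
#> peak center 0.720, FWHM 0.160

# a nanobody titration: occupancy response, EC50 5.5 nM, 3 noisy replicates
truth <- titration_truth(0, 1, ec50 = 5.5e-9, hill = 1,
                         concentrations = 10^seq(-9.5, -7, 0.5),
                         replicates = 3, noise_sd = 0.03)
fit_4pl(simulate_titration(truth, seed = 2))
#> 4PL fit: bottom = 0.00823  top = 0.969  EC50 = 4.9e-09 M  (pEC50 = 8.31 )  hill = 1.07
```

The histogram fit recovers the generative peak center (0.72) and width
(FWHM 0.16 = 2.355 × 0.068), and the 4PL fit recovers the generative EC50
(4.9 nM fitted versus 5.5 nM generated, within the sampling noise of a
3-replicate series).

## Documentation

See the methods vignette (`vignettes/ct-dynamics-methods.Rmd`) for the
models, noise assumptions, numerical choices and known limitations, and
the roxygen help pages for per-function contracts.
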