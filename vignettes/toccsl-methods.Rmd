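---
title: "Methods: two-color TOCCSL analysis of receptor dimerization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-color TOCCSL analysis of receptor dimerization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toccslr)
```

## The measurement problem

ErbB3 and ErbB2 are receptor tyrosine kinases whose signaling requires
dimerization. At physiological surface densities (tens of receptors per
square micrometer) individual fluorophore-labeled receptors cannot be
resolved, so dimer stoichiometry is invisible to ordinary imaging. TOCCSL
("thinning out clusters while conserving stoichiometry of labeling") solves
this by photobleaching every fluorophore inside a slit-shaped aperture
(~10 um wide) with a strong 700-ms pulse, waiting 5-10 s, and imaging the
few unbleached entities that have diffused back in. Each re-entering mobile
entity is a monomer, dimer or higher oligomer with its labeling
stoichiometry intact. With two spectrally distinct Fab labels on the same
receptor, dimers show up as green-red co-localizations (within one camera
pixel, 160 nm); with the two colors on two different receptors, the same
readout counts heterodimers.

`toccslr` implements both the forward model (a synthetic-data generator
that emulates the full acquisition) and the inverse analysis (localization,
registration, tracking/MSD, co-localization with false-positive
subtraction, stoichiometry corrections, a global competition model, FRAP
and binding-affinity fits). Because no raw single-molecule data are
published for this system, every quantitative claim of the package is
validated by round-trip recovery: simulate at a known ground truth, analyze
blind, compare.

## The synthetic world

`simulate_toccsl_dataset()` places entities (ErbB3 monomers, ErbB3
homodimers, ErbB3/ErbB2 heterodimers, free ErbB2, optional higher
oligomers) uniformly on a periodic 40 x 10 um field -- four aperture widths
wide, approximating the infinite unbleached reservoir outside the mask.
Defaults and what they emulate:

* pixel size 0.16 um; slit aperture 10 um; bleach pulse 0.7 s; recovery
  7.5 s (middle of the stated 5-10 s); 20 ms green-to-red exposure gap;
  localization noise sigma_xy = 20 nm/axis. These are the acquisition
  parameters of the emulated protocol.
* receptor density 10 um^-2. The protocol requires a density too high for
  single-molecule resolution in the prebleach image (about 0.26 receptors
  per pixel here) yet low enough that the TOCCSL frame at the onset of
  recovery is sparse (~1 spot/um^2 near the recovery fronts). 10 um^-2 sits
  in that regime; it is a package choice, stated once, not fitted.
* labeling: two Fabs at 200 nM each competing for the same ErbB3 epitope
  with Kd 5 nM gives p_green = p_red = 0.494 and 1.2% unlabeled --
  the "equimolar, saturating" labeling of the emulated experiments.
  Degrees of labeling exceed 1 dye/Fab, so a bound Fab is treated as
  detectable; an optional Poisson-dye mode darkens Fabs with probability
  exp(-DOL).
* motion is simulated during the bleach pulse and the channel gap. The gap
  displaces the two colors of a true pair by ~sqrt(4 D * 0.02 s) (40-90 nm),
  which matters at a 160-nm pairing radius; the pulse matters because
  entities that wander into the strip mid-pulse are bleached too (see the
  recovery model below). Bleaching during the pulse uses Brownian-bridge
  edge-crossing probabilities between substeps, so absorption is exact in
  continuous time.
* trajectory frames: the tracking frame interval is a free parameter
  (default 10 ms) because the source protocol does not print it.

What the generator does **not** emulate: blinking and reversible
photophysics, FRET, 3D membrane topography, spatially varying receptor
density, and cell-to-cell expression variability (cells differ only by
Poisson sampling). A green round-trip test therefore establishes estimator
correctness under the stated model, not robustness to all real-world
artifacts.

## Diffusion estimation

Trajectories are linked by frame-to-frame mutual nearest neighbors within
`3 * sqrt(4 D_max dt)` (linking algorithm unspecified in the source;
mutual-NN is simple and order-invariant, and recovers >= 95% of links at
TOCCSL densities). Squared displacements are pooled over all trajectories
and overlapping time origins; the diffusion coefficient comes from the
exact two-point solve of `msd = 4 D t_lag + 4 sigma_xy^2` on the first two
lags. The fitting error is the SD of 1000 re-fits with the two msd values
resampled from Gaussians. The width of those Gaussians is the per-lag SD of
squared displacements divided by sqrt(n) -- we read the published recipe's
"SD of squared displacements" as the uncertainty of the *mean* msd entering
the fit; a flag (`resample_sd = "sd"`) restores the literal reading.
Negative intercepts are reported as-is with a flag, never truncated.

## The recovery correction

Slow species are under-represented in the TOCCSL frame: the probability of
having re-entered the window by the recovery time depends on D. For
instantaneous bleaching of the strip `|x| < L/2`, the unbleached
concentration is the classic erf profile and the recovery probability
rho(D) is its mean over the analysis window. This analytic form is verified
against a brute-force 100k-walker Monte-Carlo oracle to within 0.01
absolute over a (D, t) grid (an acceptance criterion).

Because the real pulse lasts 0.7 s, molecules just outside the strip can
diffuse in and bleach during the pulse, depleting exactly the near-edge
reservoir that drives early recovery. With `bleach_duration_s > 0` the
model treats the strip as a perfect absorber for the pulse duration
(post-pulse profile `erf(d / sqrt(4 D T))` outside the strip) and then
relaxes it freely. Ignoring this finite-pulse effect biases recovered
dimer fractions by several points at the stated operating points; the
simulator, which implements the same physics by particle simulation, is
the independent check.

The analysis window defaults to the full aperture width: the TOCCSL image
is the whole illuminated field of view, and the observable recovery at
7.5 s concentrates in bands near the aperture edges. A narrower window is
supported (`analysis_width_um`).

## Co-localization and false positives

Pairing is one-to-one mutual nearest neighbor within 160 nm, symmetric
under channel swap, ties broken by spot index. The accidental-pair rate is
estimated by mirroring the red coordinates about the vertical and the
horizontal axis and re-pairing; the estimate is the mean of the two
reflections (a flag selects the single 180-degree point reflection, since
the published wording admits both readings). Two refinements matter in
practice:

* **Reflection center.** Reflecting through the data centroid misaligns
  the narrow recovery bands by twice the centroid's sampling error and
  underestimates accidentals by ~20% at realistic spot counts. When the
  aperture geometry is known (always, for an instrument) the reflection
  uses the aperture axis; `colocalize_dataset()` does this automatically.
* **Availability deflation.** In the mirrored configuration every spot is
  free to form an accidental pair, but in the real configuration spots
  bound in true pairs are not available. The mirror estimate is therefore
  deflated by the fraction of actually-available spots per channel,
  estimated from the observed singles plus the accidental count itself.
  Without this, the correction over-subtracts precisely when the dimer
  fraction is high (by ~15% of pairs at a 70% heterodimer fraction). In
  the dimer-free limit the deflation tends to 1, so the null calibration
  (corrected count unbiased around zero) is untouched.

## From counts to molecule fractions

With N_m monomer and N_d dimer entities in the window before bleaching,
labeling probabilities (p_g, p_r, u) per receptor and recovery
probabilities rho_m, rho_d:

* expected pairs: `rho_d N_d 2 p_g p_r q_det`, where q_det combines the
  probability that the pair's two exposures fall within the pairing radius
  (diffusion during the 20-ms gap plus localization noise) and within the
  analysis window (`pair_window_retention()`),
* expected green singles:
  `rho_m N_m p_g + rho_d N_d (p_g^2 + 2 p_g u)` plus the singles left by
  undetected true pairs; symmetrically for red.

The system is solved by method of moments (pairs give N_d; the two singles
equations each give an N_m, averaged), and the molecule-level fraction
`alpha = 2 N_d / (N_m + 2 N_d)` is reported with a seeded cell-level
bootstrap SE (1000 resamples). Negative solutions are clipped to the
boundary with a warning. The heterodimer-mode estimator has the same
structure with `E[pairs] = rho_het N_het q_g p_r`; its red singles cannot
distinguish ErbB3 monomers from ErbB3 homodimers, so standalone it assumes
the non-heterodimeric ErbB3 is monomeric -- the joint case is the global
model's job.

## The global competition model

Homodimer-mode experiments see heterodimers only as single-ErbB3 entities
(with heterodimer mobility); heterodimer-mode experiments see ErbB3
homodimers only as red singles (with homodimer mobility). `fit_global()`
fits one composition (mu, alpha, beta) on the 2-simplex to the six
aggregated counts of both experiments by weighted least squares (weights
1/expected, the Poisson choice), with the per-cell ErbB3 abundance shared
between experiments by default -- the emulated protocol selects cells of
similar expression, and without sharing the 6-observation/5-parameter
system is too weakly identified to pin the composition. Bootstrap SEs over
cells; boundary solutions are flagged. Increasing the seeded heterodimer
share at fixed total dimerization decreases the fitted homodimer share,
reproducing the competition signature.

## Brightness mixtures

Single-color TOCCSL classifies entities by brightness: a k-mer is the sum
of k independent monomer brightnesses. `brightness_mixture_fit()` fixes
the component densities as k-fold FFT convolutions of the monomer
reference (a parametric lognormal or a kernel density estimate of a
monomer sample) and fits only the mixture weights by EM, which keeps the
weights non-negative and normalized by construction. K defaults to 4; the
monomer+dimer share of a seeded 90/10 mixture is recovered within 5
points (an acceptance criterion).

## FRAP and binding

FRAP curves are corrected for acquisition bleaching with the exponential
rate fitted from a fast series, then `I(i t_lag)/I_pre = f_m (1 -
exp(-i t_lag / tau))` is fitted per cell by bounded least squares
(f_m in [0, 1.2], tau in (0, 1000] s; starts: last-point ratio and
half-recovery time). Cells are fitted individually and pooled as
mean +/- SD; non-convergent cells are excluded loudly. Binding titrations
use the one-site law `B = Bmax c / (Kd + c)` and, for unlabeled Fabs, the
one-site competition curve with the Cheng-Prusoff conversion
`Kd = IC50 / (1 + c_labeled / Kd_labeled)`. Fits are weighted by 1/y^2
because flow-cytometry intensities carry approximately proportional noise;
this keeps Kd recovery unbiased under the simulated 3% multiplicative
noise. Free-ligand depletion is not modeled.

## Numerical choices and degenerate inputs

* Ties in nearest-neighbor pairing/linking (< 1 nm) break by lowest index.
* `p_g p_r = 0` makes dimer counts uninformative: estimators error out.
* A spot lying exactly on a mirror axis self-pairs under reflection; it is
  counted and flagged with a warning.
* All stochastic steps (simulation, resampling, bootstrap) take explicit
  seeds; pipeline stages derive their seeds from one master seed, so a
  rerun reproduces the report bit for bit.
* Image I/O is uncompressed 16-bit grayscale TIFF written and read by the
  package itself (no TIFF library is assumed present); localization uses
  band-pass detection plus Gaussian fitting (least squares, or Poisson MLE
  behind a flag, since the original estimator's noise model is not
  printed), with Thompson-formula precision estimates.

## Known limitations

* The recovery correction and the global model reconstruct unpublished
  supplementary material; they are validated by round-trip recovery and
  by internal oracles, not against the original intermediate numbers.
* The brightness mixture assumes strictly proportional k-mer brightness
  (no self-quenching or partial bleaching).
* The moment-based estimators aggregate counts over cells; cell-to-cell
  heterogeneity beyond Poisson sampling would widen the bootstrap SE but
  is not itself modeled.
* Residual model error of the full chain at extreme compositions is about
  one to two percentage points (e.g. the 70% heterodimer operating point
  recovers ~68%), dominated by pairing competition in the dense recovery
  bands; this is visible in, and bounded by, the acceptance round-trips.
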