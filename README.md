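# toccslr

Two-color **TOCCSL** ("thinning out clusters while conserving stoichiometry
of labeling") analysis of membrane receptor dimerization, with the
ErbB2/ErbB3 receptor pair as the motivating system.

## Who this is for

Single-molecule microscopists who measure the oligomeric state of mobile
membrane proteins. At physiological surface densities individual labeled
receptors are unresolvable, so TOCCSL photobleaches a slit-shaped membrane
region (~10 um) with a 700-ms pulse and images the sparse unbleached
entities that diffuse back in during a 5-10 s recovery window. Labeling the
same receptor with green and red Fab fragments makes homodimers visible as
two-color co-localizations within one camera pixel (160 nm); labeling two
different receptors counts heterodimers. `toccslr` provides the complete
chain from raw (or simulated) frames to molecule-level dimer fractions, and
a synthetic-data generator with full ground truth for validating every
step.

## The core quantities

* **Diffusion:** pooled mean-squared displacement vs time lag, fitted on
  the first two lags as `msd = 4 D t_lag + 4 sigma_xy^2`; the error on D is
  the SD of 1000 Gaussian-resampled re-fits.
* **Recovery correction:** slow dimers re-enter the bleached strip less
  readily than monomers. After complete bleaching of `|x| < L/2`, the
  unbleached concentration is
  `c(x,t) = 1 - (erf((L/2-x)/s) + erf((L/2+x)/s))/2`, `s = sqrt(4 D t)`;
  the species-wise observation probability rho(D) is its mean over the
  analysis window (with an optional finite-pulse absorber refinement).
* **Dimer fraction:** with labeling probabilities (p_g, p_r, u) per
  receptor, `E[pairs] = rho_d N_d 2 p_g p_r`,
  `E[green singles] = rho_m N_m p_g + rho_d N_d (p_g^2 + 2 p_g u)` (and
  symmetrically in red); solved by moments after subtracting mirrored
  false positives, reported as `alpha = 2 N_d / (N_m + 2 N_d)` with a
  cell-level bootstrap SE.
* **Global competition model:** one composition (monomer, homodimer,
  heterodimer) jointly fitted to homodimer-mode and heterodimer-mode
  experiments on the 2-simplex.
* **FRAP:** `I(i t_lag)/I_pre = f_m (1 - exp(-i t_lag/tau))` after
  `exp(-i k_bleach)` correction; **binding:** one-site specific and
  competitive (Cheng-Prusoff) Kd fits.

## Worked example

Simulate 30 cells at a 23% homodimer ground truth, run the co-localization
and correction chain, and estimate a diffusion coefficient:

```r
library(toccslr)

cfg <- sim_config()                      # 160-nm px, 10-um slit, 7.5-s recovery
pop <- population_spec(density_erbb3_per_um2 = 10, f_homodimer = 0.23,
                       D = c(monomer = 0.084, homodimer = 0.052))
lab <- labeling_spec("homo")             # equimolar saturating two-color Fabs
ds  <- simulate_toccsl_dataset(cfg, pop, lab, n_cells = 30, seed = 42)

counts <- colocalize_dataset(ds)         # 160-nm pairing + mirror FP estimate
print(counts[[1]])
#> Co-localization: 6 pairs (exp. FP 1.00), 20 green-only, 32 red-only, radius 160 nm

rmod <- recovery_model(aperture_width_um = 10, recovery_time_s = 7.5,
                       bleach_duration_s = 0.7)
est <- estimate_homodimer_fraction(counts, lab, D_monomer = 0.084,
                                   D_dimer = 0.052, model = rmod)
print(est)
#> Dimer fraction: 0.264 +/- 0.027 (bootstrap SE, 30 cells)
#>   rho_monomer = 0.0663, rho_dimer = 0.0522, corrected pairs = 94.1

tr  <- simulate_trajectories(sim_config(rng_seed = 1), pop, 1991,
                             species = "monomer")
fit <- fit_diffusion(compute_msd(tr, max_lag = 2))
print(fit)
#> D = 0.0864 +/- 0.0019 um^2/s (sigma_xy = 0.0195 um)
```

Reading the output: of the first cell's TOCCSL frame, 6 green-red pairs
were found of which ~1 is expected by chance; after labeling and
diffusion-recovery corrections the 30-cell dataset yields a molecule-level
homodimer fraction of 26.4 +/- 2.7% against the seeded 23%, and the
monomer cohort's two-point MSD fit returns D = 0.086 +/- 0.002 um^2/s
against the seeded 0.084 (sigma_xy fitted at 19.5 nm vs the simulated
20 nm).

The full pipeline (simulate -> coloc -> corrections -> global fit -> FRAP
-> Kd) runs from one config: `run_pipeline(default_run_config(7))`, or from
the command line `Rscript inst/cli/toccsl.R run config.yaml --out outdir`.

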