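# shared fixtures and independent oracles

# small default acquisition geometry used across tests
tiny_config <- function(...) {
  sim_config(field_width_um = 40, field_height_um = 10,
             aperture_width_um = 10, recovery_time_s = 7.5,
             n_tracking_frames = 0, ...)
}

# brute-force Monte-Carlo oracle for the strip recovery probability:
# uniform walkers on a long 1D segment, instantaneous complete bleach of
# |x| < L/2 at t = 0, free Gaussian displacement over t, count survivors in
# the analysis window |x| < w/2 relative to the pre-bleach expectation.
mc_recovery_probability <- function(D, t, L, w, n_walkers = 1e5,
                                    seed = 1234) {
  set.seed(seed)
  half_span <- L / 2 + 6 * sqrt(4 * D * t) + w
  x0 <- runif(n_walkers, -half_span, half_span)
  live <- abs(x0) >= L / 2
  x1 <- x0[live] + rnorm(sum(live), sd = sqrt(2 * D * t))
  n_in <- sum(abs(x1) < w / 2)
  expected_prebleach <- n_walkers * w / (2 * half_span)
  n_in / expected_prebleach
}

# exhaustive mutual-nearest-neighbor oracle for small point sets
brute_force_mutual_nn_pairs <- function(g, r, radius) {
  ng <- nrow(g); nr <- nrow(r)
  if (ng == 0 || nr == 0) return(0L)
  d <- as.matrix(dist(rbind(as.matrix(g), as.matrix(r))))[seq_len(ng),
                                                          ng + seq_len(nr),
                                                          drop = FALSE]
  n_pairs <- 0L
  for (i in seq_len(ng)) {
    j <- which.min(d[i, ])
    if (which.min(d[, j]) == i && d[i, j] <= radius)
      n_pairs <- n_pairs + 1L
  }
  n_pairs
}

# homo-mode labeling at the default (saturating, equimolar) operating point
default_homo_labeling <- function() labeling_spec("homo")
default_hetero_labeling <- function() labeling_spec("hetero")

# simulate + colocalize + estimate in one call (homo mode)
homo_roundtrip <- function(f_dimer, D_mono, D_dimer, n_cells, seed,
                           n_boot = 300) {
  cfg <- tiny_config()
  lab <- default_homo_labeling()
  pop <- population_spec(density_erbb3_per_um2 = 10, f_homodimer = f_dimer,
                         D = c(monomer = D_mono, homodimer = D_dimer))
  ds <- simulate_toccsl_dataset(cfg, pop, lab, n_cells = n_cells, seed = seed)
  rmod <- recovery_model(cfg$aperture_width_um, cfg$analysis_width_um,
                         cfg$recovery_time_s, cfg$bleach_duration_s)
  estimate_homodimer_fraction(colocalize_dataset(ds), lab, D_mono, D_dimer,
                              rmod, cfg$channel_gap_s,
                              cfg$localization_sigma_um,
                              n_boot = n_boot, seed = 1)
}

hetero_roundtrip <- function(f_het, D_mono, D_het, n_cells, seed,
                             n_boot = 300) {
  cfg <- tiny_config()
  lab <- default_hetero_labeling()
  pop <- population_spec(density_erbb3_per_um2 = 10,
                         density_erbb2_per_um2 = 10,
                         f_heterodimer = f_het,
                         D = c(monomer = D_mono, heterodimer = D_het,
                               erbb2_monomer = 0.044))
  ds <- simulate_toccsl_dataset(cfg, pop, lab, n_cells = n_cells, seed = seed)
  rmod <- recovery_model(cfg$aperture_width_um, cfg$analysis_width_um,
                         cfg$recovery_time_s, cfg$bleach_duration_s)
  estimate_heterodimer_fraction(colocalize_dataset(ds), lab, D_mono, D_het,
                                rmod, cfg$channel_gap_s,
                                cfg$localization_sigma_um,
                                n_boot = n_boot, seed = 1)
}
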