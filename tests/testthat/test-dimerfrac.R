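test_that("competitive labeling probabilities", {
  # c = Kd for a single Fab alone: occupancy one half
  lm1 <- labeling_probabilities(c(5, 0), c(5, 5))
  expect_equal(lm1$p_green, 0.5)
  expect_equal(lm1$p_red, 0)
  # equal saturating concentrations, equal Kd: p ~ 0.5 each
  lm2 <- labeling_probabilities(c(5000, 5000), c(5, 5))
  expect_equal(lm2$p_green, lm2$p_red)
  expect_lt(lm2$u, 0.001)
  # Kd ratio 2 at equal concentration: p ratio 2:1 in the saturating limit
  lm3 <- labeling_probabilities(c(1e6, 1e6), c(5, 10))
  expect_equal(lm3$p_green / lm3$p_red, 2, tolerance = 1e-6)
  # Poisson-dye dark fraction
  lm4 <- labeling_probabilities(c(5000, 5000), c(5, 5),
                                degree_of_labeling = c(1.5, 1.8),
                                dye_dark_model = "poisson")
  expect_lt(lm4$p_green, lm2$p_green)
  expect_equal(lm4$p_green / lm2$p_green, 1 - exp(-1.5), tolerance = 1e-9)
})

make_counts <- function(pairs, green, red, fp = 0, radius = 0.16) {
  cc <- pair_colocalized(data.frame(x_um = numeric(0), y_um = numeric(0)),
                         data.frame(x_um = numeric(0), y_um = numeric(0)),
                         radius)
  cc$n_pairs <- pairs
  cc$n_green_only <- green
  cc$n_red_only <- red
  cc$n_false_positive_expected <- fp
  cc
}

ideal_model <- function() recovery_model(10, 10, 7.5)

test_that("homodimer boundary cases at exact expectations", {
  lab <- list(p_green = 0.5, p_red = 0.5, u = 0)
  m <- ideal_model()
  rho <- recovery_probability(c(0.05, 0.05), m)
  # all dimers: counts at expectation with N_d = 100 entities
  base <- rho[2] * 100
  cc <- make_counts(pairs = base * 0.5, green = base * 0.25,
                    red = base * 0.25)
  est <- estimate_homodimer_fraction(list(cc), lab, 0.05, 0.05, m,
                                     channel_gap_s = 0, sigma_xy_um = 0,
                                     n_boot = 10)
  expect_equal(est$fraction, 1, tolerance = 1e-9)
  # no pairs at all: alpha = 0
  cc0 <- make_counts(0, 40, 40)
  est0 <- estimate_homodimer_fraction(list(cc0), lab, 0.05, 0.05, m,
                                      channel_gap_s = 0, sigma_xy_um = 0,
                                      n_boot = 10)
  expect_equal(est0$fraction, 0)
  expect_error(
    estimate_homodimer_fraction(list(cc0), list(p_green = 0, p_red = 1,
                                                u = 0),
                                0.05, 0.05, m, n_boot = 10),
    "non-identifiable")
})

test_that("heterodimer boundary cases", {
  lab <- list(p_green = 1, p_red = 1)
  m <- ideal_model()
  rho <- recovery_probability(0.05, m)
  cc <- make_counts(pairs = rho * 50, green = 0, red = 0)
  est <- estimate_heterodimer_fraction(list(cc), lab, 0.05, 0.05, m,
                                       channel_gap_s = 0, sigma_xy_um = 0,
                                       n_boot = 10)
  expect_equal(est$fraction, 1, tolerance = 1e-9)
  est0 <- estimate_heterodimer_fraction(list(make_counts(0, 30, 30)), lab,
                                        0.05, 0.05, m, channel_gap_s = 0,
                                        sigma_xy_um = 0, n_boot = 10)
  expect_equal(est0$fraction, 0)
})

test_that("estimator is invariant under channel swap", {
  est <- homo_roundtrip(0.3, 0.08, 0.04, n_cells = 15, seed = 41,
                        n_boot = 50)
  # swap channels: same dataset with green/red labels exchanged
  cfg <- tiny_config()
  lab <- default_homo_labeling()
  pop <- population_spec(density_erbb3_per_um2 = 10, f_homodimer = 0.3,
                         D = c(monomer = 0.08, homodimer = 0.04))
  ds <- simulate_toccsl_dataset(cfg, pop, lab, n_cells = 15, seed = 41)
  for (i in seq_along(ds$cells)) {
    ch <- ds$cells[[i]]$toccsl$channel
    ds$cells[[i]]$toccsl$channel <-
      ifelse(ch == "green", "red", "green")
  }
  rmod <- recovery_model(10, 10, 7.5, 0.7)
  est_sw <- estimate_homodimer_fraction(
    colocalize_dataset(ds),
    list(p_green = lab$p_red, p_red = lab$p_green, u = lab$u_erbb3),
    0.08, 0.04, rmod, n_boot = 50)
  expect_equal(est_sw$fraction, est$fraction, tolerance = 1e-9)
})

test_that("ignoring the diffusion correction underestimates the dimer
           fraction of slow dimers", {
  cfg <- tiny_config()
  lab <- default_homo_labeling()
  pop <- population_spec(density_erbb3_per_um2 = 10, f_homodimer = 0.5,
                         D = c(monomer = 0.084, homodimer = 0.015))
  ds <- simulate_toccsl_dataset(cfg, pop, lab, n_cells = 25, seed = 42)
  cc <- colocalize_dataset(ds)
  rmod <- recovery_model(10, 10, 7.5, 0.7)
  corrected <- estimate_homodimer_fraction(cc, lab, 0.084, 0.015, rmod,
                                           n_boot = 50)
  # rho_m = rho_d: pretend both species diffuse like the monomer
  uncorrected <- estimate_homodimer_fraction(cc, lab, 0.084, 0.084, rmod,
                                             n_boot = 50)
  expect_lt(uncorrected$fraction, corrected$fraction)
  expect_lt(uncorrected$fraction, 0.5)
})

test_that("round-trip recovery without systematic bias at three seeded
           fractions", {
  for (f in c(0.1, 0.5, 0.9)) {
    est <- homo_roundtrip(f, 0.084, 0.052, n_cells = 30,
                          seed = 100 + round(100 * f), n_boot = 200)
    expect_lt(abs(est$fraction - f), 3 * est$se)
  }
})
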