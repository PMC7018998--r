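sim_pair_of_experiments <- function(f_homo, f_het, D, n_cells, seed) {
  cfg <- tiny_config()
  pop <- population_spec(density_erbb3_per_um2 = 10,
                         density_erbb2_per_um2 = 10,
                         f_homodimer = f_homo, f_heterodimer = f_het, D = D)
  lab <- default_homo_labeling()
  labh <- default_hetero_labeling()
  ds_h <- simulate_toccsl_dataset(cfg, pop, lab, n_cells = n_cells,
                                  seed = seed)
  ds_x <- simulate_toccsl_dataset(cfg, pop, labh, n_cells = n_cells,
                                  seed = seed + 1)
  list(homo = colocalize_dataset(ds_h), hetero = colocalize_dataset(ds_x),
       lab = lab, labh = labh,
       rmod = recovery_model(10, 10, 7.5, 0.7))
}

test_that("global fit agrees with the homodimer-only estimator when
           beta = 0", {
  D <- c(monomer = 0.084, homodimer = 0.052, heterodimer = 0.017,
         erbb2_monomer = 0.044)
  ex <- sim_pair_of_experiments(0.4, 0, D, n_cells = 30, seed = 201)
  gl <- fit_global(ex$homo, ex$hetero, ex$lab, ex$labh, D, ex$rmod,
                   n_boot = 40, seed = 1)
  alone <- estimate_homodimer_fraction(ex$homo, ex$lab, D[["monomer"]],
                                       D[["homodimer"]], ex$rmod,
                                       n_boot = 100)
  expect_lt(abs(gl$alpha - alone$fraction),
            2 * sqrt(gl$se[["alpha"]]^2 + alone$se^2) + 0.02)
  expect_lt(gl$beta, 0.08)
})

test_that("simplex constraint holds exactly and mixed composition is
           recovered", {
  D <- c(monomer = 0.056, homodimer = 0.018, heterodimer = 0.010,
         erbb2_monomer = 0.034)
  ex <- sim_pair_of_experiments(0.4, 0.4, D, n_cells = 30, seed = 203)
  gl <- fit_global(ex$homo, ex$hetero, ex$lab, ex$labh, D, ex$rmod,
                   n_boot = 40, seed = 1)
  expect_equal(gl$mu + gl$alpha + gl$beta, 1, tolerance = 1e-9)
  expect_lt(abs(gl$alpha - 0.4), 3 * gl$se[["alpha"]] + 0.02)
  expect_lt(abs(gl$beta - 0.4), 3 * gl$se[["beta"]] + 0.02)
})

test_that("degenerate labeling raises a diagnostic and all-zero counts
           error", {
  D <- c(monomer = 0.08, homodimer = 0.05, heterodimer = 0.02,
         erbb2_monomer = 0.04)
  ex <- sim_pair_of_experiments(0.2, 0.2, D, n_cells = 4, seed = 205)
  bad <- list(p_green = 0, p_red = 0.5, u = 0.5)
  expect_error(fit_global(ex$homo, ex$hetero, bad, ex$labh, D, ex$rmod),
               "degenerate")
  empty <- lapply(ex$homo, function(cc) {
    cc$n_pairs <- 0L; cc$n_green_only <- 0L; cc$n_red_only <- 0L
    cc$n_false_positive_expected <- 0; cc
  })
  expect_error(fit_global(empty, empty, ex$lab, ex$labh, D, ex$rmod),
               "zero")
})

test_that("competition signature: more seeded heterodimer lowers fitted
           homodimer at fixed total dimerization", {
  D <- c(monomer = 0.056, homodimer = 0.018, heterodimer = 0.010,
         erbb2_monomer = 0.034)
  ex1 <- sim_pair_of_experiments(0.6, 0.1, D, n_cells = 25, seed = 207)
  ex2 <- sim_pair_of_experiments(0.2, 0.5, D, n_cells = 25, seed = 209)
  g1 <- fit_global(ex1$homo, ex1$hetero, ex1$lab, ex1$labh, D, ex1$rmod,
                   n_boot = 30, seed = 1)
  g2 <- fit_global(ex2$homo, ex2$hetero, ex2$lab, ex2$labh, D, ex2$rmod,
                   n_boot = 30, seed = 1)
  expect_gt(g1$alpha, g2$alpha)
  expect_lt(g1$beta, g2$beta)
})
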