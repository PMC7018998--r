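test_that("frozen particle: D = 0 and no noise keeps positions identical", {
  cfg <- tiny_config(localization_sigma_um = 0, n_frames = 8, rng_seed = 1)
  pop <- population_spec(D = c(monomer = 0))
  tr <- simulate_trajectories(cfg, pop, 5, species = "monomer")
  for (id in unique(tr$trajectories$trajectory_id)) {
    sub <- tr$trajectories[tr$trajectories$trajectory_id == id, ]
    expect_equal(var(sub$x_um), 0)
    expect_equal(var(sub$y_um), 0)
  }
})

test_that("per-axis step variance matches 2 D dt (Table-style D)", {
  # 1e5 displacement steps at D = 0.084, dt = 0.01 s
  cfg <- tiny_config(localization_sigma_um = 0, frame_interval_s = 0.01,
                     n_frames = 101, rng_seed = 2)
  pop <- population_spec(D = c(monomer = 0.084))
  tr <- simulate_trajectories(cfg, pop, 1000, species = "monomer")
  df <- tr$trajectories
  dx <- diff(df$x_um)[diff(df$trajectory_id) == 0]
  n <- length(dx)
  expect_gte(n, 9e4)
  v <- var(dx)
  expected <- 2 * 0.084 * 0.01
  se <- expected * sqrt(2 / n)
  expect_lt(abs(v - expected), 3 * se)
})

test_that("lag-1 msd of noisy trajectories equals 4 D dt + 4 sigma^2", {
  cfg <- tiny_config(localization_sigma_um = 0.02, frame_interval_s = 0.01,
                     n_frames = 20, rng_seed = 3)
  pop <- population_spec(D = c(monomer = 0.1))
  tr <- simulate_trajectories(cfg, pop, 2000, species = "monomer")
  m <- compute_msd(tr, max_lag = 2)
  expected <- 4 * 0.1 * 0.01 + 4 * 0.02^2
  se <- m$sd_sq_disp[1] / sqrt(m$n[1])
  expect_lt(abs(m$msd[1] - expected), 3 * se)
})

test_that("invalid parameters are rejected", {
  cfg <- tiny_config()
  pop <- population_spec()
  expect_error(simulate_trajectories(cfg, pop, 0), "> 0")
  expect_error(simulate_trajectories(cfg, pop, 3, species = "unknown"),
               "unknown")
})

test_that("fixed seed gives bit-identical trajectory output", {
  cfg <- tiny_config(rng_seed = 99)
  pop <- population_spec()
  a <- simulate_trajectories(cfg, pop, 20)
  b <- simulate_trajectories(cfg, pop, 20)
  expect_identical(a, b)
})

test_that("bead field: identity transform with zero noise is exact", {
  bf <- simulate_bead_field(10, c(0, 0), c(1, 1), noise_nm = 0, seed = 4)
  expect_equal(bf$green, bf$red)
})

test_that("brightness samples scale with oligomer size", {
  m1 <- simulate_brightness_sample(c(1), 4000, monomer_mean = 100, seed = 5)
  m2 <- simulate_brightness_sample(c(0, 1), 4000, monomer_mean = 100,
                                   seed = 6)
  expect_lt(abs(mean(m1) - 100), 2)
  expect_lt(abs(mean(m2) - 200), 3)
  expect_error(simulate_brightness_sample(c(0.5, 0.4), 10), "sum to 1")
})
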