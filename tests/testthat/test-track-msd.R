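test_that("linking: single slow particle yields one full trajectory", {
  set.seed(31)
  locs <- data.frame(frame = 0:9, x_um = 5 + cumsum(rnorm(10, 0, 0.02)),
                     y_um = 5 + cumsum(rnorm(10, 0, 0.02)))
  tr <- link_trajectories(locs, max_disp_um = 0.3, frame_interval_s = 0.01)
  expect_equal(length(unique(tr$trajectory_id)), 1)
  expect_equal(nrow(tr), 10)
})

test_that("linking: well-separated particles stay separate", {
  locs <- data.frame(frame = rep(0:4, each = 2),
                     x_um = rep(c(1, 8), 5), y_um = rep(c(1, 8), 5))
  tr <- link_trajectories(locs, max_disp_um = 0.5, frame_interval_s = 0.01)
  expect_equal(length(unique(tr$trajectory_id)), 2)
})

test_that("linking recovers >= 95% of ground-truth links at TOCCSL density", {
  cfg <- sim_config(field_width_um = 20, field_height_um = 20,
                    frame_interval_s = 0.01, n_frames = 10,
                    localization_sigma_um = 0.02, rng_seed = 32)
  pop <- population_spec(D = c(monomer = 0.084))
  n_part <- 20  # 0.05 per um^2 on 20x20
  tr <- simulate_trajectories(cfg, pop, n_part, species = "monomer")
  locs <- tr$trajectories[, c("frame", "x_um", "y_um", "trajectory_id")]
  names(locs)[4] <- "true_id"
  linked <- link_trajectories(locs, frame_interval_s = 0.01)
  # a link is correct when consecutive members share the true id
  ok <- 0; total <- 0
  for (id in unique(linked$trajectory_id)) {
    sub <- linked[linked$trajectory_id == id, ]
    if (nrow(sub) < 2) next
    total <- total + nrow(sub) - 1
    ok <- ok + sum(sub$true_id[-1] == sub$true_id[-nrow(sub)])
  }
  expect_gte(ok / total, 0.95)
})

test_that("msd of deterministic straight-line motion is exact", {
  L <- 0.05
  df <- data.frame(trajectory_id = 1, frame = 0:9,
                   x_um = (0:9) * L, y_um = 0)
  m <- compute_msd(df, max_lag = 4, frame_interval_s = 0.01)
  expect_equal(m$msd, ((1:4) * L)^2)
  # two-point trajectory: one lag only
  m1 <- compute_msd(df[1:2, ], max_lag = 5, frame_interval_s = 0.01)
  expect_equal(nrow(m1), 1)
})

test_that("two-point diffusion fit is exact algebra", {
  mk <- function(msd) structure(
    data.frame(lag = 1:2, t_lag_s = c(0.01, 0.02), msd = msd,
               sd_sq_disp = c(1e-4, 1e-4), n = c(100, 99)),
    class = c("toccsl_msd", "data.frame"))
  f <- fit_diffusion(mk(c(0.004, 0.008)))
  expect_equal(f$D, 0.1)
  expect_equal(f$sigma_xy, 0)
  f2 <- fit_diffusion(mk(c(0.0056, 0.0096)))
  expect_equal(f2$D, 0.1)
  expect_equal(f2$sigma_xy, 0.02)
  # negative intercept is reported and flagged
  f3 <- fit_diffusion(mk(c(0.003, 0.008)))
  expect_true(f3$intercept_negative)
  expect_true(is.na(f3$sigma_xy))
  expect_error(fit_diffusion(mk(c(0.004, 0.008))[1, ]), "two")
})

test_that("resampling error is reproducible and converges", {
  cfg <- tiny_config(rng_seed = 33, n_frames = 10)
  pop <- population_spec(D = c(monomer = 0.05))
  tr <- simulate_trajectories(cfg, pop, 300, species = "monomer")
  m <- compute_msd(tr, max_lag = 2)
  f1 <- fit_diffusion(m, seed = 1)
  f1b <- fit_diffusion(m, seed = 1)
  expect_identical(f1$sd_D, f1b$sd_D)
  f2 <- fit_diffusion(m, seed = 2)
  expect_lt(abs(f1$sd_D - f2$sd_D) / f1$sd_D, 0.05)
  # raw-SD mode gives a larger error than the SE mode
  f_sd <- fit_diffusion(m, resample_sd = "sd")
  expect_gt(f_sd$sd_D, f1$sd_D)
})

test_that("diffusion ratio and its error propagation", {
  a <- list(D = 0.044, sd_D = 0.003)
  b <- list(D = 0.067, sd_D = 0.006)
  r <- diffusion_ratio(a, b)
  expect_equal(r$ratio, 0.044 / 0.067, tolerance = 1e-12)
  expect_equal(r$se,
               r$ratio * sqrt((0.003 / 0.044)^2 + (0.006 / 0.067)^2))
  expect_equal(diffusion_ratio(a, a)$ratio, 1)
  expect_error(diffusion_ratio(a, list(D = 0, sd_D = 1)), "zero")
})

test_that("simulated 1991-trajectory cohort recovers D within the printed
           SD band", {
  cfg <- tiny_config(frame_interval_s = 0.01, n_frames = 10,
                     localization_sigma_um = 0.02, rng_seed = 34)
  pop <- population_spec(D = c(monomer = 0.084))
  tr <- simulate_trajectories(cfg, pop, 1991, species = "monomer")
  f <- fit_diffusion(compute_msd(tr, max_lag = 2), seed = 1)
  expect_lt(abs(f$D - 0.084), 0.005)
  expect_lt(abs(f$D - 0.084), 3 * f$sd_D)
})
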