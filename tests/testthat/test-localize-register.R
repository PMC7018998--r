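test_that("single emitter at SNR ~ 20 is localized within 20 nm", {
  em <- data.frame(frame = 0L, x_um = 5.0, y_um = 5.0, photons = 1000)
  errs <- vapply(1:5, function(s) {
    st <- render_frames(em, camera_params(), seed = 80 + s)
    loc <- detect_and_localize(st)
    expect_equal(nrow(loc), 1)
    sqrt((loc$x_um - 5)^2 + (loc$y_um - 5)^2)
  }, numeric(1))
  expect_lt(median(errs), 0.020)
})

test_that("empty frames produce no localizations", {
  st <- render_frames(data.frame(frame = integer(0), x_um = numeric(0),
                                 y_um = numeric(0)),
                      camera_params(), n_frames = 2, seed = 81)
  expect_equal(nrow(detect_and_localize(st)), 0)
})

test_that("two emitters 1 um apart are not merged", {
  em <- data.frame(frame = 0L, x_um = c(4.5, 5.5), y_um = 5, photons = 800)
  st <- render_frames(em, camera_params(), seed = 82)
  loc <- detect_and_localize(st)
  expect_equal(nrow(loc), 2)
})

test_that("overly dense frames are rejected with a density diagnostic", {
  set.seed(83)
  em <- data.frame(frame = 0L, x_um = runif(300, 1, 9),
                   y_um = runif(300, 1, 9), photons = 800)
  st <- render_frames(em, camera_params(), seed = 83)
  expect_error(detect_and_localize(st), "density")
})

test_that("localization error shrinks roughly as 1/sqrt(photons)", {
  em <- function(N) data.frame(frame = 0L, x_um = 5, y_um = 5, photons = N)
  err_at <- function(N) {
    e <- vapply(1:8, function(s) {
      st <- render_frames(em(N), camera_params(), seed = 840 + s)
      loc <- detect_and_localize(st)
      if (nrow(loc) == 0) return(NA_real_)
      sqrt((loc$x_um[1] - 5)^2 + (loc$y_um[1] - 5)^2)
    }, numeric(1))
    mean(e, na.rm = TRUE)
  }
  e_low <- err_at(200)
  e_high <- err_at(3200)
  expect_gt(e_low / e_high, 1.8)  # ideal factor 4, allow noise margin
})

test_that("noiseless synthetic beads give exact affine recovery", {
  bf <- simulate_bead_field(30, c(0.05, -0.02), c(1.004, 0.998),
                            noise_nm = 0, seed = 85)
  map <- estimate_registration(bf$green, bf$red)
  expect_lt(map$residual_rms_nm, 1e-3)  # < 1e-6 um
  expect_equal(map$dx_um, 0.05, tolerance = 1e-9)
  expect_equal(map$sx, 1.004, tolerance = 1e-12)
})

test_that("registration round trip at realistic noise", {
  bf <- simulate_bead_field(50, c(0.2, -0.1), c(1.003, 1.0), noise_nm = 1,
                            seed = 86)
  map <- estimate_registration(bf$green, bf$red)
  expect_lt(abs(map$dx_um - 0.2), 0.005)
  expect_lt(abs(map$dy_um + 0.1), 0.005)
  expect_lt(abs(map$sx - 1.003), 2e-4)
  expect_lt(map$residual_rms_nm, 20)
  corr <- apply_registration(bf$red, map)
  resid <- sqrt((corr$x_um - bf$green$x_um)^2 +
                  (corr$y_um - bf$green$y_um)^2)
  expect_lt(median(resid) * 1000, 20)
})

test_that("apply then invert registration is the identity", {
  map <- structure(list(dx_um = 0.1, dy_um = -0.05, sx = 1.002, sy = 0.999,
                        residual_rms_nm = 0, n_beads = 10),
                   class = "toccsl_regmap")
  locs <- data.frame(x_um = c(1, 5, 9), y_um = c(2, 4, 8))
  back <- apply_registration(apply_registration(locs, map, "green_to_red"),
                             map, "red_to_green")
  expect_equal(back$x_um, locs$x_um, tolerance = 1e-9)
  expect_equal(back$y_um, locs$y_um, tolerance = 1e-9)
  expect_error(estimate_registration(locs[1:2, ], locs[1:2, ]), "3")
})

test_that("surface density estimation in both modes", {
  locs <- data.frame(x_um = runif(100, 0, 10), y_um = runif(100, 0, 10))
  expect_equal(as.numeric(estimate_surface_density(locs, 100)), 1.0)
  # intensity mode: k-times brighter field gives k-times density
  expect_equal(as.numeric(
    estimate_surface_density(rep(300, 50), 100, method = "intensity",
                             mean_single_intensity = 100)),
    3 * as.numeric(
      estimate_surface_density(rep(100, 50), 100, method = "intensity",
                               mean_single_intensity = 100)))
  expect_error(estimate_surface_density(locs, 0), "> 0")
})

test_that("synthetic dataset density is recovered within 10%", {
  cfg <- tiny_config()
  pop <- population_spec(density_erbb3_per_um2 = 10)
  lab <- default_homo_labeling()
  ds <- simulate_toccsl_dataset(cfg, pop, lab, n_cells = 10, seed = 87)
  dens <- mean(vapply(ds$cells, function(cl)
    cl$prebleach_density$erbb3_molecules, numeric(1)))
  expect_lt(abs(dens - 10) / 10, 0.1)
})
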