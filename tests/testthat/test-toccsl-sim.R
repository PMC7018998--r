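test_that("postbleach check frame is empty inside the aperture interior", {
  cfg <- tiny_config()
  pop <- population_spec(f_homodimer = 0.2)
  lab <- default_homo_labeling()
  ds <- simulate_toccsl_dataset(cfg, pop, lab, n_cells = 5, seed = 10)
  cx <- cfg$field_width_um / 2
  # interior excludes a thin re-entry rim (~3 sd of 10 ms diffusion)
  rim <- 3 * sqrt(4 * 0.084 * 0.01)
  for (cl in ds$cells) {
    chk <- cl$postbleach_check
    expect_equal(sum(abs(chk$x_um - cx) < cfg$aperture_width_um / 2 - rim), 0)
  }
})

test_that("single-color monomers give green-only TOCCSL frames", {
  cfg <- tiny_config()
  pop <- population_spec()
  lab <- labeling_spec("homo", fab_conc_red_nM = 0)
  expect_equal(lab$p_red, 0)
  ds <- simulate_toccsl_dataset(cfg, pop, lab, n_cells = 3, seed = 11)
  for (cl in ds$cells)
    expect_equal(sum(cl$toccsl$channel == "red"), 0)
})

test_that("binomial labeling of pure homodimers yields the expected
           two-color entity fraction", {
  # p_g = p_r = 0.5, u = 0: among labeled dimers, P(two-color) =
  # 2 p_g p_r / (1 - u^2) = 0.5
  cfg <- tiny_config()
  pop <- population_spec(f_homodimer = 1,
                         D = c(monomer = 0.084, homodimer = 0.084))
  lab <- list(mode = "homo", p_green = 0.5, p_red = 0.5, u_erbb3 = 0)
  class(lab) <- "toccsl_labeling"
  ds <- simulate_toccsl_dataset(cfg, pop, lab, n_cells = 10, seed = 12)
  two_color <- 0; labeled <- 0
  for (gt in ds$ground_truth$entities) {
    lb <- gt$n_green + gt$n_red > 0
    two_color <- two_color + sum(gt$n_green > 0 & gt$n_red > 0)
    labeled <- labeled + sum(lb)
  }
  frac <- two_color / labeled
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / labeled))
})

test_that("dimer protomers share positions before localization noise", {
  cfg <- tiny_config(localization_sigma_um = 0, channel_gap_s = 0)
  pop <- population_spec(f_homodimer = 1,
                         D = c(homodimer = 0.05, monomer = 0.08))
  lab <- list(mode = "homo", p_green = 0.5, p_red = 0.5, u_erbb3 = 0)
  class(lab) <- "toccsl_labeling"
  ds <- simulate_toccsl_dataset(cfg, pop, lab, n_cells = 2, seed = 13)
  for (cl in ds$cells) {
    tc <- cl$toccsl
    both <- names(which(table(tc$entity_id) == 2))
    for (id in both) {
      sub <- tc[tc$entity_id == id, ]
      expect_equal(sub$x_um[1], sub$x_um[2])
      expect_equal(sub$y_um[1], sub$y_um[2])
    }
  }
})

test_that("aperture larger than field errors; fixed seed reproduces", {
  cfg <- tiny_config()
  pop <- population_spec()
  lab <- default_homo_labeling()
  bad <- cfg
  bad$aperture_width_um <- 100
  expect_error(simulate_toccsl_dataset(bad, pop, lab, 1), "aperture")
  a <- simulate_toccsl_dataset(cfg, pop, lab, n_cells = 2, seed = 14)
  b <- simulate_toccsl_dataset(cfg, pop, lab, n_cells = 2, seed = 14)
  expect_identical(a$cells, b$cells)
})

test_that("asymmetric labeling drives the green:red count ratio", {
  cfg <- tiny_config()
  pop <- population_spec()
  lab <- list(mode = "homo", p_green = 0.7, p_red = 0.2, u_erbb3 = 0.1)
  class(lab) <- "toccsl_labeling"
  ds <- simulate_toccsl_dataset(cfg, pop, lab, n_cells = 20, seed = 15)
  ng <- sum(vapply(ds$cells, function(cl)
    sum(cl$toccsl$channel == "green"), numeric(1)))
  nr <- sum(vapply(ds$cells, function(cl)
    sum(cl$toccsl$channel == "red"), numeric(1)))
  expect_lt(abs(ng / nr - 0.7 / 0.2), 0.5)
})

test_that("localization CSV schema round-trips", {
  cfg <- tiny_config()
  ds <- simulate_toccsl_dataset(cfg, population_spec(),
                                default_homo_labeling(), n_cells = 1,
                                seed = 16)
  dir <- tempfile()
  paths <- write_toccsl_csv(ds, dir, ground_truth = TRUE)
  df <- read.csv(file.path(dir, "cell001_toccsl.csv"))
  expect_true(all(c("cell_id", "frame", "channel", "x_um", "y_um",
                    "intensity", "sigma_xy_um", "entity_id", "species") %in%
                    names(df)))
  df2 <- read.csv(write_toccsl_csv(ds, tempfile())[1])
  expect_false("entity_id" %in% names(df2))
})
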