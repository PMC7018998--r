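loc <- function(x, y) data.frame(x_um = x, y_um = y)

test_that("pairing basics: coincident, out-of-radius, empty", {
  cc <- pair_colocalized(loc(1, 1), loc(1, 1))
  expect_equal(cc$n_pairs, 1)
  expect_equal(cc$pair_distances_um, 0)
  expect_equal(pair_colocalized(loc(1, 1), loc(1.2, 1))$n_pairs, 0)
  cc0 <- pair_colocalized(loc(numeric(0), numeric(0)), loc(1, 1))
  expect_equal(cc0$n_pairs, 0)
  expect_equal(cc0$n_red_only, 1)
})

test_that("two greens flanking one red: nearest wins, one single left", {
  g <- loc(c(0.90, 1.11), c(1, 1))
  r <- loc(1, 1)
  cc <- pair_colocalized(g, r)
  expect_equal(cc$n_pairs, 1)
  expect_equal(cc$n_green_only, 1)
  # the closer green (index 2, 110 nm... index 1 at 100 nm) wins
  expect_equal(unname(cc$pairs[1, "green"]), 1L)
})

test_that("mutual-NN pairing matches the brute-force oracle", {
  set.seed(21)
  for (rep in 1:20) {
    g <- loc(runif(8, 0, 2), runif(8, 0, 2))
    r <- loc(runif(8, 0, 2), runif(8, 0, 2))
    expect_equal(pair_colocalized(g, r, 0.3)$n_pairs,
                 brute_force_mutual_nn_pairs(g, r, 0.3))
  }
})

test_that("pairing is symmetric under channel swap", {
  set.seed(22)
  g <- loc(runif(30, 0, 5), runif(30, 0, 5))
  r <- loc(runif(25, 0, 5), runif(25, 0, 5))
  a <- pair_colocalized(g, r)
  b <- pair_colocalized(r, g)
  expect_equal(a$n_pairs, b$n_pairs)
  expect_equal(sort(a$pair_distances_um), sort(b$pair_distances_um))
  expect_equal(a$n_green_only, b$n_red_only)
})

test_that("independent channels: direct count and mirror estimate match
           the analytic expectation", {
  set.seed(23)
  A <- 20 * 20; r <- 0.16; n <- 40  # density 0.1 per um^2
  reps <- 150
  direct <- mirror <- numeric(reps)
  for (k in seq_len(reps)) {
    g <- loc(runif(n, 0, 20), runif(n, 0, 20))
    rd <- loc(runif(n, 0, 20), runif(n, 0, 20))
    direct[k] <- pair_colocalized(g, rd, r)$n_pairs
    mirror[k] <- estimate_false_positives(g, rd, r, center = c(10, 10))
  }
  expected <- n * n * pi * r^2 / A
  expect_lt(abs(mean(direct) - expected), 3 * sd(direct) / sqrt(reps))
  expect_lt(abs(mean(mirror) - expected), 3 * sd(mirror) / sqrt(reps))
})

test_that("mirroring destroys true pairs", {
  set.seed(24)
  x <- runif(40, 0, 20); y <- runif(40, 0, 20)
  g <- loc(x, y)
  r <- loc(x + rnorm(40, 0, 0.02), y + rnorm(40, 0, 0.02))
  cc <- pair_colocalized(g, r)
  fp <- estimate_false_positives(g, r)
  expect_gt(cc$n_pairs, 35)
  expect_lt(fp, cc$n_pairs / 4)
})

test_that("reflection fixed point is counted and flagged", {
  g <- loc(1, 1)
  r <- loc(1, 1)  # joint COM = (1,1): reflections leave red in place
  expect_warning(fp <- estimate_false_positives(g, r), "mirror axis")
  expect_equal(as.numeric(fp), 1)
  expect_equal(attr(fp, "n_fixed_points"), 2L)
})

test_that("corrected pair count subtracts and clips with warning", {
  cc <- pair_colocalized(loc(1, 1), loc(1, 1))
  cc$n_false_positive_expected <- 2.3
  expect_warning(v <- corrected_pair_count(cc), "clipped")
  expect_equal(v, 0)
  cc$n_pairs <- 10L
  cc$n_false_positive_expected <- 2.3
  expect_equal(corrected_pair_count(cc), 7.7)
  cc$n_false_positive_expected <- NA_real_
  expect_error(corrected_pair_count(cc), "missing")
})
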