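#' Simulate 2D Brownian trajectories with localization noise
#'
#' Generates free 2D Brownian trajectories for the species mixture in
#' `population`: per-axis displacements between consecutive frames are
#' Normal(0, 2 D dt), and independent Gaussian localization noise of sd
#' sigma_xy is added to every coordinate. Species are assigned to
#' trajectories by multinomial sampling of the entity fractions. If
#' `species` is given, all trajectories belong to that one species.
#'
#' @param config a [sim_config()]; uses `frame_interval_s`, `n_frames`,
#'   `localization_sigma_um` and the field extent (starting positions only;
#'   motion is unbounded).
#' @param population a [population_spec()].
#' @param n_trajectories number of trajectories (> 0).
#' @param species optional single species name to simulate exclusively.
#' @return object of class `toccsl_trajectories`: list with `trajectories`
#'   (data.frame: trajectory_id, species, frame, x_um, y_um, x_true, y_true)
#'   and `ground_truth` (data.frame: trajectory_id, species, D).
#' @export
simulate_trajectories <- function(config, population, n_trajectories,
                                  species = NULL) {
  stopifnot(inherits(config, "toccsl_config"),
            inherits(population, "toccsl_population"))
  if (!is.numeric(n_trajectories) || n_trajectories < 1)
    stop("simulate_trajectories: n_trajectories must be > 0")
  n_trajectories <- as.integer(n_trajectories)
  dt <- config$frame_interval_s
  if (dt <= 0) stop("simulate_trajectories: frame interval must be > 0")
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)

  sp <- population$species
  if (!is.null(species)) {
    if (!species %in% sp$species)
      stop("simulate_trajectories: unknown species '", species, "'")
    idx <- rep(match(species, sp$species), n_trajectories)
  } else {
    w <- sp$entity_density
    if (sum(w) <= 0) stop("simulate_trajectories: empty population")
    idx <- sample.int(nrow(sp), n_trajectories, replace = TRUE,
                      prob = w / sum(w))
  }
  D <- sp$D[idx]
  if (any(D < 0)) stop("simulate_trajectories: invalid D < 0")
  nf <- config$n_frames
  sig <- config$localization_sigma_um

  # vectorized over all trajectories: cumulative sums of per-step jumps
  step_sd <- sqrt(2 * D * dt)                      # per axis
  x0 <- runif(n_trajectories, 0, config$field_width_um)
  y0 <- runif(n_trajectories, 0, config$field_height_um)
  jump <- function() matrix(rnorm((nf - 1L) * n_trajectories), nf - 1L,
                            n_trajectories) * matrix(step_sd, nf - 1L,
                                                     n_trajectories,
                                                     byrow = TRUE)
  # true position matrices (frames x trajectories)
  x_true <- matrix(0, nf, n_trajectories)
  y_true <- matrix(0, nf, n_trajectories)
  x_true[1L, ] <- x0; y_true[1L, ] <- y0
  if (nf > 1L) {
    cs <- function(m) if (nrow(m) == 1L) m else apply(m, 2, cumsum)
    x_true[-1L, ] <- matrix(x0, nf - 1L, n_trajectories, byrow = TRUE) + cs(jump())
    y_true[-1L, ] <- matrix(y0, nf - 1L, n_trajectories, byrow = TRUE) + cs(jump())
  }
  x_obs <- x_true + rnorm(length(x_true), sd = sig)
  y_obs <- y_true + rnorm(length(y_true), sd = sig)

  traj <- data.frame(
    trajectory_id = rep(seq_len(n_trajectories), each = nf),
    species = rep(sp$species[idx], each = nf),
    frame = rep(seq_len(nf) - 1L, times = n_trajectories),
    x_um = as.vector(x_obs), y_um = as.vector(y_obs),
    x_true = as.vector(x_true), y_true = as.vector(y_true),
    stringsAsFactors = FALSE)
  gt <- data.frame(trajectory_id = seq_len(n_trajectories),
                   species = sp$species[idx], D = D,
                   stringsAsFactors = FALSE)
  structure(list(trajectories = traj, ground_truth = gt,
                 frame_interval_s = dt,
                 localization_sigma_um = sig),
            class = "toccsl_trajectories")
}

#' Simulate a two-channel bead calibration field
#'
#' Multicolor beads immobilized on a coverslip, imaged in both channels. Red
#' positions are an axis-aligned affine image of the green positions
#' (stretch about the field origin plus shift) with Gaussian localization
#' noise added independently per channel.
#'
#' @param n_beads number of beads.
#' @param true_shift_um length-2 shift (dx, dy) in um.
#' @param true_stretch length-2 stretch (sx, sy).
#' @param noise_nm localization noise sd per axis and channel, in nm.
#' @param field_um length-2 field extent in um.
#' @param seed optional integer seed.
#' @return list with `green` and `red` localization data.frames and `truth`.
#' @export
simulate_bead_field <- function(n_beads, true_shift_um = c(0, 0),
                                true_stretch = c(1, 1), noise_nm = 1,
                                field_um = c(40, 40), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_beads < 1) stop("simulate_bead_field: n_beads must be >= 1")
  x <- runif(n_beads, 0.05 * field_um[1], 0.95 * field_um[1])
  y <- runif(n_beads, 0.05 * field_um[2], 0.95 * field_um[2])
  s <- noise_nm / 1000
  green <- data.frame(x_um = x + rnorm(n_beads, sd = s),
                      y_um = y + rnorm(n_beads, sd = s))
  red <- data.frame(
    x_um = true_stretch[1] * x + true_shift_um[1] + rnorm(n_beads, sd = s),
    y_um = true_stretch[2] * y + true_shift_um[2] + rnorm(n_beads, sd = s))
  list(green = green, red = red,
       truth = list(shift_um = true_shift_um, stretch = true_stretch,
                    noise_nm = noise_nm))
}

#' Simulate single-molecule brightness values for a k-mer mixture
#'
#' The brightness of a k-mer is the sum of k independent draws from the
#' monomer brightness distribution (lognormal by default), reflecting k
#' independently labeled protomers.
#'
#' @param fractions numeric vector of mixture weights for k = 1..K (summing
#'   to 1).
#' @param n sample size.
#' @param monomer_mean mean monomer brightness (arbitrary units).
#' @param monomer_cv coefficient of variation of monomer brightness.
#' @param seed optional seed.
#' @return numeric brightness vector with attribute `true_k` (integer
#'   oligomer size per draw).
#' @export
simulate_brightness_sample <- function(fractions, n, monomer_mean = 100,
                                       monomer_cv = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9)
    stop("simulate_brightness_sample: fractions must be non-negative and sum to 1")
  K <- length(fractions)
  k <- sample.int(K, n, replace = TRUE, prob = fractions)
  sdlog <- sqrt(log(1 + monomer_cv^2))
  meanlog <- log(monomer_mean) - sdlog^2 / 2
  vals <- vapply(k, function(ki) sum(rlnorm(ki, meanlog, sdlog)), numeric(1))
  attr(vals, "true_k") <- k
  vals
}
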