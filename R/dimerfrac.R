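# Method-of-moments inversion of TOCCSL co-localization counts into
# molecule-level dimer fractions, with labeling-stoichiometry and
# diffusion-recovery corrections and cell-level bootstrap errors.

# probability that a true pair is found within the pairing radius, given the
# inter-channel time gap and per-channel localization noise: the green-red
# distance^2 of one entity is exponential with per-axis variance
# 2 D gap + 2 sigma^2.
pair_detection_probability <- function(D, radius_um, channel_gap_s,
                                       sigma_xy_um) {
  s2 <- 2 * D * channel_gap_s + 2 * sigma_xy_um^2
  if (s2 <= 0) return(1)
  1 - exp(-radius_um^2 / (2 * s2))
}

sum_counts <- function(counts_by_cell) {
  # The mirrored configuration destroys true pairs, so every spot is free to
  # form an accidental pair there; in the real configuration only spots not
  # bound in true pairs are. The mirror estimate is therefore deflated by
  # the availability ratio (singles + accidentals) / all spots per channel.
  # Aggregation over cells is unclipped (per-cell clipping would bias the
  # dimer-free null upward); only the aggregate is floored at 0.
  fp <- vapply(counts_by_cell, `[[`, numeric(1), "n_false_positive_expected")
  fp[is.na(fp)] <- 0
  fp <- sum(fp)
  p_raw <- sum(vapply(counts_by_cell, `[[`, numeric(1), "n_pairs"))
  g_only <- sum(vapply(counts_by_cell, `[[`, numeric(1), "n_green_only"))
  r_only <- sum(vapply(counts_by_cell, `[[`, numeric(1), "n_red_only"))
  g_tot <- g_only + p_raw
  r_tot <- r_only + p_raw
  deflation <- if (g_tot > 0 && r_tot > 0)
    min(1, ((g_only + fp) * (r_only + fp)) / (g_tot * r_tot)) else 1
  fp_eff <- fp * deflation
  # accidental pairs consumed one truly-single spot per channel: add back
  list(pairs = max(0, p_raw - fp_eff),
       green = g_only + fp_eff,
       red = r_only + fp_eff,
       fp_raw = fp, fp_effective = fp_eff)
}

#' Molecule-level homodimer fraction from co-localization counts
#'
#' Converts corrected pair and single-color counts into the fraction of
#' receptor molecules residing in homodimers. With `N_m` monomer and `N_d`
#' dimer entities in the analysis region before bleaching, recovery
#' probabilities `rho_m`, `rho_d` and labeling probabilities
#' (p_g, p_r, u = 1 - p_g - p_r) per receptor, the expected counts are
#' \itemize{
#'   \item pairs: `rho_d N_d 2 p_g p_r` (times the pair-detection
#'     probability at the pairing radius),
#'   \item green singles: `rho_m N_m p_g + rho_d N_d (p_g^2 + 2 p_g u)`,
#'   \item red singles: `rho_m N_m p_r + rho_d N_d (p_r^2 + 2 p_r u)`.
#' }
#' The system is solved by moments (pairs give `N_d`; each single-color
#' equation gives an `N_m` estimate, averaged) and the molecule fraction
#' `alpha = 2 N_d / (N_m + 2 N_d)` is reported with a seeded cell-level
#' bootstrap SE.
#'
#' @param counts_by_cell list of `toccsl_coloc` (one per cell) with
#'   false-positive estimates filled in.
#' @param labeling a `toccsl_labeling_model`/[labeling_spec()] or list with
#'   `p_green`, `p_red`, `u` entries.
#' @param D_monomer,D_dimer diffusion coefficients (um^2/s).
#' @param model a [recovery_model()].
#' @param channel_gap_s,sigma_xy_um acquisition parameters for the
#'   pair-detection correction.
#' @param n_boot bootstrap resamples over cells.
#' @param seed bootstrap seed.
#' @return object of class `toccsl_dimerfrac`: `fraction`, `se`, `n_cells`,
#'   `counts`, `rho_monomer`, `rho_dimer`, `clipped`.
#' @export
estimate_homodimer_fraction <- function(counts_by_cell, labeling,
                                        D_monomer, D_dimer, model,
                                        channel_gap_s = 0.02,
                                        sigma_xy_um = 0.02,
                                        n_boot = 1000, seed = 1) {
  p_g <- labeling$p_green
  p_r <- labeling$p_red
  u <- if (!is.null(labeling$u)) labeling$u else labeling$u_erbb3
  if (p_g * p_r <= 0)
    stop("estimate_homodimer_fraction: non-identifiable labeling (p_g * p_r = 0)")
  rho_m <- recovery_probability(D_monomer, model)
  rho_d <- recovery_probability(D_dimer, model)
  radius <- counts_by_cell[[1L]]$radius_um
  q_pair <- pair_detection_probability(D_dimer, radius, channel_gap_s,
                                       sigma_xy_um)
  q_edge <- pair_window_retention(D_dimer, model, channel_gap_s)
  q_det <- q_pair * q_edge

  solve_alpha <- function(cells) {
    cnt <- sum_counts(cells)
    N_d <- cnt$pairs / (rho_d * 2 * p_g * p_r * q_det)
    # singles produced by missed true pairs: a distance miss (both spots in
    # the window, > radius apart) yields one green and one red single; a
    # window-exit miss yields a single in one channel only (1/2 each)
    base <- rho_d * N_d * 2 * p_g * p_r
    miss <- base * (q_edge * (1 - q_pair) + (1 - q_edge) / 2)
    g_dim <- rho_d * N_d * (p_g^2 + 2 * p_g * u)
    r_dim <- rho_d * N_d * (p_r^2 + 2 * p_r * u)
    N_m_g <- (cnt$green - miss - g_dim) / (rho_m * p_g)
    N_m_r <- (cnt$red - miss - r_dim) / (rho_m * p_r)
    N_m <- (N_m_g + N_m_r) / 2
    clipped <- FALSE
    if (N_m < 0) { N_m <- 0; clipped <- TRUE }
    a <- if (N_m + 2 * N_d <= 0) 0 else 2 * N_d / (N_m + 2 * N_d)
    list(alpha = min(1, max(0, a)), clipped = clipped || a > 1 || a < 0,
         N_m = N_m, N_d = N_d)
  }
  est <- solve_alpha(counts_by_cell)
  boot <- boot_cells(counts_by_cell, function(cells) solve_alpha(cells)$alpha,
                     n_boot, seed)
  if (est$clipped)
    warning("estimate_homodimer_fraction: negative solution clipped to boundary")
  structure(list(fraction = est$alpha, se = boot$se, n_cells = length(counts_by_cell),
                 counts = sum_counts(counts_by_cell),
                 rho_monomer = rho_m, rho_dimer = rho_d,
                 pair_detection = q_pair,
                 N_monomer = est$N_m, N_dimer = est$N_d,
                 clipped = est$clipped, boot = boot$values),
            class = "toccsl_dimerfrac")
}

#' Fraction of ErbB3 molecules in ErbB3/ErbB2 heterodimers
#'
#' Heterodimer-experiment geometry: the green Fab labels ErbB2 (probability
#' `q_g` per molecule), the red Fab labels ErbB3 (`p_r`). Expected counts
#' with `N_m` free-ErbB3 and `N_het` heterodimer entities:
#' pairs `rho_het N_het q_g p_r`; red singles
#' `rho_m N_m p_r + rho_het N_het (1 - q_g) p_r`. ErbB3 not bound in
#' heterodimers is treated as monomeric (red singles cannot separate ErbB3
#' monomers from ErbB3 homodimers; use [fit_global()] for the joint case).
#' Reported is `beta = N_het / (N_m + N_het)`, the fraction of ErbB3
#' molecules in heterodimers, with a cell-level bootstrap SE.
#'
#' @param counts_by_cell list of `toccsl_coloc` per cell.
#' @param labeling a hetero-mode [labeling_spec()] or list with `p_green`
#'   (ErbB2) and `p_red` (ErbB3).
#' @param D_monomer diffusion coefficient of free ErbB3.
#' @param D_heterodimer diffusion coefficient of the heterodimer.
#' @inheritParams estimate_homodimer_fraction
#' @return `toccsl_dimerfrac` (fraction = beta).
#' @export
estimate_heterodimer_fraction <- function(counts_by_cell, labeling,
                                          D_monomer, D_heterodimer, model,
                                          channel_gap_s = 0.02,
                                          sigma_xy_um = 0.02,
                                          n_boot = 1000, seed = 1) {
  q_g <- labeling$p_green
  p_r <- labeling$p_red
  if (q_g * p_r <= 0)
    stop("estimate_heterodimer_fraction: non-identifiable labeling")
  rho_m <- recovery_probability(D_monomer, model)
  rho_h <- recovery_probability(D_heterodimer, model)
  radius <- counts_by_cell[[1L]]$radius_um
  q_pair <- pair_detection_probability(D_heterodimer, radius, channel_gap_s,
                                       sigma_xy_um)
  q_edge <- pair_window_retention(D_heterodimer, model, channel_gap_s)
  q_det <- q_pair * q_edge
  solve_beta <- function(cells) {
    cnt <- sum_counts(cells)
    N_het <- cnt$pairs / (rho_h * q_g * p_r * q_det)
    base <- rho_h * N_het * q_g * p_r
    miss_red <- base * (q_edge * (1 - q_pair) + (1 - q_edge) / 2)
    r_het <- rho_h * N_het * (1 - q_g) * p_r
    N_m <- (cnt$red - miss_red - r_het) / (rho_m * p_r)
    clipped <- FALSE
    if (N_m < 0) { N_m <- 0; clipped <- TRUE }
    b <- if (N_m + N_het <= 0) 0 else N_het / (N_m + N_het)
    list(beta = min(1, max(0, b)), clipped = clipped, N_m = N_m,
         N_het = N_het)
  }
  est <- solve_beta(counts_by_cell)
  boot <- boot_cells(counts_by_cell, function(cells) solve_beta(cells)$beta,
                     n_boot, seed)
  if (est$clipped)
    warning("estimate_heterodimer_fraction: negative solution clipped")
  structure(list(fraction = est$beta, se = boot$se,
                 n_cells = length(counts_by_cell),
                 counts = sum_counts(counts_by_cell),
                 rho_monomer = rho_m, rho_dimer = rho_h,
                 pair_detection = q_pair,
                 N_monomer = est$N_m, N_dimer = est$N_het,
                 clipped = est$clipped, boot = boot$values),
            class = "toccsl_dimerfrac")
}

boot_cells <- function(counts_by_cell, stat, n_boot, seed) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  n <- length(counts_by_cell)
  vals <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    suppressWarnings(stat(counts_by_cell[idx]))
  }, numeric(1))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  list(se = sd(vals), values = vals)
}

#' @export
print.toccsl_dimerfrac <- function(x, ...) {
  cat(sprintf("Dimer fraction: %.3f +/- %.3f (bootstrap SE, %d cells)\n",
              x$fraction, x$se, x$n_cells))
  cat(sprintf("  rho_monomer = %.4f, rho_dimer = %.4f, corrected pairs = %.1f\n",
              x$rho_monomer, x$rho_dimer, x$counts$pairs))
  invisible(x)
}
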