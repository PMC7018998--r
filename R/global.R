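#' Global competition model for monomer/homodimer/heterodimer composition
#'
#' Homodimer-mode TOCCSL (both colors on ErbB3) cannot see heterodimers as
#' pairs, and heterodimer-mode TOCCSL (green on ErbB2, red on ErbB3) cannot
#' distinguish ErbB3 homodimers from monomers. This joint fit resolves a
#' single molecule-level composition (mu, alpha, beta) = (ErbB3 monomer,
#' ErbB3 homodimer, ErbB3/ErbB2 heterodimer fractions), mu+alpha+beta = 1,
#' from the corrected counts of both experiments measured under the same
#' condition.
#'
#' In the homodimer experiment heterodimers appear as single-ErbB3 entities
#' with heterodimer mobility; in the heterodimer experiment ErbB3 homodimers
#' appear as red-only entities with homodimer mobility. The loss is weighted
#' least squares on the six aggregated counts (pairs, green singles, red
#' singles per experiment), weights 1/expected (Poisson), with free per-
#' experiment ErbB3 abundances and a free free-ErbB2 abundance. SEs come
#' from a seeded cell-level bootstrap.
#'
#' @param homo_counts_by_cell,hetero_counts_by_cell lists of `toccsl_coloc`
#'   per cell from the two experiments.
#' @param labeling_homo homo-mode labeling model (`p_green`, `p_red`, `u`).
#' @param labeling_hetero hetero-mode labeling model (`p_green` on ErbB2,
#'   `p_red` on ErbB3).
#' @param D named diffusion coefficients (um^2/s): `monomer`, `homodimer`,
#'   `heterodimer`, `erbb2_monomer`.
#' @param model a [recovery_model()].
#' @param channel_gap_s,sigma_xy_um acquisition parameters for the pair
#'   detection correction.
#' @param n_boot bootstrap resamples; `seed` its seed.
#' @param condition optional condition label (e.g. "+HRG").
#' @param seed integer seed.
#' @param share_density when `TRUE` (default) the per-cell ErbB3 abundance
#'   is shared between the two experiments (cells with similar expression
#'   are selected in both), which makes the composition well identified
#'   (6 observations, 4 parameters); `FALSE` frees one abundance per
#'   experiment.
#' @return object of class `toccsl_composition`: `mu`, `alpha`, `beta`,
#'   `se` (named vector), `condition`, `boundary` flag, `fit` details.
#' @export
fit_global <- function(homo_counts_by_cell, hetero_counts_by_cell,
                       labeling_homo, labeling_hetero, D, model,
                       channel_gap_s = 0.02, sigma_xy_um = 0.02,
                       n_boot = 200, seed = 1, condition = "",
                       share_density = TRUE) {
  p_g <- labeling_homo$p_green
  p_r <- labeling_homo$p_red
  u <- if (!is.null(labeling_homo$u)) labeling_homo$u else labeling_homo$u_erbb3
  q_g <- labeling_hetero$p_green
  p_r2 <- labeling_hetero$p_red
  if (p_g * p_r <= 0 || q_g * p_r2 <= 0)
    stop("fit_global: degenerate labeling; composition not identifiable")
  obs_all <- c(unlist(sum_counts(homo_counts_by_cell)),
               unlist(sum_counts(hetero_counts_by_cell)))
  if (all(obs_all == 0)) stop("fit_global: all counts are zero")

  rho <- recovery_probability(
    c(D[["monomer"]], D[["homodimer"]], D[["heterodimer"]],
      D[["erbb2_monomer"]]), model)
  names(rho) <- c("m", "hd", "het", "e2")
  radius <- homo_counts_by_cell[[1L]]$radius_um
  qp_hd <- pair_detection_probability(D[["homodimer"]], radius,
                                      channel_gap_s, sigma_xy_um) *
    pair_window_retention(D[["homodimer"]], model, channel_gap_s)
  qp_het <- pair_detection_probability(D[["heterodimer"]], radius,
                                       channel_gap_s, sigma_xy_um) *
    pair_window_retention(D[["heterodimer"]], model, channel_gap_s)

  expected <- function(theta, N3h, N3x, N2x) {
    mu <- theta[1L]; al <- theta[2L]; be <- theta[3L]
    e_h <- c(mu * N3h, al * N3h / 2, be * N3h)      # entities: m, hd, het
    e_x <- c(mu * N3x, al * N3x / 2, be * N3x)
    c(# homodimer experiment: pairs, green singles, red singles
      rho["hd"] * e_h[2L] * 2 * p_g * p_r * qp_hd,
      p_g * (rho["m"] * e_h[1L] + rho["het"] * e_h[3L]) +
        rho["hd"] * e_h[2L] * (p_g^2 + 2 * p_g * u) +
        rho["hd"] * e_h[2L] * 2 * p_g * p_r * (1 - qp_hd),
      p_r * (rho["m"] * e_h[1L] + rho["het"] * e_h[3L]) +
        rho["hd"] * e_h[2L] * (p_r^2 + 2 * p_r * u) +
        rho["hd"] * e_h[2L] * 2 * p_g * p_r * (1 - qp_hd),
      # heterodimer experiment: pairs, green singles, red singles
      rho["het"] * e_x[3L] * q_g * p_r2 * qp_het,
      q_g * (rho["e2"] * N2x + rho["het"] * e_x[3L] * (1 - p_r2)) +
        rho["het"] * e_x[3L] * q_g * p_r2 * (1 - qp_het),
      p_r2 * (rho["m"] * e_x[1L] + rho["het"] * e_x[3L] * (1 - q_g)) +
        rho["hd"] * e_x[2L] * (1 - (1 - p_r2)^2) +
        rho["het"] * e_x[3L] * q_g * p_r2 * (1 - qp_het))
  }

  cell_ratio <- length(hetero_counts_by_cell) / length(homo_counts_by_cell)
  fit_once <- function(homo_cells, hetero_cells) {
    obs <- c(unlist(sum_counts(homo_cells))[1:3],
             unlist(sum_counts(hetero_cells))[1:3])
    n_par <- if (share_density) 4L else 5L
    unpack <- function(par) {
      N3h <- exp(par[3L])
      N3x <- if (share_density) N3h * cell_ratio else exp(par[4L])
      N2x <- exp(par[n_par])
      list(theta = softmax3(par[1:2]), N3h = N3h, N3x = N3x, N2x = N2x)
    }
    loss <- function(par) {
      q <- unpack(par)
      ex <- expected(q$theta, q$N3h, q$N3x, q$N2x)
      sum((obs - ex)^2 / pmax(ex, 0.5))
    }
    # rough moment starts: dimer entities from pairs, total from singles
    n3h0 <- max(10, (obs[2L] + obs[3L] + 4 * obs[1L]) /
                  (rho["m"] * (p_g + p_r)))
    n3x0 <- max(10, (obs[6L] + obs[4L]) / (rho["m"] * p_r2))
    n2x0 <- max(10, obs[5L] / (rho["e2"] * q_g))
    al0 <- min(0.9, max(0.02, 2 * obs[1L] /
                          (rho["hd"] * 2 * p_g * p_r * qp_hd * n3h0)))
    be0 <- min(0.9 - al0 / 2, max(0.02, obs[4L] /
                                    (rho["het"] * q_g * p_r2 * qp_het * n3x0)))
    th0 <- c(max(0.02, 1 - al0 - be0), al0, be0)
    th0 <- th0 / sum(th0)
    starts <- list(log(th0[1:2] / th0[3L]), c(0, 0), c(1, -1), c(-1, 1))
    best <- NULL
    for (st in starts) {
      p0 <- if (share_density) c(st, log(n3h0), log(n2x0)) else
        c(st, log(n3h0), log(n3x0), log(n2x0))
      f <- optim(p0, loss, method = "Nelder-Mead",
                 control = list(maxit = 4000, reltol = 1e-12))
      f <- optim(f$par, loss, method = "Nelder-Mead",
                 control = list(maxit = 4000, reltol = 1e-12))
      if (is.null(best) || f$value < best$value) best <- f
    }
    q <- unpack(best$par)
    list(theta = q$theta, value = best$value, par = best$par, q = q)
  }

  main <- fit_once(homo_counts_by_cell, hetero_counts_by_cell)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  nb_h <- length(homo_counts_by_cell)
  nb_x <- length(hetero_counts_by_cell)
  boot <- replicate(n_boot, {
    bh <- homo_counts_by_cell[sample.int(nb_h, nb_h, replace = TRUE)]
    bx <- hetero_counts_by_cell[sample.int(nb_x, nb_x, replace = TRUE)]
    suppressWarnings(fit_once(bh, bx)$theta)
  })
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  se <- apply(boot, 1, sd)
  names(se) <- c("mu", "alpha", "beta")
  theta <- main$theta
  boundary <- any(theta < 1e-4)
  structure(list(mu = theta[1L], alpha = theta[2L], beta = theta[3L],
                 se = se, condition = condition, boundary = boundary,
                 fit = list(value = main$value, par = main$par,
                            rho = rho, observed = obs_all,
                            expected = expected(theta, main$q$N3h,
                                                main$q$N3x, main$q$N2x))),
            class = "toccsl_composition")
}

softmax3 <- function(l) {
  e <- exp(c(l, 0) - max(c(l, 0)))
  e / sum(e)
}

#' @export
print.toccsl_composition <- function(x, ...) {
  cat(sprintf(
    "ErbB3 composition%s: monomer %.3f +/- %.3f, homodimer %.3f +/- %.3f, heterodimer %.3f +/- %.3f\n",
    if (nzchar(x$condition)) paste0(" (", x$condition, ")") else "",
    x$mu, x$se["mu"], x$alpha, x$se["alpha"], x$beta, x$se["beta"]))
  if (x$boundary) cat("  note: solution on the simplex boundary\n")
  invisible(x)
}
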