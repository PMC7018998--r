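#' Simulate a FRAP recovery curve
#'
#' The noiseless recovery is `I(i)/I_pre = f_m (1 - exp(-i t_lag / tau))`,
#' attenuated by acquisition photobleaching `exp(-i k_bleach)` per frame.
#' Multiplicative Gaussian noise of relative sd `noise_sd` is applied. With
#' `tau_s = 0` the mobile pool recovers immediately.
#'
#' @param f_m mobile fraction in `[0, 1]`.
#' @param tau_s characteristic recovery time (s).
#' @param k_bleach acquisition bleaching rate (1/frame).
#' @param n_postbleach number of postbleach frames (<= 120 typical).
#' @param t_lag_s frame interval (s), 2 s by default.
#' @param noise_sd relative noise sd.
#' @param I_pre prebleach intensity.
#' @param seed optional seed.
#' @return object of class `toccsl_frap`: list with `I_pre`, `series`
#'   (intensity per frame i = 1..n), `t_lag_s`.
#' @export
simulate_frap_curve <- function(f_m, tau_s, k_bleach = 0, n_postbleach = 120,
                                t_lag_s = 2, noise_sd = 0, I_pre = 1000,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (f_m < 0 || f_m > 1) stop("simulate_frap_curve: f_m must be in [0,1]")
  if (tau_s < 0 || k_bleach < 0 || t_lag_s <= 0)
    stop("simulate_frap_curve: tau, k_bleach >= 0 and t_lag > 0 required")
  i <- seq_len(n_postbleach)
  rec <- if (tau_s == 0) rep(f_m, n_postbleach) else
    f_m * (1 - exp(-i * t_lag_s / tau_s))
  series <- I_pre * rec * exp(-i * k_bleach)
  if (noise_sd > 0)
    series <- series * (1 + rnorm(n_postbleach, sd = noise_sd))
  structure(list(I_pre = I_pre, series = series, t_lag_s = t_lag_s),
            class = "toccsl_frap")
}

#' Fit the acquisition photobleaching rate
#'
#' Nonlinear least squares of `I(i) = I0 exp(-i k_bleach)` to a fast image
#' series recorded at negligible recovery, with `k_bleach >= 0` enforced.
#'
#' @param fast_series numeric intensity series (frames i = 1..n).
#' @return list with `k_bleach`, `I0`.
#' @export
fit_bleach_rate <- function(fast_series) {
  y <- as.numeric(fast_series)
  n <- length(y)
  if (n < 3L) stop("fit_bleach_rate: need at least 3 frames")
  i <- seq_len(n)
  if (all(y > 0)) {
    cf <- coef(lm(log(y) ~ i))
    k0 <- max(0, -cf[[2L]])
    I00 <- exp(cf[[1L]])
  } else {
    k0 <- 0.01
    I00 <- max(y)
  }
  fit <- tryCatch(
    nls(y ~ I0 * exp(-i * k), start = list(I0 = I00, k = k0),
        lower = c(I0 = 0, k = 0), algorithm = "port",
        control = list(warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) return(list(k_bleach = k0, I0 = I00))
  cf <- coef(fit)
  list(k_bleach = max(0, cf[["k"]]), I0 = cf[["I0"]])
}

#' Fit the FRAP mobile fraction and recovery time
#'
#' Divides the postbleach series by `exp(-i k_bleach)` and fits the
#' normalized recovery `I(i t_lag)/I_pre = f_m (1 - exp(-i t_lag / tau))`
#' by bounded nonlinear least squares (f_m in `[0, 1.2]`,
#' tau in `(0, 1000]` s). Initial guesses: f_m from the last-point ratio,
#' tau from the half-recovery time.
#'
#' @param curve a `toccsl_frap` (or list with `I_pre`, `series`, `t_lag_s`).
#' @param k_bleach acquisition bleaching rate (1/frame); fit it first with
#'   [fit_bleach_rate()].
#' @return list with `f_m`, `tau_s`, `converged`.
#' @export
fit_mobile_fraction <- function(curve, k_bleach = 0) {
  y <- curve$series / exp(-seq_along(curve$series) * k_bleach)
  y <- y / curve$I_pre
  i <- seq_along(y)
  tl <- curve$t_lag_s
  if (max(abs(y)) < 1e-12)
    return(list(f_m = 0, tau_s = NA_real_, converged = TRUE))
  fm0 <- min(1.2, max(1e-3, mean(tail(y, 5))))
  half_idx <- which(y >= fm0 / 2)
  tau0 <- if (length(half_idx)) max(tl, half_idx[1L] * tl / log(2)) else 10 * tl
  fit <- tryCatch(
    nls(y ~ fm * (1 - exp(-i * tl / tau)),
        start = list(fm = fm0, tau = tau0),
        lower = c(fm = 0, tau = 1e-6), upper = c(fm = 1.2, tau = 1000),
        algorithm = "port", control = list(warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(f_m = NA_real_, tau_s = NA_real_, converged = FALSE))
  }
  cf <- coef(fit)
  list(f_m = cf[["fm"]], tau_s = cf[["tau"]], converged = TRUE)
}

#' Fit and pool a cohort of FRAP curves
#'
#' Each cell is fitted individually; non-converging cells are excluded with
#' a message, and the pooled mean and SD of the mobile fractions are
#' reported.
#'
#' @param curves list of `toccsl_frap`.
#' @param k_bleach acquisition bleaching rate (shared across cells).
#' @return list with `f_m_mean`, `f_m_sd`, `tau_mean`, `n_cells`,
#'   `n_excluded`, `fits`.
#' @export
pool_frap_fits <- function(curves, k_bleach = 0) {
  fits <- lapply(curves, fit_mobile_fraction, k_bleach = k_bleach)
  ok <- vapply(fits, function(f) isTRUE(f$converged) && is.finite(f$f_m),
               logical(1))
  if (any(!ok))
    message("pool_frap_fits: excluded ", sum(!ok), " non-converged cell(s)")
  fm <- vapply(fits[ok], `[[`, numeric(1), "f_m")
  tau <- vapply(fits[ok], `[[`, numeric(1), "tau_s")
  list(f_m_mean = mean(fm), f_m_sd = sd(fm),
       tau_mean = mean(tau, na.rm = TRUE),
       n_cells = sum(ok), n_excluded = sum(!ok), fits = fits)
}
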