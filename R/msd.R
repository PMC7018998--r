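#' Pooled mean-squared displacement curve
#'
#' Squared displacements are pooled over all trajectories (and all cells)
#' and all overlapping time origins for each lag. Per lag the mean (the msd),
#' the SD of the squared displacements and the displacement count are
#' stored; the SD feeds the Gaussian resampling error of [fit_diffusion()].
#'
#' @param trajectories either a `toccsl_trajectories` (simulator output), a
#'   `toccsl_trajectoryset` (linker output) or a data.frame with columns
#'   `trajectory_id`, `frame`, `x_um`, `y_um`.
#' @param max_lag maximum lag (frames).
#' @param frame_interval_s frame interval; taken from the input object when
#'   available.
#' @return object of class `toccsl_msd`: data.frame with columns `lag`,
#'   `t_lag_s`, `msd`, `sd_sq_disp`, `n`.
#' @export
compute_msd <- function(trajectories, max_lag = 5, frame_interval_s = NULL) {
  if (inherits(trajectories, "toccsl_trajectories")) {
    if (is.null(frame_interval_s))
      frame_interval_s <- trajectories$frame_interval_s
    df <- trajectories$trajectories
  } else {
    if (is.null(frame_interval_s))
      frame_interval_s <- attr(trajectories, "frame_interval_s")
    df <- as.data.frame(trajectories)
  }
  if (is.null(frame_interval_s))
    stop("compute_msd: frame_interval_s required")
  stopifnot(all(c("trajectory_id", "frame", "x_um", "y_um") %in% names(df)))
  df <- df[order(df$trajectory_id, df$frame), , drop = FALSE]
  tid <- df$trajectory_id
  res <- vector("list", max_lag)
  for (lag in seq_len(max_lag)) {
    n <- nrow(df)
    if (n <= lag) break
    i <- seq_len(n - lag)
    j <- i + lag
    ok <- tid[i] == tid[j] & (df$frame[j] - df$frame[i]) == lag
    if (!any(ok)) next
    sq <- (df$x_um[j[ok]] - df$x_um[i[ok]])^2 +
      (df$y_um[j[ok]] - df$y_um[i[ok]])^2
    res[[lag]] <- data.frame(lag = lag, t_lag_s = lag * frame_interval_s,
                             msd = mean(sq), sd_sq_disp = sd(sq),
                             n = length(sq))
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0L)
    stop("compute_msd: no displacements found")
  rownames(out) <- NULL
  class(out) <- c("toccsl_msd", "data.frame")
  out
}

#' Two-point diffusion-coefficient fit with resampling error
#'
#' Fits `msd = 4 D t_lag + 4 sigma_xy^2` exactly through the first two msd
#' points: `D = (msd2 - msd1) / (4 dt)` and `4 sigma_xy^2 = msd1 - 4 D t1`.
#' The fitting error is obtained by resampling: both msd values are redrawn
#' from Gaussians centered on the measured msd, the two-point fit is
#' repeated `n_resample` times (1000 by default) and the SD of the resampled
#' D is reported. The Gaussian width per lag is the SD of the squared
#' displacements divided by sqrt(n) (a standard error) by default;
#' `resample_sd = "sd"` uses the raw SD instead.
#'
#' @param msd_curve a `toccsl_msd` with at least two lags.
#' @param n_resample number of resampling repetitions.
#' @param seed integer seed for the resampling.
#' @param resample_sd `"se"` (SD of squared displacements / sqrt(n), default)
#'   or `"sd"` (raw SD).
#' @return object of class `toccsl_diffusion`: list with `D`, `sigma_xy`
#'   (NA and flagged when the intercept is negative), `sd_D`,
#'   `intercept_negative`, `n_trajectories` (NA unless supplied by the
#'   caller), `n_resample`.
#' @examples
#' m <- structure(data.frame(lag = 1:2, t_lag_s = c(0.01, 0.02),
#'                           msd = c(0.004, 0.008),
#'                           sd_sq_disp = c(4e-4, 8e-4), n = c(100, 99)),
#'                class = c("toccsl_msd", "data.frame"))
#' fit_diffusion(m)$D  # 0.1
#' @export
fit_diffusion <- function(msd_curve, n_resample = 1000, seed = 1,
                          resample_sd = c("se", "sd")) {
  resample_sd <- match.arg(resample_sd)
  if (NROW(msd_curve) < 2L)
    stop("fit_diffusion: at least two msd lags required")
  m <- msd_curve[1:2, ]
  dt <- m$t_lag_s[2] - m$t_lag_s[1]
  two_point <- function(msd1, msd2) (msd2 - msd1) / (4 * dt)
  D <- two_point(m$msd[1], m$msd[2])
  icpt <- m$msd[1] - 4 * D * m$t_lag_s[1]
  neg <- icpt < 0
  sigma_xy <- if (neg) NA_real_ else sqrt(icpt / 4)
  sdl <- m$sd_sq_disp
  if (resample_sd == "se") sdl <- sdl / sqrt(m$n)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  Ds <- two_point(rnorm(n_resample, m$msd[1], sdl[1]),
                  rnorm(n_resample, m$msd[2], sdl[2]))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  structure(list(D = D, sigma_xy = sigma_xy, sd_D = sd(Ds),
                 intercept_negative = neg,
                 n_trajectories = NA_integer_, n_resample = n_resample,
                 msd = m),
            class = "toccsl_diffusion")
}

#' @export
print.toccsl_diffusion <- function(x, ...) {
  cat(sprintf("D = %.4f +/- %.4f um^2/s (sigma_xy = %s um%s)\n",
              x$D, x$sd_D,
              ifelse(is.na(x$sigma_xy), "NA", sprintf("%.4f", x$sigma_xy)),
              if (isTRUE(x$intercept_negative)) ", negative intercept" else ""))
  invisible(x)
}

#' Ratio of two diffusion estimates with propagated SE
#'
#' @param est_a,est_b `toccsl_diffusion` objects (or lists with `D`, `sd_D`).
#' @return list with `ratio` = D_a / D_b and `se` by first-order propagation.
#' @export
diffusion_ratio <- function(est_a, est_b) {
  if (est_b$D == 0) stop("diffusion_ratio: zero denominator")
  r <- est_a$D / est_b$D
  se <- abs(r) * sqrt((est_a$sd_D / est_a$D)^2 + (est_b$sd_D / est_b$D)^2)
  list(ratio = r, se = se)
}
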