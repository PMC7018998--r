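#' Recovery model for the bleached strip
#'
#' TOCCSL observes only entities that re-enter the bleached aperture during
#' the recovery interval, so slowly diffusing species (dimers) are
#' under-represented relative to monomers. The correction uses the 1D
#' diffusion solution for a strip `|x| < L/2` that is completely bleached at
#' t = 0 while the surrounding membrane is an infinite reservoir of
#' unbleached molecules.
#'
#' With `bleach_duration_s > 0` the finite bleach pulse is modeled: during
#' the pulse the strip acts as a perfect absorber, so at the end of the
#' pulse the unbleached concentration outside the strip is depleted to
#' `erf(d / sqrt(4 D T))` (d = distance to the nearest strip edge, T =
#' pulse duration) and zero inside; this profile then relaxes freely for
#' the recovery time. With `bleach_duration_s = 0` (default) the pulse is
#' instantaneous and the classic erf solution applies.
#'
#' @param aperture_width_um strip (slit aperture) width L in um.
#' @param analysis_width_um analysis window width w <= L in um.
#' @param recovery_time_s recovery time t_rec in s.
#' @param bleach_duration_s bleach pulse duration T in s (0 = instantaneous).
#' @return object of class `toccsl_recovery_model`.
#' @export
recovery_model <- function(aperture_width_um = 10,
                           analysis_width_um = aperture_width_um,
                           recovery_time_s = 7.5,
                           bleach_duration_s = 0) {
  if (aperture_width_um <= 0 || analysis_width_um <= 0 || recovery_time_s <= 0)
    stop("recovery_model: widths and time must be > 0")
  if (bleach_duration_s < 0)
    stop("recovery_model: bleach_duration_s must be >= 0")
  if (analysis_width_um > aperture_width_um + 1e-12)
    stop("recovery_model: analysis window must fit inside the aperture")
  structure(list(aperture_width_um = aperture_width_um,
                 analysis_width_um = analysis_width_um,
                 recovery_time_s = recovery_time_s,
                 bleach_duration_s = bleach_duration_s),
            class = "toccsl_recovery_model")
}

erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1

#' Unbleached concentration profile after strip bleaching
#'
#' Relative concentration of unbleached molecules at position `x` (um from
#' the strip center) and time `t` after instantaneous, complete bleaching of
#' the strip `|x| < L/2`:
#' `c(x,t) = 1 - (1/2) * (erf((L/2 - x)/sqrt(4 D t)) + erf((L/2 + x)/sqrt(4 D t)))`.
#'
#' @param x position(s) in um.
#' @param t time since bleaching (s).
#' @param D diffusion coefficient (um^2/s).
#' @param L strip width (um).
#' @return unbleached fraction in [0, 1], vectorized over `x`.
#' @export
strip_recovery_profile <- function(x, t, D, L) {
  if (D < 0) stop("strip_recovery_profile: D must be >= 0")
  if (D == 0 || t <= 0) {
    return(as.numeric(abs(x) >= L / 2))
  }
  s <- sqrt(4 * D * t)
  pmin(1, pmax(0, 1 - 0.5 * (erf((L / 2 - x) / s) + erf((L / 2 + x) / s))))
}

#' Probability that a species is observed in the analysis window
#'
#' Mean unbleached concentration over the analysis window `|x| < w/2` at the
#' recovery time: the probability (relative to the pre-bleach expectation)
#' that an entity of diffusion coefficient `D` contributes a live signal to
#' the TOCCSL frame. Monotone non-decreasing in `D` and in the recovery time;
#' 0 for immobile species; -> 1 for fast mixing.
#'
#' @param D_um2_s diffusion coefficient (um^2/s), scalar or vector.
#' @param model a [recovery_model()].
#' @return recovery probability rho in [0, 1].
#' @examples
#' m <- recovery_model(10, 6, 7.5)
#' recovery_probability(0, m)      # 0: immobile molecules never return
#' recovery_probability(1e4, m)    # ~1: complete mixing
#' @export
recovery_probability <- function(D_um2_s, model) {
  stopifnot(inherits(model, "toccsl_recovery_model"))
  if (any(D_um2_s < 0)) stop("recovery_probability: D must be >= 0")
  L <- model$aperture_width_um
  w <- model$analysis_width_um
  t <- model$recovery_time_s
  Tb <- if (is.null(model$bleach_duration_s)) 0 else model$bleach_duration_s
  vapply(D_um2_s, function(D) {
    if (D == 0) return(0)
    val <- if (Tb <= 0) {
      integrate(strip_recovery_profile, lower = -w / 2, upper = w / 2,
                t = t, D = D, L = L, rel.tol = 1e-9,
                abs.tol = 1e-12)$value / w
    } else {
      # trapezoidal average of the post-pulse relaxed profile
      xg <- seq(-w / 2, w / 2, length.out = 401)
      fx <- finite_pulse_profile(xg, t, D, L, Tb)
      wts <- c(0.5, rep(1, length(xg) - 2L), 0.5)
      sum(wts * fx) / sum(wts)
    }
    min(1, max(0, val))
  }, numeric(1))
}

#' Probability that a visible pair survives the inter-channel window test
#'
#' The red channel is exposed `channel_gap_s` after the green channel; an
#' entity observed inside the analysis window at the green exposure may have
#' diffused out of the window by the red exposure (and vice versa), breaking
#' the pair. The retention probability is the recovery-profile-weighted
#' probability that the displaced position is still inside the window:
#' `q = int c(x) P(|x + delta| < w/2) dx / int c(x) dx`, delta ~
#' Normal(0, 2 D gap), integrated over the window.
#'
#' @param D_um2_s diffusion coefficient of the paired species.
#' @param model a [recovery_model()].
#' @param channel_gap_s green-to-red exposure delay (s).
#' @return retention probability in (0, 1].
#' @export
pair_window_retention <- function(D_um2_s, model, channel_gap_s) {
  stopifnot(inherits(model, "toccsl_recovery_model"))
  if (D_um2_s < 0) stop("pair_window_retention: D must be >= 0")
  if (D_um2_s == 0 || channel_gap_s <= 0) return(1)
  w <- model$analysis_width_um
  s <- sqrt(2 * D_um2_s * channel_gap_s)
  x <- seq(-w / 2, w / 2, length.out = 201)
  cx <- recovery_profile_at(x, D_um2_s, model)
  if (sum(cx) <= 0) return(1)
  p_in <- pnorm((w / 2 - x) / s) - pnorm((-w / 2 - x) / s)
  sum(cx * p_in) / sum(cx)
}

# recovery profile c(x) at window coordinates for either pulse model
recovery_profile_at <- function(x, D, model) {
  Tb <- if (is.null(model$bleach_duration_s)) 0 else model$bleach_duration_s
  if (Tb <= 0) {
    strip_recovery_profile(x, model$recovery_time_s, D,
                           model$aperture_width_um)
  } else {
    finite_pulse_profile(x, model$recovery_time_s, D,
                         model$aperture_width_um, Tb)
  }
}

# unbleached profile after a finite absorbing bleach pulse of duration Tb,
# relaxed freely for time t: heat-kernel convolution of the post-pulse
# profile c0(y) = erf(dist(y, strip)/sqrt(4 D Tb)) outside, 0 inside
finite_pulse_profile <- function(x, t, D, L, Tb) {
  c0 <- function(y) {
    d <- abs(y) - L / 2
    ifelse(d <= 0, 0, erf(d / sqrt(4 * D * Tb)))
  }
  s <- sqrt(2 * D * t)
  vapply(x, function(xi) {
    integrate(function(y) c0(y) * dnorm(y, xi, s),
              lower = xi - 8 * s, upper = xi + 8 * s,
              rel.tol = 1e-8)$value
  }, numeric(1))
}
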