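#' Estimate the two-channel registration from a bead field
#'
#' Beads are matched between channels by mutual nearest neighbor within one
#' camera pixel (160 nm); the relative shift and axis-aligned stretch of the
#' red channel with respect to the green channel (about the field origin)
#' are then fitted per axis by least squares:
#' `x_red = sx * x_green + dx`, `y_red = sy * y_green + dy`.
#' Rotation and shear are not modeled; they surface in the residual RMS.
#'
#' Chromatic shifts can exceed the final matching radius, so matching is
#' two-stage: a coarse mutual-NN match (2 um) estimates the median
#' inter-channel displacement, which is removed before the final one-pixel
#' mutual-NN match.
#'
#' @param bead_locs_green,bead_locs_red data.frames with `x_um`, `y_um`.
#' @param match_radius_um bead matching radius (default one pixel).
#' @return object of class `toccsl_regmap`: `dx_um`, `dy_um`, `sx`, `sy`,
#'   `residual_rms_nm`, `n_beads`.
#' @export
estimate_registration <- function(bead_locs_green, bead_locs_red,
                                  match_radius_um = 0.16) {
  coarse <- pair_colocalized(bead_locs_green, bead_locs_red, 2)
  shift0 <- c(0, 0)
  if (coarse$n_pairs >= 3L) {
    g0 <- bead_locs_green[coarse$pairs[, "green"], ]
    r0 <- bead_locs_red[coarse$pairs[, "red"], ]
    shift0 <- c(median(r0$x_um - g0$x_um), median(r0$y_um - g0$y_um))
  }
  red_shifted <- bead_locs_red
  red_shifted$x_um <- red_shifted$x_um - shift0[1L]
  red_shifted$y_um <- red_shifted$y_um - shift0[2L]
  mm <- pair_colocalized(bead_locs_green, red_shifted, match_radius_um)
  n_un <- mm$n_green_only + mm$n_red_only
  if (n_un > 0)
    message("estimate_registration: ", n_un, " unmatched bead(s) excluded")
  if (mm$n_pairs < 3L)
    stop("estimate_registration: at least 3 matched beads required")
  g <- bead_locs_green[mm$pairs[, "green"], ]
  r <- bead_locs_red[mm$pairs[, "red"], ]
  fx <- lm(r$x_um ~ g$x_um)
  fy <- lm(r$y_um ~ g$y_um)
  res <- sqrt(mean(resid(fx)^2 + resid(fy)^2))
  map <- structure(list(dx_um = coef(fx)[[1L]], dy_um = coef(fy)[[1L]],
                        sx = coef(fx)[[2L]], sy = coef(fy)[[2L]],
                        residual_rms_nm = 1000 * res,
                        n_beads = mm$n_pairs),
                   class = "toccsl_regmap")
  if (map$sx < 0.9 || map$sx > 1.1 || map$sy < 0.9 || map$sy > 1.1)
    warning("estimate_registration: stretch outside [0.9, 1.1]; check beads")
  map
}

#' Apply (or undo) a registration map
#'
#' The map sends green-channel coordinates to red-channel coordinates.
#' `direction = "red_to_green"` (default) corrects red localizations into
#' the green reference frame; `"green_to_red"` applies the forward map.
#'
#' @param locs data.frame with `x_um`, `y_um`.
#' @param map a `toccsl_regmap`.
#' @param direction see description.
#' @return `locs` with transformed coordinates.
#' @export
apply_registration <- function(locs, map,
                               direction = c("red_to_green", "green_to_red")) {
  direction <- match.arg(direction)
  stopifnot(inherits(map, "toccsl_regmap"))
  out <- locs
  if (direction == "green_to_red") {
    out$x_um <- map$sx * locs$x_um + map$dx_um
    out$y_um <- map$sy * locs$y_um + map$dy_um
  } else {
    out$x_um <- (locs$x_um - map$dx_um) / map$sx
    out$y_um <- (locs$y_um - map$dy_um) / map$sy
  }
  out
}

#' @export
print.toccsl_regmap <- function(x, ...) {
  cat(sprintf(
    "Registration: shift (%.4f, %.4f) um, stretch (%.5f, %.5f), residual %.1f nm (%d beads)\n",
    x$dx_um, x$dy_um, x$sx, x$sy, x$residual_rms_nm, x$n_beads))
  invisible(x)
}

#' Estimate receptor surface density from prebleach data
#'
#' Counting mode divides the number of localizations by the area; intensity
#' mode divides the summed intensity by the mean single-molecule brightness
#' and the area (for prebleach images too dense to resolve single spots).
#'
#' @param x localization data.frame (counting) or numeric intensity values
#'   (intensity mode).
#' @param area_um2 analyzed membrane area.
#' @param method `"counting"` or `"intensity"`.
#' @param mean_single_intensity calibration: mean brightness of one
#'   fluorophore (intensity mode).
#' @return density per um^2 with attribute `method`.
#' @export
estimate_surface_density <- function(x, area_um2,
                                     method = c("counting", "intensity"),
                                     mean_single_intensity = NULL) {
  method <- match.arg(method)
  if (area_um2 <= 0) stop("estimate_surface_density: area must be > 0")
  d <- if (method == "counting") {
    NROW(x) / area_um2
  } else {
    if (is.null(mean_single_intensity) || mean_single_intensity <= 0)
      stop("estimate_surface_density: mean_single_intensity required")
    sum(as.numeric(x)) / (mean_single_intensity * area_um2)
  }
  attr(d, "method") <- method
  d
}
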