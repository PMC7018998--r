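#' Camera/detection parameters for frame rendering
#'
#' The image-formation model is the standard single-molecule one: symmetric
#' 2D Gaussian PSF integrated over camera pixels, Poisson photon shot noise,
#' stochastic electron-multiplying gain (gamma-distributed per photon) and
#' Gaussian read noise on top of a constant offset.
#'
#' @param nx,ny image size in pixels.
#' @param pixel_size_um camera pixel size.
#' @param psf_sigma_um PSF Gaussian sigma (default 0.2 um).
#' @param gain camera counts per photoelectron.
#' @param offset camera baseline (counts).
#' @param read_noise_sd read noise sd (counts).
#' @param bg_photons mean background photons per pixel per frame.
#' @param em_gain logical; use gamma-distributed EM gain.
#' @return list of class `toccsl_camera`.
#' @export
camera_params <- function(nx = 64, ny = 64, pixel_size_um = 0.16,
                          psf_sigma_um = 0.2, gain = 20, offset = 100,
                          read_noise_sd = 2, bg_photons = 2,
                          em_gain = TRUE) {
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 pixel_size_um = pixel_size_um, psf_sigma_um = psf_sigma_um,
                 gain = gain, offset = offset, read_noise_sd = read_noise_sd,
                 bg_photons = bg_photons, em_gain = em_gain),
            class = "toccsl_camera")
}

#' Render localizations into synthetic camera frames
#'
#' Emitters are rendered as pixel-integrated 2D Gaussian PSFs. Coordinates
#' are continuous um with origin at the lower-left field corner; pixel
#' (i, j) (row i from the bottom, column j) is centered at
#' ((j - 0.5) px, (i - 0.5) px). Emitters outside the field are clipped
#' silently (count reported in the `n_clipped` attribute).
#'
#' @param localizations data.frame with `frame` (0-based), `x_um`, `y_um`
#'   and optionally `photons` (default 500).
#' @param camera a [camera_params()].
#' @param n_frames number of frames to render (defaults to max frame + 1).
#' @param seed optional seed; `noise = FALSE` renders the noiseless
#'   expectation (offset + gain * signal).
#' @param noise logical.
#' @return list of numeric matrices (class `toccsl_stack`) with attributes
#'   `pixel_size_um`, `n_clipped`.
#' @export
render_frames <- function(localizations, camera = camera_params(),
                          n_frames = NULL, seed = NULL, noise = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  px <- camera$pixel_size_um
  nx <- camera$nx; ny <- camera$ny
  n_loc <- NROW(localizations)
  if (is.null(localizations$photons))
    localizations$photons <- rep(500, n_loc)
  if (is.null(localizations$frame))
    localizations$frame <- rep(0L, n_loc)
  if (is.null(n_frames)) n_frames <- max(0L, localizations$frame) + 1L
  inside <- localizations$x_um >= 0 & localizations$x_um <= nx * px &
    localizations$y_um >= 0 & localizations$y_um <= ny * px
  n_clipped <- sum(!inside)
  locs <- localizations[inside, , drop = FALSE]
  xs <- (0:nx) * px
  ys <- (0:ny) * px
  out <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    sub <- locs[locs$frame == f - 1L, , drop = FALSE]
    sig <- matrix(0, ny, nx)
    for (e in seq_len(nrow(sub))) {
      fx <- diff(pnorm(xs, sub$x_um[e], camera$psf_sigma_um))
      fy <- diff(pnorm(ys, sub$y_um[e], camera$psf_sigma_um))
      sig <- sig + sub$photons[e] * outer(fy, fx)
    }
    mu <- sig + camera$bg_photons
    if (noise) {
      phot <- matrix(rpois(length(mu), mu), ny, nx)
      counts <- matrix(0, ny, nx)
      nz <- phot > 0
      counts[nz] <- if (camera$em_gain)
        rgamma(sum(nz), shape = phot[nz], scale = camera$gain) else
          phot[nz] * camera$gain
      img <- counts + camera$offset +
        rnorm(length(mu), sd = camera$read_noise_sd)
    } else {
      img <- mu * camera$gain + camera$offset
    }
    out[[f]] <- matrix(pmin(65535, pmax(0, round(img))), ny, nx)
  }
  structure(out, pixel_size_um = px, n_clipped = n_clipped,
            camera = camera, class = "toccsl_stack")
}
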