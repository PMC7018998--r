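#' Spot detection parameters
#'
#' @param psf_sigma_um expected PSF sigma used for the matched filter and as
#'   the fit start value.
#' @param threshold_sigmas detection threshold in robust SDs above the local
#'   background of the band-passed image.
#' @param fit_window_px half-width of the fitting window.
#' @param method `"lsq"` (Gaussian least squares) or `"mle"` (Poisson MLE on
#'   gain-converted photon counts).
#' @param max_density_per_um2 frames with more candidates per um^2 than this
#'   are rejected (isolated-spot fitting invalid).
#' @param min_photons fits below this photon count are discarded (rejects
#'   noise-triggered candidates).
#' @param max_bg_photons frames whose median photon level exceeds this are
#'   rejected: overlapping emitters raise the apparent background far above
#'   the few photons/pixel of a resolvable single-molecule frame.
#' @param gain,offset camera calibration for photon conversion.
#' @return list of class `toccsl_detection_params`.
#' @export
detection_params <- function(psf_sigma_um = 0.2, threshold_sigmas = 5,
                             fit_window_px = 4, method = c("lsq", "mle"),
                             max_density_per_um2 = 1, min_photons = 50,
                             max_bg_photons = 20, gain = 20, offset = 100) {
  method <- match.arg(method)
  structure(list(psf_sigma_um = psf_sigma_um,
                 threshold_sigmas = threshold_sigmas,
                 fit_window_px = as.integer(fit_window_px), method = method,
                 max_density_per_um2 = max_density_per_um2,
                 min_photons = min_photons,
                 max_bg_photons = max_bg_photons, gain = gain,
                 offset = offset),
            class = "toccsl_detection_params")
}

# separable Gaussian blur with replicated edges
gauss_blur <- function(img, sigma_px) {
  r <- max(1L, ceiling(3 * sigma_px))
  k <- dnorm(-r:r, sd = sigma_px)
  k <- k / sum(k)
  smooth1 <- function(m) {
    n <- nrow(m)
    pad <- rbind(m[rep(1L, r), , drop = FALSE], m,
                 m[rep(n, r), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (o in -r:r)
      out <- out + k[o + r + 1L] * pad[(1L + r + o):(n + r + o), , drop = FALSE]
    out
  }
  t(smooth1(t(smooth1(img))))
}

#' Detect and localize single-molecule spots
#'
#' Band-pass (difference of Gaussians) filtering followed by local-maximum
#' detection above a robust significance threshold; each candidate is then
#' fitted with a symmetric 2D Gaussian, either by least squares or by
#' Poisson maximum likelihood on photon-converted counts. The localization
#' precision per spot is the Thompson approximation
#' `sqrt((s^2 + a^2/12)/N + 8 pi s^4 b^2 / (a^2 N^2))`.
#'
#' @param stack a `toccsl_stack` (list of matrices with `pixel_size_um`
#'   attribute) or single matrix plus `pixel_size_um`.
#' @param channel channel label stored in the output.
#' @param params a [detection_params()].
#' @param pixel_size_um required if the stack carries no pixel size.
#' @return data.frame of localizations: frame, channel, x_um, y_um,
#'   intensity (photons), sigma_fit_um, precision_um, saturated.
#' @export
detect_and_localize <- function(stack, channel = "green",
                                params = detection_params(),
                                pixel_size_um = NULL) {
  if (is.matrix(stack)) stack <- list(stack)
  px <- attr(stack, "pixel_size_um")
  if (is.null(px)) px <- pixel_size_um
  if (is.null(px)) stop("detect_and_localize: calibrated pixel size missing")
  out <- list()
  for (f in seq_along(stack)) {
    img <- stack[[f]]
    loc <- localize_frame(img, px, params)
    if (nrow(loc)) {
      loc$frame <- f - 1L
      loc$channel <- channel
      out[[length(out) + 1L]] <- loc
    }
  }
  if (!length(out))
    return(data.frame(frame = integer(0), channel = character(0),
                      x_um = numeric(0), y_um = numeric(0),
                      intensity = numeric(0), sigma_fit_um = numeric(0),
                      precision_um = numeric(0), saturated = logical(0)))
  res <- do.call(rbind, out)
  res[, c("frame", "channel", "x_um", "y_um", "intensity", "sigma_fit_um",
          "precision_um", "saturated")]
}

localize_frame <- function(img, px, params) {
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      intensity = numeric(0), sigma_fit_um = numeric(0),
                      precision_um = numeric(0), saturated = logical(0))
  bg_phot <- (median(img) - params$offset) / params$gain
  if (bg_phot > params$max_bg_photons)
    stop(sprintf(
      "detect_and_localize: median background of %.1f photons/px exceeds %.1f; emitter density too high for isolated-spot fitting",
      bg_phot, params$max_bg_photons))
  s_px <- params$psf_sigma_um / px
  bp <- gauss_blur(img, s_px) - gauss_blur(img, 2.5 * s_px)
  thr <- params$threshold_sigmas * mad(bp)
  ny <- nrow(img); nx <- ncol(img)
  cand <- which(bp > thr, arr.ind = TRUE)
  # keep 3x3 local maxima away from the border
  r <- params$fit_window_px
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1L]; j <- cand[k, 2L]
    if (i <= r || j <= r || i > ny - r || j > nx - r) next
    keep[k] <- bp[i, j] == max(bp[(i - 1):(i + 1), (j - 1):(j + 1)])
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  dens <- nrow(cand) / (nx * ny * px^2)
  if (dens > params$max_density_per_um2)
    stop(sprintf(
      "detect_and_localize: candidate density %.2f/um^2 exceeds %.2f/um^2; too dense for isolated-spot fitting",
      dens, params$max_density_per_um2))
  res <- lapply(seq_len(nrow(cand)), function(k)
    fit_spot(img, cand[k, 1L], cand[k, 2L], px, params))
  res <- do.call(rbind, res)
  res[res$intensity >= params$min_photons, , drop = FALSE]
}

fit_spot <- function(img, ci, cj, px, params) {
  r <- params$fit_window_px
  win <- img[(ci - r):(ci + r), (cj - r):(cj + r)]
  saturated <- any(win >= 65535)
  # photon conversion for fitting
  phot <- matrix(pmax(0, (win - params$offset) / params$gain), nrow(win))
  ii <- (ci - r):(ci + r)   # rows (y), 1-based
  jj <- (cj - r):(cj + r)
  yc <- (ii - 0.5) * px
  xc <- (jj - 0.5) * px
  bg0 <- median(phot[c(1, nrow(phot)), ])
  A0 <- max(phot) - bg0
  model <- function(p) {
    # p: x0, y0, log amplitude (photons), log sigma, bg
    fx <- diff(pnorm(c(xc - px / 2, xc[length(xc)] + px / 2), p[1L], exp(p[4L])))
    fy <- diff(pnorm(c(yc - px / 2, yc[length(yc)] + px / 2), p[2L], exp(p[4L])))
    exp(p[3L]) * outer(fy, fx) + p[5L]
  }
  p0 <- c(xc[r + 1L], yc[r + 1L],
          log(max(A0 * 2 * pi * (params$psf_sigma_um / px)^2, 1)),
          log(params$psf_sigma_um), max(bg0, 1e-3))
  objective <- if (params$method == "lsq") {
    function(p) sum((model(p) - phot)^2)
  } else {
    function(p) { m <- pmax(model(p), 1e-9); sum(m - phot * log(m)) }
  }
  opt <- optim(p0, objective, method = "Nelder-Mead",
               control = list(maxit = 800, reltol = 1e-10))
  p <- opt$par
  N <- exp(p[3L])
  s <- exp(p[4L])
  b <- max(p[5L], 0)
  a <- px
  prec <- sqrt((s^2 + a^2 / 12) / max(N, 1) +
                 8 * pi * s^4 * b^2 / (a^2 * max(N, 1)^2))
  data.frame(x_um = p[1L], y_um = p[2L], intensity = N, sigma_fit_um = s,
             precision_um = prec, saturated = saturated)
}
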