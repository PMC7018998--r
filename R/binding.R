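#' Simulate an equilibrium binding titration
#'
#' One-site specific binding: `B(c) = Bmax c / (Kd + c)` with optional
#' multiplicative noise.
#'
#' @param Kd dissociation constant (nM).
#' @param Bmax response at saturation (arbitrary units).
#' @param concentrations Fab concentrations (nM), strictly increasing.
#' @param noise_cv relative noise sd.
#' @param seed optional seed.
#' @return object of class `toccsl_titration` (data.frame: concentration_nM,
#'   response; attr `mode = "specific"`).
#' @export
simulate_binding_titration <- function(Kd, Bmax, concentrations,
                                       noise_cv = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (Kd <= 0 || Bmax <= 0) stop("Kd and Bmax must be > 0")
  if (any(concentrations < 0) || is.unsorted(concentrations, strictly = TRUE))
    stop("concentrations must be >= 0 and strictly increasing")
  b <- Bmax * concentrations / (Kd + concentrations)
  if (noise_cv > 0) b <- b * (1 + rnorm(length(b), sd = noise_cv))
  structure(data.frame(concentration_nM = concentrations, response = b),
            mode = "specific", class = c("toccsl_titration", "data.frame"))
}

#' Simulate a competitive binding titration
#'
#' The response of a fixed concentration of labeled Fab as a function of an
#' unlabeled competitor: `B([I]) = B0 / (1 + [I]/IC50)` with
#' `IC50 = Kd_unlabeled (1 + c_labeled / Kd_labeled)` (Cheng-Prusoff).
#'
#' @param Kd_labeled,Kd_unlabeled dissociation constants (nM).
#' @param c_labeled fixed labeled-Fab concentration (nM).
#' @param competitor_concentrations unlabeled-Fab concentrations (nM).
#' @param B0 response without competitor.
#' @param noise_cv relative noise sd; `seed` optional seed.
#' @inheritParams simulate_binding_titration
#' @return `toccsl_titration` with attrs `mode = "competition"`,
#'   `c_labeled`.
#' @export
simulate_competition <- function(Kd_labeled, Kd_unlabeled, c_labeled,
                                 competitor_concentrations, B0 = 1000,
                                 noise_cv = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ic50 <- Kd_unlabeled * (1 + c_labeled / Kd_labeled)
  b <- B0 / (1 + competitor_concentrations / ic50)
  if (noise_cv > 0) b <- b * (1 + rnorm(length(b), sd = noise_cv))
  structure(data.frame(concentration_nM = competitor_concentrations,
                       response = b),
            mode = "competition", c_labeled = c_labeled,
            class = c("toccsl_titration", "data.frame"))
}

#' Fit a one-site specific binding model
#'
#' Least squares of `B(c) = Bmax c / (Kd + c)`.
#'
#' @param titration data.frame with `concentration_nM`, `response`
#'   (>= 4 points).
#' @return list with `Kd`, `Bmax` and their standard errors.
#' @export
fit_specific_binding <- function(titration) {
  c_ <- titration$concentration_nM
  y <- titration$response
  if (length(y) < 4L) stop("fit_specific_binding: need >= 4 points")
  Bmax0 <- max(y) * 1.2
  Kd0 <- c_[which.min(abs(y - Bmax0 / 2))]
  if (!is.finite(Kd0) || Kd0 <= 0) Kd0 <- median(c_[c_ > 0])
  # flow-cytometry intensities carry roughly proportional noise: weight by
  # 1/y^2 (relative least squares) so low-concentration points are not
  # drowned out and Kd stays unbiased under multiplicative noise
  wts <- 1 / pmax(y, max(y) * 1e-3)^2
  fit <- nls(y ~ Bmax * c_ / (Kd + c_),
             start = list(Bmax = Bmax0, Kd = Kd0), weights = wts,
             lower = c(Bmax = 1e-12, Kd = 1e-12), algorithm = "port")
  cf <- summary(fit)$coefficients
  list(Kd = cf["Kd", "Estimate"], Bmax = cf["Bmax", "Estimate"],
       Kd_se = cf["Kd", "Std. Error"], Bmax_se = cf["Bmax", "Std. Error"])
}

#' Fit a one-site competitive binding model
#'
#' Fits `B([I]) = B0 / (1 + [I]/IC50)` and converts
#' `Kd_unlabeled = IC50 / (1 + c_labeled / Kd_labeled)` (Cheng-Prusoff).
#'
#' @param titration competition titration (competitor concentration,
#'   response).
#' @param Kd_labeled Kd of the labeled Fab (nM).
#' @param c_labeled fixed labeled-Fab concentration (nM); taken from the
#'   titration attribute when missing.
#' @return list with `Kd_unlabeled`, `IC50`, `B0` and SEs.
#' @export
fit_competitive_binding <- function(titration, Kd_labeled, c_labeled = NULL) {
  if (is.null(c_labeled)) c_labeled <- attr(titration, "c_labeled")
  if (is.null(c_labeled)) stop("fit_competitive_binding: c_labeled required")
  ci <- titration$concentration_nM
  y <- titration$response
  if (length(y) < 4L) stop("fit_competitive_binding: need >= 4 points")
  B00 <- max(y)
  ic0 <- ci[which.min(abs(y - B00 / 2))]
  if (!is.finite(ic0) || ic0 <= 0) ic0 <- median(ci[ci > 0])
  wts <- 1 / pmax(y, max(y) * 1e-3)^2
  fit <- nls(y ~ B0 / (1 + ci / IC50), start = list(B0 = B00, IC50 = ic0),
             weights = wts,
             lower = c(B0 = 1e-12, IC50 = 1e-12), algorithm = "port")
  cf <- summary(fit)$coefficients
  ic50 <- cf["IC50", "Estimate"]
  conv <- 1 + c_labeled / Kd_labeled
  list(Kd_unlabeled = ic50 / conv, IC50 = ic50,
       B0 = cf["B0", "Estimate"],
       Kd_unlabeled_se = cf["IC50", "Std. Error"] / conv)
}
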