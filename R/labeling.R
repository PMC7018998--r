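#' Per-channel labeling probabilities from competitive Fab binding
#'
#' Two Fabs (green- and red-conjugated) compete for the same epitope on one
#' receptor. At equilibrium the occupancy of Fab i with concentration c_i and
#' dissociation constant Kd_i is (c_i/Kd_i) / (1 + c_g/Kd_g + c_r/Kd_r); the
#' receptor is unlabeled with the remaining probability. A bound Fab is
#' assumed detectable (all degrees of labeling exceed one dye per Fab); the
#' optional Poisson-dye model makes a bound Fab dark with probability
#' exp(-DOL).
#'
#' @param fab_conc_nM length-2 numeric (green, red) Fab concentrations in nM.
#' @param Kd_nM length-2 numeric (green, red) dissociation constants in nM.
#' @param degree_of_labeling length-2 numeric, mean dyes per Fab.
#' @param dye_dark_model `"none"` or `"poisson"`.
#' @return object of class `toccsl_labeling_model`: list with `p_green`,
#'   `p_red`, `u` (probabilities summing to 1) and the derivation inputs.
#' @examples
#' # saturating equimolar labeling with equal affinity: p_g = p_r ~ 0.5
#' labeling_probabilities(c(200, 200), c(5, 5), c(1.5, 1.8))
#' @export
labeling_probabilities <- function(fab_conc_nM, Kd_nM,
                                   degree_of_labeling = c(1.5, 1.8),
                                   dye_dark_model = c("none", "poisson")) {
  dye_dark_model <- match.arg(dye_dark_model)
  if (length(fab_conc_nM) != 2L || length(Kd_nM) != 2L)
    stop("labeling_probabilities: fab_conc_nM and Kd_nM must have length 2 (green, red)")
  if (any(fab_conc_nM < 0) || any(Kd_nM <= 0))
    stop("labeling_probabilities: concentrations >= 0 and Kd > 0 required")
  if (any(degree_of_labeling <= 0))
    stop("labeling_probabilities: degrees of labeling must be > 0")
  r <- fab_conc_nM / Kd_nM
  occ <- r / (1 + sum(r))                 # competitive one-site occupancies
  det <- if (dye_dark_model == "poisson") 1 - exp(-degree_of_labeling) else c(1, 1)
  p <- occ * det
  out <- list(p_green = p[[1L]], p_red = p[[2L]], u = 1 - sum(p),
              inputs = list(fab_conc_nM = fab_conc_nM, Kd_nM = Kd_nM,
                            degree_of_labeling = degree_of_labeling,
                            dye_dark_model = dye_dark_model))
  stopifnot(out$u >= -1e-12)
  out$u <- max(0, out$u)
  class(out) <- "toccsl_labeling_model"
  out
}

#' @export
print.toccsl_labeling_model <- function(x, ...) {
  cat(sprintf("Labeling model: p_green = %.4f, p_red = %.4f, unlabeled = %.4f\n",
              x$p_green, x$p_red, x$u))
  invisible(x)
}
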