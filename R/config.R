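#' Simulation configuration for TOCCSL experiments
#'
#' Collects the geometry and timing of a two-color TOCCSL acquisition:
#' camera pixel size (160 nm), the slit-aperture field stop (~10 um wide in
#' the sample plane), the 700-ms bleach pulse, the 5-10 s recovery interval,
#' and the 20-ms gap between recording the green and the red channel.
#'
#' The field is periodic and at least 4x wider than the aperture along x, so
#' that the unbleached membrane outside the mask acts as an effectively
#' infinite reservoir. The aperture is a strip `|x - cx| < aperture/2`
#' spanning the full field height; the analysis window is a centered strip of
#' width `analysis_width_um` (defaults to the whole aperture, i.e. the
#' illuminated field of view).
#'
#' @param field_width_um,field_height_um field extent (um).
#' @param pixel_size_um camera pixel size (um), 0.16 by default.
#' @param frame_interval_s interval between tracking frames (s).
#' @param n_frames number of frames for plain trajectory simulation.
#' @param localization_sigma_um localization precision sigma_xy (um/axis).
#' @param aperture_width_um slit aperture width (um).
#' @param analysis_width_um width of the analysis window (um), <= aperture.
#' @param bleach_duration_s duration of the bleach pulse (s).
#' @param recovery_time_s time from end of bleach pulse to the TOCCSL frame (s).
#' @param channel_gap_s delay between green and red channel exposures (s).
#' @param n_tracking_frames number of post-TOCCSL tracking frames.
#' @param rng_seed optional integer seed used by the simulator.
#' @return an object of class `toccsl_config` (a validated list).
#' @export
sim_config <- function(field_width_um = 40,
                       field_height_um = 10,
                       pixel_size_um = 0.16,
                       frame_interval_s = 0.01,
                       n_frames = 10,
                       localization_sigma_um = 0.02,
                       aperture_width_um = 10,
                       analysis_width_um = aperture_width_um,
                       bleach_duration_s = 0.7,
                       recovery_time_s = 7.5,
                       channel_gap_s = 0.02,
                       n_tracking_frames = 10,
                       rng_seed = NULL) {
  cfg <- list(
    field_width_um = field_width_um, field_height_um = field_height_um,
    pixel_size_um = pixel_size_um, frame_interval_s = frame_interval_s,
    n_frames = as.integer(n_frames),
    localization_sigma_um = localization_sigma_um,
    aperture_width_um = aperture_width_um,
    analysis_width_um = analysis_width_um,
    bleach_duration_s = bleach_duration_s,
    recovery_time_s = recovery_time_s,
    channel_gap_s = channel_gap_s,
    n_tracking_frames = as.integer(n_tracking_frames),
    rng_seed = rng_seed)
  scalars <- c("field_width_um", "field_height_um", "pixel_size_um",
               "frame_interval_s", "localization_sigma_um",
               "aperture_width_um", "analysis_width_um",
               "bleach_duration_s", "recovery_time_s", "channel_gap_s")
  for (nm in scalars) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      stop("sim_config: '", nm, "' must be a single number")
  }
  if (cfg$field_width_um <= 0 || cfg$field_height_um <= 0 ||
      cfg$pixel_size_um <= 0 || cfg$frame_interval_s <= 0)
    stop("sim_config: lengths and times must be strictly positive")
  if (cfg$localization_sigma_um < 0)
    stop("sim_config: localization_sigma_um must be >= 0")
  if (cfg$recovery_time_s <= 0)
    stop("sim_config: recovery_time_s must be > 0")
  if (cfg$bleach_duration_s < 0 || cfg$channel_gap_s < 0)
    stop("sim_config: bleach_duration_s and channel_gap_s must be >= 0")
  if (cfg$aperture_width_um > cfg$field_width_um)
    stop("sim_config: aperture wider than the field")
  if (cfg$analysis_width_um > cfg$aperture_width_um)
    stop("sim_config: analysis window wider than the aperture")
  if (cfg$n_frames < 1L) stop("sim_config: n_frames must be >= 1")
  if (cfg$n_tracking_frames < 0L) stop("sim_config: n_tracking_frames < 0")
  class(cfg) <- "toccsl_config"
  cfg
}

#' Population composition and mobility
#'
#' Describes the molecular species on the membrane: ErbB3 monomers, ErbB3
#' homodimers, ErbB3/ErbB2 heterodimers, free ErbB2 monomers and (optionally)
#' higher ErbB3 oligomers, together with their diffusion coefficients and the
#' receptor surface densities. Molecule-level fractions refer to the fraction
#' of ErbB3 molecules in each state and must sum to 1.
#'
#' @param density_erbb3_per_um2 ErbB3 surface density (molecules/um^2).
#' @param density_erbb2_per_um2 ErbB2 surface density (molecules/um^2).
#' @param f_homodimer fraction of ErbB3 molecules in ErbB3 homodimers.
#' @param f_heterodimer fraction of ErbB3 molecules in ErbB3/ErbB2 heterodimers.
#' @param f_oligomer fraction of ErbB3 molecules in higher oligomers.
#' @param oligomer_size number of ErbB3 protomers per higher oligomer (>= 3).
#' @param D named diffusion coefficients (um^2/s) with entries `monomer`,
#'   `homodimer`, `heterodimer`, `erbb2_monomer`, `oligomer`.
#' @return object of class `toccsl_population` with a per-species entity table.
#' @export
population_spec <- function(density_erbb3_per_um2 = 10,
                            density_erbb2_per_um2 = 0,
                            f_homodimer = 0,
                            f_heterodimer = 0,
                            f_oligomer = 0,
                            oligomer_size = 4,
                            D = c(monomer = 0.084, homodimer = 0.052,
                                  heterodimer = 0.017, erbb2_monomer = 0.044,
                                  oligomer = 0.005)) {
  fr <- c(f_homodimer, f_heterodimer, f_oligomer)
  if (any(fr < 0) || sum(fr) > 1 + 1e-12)
    stop("population_spec: ErbB3 molecule fractions must lie in [0,1] and sum to <= 1")
  f_monomer <- max(0, 1 - sum(fr))
  need <- c("monomer", "homodimer", "heterodimer", "erbb2_monomer", "oligomer")
  D <- D[need[need %in% names(D)]]
  miss <- setdiff(c("monomer", "homodimer", "heterodimer", "erbb2_monomer",
                    "oligomer"), names(D))
  defaults <- c(monomer = 0.084, homodimer = 0.052, heterodimer = 0.017,
                erbb2_monomer = 0.044, oligomer = 0.005)
  D <- c(D, defaults[miss])
  if (any(D < 0)) stop("population_spec: diffusion coefficients must be >= 0")
  if (density_erbb3_per_um2 <= 0)
    stop("population_spec: density_erbb3_per_um2 must be > 0")
  if (density_erbb2_per_um2 < 0)
    stop("population_spec: density_erbb2_per_um2 must be >= 0")
  if (oligomer_size < 3) stop("population_spec: oligomer_size must be >= 3")

  n3 <- density_erbb3_per_um2
  n2 <- density_erbb2_per_um2
  het_entities <- f_heterodimer * n3
  if (het_entities > n2 + 1e-12 && f_heterodimer > 0)
    stop("population_spec: heterodimers require at least as much ErbB2 as ",
         "heterodimer-bound ErbB3")
  species <- data.frame(
    species = c("monomer", "homodimer", "heterodimer", "erbb2_monomer",
                "oligomer"),
    # entities per um^2; an entity is one mobile unit (spot)
    entity_density = c(f_monomer * n3,
                       f_homodimer * n3 / 2,
                       het_entities,
                       max(0, n2 - het_entities),
                       f_oligomer * n3 / oligomer_size),
    n_erbb3 = c(1L, 2L, 1L, 0L, as.integer(oligomer_size)),
    n_erbb2 = c(0L, 0L, 1L, 1L, 0L),
    D = as.numeric(D[c("monomer", "homodimer", "heterodimer",
                       "erbb2_monomer", "oligomer")]),
    stringsAsFactors = FALSE)
  out <- list(species = species,
              fractions = c(monomer = f_monomer, homodimer = f_homodimer,
                            heterodimer = f_heterodimer,
                            oligomer = f_oligomer),
              density_erbb3_per_um2 = n3,
              density_erbb2_per_um2 = n2,
              oligomer_size = as.integer(oligomer_size),
              D = D)
  class(out) <- "toccsl_population"
  out
}

#' @export
print.toccsl_population <- function(x, ...) {
  cat("TOCCSL population (ErbB3", x$density_erbb3_per_um2, "/um^2, ErbB2",
      x$density_erbb2_per_um2, "/um^2)\n")
  print(x$species, row.names = FALSE)
  invisible(x)
}

#' Fab labeling specification
#'
#' In the homodimer experiment two spectrally distinct Fabs compete for the
#' same epitope on ErbB3, so each receptor carries a green label with
#' probability `p_green`, a red label with `p_red`, or no detectable label
#' (`u = 1 - p_green - p_red`). In the heterodimer experiment the green Fab
#' binds ErbB2 and the red Fab binds ErbB3 with independent one-site
#' occupancies.
#'
#' @param mode `"homo"` (both colors on ErbB3) or `"hetero"` (green on ErbB2,
#'   red on ErbB3).
#' @param fab_conc_green_nM,fab_conc_red_nM Fab concentrations (nM).
#' @param Kd_green_nM,Kd_red_nM dissociation constants (nM).
#' @param dol_green,dol_red degrees of labeling (dyes per Fab).
#' @param dye_dark_model `"none"` (any bound Fab detectable) or `"poisson"`
#'   (dark with probability `exp(-DOL)`).
#' @return object of class `toccsl_labeling` with fields `mode`, `p_green`,
#'   `p_red`, `u_erbb3` (and in hetero mode `u_erbb2`).
#' @export
labeling_spec <- function(mode = c("homo", "hetero"),
                          fab_conc_green_nM = 200, fab_conc_red_nM = 200,
                          Kd_green_nM = 5, Kd_red_nM = 5,
                          dol_green = 1.5, dol_red = 1.8,
                          dye_dark_model = c("none", "poisson")) {
  mode <- match.arg(mode)
  dye_dark_model <- match.arg(dye_dark_model)
  if (any(c(fab_conc_green_nM, fab_conc_red_nM) < 0))
    stop("labeling_spec: Fab concentrations must be >= 0")
  if (any(c(Kd_green_nM, Kd_red_nM) <= 0))
    stop("labeling_spec: Kd values must be > 0")
  if (any(c(dol_green, dol_red) <= 0))
    stop("labeling_spec: degrees of labeling must be > 0")
  det_g <- if (dye_dark_model == "poisson") 1 - exp(-dol_green) else 1
  det_r <- if (dye_dark_model == "poisson") 1 - exp(-dol_red) else 1
  if (mode == "homo") {
    lm <- labeling_probabilities(
      fab_conc_nM = c(green = fab_conc_green_nM, red = fab_conc_red_nM),
      Kd_nM = c(green = Kd_green_nM, red = Kd_red_nM),
      degree_of_labeling = c(green = dol_green, red = dol_red),
      dye_dark_model = dye_dark_model)
    out <- list(mode = "homo", p_green = lm$p_green, p_red = lm$p_red,
                u_erbb3 = lm$u)
  } else {
    occ_g <- fab_conc_green_nM / (fab_conc_green_nM + Kd_green_nM)
    occ_r <- fab_conc_red_nM / (fab_conc_red_nM + Kd_red_nM)
    out <- list(mode = "hetero",
                p_green = occ_g * det_g,   # detectable label on ErbB2
                p_red = occ_r * det_r,     # detectable label on ErbB3
                u_erbb2 = 1 - occ_g * det_g,
                u_erbb3 = 1 - occ_r * det_r)
  }
  class(out) <- "toccsl_labeling"
  out
}

#' @export
print.toccsl_labeling <- function(x, ...) {
  cat(sprintf("TOCCSL labeling (%s): p_green = %.3f, p_red = %.3f, u(ErbB3) = %.3f\n",
              x$mode, x$p_green, x$p_red, x$u_erbb3))
  invisible(x)
}
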