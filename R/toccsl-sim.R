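#' Simulate a full two-color TOCCSL dataset
#'
#' Emulates the TOCCSL protocol per cell on a periodic membrane field:
#' entities (monomers, homodimers, heterodimers, free ErbB2, optional higher
#' oligomers) are placed uniformly at the pre-bleach densities, receptors are
#' labeled per the labeling model, a bleach pulse irreversibly darkens every
#' entity that visits the slit aperture during the pulse, and after the
#' recovery interval the TOCCSL frame records localizations of live labels
#' inside the analysis window. The red channel is exposed `channel_gap_s`
#' after the green channel, so members of a true pair are displaced by
#' diffusion between the two exposures. Optional tracking frames follow the
#' TOCCSL frame at the tracking frame interval.
#'
#' Labels are assigned independently per receptor; a dimer carries the union
#' of its protomers' labels and both protomers share the entity position
#' exactly before localization noise is added. Spot intensities are sums of
#' per-fluorophore lognormal brightness draws (mean 100, CV 0.3).
#'
#' @param config a [sim_config()].
#' @param population a [population_spec()].
#' @param labeling a [labeling_spec()].
#' @param n_cells number of cells (independent fields).
#' @param seed optional integer seed (overrides `config$rng_seed`).
#' @return object of class `toccsl_dataset`: list with `cells` (per cell:
#'   `toccsl` localization data.frame, `postbleach_check`, `tracking`,
#'   `prebleach_density`), `ground_truth` (true fractions and per-cell entity
#'   tables), `config`, `population`, `labeling`.
#' @export
simulate_toccsl_dataset <- function(config, population, labeling,
                                    n_cells = 1, seed = NULL) {
  stopifnot(inherits(config, "toccsl_config"),
            inherits(population, "toccsl_population"),
            inherits(labeling, "toccsl_labeling"))
  if (n_cells < 1) stop("simulate_toccsl_dataset: n_cells must be >= 1")
  if (config$aperture_width_um > config$field_width_um)
    stop("simulate_toccsl_dataset: aperture larger than field")
  if (!is.null(seed)) set.seed(seed) else if (!is.null(config$rng_seed))
    set.seed(config$rng_seed)

  cells <- vector("list", n_cells)
  gt_cells <- vector("list", n_cells)
  for (ci in seq_len(n_cells)) {
    cell <- simulate_toccsl_cell(config, population, labeling, cell_id = ci)
    cells[[ci]] <- cell$observed
    gt_cells[[ci]] <- cell$truth
  }
  structure(list(cells = cells,
                 ground_truth = list(fractions = population$fractions,
                                     entities = gt_cells),
                 config = config, population = population,
                 labeling = labeling),
            class = "toccsl_dataset")
}

# one cell; assumes RNG state is set by the caller
simulate_toccsl_cell <- function(config, population, labeling, cell_id = 1L) {
  W <- config$field_width_um
  H <- config$field_height_um
  L <- config$aperture_width_um
  w <- config$analysis_width_um
  cx <- W / 2
  area <- W * H
  sp <- population$species
  sig <- config$localization_sigma_um

  counts <- rpois(nrow(sp), sp$entity_density * area)
  n_ent <- sum(counts)
  spi <- rep(seq_len(nrow(sp)), counts)
  D <- sp$D[spi]
  x <- runif(n_ent, 0, W)
  y <- runif(n_ent, 0, H)

  # --- label assignment, independent per receptor -------------------------
  n3 <- sp$n_erbb3[spi]
  n2 <- sp$n_erbb2[spi]
  if (labeling$mode == "homo") {
    # each ErbB3 protomer: green / red / unlabeled; ErbB2 protomers dark
    ng <- rbinom(n_ent, n3, labeling$p_green)
    nr <- vapply(seq_len(n_ent), function(i) {
      rest <- n3[i] - ng[i]
      if (rest == 0L) 0L else
        rbinom(1L, rest, labeling$p_red / max(1e-300, 1 - labeling$p_green))
    }, integer(1))
  } else {
    ng <- rbinom(n_ent, n2, labeling$p_green)   # green Fab on ErbB2
    nr <- rbinom(n_ent, n3, labeling$p_red)     # red Fab on ErbB3
  }

  prebleach_density <- list(
    green = sum(ng > 0) / area, red = sum(nr > 0) / area,
    erbb3_molecules = sum(n3) / area, erbb2_molecules = sum(n2) / area)

  # --- bleach pulse with motion: continuous bleaching inside the strip.
  # Between substeps, entities that dip into the strip are caught by the
  # Brownian-bridge edge-crossing probability, so absorption is exact in
  # continuous time regardless of the substep size.
  alive <- (ng + nr) > 0L
  n_sub <- 7L
  dt_sub <- config$bleach_duration_s / n_sub
  bleached <- in_strip(x, cx, L)
  for (k in seq_len(n_sub)) {
    x_prev <- x
    x_raw <- x + rnorm(n_ent, sd = sqrt(2 * D * dt_sub))
    y <- wrap(y + rnorm(n_ent, sd = sqrt(2 * D * dt_sub)), H)
    p_cross <- bridge_crossing_prob(x_prev, x_raw, cx, L, D, dt_sub)
    x <- wrap(x_raw, W)
    bleached <- bleached | in_strip(x, cx, L) |
      (runif(n_ent) < p_cross)
  }
  live <- alive & !bleached

  # --- postbleach check frame, 10 ms after the pulse ----------------------
  dt_chk <- 0.01
  x <- wrap(x + rnorm(n_ent, sd = sqrt(2 * D * dt_chk)), W)
  y <- wrap(y + rnorm(n_ent, sd = sqrt(2 * D * dt_chk)), H)
  chk <- live & in_strip(x, cx, L)
  postbleach_check <- emit_localizations(
    cell_id, frame = -1L, x, y, ng, nr, D, sp$species[spi], which(chk),
    sig, gap = 0, cx = cx, width = L, W = W, H = H)

  # --- recovery to the TOCCSL frame ---------------------------------------
  dt_rec <- config$recovery_time_s - dt_chk
  x <- wrap(x + rnorm(n_ent, sd = sqrt(2 * D * dt_rec)), W)
  y <- wrap(y + rnorm(n_ent, sd = sqrt(2 * D * dt_rec)), H)

  frames <- list()
  gap <- config$channel_gap_s
  sel <- which(live)
  frames[[1L]] <- emit_two_channel_frame(
    cell_id, frame = 0L, x, y, ng, nr, D, sp$species[spi], sel, sig, gap,
    cx, w, W, H)
  # advance past the red exposure of the TOCCSL frame
  x <- wrap(x + rnorm(n_ent, sd = sqrt(2 * D * gap)), W)
  y <- wrap(y + rnorm(n_ent, sd = sqrt(2 * D * gap)), H)

  if (config$n_tracking_frames > 0L) {
    dt <- config$frame_interval_s
    for (f in seq_len(config$n_tracking_frames)) {
      x <- wrap(x + rnorm(n_ent, sd = sqrt(2 * D * max(0, dt - gap))), W)
      y <- wrap(y + rnorm(n_ent, sd = sqrt(2 * D * max(0, dt - gap))), H)
      frames[[f + 1L]] <- emit_two_channel_frame(
        cell_id, frame = f, x, y, ng, nr, D, sp$species[spi], sel, sig, gap,
        cx, w, W, H)
      x <- wrap(x + rnorm(n_ent, sd = sqrt(2 * D * gap)), W)
      y <- wrap(y + rnorm(n_ent, sd = sqrt(2 * D * gap)), H)
    }
  }
  toccsl <- frames[[1L]]
  tracking <- if (length(frames) > 1L)
    do.call(rbind, frames[-1L]) else frames[[1L]][0, ]

  truth <- data.frame(cell_id = cell_id, entity_id = seq_len(n_ent),
                      species = sp$species[spi], D = D,
                      n_green = ng, n_red = nr, bleached = bleached,
                      stringsAsFactors = FALSE)
  list(observed = list(toccsl = toccsl, postbleach_check = postbleach_check,
                       tracking = tracking,
                       prebleach_density = prebleach_density),
       truth = truth)
}

wrap <- function(v, span) v %% span

in_strip <- function(x, cx, width) abs(x - cx) < width / 2

# probability that a 1D Brownian bridge (variance rate 2D) from x0 to x1
# over dt touched the strip [cx - L/2, cx + L/2]; both endpoints outside
# assumed (endpoints inside are handled by the caller). For a level e with
# both endpoints at distances d0, d1 on the same side:
# P(touch) = exp(-d0 d1 / (D dt)).
bridge_crossing_prob <- function(x0, x1, cx, L, D, dt) {
  p <- numeric(length(x0))
  denom <- D * dt
  for (e in c(cx - L / 2, cx + L / 2)) {
    s0 <- x0 - e
    s1 <- x1 - e
    straddle <- s0 * s1 <= 0
    pe <- numeric(length(x0))
    pe[straddle] <- 1                    # endpoints bracket the level
    ok <- !straddle & denom > 0
    pe[ok] <- exp(-abs(s0[ok] * s1[ok]) / denom[ok])
    p <- pmax(p, pe)
  }
  pmin(1, p)
}

brightness_draw <- function(n_fluor) {
  # per-fluorophore lognormal brightness, mean 100, CV 0.3
  sdlog <- sqrt(log(1 + 0.3^2))
  meanlog <- log(100) - sdlog^2 / 2
  vapply(n_fluor, function(k)
    if (k == 0L) 0 else sum(rlnorm(k, meanlog, sdlog)), numeric(1))
}

# emit localizations for one channel at the current positions
emit_localizations <- function(cell_id, frame, x, y, ng, nr, D, species, sel,
                               sig, gap, cx, width, W, H) {
  emit_two_channel_frame(cell_id, frame, x, y, ng, nr, D, species, sel, sig,
                         gap, cx, width, W, H)
}

# green exposure at current positions; red exposure `gap` seconds later
emit_two_channel_frame <- function(cell_id, frame, x, y, ng, nr, D, species,
                                   sel, sig, gap, cx, width, W, H) {
  xg <- x[sel]; yg <- y[sel]
  xr <- wrap(xg + rnorm(length(sel), sd = sqrt(2 * D[sel] * gap)), W)
  yr <- wrap(yg + rnorm(length(sel), sd = sqrt(2 * D[sel] * gap)), H)
  g_idx <- which(ng[sel] > 0L & in_strip(xg, cx, width))
  r_idx <- which(nr[sel] > 0L & in_strip(xr, cx, width))
  mk <- function(idx, ch, xx, yy, nf) {
    if (length(idx) == 0L)
      return(data.frame(cell_id = integer(0), frame = integer(0),
                        channel = character(0), x_um = numeric(0),
                        y_um = numeric(0), intensity = numeric(0),
                        sigma_xy_um = numeric(0), entity_id = integer(0),
                        species = character(0), stringsAsFactors = FALSE))
    data.frame(cell_id = cell_id, frame = frame, channel = ch,
               x_um = xx[idx] + rnorm(length(idx), sd = sig),
               y_um = yy[idx] + rnorm(length(idx), sd = sig),
               intensity = brightness_draw(nf[idx]),
               sigma_xy_um = sig,
               entity_id = sel[idx], species = species[sel][idx],
               stringsAsFactors = FALSE)
  }
  rbind(mk(g_idx, "green", xg, yg, ng[sel]),
        mk(r_idx, "red", xr, yr, nr[sel]))
}

#' @export
print.toccsl_dataset <- function(x, ...) {
  n_spots <- sum(vapply(x$cells, function(cl) nrow(cl$toccsl), numeric(1)))
  cat(sprintf("TOCCSL dataset: %d cell(s), %d TOCCSL-frame localizations\n",
              length(x$cells), n_spots))
  cat("True ErbB3 molecule fractions:\n")
  print(round(x$ground_truth$fractions, 4))
  invisible(x)
}

#' Write dataset localization tables to CSV
#'
#' One CSV per cell and frame class, in the schema
#' (cell_id, frame, channel, x_um, y_um, intensity, sigma_xy_um) plus
#' ground-truth columns (entity_id, species) when `ground_truth = TRUE`.
#'
#' @param dataset a `toccsl_dataset`.
#' @param dir output directory (created if missing).
#' @param ground_truth keep ground-truth columns.
#' @return invisibly, the written file paths.
#' @export
write_toccsl_csv <- function(dataset, dir, ground_truth = FALSE) {
  stopifnot(inherits(dataset, "toccsl_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  strip_gt <- function(df) {
    if (ground_truth) df else
      df[, setdiff(names(df), c("entity_id", "species")), drop = FALSE]
  }
  for (ci in seq_along(dataset$cells)) {
    cl <- dataset$cells[[ci]]
    for (what in c("toccsl", "postbleach_check", "tracking")) {
      p <- file.path(dir, sprintf("cell%03d_%s.csv", ci, what))
      write.csv(strip_gt(cl[[what]]), p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
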