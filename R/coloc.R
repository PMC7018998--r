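#' Mutual nearest-neighbor pairing within a pairing radius
#'
#' Pairs are (g, r) with d(g, r) <= radius where g is the nearest red
#' neighbor of r and vice versa; each spot participates in at most one pair.
#' Mutual-NN pairing is order-invariant and symmetric under channel swap.
#' Ties closer than 1e-9 um are broken by lowest spot index.
#'
#' @param locs_green,locs_red data.frames with columns `x_um`, `y_um`
#'   (registered into a common coordinate frame).
#' @param radius_um co-localization radius; one camera pixel (0.16 um) by
#'   default.
#' @return object of class `toccsl_coloc` with fields `n_green_only`,
#'   `n_red_only`, `n_pairs`, `pair_distances_um`, `pairs` (index matrix),
#'   `n_false_positive_expected` (NA until [estimate_false_positives()] is
#'   run), `radius_um`.
#' @export
pair_colocalized <- function(locs_green, locs_red, radius_um = 0.16) {
  ng <- NROW(locs_green)
  nr <- NROW(locs_red)
  pairs <- matrix(integer(0), 0, 2,
                  dimnames = list(NULL, c("green", "red")))
  dists <- numeric(0)
  if (ng > 0L && nr > 0L) {
    dx <- outer(locs_green$x_um, locs_red$x_um, "-")
    dy <- outer(locs_green$y_um, locs_red$y_um, "-")
    dm <- sqrt(dx^2 + dy^2)
    # index tie-break: shift by a negligible index-ordered epsilon
    eps <- 1e-12
    dm_t <- dm + outer(seq_len(ng), seq_len(nr), function(i, j) (i + j) * eps)
    nn_of_green <- apply(dm_t, 1, which.min)
    nn_of_red <- apply(dm_t, 2, which.min)
    mutual <- which(nn_of_red[nn_of_green] == seq_len(ng))
    keep <- mutual[dm[cbind(mutual, nn_of_green[mutual])] <= radius_um]
    if (length(keep)) {
      pairs <- cbind(green = keep, red = nn_of_green[keep])
      dists <- dm[pairs]
    }
  }
  structure(list(n_green_only = ng - nrow(pairs),
                 n_red_only = nr - nrow(pairs),
                 n_pairs = nrow(pairs),
                 pair_distances_um = dists,
                 pairs = pairs,
                 n_false_positive_expected = NA_real_,
                 radius_um = radius_um),
            class = "toccsl_coloc")
}

#' Expected spurious pair count by channel mirroring
#'
#' Reflects the red coordinates through the joint center of mass of all
#' signals -- once about the vertical axis (x -> 2 cx - x) and once about the
#' horizontal axis (y -> 2 cy - y) -- and reruns the pairing on each mirrored
#' configuration. The reflection destroys true molecular pairs but preserves
#' each channel's single-channel spatial statistics, so the mirrored pair
#' count estimates the accidental co-localizations. The default estimate is
#' the mean of the two reflections; `method = "point"` uses the single
#' 180-degree point reflection instead.
#'
#' @inheritParams pair_colocalized
#' @param method `"mirror_xy"` (mean of the two axis reflections, default) or
#'   `"point"` (point reflection through the center of mass).
#' @param center optional reflection center `c(x, y)` in um. By default the
#'   joint center of mass of all signals is used; when the aperture geometry
#'   is known, passing its center avoids the finite-sample misalignment of
#'   the narrow recovery bands after reflection (the spot pattern is
#'   symmetric about the aperture axis, not about the noisy data centroid).
#' @return expected number of false-positive pairs (>= 0), with attribute
#'   `n_fixed_points`: red spots left in place by a reflection (pathological
#'   self-pairs).
#' @export
estimate_false_positives <- function(locs_green, locs_red, radius_um = 0.16,
                                     method = c("mirror_xy", "point"),
                                     center = NULL) {
  method <- match.arg(method)
  if (NROW(locs_green) == 0L || NROW(locs_red) == 0L) {
    out <- 0
    attr(out, "n_fixed_points") <- 0L
    return(out)
  }
  if (is.null(center)) {
    allx <- c(locs_green$x_um, locs_red$x_um)
    ally <- c(locs_green$y_um, locs_red$y_um)
    cx <- mean(allx)
    cy <- mean(ally)
  } else {
    cx <- center[[1L]]
    cy <- center[[2L]]
  }
  reflect <- function(df, axis) {
    out <- df
    if (axis %in% c("x", "xy")) out$x_um <- 2 * cx - df$x_um
    if (axis %in% c("y", "xy")) out$y_um <- 2 * cy - df$y_um
    out
  }
  fixed <- 0L
  count_pairs <- function(red_m) {
    fixed <<- fixed + sum(abs(red_m$x_um - locs_red$x_um) < 1e-9 &
                            abs(red_m$y_um - locs_red$y_um) < 1e-9)
    pair_colocalized(locs_green, red_m, radius_um)$n_pairs
  }
  est <- if (method == "point") {
    count_pairs(reflect(locs_red, "xy"))
  } else {
    mean(c(count_pairs(reflect(locs_red, "x")),
           count_pairs(reflect(locs_red, "y"))))
  }
  if (fixed > 0L)
    warning("estimate_false_positives: ", fixed,
            " red spot(s) lie on a mirror axis; self-pairs possible")
  out <- max(0, est)
  attr(out, "n_fixed_points") <- fixed
  out
}

#' Corrected (false-positive subtracted) pair count
#'
#' @param counts a `toccsl_coloc` whose `n_false_positive_expected` is set.
#' @return `max(0, n_pairs - n_false_positive_expected)`; clipping at zero
#'   emits a warning.
#' @export
corrected_pair_count <- function(counts) {
  stopifnot(inherits(counts, "toccsl_coloc"))
  fp <- counts$n_false_positive_expected
  if (is.na(fp)) stop("corrected_pair_count: false-positive estimate missing")
  val <- counts$n_pairs - fp
  if (val < 0) {
    warning(sprintf(
      "corrected_pair_count: expected false positives (%.2f) exceed pairs (%d); clipped to 0",
      fp, counts$n_pairs))
    val <- 0
  }
  val
}

#' Run pairing and false-positive estimation on a TOCCSL frame
#'
#' Convenience wrapper: splits a localization table by channel, pairs at the
#' given radius and fills in the mirrored false-positive estimate.
#'
#' @param frame localization data.frame with `channel`, `x_um`, `y_um`.
#' @inheritParams estimate_false_positives
#' @return `toccsl_coloc` with `n_false_positive_expected` set.
#' @export
colocalize_frame <- function(frame, radius_um = 0.16,
                             method = c("mirror_xy", "point"),
                             center = NULL) {
  method <- match.arg(method)
  g <- frame[frame$channel == "green", , drop = FALSE]
  r <- frame[frame$channel == "red", , drop = FALSE]
  cc <- pair_colocalized(g, r, radius_um)
  cc$n_false_positive_expected <-
    as.numeric(estimate_false_positives(g, r, radius_um, method, center))
  cc
}

#' Per-cell co-localization counts for a simulated dataset
#'
#' The reflection center is the known aperture axis from the dataset's
#' configuration (field center), not the data centroid.
#'
#' @param dataset a `toccsl_dataset`.
#' @inheritParams colocalize_frame
#' @return list of `toccsl_coloc`, one per cell (TOCCSL frame only).
#' @export
colocalize_dataset <- function(dataset, radius_um = 0.16,
                               method = c("mirror_xy", "point")) {
  stopifnot(inherits(dataset, "toccsl_dataset"))
  method <- match.arg(method)
  center <- c(dataset$config$field_width_um / 2,
              dataset$config$field_height_um / 2)
  lapply(dataset$cells, function(cl)
    colocalize_frame(cl$toccsl, radius_um, method, center))
}

#' @export
print.toccsl_coloc <- function(x, ...) {
  cat(sprintf(
    "Co-localization: %d pairs (exp. FP %.2f), %d green-only, %d red-only, radius %.0f nm\n",
    x$n_pairs,
    x$n_false_positive_expected,
    x$n_green_only, x$n_red_only, 1000 * x$radius_um))
  invisible(x)
}
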