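#' Link localizations into trajectories
#'
#' Frame-to-frame mutual-nearest-neighbor linking: a localization in frame f
#' is linked to one in frame f+1 iff each is the other's nearest neighbor and
#' their distance is at most `max_disp_um`. Unlinked spots start new
#' trajectories. Ties closer than 1e-9 um are broken by lowest spot index.
#'
#' @param locs localization data.frame with columns `frame`, `x_um`, `y_um`
#'   and optionally `channel`.
#' @param max_disp_um maximum frame-to-frame displacement. The default
#'   3 * sqrt(4 * D_max * dt) uses `D_max` and `frame_interval_s`.
#' @param channel optional channel filter.
#' @param D_max diffusion ceiling used for the default search radius
#'   (um^2/s).
#' @param frame_interval_s frame interval used for the default search radius.
#' @return data.frame of the input rows plus a `trajectory_id` column,
#'   ordered by trajectory and frame; class `toccsl_trajectoryset` with
#'   attribute `frame_interval_s`.
#' @export
link_trajectories <- function(locs, max_disp_um = NULL, channel = NULL,
                              D_max = 0.3, frame_interval_s = 0.01) {
  if (!is.null(channel)) locs <- locs[locs$channel == channel, , drop = FALSE]
  if (is.null(max_disp_um)) max_disp_um <- 3 * sqrt(4 * D_max * frame_interval_s)
  if (NROW(locs) == 0L) {
    locs$trajectory_id <- integer(0)
    return(locs)
  }
  locs <- locs[order(locs$frame), , drop = FALSE]
  frames <- sort(unique(locs$frame))
  locs$trajectory_id <- NA_integer_
  next_id <- 1L
  rows_by_frame <- split(seq_len(nrow(locs)), locs$frame)
  prev <- rows_by_frame[[1L]]
  locs$trajectory_id[prev] <- seq_along(prev)
  next_id <- length(prev) + 1L
  for (k in seq_along(frames)[-1L]) {
    cur <- rows_by_frame[[k]]
    contiguous <- frames[k] == frames[k - 1L] + 1L
    if (contiguous && length(prev) > 0L && length(cur) > 0L) {
      dx <- outer(locs$x_um[prev], locs$x_um[cur], "-")
      dy <- outer(locs$y_um[prev], locs$y_um[cur], "-")
      dm <- sqrt(dx^2 + dy^2) +
        outer(seq_along(prev), seq_along(cur), function(i, j) (i + j) * 1e-12)
      nn_prev <- apply(dm, 1, which.min)   # for each prev: best cur
      nn_cur <- apply(dm, 2, which.min)    # for each cur: best prev
      for (i in seq_along(prev)) {
        j <- nn_prev[i]
        if (nn_cur[j] == i && dm[i, j] <= max_disp_um)
          locs$trajectory_id[cur[j]] <- locs$trajectory_id[prev[i]]
      }
    }
    new <- cur[is.na(locs$trajectory_id[cur])]
    if (length(new)) {
      locs$trajectory_id[new] <- seq(next_id, length.out = length(new))
      next_id <- next_id + length(new)
    }
    prev <- cur
  }
  locs <- locs[order(locs$trajectory_id, locs$frame), , drop = FALSE]
  rownames(locs) <- NULL
  attr(locs, "frame_interval_s") <- frame_interval_s
  class(locs) <- c("toccsl_trajectoryset", class(locs))
  locs
}
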