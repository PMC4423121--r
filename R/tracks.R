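#' Per-track growth statistics from plus-end comet tracks
#'
#' Computes, for every growth track, the mean growth speed (total path length
#' over elapsed time, reported in micrometres per minute), the duration in
#' seconds, and the net growth direction relative to the cell axis (directed
#' convention, from the first-to-last displacement). Path length rather than
#' net displacement is used for speed so that curved growth is not
#' under-counted; net displacement is used only for the direction.
#'
#' @param tracks a data.frame with columns `track_id`, `t_s`, `x_um`, `y_um`
#'   (long format, one row per sample), or a list of such per-track frames.
#' @param geometry a [cell_geometry()] used as the angular reference.
#' @return data.frame with one row per usable track: `track_id`,
#'   `speed_um_min`, `duration_s`, `direction_deg` (directed; `NA` for
#'   stationary tracks). Tracks with fewer than two samples are dropped with
#'   a warning.
#' @export
track_growth_stats <- function(tracks, geometry) {
  if (is.data.frame(tracks)) {
    tracks <- split(tracks, tracks$track_id)
  }
  rows <- list()
  dropped <- 0L
  for (tr in tracks) {
    tr <- tr[order(tr$t_s), , drop = FALSE]
    if (nrow(tr) < 2) {
      dropped <- dropped + 1L
      next
    }
    if (any(diff(tr$t_s) <= 0)) stop("track times must be strictly increasing")
    xy <- cbind(tr$x_um, tr$y_um)
    path <- sum(sqrt(rowSums((xy[-1, , drop = FALSE] -
                                xy[-nrow(xy), , drop = FALSE])^2)))
    dur <- tr$t_s[nrow(tr)] - tr$t_s[1]
    disp <- xy[nrow(xy), ] - xy[1, ]
    dir <- if (all(disp == 0)) NA_real_ else {
      angle_to_axis(xy[1, ], xy[nrow(xy), ], geometry, "directed")
    }
    rows[[length(rows) + 1L]] <- data.frame(
      track_id = as.character(tr$track_id[1]),
      speed_um_min = path / dur * 60,
      duration_s = dur,
      direction_deg = dir,
      stringsAsFactors = FALSE
    )
  }
  if (dropped > 0) {
    warning(dropped, " track(s) with < 2 samples excluded")
  }
  if (length(rows) == 0) {
    return(data.frame(track_id = character(), speed_um_min = numeric(),
                      duration_s = numeric(), direction_deg = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Directed angular sample from growth-track net directions
#'
#' One unit-weight directed angle per track with a defined net direction.
#'
#' @param stats output of [track_growth_stats()].
#' @return A directed [angular_sample()].
#' @export
track_direction_sample <- function(stats) {
  ang <- stats$direction_deg[!is.na(stats$direction_deg)]
  if (length(ang) == 0) stop("empty input: no tracks with a net direction")
  angular_sample(ang, 1, "directed")
}
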