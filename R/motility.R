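#' Detect microtubule sliding events in a photoactivated-mark trajectory
#'
#' A sliding event is scored when the mark moves more than
#' `displacement_threshold` micrometres from its current rest reference
#' (default 0.5 um). The event start is back-tracked to the last rest frame
#' before sustained motion began; the event closes when per-frame motion stays
#' below the noise floor for at least `min_rest_frames` consecutive frames,
#' after which the rest reference re-anchors at the new position. Events are
#' therefore disjoint in time. The mean event velocity is the path length
#' travelled during the event divided by its duration, and the `fast` flag
#' marks events with mean velocity above `fast_threshold` nm/s (default
#' 700 nm/s).
#'
#' @param trajectory data.frame with columns `t_s`, `x_um`, `y_um` (one mark,
#'   samples ordered in time); a `region_id` column is carried through.
#' @param displacement_threshold event opening threshold, micrometres.
#' @param noise_floor per-frame motion below this (micrometres) counts as
#'   rest; default 0.15 um = 3x a typical 50 nm localisation sigma.
#' @param min_rest_frames consecutive sub-noise frames required to close an
#'   event.
#' @param fast_threshold fast-event velocity cut, nm/s.
#' @return data.frame of events: `region_id`, `t_start_s`, `t_end_s`,
#'   `displacement_um` (maximum excursion from the pre-event reference),
#'   `path_um`, `velocity_nm_s`, `fast`, plus a `path` list-column of the
#'   event sample coordinates.
#' @export
detect_events <- function(trajectory, displacement_threshold = 0.5,
                          noise_floor = 0.15, min_rest_frames = 2,
                          fast_threshold = 700) {
  if (nrow(trajectory) < 3) stop("too short: need >= 3 samples")
  if (any(diff(trajectory$t_s) <= 0)) stop("times must be strictly increasing")
  region <- if ("region_id" %in% names(trajectory)) {
    as.character(trajectory$region_id[1])
  } else NA_character_
  t <- trajectory$t_s
  xy <- cbind(trajectory$x_um, trajectory$y_um)
  n <- nrow(xy)
  step <- c(NA, sqrt(rowSums((xy[-1, , drop = FALSE] -
                                xy[-n, , drop = FALSE])^2)))
  moving <- !is.na(step) & step > noise_floor

  events <- list()
  anchor_sum <- xy[1, ]
  anchor_n <- 1
  anchor <- anchor_sum
  in_event <- FALSE
  rest_run <- 0L
  ev_start <- NA_integer_
  ev_ref <- NULL
  last_emitted_end <- 0L

  close_event <- function(i_end) {
    idx <- ev_start:i_end
    pts <- xy[idx, , drop = FALSE]
    path <- sum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                                pts[-nrow(pts), , drop = FALSE])^2)))
    excursion <- max(sqrt((pts[, 1] - ev_ref[1])^2 + (pts[, 2] - ev_ref[2])^2))
    dur <- t[i_end] - t[ev_start]
    vel <- path * 1000 / dur
    data.frame(region_id = region,
               t_start_s = t[ev_start], t_end_s = t[i_end],
               displacement_um = excursion, path_um = path,
               velocity_nm_s = vel, fast = vel > fast_threshold,
               i_start = ev_start, i_end = i_end,
               stringsAsFactors = FALSE)
  }

  for (i in 2:n) {
    if (!in_event) {
      d <- euclid(xy[i, ], anchor)
      if (d > displacement_threshold) {
        # back-track: start = last rest frame before the run of moving steps
        k <- i
        while (k > last_emitted_end + 1L && moving[k]) k <- k - 1L
        in_event <- TRUE
        ev_start <- k
        ev_ref <- anchor
        rest_run <- 0L
      } else if (!moving[i]) {
        # still at rest: refine the anchor with the new rest position
        anchor_sum <- anchor_sum + xy[i, ]
        anchor_n <- anchor_n + 1
        anchor <- anchor_sum / anchor_n
      }
    } else {
      if (!moving[i]) {
        rest_run <- rest_run + 1L
        if (rest_run >= min_rest_frames) {
          i_end <- i - rest_run
          events[[length(events) + 1L]] <- close_event(i_end)
          last_emitted_end <- i_end
          in_event <- FALSE
          anchor_sum <- xy[i, ]
          anchor_n <- 1
          anchor <- anchor_sum
          rest_run <- 0L
        }
      } else {
        rest_run <- 0L
      }
    }
  }
  if (in_event) {
    i_end <- n - rest_run
    events[[length(events) + 1L]] <- close_event(i_end)
  }
  if (length(events) == 0) {
    out <- data.frame(region_id = character(), t_start_s = numeric(),
                      t_end_s = numeric(), displacement_um = numeric(),
                      path_um = numeric(), velocity_nm_s = numeric(),
                      fast = logical(), i_start = integer(),
                      i_end = integer(), stringsAsFactors = FALSE)
    out$path <- list()
    return(out)
  }
  out <- do.call(rbind, events)
  out$path <- lapply(seq_len(nrow(out)), function(j) {
    xy[out$i_start[j]:out$i_end[j], , drop = FALSE]
  })
  out
}

#' Classify a sliding event as paraxial, off-axis, or looping
#'
#' Looping takes precedence: if any two instantaneous direction estimates
#' within the event differ by more than `looping_turn` degrees (default 90),
#' the event is looping. Otherwise the net first-to-last direction is folded
#' onto the axial range and the event is paraxial when within
#' `paraxial_halfwidth` degrees of the cell axis (default 45, toward either
#' tip), else off-axis. Instantaneous directions are estimated from
#' frame-to-frame steps longer than `noise_floor`, so localisation jitter at
#' pauses does not create spurious turns.
#'
#' @param path numeric matrix (n x 2) of event sample coordinates in
#'   micrometres, or one row of [detect_events()] output via its `path` column.
#' @param geometry a [cell_geometry()].
#' @param paraxial_halfwidth,looping_turn classification thresholds, degrees.
#' @param noise_floor minimum step length (micrometres) for a direction
#'   estimate.
#' @return one of `"paraxial"`, `"off_axis"`, `"looping"`.
#' @export
classify_event <- function(path, geometry, paraxial_halfwidth = 45,
                           looping_turn = 90, noise_floor = 0.15) {
  path <- as.matrix(path)
  if (nrow(path) < 2) stop("degenerate input: event path needs >= 2 points")
  steps <- path[-1, , drop = FALSE] - path[-nrow(path), , drop = FALSE]
  len <- sqrt(rowSums(steps^2))
  use <- len > noise_floor
  if (!any(use)) use <- len == max(len)  # fall back to the largest step
  dirs <- vec_angle_deg(steps[use, 1], steps[use, 2])
  if (length(dirs) > 1) {
    dd <- abs(wrap_directed(outer(dirs, dirs, "-")))
    if (max(dd) > looping_turn) return("looping")
  }
  net <- path[nrow(path), ] - path[1, ]
  if (all(net == 0)) stop("degenerate input: zero net displacement")
  a <- abs(fold_axial(angle_to_axis(path[1, ], path[nrow(path), ],
                                    geometry, "directed")))
  if (a <= paraxial_halfwidth) "paraxial" else "off_axis"
}

#' Sliding-event frequency per activated region per minute
#'
#' @param events data.frame of events as returned by [detect_events()],
#'   optionally with a `class` column (from [classify_event()]).
#' @param n_regions number of activated regions observed.
#' @param observed_time_min observation time per region, minutes.
#' @return list with `rate` (events per region per minute), `rate_fast`, and
#'   `rate_by_class` (named vector, present classes only).
#' @examples
#' ev <- data.frame(fast = c(TRUE, rep(FALSE, 11)))
#' event_frequency(ev, n_regions = 4, observed_time_min = 1.5)$rate  # 2
#' @export
event_frequency <- function(events, n_regions, observed_time_min) {
  if (n_regions < 1) stop("invalid input: n_regions must be >= 1")
  if (observed_time_min <= 0) stop("invalid input: observation time must be > 0")
  denom <- n_regions * observed_time_min
  out <- list(rate = nrow(events) / denom)
  out$rate_fast <- if ("fast" %in% names(events)) sum(events$fast) / denom else NA_real_
  out$rate_by_class <- if ("class" %in% names(events) && nrow(events) > 0) {
    tapply(rep(1, nrow(events)), events$class, sum) / denom
  } else {
    setNames(numeric(0), character(0))
  }
  out
}

#' Restore bleaching losses using a double-drug control series
#'
#' Both series are first normalised to their own t = 0 value; the control's
#' fractional loss is then added back to the raw series:
#' `corrected(t) = raw_norm(t) + (1 - control_norm(t))`. The control (both
#' depolymerisation and transport suppressed) decays by photobleaching only,
#' so the correction restores, to first order in the bleached fraction, the
#' dissipation curve that would have been observed without bleaching.
#' `corrected(0) = 1` by construction and the correction is the identity when
#' the control does not bleach.
#'
#' @param raw,control data.frames with columns `t_s` and `intensity`, sharing
#'   the same timebase.
#' @return data.frame with `t_s` and corrected normalised `intensity`.
#' @export
bleach_correct <- function(raw, control) {
  if (nrow(raw) != nrow(control) ||
      any(abs(raw$t_s - control$t_s) > 1e-9)) {
    stop("alignment error: raw and control series must share the timebase")
  }
  raw_n <- raw$intensity / raw$intensity[1]
  ctl_n <- control$intensity / control$intensity[1]
  data.frame(t_s = raw$t_s, intensity = raw_n + (1 - ctl_n))
}

#' Fit a single-exponential dissipation curve and report the half-life
#'
#' Least-squares fit of `I(t) = A exp(-k t)` on the linear intensity scale
#' with free amplitude `A` (not pinned to 1), by profiling the amplitude in
#' closed form and searching the decay rate on a coarse grid refined with
#' [stats::optimize()]. A series whose best fit is non-decaying (k <= 0) is
#' reported with `half_life_s = Inf` and `decaying = FALSE` rather than as an
#' error.
#'
#' @param series data.frame with columns `t_s` and `intensity` (> 0),
#'   at least 5 time points.
#' @return Object of class `decay_fit`: list with `amplitude`, `rate_s`
#'   (k, per second), `half_life_s` (= ln 2 / k), `decaying`, `residual_rms`,
#'   and the fitted `series`.
#' @examples
#' t <- seq(0, 120, by = 3)
#' fit <- fit_half_life(data.frame(t_s = t, intensity = exp(-t * log(2) / 60)))
#' fit$half_life_s  # 60
#' @export
fit_half_life <- function(series) {
  if (nrow(series) < 5) stop("need >= 5 time points")
  t <- series$t_s
  y <- series$intensity
  if (any(y <= 0)) stop("intensities must be > 0")
  t0 <- t - t[1]
  span <- max(t0)
  sse <- function(k) {
    e <- exp(-k * t0)
    a <- sum(y * e) / sum(e * e)
    sum((y - a * e)^2)
  }
  kmax <- 50 / span
  grid <- seq(-kmax / 5, kmax, length.out = 201)
  vals <- vapply(grid, sse, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  k <- stats::optimize(sse, c(lo, hi), tol = 1e-12)$minimum
  e <- exp(-k * t0)
  a <- sum(y * e) / sum(e * e)
  decaying <- k > 1e-10
  structure(list(
    amplitude = a,
    rate_s = k,
    half_life_s = if (decaying) log(2) / k else Inf,
    decaying = decaying,
    residual_rms = sqrt(mean((y - a * e)^2)),
    series = series
  ), class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (x$decaying) {
    cat(sprintf("<decay_fit> k = %.5g /s, t1/2 = %.4g s, A = %.4g, RMS = %.3g\n",
                x$rate_s, x$half_life_s, x$amplitude, x$residual_rms))
  } else {
    cat("<decay_fit> non-decaying series (t1/2 = Inf)\n")
  }
  invisible(x)
}

#' Decompose fluorescence dissipation into component rates
#'
#' Given single-exponential fits of the dissipation curve under four drug
#' conditions — untreated, taxol (depolymerisation suppressed), azide
#' (motor-driven transport suppressed), and taxol+azide (bleaching only) —
#' recovers the component rates:
#' `k_bleach = k(taxol+azide)`, `k_transport = k(taxol) - k_bleach`,
#' `k_depoly = k(azide) - k_bleach`. The consistency residual
#' `k(none) - (k_depoly + k_transport + k_bleach)` is reported; a component
#' more negative than `-tol` triggers an inconsistency warning carrying the
#' value.
#'
#' @param fits named list of [fit_half_life()] fits (or raw rates, per
#'   second) for conditions `none`, `taxol`, `azide`, `taxol_azide`.
#' @param tol tolerance for negative component rates before warning.
#' @return list with `k_depoly`, `k_transport`, `k_bleach` (per second) and
#'   `consistency_residual`.
#' @export
dissipation_decomposition <- function(fits, tol = 1e-6) {
  need <- c("none", "taxol", "azide", "taxol_azide")
  if (!all(need %in% names(fits))) {
    stop("fits for all four conditions required: ",
         paste(setdiff(need, names(fits)), collapse = ", "), " missing")
  }
  rate <- function(f) if (inherits(f, "decay_fit")) f$rate_s else as.numeric(f)
  k_bleach <- rate(fits$taxol_azide)
  k_transport <- rate(fits$taxol) - k_bleach
  k_depoly <- rate(fits$azide) - k_bleach
  resid <- rate(fits$none) - (k_depoly + k_transport + k_bleach)
  for (nm in c(k_depoly = k_depoly, k_transport = k_transport)[
    c(k_depoly, k_transport) < -tol]) {
    warning("inconsistent decomposition: negative component rate ", nm)
  }
  list(k_depoly = k_depoly, k_transport = k_transport, k_bleach = k_bleach,
       consistency_residual = resid)
}
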