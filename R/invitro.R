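#' Encounter record between two dynamic microtubules
#'
#' Container for one seed-anchored filament encounter: two polylines ordered
#' seed-to-tip (vertex 1 anchors at the seed, the last vertex is the growing
#' plus end) and the contact point where the growing tip of `B` met the
#' lattice of `A`.
#'
#' @param id identifier.
#' @param A,B lists with `vertices` (n x 2 matrix, micrometres, ordered from
#'   seed to plus end); optional `crossovers_um` numeric vector of arc
#'   positions (from the seed) of prior crossover points.
#' @param contact length-2 numeric, contact point in micrometres.
#' @return Object of class `mt_encounter`.
#' @export
mt_encounter <- function(id, A, B, contact) {
  for (f in list(A, B)) {
    if (is.null(f$vertices) || nrow(f$vertices) < 2) {
      stop("each filament needs >= 2 vertices")
    }
  }
  structure(list(id = as.character(id), A = A, B = B,
                 contact = as.numeric(contact)),
            class = "mt_encounter")
}

# Arc position of the point on `poly` nearest to p; returns list(s, dist).
nearest_arc_position <- function(poly, p) {
  n <- nrow(poly)
  arc <- polyline_arclength(poly)
  best <- list(s = 0, dist = Inf)
  for (i in seq_len(n - 1)) {
    a <- poly[i, ]; b <- poly[i + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    tt <- if (len2 == 0) 0 else sum((p - a) * ab) / len2
    tt <- min(1, max(0, tt))
    q <- a + tt * ab
    d <- euclid(p, q)
    if (d < best$dist) best <- list(s = arc[i] + tt * sqrt(len2), dist = d)
  }
  best
}

# Mean unit tangent of `poly` over the arc window [s0, s1] (plus-end-ward).
mean_tangent <- function(poly, s0, s1) {
  arc <- polyline_arclength(poly)
  acc <- c(0, 0)
  for (i in seq_len(nrow(poly) - 1)) {
    lo <- max(arc[i], s0)
    hi <- min(arc[i + 1], s1)
    if (hi <= lo) next
    seg <- poly[i + 1, ] - poly[i, ]
    acc <- acc + seg / sqrt(sum(seg^2)) * (hi - lo)
  }
  nrm <- sqrt(sum(acc^2))
  if (nrm == 0) stop("geometry error: undefined tangent over requested window")
  acc / nrm
}

#' Incident angle between two filaments at their contact point
#'
#' The angle between the growth-direction tangents (toward the plus ends) of
#' the two filaments at the contact point, in \[0, 180\] degrees. Tangents are
#' averaged over `tangent_window` micrometres of arc on the incoming
#' (seed-ward) side of the contact to damp tracing noise on curved filaments.
#' By convention encounters at angles above 90 degrees are antiparallel.
#'
#' @param encounter an [mt_encounter()].
#' @param tangent_window arc length for tangent averaging, micrometres.
#' @param tol maximum distance (micrometres) allowed between the annotated
#'   contact and each polyline.
#' @return list with `angle_deg` in \[0, 180\] and `orientation`
#'   (`"parallel"` if <= 90 else `"antiparallel"`).
#' @export
encounter_angle <- function(encounter, tangent_window = 0.5, tol = 0.3) {
  tangents <- lapply(list(encounter$A, encounter$B), function(f) {
    hit <- nearest_arc_position(f$vertices, encounter$contact)
    if (hit$dist > tol) {
      stop("geometry error: contact point not on filament (distance ",
           format(hit$dist, digits = 3), " um)")
    }
    mean_tangent(f$vertices, max(0, hit$s - tangent_window), max(hit$s, 1e-6))
  })
  ca <- sum(tangents[[1]] * tangents[[2]])
  ca <- min(1, max(-1, ca))
  alpha <- rad2deg(acos(ca))
  list(angle_deg = alpha,
       orientation = if (alpha > 90) "antiparallel" else "parallel")
}

#' Classify an encounter outcome as zippered or crossed
#'
#' An encounter is zippered when, past the contact point, the growing
#' filament `B` runs along the lattice of `A` — inter-filament distance below
#' the co-alignment `gap` (default 0.1 um, a sub-resolution bundling proxy) —
#' for at least `min_coalign` micrometres (default 2 um), and the direction of
#' the co-aligned run is polarity-consistent with the encounter orientation
#' (same direction as `A`'s plus end for parallel encounters, opposite for
#' antiparallel). Otherwise it is crossed. Distances along the run are
#' smoothed over a +/- `smooth`/2 arc window before thresholding, so
#' vertex-level tracing noise (tens of nanometres) does not truncate a
#' genuine bundle while a diverging crossed filament still exceeds the gap
#' within well under the 2-um rule at all generated encounter angles.
#'
#' @param encounter an [mt_encounter()].
#' @param min_coalign minimum co-aligned run length, micrometres.
#' @param gap co-alignment distance threshold, micrometres.
#' @param smooth arc length of the distance-smoothing window, micrometres.
#' @param step arc sampling interval along `B`, micrometres.
#' @return list with `outcome` (`"zippered"`/`"crossed"`), `orientation`,
#'   `angle_deg`, and `coaligned_um` (the measured co-aligned run length).
#' @export
classify_outcome <- function(encounter, min_coalign = 2, gap = 0.1,
                             smooth = 1, step = 0.1) {
  ang <- encounter_angle(encounter)
  B <- encounter$B$vertices
  A <- encounter$A$vertices
  hitB <- nearest_arc_position(B, encounter$contact)
  arcB <- polyline_arclength(B)
  total <- arcB[length(arcB)]
  post_len <- total - hitB$s
  coaligned <- 0
  if (post_len > step) {
    s_grid <- seq(hitB$s, total, by = step)
    pts <- t(vapply(s_grid, function(s) point_at_arc(B, arcB, s), numeric(2)))
    d <- points_polyline_dist(pts, A)
    ds <- moving_mean_window(s_grid - hitB$s, d, smooth / 2)
    bad <- which(ds > gap)
    coaligned <- if (length(bad) == 0) post_len else s_grid[bad[1]] - hitB$s
  }
  polarity_ok <- TRUE
  if (coaligned >= min_coalign) {
    # direction of the co-aligned run vs A's plus-end tangent at contact
    run_dir <- mean_tangent(B, hitB$s, hitB$s + min(coaligned, min_coalign))
    hitA <- nearest_arc_position(A, encounter$contact)
    a_dir <- mean_tangent(A, max(0, hitA$s - 0.5), max(hitA$s, 1e-6))
    same <- sum(run_dir * a_dir) > 0
    polarity_ok <- if (ang$orientation == "parallel") same else !same
  }
  zip <- coaligned >= min_coalign && polarity_ok
  list(outcome = if (zip) "zippered" else "crossed",
       orientation = ang$orientation,
       angle_deg = ang$angle_deg,
       coaligned_um = coaligned)
}

# Point at arc position s along poly with precomputed arc lengths.
point_at_arc <- function(poly, arc, s) {
  if (s <= 0) return(poly[1, ])
  n <- length(arc)
  if (s >= arc[n]) return(poly[n, ])
  i <- findInterval(s, arc)
  f <- (s - arc[i]) / (arc[i + 1] - arc[i])
  poly[i, ] + f * (poly[i + 1, ] - poly[i, ])
}

#' Angle-resolved zippering histogram
#'
#' @param encounters data.frame with columns `angle_deg` (in \[0, 180\]) and
#'   `zippered` (logical).
#' @param bin_edges increasing bin edges in degrees covering \[0, 180\];
#'   default every 10 degrees.
#' @return data.frame per bin: `bin_lo`, `bin_hi`, `n`, `n_zippered`,
#'   `fraction` (NA for empty bins, not 0).
#' @export
zippering_histogram <- function(encounters, bin_edges = seq(0, 180, by = 10)) {
  a <- encounters$angle_deg
  if (any(a < 0 | a > 180)) stop("encounter angles must lie in [0, 180]")
  bins <- cut(a, breaks = bin_edges, include.lowest = TRUE, right = TRUE)
  n <- as.integer(table(bins))
  nz <- as.integer(tapply(encounters$zippered, bins, sum, default = 0L))
  nz[is.na(nz)] <- 0L
  data.frame(bin_lo = bin_edges[-length(bin_edges)],
             bin_hi = bin_edges[-1],
             n = n, n_zippered = nz,
             fraction = ifelse(n > 0, nz / n, NA_real_))
}

#' Arc length from the contact point to the seed (or nearest prior crossover)
#'
#' For each filament of an encounter, the distance along the filament from
#' the contact point back to its seed anchor, or to the nearest crossover
#' point on the seed side if one is annotated closer (`crossovers_um` arc
#' positions on the filament).
#'
#' @param encounter an [mt_encounter()].
#' @return named numeric: `len_A_um`, `len_B_um`.
#' @export
encounter_lengths <- function(encounter) {
  one <- function(f) {
    hit <- nearest_arc_position(f$vertices, encounter$contact)
    to_seed <- hit$s
    cx <- f$crossovers_um
    if (!is.null(cx) && length(cx) > 0) {
      prior <- cx[cx <= hit$s]
      if (length(prior) > 0) to_seed <- min(to_seed, hit$s - max(prior))
    }
    to_seed
  }
  c(len_A_um = one(encounter$A), len_B_um = one(encounter$B))
}

#' Select unsuccessful shallow-angle encounters
#'
#' Companion filter for length-control analyses: crossed encounters whose
#' incident angle folds into the shallow band 10-30 degrees (i.e. angle in
#' \[10, 30\] or \[150, 170\]).
#'
#' @param encounters data.frame with `angle_deg` and `zippered` columns.
#' @return logical vector selecting the shallow unsuccessful encounters.
#' @export
shallow_unsuccessful <- function(encounters) {
  a <- encounters$angle_deg
  shallow <- (a >= 10 & a <= 30) | (a >= 150 & a <= 170)
  shallow & !encounters$zippered
}

#' Instantaneous gliding speeds per object type
#'
#' Instantaneous speed is frame-to-frame displacement over the frame
#' interval, in nm/s. Tracks with fewer than two frames are excluded with a
#' warning.
#'
#' @param tracks data.frame with columns `object_id`, `type` (`"single"` /
#'   `"bundle"`), `t_s`, `x_um`, `y_um`.
#' @return list with `speeds` (data.frame `object_id`, `type`, `speed_nm_s`,
#'   one row per step), `per_object` (mean per object), and `summary` (mean
#'   and sd per type).
#' @export
gliding_speeds <- function(tracks) {
  parts <- split(tracks, tracks$object_id)
  rows <- list()
  dropped <- 0L
  for (tr in parts) {
    tr <- tr[order(tr$t_s), , drop = FALSE]
    if (nrow(tr) < 2) {
      dropped <- dropped + 1L
      next
    }
    d <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2) * 1000
    rows[[length(rows) + 1L]] <- data.frame(
      object_id = as.character(tr$object_id[1]),
      type = as.character(tr$type[1]),
      speed_nm_s = d / diff(tr$t_s),
      stringsAsFactors = FALSE
    )
  }
  if (dropped > 0) warning(dropped, " single-frame track(s) excluded")
  speeds <- do.call(rbind, rows)
  per_object <- stats::aggregate(speed_nm_s ~ object_id + type, speeds, mean)
  summary <- do.call(rbind, lapply(split(speeds, speeds$type), function(s) {
    data.frame(type = s$type[1], mean_nm_s = mean(s$speed_nm_s),
               sd_nm_s = stats::sd(s$speed_nm_s), n_steps = nrow(s),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(speeds = speeds, per_object = per_object, summary = summary)
}

#' Fraction of bundles surviving motor forces at a horizon
#'
#' Bundles that left the field of view or dissociated as an intact bundle are
#' right-censored and excluded; the survival fraction is intact-at-horizon
#' over (intact + separated).
#'
#' @param bundles data.frame with columns `survival_time_s` (time to
#'   separation, or end of observation if intact), `separated` (logical) and
#'   `censored` (logical).
#' @param horizon_s evaluation horizon in seconds.
#' @return survival fraction in \[0, 1\], or `NA` if all bundles are censored.
#' @examples
#' b <- data.frame(survival_time_s = c(rep(500, 9), rep(100, 3), 50, 60),
#'                 separated = c(rep(FALSE, 9), rep(TRUE, 3), FALSE, FALSE),
#'                 censored = c(rep(FALSE, 12), TRUE, TRUE))
#' bundle_survival(b, 450)  # 9/12
#' @export
bundle_survival <- function(bundles, horizon_s) {
  b <- bundles[!bundles$censored, , drop = FALSE]
  if (nrow(b) == 0) return(NA_real_)
  intact <- !b$separated | b$survival_time_s > horizon_s
  sum(intact) / nrow(b)
}

#' Count microtubule bundles from region length and brightness
#'
#' A region is scored as a bundle when it is longer than the length threshold
#' and at least threefold brighter than a single microtubule. Two presets
#' reflect the two published scoring variants: in cells, elongated regions of
#' more than 2.3 um with intensity ratio strictly above 3; in vitro, regions
#' at least three times as bright as single microtubules (ratio >= 3, length
#' threshold 2 um).
#'
#' @param regions data.frame with columns `length_um` and `intensity_ratio`.
#' @param mode `"cell"` (length > 2.3 um, ratio > 3) or `"invitro"`
#'   (length > 2 um, ratio >= 3).
#' @param len_threshold,ratio_threshold override the preset thresholds.
#' @return list with `n_bundles` and the per-region logical `is_bundle`.
#' @export
score_bundles <- function(regions, mode = c("cell", "invitro"),
                          len_threshold = NULL, ratio_threshold = NULL) {
  mode <- match.arg(mode)
  if (any(regions$intensity_ratio < 0)) stop("intensity ratios must be >= 0")
  len_thr <- len_threshold %||% if (mode == "cell") 2.3 else 2.0
  rat_thr <- ratio_threshold %||% 3
  is_bundle <- if (mode == "cell") {
    regions$length_um > len_thr & regions$intensity_ratio > rat_thr
  } else {
    regions$length_um > len_thr & regions$intensity_ratio >= rat_thr
  }
  list(n_bundles = sum(is_bundle), is_bundle = is_bundle)
}
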