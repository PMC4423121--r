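#' Configuration for the synthetic-data generators
#'
#' One validated configuration object drives every generator. A single root
#' `seed` is split into fixed per-generator child streams, so adding or
#' re-running one generator never perturbs the draws of another, and an
#' identical configuration yields bit-identical output.
#'
#' Defaults emulate the imaging conditions of the motivating experiments:
#' plus-end comets imaged every 3 s for 120 s; photoactivated marks every
#' 1.6 s for 60 s; an elongated (aspect 8) cell of 100 um; sliding-event
#' velocities log-normal with median 500 nm/s; dissipation rates giving
#' half-lives of order one to several minutes; gliding at 600 nm/s; bundle
#' breakup with a 450 s half-life; 250-ul gradient fractions over a 5-ml
#' gradient. See the package vignette for the rationale behind every default.
#'
#' @param seed integer root seed.
#' @param cell_length tip-to-tip cell length, micrometres.
#' @param cell_aspect outline aspect ratio (>= 1).
#' @param kappa von Mises concentration of filament orientations around the
#'   axis (0 = uniform).
#' @param n_filaments number of filaments per network.
#' @param filament_length_um mean filament length, micrometres.
#' @param vertex_spacing_um polyline vertex spacing, micrometres.
#' @param frame_interval_s,duration_s comet imaging interval and duration.
#' @param n_tracks number of growth tracks.
#' @param track_speed_mean,track_speed_sd growth speed distribution, um/min.
#' @param track_aligned_frac fraction of tracks growing along the axis.
#' @param track_kappa von Mises concentration of aligned track directions.
#' @param n_marks number of photoactivated marks.
#' @param mark_interval_s,mark_duration_s mark imaging interval and duration.
#' @param slide_rate sliding events per mark per minute.
#' @param velocity_logmean,velocity_logsd log-normal sliding velocity
#'   parameters, ln(nm/s).
#' @param class_probs named probabilities over `paraxial`, `off_axis`,
#'   `looping` (sum to 1).
#' @param loc_sigma_um localisation noise sigma on mark centroids (0 = none).
#' @param k_depoly,k_transport,k_bleach dissipation component rates, per s.
#' @param intensity_noise multiplicative intensity noise (sd, fraction).
#' @param n_encounters number of filament encounters.
#' @param zipper_prob_parallel,zipper_prob_antiparallel functions mapping an
#'   encounter angle in degrees to a zippering probability in \[0, 1\].
#' @param encounter_vertex_noise_um vertex noise on encounter polylines.
#' @param n_singles,n_bundles gliding-assay object counts.
#' @param v_glide_mean,v_glide_sd single-microtubule gliding speed, nm/s.
#' @param bundle_breakup_rate exponential bundle breakup rate, per s.
#' @param glide_interval_s,glide_duration_s gliding imaging parameters.
#' @param censor_frac fraction of bundles censored (left field / dissociated
#'   intact).
#' @param gradient_slope,gradient_intercept linear volume-to-S calibration
#'   (S per ul; S).
#' @param fraction_ul fraction volume, microlitres.
#' @param gradient_total_ul gradient volume, microlitres.
#' @param peak_width_ul Gaussian peak sigma, microlitres.
#' @param gradient_noise additive signal noise sd (fraction of peak).
#' @return Object of class `synth_config` (validated named list).
#' @export
synth_config <- function(seed = 1L,
                         cell_length = 100, cell_aspect = 8,
                         kappa = 4, n_filaments = 150,
                         filament_length_um = 8, vertex_spacing_um = 0.5,
                         frame_interval_s = 3, duration_s = 120,
                         n_tracks = 200,
                         track_speed_mean = 10, track_speed_sd = 2,
                         track_aligned_frac = 0.8, track_kappa = 20,
                         n_marks = 30,
                         mark_interval_s = 1.6, mark_duration_s = 60,
                         slide_rate = 1,
                         velocity_logmean = log(500), velocity_logsd = 0.4,
                         class_probs = c(paraxial = 0.6, off_axis = 0.25,
                                         looping = 0.15),
                         loc_sigma_um = 0.05,
                         k_depoly = 0.01, k_transport = 0.005,
                         k_bleach = 0.002,
                         intensity_noise = 0.05,
                         n_encounters = 200,
                         zipper_prob_parallel = function(a) ifelse(a < 25, 0.7, 0),
                         zipper_prob_antiparallel = function(a) ifelse(a > 150, 0.8, 0),
                         encounter_vertex_noise_um = 0,
                         n_singles = 50, n_bundles = 50,
                         v_glide_mean = 600, v_glide_sd = 50,
                         bundle_breakup_rate = log(2) / 450,
                         glide_interval_s = 2, glide_duration_s = 450,
                         censor_frac = 0.1,
                         gradient_slope = 0.0025, gradient_intercept = 0.5,
                         fraction_ul = 250, gradient_total_ul = 5000,
                         peak_width_ul = 400, gradient_noise = 0.03) {
  cfg <- as.list(environment())
  stopifnot_scalar_pos(cell_length, "cell_length")
  if (cell_aspect < 1) stop("invalid config: cell_aspect must be >= 1")
  stopifnot_scalar_pos(kappa, "kappa", strict = FALSE)
  if (n_filaments < 1) stop("invalid config: n_filaments must be >= 1")
  stopifnot_scalar_pos(frame_interval_s, "frame_interval_s")
  if (duration_s < 2 * frame_interval_s) {
    stop("invalid config: duration must cover at least 2 frames")
  }
  for (nm in c("slide_rate", "k_depoly", "k_transport", "k_bleach",
               "loc_sigma_um", "intensity_noise", "bundle_breakup_rate",
               "encounter_vertex_noise_um", "gradient_noise",
               "track_speed_sd", "v_glide_sd")) {
    stopifnot_scalar_pos(cfg[[nm]], nm, strict = FALSE)
  }
  stopifnot_scalar_pos(v_glide_mean, "v_glide_mean")
  if (abs(sum(class_probs) - 1) > 1e-9 || any(class_probs < 0)) {
    stop("invalid config: class_probs must be non-negative and sum to 1")
  }
  if (!all(c("paraxial", "off_axis", "looping") %in% names(class_probs))) {
    stop("invalid config: class_probs must name paraxial, off_axis, looping")
  }
  if (track_aligned_frac < 0 || track_aligned_frac > 1) {
    stop("invalid config: track_aligned_frac must be in [0, 1]")
  }
  if (gradient_slope == 0) stop("invalid config: gradient_slope must be nonzero")
  probe <- c(0, 45, 90, 135, 180)
  for (fnm in c("zipper_prob_parallel", "zipper_prob_antiparallel")) {
    p <- cfg[[fnm]](probe)
    if (any(p < 0 | p > 1)) {
      stop("invalid config: ", fnm, " must map [0, 180] into [0, 1]")
    }
  }
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config> seed", x$seed, "| cell", x$cell_length, "um (aspect",
      paste0(x$cell_aspect, ")"), "| kappa", x$kappa, "|", x$n_filaments,
      "filaments,", x$n_tracks, "tracks,", x$n_marks, "marks\n")
  invisible(x)
}

#' Generate a synthetic filament network inside an elongated cell
#'
#' Filament orientations are axial von Mises around the cell axis: the
#' doubled orientation angle is von Mises with concentration `kappa` on the
#' full circle, so `kappa = 0` gives uniform orientations on (-90, 90] and
#' large `kappa` concentrates filaments along the axis. Filaments are
#' straight polylines clipped to the elliptical outline.
#'
#' @param config a [synth_config()].
#' @return list with `geometry` ([cell_geometry()]), `filaments` (list of
#'   [filament_trace()]), and `truth` (list with `kappa` and per-filament
#'   `orientation_deg`).
#' @export
gen_filament_network <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(child_seed(config$seed, "filament_network"))
  geom <- ellipse_cell(config$cell_length, config$cell_aspect)
  a <- config$cell_length / 2
  b <- a / config$cell_aspect
  theta <- rad2deg(rvonmises(config$n_filaments, 0, config$kappa)) / 2
  filaments <- vector("list", config$n_filaments)
  for (i in seq_len(config$n_filaments)) {
    # start point uniform in the ellipse (rejection from bounding box)
    repeat {
      p <- c(stats::runif(1, -a, a), stats::runif(1, -b, b))
      if ((p[1] / a)^2 + (p[2] / b)^2 <= 1) break
    }
    u <- c(cos(deg2rad(theta[i])), sin(deg2rad(theta[i])))
    len <- stats::rlnorm(1, log(config$filament_length_um), 0.3)
    # clip the segment centred on p to the ellipse interior
    tmax <- ellipse_ray_extent(p, u, a, b)
    tmin <- -ellipse_ray_extent(p, -u, a, b)
    lo <- max(tmin, -len / 2)
    hi <- min(tmax, len / 2)
    if (hi - lo < 1e-3) {
      lo <- tmin
      hi <- min(tmax, tmin + max(len, 1e-2))
    }
    s <- seq(lo, hi, by = config$vertex_spacing_um)
    if (length(s) < 2 || s[length(s)] < hi) s <- c(s, hi)
    verts <- cbind(p[1] + s * u[1], p[2] + s * u[2])
    filaments[[i]] <- filament_trace(paste0("f", i), verts)
  }
  list(geometry = geom, filaments = filaments,
       truth = list(kappa = config$kappa, orientation_deg = theta))
}

# Largest t >= 0 with p + t*u inside the (a, b) ellipse (0.999 safety factor).
ellipse_ray_extent <- function(p, u, a, b) {
  A <- (u[1] / a)^2 + (u[2] / b)^2
  B <- 2 * (p[1] * u[1] / a^2 + p[2] * u[2] / b^2)
  C <- (p[1] / a)^2 + (p[2] / b)^2 - 1
  disc <- B^2 - 4 * A * C
  if (disc <= 0) return(0)
  t <- (-B + sqrt(disc)) / (2 * A)
  max(0, t * 0.999)
}

#' Generate synthetic plus-end growth tracks
#'
#' Per-track growth speed is normal (`track_speed_mean`, `track_speed_sd`,
#' truncated at a small positive floor); directions are a mixture of
#' axis-aligned (von Mises around 0 with concentration `track_kappa`; exactly
#' 0 when `track_kappa = Inf`) and uniform, with aligned fraction
#' `track_aligned_frac`. Tracks advance in a straight line and are sampled at
#' the comet frame interval for a random whole number of frames.
#'
#' @param config a [synth_config()].
#' @return list with `tracks` (long data.frame: `track_id`, `frame`, `t_s`,
#'   `x_um`, `y_um`), `geometry`, and `truth` (per-track `speed_um_min`,
#'   `direction_deg`, `aligned`).
#' @export
gen_growth_tracks <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (config$duration_s < 2 * config$frame_interval_s) {
    stop("invalid config: duration must cover at least 2 frames")
  }
  set.seed(child_seed(config$seed, "growth_tracks"))
  geom <- ellipse_cell(config$cell_length, config$cell_aspect)
  n <- config$n_tracks
  aligned <- stats::runif(n) < config$track_aligned_frac
  dirs <- numeric(n)
  n_al <- sum(aligned)
  if (n_al > 0) {
    dirs[aligned] <- if (is.infinite(config$track_kappa)) 0 else {
      rad2deg(rvonmises(n_al, 0, config$track_kappa))
    }
  }
  if (n_al < n) dirs[!aligned] <- stats::runif(n - n_al, -180, 180)
  speeds <- pmax(0.1, stats::rnorm(n, config$track_speed_mean,
                                   config$track_speed_sd))
  if (config$track_speed_sd == 0) speeds <- rep(config$track_speed_mean, n)
  nmax <- floor(config$duration_s / config$frame_interval_s)
  nframes <- sample(2:max(2, nmax), n, replace = TRUE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    t <- (seq_len(nframes[i] + 1) - 1) * config$frame_interval_s
    v_um_s <- speeds[i] / 60
    u <- c(cos(deg2rad(dirs[i])), sin(deg2rad(dirs[i])))
    x0 <- c(stats::runif(1, -config$cell_length / 4, config$cell_length / 4),
            stats::runif(1, -config$cell_length / (4 * config$cell_aspect),
                         config$cell_length / (4 * config$cell_aspect)))
    rows[[i]] <- data.frame(track_id = paste0("t", i),
                            frame = seq_along(t), t_s = t,
                            x_um = x0[1] + v_um_s * t * u[1],
                            y_um = x0[2] + v_um_s * t * u[2],
                            stringsAsFactors = FALSE)
  }
  list(tracks = do.call(rbind, rows), geometry = geom,
       truth = data.frame(track_id = paste0("t", seq_len(n)),
                          speed_um_min = speeds, direction_deg = dirs,
                          aligned = aligned, stringsAsFactors = FALSE))
}

#' Generate photoactivated-mark trajectories with injected sliding events
#'
#' Marks are stationary (up to isotropic Gaussian localisation noise of sigma
#' `loc_sigma_um`) except during injected sliding events. The number of
#' events per mark is Poisson with mean `slide_rate * duration / 60`; events
#' that cannot be placed without overlapping are dropped (the ground truth
#' records only what was injected). Event velocities are log-normal, the
#' direction class is drawn from `class_probs` (paraxial runs within 30
#' degrees of the axis, off-axis runs at 50-85 degrees, looping runs turn
#' through 100-160 degrees), and event displacements are 1-2.5 um so every
#' injected event exceeds the 0.5-um scoring threshold. Mark intensity decays
#' as `exp(-(k_depoly + k_transport + k_bleach) t)` with condition flags
#' zeroing the corresponding rate (taxol suppresses depolymerisation, azide
#' suppresses transport), times multiplicative noise.
#'
#' @param config a [synth_config()].
#' @param conditions character vector of conditions to generate, from
#'   `"none"`, `"taxol"`, `"azide"`, `"taxol_azide"`; `n_marks` marks each.
#' @return list with `marks` (long data.frame: `region_id`, `condition`,
#'   `frame`, `t_s`, `x_um`, `y_um`, `intensity`), `geometry`, and `truth`
#'   (list with `events` data.frame — `region_id`, `t_start_s`, `t_end_s`,
#'   `velocity_nm_s`, `class`, `displacement_um` — and per-condition
#'   `rates` / `half_life_s`).
#' @export
gen_mark_trajectories <- function(config, conditions = "none") {
  stopifnot(inherits(config, "synth_config"))
  bad <- setdiff(conditions, c("none", "taxol", "azide", "taxol_azide"))
  if (length(bad) > 0) stop("unknown condition(s): ", paste(bad, collapse = ", "))
  set.seed(child_seed(config$seed, "mark_trajectories"))
  geom <- ellipse_cell(config$cell_length, config$cell_aspect)
  dt <- config$mark_interval_s
  nframes <- floor(config$mark_duration_s / dt) + 1
  t_grid <- (seq_len(nframes) - 1) * dt

  cond_rates <- function(cond) {
    kd <- if (cond %in% c("taxol", "taxol_azide")) 0 else config$k_depoly
    kt <- if (cond %in% c("azide", "taxol_azide")) 0 else config$k_transport
    c(k_depoly = kd, k_transport = kt, k_bleach = config$k_bleach)
  }

  marks <- list()
  truth_events <- list()
  for (cond in conditions) {
    rates <- cond_rates(cond)
    k_tot <- sum(rates)
    for (m in seq_len(config$n_marks)) {
      id <- paste0(cond, "_m", m)
      pos <- matrix(0, nframes, 2)
      occupied <- rep(FALSE, nframes)  # frames involved in an event or buffer
      n_ev <- stats::rpois(1, config$slide_rate * config$mark_duration_s / 60)
      # choose non-overlapping event windows first, then replay in time order
      specs <- list()
      if (n_ev > 0) {
        for (e in seq_len(n_ev)) {
          v <- stats::rlnorm(1, config$velocity_logmean, config$velocity_logsd)
          disp_target <- stats::runif(1, 1, 2.5)
          cls <- sample(names(config$class_probs), 1,
                        prob = config$class_probs)
          # looping runs need >= 3 steps so the curved path still exceeds the
          # 0.5-um scoring excursion by construction
          min_frames <- if (cls == "looping") 3 else 2
          dur_frames <- max(min_frames,
                            min(15, round(disp_target * 1000 / (v * dt))))
          gap <- 3L  # rest frames around events so segmentation is unambiguous
          ok_start <- which(vapply(seq_len(nframes), function(s) {
            s + dur_frames <= nframes &&
              !any(occupied[max(1, s - gap):min(nframes, s + dur_frames + gap)])
          }, logical(1)))
          if (length(ok_start) == 0) next
          s <- ok_start[sample.int(length(ok_start), 1)]
          headings <- switch(
            cls,
            paraxial = rep(sample(c(0, 180), 1) +
                             stats::runif(1, -30, 30), dur_frames),
            off_axis = rep(sample(c(-1, 1), 1) * stats::runif(1, 50, 85) +
                             sample(c(0, 180), 1), dur_frames),
            looping = {
              h0 <- stats::runif(1, -180, 180)
              turn <- sample(c(-1, 1), 1) * stats::runif(1, 100, 160)
              h0 + seq(0, turn, length.out = dur_frames)
            }
          )
          occupied[s:min(nframes, s + dur_frames)] <- TRUE
          specs[[length(specs) + 1L]] <- list(
            s = s, dur = dur_frames, v = v, cls = cls, headings = headings)
        }
      }
      ev_rows <- list()
      if (length(specs) > 0) {
        specs <- specs[order(vapply(specs, `[[`, numeric(1), "s"))]
        for (sp in specs) {
          step_len <- sp$v * dt / 1000
          p <- pos[sp$s, ]
          for (j in seq_len(sp$dur)) {
            p <- p + step_len * c(cos(deg2rad(sp$headings[j])),
                                  sin(deg2rad(sp$headings[j])))
            pos[sp$s + j, ] <- p
          }
          if (sp$s + sp$dur < nframes) {
            pos[(sp$s + sp$dur + 1):nframes, 1] <- p[1]
            pos[(sp$s + sp$dur + 1):nframes, 2] <- p[2]
          }
          path <- pos[sp$s:(sp$s + sp$dur), , drop = FALSE]
          ev_rows[[length(ev_rows) + 1L]] <- data.frame(
            region_id = id, condition = cond,
            t_start_s = t_grid[sp$s], t_end_s = t_grid[sp$s + sp$dur],
            velocity_nm_s = sp$v, class = sp$cls,
            displacement_um = max(sqrt((path[, 1] - path[1, 1])^2 +
                                         (path[, 2] - path[1, 2])^2)),
            stringsAsFactors = FALSE)
        }
      }
      noise <- if (config$loc_sigma_um > 0) {
        matrix(stats::rnorm(2 * nframes, 0, config$loc_sigma_um), nframes, 2)
      } else 0
      intensity <- exp(-k_tot * t_grid)
      if (config$intensity_noise > 0) {
        intensity <- intensity *
          (1 + stats::rnorm(nframes, 0, config$intensity_noise))
        intensity <- pmax(intensity, 1e-6)
      }
      marks[[length(marks) + 1L]] <- data.frame(
        region_id = id, condition = cond, frame = seq_len(nframes),
        t_s = t_grid,
        x_um = pos[, 1] + if (is.matrix(noise)) noise[, 1] else 0,
        y_um = pos[, 2] + if (is.matrix(noise)) noise[, 2] else 0,
        intensity = intensity, stringsAsFactors = FALSE)
      if (length(ev_rows) > 0) {
        truth_events[[length(truth_events) + 1L]] <- do.call(rbind, ev_rows)
      }
    }
  }
  rates_by_cond <- lapply(stats::setNames(conditions, conditions), cond_rates)
  list(
    marks = do.call(rbind, marks),
    geometry = geom,
    truth = list(
      events = if (length(truth_events) > 0) {
        do.call(rbind, truth_events)
      } else {
        data.frame(region_id = character(), condition = character(),
                   t_start_s = numeric(), t_end_s = numeric(),
                   velocity_nm_s = numeric(), class = character(),
                   displacement_um = numeric(), stringsAsFactors = FALSE)
      },
      rates = rates_by_cond,
      half_life_s = vapply(rates_by_cond, function(r) log(2) / sum(r),
                           numeric(1))
    )
  )
}

#' Generate synthetic dynamic-filament encounters
#'
#' Each encounter places a target filament `A` (straight, seed-anchored) and
#' an incoming filament `B` whose growth direction meets `A` at an incident
#' angle drawn uniformly from \[5, 175\] degrees. The outcome is sampled from
#' the configured angle-dependent zippering probabilities (parallel branch
#' for angles <= 90, antiparallel above). Zippered geometries bend `B` at the
#' contact to run along `A`'s lattice (at a 30-nm lattice offset) for
#' 2.3-3.5 um, satisfying the 2-um co-alignment rule by construction; crossed
#' geometries continue straight through. The whole scene is randomly rotated
#' and optional Gaussian vertex noise is added.
#'
#' @param config a [synth_config()].
#' @return list with `encounters` (list of [mt_encounter()]), and `truth`
#'   (data.frame: `id`, `angle_deg`, `orientation`, `zippered`,
#'   `coaligned_um`, `len_A_um`, `len_B_um`).
#' @export
gen_encounters <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(child_seed(config$seed, "encounters"))
  n <- config$n_encounters
  encs <- vector("list", n)
  truth <- vector("list", n)
  spacing <- 0.1
  for (i in seq_len(n)) {
    alpha <- stats::runif(1, 5, 175)
    orientation <- if (alpha > 90) "antiparallel" else "parallel"
    p_zip <- if (orientation == "parallel") {
      config$zipper_prob_parallel(alpha)
    } else {
      config$zipper_prob_antiparallel(alpha)
    }
    zippered <- stats::runif(1) < p_zip
    coaligned <- if (zippered) stats::runif(1, 2.3, 3.5) else 0
    L_A_pre <- stats::runif(1, 4, 6)    # seed-to-contact on A
    L_A_post <- stats::runif(1, 4, 6)   # contact-to-tip on A
    L_B_pre <- stats::runif(1, 2, 5)    # seed-to-contact on B
    uB <- c(cos(deg2rad(alpha)), sin(deg2rad(alpha)))
    # A: seed at (-L_A_pre, 0), plus end at (L_A_post, 0); contact at origin
    sA <- seq(-L_A_pre, L_A_post, by = spacing)
    if (sA[length(sA)] < L_A_post) sA <- c(sA, L_A_post)
    vA <- cbind(sA, 0)
    # B: approaches the contact from its seed along uB
    sB_pre <- seq(-L_B_pre, 0, by = spacing)
    if (sB_pre[length(sB_pre)] < 0) sB_pre <- c(sB_pre, 0)
    vB_pre <- cbind(sB_pre * uB[1], sB_pre * uB[2])
    if (zippered) {
      run_dir <- if (orientation == "parallel") c(1, 0) else c(-1, 0)
      sB_post <- seq(spacing, coaligned, by = spacing)
      offset <- c(0, 0.03)  # lattice offset of the zippered run
      vB_post <- cbind(offset[1] + sB_post * run_dir[1],
                       offset[2] + sB_post * run_dir[2])
    } else {
      L_B_post <- stats::runif(1, 3, 5)
      sB_post <- seq(spacing, L_B_post, by = spacing)
      vB_post <- cbind(sB_post * uB[1], sB_post * uB[2])
    }
    vB <- rbind(vB_pre, vB_post)
    # random rigid motion of the whole scene
    phi <- stats::runif(1, -pi, pi)
    R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
    shift <- stats::runif(2, -10, 10)
    xf <- function(v) sweep(v %*% t(R), 2, -shift)
    vA <- xf(vA)
    vB <- xf(vB)
    contact <- as.numeric(xf(matrix(0, 1, 2)))
    if (config$encounter_vertex_noise_um > 0) {
      vA <- vA + matrix(stats::rnorm(length(vA), 0,
                                     config$encounter_vertex_noise_um),
                        ncol = 2)
      vB <- vB + matrix(stats::rnorm(length(vB), 0,
                                     config$encounter_vertex_noise_um),
                        ncol = 2)
    }
    encs[[i]] <- mt_encounter(paste0("e", i),
                              A = list(vertices = vA),
                              B = list(vertices = vB),
                              contact = contact)
    truth[[i]] <- data.frame(
      id = paste0("e", i), angle_deg = alpha, orientation = orientation,
      zippered = zippered, coaligned_um = coaligned,
      len_A_um = L_A_pre, len_B_um = L_B_pre, stringsAsFactors = FALSE)
  }
  list(encounters = encs, truth = do.call(rbind, truth))
}

#' Generate synthetic gliding-assay tracks
#'
#' Single microtubules glide persistently in a fixed random direction with
#' per-frame speeds normal around `v_glide_mean`. Bundles jitter in place
#' (sub-resolution Brownian wobble) until an exponential breakup time with
#' rate `bundle_breakup_rate`; tracks of bundles that separate end at the
#' breakup (the fragments then glide apart at single-microtubule speed and
#' are no longer the bundle object). A fraction of bundles is censored
#' (moved out of the field or dissociated intact).
#'
#' @param config a [synth_config()].
#' @return list with `tracks` (long data.frame: `object_id`, `type`, `frame`,
#'   `t_s`, `x_um`, `y_um`), `meta` (per-bundle `survival_time_s`,
#'   `separated`, `censored`), and `truth` (list with `v_mean_nm_s`,
#'   `breakup_rate`).
#' @export
gen_gliding_tracks <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(child_seed(config$seed, "gliding"))
  dt <- config$glide_interval_s
  t_grid <- seq(0, config$glide_duration_s, by = dt)
  nf <- length(t_grid)
  rows <- list()
  meta <- list()
  for (i in seq_len(config$n_singles)) {
    dir <- stats::runif(1, -pi, pi)
    sp <- pmax(0, stats::rnorm(nf - 1, config$v_glide_mean, config$v_glide_sd))
    if (config$v_glide_sd == 0) sp <- rep(config$v_glide_mean, nf - 1)
    steps <- sp * dt / 1000
    x <- cumsum(c(stats::runif(1, 0, 50), steps * cos(dir)))
    y <- cumsum(c(stats::runif(1, 0, 50), steps * sin(dir)))
    rows[[length(rows) + 1L]] <- data.frame(
      object_id = paste0("s", i), type = "single", frame = seq_len(nf),
      t_s = t_grid, x_um = x, y_um = y, stringsAsFactors = FALSE)
  }
  for (i in seq_len(config$n_bundles)) {
    breakup <- if (config$bundle_breakup_rate > 0) {
      stats::rexp(1, config$bundle_breakup_rate)
    } else Inf
    censored <- stats::runif(1) < config$censor_frac
    separated <- !censored && breakup <= config$glide_duration_s
    t_obs <- if (censored) {
      stats::runif(1, config$glide_duration_s / 4, config$glide_duration_s)
    } else {
      min(breakup, config$glide_duration_s)
    }
    nfo <- max(2, floor(t_obs / dt) + 1)
    jitter <- matrix(stats::rnorm(2 * nfo, 0, 0.01), nfo, 2)
    rows[[length(rows) + 1L]] <- data.frame(
      object_id = paste0("b", i), type = "bundle", frame = seq_len(nfo),
      t_s = t_grid[seq_len(nfo)],
      x_um = stats::runif(1, 0, 50) + jitter[, 1],
      y_um = stats::runif(1, 0, 50) + jitter[, 2],
      stringsAsFactors = FALSE)
    meta[[length(meta) + 1L]] <- data.frame(
      object_id = paste0("b", i),
      survival_time_s = min(breakup, t_obs),
      separated = separated, censored = censored,
      breakup_time_s = breakup, stringsAsFactors = FALSE)
  }
  list(tracks = do.call(rbind, rows), meta = do.call(rbind, meta),
       truth = list(v_mean_nm_s = config$v_glide_mean,
                    breakup_rate = config$bundle_breakup_rate))
}

#' Generate a synthetic gradient fraction profile
#'
#' A Gaussian band of sigma `peak_width_ul` centred at the volume where the
#' configured linear calibration `S = slope * v + intercept` equals `true_S`,
#' sampled at the fraction grid, plus additive Gaussian signal noise.
#'
#' @param config a [synth_config()].
#' @param true_S true sedimentation coefficient, Svedberg.
#' @param label profile label.
#' @param stream_offset integer added to the child seed so that several
#'   profiles drawn from one config are independent yet reproducible.
#' @return list with `profile` (data.frame `label`, `volume_ul`, `signal`)
#'   and `truth` (list `S`, `peak_volume_ul`).
#' @export
gen_gradient_profile <- function(config, true_S, label = "sample",
                                 stream_offset = 0L) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(as.integer((child_seed(config$seed, "gradient") +
                         as.numeric(stream_offset) * 7919) %% 2147483647))
  peak_v <- (true_S - config$gradient_intercept) / config$gradient_slope
  v <- seq(config$fraction_ul, config$gradient_total_ul,
           by = config$fraction_ul)
  sig <- exp(-(v - peak_v)^2 / (2 * config$peak_width_ul^2))
  if (config$gradient_noise > 0) {
    sig <- pmax(0, sig + stats::rnorm(length(v), 0, config$gradient_noise))
  }
  list(profile = data.frame(label = label, volume_ul = v, signal = sig,
                            stringsAsFactors = FALSE),
       truth = list(S = true_S, peak_volume_ul = peak_v))
}

#' Generate synthetic cell morphology records
#'
#' Tip-to-tip lengths are normal per condition; nuclei counts mix
#' mono-/bi-nucleated and syncytial cells with the given fused fraction.
#'
#' @param config a [synth_config()] (seed stream only).
#' @param conditions data.frame with columns `condition`, `mean_um`, `sd_um`,
#'   `n`, `fused_frac`.
#' @return data.frame: `cell_id`, `condition`, `length_um`, `nuclei`.
#' @export
gen_cell_records <- function(config, conditions) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(child_seed(config$seed, "morphology"))
  out <- list()
  for (j in seq_len(nrow(conditions))) {
    cd <- conditions[j, ]
    len <- pmax(5, stats::rnorm(cd$n, cd$mean_um, cd$sd_um))
    fused <- stats::runif(cd$n) < cd$fused_frac
    nuclei <- ifelse(fused, 3L + stats::rpois(cd$n, 2),
                     sample(1:2, cd$n, replace = TRUE, prob = c(0.8, 0.2)))
    out[[j]] <- data.frame(
      cell_id = paste0(cd$condition, "_c", seq_len(cd$n)),
      condition = cd$condition, length_um = len, nuclei = as.integer(nuclei),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
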