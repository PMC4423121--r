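#' Run the full synthetic-to-analysis pipeline
#'
#' Orchestrates the pipeline stages from one configuration: generates
#' synthetic inputs, runs each selected analysis stage, writes per-stage
#' outputs under `outdir`, and consolidates headline statistics into a
#' machine-readable `summary.json`. Given the same configuration and seed the
#' summary is byte-identical across runs: nothing time- or host-dependent
#' enters the outputs (the log carries thresholds and seeds, but no clock).
#'
#' @param config either a named list, or a path to a YAML/JSON file with the
#'   same fields. Recognised fields: `seed` (integer, default 1), `outdir`
#'   (required), `stages` (subset of `"orientation"`, `"motility"`,
#'   `"invitro"`, `"hydrodynamics"`, `"morphology"`; default all),
#'   `synth` (named overrides passed to [synth_config()]), and `thresholds`
#'   (named overrides of the scoring thresholds: `displacement_um` 0.5,
#'   `fast_nm_s` 700, `paraxial_deg` 45, `looping_deg` 90, `min_coalign_um`
#'   2, `bundle_len_um` 2.3, `bundle_ratio` 3, `survival_horizon_s` 450,
#'   `mass_da` 99000, `sample_S` 3.6).
#' @param plots write diagnostic ggplot figures alongside the stage outputs.
#' @return invisibly, the summary list (also written to
#'   `file.path(outdir, "summary.json")`).
#' @export
run_pipeline <- function(config, plots = FALSE) {
  cfg <- load_run_config(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  input_dir <- file.path(cfg$outdir, "inputs")
  dir.create(input_dir, showWarnings = FALSE)
  sc <- do.call(synth_config, c(list(seed = cfg$seed), cfg$synth))
  thr <- cfg$thresholds
  summary <- list(seed = cfg$seed, stages = cfg$stages, thresholds = thr)
  log_lines <- c(
    paste("mtarray pipeline, package version",
          as.character(utils::packageVersion("mtarray"))),
    paste("seed:", cfg$seed),
    paste("stages:", paste(cfg$stages, collapse = ", ")),
    paste("thresholds:", paste(names(thr), unlist(thr), sep = "=",
                               collapse = ", ")))

  if ("orientation" %in% cfg$stages) {
    summary$orientation <- stage_orientation(sc, input_dir, cfg$outdir, plots)
    log_lines <- c(log_lines, "stage orientation: done")
  }
  if ("motility" %in% cfg$stages) {
    summary$motility <- stage_motility(sc, thr, input_dir, cfg$outdir)
    log_lines <- c(log_lines, "stage motility: done")
  }
  if ("invitro" %in% cfg$stages) {
    summary$invitro <- stage_invitro(sc, thr, input_dir, cfg$outdir, plots)
    log_lines <- c(log_lines, "stage invitro: done")
  }
  if ("hydrodynamics" %in% cfg$stages) {
    summary$hydrodynamics <- stage_hydro(sc, thr, input_dir, cfg$outdir)
    log_lines <- c(log_lines, "stage hydrodynamics: done")
  }
  if ("morphology" %in% cfg$stages) {
    summary$morphology <- stage_morphology(sc, input_dir, cfg$outdir, plots)
    log_lines <- c(log_lines, "stage morphology: done")
  }

  jsonlite::write_json(summary, file.path(cfg$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  writeLines(log_lines, file.path(cfg$outdir, "run.log"))
  invisible(summary)
}

load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON path")
  if (is.null(config$outdir)) stop("config must name an `outdir`")
  all_stages <- c("orientation", "motility", "invitro", "hydrodynamics",
                  "morphology")
  stages <- config$stages %||% all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  thr_default <- list(displacement_um = 0.5, fast_nm_s = 700,
                      paraxial_deg = 45, looping_deg = 90,
                      min_coalign_um = 2, bundle_len_um = 2.3,
                      bundle_ratio = 3, survival_horizon_s = 450,
                      mass_da = 99000, sample_S = 3.6)
  thr <- utils::modifyList(thr_default, config$thresholds %||% list())
  if (any(unlist(thr) <= 0)) stop("thresholds must be positive")
  list(seed = as.integer(config$seed %||% 1L),
       outdir = config$outdir,
       stages = stages,
       synth = config$synth %||% list(),
       thresholds = thr)
}

stage_orientation <- function(sc, input_dir, outdir, plots) {
  net <- gen_filament_network(sc)
  write_filaments_csv(net$filaments, file.path(input_dir, "filaments.csv"))
  write_cell_json(net$geometry, file.path(input_dir, "cell.json"))
  smp <- filament_angles(net$filaments, net$geometry)
  ku <- kuiper_statistic(smp)
  gt <- gen_growth_tracks(sc)
  write_tracks_csv(gt$tracks, file.path(input_dir, "tracks.csv"))
  st <- track_growth_stats(gt$tracks, gt$geometry)
  dir_sample <- track_direction_sample(st)
  if (plots) save_angle_plot(smp, file.path(outdir, "orientation_ecdf.png"))
  list(kuiper_K = ku$K, kuiper_d1 = ku$d1, kuiper_d2 = ku$d2,
       n_effective = ku$n_effective,
       fraction_within_15 = fraction_within(smp, 15),
       asymmetry = asymmetry_index(smp),
       track_asymmetry = asymmetry_index(dir_sample),
       growth_speed_um_min = mean(st$speed_um_min),
       growth_duration_s = mean(st$duration_s),
       n_filaments = length(net$filaments), n_tracks = nrow(st))
}

stage_motility <- function(sc, thr, input_dir, outdir) {
  mk <- gen_mark_trajectories(sc, conditions = "none")
  write_tracks_csv(mk$marks, file.path(input_dir, "marks.csv"))
  evs <- list()
  for (tr in split(mk$marks, mk$marks$region_id)) {
    ev <- detect_events(tr, displacement_threshold = thr$displacement_um,
                        fast_threshold = thr$fast_nm_s)
    if (nrow(ev) > 0) {
      ev$class <- vapply(ev$path, classify_event, character(1),
                         geometry = mk$geometry,
                         paraxial_halfwidth = thr$paraxial_deg,
                         looping_turn = thr$looping_deg)
    }
    evs[[length(evs) + 1L]] <- ev[, setdiff(names(ev), "path")]
  }
  events <- do.call(rbind, evs)
  utils::write.csv(events, file.path(outdir, "events.csv"), row.names = FALSE)
  freq <- event_frequency(events, n_regions = sc$n_marks,
                          observed_time_min = sc$mark_duration_s / 60)
  dk <- gen_mark_trajectories(sc, conditions = c("none", "taxol", "azide",
                                                 "taxol_azide"))
  fits <- lapply(split(dk$marks, dk$marks$condition), function(d) {
    avg <- stats::aggregate(intensity ~ t_s, d, mean)
    fit_half_life(data.frame(t_s = avg$t_s, intensity = avg$intensity))
  })
  deco <- dissipation_decomposition(fits)
  list(n_events = nrow(events),
       rate_per_region_min = freq$rate,
       rate_fast = freq$rate_fast,
       rate_by_class = as.list(freq$rate_by_class),
       mean_velocity_nm_s = if (nrow(events) > 0) {
         mean(events$velocity_nm_s)
       } else NA_real_,
       half_life_s = lapply(fits, function(f) f$half_life_s),
       decomposition = deco[c("k_depoly", "k_transport", "k_bleach")])
}

stage_invitro <- function(sc, thr, input_dir, outdir, plots) {
  en <- gen_encounters(sc)
  write_encounter_geometry_json(en$encounters,
                                file.path(input_dir, "encounters_geometry.json"))
  cls <- lapply(en$encounters, classify_outcome,
                min_coalign = thr$min_coalign_um)
  df <- data.frame(
    encounter_id = vapply(en$encounters, function(e) e$id, character(1)),
    angle_deg = vapply(cls, function(x) x$angle_deg, numeric(1)),
    orientation = vapply(cls, function(x) x$orientation, character(1)),
    zippered = vapply(cls, function(x) x$outcome == "zippered", logical(1)),
    coaligned_um = vapply(cls, function(x) x$coaligned_um, numeric(1)),
    stringsAsFactors = FALSE)
  lens <- t(vapply(en$encounters, encounter_lengths, numeric(2)))
  df$len_A_um <- lens[, 1]
  df$len_B_um <- lens[, 2]
  utils::write.csv(df, file.path(outdir, "encounters.csv"), row.names = FALSE)
  hist <- zippering_histogram(df)
  utils::write.csv(hist, file.path(outdir, "zippering_histogram.csv"),
                   row.names = FALSE)
  gl <- gen_gliding_tracks(sc)
  write_tracks_csv(gl$tracks, file.path(input_dir, "gliding.csv"))
  sp <- gliding_speeds(gl$tracks)
  surv <- bundle_survival(gl$meta, thr$survival_horizon_s)
  if (plots) save_zippering_plot(hist, file.path(outdir, "zippering.png"))
  single_mean <- sp$summary$mean_nm_s[sp$summary$type == "single"]
  list(n_encounters = nrow(df),
       zippered_fraction = mean(df$zippered),
       zippered_parallel = sum(df$zippered & df$orientation == "parallel"),
       zippered_antiparallel = sum(df$zippered &
                                     df$orientation == "antiparallel"),
       gliding_single_mean_nm_s = if (length(single_mean)) single_mean else NA_real_,
       bundle_survival = surv)
}

stage_hydro <- function(sc, thr, input_dir, outdir) {
  standards_S <- c(bsa = 4.3, aldolase = 7.35, catalase = 11.35)
  peaks <- numeric(0)
  profs <- list()
  for (j in seq_along(standards_S)) {
    g <- gen_gradient_profile(sc, standards_S[[j]], names(standards_S)[j],
                              stream_offset = j)
    peaks <- c(peaks, peak_volume(g$profile))
    profs[[j]] <- g$profile
  }
  standards <- data.frame(volume_ul = peaks, S = unname(standards_S))
  cal <- calibrate_gradient(standards)
  samp <- gen_gradient_profile(sc, thr$sample_S, "sample", stream_offset = 0L)
  profs[[length(profs) + 1L]] <- samp$profile
  write_gradient_csv(do.call(rbind, profs),
                     file.path(input_dir, "gradient.csv"))
  S_hat <- sedimentation_coefficient(samp$profile, cal)
  fr <- frictional_ratio(thr$mass_da, S_hat)
  list(calibration_slope = cal$slope, calibration_intercept = cal$intercept,
       calibration_r2 = cal$r_squared,
       S = S_hat, S_max = fr$S_max, f_ratio = fr$f_ratio,
       mass_da = thr$mass_da)
}

stage_morphology <- function(sc, input_dir, outdir, plots) {
  # condition means follow the published control / mMAP4- / oMAP4-depleted
  # myoblast lengths; alignment (kappa) is coupled to elongation
  conditions <- data.frame(
    condition = c("shControl", "shmMAP4", "shoMAP4"),
    mean_um = c(107, 143, 82), sd_um = c(40, 58, 39),
    n = c(500, 500, 500), fused_frac = c(0.35, 0.33, 0.08),
    kappa = c(4, 6, 1),
    stringsAsFactors = FALSE)
  cells <- gen_cell_records(sc, conditions)
  write_cells_csv(cells, file.path(input_dir, "cells.csv"))
  summaries <- list()
  for (j in seq_len(nrow(conditions))) {
    cd <- conditions[j, ]
    sub <- cells[cells$condition == cd$condition, ]
    ls <- length_stats(sub)
    sc_j <- do.call(synth_config, utils::modifyList(
      list(seed = child_seed(sc$seed, "pipeline") + j),
      list(kappa = cd$kappa, n_filaments = sc$n_filaments,
           cell_length = cd$mean_um)))
    net <- gen_filament_network(sc_j)
    ku <- kuiper_statistic(filament_angles(net$filaments, net$geometry))
    summaries[[j]] <- data.frame(
      condition = cd$condition, mean_length_um = ls$mean_um,
      sd_length_um = ls$sd_um, n = ls$n,
      fusion_index = fusion_index(sub), kuiper_K = ku$K,
      stringsAsFactors = FALSE)
  }
  summaries <- do.call(rbind, summaries)
  utils::write.csv(summaries, file.path(outdir, "morphology_summary.csv"),
                   row.names = FALSE)
  fit <- orderliness_vs_length(summaries)
  if (plots) save_orderliness_plot(summaries, fit,
                                   file.path(outdir, "orderliness.png"))
  list(conditions = summaries,
       slope_per_um = fit$slope, intercept = fit$intercept, r = fit$r)
}

#' Write a human-readable pipeline report
#'
#' Renders the consolidated summary as a Markdown report with one section per
#' stage that ran, referencing the per-stage output files.
#'
#' @param summary the list returned by [run_pipeline()], or the path to a
#'   `summary.json` it wrote.
#' @param path output Markdown file path.
#' @return invisibly, `path`.
#' @export
write_report <- function(summary, path) {
  if (is.character(summary)) {
    summary <- jsonlite::read_json(summary, simplifyVector = TRUE)
  }
  fmt <- function(x, d = 4) formatC(unlist(x), digits = d, format = "g")
  lines <- c("# Microtubule array quantification report", "",
             paste("Seed:", summary$seed), "")
  if (!is.null(summary$orientation)) {
    o <- summary$orientation
    lines <- c(lines, "## Orientation", "",
               paste0("- Kuiper alignment K = ", fmt(o$kuiper_K),
                      " (d1 = ", fmt(o$kuiper_d1), ", d2 = ", fmt(o$kuiper_d2),
                      "; n_eff = ", fmt(o$n_effective), ")"),
               paste0("- Fraction within 15 deg of axis: ",
                      fmt(o$fraction_within_15)),
               paste0("- Asymmetry index: ", fmt(o$asymmetry)),
               paste0("- Mean growth speed: ", fmt(o$growth_speed_um_min),
                      " um/min over ", o$n_tracks, " tracks"),
               "- Inputs: `inputs/filaments.csv`, `inputs/tracks.csv`,",
               "  `inputs/cell.json`", "")
  }
  if (!is.null(summary$motility)) {
    m <- summary$motility
    lines <- c(lines, "## Motility", "",
               paste0("- ", m$n_events, " sliding events; ",
                      fmt(m$rate_per_region_min),
                      " events/region/min (fast: ", fmt(m$rate_fast), ")"),
               paste0("- Mean event velocity: ", fmt(m$mean_velocity_nm_s),
                      " nm/s"),
               paste0("- Dissipation rates (/s): depoly ",
                      fmt(m$decomposition$k_depoly), ", transport ",
                      fmt(m$decomposition$k_transport), ", bleach ",
                      fmt(m$decomposition$k_bleach)),
               "- Outputs: `events.csv`; inputs: `inputs/marks.csv`", "")
  }
  if (!is.null(summary$invitro)) {
    v <- summary$invitro
    lines <- c(lines, "## In vitro assays", "",
               paste0("- ", v$n_encounters, " encounters, zippered fraction ",
                      fmt(v$zippered_fraction), " (parallel ",
                      v$zippered_parallel, ", antiparallel ",
                      v$zippered_antiparallel, ")"),
               paste0("- Gliding single-MT mean speed: ",
                      fmt(v$gliding_single_mean_nm_s), " nm/s"),
               paste0("- Bundle survival: ", fmt(v$bundle_survival)),
               "- Outputs: `encounters.csv`, `zippering_histogram.csv`", "")
  }
  if (!is.null(summary$hydrodynamics)) {
    h <- summary$hydrodynamics
    lines <- c(lines, "## Hydrodynamics", "",
               paste0("- Calibration: S = ", fmt(h$calibration_slope),
                      " * v + ", fmt(h$calibration_intercept),
                      " (r2 = ", fmt(h$calibration_r2), ")"),
               paste0("- Sample S = ", fmt(h$S), " S; f/f_min = ",
                      fmt(h$f_ratio), " at M = ", h$mass_da, " Da"),
               "- Inputs: `inputs/gradient.csv`", "")
  }
  if (!is.null(summary$morphology)) {
    mo <- summary$morphology
    lines <- c(lines, "## Morphology", "",
               paste0("- K vs length slope: ", fmt(mo$slope_per_um),
                      " per um (r = ", fmt(mo$r), ")"),
               "- Outputs: `morphology_summary.csv`; inputs: `inputs/cells.csv`",
               "")
  }
  writeLines(lines, path)
  invisible(path)
}

utils::globalVariables(c("angle", "weight", "bin_lo", "bin_hi", "fraction",
                         "mean_length_um", "kuiper_K"))

save_angle_plot <- function(sample, path) {
  s <- fold_sample(sample)
  df <- data.frame(angle = s$angles, weight = s$weights)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = angle, weight = weight)) +
    ggplot2::geom_histogram(breaks = seq(-90, 90, by = 10)) +
    ggplot2::labs(x = "angle to cell axis (deg)", y = "weighted count")
  ggplot2::ggsave(path, p, width = 5, height = 3.5, dpi = 120)
}

save_zippering_plot <- function(hist, path) {
  p <- ggplot2::ggplot(hist, ggplot2::aes(x = (bin_lo + bin_hi) / 2,
                                          y = fraction)) +
    ggplot2::geom_col(width = 8, na.rm = TRUE) +
    ggplot2::labs(x = "encounter angle (deg)", y = "zippering fraction")
  ggplot2::ggsave(path, p, width = 5, height = 3.5, dpi = 120)
}

save_orderliness_plot <- function(summaries, fit, path) {
  p <- ggplot2::ggplot(summaries, ggplot2::aes(x = mean_length_um,
                                               y = kuiper_K)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept) +
    ggplot2::labs(x = "mean cell length (um)", y = "Kuiper K")
  ggplot2::ggsave(path, p, width = 5, height = 3.5, dpi = 120)
}
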