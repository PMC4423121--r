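test_that("synth_config validates rates, probabilities and dimensions", {
  expect_s3_class(synth_config(), "synth_config")
  expect_error(synth_config(cell_length = -5), "cell_length")
  expect_error(synth_config(cell_aspect = 0.5), "aspect")
  expect_error(synth_config(slide_rate = -1), "slide_rate")
  expect_error(synth_config(class_probs = c(paraxial = 0.5, off_axis = 0.2,
                                            looping = 0.2)), "sum to 1")
  expect_error(synth_config(duration_s = 1), "2 frames")
  expect_error(synth_config(zipper_prob_parallel = function(a) a / 10),
               "zipper_prob_parallel")
})

test_that("generators are bit-identical under the same seed and differ across seeds", {
  cfg <- synth_config(seed = 123, n_filaments = 20, n_tracks = 10,
                      n_marks = 5, n_encounters = 10, n_singles = 5,
                      n_bundles = 5)
  a <- gen_filament_network(cfg)
  b <- gen_filament_network(cfg)
  expect_identical(a, b)
  expect_identical(gen_mark_trajectories(cfg), gen_mark_trajectories(cfg))
  expect_identical(gen_encounters(cfg), gen_encounters(cfg))
  expect_identical(gen_gliding_tracks(cfg), gen_gliding_tracks(cfg))
  expect_identical(gen_gradient_profile(cfg, 3.6), gen_gradient_profile(cfg, 3.6))
  cfg2 <- synth_config(seed = 124, n_filaments = 20)
  expect_false(identical(gen_filament_network(cfg2)$filaments, a$filaments))
})

test_that("filament orientations follow the axial von Mises model", {
  # kappa = 0: circular resultant of the doubled orientations is near zero
  cfg0 <- synth_config(seed = 9, kappa = 0, n_filaments = 10000)
  th0 <- gen_filament_network(cfg0)$truth$orientation_deg
  rbar <- Mod(mean(exp(2i * th0 * pi / 180)))
  expect_lt(rbar, 0.05)  # closed form: I1(0)/I0(0) = 0, sampling se ~ 1/sqrt(n)

  # large kappa: >= 99% of orientations within +/- 15 degrees of the axis
  cfg1 <- synth_config(seed = 10, kappa = 100, n_filaments = 1000)
  th1 <- gen_filament_network(cfg1)$truth$orientation_deg
  expect_gte(mean(abs(th1) <= 15), 0.99)
  expect_gt(axial_vm_mass(15, 100), 0.996)  # the von Mises mass itself
})

test_that("filament vertices lie inside the cell outline", {
  cfg <- synth_config(seed = 31, n_filaments = 100, cell_length = 80,
                      cell_aspect = 6)
  net <- gen_filament_network(cfg)
  a <- 40
  b <- 40 / 6
  for (f in net$filaments) {
    v <- f$vertices
    expect_true(all((v[, 1] / a)^2 + (v[, 2] / b)^2 <= 1 + 1e-9))
  }
  expect_length(net$truth$orientation_deg, length(net$filaments))
})

test_that("mark trajectories honour the event budget and decay closed form", {
  # slide_rate = 0: stationary marks, no truth events
  cfg0 <- synth_config(seed = 3, slide_rate = 0, loc_sigma_um = 0.02,
                       n_marks = 10)
  mk0 <- gen_mark_trajectories(cfg0)
  expect_equal(nrow(mk0$truth$events), 0)
  excursions <- tapply(sqrt(mk0$marks$x_um^2 + mk0$marks$y_um^2),
                       mk0$marks$region_id, max)
  expect_true(all(excursions < 5 * 0.02 * sqrt(2) + 0.1))

  # bleaching-only decay: intensity halves at t = 100 s in every condition
  cfgb <- synth_config(seed = 4, slide_rate = 0, k_depoly = 0, k_transport = 0,
                       k_bleach = log(2) / 100, intensity_noise = 0,
                       n_marks = 2, mark_duration_s = 120, mark_interval_s = 10)
  for (cond in c("none", "taxol", "azide", "taxol_azide")) {
    mk <- gen_mark_trajectories(cfgb, conditions = cond)
    one <- mk$marks[mk$marks$region_id == mk$marks$region_id[1], ]
    expect_equal(one$intensity[one$t_s == 100], 0.5, tolerance = 1e-12)
    expect_equal(mk$truth$half_life_s[[cond]], 100)
  }

  # Poisson event budget: total injected close to n_marks * rate * duration
  cfgp <- synth_config(seed = 6, slide_rate = 2, mark_duration_s = 60,
                       n_marks = 200, loc_sigma_um = 0)
  mkp <- gen_mark_trajectories(cfgp)
  expected <- 200 * 2 * 1
  expect_lt(abs(nrow(mkp$truth$events) - expected), 3 * sqrt(expected))
})

test_that("encounter generation respects forced probabilities and geometry rules", {
  cfg0 <- synth_config(seed = 8, n_encounters = 50,
                       zipper_prob_parallel = function(a) rep(0, length(a)),
                       zipper_prob_antiparallel = function(a) rep(0, length(a)))
  en0 <- gen_encounters(cfg0)
  expect_true(all(!en0$truth$zippered))

  cfg1 <- synth_config(seed = 9, n_encounters = 100,
                       zipper_prob_parallel = function(a) rep(0, length(a)),
                       zipper_prob_antiparallel = function(a) as.numeric(a > 150))
  en1 <- gen_encounters(cfg1)
  tr <- en1$truth
  expect_true(all(tr$zippered[tr$angle_deg > 150]))
  expect_true(all(!tr$zippered[tr$angle_deg <= 150]))
  expect_true(all(tr$coaligned_um[tr$zippered] >= 2))
  expect_true(all((tr$orientation == "antiparallel") == (tr$angle_deg > 90)))
  expect_equal(nrow(tr), length(en1$encounters))
})

test_that("gliding generator reproduces speed and breakup settings", {
  # zero speed variance: all single-MT instantaneous speeds equal the mean
  cfg0 <- synth_config(seed = 12, v_glide_sd = 0, n_singles = 5, n_bundles = 2,
                       glide_duration_s = 60)
  gl0 <- gen_gliding_tracks(cfg0)
  sp0 <- gliding_speeds(gl0$tracks)
  singles <- sp0$speeds[sp0$speeds$type == "single", ]
  expect_equal(singles$speed_nm_s, rep(600, nrow(singles)), tolerance = 1e-9)

  # zero breakup rate: every non-censored bundle survives the observation
  cfg1 <- synth_config(seed = 13, bundle_breakup_rate = 0, censor_frac = 0,
                       n_bundles = 30, n_singles = 2, glide_duration_s = 100)
  gl1 <- gen_gliding_tracks(cfg1)
  expect_true(all(!gl1$meta$separated))
  expect_equal(bundle_survival(gl1$meta, 100), 1)
})

test_that("gradient profiles map back to the true S in the noiseless limit", {
  cfg <- synth_config(seed = 14, gradient_noise = 0)
  g <- gen_gradient_profile(cfg, true_S = 4.25)  # peak at 1500 ul, on-grid
  expect_equal(g$truth$peak_volume_ul, 1500)
  prof <- g$profile
  expect_equal(prof$volume_ul[which.max(prof$signal)], 1500)
  expect_equal(peak_volume(prof), 1500, tolerance = 1e-9)
})

test_that("generated records round-trip through the interchange formats", {
  cfg <- synth_config(seed = 15, n_filaments = 8, n_encounters = 5,
                      n_marks = 3)
  net <- gen_filament_network(cfg)
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "filaments.csv")
  write_filaments_csv(net$filaments, f)
  back <- read_filaments_csv(f)
  orig <- net$filaments[order(vapply(net$filaments, function(x) x$id,
                                     character(1)))]
  expect_equal(lapply(back, function(x) x$vertices),
               lapply(orig, function(x) x$vertices),
               tolerance = 1e-7, ignore_attr = TRUE)

  cj <- file.path(tmp, "cell.json")
  write_cell_json(net$geometry, cj)
  geom2 <- read_cell_json(cj)
  expect_equal(geom2$length, net$geometry$length, tolerance = 1e-9)

  en <- gen_encounters(cfg)
  ej <- file.path(tmp, "enc.json")
  write_encounter_geometry_json(en$encounters, ej)
  back_en <- read_encounter_geometry_json(ej)
  expect_equal(back_en[[3]]$A$vertices, en$encounters[[3]]$A$vertices,
               tolerance = 1e-9, ignore_attr = TRUE)
  # classification is unchanged by the round trip
  expect_equal(classify_outcome(back_en[[1]])$outcome,
               classify_outcome(en$encounters[[1]])$outcome)
})
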