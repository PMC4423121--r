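geom <- ellipse_cell(100, aspect = 8)

test_that("detect_events applies the 0.5-um displacement rule", {
  # jitter staying within 0.4 um of the original location never opens an event
  set.seed(1)
  th <- runif(40, 0, 2 * pi)
  r <- c(0, runif(39, 0, 0.4))
  tr <- data.frame(region_id = "m0", t_s = seq_len(40) * 1.6,
                   x_um = r * cos(th), y_um = r * sin(th))
  expect_equal(nrow(detect_events(tr)), 0)

  # constant-velocity run of 3 um at 0.2 um/s, then stop: one slow event
  tr1 <- straight_mark(dt = 1.5, n_move = 10, v_um_s = 0.2)
  ev <- detect_events(tr1, noise_floor = 1e-9)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$velocity_nm_s, 200, tolerance = 1e-9)
  expect_false(ev$fast)
  expect_equal(ev$path_um, 3, tolerance = 1e-9)

  # two 1-um excursions separated by a long rest: two events
  dt <- 1.6
  seg <- function(n, v, x0, t0) {
    data.frame(t_s = t0 + seq_len(n) * dt, x_um = x0 + v * dt * seq_len(n))
  }
  xs <- c(rep(0, 5), 0.25 * dt * seq_len(5), rep(0.25 * dt * 5, 6))
  xs <- c(xs, xs[length(xs)] + 0.25 * dt * seq_len(5),
          rep(xs[length(xs)] + 0.25 * dt * 5, 4))
  tr2 <- data.frame(region_id = "m2", t_s = seq_along(xs) * dt,
                    x_um = xs, y_um = 0)
  ev2 <- detect_events(tr2, noise_floor = 1e-9)
  expect_equal(nrow(ev2), 2)
  expect_true(all(ev2$displacement_um > 0.5))
})

test_that("event segmentation is invariant to time reversal of a symmetric trajectory", {
  tr <- straight_mark(dt = 2, n_rest_pre = 6, n_move = 8, n_rest_post = 6,
                      v_um_s = 0.3)
  rev_tr <- tr
  rev_tr$x_um <- rev(tr$x_um)
  rev_tr$y_um <- rev(tr$y_um)
  n_fwd <- nrow(detect_events(tr, noise_floor = 1e-9))
  n_rev <- nrow(detect_events(rev_tr, noise_floor = 1e-9))
  expect_equal(n_fwd, n_rev)
})

test_that("the fast flag encodes the 700 nm/s rule on every emitted event", {
  cfg <- synth_config(seed = 51, slide_rate = 2, n_marks = 60,
                      loc_sigma_um = 0)
  mk <- gen_mark_trajectories(cfg)
  for (tr in split(mk$marks, mk$marks$region_id)) {
    ev <- detect_events(tr, noise_floor = 1e-9)
    if (nrow(ev) > 0) {
      expect_identical(ev$fast, ev$velocity_nm_s > 700)
    }
  }
})

test_that("classify_event separates paraxial, off-axis and looping", {
  mk_path <- function(headings, step = 0.4) {
    p <- matrix(0, length(headings) + 1, 2)
    for (j in seq_along(headings)) {
      p[j + 1, ] <- p[j, ] + step * c(cos(headings[j] * pi / 180),
                                      sin(headings[j] * pi / 180))
    }
    p
  }
  expect_equal(classify_event(mk_path(rep(10, 6)), geom), "paraxial")
  expect_equal(classify_event(mk_path(rep(170, 6)), geom), "paraxial")
  expect_equal(classify_event(mk_path(rep(60, 6)), geom), "off_axis")
  expect_equal(classify_event(mk_path(seq(0, 120, by = 20)), geom), "looping")
  expect_error(classify_event(matrix(0, 1, 2), geom), "degenerate")
})

test_that("event_frequency divides by regions and time, split by class and speed", {
  ev <- data.frame(fast = c(TRUE, TRUE, rep(FALSE, 10)),
                   class = c(rep("paraxial", 8), rep("off_axis", 4)))
  fr <- event_frequency(ev, n_regions = 4, observed_time_min = 1.5)
  expect_equal(fr$rate, 2)
  expect_equal(fr$rate_fast, 2 / 6)
  expect_equal(unname(fr$rate_by_class["paraxial"]), 8 / 6)
  expect_equal(event_frequency(ev[0, , drop = FALSE], 3, 2)$rate, 0)
  expect_error(event_frequency(ev, 4, 0), "time")
})

test_that("synthetic sliding rate is recovered within sampling error", {
  # sparse regime: events are 15-25 s long, so at low rates the placement
  # constraint (no overlapping events in a 60-s record) rarely bites and the
  # injected count stays Poisson
  n_marks <- 240
  rate <- 0.5
  cfg <- synth_config(seed = 52, slide_rate = rate, mark_duration_s = 60,
                      n_marks = n_marks, loc_sigma_um = 0.05)
  mk <- gen_mark_trajectories(cfg)
  det <- do.call(rbind, lapply(split(mk$marks, mk$marks$region_id),
                               function(tr) {
                                 ev <- detect_events(tr)
                                 ev[, setdiff(names(ev), "path")]
                               }))
  fr <- event_frequency(det, n_regions = n_marks, observed_time_min = 1)
  mean_total <- n_marks * rate
  expect_lt(abs(nrow(mk$truth$events) - mean_total), 3 * sqrt(mean_total))
  expect_lt(abs(fr$rate * n_marks - nrow(mk$truth$events)),
            3 * sqrt(mean_total))
})

test_that("bleach_correct restores the control's fractional loss", {
  t <- seq(0, 60, by = 3)
  raw <- data.frame(t_s = t, intensity = rep(1, length(t)))
  ctl <- data.frame(t_s = t, intensity = rep(1, length(t)))
  expect_equal(bleach_correct(raw, ctl)$intensity, rep(1, length(t)))

  raw2 <- data.frame(t_s = c(0, 10), intensity = c(2, 0.8))   # raw_norm 0.4
  ctl2 <- data.frame(t_s = c(0, 10), intensity = c(1, 0.9))
  expect_equal(bleach_correct(raw2, ctl2)$intensity, c(1, 0.5))
  expect_error(bleach_correct(raw2, data.frame(t_s = c(0, 11),
                                               intensity = c(1, 1))),
               "alignment")

  # generator closed form: corrected series tracks the bleach-free decay
  # (additive restoration is first-order in the bleached fraction, so use a
  # modest bleaching rate over a 60-s observation)
  cfg <- synth_config(seed = 53, slide_rate = 0, k_depoly = 0.008,
                      k_transport = 0.004, k_bleach = 0.0005,
                      intensity_noise = 0, n_marks = 1)
  raw3 <- gen_mark_trajectories(cfg, "none")$marks
  ctl3 <- gen_mark_trajectories(cfg, "taxol_azide")$marks
  corr <- bleach_correct(data.frame(t_s = raw3$t_s, intensity = raw3$intensity),
                         data.frame(t_s = ctl3$t_s, intensity = ctl3$intensity))
  bleach_free <- exp(-(0.008 + 0.004) * corr$t_s)
  expect_lt(sqrt(mean((corr$intensity - bleach_free)^2)), 0.02)
})

test_that("fit_half_life recovers closed-form decays and flags non-decaying series", {
  t <- seq(0, 120, by = 3)
  f <- fit_half_life(data.frame(t_s = t, intensity = exp(-t * log(2) / 60)))
  expect_equal(f$half_life_s, 60, tolerance = 1e-6)
  expect_equal(f$amplitude, 1, tolerance = 1e-6)

  f2 <- fit_half_life(data.frame(t_s = t, intensity = rep(2, length(t))))
  expect_false(f2$decaying)
  expect_identical(f2$half_life_s, Inf)
  expect_error(fit_half_life(data.frame(t_s = 1:3, intensity = c(1, 1, 1))),
               ">= 5")
})

test_that("dissipation decomposition inverts the condition design", {
  t <- seq(0, 120, by = 3)
  mk_fit <- function(k) fit_half_life(data.frame(t_s = t,
                                                 intensity = exp(-k * t)))
  fits <- list(none = mk_fit(0.017), taxol = mk_fit(0.007),
               azide = mk_fit(0.012), taxol_azide = mk_fit(0.002))
  d <- dissipation_decomposition(fits)
  expect_equal(d$k_depoly, 0.01, tolerance = 1e-6)
  expect_equal(d$k_transport, 0.005, tolerance = 1e-6)
  expect_equal(d$k_bleach, 0.002, tolerance = 1e-6)
  expect_equal(d$consistency_residual, 0, tolerance = 1e-6)

  # identical conditions: both drug-sensitive components vanish
  same <- list(none = mk_fit(0.004), taxol = mk_fit(0.004),
               azide = mk_fit(0.004), taxol_azide = mk_fit(0.004))
  d0 <- dissipation_decomposition(same)
  expect_equal(d0$k_depoly, 0, tolerance = 1e-9)
  expect_equal(d0$k_transport, 0, tolerance = 1e-9)
  expect_error(dissipation_decomposition(list(none = mk_fit(0.01))),
               "taxol")
})
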