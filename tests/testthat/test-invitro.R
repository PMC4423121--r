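# hand-built encounter: A along +x from (-4,0) to (4,0), contact at origin
make_encounter <- function(alpha_deg, zip_len = 0, L_B_pre = 3,
                           L_B_post = 3, id = "e1") {
  sp <- 0.1
  u <- c(cos(alpha_deg * pi / 180), sin(alpha_deg * pi / 180))
  vA <- cbind(seq(-4, 4, by = sp), 0)
  sB <- seq(-L_B_pre, 0, by = sp)
  vB <- cbind(sB * u[1], sB * u[2])
  if (zip_len > 0) {
    run <- if (alpha_deg > 90) c(-1, 0) else c(1, 0)
    s2 <- seq(sp, zip_len, by = sp)
    vB <- rbind(vB, cbind(s2 * run[1], 0.03 + 0 * s2))
  } else {
    s2 <- seq(sp, L_B_post, by = sp)
    vB <- rbind(vB, cbind(s2 * u[1], s2 * u[2]))
  }
  mt_encounter(id, A = list(vertices = vA), B = list(vertices = vB),
               contact = c(0, 0))
}

test_that("encounter_angle returns the angle between growth tangents", {
  expect_equal(encounter_angle(make_encounter(0.5))$angle_deg, 0.5,
               tolerance = 1e-6)
  expect_equal(encounter_angle(make_encounter(90))$angle_deg, 90,
               tolerance = 1e-6)
  e180 <- encounter_angle(make_encounter(179.5))
  expect_equal(e180$angle_deg, 179.5, tolerance = 1e-6)
  expect_equal(e180$orientation, "antiparallel")
  expect_equal(encounter_angle(make_encounter(60))$orientation, "parallel")
  bad <- make_encounter(60)
  bad$contact <- c(10, 10)
  expect_error(encounter_angle(bad), "geometry error")
})

test_that("classify_outcome applies the 2-um co-alignment and polarity rules", {
  # straight 60-degree crossing: crossed
  r <- classify_outcome(make_encounter(60))
  expect_equal(r$outcome, "crossed")
  # antiparallel 170-degree encounter zippering for 2.5 um: zippered
  r2 <- classify_outcome(make_encounter(170, zip_len = 2.5))
  expect_equal(r2$outcome, "zippered")
  expect_equal(r2$orientation, "antiparallel")
  expect_gte(r2$coaligned_um, 2)
  # same geometry but co-alignment only 1.5 um: crossed by the length rule
  r3 <- classify_outcome(make_encounter(170, zip_len = 1.5))
  expect_equal(r3$outcome, "crossed")
  # parallel zippering at a shallow angle
  r4 <- classify_outcome(make_encounter(15, zip_len = 2.6))
  expect_equal(r4$outcome, "zippered")
  expect_equal(r4$orientation, "parallel")
})

test_that("classification agrees with generator ground truth", {
  cfg <- synth_config(seed = 61, n_encounters = 200)
  en <- gen_encounters(cfg)
  out <- vapply(en$encounters,
                function(e) classify_outcome(e)$outcome == "zippered",
                logical(1))
  expect_identical(out, en$truth$zippered)

  cfgn <- synth_config(seed = 62, n_encounters = 200,
                       encounter_vertex_noise_um = 0.05)
  enn <- gen_encounters(cfgn)
  outn <- vapply(enn$encounters,
                 function(e) classify_outcome(e)$outcome == "zippered",
                 logical(1))
  expect_gte(mean(outn == enn$truth$zippered), 0.95)
})

test_that("orientation label, angle and outcome survive mirror reflection", {
  cfg <- synth_config(seed = 63, n_encounters = 30)
  en <- gen_encounters(cfg)
  for (e in en$encounters[1:10]) {
    m <- e
    m$A$vertices[, 2] <- -m$A$vertices[, 2]
    m$B$vertices[, 2] <- -m$B$vertices[, 2]
    m$contact[2] <- -m$contact[2]
    a <- classify_outcome(e)
    b <- classify_outcome(m)
    expect_equal(b$angle_deg, a$angle_deg, tolerance = 1e-9)
    expect_identical(b$orientation, a$orientation)
    expect_identical(b$outcome, a$outcome)
  }
})

test_that("zippering_histogram conserves counts and marks empty bins as NA", {
  df <- data.frame(angle_deg = c(5, 12, 17, 165, 172),
                   zippered = c(FALSE, TRUE, FALSE, TRUE, TRUE))
  h <- zippering_histogram(df)
  expect_equal(sum(h$n), nrow(df))
  expect_true(all(is.na(h$fraction[h$n == 0])))
  expect_true(all(h$fraction[!is.na(h$fraction)] >= 0 &
                    h$fraction[!is.na(h$fraction)] <= 1))
  # all crossed: every populated bin has fraction 0
  h0 <- zippering_histogram(data.frame(angle_deg = c(10, 70, 160),
                                       zippered = rep(FALSE, 3)))
  expect_true(all(h0$fraction[!is.na(h0$fraction)] == 0))
  expect_error(zippering_histogram(data.frame(angle_deg = 190,
                                              zippered = TRUE)), "0, 180")
})

test_that("encounter_lengths measures contact-to-seed arc, capped at crossovers", {
  # A's seed is 4 um before the contact; B's 3 um
  e <- make_encounter(60)
  l <- encounter_lengths(e)
  expect_equal(unname(l["len_A_um"]), 4, tolerance = 1e-6)
  expect_equal(unname(l["len_B_um"]), 3, tolerance = 1e-6)
  # a crossover 1 um before the contact truncates the length
  e$A$crossovers_um <- 3
  expect_equal(unname(encounter_lengths(e)["len_A_um"]), 1, tolerance = 1e-6)
  # contact at the seed itself gives zero
  e2 <- make_encounter(60, L_B_pre = 0.2)
  e2$B$vertices <- e2$B$vertices[3:nrow(e2$B$vertices), ]
  expect_lt(encounter_lengths(e2)["len_B_um"], 0.11)
})

test_that("shallow_unsuccessful selects the 10-30 degree folded band", {
  df <- data.frame(angle_deg = c(5, 15, 25, 60, 155, 165, 175),
                   zippered = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE))
  sel <- shallow_unsuccessful(df)
  expect_equal(which(sel), c(2, 5, 6))
})

test_that("gliding_speeds recovers constant and distributional speeds", {
  # constant 500 nm/s track
  tr <- data.frame(object_id = "s1", type = "single",
                   t_s = seq(0, 20, by = 2),
                   x_um = seq(0, 10, by = 1) * 0.5 * 2, y_um = 0)
  sp <- gliding_speeds(tr)
  expect_equal(sp$speeds$speed_nm_s, rep(500, 10), tolerance = 1e-9)

  cfg <- synth_config(seed = 71, n_singles = 50, n_bundles = 5,
                      v_glide_mean = 600, v_glide_sd = 50,
                      glide_duration_s = 200)
  gl <- gen_gliding_tracks(cfg)
  sp2 <- gliding_speeds(gl$tracks)
  singles <- sp2$speeds[sp2$speeds$type == "single", ]
  se <- 50 / sqrt(nrow(singles))
  expect_lt(abs(mean(singles$speed_nm_s) - 600), 3 * se)
  bundles <- sp2$speeds[sp2$speeds$type == "bundle", ]
  expect_lt(mean(bundles$speed_nm_s), 50)  # static wobble only

  expect_warning(gliding_speeds(rbind(tr,
    data.frame(object_id = "x", type = "single", t_s = 0, x_um = 0, y_um = 0))),
    "excluded")
})

test_that("bundle_survival excludes censored bundles and is monotone in horizon", {
  b <- data.frame(survival_time_s = c(rep(500, 9), rep(100, 3), 50, 60),
                  separated = c(rep(FALSE, 9), rep(TRUE, 3), FALSE, FALSE),
                  censored = c(rep(FALSE, 12), TRUE, TRUE))
  expect_equal(bundle_survival(b, 450), 9 / 12)
  expect_true(is.na(bundle_survival(b[b$censored, ], 450)))
  hs <- c(50, 150, 300, 450)
  surv <- vapply(hs, function(h) bundle_survival(b, h), numeric(1))
  expect_true(all(diff(surv) <= 0))
})

test_that("score_bundles applies the length and brightness thresholds per preset", {
  regions <- data.frame(length_um = c(2.0, 2.5, 4.0),
                        intensity_ratio = c(5, 3.5, 2.9))
  expect_equal(score_bundles(regions)$n_bundles, 1)
  expect_equal(score_bundles(data.frame(length_um = 3, intensity_ratio = 4))$n_bundles, 1)
  expect_equal(score_bundles(data.frame(length_um = 3, intensity_ratio = 2))$n_bundles, 0)
  # in vitro preset counts ratio >= 3 and uses the 2-um length rule
  expect_equal(score_bundles(data.frame(length_um = 2.2, intensity_ratio = 3),
                             mode = "invitro")$n_bundles, 1)
  expect_equal(score_bundles(data.frame(length_um = 2.2, intensity_ratio = 3),
                             mode = "cell")$n_bundles, 0)
})
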