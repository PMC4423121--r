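# Independent oracles used to pin expected values.

# Brute-force sup-norm evaluation of the two one-sided ECDF deviations
# against the uniform CDF on (0, 1], by direct summation at a dense grid
# plus every jump point. Independent of the package's jump-based recursion.
brute_kuiper_unit <- function(u, w) {
  w <- w / sum(w)
  cand <- sort(unique(c(u, 1, seq(0, 1, length.out = 1501))))
  le <- outer(u, cand, "<=")
  lt <- outer(u, cand, "<")
  ec_right <- colSums(le * w)
  ec_left <- colSums(lt * w)
  d1 <- max(ec_right - cand)
  d2 <- max(cand - ec_left)
  list(d1 = d1, d2 = d2, K = d1 + d2)
}

brute_kuiper <- function(sample) {
  u <- if (sample$convention == "undirected") {
    (sample$angles + 90) / 180
  } else {
    (sample$angles + 180) / 360
  }
  brute_kuiper_unit(u, sample$weights)
}

# von Mises CDF mass on [-x, x] radians (mean 0, concentration kappa),
# by numerical integration of the density.
vm_mass <- function(x, kappa) {
  if (kappa == 0) return(x / pi)
  dens <- function(t) exp(kappa * cos(t)) / (2 * pi * besselI(kappa, 0))
  2 * stats::integrate(dens, 0, x, rel.tol = 1e-10)$value
}

# Mass of the axial von Mises orientation distribution within +/- h degrees
# of the axis: orientation = psi / 2 with psi ~ VM(0, kappa).
axial_vm_mass <- function(h_deg, kappa) {
  vm_mass(2 * h_deg * pi / 180, kappa)
}

# Random weighted angular sample for property tests.
random_angular_sample <- function(n, convention = "undirected") {
  if (convention == "undirected") {
    ang <- stats::runif(n, -90 + 1e-9, 90)
  } else {
    ang <- stats::runif(n, -180 + 1e-9, 180)
  }
  angular_sample(ang, stats::rexp(n) + 0.01, convention)
}

# Straight-line mark trajectory builder: rest, then a constant-velocity run,
# then rest, on a regular frame grid.
straight_mark <- function(dt = 1.6, n_rest_pre = 5, n_move = 10,
                          n_rest_post = 5, v_um_s = 0.2, heading_deg = 0,
                          origin = c(0, 0)) {
  n <- n_rest_pre + n_move + n_rest_post
  pos <- matrix(rep(origin, each = n), n, 2)
  u <- c(cos(heading_deg * pi / 180), sin(heading_deg * pi / 180))
  for (j in seq_len(n_move)) {
    pos[n_rest_pre + j, ] <- pos[n_rest_pre + j - 1, ] + v_um_s * dt * u
  }
  if (n_rest_post > 0) {
    idx <- (n_rest_pre + n_move + 1):n
    pos[idx, 1] <- pos[n_rest_pre + n_move, 1]
    pos[idx, 2] <- pos[n_rest_pre + n_move, 2]
  }
  data.frame(region_id = "m1", t_s = (seq_len(n) - 1) * dt,
             x_um = pos[, 1], y_um = pos[, 2])
}

# Rotate a cell geometry and a list of filament traces by phi degrees.
rotate_scene <- function(geometry, filaments, phi_deg) {
  phi <- phi_deg * pi / 180
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  geom2 <- cell_geometry(geometry$outline %*% t(R), geometry$axis %*% t(R))
  fil2 <- lapply(filaments, function(f) {
    filament_trace(f$id, f$vertices %*% t(R))
  })
  list(geometry = geom2, filaments = fil2)
}
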