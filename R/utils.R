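# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic per-generator child seeds: one root seed, fixed stream offsets,
# so adding a generator never perturbs the draws of another.
.stream_offsets <- c(
  filament_network = 1L, growth_tracks = 2L, mark_trajectories = 3L,
  encounters = 4L, gliding = 5L, gradient = 6L, morphology = 7L,
  pipeline = 8L
)

child_seed <- function(seed, stream) {
  if (!stream %in% names(.stream_offsets)) {
    stop("unknown generator stream: ", stream)
  }
  s <- as.numeric(seed) %% 2147483647
  as.integer((s * 48271 + .stream_offsets[[stream]] * 16807) %% 2147483647)
}

# Wrap an angle in degrees onto (-180, 180].
wrap_directed <- function(a) {
  x <- a %% 360
  x[x > 180] <- x[x > 180] - 360
  x
}

# Fold an angle in degrees onto the axial (undirected) range (-90, 90].
fold_axial <- function(a) {
  x <- a %% 180
  x[x > 90] <- x[x > 90] - 180
  x
}

vec_angle_deg <- function(dx, dy) atan2(dy, dx) * 180 / pi

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

euclid <- function(p, q) sqrt(sum((p - q)^2))

# Cumulative arc length along an n x 2 vertex matrix.
polyline_arclength <- function(v) {
  if (nrow(v) < 2) return(0)
  d <- sqrt(rowSums((v[-1, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2))
  c(0, cumsum(d))
}

# Minimum distance from point p to segment a-b.
point_segment_dist <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax
  dy <- by - ay
  len2 <- dx^2 + dy^2
  t <- ifelse(len2 == 0, 0, ((px - ax) * dx + (py - ay) * dy) / len2)
  t <- pmin(1, pmax(0, t))
  sqrt((ax + t * dx - px)^2 + (ay + t * dy - py)^2)
}

# Minimum distance from each row of pts (m x 2) to a polyline (n x 2).
points_polyline_dist <- function(pts, poly) {
  n <- nrow(poly)
  if (n == 1) {
    return(sqrt((pts[, 1] - poly[1, 1])^2 + (pts[, 2] - poly[1, 2])^2))
  }
  out <- rep(Inf, nrow(pts))
  for (i in seq_len(n - 1)) {
    d <- point_segment_dist(pts[, 1], pts[, 2],
                            poly[i, 1], poly[i, 2],
                            poly[i + 1, 1], poly[i + 1, 2])
    out <- pmin(out, d)
  }
  out
}

# Moving mean of y over a +/- half-window in the covariate s (arc length).
moving_mean_window <- function(s, y, half_window) {
  vapply(seq_along(s), function(i) {
    keep <- abs(s - s[i]) <= half_window
    mean(y[keep])
  }, numeric(1))
}

# von Mises sampler (Best & Fisher 1979 rejection scheme); kappa = 0 is uniform.
rvonmises <- function(n, mu = 0, kappa = 0) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (c_ * (2 - c_) - u2 > 0 || log(c_ / u2) + 1 - c_ >= 0) {
      u3 <- stats::runif(1)
      out[i] <- sign(u3 - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  wrap_directed(rad2deg(out) + rad2deg(mu)) * pi / 180
}

stopifnot_scalar_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) {
    stop("invalid config: `", name, "` must be a ",
         if (strict) "positive" else "non-negative", " finite scalar")
  }
  invisible(x)
}
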