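#' Cell geometry: outline polygon and longitudinal axis
#'
#' Container for the reference frame of a single elongated cell: the traced
#' outline (a simple polygon) and the longitudinal axis, given as an ordered
#' pair of tip coordinates. Cell length is the straight-line tip-to-tip
#' distance between the axis endpoints.
#'
#' @param outline numeric matrix (n x 2) of outline vertices in micrometres;
#'   the polygon is treated as closed (last vertex connects to the first).
#' @param axis numeric matrix (2 x 2); rows are the two axis endpoints in
#'   micrometres, ordered (the first row is the reference tip).
#' @return An object of class `cell_geometry` with elements `outline`, `axis`
#'   and `length` (micrometres).
#' @examples
#' geom <- cell_geometry(
#'   outline = cbind(c(-50, 50, 50, -50), c(-5, -5, 5, 5)),
#'   axis = rbind(c(-50, 0), c(50, 0))
#' )
#' geom$length
#' @export
cell_geometry <- function(outline, axis) {
  outline <- as.matrix(outline)
  axis <- as.matrix(axis)
  if (ncol(outline) != 2 || nrow(outline) < 3) {
    stop("outline must be an (n x 2) matrix with n >= 3")
  }
  if (!all(dim(axis) == c(2, 2))) stop("axis must be a 2 x 2 matrix")
  if (!all(is.finite(outline)) || !all(is.finite(axis))) {
    stop("non-finite coordinates in cell geometry")
  }
  len <- euclid(axis[1, ], axis[2, ])
  if (len <= 0) stop("invalid config: cell axis endpoints coincide (length must be > 0)")
  structure(list(outline = outline, axis = axis, length = len),
            class = "cell_geometry")
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat("<cell_geometry> length", format(x$length, digits = 4), "um,",
      nrow(x$outline), "outline vertices\n")
  invisible(x)
}

#' Construct an elliptical cell outline
#'
#' Convenience constructor for synthetic cells: an ellipse of given tip-to-tip
#' length and aspect ratio, with the longitudinal axis along the major axis.
#'
#' @param length tip-to-tip cell length (micrometres).
#' @param aspect ratio of major to minor axis (>= 1).
#' @param n_vertices number of outline vertices.
#' @return A [cell_geometry()] object centred on the origin, major axis along x.
#' @export
ellipse_cell <- function(length, aspect = 8, n_vertices = 72) {
  stopifnot_scalar_pos(length, "length")
  if (!is.numeric(aspect) || aspect < 1) {
    stop("invalid config: aspect must be >= 1")
  }
  a <- length / 2
  b <- a / aspect
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  cell_geometry(cbind(a * cos(th), b * sin(th)),
                rbind(c(-a, 0), c(a, 0)))
}

#' Filament trace
#'
#' A manually traced microtubule filament as an ordered polyline.
#'
#' @param id identifier (coerced to character).
#' @param vertices numeric matrix (n x 2), ordered vertices in micrometres.
#' @return Object of class `filament_trace`.
#' @export
filament_trace <- function(id, vertices) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2 || nrow(vertices) < 2) {
    stop("filament trace needs >= 2 vertices (n x 2 matrix)")
  }
  step <- sqrt(rowSums((vertices[-1, , drop = FALSE] -
                          vertices[-nrow(vertices), , drop = FALSE])^2))
  if (any(step == 0)) stop("consecutive filament vertices must be distinct")
  structure(list(id = as.character(id), vertices = vertices),
            class = "filament_trace")
}

#' Angle of a segment relative to the cell axis
#'
#' @param p1,p2 numeric length-2 vectors, segment endpoints (micrometres). For
#'   the directed convention the segment runs from `p1` to `p2`.
#' @param geometry a [cell_geometry()].
#' @param convention `"undirected"` folds the angle to (-90, 90] (filament
#'   orientation); `"directed"` keeps the direction of travel in (-180, 180].
#' @return Angle in degrees; positive = counter-clockwise from the axis.
#' @examples
#' geom <- ellipse_cell(100)
#' angle_to_axis(c(0, 0), c(1, 1), geom)            # 45
#' angle_to_axis(c(0, 0), c(-1, 0), geom, "directed") # 180
#' @export
angle_to_axis <- function(p1, p2, geometry,
                          convention = c("undirected", "directed")) {
  convention <- match.arg(convention)
  v <- c(p2[1] - p1[1], p2[2] - p1[2])
  if (all(v == 0)) stop("degenerate input: zero-length segment")
  ax <- geometry$axis[2, ] - geometry$axis[1, ]
  a <- vec_angle_deg(v[1], v[2]) - vec_angle_deg(ax[1], ax[2])
  if (convention == "undirected") fold_axial(a) else wrap_directed(a)
}

#' Weighted angular sample
#'
#' A set of angles relative to the cell axis together with non-negative
#' weights (segment lengths for filament orientations, 1 per track for comet
#' directions) and the declared angular convention.
#'
#' @param angles numeric vector of angles in degrees.
#' @param weights non-negative weights, recycled if scalar; must not all be zero.
#' @param convention `"undirected"` (angles in (-90, 90]) or `"directed"`
#'   (angles in (-180, 180]).
#' @return Object of class `angular_sample`.
#' @export
angular_sample <- function(angles, weights = 1,
                           convention = c("undirected", "directed")) {
  convention <- match.arg(convention)
  if (length(angles) == 0) stop("empty input: no angles")
  weights <- rep_len(weights, length(angles))
  if (any(weights < 0) || all(weights == 0)) {
    stop("weights must be non-negative and not all zero")
  }
  rng <- if (convention == "undirected") c(-90, 90) else c(-180, 180)
  if (any(angles <= rng[1] - 1e-9) || any(angles > rng[2] + 1e-9)) {
    stop("angles outside declared ", convention, " range (",
         rng[1], ", ", rng[2], "]")
  }
  structure(list(angles = as.numeric(angles), weights = as.numeric(weights),
                 convention = convention),
            class = "angular_sample")
}

#' @export
print.angular_sample <- function(x, ...) {
  cat("<angular_sample>", length(x$angles), x$convention, "angles, n_eff =",
      format(sum(x$weights), digits = 4), "\n")
  invisible(x)
}

#' Orientation sample from filament traces
#'
#' Each polyline segment contributes one undirected angle to the cell axis,
#' weighted by its length, so long aligned filaments dominate the sample the
#' way they dominate the image.
#'
#' @param filaments a list of [filament_trace()] objects.
#' @param geometry a [cell_geometry()].
#' @return An undirected [angular_sample()].
#' @export
filament_angles <- function(filaments, geometry) {
  if (length(filaments) == 0) stop("empty input: no filaments")
  ang <- numeric(0)
  w <- numeric(0)
  for (f in filaments) {
    v <- f$vertices
    for (i in seq_len(nrow(v) - 1)) {
      ang <- c(ang, angle_to_axis(v[i, ], v[i + 1, ], geometry, "undirected"))
      w <- c(w, euclid(v[i, ], v[i + 1, ]))
    }
  }
  angular_sample(ang, w, "undirected")
}

# Fold a sample to the undirected convention (no-op if already undirected).
fold_sample <- function(sample) {
  if (sample$convention == "undirected") return(sample)
  angular_sample(fold_axial(sample$angles), sample$weights, "undirected")
}
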