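# Readers and writers for the package's plain-text interchange formats.
# All numeric values round-trip at full double precision.

#' Write / read filament traces as CSV
#'
#' Format: `filament_id, vertex_index, x_um, y_um`, one row per vertex.
#'
#' @param filaments list of [filament_trace()] objects.
#' @param path file path.
#' @return `read_filaments_csv()` returns a list of [filament_trace()].
#' @export
write_filaments_csv <- function(filaments, path) {
  rows <- lapply(filaments, function(f) {
    data.frame(filament_id = f$id,
               vertex_index = seq_len(nrow(f$vertices)),
               x_um = f$vertices[, 1], y_um = f$vertices[, 2],
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_filaments_csv
#' @export
read_filaments_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$filament_id), function(d) {
    d <- d[order(d$vertex_index), ]
    filament_trace(d$filament_id[1], cbind(d$x_um, d$y_um))
  })
}

#' Write / read cell geometry as JSON
#'
#' Format: `{"outline": [[x, y], ...], "axis": [[x1, y1], [x2, y2]]}`.
#'
#' @param geometry a [cell_geometry()].
#' @param path file path.
#' @return `read_cell_json()` returns a [cell_geometry()].
#' @export
write_cell_json <- function(geometry, path) {
  jsonlite::write_json(list(outline = geometry$outline,
                            axis = geometry$axis),
                       path, digits = NA)
  invisible(path)
}

#' @rdname write_cell_json
#' @export
read_cell_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cell_geometry(x$outline, x$axis)
}

#' Write / read long-format track tables as CSV
#'
#' Used for growth tracks (`track_id, frame, t_s, x_um, y_um`), mark
#' trajectories (plus `intensity`, `condition`, keyed by `region_id`) and
#' gliding tracks (keyed by `object_id`, plus `type`).
#'
#' @param tracks a data.frame.
#' @param path file path.
#' @return `read_tracks_csv()` returns the data.frame.
#' @export
write_tracks_csv <- function(tracks, path) {
  utils::write.csv(tracks, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read encounter geometry as JSON
#'
#' Stores, per encounter, both polylines (ordered seed to plus end), the
#' contact point, and any crossover annotations.
#'
#' @param encounters list of [mt_encounter()] objects.
#' @param path file path.
#' @return `read_encounter_geometry_json()` returns a list of
#'   [mt_encounter()].
#' @export
write_encounter_geometry_json <- function(encounters, path) {
  payload <- lapply(encounters, function(e) {
    list(id = e$id,
         A = list(vertices = e$A$vertices,
                  crossovers_um = e$A$crossovers_um),
         B = list(vertices = e$B$vertices,
                  crossovers_um = e$B$crossovers_um),
         contact = e$contact)
  })
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_encounter_geometry_json
#' @export
read_encounter_geometry_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  as_mat <- function(v) if (is.matrix(v)) v else do.call(rbind, v)
  lapply(payload, function(e) {
    mt_encounter(e$id,
                 A = list(vertices = as_mat(e$A$vertices),
                          crossovers_um = unlist(e$A$crossovers_um)),
                 B = list(vertices = as_mat(e$B$vertices),
                          crossovers_um = unlist(e$B$crossovers_um)),
                 contact = unlist(e$contact))
  })
}

#' Write / read gradient fraction profiles as CSV
#'
#' Format: `label, volume_ul, signal`.
#'
#' @param profile data.frame with those columns.
#' @param path file path.
#' @return `read_gradient_csv()` returns the data.frame.
#' @export
write_gradient_csv <- function(profile, path) {
  utils::write.csv(profile, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gradient_csv
#' @export
read_gradient_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read cell morphology records as CSV
#'
#' Format: `cell_id, condition, length_um, nuclei`.
#'
#' @param cells data.frame with those columns.
#' @param path file path.
#' @return `read_cells_csv()` returns the data.frame.
#' @export
write_cells_csv <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cells_csv
#' @export
read_cells_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
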