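#' Generate a rectangular lattice of suburb footprints
#'
#' Builds an `n_rows` by `n_cols` lattice of square cells standing in for
#' suburb polygons, on planar coordinates with unit cell size (read as 1 km
#' per cell so distance thresholds are in km). With `river = TRUE` one row of
#' cell boundaries (by default the middle one) is marked as a river: the
#' rows south of it are shifted down by `river_width`, so contiguity across
#' the river is severed in [contiguity_adjacency()] and can be restored with
#' [add_supplementary_edges()].
#'
#' @param n_rows,n_cols positive lattice dimensions.
#' @param river logical; cut the lattice with an east-west river.
#' @param seed integer seed, kept in the object for provenance (the lattice
#'   itself is deterministic).
#' @param river_row the row after which the river runs (defaults to the
#'   middle row).
#' @param river_width width of the river channel in cell units.
#' @return A `suburb_geography`: list with `units` (data frame `id`, `row`,
#'   `col`, `xmin`, `xmax`, `ymin`, `ymax`, `cx`, `cy`), lattice dimensions
#'   and the river description (or `NULL`).
#' @export
generate_geography <- function(n_rows, n_cols, river = FALSE, seed = 1L,
                               river_row = NULL, river_width = 0.3) {
  if (!is.numeric(n_rows) || !is.numeric(n_cols) || n_rows < 1 || n_cols < 1) {
    stop("n_rows and n_cols must be positive integers")
  }
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (river && n_rows < 2) stop("a river needs at least two rows")
  rr <- if (river) {
    if (is.null(river_row)) n_rows %/% 2L else as.integer(river_row)
  } else NA_integer_
  if (river && (rr < 1L || rr >= n_rows)) stop("river_row must split the lattice")

  grid <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  id <- sprintf("S%03d", seq_len(nrow(grid)))
  yshift <- if (river) ifelse(grid$row > rr, river_width, 0) else 0
  units <- data.frame(
    id = id, row = grid$row, col = grid$col,
    xmin = grid$col - 1, xmax = grid$col,
    ymin = grid$row - 1 + yshift, ymax = grid$row + yshift,
    stringsAsFactors = FALSE
  )
  units$cx <- (units$xmin + units$xmax) / 2
  units$cy <- (units$ymin + units$ymax) / 2
  structure(list(units = units, n_rows = n_rows, n_cols = n_cols,
                 river = if (river) list(after_row = rr, width = river_width) else NULL,
                 seed = as.integer(seed)),
            class = "suburb_geography")
}

#' @export
print.suburb_geography <- function(x, ...) {
  cat("suburb_geography:", nrow(x$units), "units on a", x$n_rows, "x", x$n_cols,
      "lattice", if (!is.null(x$river)) sprintf("(river after row %d)", x$river$after_row) else "",
      "\n")
  invisible(x)
}

#' Write / read a geography as GeoJSON
#'
#' Cells are written as a `FeatureCollection` of rectangular `Polygon`
#' features with planar coordinates; per-unit attributes passed via
#' `properties` are attached to the features.
#'
#' @param geography a `suburb_geography`.
#' @param path output file.
#' @param properties optional data frame keyed by `suburb_id` with extra
#'   per-unit fields to embed.
#' @return `path` invisibly; [read_geography_geojson()] returns a
#'   `suburb_geography`.
#' @export
write_geography_geojson <- function(geography, path, properties = NULL) {
  un <- geography$units
  feats <- lapply(seq_len(nrow(un)), function(k) {
    props <- list(id = un$id[k], row = un$row[k], col = un$col[k])
    if (!is.null(properties)) {
      r <- properties[match(un$id[k], as.character(properties$suburb_id)), , drop = FALSE]
      extra <- as.list(r[setdiff(names(r), "suburb_id")])
      props <- c(props, extra)
    }
    ring <- list(c(un$xmin[k], un$ymin[k]), c(un$xmax[k], un$ymin[k]),
                 c(un$xmax[k], un$ymax[k]), c(un$xmin[k], un$ymax[k]),
                 c(un$xmin[k], un$ymin[k]))
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  gj <- list(type = "FeatureCollection",
             river = if (is.null(geography$river)) NULL else geography$river,
             lattice = list(n_rows = geography$n_rows, n_cols = geography$n_cols),
             features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_geography_geojson
#' @export
read_geography_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  rows <- lapply(feats, function(f) {
    ring <- f$geometry$coordinates[[1]]
    xs <- vapply(ring, function(p) as.numeric(p[[1]]), numeric(1))
    ys <- vapply(ring, function(p) as.numeric(p[[2]]), numeric(1))
    data.frame(id = as.character(f$properties$id),
               row = as.integer(f$properties$row),
               col = as.integer(f$properties$col),
               xmin = min(xs), xmax = max(xs), ymin = min(ys), ymax = max(ys),
               stringsAsFactors = FALSE)
  })
  units <- do.call(rbind, rows)
  units$cx <- (units$xmin + units$xmax) / 2
  units$cy <- (units$ymin + units$ymax) / 2
  river <- if (is.null(gj$river)) NULL else {
    list(after_row = as.integer(gj$river$after_row), width = as.numeric(gj$river$width))
  }
  structure(list(units = units,
                 n_rows = if (is.null(gj$lattice)) max(units$row) else as.integer(gj$lattice$n_rows),
                 n_cols = if (is.null(gj$lattice)) max(units$col) else as.integer(gj$lattice$n_cols),
                 river = river, seed = NA_integer_),
            class = "suburb_geography")
}
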