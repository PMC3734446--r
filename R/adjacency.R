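#' Areal adjacency structure
#'
#' A `suburb_adjacency` is the neighbour structure used by the ICAR prior and
#' the spatial tests: an ordered set of unit ids, a neighbour list, and a
#' provenance flag per edge (`"contiguity"` for shared boundaries/vertices,
#' `"supplementary"` for edges added across a river). The structure is always
#' symmetric and irreflexive; every constructor in the package validates this.
#'
#' @param ids character vector of unique unit ids.
#' @param nbr named list (one element per id) of character vectors of
#'   neighbour ids.
#' @param flag named list parallel to `nbr` giving the provenance of each
#'   edge; defaults to `"contiguity"` everywhere.
#' @return An object of class `suburb_adjacency`.
#' @export
new_adjacency <- function(ids, nbr, flag = NULL) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("unit ids must be unique")
  if (!setequal(names(nbr), ids)) stop("neighbour list must be named by the unit ids")
  nbr <- lapply(nbr[ids], as.character)
  names(nbr) <- ids
  if (is.null(flag)) {
    flag <- lapply(nbr, function(v) rep("contiguity", length(v)))
  } else {
    flag <- flag[ids]
  }
  obj <- structure(list(ids = ids, nbr = nbr, flag = flag),
                   class = "suburb_adjacency")
  validate_adjacency(obj)
  obj
}

#' Validate symmetry and irreflexivity of an adjacency
#'
#' @param adj a `suburb_adjacency`.
#' @return `adj`, invisibly; errors listing the offending pairs otherwise.
#' @export
validate_adjacency <- function(adj) {
  stopifnot(inherits(adj, "suburb_adjacency"))
  ids <- adj$ids
  bad_ref <- ids[vapply(ids, function(i) i %in% adj$nbr[[i]], logical(1))]
  if (length(bad_ref)) {
    stop("self-neighbouring units: ", paste(bad_ref, collapse = ", "))
  }
  bad <- character(0)
  for (i in ids) {
    for (j in adj$nbr[[i]]) {
      if (!j %in% ids) bad <- c(bad, paste0(i, "->", j, " (unknown unit)"))
      else if (!i %in% adj$nbr[[j]]) bad <- c(bad, paste0(i, "->", j))
    }
  }
  if (length(bad)) {
    stop("asymmetric adjacency; offending pairs: ", paste(bad, collapse = ", "))
  }
  lens <- vapply(adj$nbr, length, integer(1))
  flens <- vapply(adj$flag, length, integer(1))
  if (!all(lens == flens)) stop("edge flags out of step with neighbour lists")
  invisible(adj)
}

#' @export
print.suburb_adjacency <- function(x, ...) {
  ne <- sum(lengths(x$nbr)) / 2
  nsup <- sum(vapply(x$flag, function(f) sum(f == "supplementary"), numeric(1))) / 2
  cat("suburb_adjacency:", length(x$ids), "units,", ne, "undirected edges",
      sprintf("(%d supplementary)\n", as.integer(nsup)))
  invisible(x)
}

#' Number of undirected edges in an adjacency
#' @param adj a `suburb_adjacency`.
#' @return integer edge count.
#' @export
n_edges <- function(adj) {
  sum(lengths(adj$nbr)) / 2
}

#' Queen-contiguity adjacency from a lattice geography
#'
#' Two cells are neighbours when they share one or more boundaries or
#' vertices (queen contiguity). Contiguity is severed across a river: cell
#' pairs on opposite banks are not joined here even where they would touch;
#' use [add_supplementary_edges()] to restore crossings within a distance
#' threshold, mirroring how estuary crossings are handled in small-area
#' studies.
#'
#' @param geography a `suburb_geography` from [generate_geography()] or
#'   [read_geography_geojson()].
#' @return a `suburb_adjacency` with all edges flagged `"contiguity"`.
#' @export
contiguity_adjacency <- function(geography) {
  stopifnot(inherits(geography, "suburb_geography"))
  un <- geography$units
  bad <- un$id[un$xmax <= un$xmin | un$ymax <= un$ymin]
  if (length(bad)) stop("degenerate footprint for unit(s): ", paste(bad, collapse = ", "))
  n <- nrow(un)
  nbr <- stats::setNames(vector("list", n), un$id)
  river_row <- if (is.null(geography$river)) NA_integer_ else geography$river$after_row
  for (k in seq_len(n)) {
    dr <- abs(un$row - un$row[k])
    dc <- abs(un$col - un$col[k])
    is_nb <- dr <= 1 & dc <= 1 & !(dr == 0 & dc == 0)
    if (!is.na(river_row)) {
      crosses <- (pmin(un$row, un$row[k]) <= river_row) &
        (pmax(un$row, un$row[k]) > river_row)
      is_nb <- is_nb & !crosses
    }
    nbr[[k]] <- un$id[is_nb]
  }
  new_adjacency(un$id, nbr)
}

#' Add supplementary edges across a river
#'
#' Joins unit pairs on opposite banks of the river whose minimum footprint
#' distance is strictly below `max_distance`; added edges are flagged
#' `"supplementary"`. With `max_distance = 0` the adjacency is returned
#' unchanged.
#'
#' @param adj a `suburb_adjacency`.
#' @param geography the `suburb_geography` the adjacency was built from; must
#'   carry a river for any edge to be added.
#' @param max_distance non-negative distance threshold in the geography's
#'   planar units.
#' @return a `suburb_adjacency` including the supplementary edges.
#' @export
add_supplementary_edges <- function(adj, geography, max_distance) {
  stopifnot(inherits(adj, "suburb_adjacency"), inherits(geography, "suburb_geography"))
  if (!is.numeric(max_distance) || length(max_distance) != 1 || is.na(max_distance) ||
      max_distance < 0) {
    stop("max_distance must be a single non-negative number")
  }
  if (max_distance == 0 || is.null(geography$river)) return(adj)
  un <- geography$units
  river_row <- geography$river$after_row
  north <- which(un$row <= river_row)
  south <- which(un$row > river_row)
  nbr <- adj$nbr
  flag <- adj$flag
  for (i in north) {
    for (j in south) {
      dx <- max(0, un$xmin[j] - un$xmax[i], un$xmin[i] - un$xmax[j])
      dy <- max(0, un$ymin[j] - un$ymax[i], un$ymin[i] - un$ymax[j])
      if (sqrt(dx^2 + dy^2) < max_distance) {
        a <- un$id[i]; b <- un$id[j]
        if (!b %in% nbr[[a]]) {
          nbr[[a]] <- c(nbr[[a]], b); flag[[a]] <- c(flag[[a]], "supplementary")
          nbr[[b]] <- c(nbr[[b]], a); flag[[b]] <- c(flag[[b]], "supplementary")
        }
      }
    }
  }
  new_adjacency(adj$ids, nbr, flag)
}

#' Restrict an adjacency to a subset of units
#'
#' Drops units and any edges touching them; never creates edges.
#'
#' @param adj a `suburb_adjacency`.
#' @param ids character vector of unit ids to retain.
#' @return the restricted `suburb_adjacency`.
#' @export
restrict_adjacency <- function(adj, ids) {
  stopifnot(inherits(adj, "suburb_adjacency"))
  ids <- as.character(ids)
  if (!all(ids %in% adj$ids)) {
    stop("unknown unit ids: ", paste(setdiff(ids, adj$ids), collapse = ", "))
  }
  keep <- adj$ids[adj$ids %in% ids]
  nbr <- lapply(keep, function(i) adj$nbr[[i]][adj$nbr[[i]] %in% keep])
  flag <- lapply(keep, function(i) adj$flag[[i]][adj$nbr[[i]] %in% keep])
  names(nbr) <- keep; names(flag) <- keep
  new_adjacency(keep, nbr, flag)
}

#' Connected components of an adjacency
#'
#' @param adj a `suburb_adjacency`.
#' @return integer vector of 1-based component labels, named by unit id.
#'   Units with no neighbours form singleton components (islands).
#' @export
connected_components <- function(adj) {
  ids <- adj$ids
  comp <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  lab <- 0L
  for (s in ids) {
    if (!is.na(comp[[s]])) next
    lab <- lab + 1L
    queue <- s
    comp[[s]] <- lab
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (j in adj$nbr[[cur]]) {
        if (is.na(comp[[j]])) { comp[[j]] <- lab; queue <- c(queue, j) }
      }
    }
  }
  comp
}

#' Apply the study-area exclusion rules
#'
#' Drops areal units in three rules applied in a fixed order of precedence:
#' units with most of their area outside the study region, units with zero
#' births in at least one study period, and units with no socioeconomic
#' data. A unit failing several rules is logged once, under the first rule
#' in that order. The operation is idempotent.
#'
#' @param suburbs_by_period named list of per-period data frames, each with
#'   columns `suburb_id` and `births`; every unit must appear in each period
#'   (a unit absent from a period counts as zero births there).
#' @param area_flags data frame with columns `suburb_id`, `outside_area`
#'   (logical), `ses_available` (logical), covering every unit.
#' @return list with `tables` (the filtered per-period data frames),
#'   `log` (data frame `suburb_id`, `reason`), `counts` (named integer vector
#'   over reasons `outside_area`, `zero_births`, `missing_ses`, `retained`),
#'   and `retained_ids`.
#' @export
apply_study_area_filters <- function(suburbs_by_period, area_flags) {
  stopifnot(is.list(suburbs_by_period), length(suburbs_by_period) >= 1)
  all_ids <- unique(unlist(lapply(suburbs_by_period, function(d) as.character(d$suburb_id))))
  if (!all(all_ids %in% as.character(area_flags$suburb_id))) {
    stop("area_flags must cover every unit")
  }
  flags <- area_flags[match(all_ids, as.character(area_flags$suburb_id)), ]
  births_mat <- vapply(suburbs_by_period, function(d) {
    b <- d$births[match(all_ids, as.character(d$suburb_id))]
    b[is.na(b)] <- 0
    as.numeric(b)
  }, numeric(length(all_ids)))
  births_mat <- matrix(births_mat, nrow = length(all_ids))
  zero_birth <- apply(births_mat == 0, 1, any)

  reason <- rep("retained", length(all_ids))
  reason[!flags$ses_available] <- "missing_ses"
  reason[zero_birth] <- "zero_births"          # higher precedence overwrites
  reason[isTRUE_vec(flags$outside_area)] <- "outside_area"

  retained <- all_ids[reason == "retained"]
  if (!length(retained)) stop("empty study area: every unit was excluded")
  tables <- lapply(suburbs_by_period, function(d) {
    d[as.character(d$suburb_id) %in% retained, , drop = FALSE]
  })
  counts <- c(outside_area = sum(reason == "outside_area"),
              zero_births  = sum(reason == "zero_births"),
              missing_ses  = sum(reason == "missing_ses"),
              retained     = length(retained))
  list(tables = tables,
       log = data.frame(suburb_id = all_ids, reason = reason,
                        stringsAsFactors = FALSE),
       counts = counts,
       retained_ids = retained)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Read and write GAL neighbour files
#'
#' The GAL dialect used here is: a header line with the unit count, then for
#' each unit a line `"id n_neighbours"` followed by a line listing the
#' neighbour ids (an empty line for units with no neighbours). Edge
#' provenance flags are not part of the format; [read_gal()] marks all edges
#' `"contiguity"`.
#'
#' @param path file path.
#' @return [read_gal()] returns a `suburb_adjacency`; [write_gal()] returns
#'   `path` invisibly.
#' @export
read_gal <- function(path) {
  lines <- readLines(path)
  n <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]][1])
  ids <- character(n)
  nbr <- vector("list", n)
  pos <- 2L
  for (k in seq_len(n)) {
    hdr <- strsplit(trimws(lines[pos]), "\\s+")[[1]]
    ids[k] <- hdr[1]
    deg <- as.integer(hdr[2])
    nb_line <- if (pos + 1L <= length(lines)) trimws(lines[pos + 1L]) else ""
    nbr[[k]] <- if (deg == 0L) character(0) else strsplit(nb_line, "\\s+")[[1]]
    if (length(nbr[[k]]) != deg) {
      stop("unit ", ids[k], " declares ", deg, " neighbours but lists ", length(nbr[[k]]))
    }
    pos <- pos + 2L
  }
  names(nbr) <- ids
  new_adjacency(ids, nbr)  # validation rejects asymmetric files
}

#' @rdname read_gal
#' @param adj a `suburb_adjacency` to write.
#' @export
write_gal <- function(adj, path) {
  stopifnot(inherits(adj, "suburb_adjacency"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(length(adj$ids)), con)
  for (i in adj$ids) {
    writeLines(paste(i, length(adj$nbr[[i]])), con)
    writeLines(paste(adj$nbr[[i]], collapse = " "), con)
  }
  invisible(path)
}
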