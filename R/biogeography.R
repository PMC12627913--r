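# Biogeographic-boundary hypothesis testing: partition sampling stations by
# a west-to-east polyline and compare community composition on the two sides
# with PERMANOVA, both with (p1) and without (p2) a user-specified set of
# excluded stations (e.g., stations on a current axis that transports DNA
# across the boundary).

#' Define a boundary hypothesis
#'
#' A named west-to-east polyline (e.g., a hypothesized faunal dividing line)
#' given as vertices with strictly increasing longitude. Points are
#' classified by comparing their latitude with the boundary's latitude at
#' their longitude.
#'
#' @param name Boundary name.
#' @param vertices Data frame (or matrix) with columns `lon`, `lat`;
#'   >= 2 rows, longitudes strictly increasing.
#' @return A `boundary_hypothesis` object.
#' @export
boundary_hypothesis <- function(name, vertices) {
  vertices <- as.data.frame(vertices)
  if (!all(c("lon", "lat") %in% names(vertices)))
    stop("vertices need columns lon and lat")
  vertices <- vertices[c("lon", "lat")]
  if (nrow(vertices) < 2) stop("a boundary needs >= 2 vertices")
  if (any(diff(vertices$lon) <= 0))
    stop("boundary longitudes must be strictly increasing (west to east)")
  structure(list(name = as.character(name), vertices = vertices),
            class = "boundary_hypothesis")
}

#' Read a boundary polyline from CSV
#'
#' @param path CSV with header `lon,lat`.
#' @param name Boundary name (default: file stem).
#' @return A [boundary_hypothesis].
#' @export
read_boundary_csv <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  boundary_hypothesis(name, utils::read.csv(path))
}

#' Classify sampling points as north or south of a boundary
#'
#' The boundary latitude at each point's longitude is linearly interpolated
#' between the bracketing vertices (nearest-endpoint latitude outside the
#' vertex span). A point is `north` iff its latitude exceeds the boundary
#' latitude; points exactly on the boundary are labeled north, flagged in
#' the `on_boundary` attribute, and reported with a warning.
#'
#' @param points Data frame of sampling points (needs `point_id`,
#'   `latitude`, `longitude`) or an [edna_dataset].
#' @return Named character vector (`"north"`/`"south"` per point) with a
#'   logical `on_boundary` attribute.
#' @export
assign_side <- function(points, boundary) {
  stopifnot(inherits(boundary, "boundary_hypothesis"))
  if (inherits(points, "edna_dataset")) points <- points$points
  if (any(is.na(points$latitude) | is.na(points$longitude)))
    stop("point(s) lacking coordinates: ",
         paste(points$point_id[is.na(points$latitude) | is.na(points$longitude)],
               collapse = ", "))
  blat <- stats::approx(boundary$vertices$lon, boundary$vertices$lat,
                        xout = points$longitude, rule = 2, ties = "ordered")$y
  on_b <- points$latitude == blat
  side <- ifelse(points$latitude >= blat, "north", "south")
  names(side) <- points$point_id
  if (any(on_b))
    warning("point(s) exactly on boundary '", boundary$name,
            "' labeled north: ", paste(points$point_id[on_b], collapse = ", "))
  attr(side, "on_boundary") <- stats::setNames(on_b, points$point_id)
  side
}

#' Test community differentiation across a boundary
#'
#' Labels every sampling point by its station's side of the boundary, builds
#' the dissimilarity matrix on the (already filtered) table, and runs a
#' two-group PERMANOVA twice: `p1` over all stations and `p2` after removing
#' the stations in `exclude_ids`. With an empty exclusion set the two runs
#' are identical (same seed). A side left empty (before or after exclusion)
#' makes the corresponding test untestable and is reported as an error.
#'
#' @param dataset A filtered [edna_dataset] (no all-zero points).
#' @param boundary A [boundary_hypothesis].
#' @param method Distance method, `"jaccard"` (default) or `"bray_curtis"`.
#' @param exclude_ids Station or point IDs to drop for the `p2` run
#'   (default none).
#' @param n_perm,seed Passed to [permanova].
#' @return A `boundary_test` result: `boundary_name`, `sides`, `p1`, `p2`,
#'   `n_north`, `n_south`, `excluded_ids`.
#' @export
boundary_test <- function(dataset, boundary, method = "jaccard",
                          exclude_ids = character(), n_perm = 999, seed = 1) {
  stopifnot(inherits(dataset, "edna_dataset"))
  run_one <- function(ds) {
    sides <- assign_side(ds, boundary)
    if (length(unique(sides)) < 2)
      stop("boundary '", boundary$name, "' leaves a side empty (all points ",
           unique(sides), "): untestable")
    ds <- drop_empty_features(ds)$table
    D <- dissimilarity_matrix(ds, method = method)
    list(sides = sides,
         res = permanova(D, sides, n_perm = n_perm, seed = seed))
  }
  full <- run_one(dataset)
  if (length(exclude_ids)) {
    reduced <- subset_points(dataset, exclude_ids)$dataset
    p2 <- run_one(reduced)$res
  } else {
    p2 <- full$res
  }
  structure(list(boundary_name = boundary$name, sides = full$sides,
                 p1 = full$res, p2 = p2,
                 n_north = sum(full$sides == "north"),
                 n_south = sum(full$sides == "south"),
                 excluded_ids = as.character(exclude_ids)),
            class = "boundary_test")
}

#' @export
print.boundary_test <- function(x, ...) {
  cat("Boundary test '", x$boundary_name, "': ", x$n_north, " north / ",
      x$n_south, " south\n  p1 (all stations)      = ",
      signif(x$p1$p_value, 4), "\n  p2 (",
      length(x$excluded_ids), " station(s) excluded) = ",
      signif(x$p2$p_value, 4), "\n", sep = "")
  invisible(x)
}
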