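# Search, list matching, diagnostics, station aggregation, heatmap ordering
# and GeoJSON map layers.

#' Normalize a species/feature name for matching
#'
#' Trim, collapse internal whitespace, map underscores to spaces, and fold
#' case, so `"Katsuwonus_pelamis"` matches `"katsuwonus pelamis"`. Matching
#' is exact on the normalized string (genus + epithet tokens); there is no
#' fuzzy matching or synonym resolution.
#'
#' @param x Character vector.
#' @return Normalized character vector.
#' @export
normalize_species_name <- function(x) {
  x <- gsub("_", " ", as.character(x))
  x <- gsub("\\s+", " ", trimws(x))
  tolower(x)
}

detection_records <- function(dataset, feature_ids) {
  m <- dataset$counts[feature_ids, , drop = FALSE]
  hit <- which(m > 0, arr.ind = TRUE)
  if (nrow(hit) == 0) {
    return(data.frame(feature_id = character(), point_id = character(),
                      station_id = character(), depth_m = numeric(),
                      dataset_label = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  pid <- colnames(m)[hit[, 2]]
  meta <- dataset$points[match(pid, dataset$points$point_id), ]
  out <- data.frame(feature_id = rownames(m)[hit[, 1]], point_id = pid,
                    station_id = meta$station_id, depth_m = meta$depth_m,
                    dataset_label = meta$dataset_label,
                    count = m[hit], stringsAsFactors = FALSE)
  out <- out[order(out$feature_id, out$point_id), ]
  rownames(out) <- NULL
  out
}

#' Search features across datasets
#'
#' Finds every detection (count > 0) of the queried feature IDs or species
#' names across one or more datasets, matching either the exact feature ID
#' or its normalized name. Stations are partitioned into detected (any
#' query feature present at any depth) versus not detected, the layer used
#' to highlight stations on the output map.
#'
#' @param datasets An [edna_dataset] or list of them.
#' @param queries Character vector of feature IDs / species names. Querying
#'   a list of IDs behaves as the union of single queries.
#' @return `list(records, stations)`: per-detection rows and a per-station
#'   data frame with a logical `detected` column.
#' @export
search_taxa <- function(datasets, queries) {
  if (inherits(datasets, "edna_dataset")) datasets <- list(datasets)
  queries <- as.character(queries)
  if (!length(queries)) stop("empty query set")
  qn <- normalize_species_name(queries)
  recs <- lapply(datasets, function(d) {
    fid <- rownames(d$counts)
    hit <- fid[fid %in% queries | normalize_species_name(fid) %in% qn]
    detection_records(d, hit)
  })
  records <- do.call(rbind, recs)
  stations <- do.call(rbind, lapply(datasets, function(d) {
    unique(d$points[!d$points$is_control,
                    c("station_id", "latitude", "longitude", "dataset_label")])
  }))
  stations <- stations[!duplicated(stations$station_id), , drop = FALSE]
  stations$detected <- stations$station_id %in% records$station_id
  rownames(stations) <- NULL
  list(records = records, stations = stations)
}

#' Match an uploaded species list against datasets
#'
#' Compares a plain list of species names with the feature IDs of each
#' dataset (normalized exact matching) and summarizes, per species, in
#' which datasets it was detected, its total read count, and the number of
#' sampling points with detections. Also reports the per-dataset detected
#' sets and their cross-dataset intersection.
#'
#' @param species Character vector of species names (one per line when read
#'   from a file).
#' @param datasets An [edna_dataset] or list of them; list names (or
#'   `dataset_label`s) identify the datasets in the summary.
#' @return `list(summary, detected_by_dataset, shared)`.
#' @export
match_species_list <- function(species, datasets) {
  if (inherits(datasets, "edna_dataset")) datasets <- list(datasets)
  species <- unique(as.character(species))
  if (!length(species)) stop("empty species list")
  if (is.null(names(datasets)))
    names(datasets) <- vapply(datasets, function(d)
      paste(unique(d$points$dataset_label), collapse = "+"), character(1))
  sn <- normalize_species_name(species)
  per_ds <- lapply(datasets, function(d) {
    fn <- normalize_species_name(rownames(d$counts))
    idx <- match(sn, fn)
    hit <- !is.na(idx)
    reads <- points <- integer(length(sn))
    if (any(hit)) {
      sub <- d$counts[idx[hit], , drop = FALSE]
      reads[hit] <- as.integer(rowSums(sub))
      points[hit] <- as.integer(rowSums(sub > 0))
    }
    list(detected = hit & reads > 0, reads = reads, points = points)
  })
  summary <- data.frame(species = species, stringsAsFactors = FALSE)
  for (nm in names(per_ds)) {
    summary[[paste0("detected_", nm)]] <- per_ds[[nm]]$detected
    summary[[paste0("reads_", nm)]] <- per_ds[[nm]]$reads
    summary[[paste0("points_", nm)]] <- per_ds[[nm]]$points
  }
  det_mat <- vapply(per_ds, `[[`, logical(length(species)), "detected")
  if (length(species) == 1) det_mat <- matrix(det_mat, nrow = 1)
  summary$n_datasets_detected <- rowSums(det_mat)
  detected_by_dataset <- lapply(per_ds, function(p) species[p$detected])
  shared <- species[rowSums(det_mat) == length(per_ds)]
  list(summary = summary, detected_by_dataset = detected_by_dataset,
       shared = shared)
}

#' Tally detections by depth level
#'
#' Groups the detection records of the selected features (all features by
#' default) by `depth_m`; points without a recorded depth fall into an
#' `"unknown"` bin. Bin totals sum to the total number of detections.
#'
#' @param dataset An [edna_dataset].
#' @param features Optional feature-ID subset.
#' @return Data frame with columns `depth`, `n_detections`.
#' @export
detection_by_depth <- function(dataset, features = NULL) {
  stopifnot(inherits(dataset, "edna_dataset"))
  if (is.null(features)) features <- rownames(dataset$counts)
  recs <- detection_records(dataset, intersect(features, rownames(dataset$counts)))
  depth <- ifelse(is.na(recs$depth_m), "unknown", as.character(recs$depth_m))
  tab <- table(depth)
  lev <- names(tab)
  num <- suppressWarnings(as.numeric(lev))
  lev <- lev[order(is.na(num), num)]
  data.frame(depth = lev, n_detections = as.integer(tab[lev]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-point richness and batch diagnostics
#'
#' Computes the number of detected features and total reads per sampling
#' point, then group means by `dataset_label` (or another metadata column).
#' Flags a potential batch effect when the ratio of the largest to smallest
#' group mean richness exceeds `warn_ratio` -- large systematic differences
#' in per-station detections between runs swamp biological signal in
#' presence/absence comparisons.
#'
#' @param dataset An [edna_dataset].
#' @param group_by Metadata column to group by (default `"dataset_label"`).
#' @param warn_ratio Warning threshold on the group-mean richness ratio
#'   (default 3).
#' @return `list(per_point, per_group, ratio, warning)`.
#' @export
batch_diagnostics <- function(dataset, group_by = "dataset_label",
                              warn_ratio = 3) {
  stopifnot(inherits(dataset, "edna_dataset"))
  keep <- !dataset$points$is_control
  pts <- dataset$points[keep, , drop = FALSE]
  m <- dataset$counts[, pts$point_id, drop = FALSE]
  per_point <- data.frame(point_id = pts$point_id,
                          group = as.character(pts[[group_by]]),
                          richness = as.integer(colSums(m > 0)),
                          reads = as.integer(colSums(m)),
                          stringsAsFactors = FALSE)
  agg <- function(v) tapply(v, per_point$group, mean)
  per_group <- data.frame(group = names(agg(per_point$richness)),
                          mean_richness = as.numeric(agg(per_point$richness)),
                          mean_reads = as.numeric(agg(per_point$reads)),
                          n_points = as.integer(table(per_point$group)[names(agg(per_point$richness))]),
                          row.names = NULL, stringsAsFactors = FALSE)
  ratio <- if (nrow(per_group) > 1 && min(per_group$mean_richness) > 0)
    max(per_group$mean_richness) / min(per_group$mean_richness)
  else if (nrow(per_group) > 1) Inf else 1
  list(per_point = per_point, per_group = per_group, ratio = ratio,
       warning = ratio > warn_ratio)
}

#' Aggregate depth points to station resolution
#'
#' Produces one column per station with counts summed over that station's
#' depth points (the aggregated presence set is therefore the union of the
#' member presence sets). Coordinates come from the station's first point
#' (a warning is raised if points of one station disagree); depth is
#' cleared.
#'
#' @param dataset An [edna_dataset].
#' @return An [edna_dataset] at station resolution (`point_id` =
#'   `station_id`).
#' @export
stations_aggregate <- function(dataset) {
  stopifnot(inherits(dataset, "edna_dataset"))
  pts <- dataset$points
  stations <- unique(pts$station_id)
  counts <- vapply(stations, function(s) {
    cols <- pts$point_id[pts$station_id == s]
    as.integer(rowSums(dataset$counts[, cols, drop = FALSE]))
  }, integer(nrow(dataset$counts)))
  if (nrow(dataset$counts) == 1)
    counts <- matrix(counts, nrow = 1)
  dimnames(counts) <- list(rownames(dataset$counts), stations)
  meta <- lapply(stations, function(s) {
    sub <- pts[pts$station_id == s, , drop = FALSE]
    if (nrow(unique(sub[c("latitude", "longitude")])) > 1)
      warning("station ", s, " has conflicting coordinates; first point wins")
    data.frame(point_id = s, station_id = s,
               latitude = sub$latitude[1], longitude = sub$longitude[1],
               depth_m = NA_real_, dataset_label = sub$dataset_label[1],
               is_control = any(sub$is_control), stringsAsFactors = FALSE)
  })
  edna_dataset(counts, do.call(rbind, meta))
}

#' Ordered presence/absence matrix for heatmap display
#'
#' Binarizes the table, orders columns by the dendrogram leaf order of the
#' active distance method, and rows by descending prevalence (number of
#' points detected) with ties broken by feature ID. Batch-structured data
#' shows up as blocks of columns with very different row coverage.
#'
#' @param dataset An [edna_dataset] (or count matrix).
#' @param method Distance method for the column dendrogram.
#' @param linkage Linkage for the column dendrogram.
#' @return `list(matrix, row_order, col_order, tree)`.
#' @export
heatmap_matrix <- function(dataset, method = "jaccard", linkage = "complete") {
  m <- get_counts(dataset)
  if (ncol(m) < 2 || nrow(m) < 1) stop("need >= 2 points and >= 1 feature")
  m <- drop_empty_features(m)$table
  b <- to_presence_absence(m)
  tree <- hierarchical_cluster(dissimilarity_matrix(m, method = method),
                               linkage = linkage)
  col_order <- tree$leaf_ids[dendrogram_leaf_order(tree)]
  prevalence <- rowSums(b)
  row_order <- rownames(b)[order(-prevalence, rownames(b))]
  list(matrix = b[row_order, col_order, drop = FALSE],
       row_order = row_order, col_order = col_order, tree = tree)
}

#' Build a GeoJSON FeatureCollection of stations and boundaries
#'
#' One Point feature per mappable station (controls without coordinates are
#' excluded) with properties `station_id`, `dataset_label`, `n_points` and,
#' when a [search_taxa] result is supplied, a `detected` flag; boundary
#' polylines become LineString features. Coordinates are `[lon, lat]` per
#' RFC 7946.
#'
#' @param dataset An [edna_dataset].
#' @param detections Optional result of [search_taxa].
#' @param boundaries Optional [boundary_hypothesis] or list of them.
#' @return A list structured as a GeoJSON FeatureCollection (serialize with
#'   [write_geojson]).
#' @export
map_geojson <- function(dataset, detections = NULL, boundaries = NULL) {
  stopifnot(inherits(dataset, "edna_dataset"))
  pts <- dataset$points
  pts <- pts[!is.na(pts$latitude) & !is.na(pts$longitude), , drop = FALSE]
  if (nrow(pts) == 0) stop("no mappable points (no coordinates)")
  stations <- unique(pts$station_id)
  feats <- lapply(stations, function(s) {
    sub <- pts[pts$station_id == s, , drop = FALSE]
    props <- list(station_id = s,
                  dataset_label = sub$dataset_label[1],
                  n_points = nrow(sub))
    if (!is.null(detections))
      props$detected <- s %in% detections$stations$station_id[detections$stations$detected]
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(sub$longitude[1], sub$latitude[1])),
         properties = props)
  })
  if (!is.null(boundaries)) {
    if (inherits(boundaries, "boundary_hypothesis")) boundaries <- list(boundaries)
    feats <- c(feats, lapply(boundaries, function(b) {
      list(type = "Feature",
           geometry = list(type = "LineString",
                           coordinates = unname(as.matrix(b$vertices))),
           properties = list(name = b$name, layer = "boundary"))
    }))
  }
  list(type = "FeatureCollection", features = feats)
}

#' Write GeoJSON to a file
#'
#' @param geojson Output of [map_geojson].
#' @param path Output path.
#' @export
write_geojson <- function(geojson, path) {
  jsonlite::write_json(geojson, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
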