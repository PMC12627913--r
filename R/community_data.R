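# Location-sheet schema, fixed and documented: one row per sampling point.
LOCATION_COLUMNS <- c("point_id", "station_id", "latitude", "longitude",
                      "depth_m", "dataset_label", "is_control")

#' Construct a geolocated community dataset
#'
#' An `edna_dataset` binds a feature-by-point count table to per-point
#' metadata (station, coordinates, depth, dataset label, control flag).
#' A sampling point is one water sample (typically a station x depth
#' combination); a station groups the depth points taken at one location.
#'
#' @param counts Matrix of nonnegative integer read counts; rows are features
#'   (ASV IDs or species names), columns are sampling points. Dimnames are
#'   required and must be unique.
#' @param points Data frame with columns `point_id`, `station_id`, `latitude`,
#'   `longitude`, `depth_m`, `dataset_label`, `is_control`. Coordinates are
#'   WGS84 decimal degrees; longitudes are normalized into \[-180, 180\].
#'   Control points (e.g., filtration blanks) may lack coordinates.
#' @return An object of class `edna_dataset` with elements `counts` and
#'   `points`. The set of column names of `counts` and of `points$point_id`
#'   is identical and in the same order.
#' @export
#' @examples
#' counts <- matrix(c(5L, 0L, 2L, 1L), 2, 2,
#'                  dimnames = list(c("ASV_1", "ASV_2"), c("P1", "P2")))
#' pts <- data.frame(point_id = c("P1", "P2"), station_id = c("S1", "S1"),
#'                   latitude = 30, longitude = 130, depth_m = c(10, 50),
#'                   dataset_label = "cruise", is_control = FALSE)
#' ds <- edna_dataset(counts, pts)
edna_dataset <- function(counts, points) {
  counts <- validate_counts(counts)
  points <- validate_points(points)
  cn <- colnames(counts)
  if (!setequal(cn, points$point_id)) {
    only_counts <- setdiff(cn, points$point_id)
    only_points <- setdiff(points$point_id, cn)
    stop("Read/Location point mismatch: ",
         if (length(only_counts)) paste0("points only in Read sheet: ",
                                         paste(only_counts, collapse = ", "), "; ") else "",
         if (length(only_points)) paste0("points only in Location sheet: ",
                                         paste(only_points, collapse = ", ")) else "")
  }
  points <- points[match(cn, points$point_id), , drop = FALSE]
  rownames(points) <- NULL
  structure(list(counts = counts, points = points), class = "edna_dataset")
}

validate_counts <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if ((nrow(counts) > 0 && is.null(rownames(counts))) || is.null(colnames(counts)))
    stop("count matrix must have feature row names and point column names")
  if (nrow(counts) == 0 && is.null(rownames(counts)))
    rownames(counts) <- character(0)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate feature IDs: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate point IDs: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (!is.numeric(counts)) stop("non-numeric read counts")
  if (anyNA(counts)) stop("missing (NA) read counts; blank cells must be read as 0")
  if (any(counts < 0)) stop("negative read counts")
  if (any(counts != floor(counts))) stop("fractional read counts (ASV tables are integer reads)")
  storage.mode(counts) <- "integer"
  counts
}

validate_points <- function(points) {
  points <- as.data.frame(points, stringsAsFactors = FALSE)
  missing_cols <- setdiff(LOCATION_COLUMNS, names(points))
  if (length(missing_cols))
    stop("Location sheet missing column(s): ", paste(missing_cols, collapse = ", "))
  points <- points[LOCATION_COLUMNS]
  points$point_id <- as.character(points$point_id)
  points$station_id <- as.character(points$station_id)
  points$dataset_label <- as.character(points$dataset_label)
  points$latitude <- as.numeric(points$latitude)
  points$longitude <- as.numeric(points$longitude)
  points$depth_m <- suppressWarnings(as.numeric(points$depth_m))
  points$is_control <- parse_flag(points$is_control)
  if (anyDuplicated(points$point_id))
    stop("duplicate point IDs in Location sheet: ",
         paste(unique(points$point_id[duplicated(points$point_id)]), collapse = ", "))
  has_coord <- !is.na(points$latitude) | !is.na(points$longitude)
  bad_lat <- has_coord & (is.na(points$latitude) | points$latitude < -90 | points$latitude > 90)
  if (any(bad_lat))
    stop("latitude out of [-90, 90] for point(s): ",
         paste(points$point_id[bad_lat], collapse = ", "))
  # normalize longitudes into [-180, 180]
  lon <- points$longitude
  lon_ok <- !is.na(lon)
  lon[lon_ok] <- ((lon[lon_ok] + 180) %% 360) - 180
  points$longitude <- lon
  if (any(!points$is_control & !has_coord))
    stop("non-control point(s) lack coordinates: ",
         paste(points$point_id[!points$is_control & !has_coord], collapse = ", "))
  if (any(points$depth_m < 0, na.rm = TRUE))
    stop("negative depth_m")
  points
}

parse_flag <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  x <- tolower(trimws(as.character(x)))
  out <- x %in% c("true", "t", "1", "yes", "y")
  out
}

#' @export
print.edna_dataset <- function(x, ...) {
  cat("edna_dataset: ", nrow(x$counts), " features x ", ncol(x$counts),
      " sampling points (", length(unique(x$points$station_id)), " stations, ",
      sum(x$points$is_control), " controls)\n", sep = "")
  invisible(x)
}

#' @export
dim.edna_dataset <- function(x) dim(x$counts)

#' Read a two-sheet Read/Location workbook
#'
#' The canonical input is a single workbook holding a `Read` sheet (first
#' column feature IDs, one further column per sampling point, header row of
#' point IDs) and a `Location` sheet (one row per point with the
#' `point_id, station_id, latitude, longitude, depth_m, dataset_label,
#' is_control` schema). Sheet names are matched case-insensitively. A CSV
#' dialect of the same two tables is also accepted: either a directory
#' containing `Read.csv` and `Location.csv`, or a length-2 character vector
#' `c(read = ..., location = ...)` of the two CSV paths.
#'
#' Blank cells in the Read sheet are read as 0; negative, missing-after-0
#' or fractional counts, duplicate IDs, out-of-range coordinates, and
#' Read/Location point mismatches are errors.
#'
#' @param path Path to an `.xlsx` workbook, a directory holding the CSV pair,
#'   or a length-2 vector of CSV paths.
#' @return A validated [edna_dataset].
#' @export
read_workbook <- function(path) {
  if (length(path) == 2) {
    read_df <- utils::read.csv(path[[1]], check.names = FALSE,
                               stringsAsFactors = FALSE)
    loc_df <- utils::read.csv(path[[2]], check.names = FALSE,
                              stringsAsFactors = FALSE)
  } else if (length(path) == 1 && dir.exists(path)) {
    files <- list.files(path, full.names = TRUE)
    pick <- function(stem) {
      hit <- files[tolower(basename(files)) == paste0(stem, ".csv")]
      if (length(hit) != 1) stop("missing ", stem, ".csv in ", path)
      hit
    }
    read_df <- utils::read.csv(pick("read"), check.names = FALSE,
                               stringsAsFactors = FALSE)
    loc_df <- utils::read.csv(pick("location"), check.names = FALSE,
                              stringsAsFactors = FALSE)
  } else if (length(path) == 1 && grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!file.exists(path)) stop("no such file: ", path)
    sheets <- readxl::excel_sheets(path)
    pick <- function(stem) {
      hit <- sheets[tolower(sheets) == stem]
      if (length(hit) != 1) stop("workbook lacks a '", stem, "' sheet (found: ",
                                 paste(sheets, collapse = ", "), ")")
      hit
    }
    read_df <- as.data.frame(
      readxl::read_excel(path, sheet = pick("read"), col_types = "text"),
      stringsAsFactors = FALSE, check.names = FALSE)
    loc_df <- as.data.frame(
      readxl::read_excel(path, sheet = pick("location")),
      stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    stop("path must be an .xlsx workbook, a directory with Read.csv/Location.csv, ",
         "or a length-2 vector of the two CSV paths")
  }
  dataset_from_sheets(read_df, loc_df)
}

dataset_from_sheets <- function(read_df, loc_df) {
  if (ncol(read_df) < 2) stop("Read sheet needs a feature-ID column plus >= 1 point column")
  feature_ids <- as.character(read_df[[1]])
  vals <- read_df[-1]
  num <- vapply(vals, function(col) {
    col <- as.character(col)
    col[is.na(col) | trimws(col) == ""] <- "0"
    out <- suppressWarnings(as.numeric(col))
    if (anyNA(out)) stop("non-numeric read count value(s): ",
                         paste(utils::head(col[is.na(out)], 3), collapse = ", "))
    out
  }, numeric(max(nrow(read_df), 0L)))
  if (nrow(read_df) == 1) num <- matrix(num, nrow = 1)
  if (nrow(read_df) == 0) num <- matrix(numeric(0), nrow = 0, ncol = ncol(vals))
  dimnames(num) <- list(feature_ids, names(vals))
  edna_dataset(num, loc_df)
}

#' Write a dataset as the CSV workbook dialect
#'
#' Writes `Read.csv` and `Location.csv` into `path` (created if needed).
#' The produced files re-read with [read_workbook] to an identical dataset.
#'
#' @param dataset An [edna_dataset].
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
write_workbook <- function(dataset, path) {
  stopifnot(inherits(dataset, "edna_dataset"))
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", path)
  }
  fid <- rownames(dataset$counts)
  if (is.null(fid)) fid <- character(0)   # 0-row matrices report NULL rownames
  read_df <- data.frame(feature_id = fid,
                        as.data.frame(dataset$counts, check.names = FALSE),
                        stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.csv(read_df, file.path(path, "Read.csv"), row.names = FALSE)
  loc <- dataset$points
  # full precision so the CSV round-trips to bit-identical coordinates
  for (col in c("latitude", "longitude", "depth_m"))
    loc[[col]] <- ifelse(is.na(loc[[col]]), "", sprintf("%.17g", loc[[col]]))
  utils::write.csv(loc, file.path(path, "Location.csv"), row.names = FALSE)
  invisible(path)
}

#' Merge datasets with disjoint sampling points
#'
#' Features are matched by exact ID; the merged feature set is the union and
#' counts absent in a source dataset are 0. Per-point metadata (including
#' `dataset_label`) is preserved, supporting integrated analyses of several
#' uploaded tables.
#'
#' @param datasets List of [edna_dataset] objects with pairwise-disjoint
#'   `point_id` sets.
#' @return A single merged [edna_dataset].
#' @export
merge_datasets <- function(datasets) {
  if (inherits(datasets, "edna_dataset")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1,
            all(vapply(datasets, inherits, TRUE, "edna_dataset")))
  if (length(datasets) == 1) return(datasets[[1]])
  all_pts <- unlist(lapply(datasets, function(d) d$points$point_id))
  if (anyDuplicated(all_pts))
    stop("duplicate point_id across datasets: ",
         paste(unique(all_pts[duplicated(all_pts)]), collapse = ", "))
  features <- unique(unlist(lapply(datasets, function(d) rownames(d$counts))))
  counts <- matrix(0L, nrow = length(features), ncol = length(all_pts),
                   dimnames = list(features, all_pts))
  for (d in datasets)
    counts[rownames(d$counts), colnames(d$counts)] <- d$counts
  points <- do.call(rbind, lapply(datasets, function(d) d$points))
  edna_dataset(counts, points)
}

#' Reduce a count table to presence/absence
#'
#' Cells become 1 where the source count is positive, 0 otherwise; the
#' operation is idempotent. Accepts either a count matrix or a full dataset
#' (returned with its table binarized).
#'
#' @param x Count matrix (features x points) or [edna_dataset].
#' @return Object of the same kind with counts in \{0, 1\}.
#' @export
to_presence_absence <- function(x) {
  if (inherits(x, "edna_dataset")) {
    x$counts <- to_presence_absence(x$counts)
    return(x)
  }
  out <- (x > 0) + 0L
  dimnames(out) <- dimnames(x)
  storage.mode(out) <- "integer"
  out
}
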