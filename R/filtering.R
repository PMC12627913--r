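# Table-cleaning rules applied before any community comparison.
# Every filter returns list(result, report) where report is one FilterReport
# row; reports accumulate in application order and reconcile exactly with
# before/after dimensions.

filter_report <- function(rule, features_removed = 0L, points_removed = 0L,
                          cells_zeroed = 0L) {
  data.frame(rule = rule,
             features_removed = as.integer(features_removed),
             points_removed = as.integer(points_removed),
             cells_zeroed = as.integer(cells_zeroed),
             stringsAsFactors = FALSE)
}

get_counts <- function(x) if (inherits(x, "edna_dataset")) x$counts else x

set_counts <- function(x, counts) {
  if (inherits(x, "edna_dataset")) { x$counts <- counts; x } else counts
}

#' Zero out low read counts per sample
#'
#' Removes false-positive-prone low counts: every cell with
#' `1 <= count <= t` is set to 0. With the default `t = 3` this drops
#' singletons, doubletons and tripletons per sample. Features reduced to
#' all-zero rows are retained (dropping them is [drop_empty_features]).
#'
#' @param table Count matrix (features x points) or [edna_dataset].
#' @param t Nonnegative integer threshold; `t = 0` leaves the table unchanged.
#' @return `list(table, report)`.
#' @export
remove_low_counts <- function(table, t = 3) {
  stopifnot(length(t) == 1, !is.na(t))
  if (t < 0) stop("low-count threshold t must be >= 0")
  m <- get_counts(table)
  low <- m >= 1 & m <= t
  m[low] <- 0L
  list(table = set_counts(table, m),
       report = filter_report(sprintf("remove_low_counts(t=%d)", as.integer(t)),
                              cells_zeroed = sum(low)))
}

#' Exclude features detected in negative controls
#'
#' Drops every feature with a positive count in any control point (the
#' presumed contaminants), then drops the control points themselves.
#' With no control points this is the identity plus an empty report.
#'
#' @param dataset An [edna_dataset].
#' @return `list(dataset, report)`.
#' @export
remove_control_features <- function(dataset) {
  stopifnot(inherits(dataset, "edna_dataset"))
  ctrl <- dataset$points$is_control
  if (!any(ctrl)) {
    return(list(dataset = dataset,
                report = filter_report("remove_control_features")))
  }
  ctrl_cols <- dataset$points$point_id[ctrl]
  in_ctrl <- rowSums(dataset$counts[, ctrl_cols, drop = FALSE] > 0) > 0
  counts <- dataset$counts[!in_ctrl, !(colnames(dataset$counts) %in% ctrl_cols),
                           drop = FALSE]
  points <- dataset$points[!ctrl, , drop = FALSE]
  list(dataset = edna_dataset(counts, points),
       report = filter_report("remove_control_features",
                              features_removed = sum(in_ctrl),
                              points_removed = length(ctrl_cols)))
}

#' Keep features detected at a minimum number of sampling points
#'
#' The "ASV comparison criteria": a feature is retained when its count is
#' positive at `>= k` points. The default `k = 1` keeps every detected
#' feature; raising `k` (e.g., to 5) excludes rarely detected features from
#' ordination and clustering.
#'
#' @param table Count matrix or [edna_dataset].
#' @param k Integer minimum number of detection points, `k >= 1`.
#' @return `list(table, report)`.
#' @export
prevalence_filter <- function(table, k = 1) {
  stopifnot(length(k) == 1, !is.na(k))
  if (k < 1) stop("prevalence threshold k must be >= 1")
  m <- get_counts(table)
  keep <- rowSums(m > 0) >= k
  list(table = set_counts(table, m[keep, , drop = FALSE]),
       report = filter_report(sprintf("prevalence_filter(k=%d)", as.integer(k)),
                              features_removed = sum(!keep)))
}

#' Drop features by an explicit ID list
#'
#' Consumes a pre-computed exclusion list (e.g., non-target or freshwater
#' taxa identified outside this package). Unknown names are ignored but
#' reported back in the `unmatched` element.
#'
#' @param table Count matrix or [edna_dataset].
#' @param names Character vector of feature IDs to drop.
#' @return `list(table, report, unmatched)`.
#' @export
exclude_features_by_name <- function(table, names) {
  names <- unique(as.character(names))
  m <- get_counts(table)
  hit <- rownames(m) %in% names
  list(table = set_counts(table, m[!hit, , drop = FALSE]),
       report = filter_report("exclude_features_by_name",
                              features_removed = sum(hit)),
       unmatched = setdiff(names, rownames(m)))
}

#' Drop sampling points by point or station ID
#'
#' Removes every point whose `point_id` or `station_id` appears in
#' `exclude_ids` (so excluding one station drops all of its depth points).
#' Features are untouched. Removing every point is an error.
#'
#' @param dataset An [edna_dataset].
#' @param exclude_ids Character vector of point or station IDs.
#' @return `list(dataset, report)`.
#' @export
subset_points <- function(dataset, exclude_ids) {
  stopifnot(inherits(dataset, "edna_dataset"))
  exclude_ids <- as.character(exclude_ids)
  drop <- dataset$points$point_id %in% exclude_ids |
    dataset$points$station_id %in% exclude_ids
  if (all(drop)) stop("no points remain after exclusion")
  if (!any(drop)) {
    return(list(dataset = dataset, report = filter_report("subset_points")))
  }
  keep_ids <- dataset$points$point_id[!drop]
  list(dataset = edna_dataset(dataset$counts[, keep_ids, drop = FALSE],
                              dataset$points[!drop, , drop = FALSE]),
       report = filter_report("subset_points", points_removed = sum(drop)))
}

#' Drop all-zero feature rows
#'
#' Features whose counts are zero everywhere (often the residue of earlier
#' filters) carry no information and are removed immediately before distance
#' computation.
#'
#' @param table Count matrix or [edna_dataset].
#' @return `list(table, report)`.
#' @export
drop_empty_features <- function(table) {
  m <- get_counts(table)
  keep <- rowSums(m) > 0
  list(table = set_counts(table, m[keep, , drop = FALSE]),
       report = filter_report("drop_empty_features",
                              features_removed = sum(!keep)))
}

#' Apply the canonical filter pipeline
#'
#' Applies, in this fixed order: [remove_low_counts] (threshold `t`),
#' [remove_control_features], [exclude_features_by_name],
#' [subset_points], [prevalence_filter] (threshold `k`), then
#' [drop_empty_features]. The order mirrors the upstream workflow:
#' per-sample low-count removal during preprocessing, control and taxon-list
#' exclusion, then analysis-time point subsetting and prevalence criteria.
#'
#' @param dataset An [edna_dataset].
#' @param t Low-count threshold (default 3).
#' @param k Prevalence threshold (default 1).
#' @param exclude_features Optional feature-ID exclusion list.
#' @param exclude_points Optional point/station-ID exclusion list.
#' @param drop_controls Apply control-based exclusion (default TRUE).
#' @return `list(dataset, reports)` where `reports` stacks the FilterReport
#'   rows in application order.
#' @export
apply_filters <- function(dataset, t = 3, k = 1, exclude_features = NULL,
                          exclude_points = NULL, drop_controls = TRUE) {
  stopifnot(inherits(dataset, "edna_dataset"))
  reports <- list()
  step <- remove_low_counts(dataset, t)
  dataset <- step$table; reports[[length(reports) + 1L]] <- step$report
  if (drop_controls) {
    step <- remove_control_features(dataset)
    dataset <- step$dataset; reports[[length(reports) + 1L]] <- step$report
  }
  if (length(exclude_features)) {
    step <- exclude_features_by_name(dataset, exclude_features)
    dataset <- step$table; reports[[length(reports) + 1L]] <- step$report
  }
  if (length(exclude_points)) {
    step <- subset_points(dataset, exclude_points)
    dataset <- step$dataset; reports[[length(reports) + 1L]] <- step$report
  }
  step <- prevalence_filter(dataset, k)
  dataset <- step$table; reports[[length(reports) + 1L]] <- step$report
  step <- drop_empty_features(dataset)
  dataset <- step$table; reports[[length(reports) + 1L]] <- step$report
  list(dataset = dataset, reports = do.call(rbind, reports))
}
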