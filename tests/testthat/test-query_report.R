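test_that("search_taxa finds planted features and behaves as a union", {
  fx <- case_fixtures()$distribution
  res <- search_taxa(fx$dataset, fx$planted_feature)
  expect_setequal(unique(res$records$point_id), fx$planted_points)
  expect_setequal(res$stations$station_id[res$stations$detected],
                  fx$planted_stations)
  # absent query: zero records, all stations undetected
  none <- search_taxa(fx$dataset, "no_such_feature")
  expect_equal(nrow(none$records), 0)
  expect_false(any(none$stations$detected))
  # union property over query sets
  q1 <- c(fx$planted_feature)
  q2 <- rownames(fx$dataset$counts)[1:3]
  both <- search_taxa(fx$dataset, c(q1, q2))
  u <- rbind(search_taxa(fx$dataset, q1)$records,
             search_taxa(fx$dataset, q2)$records)
  key <- function(df) sort(paste(df$feature_id, df$point_id))
  expect_identical(key(both$records), key(u))
})

test_that("species-list matching normalizes names and summarizes per dataset", {
  fx <- case_fixtures()$species_lists
  res <- match_species_list(fx$species, fx$datasets)
  expect_equal(length(res$detected_by_dataset$dsA), fx$expected$dsA)
  expect_equal(length(res$detected_by_dataset$dsB), fx$expected$dsB)
  expect_equal(length(res$shared), fx$expected$shared)
  expect_identical(res$shared, "Katsuwonus pelamis")
  # underscore/case normalization
  expect_identical(normalize_species_name("Katsuwonus_pelamis"),
                   "katsuwonus pelamis")
  expect_identical(normalize_species_name("  Mola   mola "), "mola mola")
  # all-absent list
  res0 <- match_species_list(c("Nemo fishus"), fx$datasets)
  expect_equal(res0$summary$n_datasets_detected, 0)
})

test_that("detection_by_depth bins detections and conserves totals", {
  m <- matrix(c(3L, 0L, 5L, 2L, 0L, 0L, 1L, 4L), 2, 4,
              dimnames = list(c("a", "b"), paste0("p", 1:4)))
  pts <- make_points(paste0("p", 1:4), station = c("S1", "S1", "S2", "S2"),
                     depth = c(10, 50, 10, NA))
  ds <- edna_dataset(m, pts)
  tab <- detection_by_depth(ds)
  expect_equal(sum(tab$n_detections), sum(m > 0))
  expect_equal(tab$n_detections[tab$depth == "10"], 1L)  # p1: a only
  expect_equal(tab$n_detections[tab$depth == "50"], 2L)  # p2: a, b
  expect_equal(tab$n_detections[tab$depth == "unknown"], 2L)  # p4: a, b
  # restricting to one feature partitions its detections across bins
  onlyA <- detection_by_depth(ds, features = "a")
  expect_equal(sum(onlyA$n_detections), sum(m["a", ] > 0))
  expect_equal(onlyA$n_detections[onlyA$depth == "10"], 1L)
})

test_that("batch diagnostics flag detection-rate imbalances", {
  fx <- case_fixtures()$batch
  diag5 <- batch_diagnostics(fx$dataset)
  expect_true(diag5$warning)
  expect_gt(diag5$ratio, 3)
  # an independent tally of the group means
  pts <- fx$dataset$points
  rich <- colSums(fx$dataset$counts > 0)
  for (g in unique(pts$dataset_label)) {
    ids <- pts$point_id[pts$dataset_label == g]
    expect_equal(
      diag5$per_group$mean_richness[diag5$per_group$group == g],
      mean(rich[ids]))
  }
  # identical groups: no warning; single group: ratio 1
  m <- matrix(c(1L, 1L, 1L, 1L), 2, 2, dimnames = list(c("a", "b"), c("p", "q")))
  two <- edna_dataset(m, make_points(c("p", "q"), label = c("A", "B")))
  expect_false(batch_diagnostics(two)$warning)
  one <- make_dataset(m)
  expect_equal(batch_diagnostics(one)$ratio, 1)
})

test_that("stations_aggregate sums depth points and conserves reads", {
  m <- matrix(c(0L, 3L, 2L, 0L, 5L, 1L), 2, 3,
              dimnames = list(c("a", "b"), c("p1", "p2", "p3")))
  pts <- make_points(c("p1", "p2", "p3"), station = c("S1", "S1", "S2"),
                     depth = c(10, 50, 10))
  agg <- stations_aggregate(edna_dataset(m, pts))
  # per-feature sums over S1's two depths: a: 0+2 = 2, b: 3+0 = 3
  expect_equal(agg$counts[, "S1"], c(a = 2L, b = 3L))
  expect_equal(agg$counts[, "S2"], c(a = 5L, b = 1L))
  expect_equal(sum(agg$counts), sum(m))
  expect_true(all(is.na(agg$points$depth_m)))
  # presence of aggregate = union of member presences
  expect_equal(agg$counts[, "S1"] > 0, (m[, "p1"] > 0) | (m[, "p2"] > 0))
  # single-depth station passes through unchanged
  expect_equal(unname(agg$counts[, "S2"]), unname(m[, "p3"]))
})

test_that("heatmap ordering is a permutation following the dendrogram", {
  fx <- case_fixtures()$batch
  hm <- heatmap_matrix(fx$dataset)
  expect_setequal(hm$col_order, colnames(fx$dataset$counts))
  expect_true(all(hm$matrix %in% c(0L, 1L)))
  expect_identical(hm$col_order,
                   hm$tree$leaf_ids[ednacomp:::dendrogram_leaf_order(hm$tree)])
  # rows ordered by descending prevalence
  prev <- rowSums(hm$matrix)
  expect_true(all(diff(prev) <= 0 | diff(prev) == 0))
  expect_true(all(diff(unname(prev)) <= 0))
})

test_that("map_geojson emits a valid FeatureCollection", {
  fx <- case_fixtures()$distribution
  det <- search_taxa(fx$dataset, fx$planted_feature)
  b <- boundary_hypothesis("test line", data.frame(lon = c(125, 135),
                                                   lat = c(30, 30)))
  gj <- map_geojson(fx$dataset, detections = det, boundaries = b)
  expect_identical(gj$type, "FeatureCollection")
  stations <- unique(fx$dataset$points$station_id)
  pt_feats <- Filter(function(f) f$geometry$type == "Point", gj$features)
  expect_equal(length(pt_feats), length(stations))
  for (f in pt_feats) {
    expect_identical(f$type, "Feature")
    lonlat <- f$geometry$coordinates
    expect_length(lonlat, 2)
    expect_true(lonlat[1] >= -180 && lonlat[1] <= 180)  # lon first
    expect_true(lonlat[2] >= -90 && lonlat[2] <= 90)
    expect_identical(f$properties$detected,
                     f$properties$station_id %in% fx$planted_stations)
  }
  line_feats <- Filter(function(f) f$geometry$type == "LineString", gj$features)
  expect_length(line_feats, 1)
  # serialized form parses back as valid JSON with the same feature count
  tf <- withr::local_tempfile(fileext = ".geojson")
  write_geojson(gj, tf)
  parsed <- jsonlite::read_json(tf)
  expect_identical(parsed$type, "FeatureCollection")
  expect_length(parsed$features, length(gj$features))
})

test_that("render_report writes the seven ordered sections", {
  fx <- case_fixtures()$boundary
  filt <- apply_filters(fx$dataset)
  ds <- filt$dataset
  D <- dissimilarity_matrix(ds)
  results <- list(dataset = ds, map = map_geojson(ds),
                  depth = detection_by_depth(ds),
                  heatmap = heatmap_matrix(ds),
                  nmds = nmds(D, n_starts = 3, seed = 1),
                  cluster = hierarchical_cluster(D),
                  species_list = data.frame(feature_id = rownames(ds$counts),
                                            total_reads = rowSums(ds$counts)),
                  batch = batch_diagnostics(ds),
                  filter_reports = filt$reports,
                  run_log = list(seed = 1))
  out <- withr::local_tempdir()
  render_report(results, out, plots = FALSE)
  html <- readLines(file.path(out, "report.html"))
  sections <- c("Sampling site map", "Detection depth", "Heatmap", "nMDS",
                "Cluster", "Species list", "Dependencies")
  pos <- vapply(sections, function(s) grep(paste0("<h2>", s, "</h2>"), html)[1],
                numeric(1))
  expect_false(anyNA(pos))
  expect_true(all(diff(pos) > 0))   # paper-ordered sections
  expect_true(file.exists(file.path(out, "map.geojson")))
  expect_true(file.exists(file.path(out, "nmds_coords.csv")))
  expect_true(file.exists(file.path(out, "cluster.nwk")))
  # partial bundle: missing sections marked skipped, present ones rendered
  out2 <- withr::local_tempdir()
  render_report(list(dataset = ds, map = map_geojson(ds)), out2, plots = FALSE)
  html2 <- paste(readLines(file.path(out2, "report.html")), collapse = "\n")
  expect_match(html2, "<h2>nMDS</h2>\\s*<p>skipped</p>")
  expect_error(render_report(list(), withr::local_tempdir()), "empty")
  # byte-identical regeneration from the same bundle
  out3 <- withr::local_tempdir()
  render_report(results, out3, plots = FALSE)
  expect_identical(readLines(file.path(out3, "report.html")), html)
})
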