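# Ordered multi-section report. Sections follow the summary-output order:
# sampling-site map, detection depth, heatmap, nMDS, cluster, species list,
# and a closing dependencies section. Every numeric result is also written
# as CSV/JSON next to the HTML. Output is deterministic (no timestamps), so
# re-rendering the same results bundle reproduces the files byte for byte.

REPORT_SECTIONS <- c("Sampling site map", "Detection depth", "Heatmap",
                     "nMDS", "Cluster", "Species list", "Dependencies")

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_table <- function(df, max_rows = 50) {
  shown <- utils::head(df, max_rows)
  cells <- function(row, tag) paste0("<", tag, ">",
                                     html_escape(as.character(row)),
                                     "</", tag, ">", collapse = "")
  rows <- apply(shown, 1, cells, tag = "td")
  paste0("<table><tr>", cells(names(df), "th"), "</tr>",
         paste0("<tr>", rows, "</tr>", collapse = ""), "</table>",
         if (nrow(df) > max_rows)
           sprintf("<p>(%d of %d rows shown)</p>", max_rows, nrow(df)) else "")
}

#' Render the multi-section analysis report
#'
#' Writes `report.html` plus machine-readable companions (GeoJSON, CSV,
#' JSON, newick) and static PNG plots into `out_dir`. Sections appear in the
#' fixed order: sampling-site map, detection depth, heatmap, nMDS, cluster,
#' species list, dependencies; a section whose result is absent from the
#' bundle is marked skipped.
#'
#' @param results Bundle as produced by [cmd_analyze]: any subset of
#'   `dataset`, `map` ([map_geojson] output), `depth`
#'   ([detection_by_depth]), `heatmap` ([heatmap_matrix]), `nmds`, `cluster`,
#'   `species_list` (data frame), `boundary` ([boundary_test]), `batch`
#'   ([batch_diagnostics]), `filter_reports`, `run_log` (list).
#' @param out_dir Output directory (created if needed).
#' @param plots Emit PNG figures (default TRUE).
#' @return `out_dir`, invisibly.
#' @export
render_report <- function(results, out_dir, plots = TRUE) {
  have <- intersect(c("map", "depth", "heatmap", "nmds", "cluster",
                      "species_list"), names(results))
  if (length(have) == 0) stop("empty results bundle: nothing to report")
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  body <- character()
  sec <- function(title, content) {
    body <<- c(body, sprintf("<h2>%s</h2>", title), content)
  }
  # 1. Sampling site map
  if (!is.null(results$map)) {
    write_geojson(results$map, file.path(out_dir, "map.geojson"))
    if (plots && !is.null(results$dataset))
      plot_png(file.path(out_dir, "map.png"),
               function() plot_station_map(results$dataset, results$boundary_lines))
    sec("Sampling site map",
        sprintf("<p>%d map features written to map.geojson</p>%s",
                length(results$map$features),
                if (plots && !is.null(results$dataset))
                  "<img src='map.png' width='640'/>" else ""))
  } else sec("Sampling site map", "<p>skipped</p>")
  # 2. Detection depth
  if (!is.null(results$depth)) {
    utils::write.csv(results$depth, file.path(out_dir, "detection_depth.csv"),
                     row.names = FALSE)
    sec("Detection depth", html_table(results$depth))
  } else sec("Detection depth", "<p>skipped</p>")
  # 3. Heatmap
  if (!is.null(results$heatmap)) {
    hm <- results$heatmap
    utils::write.csv(data.frame(feature_id = rownames(hm$matrix),
                                as.data.frame(hm$matrix, check.names = FALSE),
                                check.names = FALSE),
                     file.path(out_dir, "heatmap.csv"), row.names = FALSE)
    if (plots)
      plot_png(file.path(out_dir, "heatmap.png"),
               function() plot_presence_heatmap(hm))
    batch_note <- if (!is.null(results$batch)) {
      sprintf("<p>Group mean richness ratio: %.2f%s</p>",
              results$batch$ratio,
              if (results$batch$warning)
                " &mdash; WARNING: possible batch effect" else "")
    } else ""
    sec("Heatmap", paste0(
      sprintf("<p>%d features x %d points (presence/absence) in heatmap.csv</p>",
              nrow(hm$matrix), ncol(hm$matrix)), batch_note,
      if (plots) "<img src='heatmap.png' width='640'/>" else ""))
  } else sec("Heatmap", "<p>skipped</p>")
  # 4. nMDS
  if (!is.null(results$nmds)) {
    write_ordination_csv(results$nmds, file.path(out_dir, "nmds_coords.csv"))
    if (plots)
      plot_png(file.path(out_dir, "nmds.png"),
               function() plot_nmds(results$nmds, results$dataset))
    perma_html <- ""
    if (!is.null(results$boundary)) {
      bt <- results$boundary
      jsonlite::write_json(
        list(boundary = bt$boundary_name,
             n_north = bt$n_north, n_south = bt$n_south,
             excluded_ids = bt$excluded_ids,
             p1 = unclass(bt$p1)[c("f_stat", "r2", "p_value", "n_perm",
                                   "exhaustive", "df_among", "df_within")],
             p2 = unclass(bt$p2)[c("f_stat", "r2", "p_value", "n_perm",
                                   "exhaustive", "df_among", "df_within")]),
        file.path(out_dir, "permanova.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
      perma_html <- sprintf(
        "<p>PERMANOVA across boundary '%s': p1 = %.4g (all stations), p2 = %.4g (%d excluded)</p>",
        html_escape(bt$boundary_name), bt$p1$p_value, bt$p2$p_value,
        length(bt$excluded_ids))
    }
    sec("nMDS", paste0(
      sprintf("<p>Stress-1 = %.5f (%d starts, converged = %s); coordinates in nmds_coords.csv</p>",
              results$nmds$stress, results$nmds$n_starts,
              results$nmds$converged),
      perma_html,
      if (plots) "<img src='nmds.png' width='640'/>" else ""))
  } else sec("nMDS", "<p>skipped</p>")
  # 5. Cluster
  if (!is.null(results$cluster)) {
    writeLines(dendrogram_to_newick(results$cluster),
               file.path(out_dir, "cluster.nwk"))
    if (plots)
      plot_png(file.path(out_dir, "cluster.png"),
               function() graphics::plot(stats::as.hclust(results$cluster),
                                         main = "", sub = "", xlab = ""))
    sec("Cluster",
        paste0(sprintf("<p>%s-linkage dendrogram of %d points in cluster.nwk</p>",
                       results$cluster$linkage,
                       length(results$cluster$leaf_ids)),
               if (plots) "<img src='cluster.png' width='640'/>" else ""))
  } else sec("Cluster", "<p>skipped</p>")
  # 6. Species list
  if (!is.null(results$species_list)) {
    utils::write.csv(results$species_list,
                     file.path(out_dir, "species_list.csv"), row.names = FALSE)
    sec("Species list", html_table(results$species_list))
  } else sec("Species list", "<p>skipped</p>")
  # 7. Dependencies
  deps <- data.frame(
    software = c("R", "ednacomp", "jsonlite", "readxl"),
    version = c(paste(R.version$major, R.version$minor, sep = "."),
                as.character(utils::packageVersion("ednacomp")),
                as.character(utils::packageVersion("jsonlite")),
                as.character(utils::packageVersion("readxl"))),
    stringsAsFactors = FALSE)
  sec("Dependencies", html_table(deps))
  # companions
  if (!is.null(results$filter_reports))
    utils::write.csv(results$filter_reports,
                     file.path(out_dir, "filter_reports.csv"), row.names = FALSE)
  if (!is.null(results$run_log))
    jsonlite::write_json(results$run_log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  html <- c("<!DOCTYPE html>", "<html><head><meta charset='utf-8'/>",
            "<title>eDNA community comparison report</title>",
            "<style>body{font-family:sans-serif;margin:2em}table{border-collapse:collapse}",
            "td,th{border:1px solid #999;padding:2px 6px}</style></head><body>",
            "<h1>eDNA community comparison report</h1>", body,
            "</body></html>")
  writeLines(html, file.path(out_dir, "report.html"))
  invisible(out_dir)
}

plot_png <- function(path, fn, width = 800, height = 600) {
  grDevices::png(path, width = width, height = height, type = "cairo")
  on.exit(grDevices::dev.off())
  fn()
}

plot_station_map <- function(dataset, boundaries = NULL) {
  pts <- dataset$points
  pts <- pts[!is.na(pts$latitude) & !is.na(pts$longitude), , drop = FALSE]
  st <- pts[!duplicated(pts$station_id), , drop = FALSE]
  labs <- factor(st$dataset_label)
  graphics::plot(st$longitude, st$latitude, pch = 19,
                 col = as.integer(labs) + 1, asp = 1,
                 xlab = "Longitude (deg E)", ylab = "Latitude (deg N)")
  graphics::text(st$longitude, st$latitude, st$station_id, pos = 3, cex = 0.6)
  if (!is.null(boundaries)) {
    if (inherits(boundaries, "boundary_hypothesis")) boundaries <- list(boundaries)
    for (b in boundaries)
      graphics::lines(b$vertices$lon, b$vertices$lat, lty = 2)
  }
  if (nlevels(labs) > 1)
    graphics::legend("topright", legend = levels(labs), pch = 19,
                     col = seq_len(nlevels(labs)) + 1)
}

plot_presence_heatmap <- function(hm) {
  m <- hm$matrix
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m[rev(seq_len(nrow(m))), ]),
                  col = c("white", "steelblue4"), axes = FALSE,
                  xlab = "Sampling points (dendrogram order)",
                  ylab = "Features (by prevalence)")
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2,
                 cex.axis = 0.6)
  graphics::box()
}

plot_nmds <- function(ord, dataset = NULL) {
  cols <- 1
  if (!is.null(dataset)) {
    labs <- factor(dataset$points$dataset_label[
      match(ord$point_ids, dataset$points$point_id)])
    cols <- as.integer(labs) + 1
  }
  graphics::plot(ord$coords[, 1], ord$coords[, 2], pch = 19, col = cols,
                 xlab = "nMDS axis 1", ylab = "nMDS axis 2",
                 main = sprintf("stress-1 = %.4f", ord$stress))
  graphics::text(ord$coords[, 1], ord$coords[, 2], ord$point_ids,
                 pos = 3, cex = 0.6)
}
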