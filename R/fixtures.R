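# Seeded synthetic-dataset generator. The generative model is
# occupancy-then-abundance (a hurdle): whether a feature is detected at a
# point follows a logistic model with regional, depth, and batch terms, and
# read counts conditional on detection are 1 + negative binomial. Detection
# (presence/absence) carries the regional signal, matching the use of the
# Jaccard measure on field data where detection is the reliable signal;
# abundance matters only for Bray-Curtis paths.

#' Configuration for the synthetic-data generator
#'
#' @param n_stations Number of stations (>= 2), placed on a west-east
#'   transect straddling a synthetic zonal boundary at latitude 30 between
#'   longitudes 128 and 134, alternating north/south.
#' @param depths Depth levels sampled at every station, meters (default
#'   10/50/100/150).
#' @param n_features Number of features (ASVs).
#' @param baseline_occupancy Baseline per-feature, per-point detection
#'   probability.
#' @param region_effect Log-odds shift added to the occupancy of the
#'   region-affected feature fraction at points south of the boundary
#'   (0 = no regional structure).
#' @param region_fraction Fraction of features carrying the regional effect.
#' @param batch_detection_rate Named vector of per-dataset-label detection
#'   multipliers in (0, 1]; detections are thinned by this rate, emulating
#'   platform/protocol batch effects. Stations are assigned to labels in
#'   round-robin order. Default: one label, rate 1.
#' @param depth_effect Log-odds trend per depth level (0-based index into
#'   `depths`) applied to the depth-affected feature fraction.
#' @param depth_fraction Fraction of features carrying the depth trend.
#' @param read_mean,read_dispersion Negative-binomial mean and dispersion
#'   (size) for counts given detection; the stored count is 1 + NB so
#'   detected features always have a positive read count.
#' @param n_controls Number of negative-control points (no coordinates).
#' @param n_contaminants Number of features injected into the controls.
#' @param seed Integer seed; everything downstream is deterministic in it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_stations = 20, depths = c(10, 50, 100, 150),
                       n_features = 200, baseline_occupancy = 0.25,
                       region_effect = 0, region_fraction = 0.3,
                       batch_detection_rate = c(batchA = 1),
                       depth_effect = 0, depth_fraction = 0.3,
                       read_mean = 50, read_dispersion = 0.8,
                       n_controls = 0, n_contaminants = 0, seed = 1) {
  cfg <- list(n_stations = as.integer(n_stations), depths = as.numeric(depths),
              n_features = as.integer(n_features),
              baseline_occupancy = baseline_occupancy,
              region_effect = region_effect, region_fraction = region_fraction,
              batch_detection_rate = batch_detection_rate,
              depth_effect = depth_effect, depth_fraction = depth_fraction,
              read_mean = read_mean, read_dispersion = read_dispersion,
              n_controls = as.integer(n_controls),
              n_contaminants = as.integer(n_contaminants),
              seed = as.integer(seed))
  stopifnot(cfg$n_stations >= 2, cfg$n_features >= 1,
            cfg$baseline_occupancy >= 0, cfg$baseline_occupancy <= 1,
            cfg$region_fraction >= 0, cfg$region_fraction <= 1,
            cfg$depth_fraction >= 0, cfg$depth_fraction <= 1,
            all(cfg$batch_detection_rate > 0),
            all(cfg$batch_detection_rate <= 1),
            cfg$read_dispersion > 0, length(cfg$depths) >= 1)
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic geolocated community dataset
#'
#' Stations are laid out west to east across a zonal boundary at latitude
#' 30 (even stations north, odd stations south, with seeded jitter); each
#' station carries one sampling point per configured depth. Occupancy is
#' drawn from the logistic model (baseline + regional shift south of the
#' boundary on the affected features + depth trend), thinned by the
#' dataset's batch detection rate; counts given detection are
#' 1 + NB(mean, dispersion). Controls are all-zero except the configured
#' contaminant features.
#'
#' @param config A [sim_config].
#' @return `list(dataset, truth)` where `truth` records the generating
#'   boundary, each station's true side, each point's batch, and the
#'   affected/contaminant feature sets.
#' @export
generate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ns <- config$n_stations
  station_ids <- sprintf("St%02d", seq_len(ns))
  lon <- 128 + 6 * (seq_len(ns) - 1) / max(ns - 1, 1)
  north <- seq_len(ns) %% 2 == 0
  lat <- ifelse(north, 30 + 0.5 + stats::runif(ns, 0, 1.5),
                30 - 0.5 - stats::runif(ns, 0, 1.5))
  labels <- names(config$batch_detection_rate)
  batch <- labels[(seq_len(ns) - 1) %% length(labels) + 1]
  feature_ids <- sprintf("ASV_%04d", seq_len(config$n_features))
  n_region <- round(config$region_fraction * config$n_features)
  region_features <- feature_ids[seq_len(n_region)]
  n_depth <- round(config$depth_fraction * config$n_features)
  depth_features <- if (n_depth > 0)
    feature_ids[(config$n_features - n_depth + 1):config$n_features]
  else character()

  pts <- expand.grid(depth = config$depths, station = seq_len(ns),
                     KEEP.OUT.ATTRS = FALSE)
  point_ids <- sprintf("%s_d%03d", station_ids[pts$station], pts$depth)
  base_logit <- stats::qlogis(min(max(config$baseline_occupancy, 1e-6), 1 - 1e-6))
  counts <- matrix(0L, config$n_features, length(point_ids),
                   dimnames = list(feature_ids, point_ids))
  for (j in seq_along(point_ids)) {
    st <- pts$station[j]
    depth_idx <- match(pts$depth[j], config$depths) - 1
    eta <- rep(base_logit, config$n_features)
    if (!north[st])
      eta[feature_ids %in% region_features] <-
        eta[feature_ids %in% region_features] + config$region_effect
    eta[feature_ids %in% depth_features] <-
      eta[feature_ids %in% depth_features] + config$depth_effect * depth_idx
    p <- stats::plogis(eta) * config$batch_detection_rate[[batch[st]]]
    occ <- stats::runif(config$n_features) < p
    n_occ <- sum(occ)
    if (n_occ > 0)
      counts[occ, j] <- 1L + stats::rnbinom(n_occ, size = config$read_dispersion,
                                            mu = config$read_mean)
  }
  points <- data.frame(point_id = point_ids,
                       station_id = station_ids[pts$station],
                       latitude = lat[pts$station],
                       longitude = lon[pts$station],
                       depth_m = pts$depth,
                       dataset_label = batch[pts$station],
                       is_control = FALSE, stringsAsFactors = FALSE)
  contaminant_features <- character()
  if (config$n_controls > 0) {
    ctrl_ids <- sprintf("CTRL%02d", seq_len(config$n_controls))
    ctrl_counts <- matrix(0L, config$n_features, config$n_controls,
                          dimnames = list(feature_ids, ctrl_ids))
    if (config$n_contaminants > 0) {
      contaminant_features <- sample(feature_ids, config$n_contaminants)
      ctrl_counts[contaminant_features, ] <-
        1L + stats::rnbinom(config$n_contaminants * config$n_controls,
                            size = config$read_dispersion,
                            mu = config$read_mean)
    }
    counts <- cbind(counts, ctrl_counts)
    points <- rbind(points,
                    data.frame(point_id = ctrl_ids, station_id = ctrl_ids,
                               latitude = NA_real_, longitude = NA_real_,
                               depth_m = NA_real_,
                               dataset_label = labels[1],
                               is_control = TRUE, stringsAsFactors = FALSE))
  }
  truth <- list(
    boundary = boundary_hypothesis("synthetic zonal boundary",
                                   data.frame(lon = c(127, 135), lat = c(30, 30))),
    station_side = stats::setNames(ifelse(north, "north", "south"), station_ids),
    point_side = stats::setNames(ifelse(north[pts$station], "north", "south"),
                                 point_ids),
    batch = stats::setNames(batch[pts$station], point_ids),
    region_features = region_features,
    depth_features = depth_features,
    contaminant_features = contaminant_features)
  list(dataset = edna_dataset(counts, points), truth = truth)
}

#' Deterministic mini-fixtures for the five analysis shapes
#'
#' Small named datasets, one per case-study shape: a batch-confounded merge
#' (`batch`), a north/south boundary contrast (`boundary`), an
#' abundance-structured community where presences agree but counts differ
#' (`abundance`), a pair of species-name tables for list matching
#' (`species_lists`), and a single planted feature with a known
#' distribution (`distribution`).
#'
#' @return Named list of fixtures; each element is a `list(dataset, ...)`
#'   with the ground truth needed by its tests.
#' @export
case_fixtures <- function() {
  out <- list()
  # batch: two cruise labels, second with strongly thinned detection (5x)
  out$batch <- generate_dataset(sim_config(
    n_stations = 10, depths = c(10, 50), n_features = 80,
    baseline_occupancy = 0.5,
    batch_detection_rate = c(cruiseA = 1, cruiseB = 0.2), seed = 101))
  # boundary: strong regional contrast
  out$boundary <- generate_dataset(sim_config(
    n_stations = 12, depths = 10, n_features = 100,
    baseline_occupancy = 0.2, region_effect = 2.5, seed = 102))
  # abundance: same presence sets, different counts (Bray-Curtis vs Jaccard)
  counts <- matrix(c(10L, 1L, 5L,
                     100L, 1L, 5L,
                     10L, 80L, 5L), nrow = 3,
                   dimnames = list(c("sp1", "sp2", "sp3"), c("P1", "P2", "P3")))
  pts <- data.frame(point_id = c("P1", "P2", "P3"),
                    station_id = c("S1", "S2", "S3"),
                    latitude = c(29, 30.5, 31), longitude = c(129, 130, 131),
                    depth_m = 10, dataset_label = "abund",
                    is_control = FALSE, stringsAsFactors = FALSE)
  out$abundance <- list(dataset = edna_dataset(counts, pts))
  # species_lists: 10-name query list; 3 detected in A, 2 in B, 1 shared
  listed <- c("Katsuwonus pelamis", "Caranx ignobilis", "Thunnus albacares",
              "Seriola dumerili", "Sphyraena barracuda", "Cheilinus undulatus",
              "Carcharhinus melanopterus", "Naso unicornis",
              "Epinephelus lanceolatus", "Mola mola")
  mkds <- function(features, label, lon0) {
    m <- matrix(5L, length(features), 2,
                dimnames = list(features, paste0(label, c("_p1", "_p2"))))
    p <- data.frame(point_id = paste0(label, c("_p1", "_p2")),
                    station_id = paste0(label, c("_s1", "_s2")),
                    latitude = c(30, 31), longitude = c(lon0, lon0 + 1),
                    depth_m = 10, dataset_label = label,
                    is_control = FALSE, stringsAsFactors = FALSE)
    edna_dataset(m, p)
  }
  dsA <- mkds(c("Katsuwonus_pelamis", "Thunnus_albacares", "Mola_mola",
                "Decapterus_macarellus"), "dsA", 130)
  dsB <- mkds(c("Katsuwonus_pelamis", "Naso_unicornis", "Auxis_thazard"),
              "dsB", 140)
  out$species_lists <- list(datasets = list(dsA = dsA, dsB = dsB),
                            species = listed,
                            expected = list(dsA = 3L, dsB = 2L, shared = 1L))
  # distribution: planted feature at known stations and depths (10/50 m)
  gen <- generate_dataset(sim_config(n_stations = 8, depths = c(10, 50, 100, 150),
                                     n_features = 40, baseline_occupancy = 0.3,
                                     seed = 105))
  ds <- gen$dataset
  planted <- "ASV_TARGET"
  planted_points <- ds$points$point_id[ds$points$station_id %in%
                                         c("St01", "St03", "St05") &
                                         ds$points$depth_m %in% c(10, 50)]
  row <- matrix(0L, 1, ncol(ds$counts),
                dimnames = list(planted, colnames(ds$counts)))
  row[1, planted_points] <- 7L
  out$distribution <- list(dataset = edna_dataset(rbind(ds$counts, row), ds$points),
                           planted_feature = planted,
                           planted_points = planted_points,
                           planted_stations = c("St01", "St03", "St05"))
  out
}
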