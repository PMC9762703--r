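## default analysis configuration; every entry can be overridden from JSON
default_config <- function() {
  list(
    seed = 1L,
    out_dir = "devnetdyn-out",
    stages = c("simulate", "detect", "netstats", "stprnn"),
    simulate = list(
      n_frames = 2400L, frame_rate = 11.63, frame_shape = c(40L, 60L),
      overlap_fraction = 0.5, cell_rates = 3, neuropil_rate = 3,
      neuropil_amplitude = 10, noise_scale = 4, min_isi_frames = 12L,
      min_cross_isi_frames = 6L,
      cells = list(list(center = c(20, 20), inner_radius = 4,
                        outer_radius = 7, amplitude = 50),
                   list(center = c(20, 40), inner_radius = 4,
                        outer_radius = 7, amplitude = 50))),
    detect = list(expand_px = 2, baseline_window = 500L, n_candidates = 8L,
                  sg_window = 6L, min_separation = 5L, avg_frames = 5L,
                  qc_min_correlation = 0.5, qc_center_contrast = TRUE,
                  smooth_window = 5L, k_lead = 3.5, threshold_floor = 1.0,
                  refractory = 3L, threshold_floor_dff = 0,
                  compare_mean_dff = TRUE, tolerance_frames = 3L),
    netstats = list(dilation = 3L, nb_shuffles = 200L,
                    nb_percentile = 99.99, sttc_dt = 3L,
                    sttc_shuffles = 200L, popc_shuffles = 200L,
                    popc_sd = 3L, popc_bin = 10L, motif_bin = 10L,
                    motif_shuffles = 200L, continuity_bin = 116L),
    stprnn = list(variant = "STP-RNN", run_deadline = FALSE,
                  silence = c(0.25, 1), probe = c(0.25, 0.25)))
}

## deep merge of user values into defaults; unknown keys are an error
merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (path == "") key else paste0(path, "$", key)
    if (!key %in% names(defaults))
      stop("unknown configuration key: ", full)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        is.list(user[[key]]))
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    else defaults[[key]] <- user[[key]]
  }
  defaults
}

#' Load an analysis configuration from JSON
#'
#' Fills defaults for every unset key and rejects unknown keys (naming
#' the offending key). An empty JSON object yields the full default
#' configuration.
#'
#' @param path JSON file path, or `NULL` for the defaults.
#' @return list of class `analysis_config`.
#' @export
load_config <- function(path = NULL) {
  user <- if (is.null(path)) list()
    else jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- merge_config(default_config(), user)
  structure(cfg, class = "analysis_config")
}

#' Save an analysis configuration as JSON
#'
#' @param config `analysis_config`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

## stable per-stage sub-seed: editing one stage's settings does not
## perturb another stage's random draws
stage_seed <- function(global_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131L)
  (as.integer(global_seed) * 7919L + h) %% 2147483562L
}

#' Run the end-to-end pipeline
#'
#' Executes the selected stages in dependency order: movie simulation,
#' transient detection (with ground-truth evaluation and the mean
#' fluorescence-change comparison detector), network statistics on the
#' resulting raster, and the network-model fixed-point analysis. All
#' artifacts are written under the configured output directory together
#' with the fully resolved configuration; a fixed seed makes every
#' numeric output reproducible.
#'
#' @param config `analysis_config` from [load_config()].
#' @return list of class `result_bundle`: per-stage results plus an
#'   `index` of written files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  save_config(config, file.path(out, "resolved_config.json"))
  index <- c(resolved_config = file.path(out, "resolved_config.json"))
  results <- list()
  sim <- NULL
  if ("simulate" %in% config$stages) {
    sc <- config$simulate
    cells <- lapply(sc$cells, function(cc)
      ring_cell_spec(cc$center, cc$inner_radius, cc$outer_radius,
                     cc$amplitude))
    mc <- movie_sim_config(
      n_frames = sc$n_frames, cells = cells, frame_rate = sc$frame_rate,
      frame_shape = sc$frame_shape,
      overlap_fraction = sc$overlap_fraction, cell_rates = sc$cell_rates,
      neuropil_rate = sc$neuropil_rate,
      neuropil_amplitude = sc$neuropil_amplitude,
      noise_scale = sc$noise_scale, min_isi_frames = sc$min_isi_frames,
      min_cross_isi_frames = sc$min_cross_isi_frames,
      seed = stage_seed(config$seed, "simulate"))
    sim <- simulate_movie(mc)
    write_movie_tiff(sim$movie, file.path(out, "movie.tif"),
                     scale = 65535)
    write_label_tiff(masks_to_labels(sim$masks), file.path(out, "rois.tif"))
    truth_mat <- matrix(0L, length(sim$truth$spikes), sc$n_frames)
    for (i in seq_along(sim$truth$spikes))
      truth_mat[i, sim$truth$spikes[[i]]] <- 1L
    write_raster_csv(event_raster(truth_mat, sc$frame_rate),
                     file.path(out, "ground_truth.csv"))
    index <- c(index, movie = file.path(out, "movie.tif"),
               rois = file.path(out, "rois.tif"),
               ground_truth = file.path(out, "ground_truth.csv"))
    results$simulate <- sim
  }
  raster <- NULL
  if ("detect" %in% config$stages) {
    if (is.null(sim)) stop("detect stage requires the simulate stage")
    dc <- config$detect
    det_cfg <- detection_config(
      expand_px = dc$expand_px, baseline_window = dc$baseline_window,
      n_candidates = dc$n_candidates, sg_window = dc$sg_window,
      min_separation = dc$min_separation, avg_frames = dc$avg_frames,
      qc_min_correlation = dc$qc_min_correlation,
      qc_center_contrast = dc$qc_center_contrast,
      smooth_window = dc$smooth_window, k_lead = dc$k_lead,
      threshold_floor = dc$threshold_floor, refractory = dc$refractory,
      threshold_floor_dff = dc$threshold_floor_dff)
    det <- detect(sim$movie, masks_to_labels(sim$masks), det_cfg)
    raster <- det$raster
    write_raster_csv(raster, file.path(out, "raster.csv"))
    metrics <- lapply(seq_along(sim$truth$spikes), function(i)
      unclass(evaluate_detection(which(raster$mat[i, ] == 1L),
                                 sim$truth$spikes[[i]],
                                 dc$tolerance_frames)))
    if (isTRUE(dc$compare_mean_dff)) {
      det2 <- detect_mean_dff(sim$movie, masks_to_labels(sim$masks),
                              det_cfg)
      metrics_mean <- lapply(seq_along(sim$truth$spikes), function(i)
        unclass(evaluate_detection(which(det2$raster$mat[i, ] == 1L),
                                   sim$truth$spikes[[i]],
                                   dc$tolerance_frames)))
    } else metrics_mean <- NULL
    jsonlite::write_json(
      list(template_matching = metrics, mean_dff = metrics_mean),
      file.path(out, "detection_metrics.json"),
      auto_unbox = TRUE, digits = NA)
    index <- c(index, raster = file.path(out, "raster.csv"),
               detection_metrics = file.path(out, "detection_metrics.json"))
    results$detect <- list(result = det, metrics = metrics,
                           metrics_mean = metrics_mean)
  }
  if ("netstats" %in% config$stages) {
    if (is.null(raster)) stop("netstats stage requires the detect stage")
    nc <- config$netstats
    ns_seed <- stage_seed(config$seed, "netstats")
    cs <- cell_statistics(raster)
    phi <- fraction_active(raster, nc$dilation)
    thr <- nb_threshold(raster, nc$dilation, nc$nb_shuffles,
                        nc$nb_percentile, seed = ns_seed)
    nbs <- detect_network_bursts(phi, thr)
    cont <- classify_continuity(phi, nc$continuity_bin)
    sttc <- sttc_analysis(raster, nc$sttc_dt, nc$sttc_shuffles,
                          seed = ns_seed + 1L)
    stats <- list(
      n_cells = nrow(raster$mat),
      mean_frequency = mean(cs$frequency),
      mean_cv2 = mean(cs$cv2, na.rm = TRUE),
      gini = if (any(cs$frequency > 0))
        gini_coefficient(cs$frequency)$gini else NA,
      nb_threshold = thr, n_bursts = nrow(nbs$segments),
      time_in_nb = nbs$time_in_nb,
      proportion_continuous = cont$proportion_continuous,
      fraction_significant_sttc = sttc$fraction_significant)
    jsonlite::write_json(stats, file.path(out, "network_stats.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(nbs$segments, file.path(out, "nb_segments.csv"),
                     row.names = FALSE)
    utils::write.table(sttc$sttc, file.path(out, "sttc_matrix.csv"),
                       sep = ",", row.names = FALSE, col.names = FALSE)
    index <- c(index, network_stats = file.path(out, "network_stats.json"),
               nb_segments = file.path(out, "nb_segments.csv"),
               sttc_matrix = file.path(out, "sttc_matrix.csv"))
    results$netstats <- list(cell_statistics = cs, phi = phi,
                             nb = nbs, continuity = cont, sttc = sttc,
                             summary = stats)
  }
  if ("stprnn" %in% config$stages) {
    mc <- config$stprnn
    params <- make_variant(mc$variant)
    fps <- find_fixed_points(params)
    utils::write.csv(as.data.frame(fps),
                     file.path(out, "fixed_points.csv"), row.names = FALSE)
    index <- c(index, fixed_points = file.path(out, "fixed_points.csv"))
    results$stprnn <- list(fixed_points = fps)
    if (isTRUE(mc$run_deadline)) {
      dl <- deadline_scan(params, mc$silence, mc$probe)
      utils::write.csv(dl$scan, file.path(out, "deadline_scan.csv"),
                       row.names = FALSE)
      index <- c(index, deadline_scan = file.path(out, "deadline_scan.csv"))
      results$stprnn$deadline <- dl
    }
  }
  structure(list(results = results, index = index,
                 seed = config$seed,
                 package_version = as.character(utils::packageVersion("devnetdyn"))),
            class = "result_bundle")
}
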