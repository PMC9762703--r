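#' Detection configuration
#'
#' Bundles the parameters of the template-matching detector. The defaults
#' follow the reference protocol: 2-pixel ROI expansion, 500-frame
#' rolling-median baseline, 8 candidate onsets from the Savitzky-Golay
#' smoothed derivative (window 6, minimum peak separation 5 frames),
#' 5-frame template averaging, and noise-scaled event extraction with a
#' lower-bounded leading threshold. `threshold_floor_dff` is the floor
#' used by the mean fluorescence-change detector (its trace is in
#' intensity units, not criterion units).
#'
#' @param expand_px,baseline_window,n_candidates,sg_window,min_separation,avg_frames
#'   see [roi_set()], [rolling_baseline()], [candidate_onsets()],
#'   [build_template()].
#' @param qc_min_correlation,qc_center_contrast template quality control,
#'   see [build_template()].
#' @param smooth_window,k_lead,threshold_floor,refractory event
#'   extraction, see [event_extraction_config()].
#' @param threshold_floor_dff leading-threshold floor for the mean-change
#'   detector.
#' @return list of class `detection_config`.
#' @export
detection_config <- function(expand_px = 2, baseline_window = 500,
                             n_candidates = 8, sg_window = 6,
                             min_separation = 5, avg_frames = 5,
                             qc_min_correlation = 0.5,
                             qc_center_contrast = TRUE,
                             smooth_window = 5, k_lead = 3.5,
                             threshold_floor = 1.0, refractory = 3,
                             threshold_floor_dff = 0) {
  structure(as.list(environment()), class = "detection_config")
}

## pixels x frames intensity matrix for a logical mask
mask_pixmat <- function(movie, mask) {
  pix <- which(mask)
  npx <- prod(dim(movie$stack)[1:2])
  n <- dim(movie$stack)[3]
  matrix(movie$stack[rep(pix, n) + rep((seq_len(n) - 1) * npx,
                                       each = length(pix))],
         nrow = length(pix))
}

#' Template-matching transient detection
#'
#' The full spatial-template pipeline, per cell: candidate onsets from
#' the smoothed derivative of the ROI-mean fluorescence, spatial template
#' construction with quality control, the Clements-Bekkers criterion
#' `D(t)` over the expanded ROI, and threshold-based onset extraction
#' from `D(t)`. Cells whose candidates are all rejected are carried as
#' all-zero rows and flagged excluded.
#'
#' @param movie `fluorescence_movie`.
#' @param rois `roi_set` (or an integer label matrix).
#' @param config `detection_config`.
#' @return list of class `detection_result`: `raster` (`event_raster`
#'   with centroids and validity mask), `templates`, `traces` (per-cell
#'   `detection_trace`), `event_series`.
#' @export
detect <- function(movie, rois, config = detection_config()) {
  if (!inherits(rois, "roi_set")) rois <- roi_set(rois, config$expand_px)
  n_cells <- length(rois$raw)
  if (!n_cells) stop("no usable cells")
  n <- dim(movie$stack)[3]
  mat <- matrix(0L, n_cells, n)
  templates <- vector("list", n_cells)
  traces <- vector("list", n_cells)
  series <- vector("list", n_cells)
  excluded <- logical(n_cells)
  ext_cfg <- event_extraction_config(config$smooth_window, config$k_lead,
                                     config$threshold_floor,
                                     config$refractory)
  for (ci in seq_len(n_cells)) {
    pm_exp <- mask_pixmat(movie, rois$expanded[[ci]])
    raw_sel <- rois$raw[[ci]][rois$expanded[[ci]]]
    f_mean <- colMeans(pm_exp[raw_sel, , drop = FALSE])
    cand <- candidate_onsets(f_mean, config$n_candidates, config$sg_window,
                             config$min_separation)
    if (!length(cand)) {
      excluded[ci] <- TRUE
      next
    }
    f0 <- t(apply(pm_exp, 1, rolling_baseline,
                  window = config$baseline_window))
    dff <- pm_exp - f0
    tmpl <- build_template(NULL, raw_sel, cand, config$avg_frames,
                           config$baseline_window,
                           config$qc_min_correlation,
                           config$qc_center_contrast, dff = dff)
    templates[[ci]] <- tmpl
    if (tmpl$excluded) {
      excluded[ci] <- TRUE
      next
    }
    tr <- detection_criterion(dff, tmpl)
    traces[[ci]] <- tr
    ev <- extract_events(tr$D, ext_cfg, movie$valid_frames)
    series[[ci]] <- ev
    mat[ci, ev$onsets] <- 1L
  }
  raster <- event_raster(mat, movie$frame_rate, movie$valid_frames,
                         centroids = rois$centroids, excluded = excluded)
  structure(list(raster = raster, templates = templates, traces = traces,
                 event_series = series),
            class = "detection_result")
}

#' Mean fluorescence-change baseline detector
#'
#' Reference detector for comparison: the per-frame statistic is the
#' ROI-mean fluorescence change (intensity minus rolling baseline) of the
#' raw ROI instead of the spatial criterion `D(t)`; onset extraction is
#' identical. In densely labeled tissue this detector inherits the
#' contamination of overlapping cells and neuropil.
#'
#' @inheritParams detect
#' @return list of class `detection_result` (no templates).
#' @export
detect_mean_dff <- function(movie, rois, config = detection_config()) {
  if (!inherits(rois, "roi_set")) rois <- roi_set(rois, config$expand_px)
  n_cells <- length(rois$raw)
  if (!n_cells) stop("no usable cells")
  n <- dim(movie$stack)[3]
  mat <- matrix(0L, n_cells, n)
  series <- vector("list", n_cells)
  traces <- vector("list", n_cells)
  ext_cfg <- event_extraction_config(config$smooth_window, config$k_lead,
                                     config$threshold_floor_dff,
                                     config$refractory)
  for (ci in seq_len(n_cells)) {
    pm <- mask_pixmat(movie, rois$raw[[ci]])
    f_mean <- colMeans(pm)
    dff <- f_mean - rolling_baseline(f_mean, config$baseline_window)
    ev <- extract_events(dff, ext_cfg, movie$valid_frames)
    series[[ci]] <- ev
    traces[[ci]] <- dff
    mat[ci, ev$onsets] <- 1L
  }
  raster <- event_raster(mat, movie$frame_rate, movie$valid_frames,
                         centroids = rois$centroids)
  structure(list(raster = raster, templates = NULL, traces = traces,
                 event_series = series),
            class = "detection_result")
}

#' Label image from simulated cell masks
#'
#' Converts the masks returned by [simulate_movie()] into an integer
#' label image; overlapping pixels are assigned to the first cell (raw
#' labels are disjoint by construction, as with manually drawn ROIs).
#'
#' @param masks list of logical matrices.
#' @return integer matrix of labels.
#' @export
masks_to_labels <- function(masks) {
  lab <- matrix(0L, nrow(masks[[1]]), ncol(masks[[1]]))
  for (i in seq_along(masks)) lab[masks[[i]] & lab == 0L] <- i
  lab
}
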