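#' Region-of-interest set
#'
#' Builds the per-cell raw masks, radially expanded masks (Euclidean
#' distance transform), and centroids from an integer label image
#' (0 = background). Expanding the somatic ROI by a small rim enhances
#' the spatial contrast exploited by the template matching. Expanded
#' ROIs of neighboring cells may share pixels.
#'
#' @param labels integer matrix; positive labels mark cells.
#' @param expand_px radial expansion distance (pixels).
#' @return object of class `roi_set`: lists `raw`, `expanded` (logical
#'   matrices) and `centroids` (cells x 2, row/col), indexed by cell.
#' @export
roi_set <- function(labels, expand_px = 2) {
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids)) stop("no ROI labels")
  raw <- lapply(ids, function(i) labels == i)
  expanded <- lapply(raw, expand_roi, distance = expand_px)
  centroids <- t(vapply(raw, function(m) {
    idx <- which(m, arr.ind = TRUE)
    c(mean(idx[, 1]), mean(idx[, 2]))
  }, c(0, 0)))
  structure(list(raw = raw, expanded = expanded, centroids = centroids,
                 ids = ids), class = "roi_set")
}

#' Radially expand a binary mask
#'
#' Returns the pixels whose Euclidean distance to the input mask is at
#' most `distance` (distance-transform expansion).
#'
#' @param mask logical matrix (non-empty).
#' @param distance expansion radius (pixels); 0 returns the mask.
#' @return logical matrix, superset of `mask`.
#' @export
expand_roi <- function(mask, distance = 2) {
  if (!any(mask)) stop("empty mask")
  if (distance <= 0) return(mask)
  idx <- which(mask, arr.ind = TRUE)
  out <- mask
  r <- ceiling(distance)
  cand_r <- max(1, min(idx[, 1]) - r):min(nrow(mask), max(idx[, 1]) + r)
  cand_c <- max(1, min(idx[, 2]) - r):min(ncol(mask), max(idx[, 2]) + r)
  for (i in cand_r) for (j in cand_c) {
    if (out[i, j]) next
    if (min((idx[, 1] - i)^2 + (idx[, 2] - j)^2) <= distance^2)
      out[i, j] <- TRUE
  }
  out
}

#' Rolling-median resting fluorescence
#'
#' Centered moving median; the window shrinks at the trace edges.
#'
#' @param f per-frame intensity trace.
#' @param window window length (frames).
#' @return baseline trace of the same length.
#' @export
rolling_baseline <- function(f, window = 500) {
  stopifnot(length(f) >= 1, window >= 1)
  .rolling_median_cpp(as.numeric(f), as.integer(window))
}

## Savitzky-Golay smoothing supporting even window lengths: fit a
## polynomial of the given order over the window and evaluate at the
## center frame; edge windows shrink.
sg_smooth <- function(x, window, order = 2) {
  n <- length(x)
  if (n <= window) window <- max(1, n - 1)
  back <- (window + 1) %/% 2 - 1
  fwd <- window %/% 2
  offs <- (-back):fwd
  X <- outer(offs, 0:order, `^`)
  w_full <- (solve(crossprod(X)) %*% t(X))[1, ]
  out <- numeric(n)
  core <- (back + 1):(n - fwd)
  acc <- numeric(length(core))
  for (k in seq_along(offs))
    acc <- acc + w_full[k] * x[core + offs[k]]
  out[core] <- acc
  for (i in seq_len(n)[-core]) {
    o <- offs[i + offs >= 1 & i + offs <= n]
    Xe <- outer(o, 0:min(order, length(o) - 1), `^`)
    we <- (solve(crossprod(Xe)) %*% t(Xe))[1, ]
    out[i] <- sum(we * x[i + o])
  }
  out
}

#' Candidate transient onsets from a mean-fluorescence trace
#'
#' The first derivative of the trace is Savitzky-Golay smoothed (second
#' order), its positive peaks are ranked by amplitude, and peaks are
#' greedily selected in descending order, suppressing any peak closer
#' than `min_separation` frames to an already selected one (which avoids
#' picking several frames of the same transient).
#'
#' @param f_mean per-frame mean fluorescence of the ROI.
#' @param n_candidates maximum number of candidates.
#' @param sg_window smoothing window (frames).
#' @param min_separation exclusion distance (frames).
#' @return integer frame indices in descending peak amplitude (the order
#'   encodes reliability: larger derivative peaks are more likely the
#'   cell's own transients than crosstalk), with the smoothed peak
#'   amplitudes as attribute `amplitude`; empty when the trace has no
#'   positive derivative peaks.
#' @export
candidate_onsets <- function(f_mean, n_candidates = 8, sg_window = 6,
                             min_separation = 5) {
  stopifnot(length(f_mean) > sg_window)
  df <- c(0, diff(f_mean))
  sm <- sg_smooth(df, sg_window)
  n <- length(sm)
  pk <- which(sm > 0 &
                sm >= c(-Inf, sm[-n]) & sm > c(sm[-1], -Inf))
  if (!length(pk)) return(integer(0))
  pk <- pk[order(sm[pk], decreasing = TRUE)]
  sel <- integer(0)
  for (p in pk) {
    if (length(sel) >= n_candidates) break
    if (!length(sel) || all(abs(sel - p) >= min_separation))
      sel <- c(sel, p)
  }
  structure(sel, amplitude = sm[sel])
}

#' Build the spatial fluorescence-change template of a cell
#'
#' For each candidate onset the spatial change image is averaged over
#' `avg_frames` successive frames (fluorescence minus its rolling-median
#' baseline), restricted to the expanded ROI and z-scored across the ROI
#' pixels. Candidates that putatively reflect activity of overlapping
#' somata or neurites are rejected by two quality checks replacing visual
#' inspection: spatial correlation below `qc_min_correlation` with a
#' reference template (the pixelwise median of the most reliable half of
#' the candidates, ranked by derivative-peak amplitude), or mean weight
#' inside the raw ROI not exceeding the mean weight in the expansion rim.
#' Survivors are averaged and re-z-scored.
#'
#' @param pixmat pixels x frames matrix of the expanded-ROI intensities.
#' @param raw_sel logical per ROI pixel: inside the raw (unexpanded) ROI.
#' @param candidates candidate onset frames.
#' @param avg_frames frames averaged per candidate.
#' @param baseline_window rolling-median window (frames).
#' @param qc_min_correlation minimum correlation with the median template.
#' @param qc_center_contrast require inside-ROI mean > rim mean.
#' @param dff optional precomputed pixels x frames fluorescence-change
#'   matrix (skips the baseline computation; `pixmat` may then be NULL).
#' @return list of class `spatial_template`: `weights` (z-scored, per ROI
#'   pixel), `n_candidates_used`, `rejected`, `excluded` (TRUE when every
#'   candidate was rejected; `weights` is then NULL).
#' @export
build_template <- function(pixmat, raw_sel, candidates, avg_frames = 5,
                           baseline_window = 500, qc_min_correlation = 0.5,
                           qc_center_contrast = TRUE, dff = NULL) {
  stopifnot(length(candidates) >= 1)
  if (is.null(dff)) {
    f0 <- t(apply(pixmat, 1, rolling_baseline, window = baseline_window))
    dff <- pixmat - f0
  }
  n <- ncol(dff)
  candidates <- candidates[candidates + avg_frames - 1 <= n]
  if (!length(candidates))
    return(structure(list(weights = NULL, n_candidates_used = 0,
                          rejected = 0, excluded = TRUE),
                     class = "spatial_template"))
  zscore <- function(v) {
    s <- sd(v)
    if (!is.finite(s) || s == 0) return(rep(0, length(v)))
    (v - mean(v)) / s
  }
  cand_t <- vapply(candidates, function(k)
    zscore(rowMeans(dff[, k:(k + avg_frames - 1), drop = FALSE])),
    numeric(nrow(dff)))
  # QC reference: pixelwise median of the most reliable half of the
  # candidates (candidates arrive in descending derivative-peak order,
  # so crosstalk-dominated candidates concentrate in the lower half)
  n_ref <- max(1, ceiling(ncol(cand_t) / 2))
  ref <- apply(cand_t[, seq_len(n_ref), drop = FALSE], 1, median)
  keep <- rep(TRUE, ncol(cand_t))
  for (k in seq_len(ncol(cand_t))) {
    cc <- suppressWarnings(cor(cand_t[, k], ref))
    if (sd(cand_t[, k]) == 0 || (is.finite(cc) && cc < qc_min_correlation))
      keep[k] <- FALSE
    else if (qc_center_contrast &&
             mean(cand_t[raw_sel, k]) <= mean(cand_t[!raw_sel, k]))
      keep[k] <- FALSE
  }
  if (!any(keep))
    return(structure(list(weights = NULL, n_candidates_used = 0,
                          rejected = sum(!keep), excluded = TRUE),
                     class = "spatial_template"))
  w <- zscore(rowMeans(cand_t[, keep, drop = FALSE]))
  structure(list(weights = w, n_candidates_used = sum(keep),
                 rejected = sum(!keep), excluded = FALSE),
            class = "spatial_template")
}

#' Clements-Bekkers detection criterion in the spatial domain
#'
#' For each frame the cell's template is optimally scaled (least squares,
#' with free offset) to the frame's spatial fluorescence change over the
#' ROI pixels: `dF ~ A T + C`. The detection criterion is the scaling
#' factor divided by the residual standard error, `D = A / sigma`. `D`
#' rises only when the frame's spatial configuration matches the
#' template; it is insensitive to spatially uniform offsets. The residual
#' sum of squares is floored at `1e-12 N Var(T)` so that exact fits give
#' a large finite `D` rather than a division by zero.
#'
#' @param dff pixels x frames matrix of fluorescence changes over the ROI.
#' @param template `spatial_template` (or numeric weight vector).
#' @return data.frame of class `detection_trace`: per-frame `A`, `C`,
#'   `sigma`, `D`.
#' @export
detection_criterion <- function(dff, template) {
  w <- if (inherits(template, "spatial_template")) template$weights
       else as.numeric(template)
  if (is.null(w)) stop("excluded cell has no template")
  N <- length(w)
  stopifnot(N >= 2, nrow(dff) == N)
  if (sd(w) == 0) stop("degenerate template (zero variance)")
  sT <- sum(w); sT2 <- sum(w^2)
  den <- sT2 - sT^2 / N
  sX <- colSums(dff)
  sTX <- as.numeric(crossprod(w, dff))
  A <- (sTX - sT * sX / N) / den
  C <- (sX - A * sT) / N
  sse <- colSums(dff^2) - 2 * A * sTX - 2 * C * sX +
    A^2 * sT2 + 2 * A * C * sT + N * C^2
  eps <- 1e-12 * N * stats::var(w)
  sse <- pmax(sse, eps)
  sigma <- sqrt(sse / (N - 1))
  out <- data.frame(A = A, C = C, sigma = sigma, D = A / sigma)
  class(out) <- c("detection_trace", "data.frame")
  out
}

#' Event-extraction configuration
#'
#' Controls the onset extraction from a detection-criterion (or mean
#' fluorescence-change) trace: Savitzky-Golay smoothing, clamping of
#' negative values to zero (negative-to-positive transitions otherwise
#' cause false positives), a noise-scaled leading threshold with a lower
#' bound, rise-based detection of events riding on the falling phase of a
#' previous event, and a refractory merge.
#'
#' @param smooth_window smoothing window (frames).
#' @param k_lead threshold multiplier on the estimated noise scale.
#' @param threshold_floor lower bound of the leading threshold (trace
#'   units).
#' @param refractory minimum spacing between onsets (frames).
#' @param trail_frac trailing threshold as a fraction of the leading one;
#'   an event region stays open (suppressing re-crossings of the leading
#'   threshold during the slow decay) until the trace drops below it.
#' @return list of class `event_extraction_config`.
#' @export
event_extraction_config <- function(smooth_window = 5, k_lead = 3.5,
                                    threshold_floor = 1.0, refractory = 3,
                                    trail_frac = 0.5) {
  structure(list(smooth_window = smooth_window, k_lead = k_lead,
                 threshold_floor = threshold_floor, refractory = refractory,
                 trail_frac = trail_frac),
            class = "event_extraction_config")
}

#' Extract event onsets from a detection trace
#'
#' The trace is smoothed, negatives are clamped to zero, and the noise
#' scale is estimated from the negative-mirrored fluctuations
#' (`1.4826 x median |negative values|`). The leading threshold is
#' `max(k_lead x noise, threshold_floor)`. Onsets are upward threshold
#' crossings; inside a supra-threshold run, an additional onset is placed
#' at every local minimum followed by a rise of at least the threshold
#' (events overlapping the decay of a previous event). Onsets closer than
#' the refractory gap are merged and invalid frames never yield onsets.
#'
#' @param d per-frame detection criterion (or mean fluorescence change).
#' @param config `event_extraction_config`.
#' @param valid logical per frame.
#' @return list of class `event_series`: `onsets` (frames), `binary`
#'   (0/1 per frame), `threshold`, `noise_scale`.
#' @export
extract_events <- function(d, config = event_extraction_config(),
                           valid = NULL) {
  n <- length(d)
  if (is.null(valid)) valid <- rep(TRUE, n)
  if (!any(valid)) stop("no valid frames")
  work <- d
  work[!valid] <- 0
  sm <- sg_smooth(work, config$smooth_window)
  neg <- sm[sm < 0]
  noise <- if (length(neg) >= 5) 1.4826 * median(abs(neg))
           else stats::mad(sm)
  thr <- max(config$k_lead * noise, config$threshold_floor)
  cl <- pmax(sm, 0)
  above <- cl > thr
  # hysteresis: an event region opens at an upward crossing of the
  # leading threshold and closes when the trace falls below the trailing
  # threshold; leading-threshold re-crossings inside an open region (the
  # slow decay hovering around threshold) are not onsets
  thr_trail <- config$trail_frac * thr
  crossings <- integer(0)
  in_region <- logical(n)
  open_region <- FALSE
  for (i in seq_len(n)) {
    if (!open_region && above[i] && (i == 1 || !above[i - 1])) {
      crossings <- c(crossings, i)
      open_region <- TRUE
    } else if (open_region && cl[i] < thr_trail) open_region <- FALSE
    in_region[i] <- open_region
  }
  # onset = first rising frame: backtrack each crossing to the preceding
  # local minimum of the smoothed trace, the onset is the frame after it
  rise_start <- function(i) {
    while (i > 1 && sm[i - 1] < sm[i]) i <- i - 1
    min(i + 1, n)
  }
  onsets <- as.integer(vapply(crossings, rise_start, numeric(1)))
  # re-rises inside open event regions: a local minimum followed by a
  # rise of at least the threshold before the next local maximum marks an
  # event overlapping the decay of the previous one
  d2 <- diff(cl)
  mins <- which(c(FALSE, d2 < 0) & c(d2 > 0, FALSE))  # local minima
  maxs <- which(c(FALSE, d2 > 0) & c(d2 < 0, FALSE))  # local maxima
  for (m in mins[in_region[mins]]) {
    nx <- maxs[maxs > m]
    if (!length(nx)) next
    if (cl[nx[1]] - cl[m] >= thr) onsets <- c(onsets, m + 1L)
  }
  onsets <- sort(unique(onsets))
  if (length(onsets) > 1) {
    # collapse chains closer than the refractory gap, greedily from the left
    res <- onsets[1]
    for (o in onsets[-1]) if (o - res[length(res)] >= config$refractory)
      res <- c(res, o)
    onsets <- res
  }
  onsets <- onsets[valid[onsets]]
  binary <- integer(n)
  binary[onsets] <- 1L
  structure(list(onsets = onsets, binary = binary, threshold = thr,
                 noise_scale = noise), class = "event_series")
}

#' Noise level of fluorescence traces
#'
#' Difference between the 50th and the 10th percentile of each trace's
#' relative fluorescence-change distribution.
#'
#' @param dff numeric vector, or cells x frames matrix of relative
#'   fluorescence changes.
#' @return scalar, or one value per row.
#' @export
noise_level <- function(dff) {
  one <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) stop("empty trace")
    unname(quantile(v, 0.5) - quantile(v, 0.1))
  }
  if (is.matrix(dff)) apply(dff, 1, one) else one(dff)
}

#' Match detected onsets against ground truth
#'
#' Greedy one-to-one matching: detections (in order) are matched to the
#' nearest unmatched reference event within the tolerance. Reports
#' recall, precision, F1 and the mean signed onset delay (detected minus
#' reference, frames). With no detections, precision is reported as 1 and
#' flagged.
#'
#' @param detected detected onset frames (or an `event_series`).
#' @param truth reference event frames.
#' @param tolerance matching tolerance (frames).
#' @return list of class `detection_metrics`: `recall`, `precision`,
#'   `f1`, `mean_delay`, `n_matched`, `n_detected`, `n_truth`,
#'   `no_detections` flag.
#' @export
evaluate_detection <- function(detected, truth, tolerance = 3) {
  stopifnot(tolerance >= 0)
  if (inherits(detected, "event_series")) detected <- detected$onsets
  unmatched <- rep(TRUE, length(truth))
  delays <- numeric(0)
  for (d in detected) {
    if (!any(unmatched)) break
    cand <- which(unmatched)
    j <- cand[which.min(abs(truth[cand] - d))]
    if (abs(truth[j] - d) <= tolerance) {
      unmatched[j] <- FALSE
      delays <- c(delays, d - truth[j])
    }
  }
  n_m <- length(delays)
  recall <- if (length(truth)) n_m / length(truth) else 1
  precision <- if (length(detected)) n_m / length(detected) else 1
  f1 <- if (recall + precision > 0)
    2 * recall * precision / (recall + precision) else 0
  structure(list(recall = recall, precision = precision, f1 = f1,
                 mean_delay = if (n_m) mean(delays) else NA_real_,
                 n_matched = n_m, n_detected = length(detected),
                 n_truth = length(truth),
                 no_detections = length(detected) == 0),
            class = "detection_metrics")
}
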