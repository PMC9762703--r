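#' Per-cell event statistics: frequency and firing irregularity
#'
#' Event frequency counts valid recording time only. Firing irregularity
#' is quantified by CV2, a local, largely rate-independent measure on the
#' inter-event intervals (ICIs):
#' `CV2 = 1/(K-1) * sum_k 2 |ICI_{k+1} - ICI_k| / (ICI_{k+1} + ICI_k)`,
#' where K is the number of ICIs. CV2 is 0 for a perfectly periodic train
#' and 1 for a Poisson process. Cells with fewer than `min_ici` ICIs get
#' `NA` (flagged in `cv2_valid`).
#'
#' @param raster `event_raster`.
#' @param min_ici minimum number of ICIs required for CV2.
#' @return data.frame with one row per cell: `n_events`, `frequency`
#'   (events/min), `n_ici`, `cv2`, `cv2_valid`, `excluded`.
#' @export
cell_statistics <- function(raster, min_ici = 10) {
  dur_min <- sum(raster$valid_frames) / raster$frame_rate / 60
  if (dur_min <= 0) stop("no valid recording time")
  onsets <- onset_list(raster)
  rows <- lapply(seq_along(onsets), function(i) {
    idx <- onsets[[i]]
    ici <- diff(idx)
    k <- length(ici)
    cv2 <- if (k >= min_ici) cv2_of_intervals(ici) else NA_real_
    data.frame(n_events = length(idx), frequency = length(idx) / dur_min,
               n_ici = k, cv2 = cv2, cv2_valid = k >= min_ici,
               excluded = raster$excluded[i])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname cell_statistics
#' @param ici numeric vector of inter-event intervals.
#' @export
cv2_of_intervals <- function(ici) {
  k <- length(ici)
  if (k < 2) return(NA_real_)
  sum(2 * abs(diff(ici)) / (ici[-1] + ici[-k])) / (k - 1)
}

#' Lorenz curve and Gini coefficient of per-cell event frequencies
#'
#' Dispersion of activity across the population: the Lorenz curve plots
#' the cumulative share of events against the cumulative share of cells
#' (rank-ordered); the Gini coefficient is one minus twice the area under
#' the piecewise-linear Lorenz curve. 0 means all cells fire equally.
#'
#' @param values non-negative per-cell frequencies (>= 2 values, not all 0).
#' @return list with `lorenz` (data.frame `p`, `share`) and `gini`.
#' @export
gini_coefficient <- function(values) {
  stopifnot(length(values) >= 2, all(values >= 0))
  if (all(values == 0)) stop("all values are zero")
  v <- sort(values)
  p <- seq(0, 1, length.out = length(v) + 1)
  share <- c(0, cumsum(v) / sum(v))
  auc <- sum(diff(p) * (share[-1] + share[-length(share)]) / 2)
  list(lorenz = data.frame(p = p, share = share), gini = 1 - 2 * auc)
}

#' Fraction of active cells per frame
#'
#' Each cell's binary vector is dilated by +/- `dt` frames (tolerating
#' onset-timing jitter), then averaged across non-excluded cells to give
#' the empirical fraction of active cells Phi(t). Invalid frames are NA.
#'
#' @param raster `event_raster`.
#' @param dt dilation half-width (frames).
#' @return list of class `phi_trace`: `phi` (per frame), `dt`, `valid`,
#'   `frame_rate`, `n_cells`, and the dilated binary matrix `dilated`.
#' @export
fraction_active <- function(raster, dt = 3) {
  stopifnot(dt >= 0)
  n <- ncol(raster$mat)
  use <- which(!raster$excluded)
  dil <- matrix(0L, length(use), n)
  onsets <- onset_list(raster)
  for (i in seq_along(use))
    dil[i, dilate_events(onsets[[use[i]]], dt, n)] <- 1L
  phi <- colMeans(dil)
  phi[!raster$valid_frames] <- NA_real_
  structure(list(phi = phi, dt = dt, valid = raster$valid_frames,
                 frame_rate = raster$frame_rate, n_cells = length(use),
                 dilated = dil),
            class = "phi_trace")
}

#' Surrogate-based network burst threshold
#'
#' Onsets of every cell are redrawn uniformly over the valid frames
#' (keeping each cell's event count), the surrogate fraction of active
#' cells is computed as in [fraction_active()], and the threshold is the
#' given percentile of all pooled surrogate Phi values. Determined per
#' recording, which adapts the threshold to the mean event frequency.
#'
#' @param raster `event_raster`.
#' @param dt dilation half-width (frames).
#' @param n_shuffles number of surrogate rasters.
#' @param percentile pooled-percentile defining the threshold.
#' @param seed RNG seed.
#' @return threshold (fraction of active cells).
#' @export
nb_threshold <- function(raster, dt = 3, n_shuffles = 1000,
                         percentile = 99.99, seed = 1) {
  set.seed(seed)
  n <- ncol(raster$mat)
  use <- which(!raster$excluded)
  counts <- rowSums(raster$mat[use, , drop = FALSE])
  if (all(counts == 0)) return(0)
  valid_idx <- which(raster$valid_frames)
  pool <- matrix(0, length(valid_idx), n_shuffles)
  for (s in seq_len(n_shuffles)) {
    cover <- integer(n)
    for (ci in seq_along(use)) {
      k <- counts[ci]
      if (k == 0) next
      idx <- dilate_events(sample(valid_idx, k), dt, n)
      cover[idx] <- cover[idx] + 1L
    }
    pool[, s] <- cover[valid_idx] / length(use)
  }
  unname(quantile(pool, percentile / 100))
}

#' Detect network bursts from the fraction of active cells
#'
#' Frames with Phi above the threshold form network bursts (NBs). Burst
#' size is the fraction of cells active (dilated raster) in at least one
#' frame of the burst, chance-corrected by subtracting the threshold
#' (floored at 0). Participation of a cell is the fraction of NBs it
#' joins.
#'
#' @param phi `phi_trace` from [fraction_active()].
#' @param threshold NB threshold (fraction of active cells).
#' @return list of class `network_burst_set`: `segments` (data.frame
#'   `onset`, `offset`, `duration_s`, `size`), `threshold`, `time_in_nb`,
#'   `mean_duration`, `participation` (per non-excluded cell).
#' @export
detect_network_bursts <- function(phi, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  supra <- !is.na(phi$phi) & phi$phi > threshold
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  seg <- data.frame(onset = starts[r$values], offset = ends[r$values])
  n_valid <- sum(phi$valid)
  sizes <- numeric(nrow(seg)); part <- NULL
  if (nrow(seg)) {
    active_mat <- vapply(seq_len(nrow(seg)), function(i)
      rowSums(phi$dilated[, seg$onset[i]:seg$offset[i], drop = FALSE]) > 0,
      logical(nrow(phi$dilated)))
    sizes <- pmax(colMeans(active_mat) - threshold, 0)
    part <- rowMeans(active_mat)
  }
  seg$duration_s <- (seg$offset - seg$onset + 1) / phi$frame_rate
  seg$size <- sizes
  structure(list(segments = seg, threshold = threshold,
                 time_in_nb = sum(supra) / n_valid,
                 mean_duration = if (nrow(seg)) mean(seg$duration_s) else 0,
                 participation = part),
            class = "network_burst_set")
}

#' Classify discontinuous vs continuous network activity
#'
#' The recording is partitioned into non-overlapping bins; a bin is
#' continuous if Phi exceeds `activity_threshold` in more than
#' `frame_fraction` of its frames. A trailing partial bin is dropped.
#'
#' @param phi `phi_trace`.
#' @param bin bin length (frames); 116 frames is about 10 s at 11.63 Hz.
#' @param activity_threshold Phi level counting as activity.
#' @param frame_fraction required fraction of supra-threshold frames.
#' @return list: `labels` (per bin, `"continuous"`/`"discontinuous"`),
#'   `proportion_continuous`.
#' @export
classify_continuity <- function(phi, bin = 116, activity_threshold = 0.03,
                                frame_fraction = 0.70) {
  n_bins <- length(phi$phi) %/% bin
  if (n_bins < 1) stop("recording shorter than one bin")
  lab <- vapply(seq_len(n_bins), function(b) {
    v <- phi$phi[((b - 1) * bin + 1):(b * bin)]
    frac <- sum(!is.na(v) & v > activity_threshold) / bin
    if (frac > frame_fraction) "continuous" else "discontinuous"
  }, "")
  list(labels = lab,
       proportion_continuous = mean(lab == "continuous"))
}

#' Spectral power of the fraction of active cells
#'
#' The Lomb-Scargle periodogram handles the unevenly sampled series that
#' remains after invalid (drift) frames are removed. Band power is the
#' trapezoidal integral of the normalized periodogram over the band.
#'
#' @param phi `phi_trace`.
#' @param band frequency band (Hz) for the band power.
#' @param oversample frequency-grid oversampling factor.
#' @return list: `frequency` (Hz), `power` (normalized periodogram),
#'   `bandpower`, `band`.
#' @export
spectral_power <- function(phi, band = c(0.1, 0.5), oversample = 4) {
  ok <- phi$valid & !is.na(phi$phi)
  if (sum(ok) < 2) stop("too few valid samples")
  t <- (which(ok) - 1) / phi$frame_rate
  y <- phi$phi[ok]
  span <- diff(range(t))
  f <- seq(1 / span, phi$frame_rate / 2, by = 1 / (oversample * span))
  p <- lomb_scargle(t, y, f)
  sel <- f >= band[1] & f <= band[2]
  bp <- if (sum(sel) >= 2)
    sum(diff(f[sel]) * (p[sel][-1] + p[sel][-sum(sel)]) / 2) else 0
  list(frequency = f, power = p, bandpower = bp, band = band)
}

#' Lomb-Scargle periodogram
#'
#' Classical variance-normalized Lomb-Scargle periodogram for unevenly
#' sampled series, with the per-frequency time offset that makes the
#' estimate invariant to time translation.
#'
#' @param t sample times.
#' @param y sample values.
#' @param freq frequencies (Hz) at which to evaluate.
#' @return periodogram values, same length as `freq`.
#' @export
lomb_scargle <- function(t, y, freq) {
  y <- y - mean(y)
  s2 <- stats::var(y)
  if (s2 == 0) return(rep(0, length(freq)))
  vapply(freq, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau)); st <- sin(w * (t - tau))
    (sum(y * ct)^2 / sum(ct^2) + sum(y * st)^2 / sum(st^2)) / (2 * s2)
  }, 0)
}
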