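#' Cardiovascular rates and movement periods from a pressure trace
#'
#' A chest pressure sensor picks up respiration, heart beat, and gross
#' body movements. The short-time Fourier transform (1-s window, 50%
#' overlap) gives a spectrogram; the median power spectral density across
#' time exposes respiration and heart rate as its first two spectral
#' peaks (in ascending frequency). Movement periods are detected from the
#' band power (0.1-8 Hz by default) per time bin with an adaptive
#' threshold: the moving median (over `median_window_s`) plus three times
#' the moving absolute deviation (over `mad_window_s`).
#'
#' @param pressure pressure signal (numeric vector).
#' @param sample_rate sampling rate (Hz).
#' @param band movement band (Hz).
#' @param window_s STFT window length (s).
#' @param median_window_s,mad_window_s moving-window lengths (s) for the
#'   movement threshold.
#' @param mad_factor threshold multiplier on the moving absolute deviation.
#' @param peak_min_height minimum height of a rate peak, as a fraction of
#'   the maximum median PSD (guards against picking noise ripples).
#' @return list of class `physio_recording`: `respiration_rate`,
#'   `heart_rate` (Hz, NA when not separable), `psd` (data.frame
#'   `frequency`, `power`), `movement` (data.frame `time`, `bandpower`,
#'   `threshold`, `moving`), `movement_onsets`, `movement_offsets`
#'   (bin times, s).
#' @export
physio_analysis <- function(pressure, sample_rate, band = c(0.1, 8),
                            window_s = 1, median_window_s = 60,
                            mad_window_s = 300, mad_factor = 3,
                            peak_min_height = 0.2) {
  nwin <- round(window_s * sample_rate)
  stopifnot(length(pressure) >= 4 * nwin)
  sg <- signal::specgram(pressure - mean(pressure), n = nwin,
                         Fs = sample_rate, overlap = floor(nwin / 2))
  psd <- abs(sg$S)^2
  med <- apply(psd, 1, median)
  f <- as.numeric(sg$f)
  # spectral peaks: strict local maxima above the height floor, ascending f
  pk <- which(diff(sign(diff(med))) == -2) + 1
  pk <- pk[med[pk] >= peak_min_height * max(med) & f[pk] > 0]
  resp <- if (length(pk) >= 1) f[pk[1]] else NA_real_
  heart <- if (length(pk) >= 2) f[pk[2]] else NA_real_
  # movement: band power per STFT bin with adaptive threshold
  in_band <- f >= band[1] & f <= band[2]
  bp <- colSums(psd[in_band, , drop = FALSE])
  t_bin <- as.numeric(sg$t)
  bin_dt <- if (length(t_bin) > 1) t_bin[2] - t_bin[1] else window_s
  w_med <- max(1, round(median_window_s / bin_dt))
  w_mad <- max(1, round(mad_window_s / bin_dt))
  mov_med <- .rolling_median_cpp(bp, w_med)
  mov_mad <- .rolling_median_cpp(abs(bp - .rolling_median_cpp(bp, w_mad)),
                                 w_mad)
  thr <- mov_med + mad_factor * mov_mad
  moving <- bp > thr
  d <- diff(c(FALSE, moving, FALSE))
  structure(list(respiration_rate = resp, heart_rate = heart,
                 psd = data.frame(frequency = f, power = med),
                 movement = data.frame(time = t_bin, bandpower = bp,
                                       threshold = thr, moving = moving),
                 movement_onsets = t_bin[which(d[-length(d)] == 1)],
                 movement_offsets = t_bin[pmin(which(d == -1) - 1,
                                               length(t_bin))]),
            class = "physio_recording")
}
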