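#' Spike-time tiling coefficient of two event trains
#'
#' Frequency-robust pairwise correlation of event trains:
#' `STTC = 1/2 [ (P_A - T_B)/(1 - P_A T_B) + (P_B - T_A)/(1 - P_B T_A) ]`,
#' where `T_X` is the fraction of the recording tiled by +/- `dt` frames
#' around X's events and `P_X` the fraction of X's events falling within
#' +/- `dt` frames of any event of the other train. Undefined cases
#' (an empty train, or a zero denominator) give `NA`.
#'
#' @param trainA,trainB event frame indices (1-based).
#' @param dt synchronicity window half-width (frames); 3 frames is about
#'   258 ms at 11.63 Hz.
#' @param duration recording length (frames).
#' @return STTC value in `[-1, 1]`, or `NA`.
#' @export
sttc_pair <- function(trainA, trainB, dt = 3, duration) {
  stopifnot(duration > 0)
  if (!length(trainA) || !length(trainB)) return(NA_real_)
  tA <- tiled_fraction(trainA, dt, duration)
  tB <- tiled_fraction(trainB, dt, duration)
  pA <- prop_within(trainA, trainB, dt)
  pB <- prop_within(trainB, trainA, dt)
  d1 <- 1 - pA * tB; d2 <- 1 - pB * tA
  if (d1 == 0 || d2 == 0) return(NA_real_)
  0.5 * ((pA - tB) / d1 + (pB - tA) / d2)
}

## fraction of [1, n] covered by the union of +/- dt windows around idx
tiled_fraction <- function(idx, dt, n) {
  idx <- sort(idx)
  s <- pmax(idx - dt, 1); e <- pmin(idx + dt, n)
  k <- length(idx)
  if (k > 1) {
    new_run <- c(TRUE, s[-1] > e[-k] + 1)   # e is non-decreasing
    s <- s[new_run]
    e <- e[c(new_run[-1], TRUE)]            # last element of each run
  }
  sum(e - s + 1) / n
}

## fraction of events in a that fall within +/- dt of any event in b
prop_within <- function(a, b, dt) {
  b <- sort(b)
  pos <- findInterval(a, b)
  d_lo <- ifelse(pos >= 1, a - b[pmax(pos, 1)], Inf)
  d_hi <- ifelse(pos < length(b), b[pmin(pos + 1, length(b))] - a, Inf)
  mean(pmin(d_lo, d_hi) <= dt)
}

## all pairwise STTCs for a list of trains (compiled kernel)
sttc_all_pairs <- function(onsets, dt, duration) {
  .sttc_matrix_cpp(lapply(onsets, as.integer), as.integer(dt),
                   as.integer(duration))
}

#' Pairwise STTC analysis with surrogate significance
#'
#' Computes the full STTC matrix over non-excluded cells, assesses
#' per-pair significance against surrogate rasters in which every cell's
#' onsets are redrawn uniformly over the valid frames (event counts, and
#' hence mean frequencies, preserved), and relates STTC to the Euclidean
#' centroid distance of the pair (Spearman rank correlation over
#' significant pairs).
#'
#' @param raster `event_raster`.
#' @param dt synchronicity window half-width (frames).
#' @param n_shuffles number of surrogate rasters.
#' @param percentile one-sided significance percentile.
#' @param seed RNG seed.
#' @return list of class `sttc_result`: `sttc` (matrix), `significant`
#'   (logical matrix), `fraction_significant`, `distance` (matrix or
#'   NULL), `spearman_rho` (STTC vs distance over significant pairs),
#'   `dt`, `n_shuffles`.
#' @export
sttc_analysis <- function(raster, dt = 3, n_shuffles = 1000,
                          percentile = 95, seed = 1) {
  set.seed(seed)
  use <- which(!raster$excluded)
  stopifnot(length(use) >= 2)
  n <- ncol(raster$mat)
  onsets <- onset_list(raster)[use]
  emp <- sttc_all_pairs(onsets, dt, n)
  ut <- upper.tri(emp)
  sur <- matrix(NA_real_, n_shuffles, sum(ut))
  valid_idx <- which(raster$valid_frames)
  counts <- lengths(onsets)
  for (s in seq_len(n_shuffles)) {
    sh <- lapply(counts, function(k)
      if (k) sort(sample(valid_idx, k)) else integer(0))
    sur[s, ] <- sttc_all_pairs(sh, dt, n)[ut]
  }
  crit <- apply(sur, 2, quantile, probs = percentile / 100, na.rm = TRUE)
  sig <- matrix(FALSE, length(use), length(use))
  sig[ut] <- !is.na(emp[ut]) & emp[ut] > crit
  sig <- sig | t(sig)
  dist_mat <- NULL; rho <- NA_real_
  if (!is.null(raster$centroids)) {
    dist_mat <- as.matrix(stats::dist(raster$centroids[use, , drop = FALSE]))
    if (any(sig[ut]))
      rho <- suppressWarnings(
        cor(emp[ut][sig[ut]], dist_mat[ut][sig[ut]], method = "spearman"))
  }
  structure(list(sttc = emp, significant = sig,
                 fraction_significant = mean(sig[ut][!is.na(emp[ut])]),
                 distance = dist_mat, spearman_rho = rho,
                 dt = dt, n_shuffles = n_shuffles),
            class = "sttc_result")
}

## Gaussian smoothing of the rows of a binary matrix (zero-padded edges)
gaussian_smooth_rows <- function(mat, sd_frames) {
  h <- ceiling(4 * sd_frames)
  k <- stats::dnorm(-h:h, sd = sd_frames)
  k <- k / sum(k)
  n <- ncol(mat)
  padded <- cbind(matrix(0, nrow(mat), h), mat, matrix(0, nrow(mat), h))
  sm <- stats::filter(t(padded), k, sides = 2)   # filters each column
  t(sm[(h + 1):(h + n), , drop = FALSE])
}

#' Population coupling of single cells
#'
#' For each cell, the Pearson correlation between its Gaussian-smoothed
#' binary event vector and the smoothed summed vector of all other cells.
#' Chance level is estimated from surrogates that randomly exchange event
#' times across cells within non-overlapping time bins, which preserves
#' each cell's event count and the population count of every bin; the
#' reported coupling is the raw value minus the mean surrogate value, and
#' a cell is significantly coupled if its raw value exceeds the given
#' surrogate percentile. Cells with fewer than `min_events` events are
#' excluded.
#'
#' @param raster `event_raster`.
#' @param smoothing_sd Gaussian kernel SD (frames).
#' @param bin surrogate exchange bin (frames).
#' @param n_shuffles number of surrogates.
#' @param min_events minimum event count for a cell to be analyzed.
#' @param percentile one-sided significance percentile.
#' @param seed RNG seed.
#' @return data.frame with one row per non-excluded cell: `raw`
#'   (Pearson r), `surrogate_mean`, `popc` (raw - surrogate mean),
#'   `significant`, `analyzed`.
#' @export
population_coupling <- function(raster, smoothing_sd = 3, bin = 10,
                                n_shuffles = 500, min_events = 5,
                                percentile = 95, seed = 1) {
  set.seed(seed)
  use <- which(!raster$excluded)
  stopifnot(length(use) >= 2)
  mat <- raster$mat[use, , drop = FALSE]
  n_cells <- nrow(mat); n <- ncol(mat)
  analyzed <- rowSums(mat) >= min_events
  popc_of <- function(m) {
    sm <- gaussian_smooth_rows(m, smoothing_sd)
    tot <- colSums(sm)
    vapply(seq_len(n_cells), function(i) {
      if (!analyzed[i]) return(NA_real_)
      suppressWarnings(cor(sm[i, ], tot - sm[i, ]))
    }, 0)
  }
  raw <- popc_of(mat)
  bins <- split(seq_len(n), ceiling(seq_len(n) / bin))
  sur <- matrix(NA_real_, n_shuffles, n_cells)
  for (s in seq_len(n_shuffles))
    sur[s, ] <- popc_of(exchange_within_bins(mat, bins))
  sur_mean <- colMeans(sur)
  crit <- apply(sur, 2, quantile, probs = percentile / 100, na.rm = TRUE)
  data.frame(raw = raw, surrogate_mean = sur_mean, popc = raw - sur_mean,
             significant = !is.na(raw) & raw > crit, analyzed = analyzed)
}

## permute, within each time bin, the frame positions among that bin's
## events: per-cell counts and per-frame population counts are unchanged
exchange_within_bins <- function(mat, bins) {
  frame_bin <- rep(seq_along(bins), lengths(bins))
  ev <- which(mat == 1L, arr.ind = TRUE)
  if (nrow(ev) < 2) return(mat)
  bid <- frame_bin[ev[, 2]]
  perm_frames <- stats::ave(ev[, 2], bid, FUN = function(v)
    if (length(v) > 1) sample(v) else v)
  # resolve (cell, frame) collisions by re-permuting the affected bins
  for (try in 1:25) {
    cand <- cbind(ev[, 1], perm_frames)
    dup <- duplicated(cand) | duplicated(cand, fromLast = TRUE)
    if (!any(dup)) break
    bad <- bid %in% unique(bid[dup])
    perm_frames[bad] <- stats::ave(ev[bad, 2], bid[bad], FUN = function(v)
      if (length(v) > 1) sample(v) else v)
  }
  if (any(duplicated(cbind(ev[, 1], perm_frames)))) {
    # keep the empirical arrangement in the stubborn bins
    cand <- cbind(ev[, 1], perm_frames)
    dup <- duplicated(cand) | duplicated(cand, fromLast = TRUE)
    bad <- bid %in% unique(bid[dup])
    perm_frames[bad] <- ev[bad, 2]
  }
  out <- matrix(0L, nrow(mat), ncol(mat))
  out[cbind(ev[, 1], perm_frames)] <- 1L
  out
}
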