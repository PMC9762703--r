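#' Ring-shaped cell specification
#'
#' Spike-induced somatic GCaMP fluorescence changes have a ring-like
#' (annular) spatial profile; simulated cells are therefore annuli.
#'
#' @param center `c(row, col)` pixel coordinates (may be fractional).
#' @param inner_radius,outer_radius annulus radii (pixels).
#' @param amplitude fluorescence change per spike (intensity units).
#' @return object of class `ring_cell_spec`.
#' @export
ring_cell_spec <- function(center, inner_radius, outer_radius, amplitude) {
  stopifnot(length(center) == 2, outer_radius > inner_radius,
            inner_radius > 0, amplitude >= 0)
  structure(list(center = as.numeric(center), inner_radius = inner_radius,
                 outer_radius = outer_radius, amplitude = amplitude),
            class = "ring_cell_spec")
}

## pixel mask (logical matrix) of an annulus, clipped check done by caller
ring_mask <- function(spec, shape) {
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  d <- sqrt((rows - spec$center[1])^2 + (cols - spec$center[2])^2)
  d >= spec$inner_radius & d <= spec$outer_radius
}

#' Movie simulation configuration
#'
#' Describes a synthetic two-photon movie: ring-shaped cells firing
#' Poisson spike trains whose transients have difference-of-exponentials
#' kinetics, spatially uniform neuropil-like events, and per-pixel Poisson
#' (photon) noise. When `overlap_fraction` is given (two cells), the
#' second cell is translated along the line of centers until the realized
#' pixel overlap, as a fraction of the single-cell area, matches.
#'
#' @param n_frames number of frames.
#' @param cells list of [ring_cell_spec()].
#' @param frame_rate acquisition rate (Hz).
#' @param frame_shape `c(rows, cols)` pixels.
#' @param overlap_fraction requested pairwise overlap in `[0, 0.75]`, or
#'   `NULL` to keep the specified centers.
#' @param cell_rates spikes/min per cell (recycled).
#' @param neuropil_rate,neuropil_amplitude rate (events/min) and
#'   amplitude of the spatially uniform contamination.
#' @param transient_rise,transient_decay kernel time constants (s);
#'   GCaMP6s-like defaults.
#' @param baseline_f0 resting fluorescence (intensity units).
#' @param noise_scale photons per intensity unit for the Poisson noise;
#'   0 disables noise.
#' @param min_isi_frames minimum spacing between spikes of one cell
#'   (frames); somatic transient events in vivo are separated by seconds,
#'   so benchmarks typically set this to about one second.
#' @param min_cross_isi_frames minimum spacing between spikes of
#'   different cells (frames). Non-coincident trains isolate the spatial
#'   crosstalk question that the overlap benchmark probes; resolving
#'   near-synchronous events of overlapping cells is a separate problem.
#' @param seed RNG seed; all draws derive from it via fixed per-cell
#'   sub-streams, so editing one cell does not perturb the others.
#' @return object of class `movie_sim_config`.
#' @export
movie_sim_config <- function(n_frames, cells, frame_rate = 11.63,
                             frame_shape = c(256, 256),
                             overlap_fraction = NULL,
                             cell_rates = 3, neuropil_rate = 0,
                             neuropil_amplitude = 0,
                             transient_rise = 0.18, transient_decay = 1.6,
                             baseline_f0 = 100, noise_scale = 0,
                             min_isi_frames = 0, min_cross_isi_frames = 0,
                             seed = 1) {
  stopifnot(n_frames >= 1, length(cells) >= 0, frame_rate > 0,
            transient_decay > transient_rise, transient_rise > 0,
            all(cell_rates >= 0), neuropil_rate >= 0, noise_scale >= 0)
  if (!is.null(overlap_fraction)) {
    stopifnot(overlap_fraction >= 0, overlap_fraction <= 0.75,
              length(cells) == 2)
  }
  cfg <- list(n_frames = as.integer(n_frames), cells = cells,
              frame_rate = frame_rate, frame_shape = as.integer(frame_shape),
              overlap_fraction = overlap_fraction,
              cell_rates = rep_len(cell_rates, length(cells)),
              neuropil_rate = neuropil_rate,
              neuropil_amplitude = neuropil_amplitude,
              transient_rise = transient_rise,
              transient_decay = transient_decay,
              baseline_f0 = baseline_f0, noise_scale = noise_scale,
              min_isi_frames = as.integer(min_isi_frames),
              min_cross_isi_frames = as.integer(min_cross_isi_frames),
              seed = as.integer(seed))
  class(cfg) <- "movie_sim_config"
  cfg
}

#' Calcium transient kernel
#'
#' Difference-of-exponentials impulse response, normalized to unit peak.
#'
#' @param rise,decay time constants (s).
#' @param frame_rate sampling rate (Hz).
#' @param length_s kernel support (s); defaults to 6 decay constants.
#' @return numeric vector, kernel sampled at frame intervals starting at
#'   lag 0 (the spike frame itself, where the kernel is 0).
#' @export
transient_kernel <- function(rise, decay, frame_rate, length_s = 6 * decay) {
  t <- seq(0, length_s, by = 1 / frame_rate)
  k <- exp(-t / decay) - exp(-t / rise)
  k / max(k)
}

## realized pairwise overlap (fraction of the area of cell 1's mask)
mask_overlap <- function(m1, m2) sum(m1 & m2) / sum(m1)

## translate cell 2 along the line of centers to match the requested
## overlap fraction; returns the adjusted spec
place_for_overlap <- function(c1, c2, target, shape, tol = 0.02) {
  dir <- c2$center - c1$center
  if (all(dir == 0)) dir <- c(0, 1)
  dir <- dir / sqrt(sum(dir^2))
  m1 <- ring_mask(c1, shape)
  at <- function(d) {
    spec <- c2; spec$center <- c1$center + d * dir
    spec
  }
  ov <- function(d) mask_overlap(m1, ring_mask(at(d), shape))
  if (target == 0) {
    d <- c1$outer_radius + c2$outer_radius + 2
    return(at(d))
  }
  lo <- 0; hi <- c1$outer_radius + c2$outer_radius + 2
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (ov(mid) > target) lo <- mid else hi <- mid
  }
  # fine scan around the bisection point against pixel quantization
  ds <- seq(max(0, lo - 0.75), hi + 0.75, by = 0.02)
  errs <- vapply(ds, function(d) abs(ov(d) - target), 0)
  best <- ds[which.min(errs)]
  if (min(errs) > tol)
    stop(sprintf("requested overlap %.2f not attainable (best error %.3f)",
                 target, min(errs)))
  at(best)
}

#' Simulate a fluorescence movie with ground truth
#'
#' Builds `baseline + sum_cells(ring mask x spike-convolved transient) +
#' uniform neuropil-convolved transient`, then applies per-pixel Poisson
#' noise with intensity `noise_scale x` the noiseless image (rescaled
#' back). Spike counts are Poisson draws at the per-cell rates; spike
#' frames are uniform without replacement.
#'
#' @param config `movie_sim_config`.
#' @return list with `movie` ([fluorescence_movie()]), `truth` (list
#'   `spikes` per cell, `neuropil` event frames), `masks` (list of cell
#'   masks), `cells` (specs after overlap placement), and
#'   `realized_overlap` (or NULL).
#' @export
simulate_movie <- function(config) {
  stopifnot(inherits(config, "movie_sim_config"))
  shape <- config$frame_shape; n <- config$n_frames
  cells <- config$cells
  realized <- NULL
  if (!is.null(config$overlap_fraction)) {
    cells[[2]] <- place_for_overlap(cells[[1]], cells[[2]],
                                    config$overlap_fraction, shape)
    realized <- mask_overlap(ring_mask(cells[[1]], shape),
                             ring_mask(cells[[2]], shape))
  }
  masks <- lapply(cells, function(cc) {
    if (cc$center[1] - cc$outer_radius < 1 ||
        cc$center[1] + cc$outer_radius > shape[1] ||
        cc$center[2] - cc$outer_radius < 1 ||
        cc$center[2] + cc$outer_radius > shape[2])
      stop("ring exceeds frame bounds")
    m <- ring_mask(cc, shape)
    if (!any(m)) stop("empty ring mask")
    m
  })
  dur_min <- n / config$frame_rate / 60
  kern <- transient_kernel(config$transient_rise, config$transient_decay,
                           config$frame_rate)
  draw_train <- function(rate, stream, min_isi = config$min_isi_frames) {
    set.seed(config$seed + stream)
    cnt <- rpois(1, rate * dur_min)
    if (min_isi <= 1) return(sort(sample.int(n, min(cnt, n))))
    # uniform draw among min-separated spike configurations
    gap <- min_isi - 1L
    avail <- n - (cnt - 1L) * gap
    if (avail < cnt) stop("spike count incompatible with min_isi_frames")
    sort(sample.int(avail, cnt)) + (seq_len(cnt) - 1L) * gap
  }
  spikes <- list()
  for (i in seq_along(cells)) {
    tr <- draw_train(config$cell_rates[i], 1000L * i)
    if (config$min_cross_isi_frames > 0 && i > 1) {
      prev <- sort(unlist(spikes))
      for (attempt in seq_len(100)) {
        gap <- vapply(tr, function(f) min(abs(prev - f)), 0)
        if (all(gap >= config$min_cross_isi_frames)) break
        tr <- draw_train(config$cell_rates[i], 1000L * i + 17L * attempt)
      }
      if (!all(vapply(tr, function(f) min(abs(prev - f)), 0) >=
               config$min_cross_isi_frames))
        stop("could not place non-coincident spike trains")
    }
    spikes[[i]] <- tr
  }
  neuropil <- draw_train(config$neuropil_rate, 777L, min_isi = 0L)
  conv_train <- function(frames) {
    y <- numeric(n)
    for (f in frames) {
      idx <- f:min(n, f + length(kern) - 1)
      y[idx] <- y[idx] + kern[seq_along(idx)]
    }
    y
  }
  npx <- prod(shape)
  neu_trace <- config$neuropil_amplitude * conv_train(neuropil)
  stack <- array(rep(config$baseline_f0 + neu_trace, each = npx),
                 dim = c(shape, n))
  for (i in seq_along(cells)) {
    tr <- cells[[i]]$amplitude * conv_train(spikes[[i]])
    pix <- which(masks[[i]])
    on <- which(tr != 0)
    if (length(on))
      stack[rep(pix, length(on)) +
              rep((on - 1) * npx, each = length(pix))] <-
        stack[rep(pix, length(on)) + rep((on - 1) * npx, each = length(pix))] +
        rep(tr[on], each = length(pix))
  }
  if (config$noise_scale > 0) {
    set.seed(config$seed + 555L)
    stack[] <- rpois(length(stack), config$noise_scale * pmax(stack, 0)) /
      config$noise_scale
  }
  list(movie = fluorescence_movie(stack, config$frame_rate),
       truth = list(spikes = spikes, neuropil = neuropil),
       masks = masks, cells = cells, realized_overlap = realized)
}

#' Overlap benchmark: one movie per requested overlap
#'
#' Re-simulates the same two-cell configuration at several spatial
#' overlaps. The same seed is reused, so each cell's spike train is
#' identical across entries and only the geometry changes.
#'
#' @param base_config two-cell `movie_sim_config`.
#' @param overlaps requested overlap fractions, each in `[0, 0.75]`.
#' @return list with one [simulate_movie()] result per overlap.
#' @export
overlap_benchmark <- function(base_config, overlaps) {
  stopifnot(all(overlaps >= 0), all(overlaps <= 0.75))
  lapply(overlaps, function(o) {
    cfg <- base_config
    cfg$overlap_fraction <- o
    simulate_movie(cfg)
  })
}

#' Standard two-cell overlap benchmark configuration
#'
#' The canonical configuration used to benchmark detection against
#' ground truth: two identical ring cells (inner radius 4 px, outer
#' 7 px, transient amplitude 50% of baseline) in a small field of view,
#' 10 min at 11.63 Hz, about 3 events/min per cell with at least 1 s
#' within-cell and 0.5 s across-cell event separation, spatially uniform
#' neuropil events (3/min, amplitude 10% of baseline) and moderate
#' photon noise. Pass the returned config to [overlap_benchmark()] with
#' the overlap fractions to probe.
#'
#' @param seed RNG seed.
#' @param n_frames recording length (frames).
#' @return `movie_sim_config`.
#' @export
overlap_benchmark_config <- function(seed = 11, n_frames = 6978) {
  movie_sim_config(
    n_frames = n_frames,
    cells = list(ring_cell_spec(c(20, 20), 4, 7, 50),
                 ring_cell_spec(c(20, 40), 4, 7, 50)),
    frame_shape = c(40, 60), overlap_fraction = 0,
    cell_rates = 3, neuropil_rate = 3, neuropil_amplitude = 10,
    noise_scale = 4, min_isi_frames = 12, min_cross_isi_frames = 6,
    seed = seed)
}

#' Simulate a structured binary event raster
#'
#' Background events are Poissonian per cell (uniform or lognormal rate
#' distribution across cells). Optional co-activation bursts recruit each
#' cell with a participation probability inside short windows; optional
#' motifs plant repeated binary patterns at bin-aligned windows.
#'
#' @param n_cells,n_frames raster dimensions.
#' @param frame_rate Hz.
#' @param rate mean background rate (events/min).
#' @param rate_model `"uniform"` (all cells at `rate`) or `"lognormal"`
#'   (lognormal across cells with mean `rate` and `rate_sdlog`).
#' @param rate_sdlog sdlog of the lognormal rate distribution.
#' @param burst_spec optional list: `rate` (bursts/min), `duration`
#'   (frames), `participation` (probability per cell per burst).
#' @param motif_spec optional list: `patterns` (cells x motifs binary
#'   matrix), `repeats` (occurrences per motif), `bin` (window, frames).
#' @param seed RNG seed.
#' @return `event_raster`, with attributes `burst_windows` and
#'   `motif_windows` recording the planted structure.
#' @export
simulate_raster <- function(n_cells, n_frames, frame_rate = 11.63,
                            rate = 2, rate_model = c("uniform", "lognormal"),
                            rate_sdlog = 0.6, burst_spec = NULL,
                            motif_spec = NULL, seed = 1) {
  rate_model <- match.arg(rate_model)
  stopifnot(rate >= 0)
  set.seed(seed)
  dur_min <- n_frames / frame_rate / 60
  rates <- if (rate_model == "uniform") rep(rate, n_cells) else
    stats::rlnorm(n_cells, meanlog = log(rate) - rate_sdlog^2 / 2,
                  sdlog = rate_sdlog)
  mat <- matrix(0L, n_cells, n_frames)
  for (i in seq_len(n_cells)) {
    cnt <- rpois(1, rates[i] * dur_min)
    if (cnt) mat[i, sample.int(n_frames, min(cnt, n_frames))] <- 1L
  }
  burst_windows <- NULL
  if (!is.null(burst_spec)) {
    stopifnot(burst_spec$participation >= 0, burst_spec$participation <= 1)
    nb <- rpois(1, burst_spec$rate * dur_min)
    if (nb) {
      starts <- sort(sample.int(max(1, n_frames - burst_spec$duration), nb))
      for (s in starts) {
        hit <- runif(n_cells) < burst_spec$participation
        frames <- s + sample.int(burst_spec$duration, n_cells,
                                 replace = TRUE) - 1
        mat[cbind(which(hit), frames[hit])] <- 1L
      }
      burst_windows <- data.frame(onset = starts,
                                  offset = starts + burst_spec$duration - 1)
    }
  }
  motif_windows <- NULL
  if (!is.null(motif_spec)) {
    pats <- as.matrix(motif_spec$patterns)
    if (nrow(pats) != n_cells) stop("motif pattern length != n_cells")
    bin <- if (is.null(motif_spec$bin)) 10L else motif_spec$bin
    n_bins <- n_frames %/% bin
    need <- ncol(pats) * motif_spec$repeats
    if (need > n_bins) stop("not enough bins to plant the motifs")
    slots <- sample.int(n_bins, need)
    motif_windows <- data.frame(
      motif = rep(seq_len(ncol(pats)), each = motif_spec$repeats),
      bin = slots)
    for (r in seq_len(nrow(motif_windows))) {
      b <- motif_windows$bin[r]
      on <- which(pats[, motif_windows$motif[r]] > 0)
      frames <- (b - 1) * bin + sample.int(bin, length(on), replace = TRUE)
      mat[cbind(on, frames)] <- 1L
    }
  }
  out <- event_raster(mat, frame_rate)
  attr(out, "burst_windows") <- burst_windows
  attr(out, "motif_windows") <- motif_windows
  attr(out, "rates") <- rates
  out
}
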