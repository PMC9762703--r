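# Independent brute-force oracles used to validate the implementations.

# STTC by direct definition: frame-wise tiling and per-event coincidence.
sttc_brute <- function(a, b, dt, duration) {
  if (!length(a) || !length(b)) return(NA_real_)
  tiles <- function(idx) {
    covered <- logical(duration)
    for (i in idx)
      covered[max(1, i - dt):min(duration, i + dt)] <- TRUE
    mean(covered)
  }
  prop <- function(x, y) mean(vapply(x, function(i) any(abs(y - i) <= dt),
                                     TRUE))
  tA <- tiles(a); tB <- tiles(b)
  pA <- prop(a, b); pB <- prop(b, a)
  0.5 * ((pA - tB) / (1 - pA * tB) + (pB - tA) / (1 - pB * tA))
}

# Gini via the mean absolute pairwise difference.
gini_brute <- function(x) {
  n <- length(x)
  sum(abs(outer(x, x, `-`))) / (2 * n^2 * mean(x))
}

# Matching index by explicit set operations.
mi_brute <- function(a, b) {
  sa <- which(a > 0); sb <- which(b > 0)
  2 * length(intersect(sa, sb)) / (length(sa) + length(sb))
}

# CV2 by an explicit loop over the definition.
cv2_brute <- function(ici) {
  k <- length(ici)
  s <- 0
  for (j in 1:(k - 1))
    s <- s + 2 * abs(ici[j + 1] - ici[j]) / (ici[j + 1] + ici[j])
  s / (k - 1)
}

# small noiseless one-cell movie used by several detection tests
tiny_single_cell_sim <- function(seed = 5, n_frames = 1500, noise = 0,
                                 rate = 3) {
  cfg <- movie_sim_config(
    n_frames = n_frames,
    cells = list(ring_cell_spec(c(15, 15), 4, 7, 50)),
    frame_shape = c(30, 30), cell_rates = rate, noise_scale = noise,
    min_isi_frames = 12, seed = seed)
  simulate_movie(cfg)
}

# state-vector column order of the plasticity network trajectories
state_cols <- c("A_P", "A_I", "x_PP", "u_PP", "x_IP", "u_IP",
                "x_PI", "u_PI", "x_II", "u_II")
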