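test_that("a configuration without events or noise gives a constant movie", {
  cfg <- movie_sim_config(n_frames = 50,
                          cells = list(ring_cell_spec(c(10, 10), 3, 5, 20)),
                          frame_shape = c(20, 20), cell_rates = 0,
                          noise_scale = 0, seed = 1)
  sim <- simulate_movie(cfg)
  expect_true(all(sim$movie$stack == cfg$baseline_f0))
  expect_length(sim$truth$spikes[[1]], 0)
})

test_that("ring-mean fluorescence change equals amplitude times the kernel", {
  cfg <- movie_sim_config(n_frames = 240,
                          cells = list(ring_cell_spec(c(12, 12), 3, 5, 37)),
                          frame_shape = c(24, 24), cell_rates = 6,
                          noise_scale = 0, min_isi_frames = 30, seed = 7)
  sim <- simulate_movie(cfg)
  spikes <- sim$truth$spikes[[1]]
  expect_gte(length(spikes), 1)
  kern <- transient_kernel(cfg$transient_rise, cfg$transient_decay,
                           cfg$frame_rate)
  ring <- sim$masks[[1]]
  dff <- apply(sim$movie$stack, 3, function(fr) mean(fr[ring])) -
    cfg$baseline_f0
  expected <- numeric(cfg$n_frames)
  for (s in spikes) {
    idx <- s:min(cfg$n_frames, s + length(kern) - 1)
    expected[idx] <- expected[idx] + 37 * kern[seq_along(idx)]
  }
  expect_equal(dff, expected, tolerance = 1e-12)
  # peak within a few frames after the spike, then decay
  pk <- which.max(dff[spikes[1]:(spikes[1] + 15)])
  expect_lte(pk - 1, 8)
})

test_that("simulation is bit-identical under the same seed", {
  cfg <- movie_sim_config(n_frames = 200,
                          cells = list(ring_cell_spec(c(12, 12), 3, 5, 40),
                                       ring_cell_spec(c(12, 24), 3, 5, 40)),
                          frame_shape = c(24, 36), overlap_fraction = 0.5,
                          cell_rates = 4, neuropil_rate = 2,
                          neuropil_amplitude = 8, noise_scale = 2, seed = 9)
  s1 <- simulate_movie(cfg)
  s2 <- simulate_movie(cfg)
  expect_identical(s1$movie$stack, s2$movie$stack)
  expect_identical(s1$truth, s2$truth)
})

test_that("ground-truth spike counts equal the seeded Poisson draws", {
  cfg <- movie_sim_config(n_frames = 600,
                          cells = list(ring_cell_spec(c(12, 12), 3, 5, 40),
                                       ring_cell_spec(c(12, 24), 3, 5, 40)),
                          frame_shape = c(24, 36), overlap_fraction = 0.75,
                          cell_rates = 3, seed = 21)
  sim <- simulate_movie(cfg)
  dur_min <- cfg$n_frames / cfg$frame_rate / 60
  for (i in 1:2) {
    set.seed(cfg$seed + 1000L * i)
    expect_length(sim$truth$spikes[[i]], rpois(1, 3 * dur_min))
  }
})

test_that("overlap placement hits the requested fraction", {
  base <- movie_sim_config(n_frames = 10,
                           cells = list(ring_cell_spec(c(20, 20), 4, 7, 40),
                                        ring_cell_spec(c(20, 40), 4, 7, 40)),
                           frame_shape = c(40, 60), overlap_fraction = 0,
                           cell_rates = 0, seed = 1)
  req <- c(0, 0.25, 0.5, 0.75)
  bench <- overlap_benchmark(base, req)
  realized <- vapply(bench, `[[`, 0, "realized_overlap")
  expect_equal(realized[1], 0)
  expect_true(all(abs(realized - req) <= 0.02))
  expect_true(all(diff(realized) > 0))
  # zero overlap means disjoint masks
  expect_equal(sum(bench[[1]]$masks[[1]] & bench[[1]]$masks[[2]]), 0)
})

test_that("raster generator honors rates, structure, and determinism", {
  # all-zero raster
  r0 <- simulate_raster(5, 100, rate = 0, seed = 1)
  expect_true(all(r0$mat == 0L))
  # Poisson marginals: counts within 4 SD of the expectation
  r <- simulate_raster(40, 6978, rate = 3, seed = 2)
  expected <- 3 * 6978 / 11.63 / 60
  expect_true(all(abs(rowSums(r$mat) - expected) <= 4 * sqrt(expected)))
  # determinism
  expect_identical(simulate_raster(10, 500, rate = 2, seed = 7)$mat,
                   simulate_raster(10, 500, rate = 2, seed = 7)$mat)
  # planted motif windows are identical patterns before background
  pat <- matrix(0L, 12, 1); pat[c(2, 5, 9), 1] <- 1L
  rm <- simulate_raster(12, 600, rate = 0,
                        motif_spec = list(patterns = pat, repeats = 10,
                                          bin = 10), seed = 3)
  mim <- matching_index_matrix(rm, bin = 10)
  expect_true(all(mim$mi == 1))
  expect_equal(ncol(mim$patterns), 10)
})
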