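test_that("CV2 matches hand-computed cases and the brute-force oracle", {
  # perfectly periodic: 0
  per <- event_raster(matrix(as.integer(seq_len(200) %% 10 == 0), 1,
                             byrow = TRUE), 10)
  cs <- cell_statistics(per)
  expect_equal(cs$cv2, 0)
  # alternating ICIs 1, 2 -> 2/3
  ici <- rep(c(1, 2), 10)
  expect_equal(cv2_of_intervals(ici), 2 / 3, tolerance = 1e-12)
  set.seed(10)
  for (i in 1:20) {
    x <- rexp(sample(10:50, 1)) + 0.01
    expect_equal(cv2_of_intervals(x), cv2_brute(x), tolerance = 1e-12)
  }
  # cells with fewer than 10 ICIs are flagged
  few <- event_raster(matrix(c(rep(0L, 90), rep(1L, 5), rep(0L, 5)), 1), 10)
  expect_true(is.na(cell_statistics(few)$cv2))
})

test_that("frequency counts valid time only", {
  mat <- matrix(0L, 2, 1200); mat[1, seq(10, 1100, by = 50)] <- 1L
  valid <- rep(TRUE, 1200); valid[1150:1200] <- FALSE
  r <- event_raster(mat, 10, valid)
  cs <- cell_statistics(r)
  expect_equal(cs$frequency[1], 22 / (sum(valid) / 10 / 60))
  expect_equal(cs$frequency[2], 0)
})

test_that("Gini coefficient matches closed forms and the pairwise oracle", {
  expect_equal(gini_coefficient(rep(4, 10))$gini, 0, tolerance = 1e-12)
  expect_equal(gini_coefficient(c(1, 2, 3, 4))$gini, 0.25,
               tolerance = 1e-12)
  for (n in c(3, 7, 20)) {
    x <- c(rep(0, n - 1), 5)
    expect_equal(gini_coefficient(x)$gini, (n - 1) / n, tolerance = 1e-12)
  }
  set.seed(11)
  for (i in 1:20) {
    x <- rexp(sample(5:40, 1))
    expect_equal(gini_coefficient(x)$gini, gini_brute(x),
                 tolerance = 1e-9)
  }
  expect_error(gini_coefficient(c(0, 0)), "zero")
})

test_that("the fraction of active cells uses dilated vectors", {
  r0 <- event_raster(matrix(0L, 10, 60), 10)
  expect_true(all(fraction_active(r0)$phi == 0))
  mat <- matrix(0L, 10, 60); mat[1, 30] <- 1L
  phi <- fraction_active(event_raster(mat, 10), dt = 3)
  expect_equal(sum(phi$phi > 0), 7)
  expect_true(all(phi$phi[27:33] == 0.1))
  # monotone in the dilation half-width
  phi5 <- fraction_active(event_raster(mat, 10), dt = 5)
  expect_true(all(phi5$phi >= phi$phi))
})

test_that("surrogate NB threshold is seeded, adaptive, and zero for silence", {
  expect_equal(nb_threshold(event_raster(matrix(0L, 5, 100), 10)), 0)
  set.seed(20)
  lo <- simulate_raster(20, 2000, rate = 2, seed = 31)
  hi <- simulate_raster(20, 2000, rate = 8, seed = 31)
  t_lo <- nb_threshold(lo, n_shuffles = 100, seed = 5)
  t_hi <- nb_threshold(hi, n_shuffles = 100, seed = 5)
  expect_gte(t_hi, t_lo)
  expect_identical(t_lo, nb_threshold(lo, n_shuffles = 100, seed = 5))
})

test_that("network bursts are segmented, sized, and attributed correctly", {
  mat <- matrix(0L, 10, 200)
  mat[1:5, 100] <- 1L          # burst recruiting 50% of cells
  mat[1, 30] <- 1L             # lone event of cell 1
  r <- event_raster(mat, 10)
  phi <- fraction_active(r, dt = 3)
  nb <- detect_network_bursts(phi, threshold = 0.1)
  expect_equal(nrow(nb$segments), 1)
  expect_equal(nb$segments$size, 0.4, tolerance = 1e-12)
  expect_equal(nb$segments$onset, 97)
  expect_equal(nb$segments$offset, 103)
  expect_equal(nb$participation[1], 1)  # cell 1 active in every NB
  expect_equal(nb$participation[6], 0)
  # all sub-threshold: empty set
  nb2 <- detect_network_bursts(phi, threshold = 0.9)
  expect_equal(nrow(nb2$segments), 0)
  expect_equal(nb2$time_in_nb, 0)
})

test_that("continuity classification applies the frame-fraction rule", {
  mk_phi <- function(v) structure(
    list(phi = v, dt = 3, valid = rep(TRUE, length(v)), frame_rate = 11.63,
         n_cells = 10, dilated = matrix(0L, 1, length(v))),
    class = "phi_trace")
  expect_equal(classify_continuity(mk_phi(rep(0, 232)))$labels,
               rep("discontinuous", 2))
  expect_equal(classify_continuity(mk_phi(rep(0.05, 232)))$labels,
               rep("continuous", 2))
  # exactly 81 of 116 supra-threshold frames: 81/116 < 0.70, discontinuous
  v81 <- c(rep(0.05, 81), rep(0, 35))
  v82 <- c(rep(0.05, 82), rep(0, 34))
  expect_equal(classify_continuity(mk_phi(v81))$labels, "discontinuous")
  expect_equal(classify_continuity(mk_phi(v82))$labels, "continuous")
  # trailing partial bin dropped
  expect_length(classify_continuity(mk_phi(rep(0, 300)))$labels, 2)
})

test_that("spectral power localizes oscillations despite missing frames", {
  n <- 1200; fr <- 11.63
  t <- (0:(n - 1)) / fr
  v <- 0.1 + 0.05 * sin(2 * pi * 0.3 * t)
  mk_phi <- function(phi, valid) structure(
    list(phi = phi, dt = 3, valid = valid, frame_rate = fr, n_cells = 10,
         dilated = NULL), class = "phi_trace")
  sp <- spectral_power(mk_phi(v, rep(TRUE, n)))
  expect_equal(sp$frequency[which.max(sp$power)], 0.3, tolerance = 0.02)
  expect_gt(sp$bandpower, 0)
  # remove 30% of frames: the peak stays put
  set.seed(12)
  valid <- rep(TRUE, n); valid[sample(n, 360)] <- FALSE
  v2 <- v; v2[!valid] <- NA
  sp2 <- spectral_power(mk_phi(v2, valid))
  expect_equal(sp2$frequency[which.max(sp2$power)], 0.3, tolerance = 0.02)
  # constant series: essentially no power
  sp3 <- spectral_power(mk_phi(rep(0.2, n), rep(TRUE, n)))
  expect_true(all(sp3$power < 1e-9))
})

test_that("physiological traces yield rates and movement epochs", {
  sr <- 100; n <- 400 * sr
  t <- (0:(n - 1)) / sr
  set.seed(13)
  x <- sin(2 * pi * 3 * t) + 0.7 * sin(2 * pi * 8 * t) + rnorm(n, sd = 0.2)
  ph <- physio_analysis(x, sr)
  expect_equal(ph$respiration_rate, 3, tolerance = 0.5)
  expect_equal(ph$heart_rate, 8, tolerance = 0.5)
  # stationary noise: the adaptive threshold flags only the skewed
  # upper tail of the band-power distribution
  ph2 <- physio_analysis(rnorm(n, sd = 0.3), sr)
  expect_lt(mean(ph2$movement$moving), 0.12)
  # an injected high-power epoch is covered by the movement mask
  y <- rnorm(n, sd = 0.2)
  y[(200 * sr):(210 * sr)] <- y[(200 * sr):(210 * sr)] +
    4 * sin(2 * pi * 2 * t[(200 * sr):(210 * sr)])
  ph3 <- physio_analysis(y, sr)
  inside <- ph3$movement$time > 201 & ph3$movement$time < 209
  expect_gt(mean(ph3$movement$moving[inside]), 0.8)
})
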