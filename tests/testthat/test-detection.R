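test_that("ROI expansion is a Euclidean distance-transform dilation", {
  m <- matrix(FALSE, 9, 9); m[5, 5] <- TRUE
  e <- expand_roi(m, 2)
  expect_equal(sum(e), 13)  # disk of radius 2
  expect_identical(expand_roi(m, 0), m)
  m2 <- matrix(FALSE, 8, 8); m2[3:5, 3:4] <- TRUE
  expect_true(all(m2[expand_roi(m2, 2)] | TRUE))  # superset
  expect_true(all(expand_roi(m2, 2)[m2]))
  expect_gte(sum(expand_roi(m2, 2)), sum(m2))
  expect_error(expand_roi(matrix(FALSE, 3, 3)), "empty")
})

test_that("rolling baseline is a centered truncated moving median", {
  expect_equal(rolling_baseline(rep(3, 100), 10), rep(3, 100))
  x <- rep(1, 200); x[100] <- 50
  expect_equal(rolling_baseline(x, 21)[95:105], rep(1, 11))
  tr <- as.numeric(1:1000)
  expect_equal(rolling_baseline(tr, 500)[600], median(351:850))
  # odd windows agree with stats::runmed in the interior
  y <- sin(1:300 / 7) + cos(1:300 / 3)
  expect_equal(rolling_baseline(y, 21)[50:250],
               as.numeric(stats::runmed(y, 21))[50:250])
})

test_that("candidate onsets follow the descending greedy selection", {
  # monotone decreasing trace: no positive derivative peaks
  expect_length(candidate_onsets(seq(100, 1, length.out = 150)), 0)
  # two equal steps 20 frames apart are both selected
  f <- rep(0, 100); f[30:100] <- 5; f[50:100] <- 10
  sel <- candidate_onsets(f)
  expect_equal(length(sel), 2)
  expect_true(any(abs(sel - 30) <= 1) && any(abs(sel - 50) <= 1))
  # a smaller peak within the exclusion distance of a larger one is
  # suppressed; a distant one survives
  g <- rep(0, 120)
  g[30:120] <- g[30:120] + 10   # large step at 30
  g[33:120] <- g[33:120] + 6    # nearby smaller step at 33
  g[80:120] <- g[80:120] + 3    # distant small step at 80
  sel2 <- candidate_onsets(g, min_separation = 5)
  expect_true(any(abs(sel2 - 80) <= 1))
  expect_true(all(abs(sel2 - 33) > 1 | abs(sel2 - 30) <= 1))
  d <- outer(sel2, sel2, function(a, b) abs(a - b))
  expect_true(all(d[upper.tri(d)] >= 5))
})

test_that("templates are z-scored, averaged, and quality controlled", {
  set.seed(1)
  npx <- 60
  ring <- c(rep(1, 30), rep(0, 30))      # "ring" pattern
  raw_sel <- as.logical(ring)
  n <- 400
  pix <- matrix(100 + rnorm(npx * n, sd = 0.01), npx, n)
  for (k in c(101, 201)) pix[, k:(k + 4)] <- pix[, k:(k + 4)] + 30 * ring
  tm <- build_template(pix, raw_sel, c(101, 201), baseline_window = 99)
  expect_s3_class(tm, "spatial_template")
  expect_false(tm$excluded)
  expect_equal(tm$n_candidates_used, 2)
  expect_lt(abs(mean(tm$weights)), 1e-9)
  expect_lt(abs(sd(tm$weights) - 1), 1e-9)
  expect_gt(mean(tm$weights[raw_sel]), mean(tm$weights[!raw_sel]))
  # two identical candidates average to the single-candidate template
  tm1 <- build_template(pix, raw_sel, 101, baseline_window = 99)
  expect_equal(tm$weights, tm1$weights, tolerance = 0.05)
  # rim-dominated candidates are rejected, excluding the cell
  pix2 <- matrix(100 + rnorm(npx * n, sd = 0.01), npx, n)
  for (k in c(101, 201)) pix2[, k:(k + 4)] <- pix2[, k:(k + 4)] +
    30 * (1 - ring)
  tm2 <- build_template(pix2, raw_sel, c(101, 201), baseline_window = 99)
  expect_true(tm2$excluded)
  expect_null(tm2$weights)
})

test_that("the detection criterion behaves like a spatial matched filter", {
  set.seed(2)
  w <- rnorm(50)
  tmpl <- structure(list(weights = (w - mean(w)) / sd(w), excluded = FALSE),
                    class = "spatial_template")
  tw <- tmpl$weights
  # spatially constant frame: A = 0, D = 0
  tr <- detection_criterion(matrix(7, 50, 3), tmpl)
  expect_lt(max(abs(tr$A)), 1e-9)
  expect_lt(max(abs(tr$D)), 1e-6)   # SSE floor keeps sigma > 0
  # exact fit: A and C recovered, SSE guard engages
  tr2 <- detection_criterion(cbind(2 * tw + 5), tmpl)
  expect_equal(tr2$A, 2, tolerance = 1e-9)
  expect_equal(tr2$C, 5, tolerance = 1e-9)
  expect_gt(tr2$D, 1e3)
  # anti-correlated frame: negative criterion
  tr3 <- detection_criterion(cbind(-tw), tmpl)
  expect_equal(tr3$A, -1, tolerance = 1e-9)
  expect_lt(tr3$D, 0)
  expect_error(detection_criterion(matrix(1, 50, 2),
                                   structure(list(weights = rep(1, 50),
                                                  excluded = FALSE),
                                             class = "spatial_template")),
               "degenerate")
})

test_that("the criterion is immune to uniform offsets and global rescaling", {
  set.seed(3)
  w <- rnorm(40); w <- (w - mean(w)) / sd(w)
  tmpl <- structure(list(weights = w, excluded = FALSE),
                    class = "spatial_template")
  dff <- matrix(rnorm(40 * 30), 40, 30) + outer(w, c(rep(0, 20), rep(4, 10)))
  base <- detection_criterion(dff, tmpl)
  shifted <- detection_criterion(dff + 123.456, tmpl)
  expect_equal(base$D, shifted$D, tolerance = 1e-10)
  scaled <- detection_criterion(dff * 7.5, tmpl)
  expect_equal(base$D, scaled$D, tolerance = 1e-10)
})

test_that("event extraction finds onsets at rising edges and respects validity", {
  cfg <- event_extraction_config()
  expect_length(extract_events(rep(0, 300), cfg)$onsets, 0)
  # one clean rectangular pulse: one onset at the rising edge
  d <- rep(0, 300); d[100:130] <- 8
  ev <- extract_events(d, cfg)
  expect_equal(length(ev$onsets), 1)
  expect_lte(abs(ev$onsets - 100), 2)
  # invalid frames cannot carry onsets
  valid <- rep(TRUE, 300); valid[95:135] <- FALSE
  ev2 <- extract_events(d, cfg, valid)
  expect_length(ev2$onsets, 0)
})

test_that("detection metrics implement greedy one-to-one matching", {
  m <- evaluate_detection(c(10, 50), c(10, 50), 3)
  expect_equal(c(m$recall, m$precision, m$f1), c(1, 1, 1))
  expect_equal(m$mean_delay, 0)
  m2 <- evaluate_detection(integer(0), c(5, 9), 3)
  expect_equal(m2$recall, 0)
  expect_equal(m2$precision, 1)
  expect_true(m2$no_detections)
  m3 <- evaluate_detection(c(11, 49, 80), c(10, 50), 3)
  expect_equal(m3$recall, 1)
  expect_equal(m3$precision, 2 / 3)
  expect_equal(m3$mean_delay, 0)
  expect_equal(m3$f1, 2 * 1 * (2 / 3) / (1 + 2 / 3))
})

test_that("noise level is the p50 - p10 spread and scales linearly", {
  expect_equal(noise_level(rep(2, 100)), 0)
  set.seed(4)
  u <- runif(40000)
  expect_equal(noise_level(u), 0.4, tolerance = 0.01)
  x <- rnorm(5000)
  expect_equal(noise_level(3 * x), 3 * noise_level(x), tolerance = 1e-12)
  m <- rbind(u[1:1000], 2 * u[1:1000])
  expect_equal(noise_level(m)[2], 2 * noise_level(m)[1], tolerance = 1e-12)
})

test_that("noiseless single-cell movies are detected perfectly and deterministically", {
  sim <- tiny_single_cell_sim()
  lab <- masks_to_labels(sim$masks)
  res <- detect(sim$movie, lab)
  m <- evaluate_detection(res$event_series[[1]], sim$truth$spikes[[1]], 3)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)
  expect_lte(abs(m$mean_delay), 1)
  res2 <- detect(sim$movie, lab)
  expect_identical(res$raster$mat, res2$raster$mat)
  # both detectors agree on an isolated, uncontaminated cell
  res3 <- detect_mean_dff(sim$movie, lab)
  m3 <- evaluate_detection(res3$event_series[[1]], sim$truth$spikes[[1]], 3)
  expect_equal(m3$recall, 1)
})

test_that("cells without usable templates are excluded with all-zero rows", {
  # constant movie: no derivative peaks anywhere
  stack <- array(100, dim = c(20, 20, 300))
  movie <- fluorescence_movie(stack, 11.63)
  lab <- matrix(0L, 20, 20); lab[8:12, 8:12] <- 1L
  res <- detect(movie, lab)
  expect_true(res$raster$excluded[1])
  expect_true(all(res$raster$mat == 0L))
  expect_error(detect(movie, matrix(0L, 20, 20)), "no ROI")
})
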