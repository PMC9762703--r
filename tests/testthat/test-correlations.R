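test_that("STTC matches the definition on canonical cases", {
  expect_equal(sttc_pair(c(5, 20, 60), c(5, 20, 60), 3, 100), 1)
  expect_true(is.na(sttc_pair(c(5, 20), integer(0), 3, 100)))
  expect_true(is.na(sttc_pair(integer(0), integer(0), 3, 100)))
  # far-apart single events: P = 0, T = 7/100 each
  v <- sttc_pair(10, 30, 3, 100)
  expect_equal(v, sttc_brute(10, 30, 3, 100), tolerance = 1e-12)
  expect_equal(v, 0.5 * (2 * (0 - 0.07) / 1), tolerance = 1e-12)
})

test_that("STTC equals the brute-force tiling implementation", {
  set.seed(14)
  for (i in 1:100) {
    dur <- sample(50:300, 1)
    a <- sort(sample(dur, sample(1:12, 1)))
    b <- sort(sample(dur, sample(1:12, 1)))
    dt <- sample(1:5, 1)
    expect_equal(sttc_pair(a, b, dt, dur), sttc_brute(a, b, dt, dur),
                 tolerance = 1e-9)
  }
})

test_that("STTC analysis is symmetric, seeded, and flags planted pairs", {
  set.seed(15)
  r <- simulate_raster(12, 3000, rate = 4, seed = 41)
  # plant a strongly synchronous pair
  r$mat[2, ] <- 0L
  sync <- which(r$mat[1, ] == 1L)
  r$mat[2, pmin(sync + 1, 3000)] <- 1L
  res <- sttc_analysis(r, n_shuffles = 100, seed = 6)
  expect_equal(res$sttc, t(res$sttc))
  expect_true(all(res$sttc[upper.tri(res$sttc)] >= -1 &
                    res$sttc[upper.tri(res$sttc)] <= 1, na.rm = TRUE))
  expect_true(res$significant[1, 2])
  res2 <- sttc_analysis(r, n_shuffles = 100, seed = 6)
  expect_identical(res$sttc, res2$sttc)
  expect_identical(res$fraction_significant, res2$fraction_significant)
})

test_that("STTC distance dependence is computed over significant pairs", {
  set.seed(19)
  r <- simulate_raster(8, 3000, rate = 5, seed = 43)
  # two synchronous pairs at different separations and coupling lags
  r$mat[2, ] <- 0L
  r$mat[2, pmin(which(r$mat[1, ] == 1L) + 1L, 3000L)] <- 1L
  r$mat[4, ] <- 0L
  r$mat[4, pmin(which(r$mat[3, ] == 1L) + 3L, 3000L)] <- 1L
  r$centroids <- cbind(c(0, 1, 0, 30, 60, 90, 120, 150),
                       rep(0, 8))
  res <- sttc_analysis(r, n_shuffles = 100, seed = 8)
  expect_true(res$significant[1, 2] && res$significant[3, 4])
  expect_true(is.finite(res$spearman_rho))
  expect_gte(res$spearman_rho, -1)
  expect_lte(res$spearman_rho, 1)
  expect_equal(res$distance[1, 2], 1)
})

test_that("population coupling: proportional vectors give r = 1 and surrogates preserve marginals", {
  mat <- matrix(0L, 2, 400)
  ev <- seq(20, 380, by = 20)
  mat[1, ev] <- 1L; mat[2, ev] <- 1L
  r <- event_raster(mat, 10)
  pc <- population_coupling(r, n_shuffles = 20, seed = 3)
  expect_equal(pc$raw[1], 1, tolerance = 1e-9)
  # surrogate exchange preserves per-cell totals and per-frame sums
  set.seed(16)
  m <- simulate_raster(15, 600, rate = 8, seed = 77)$mat
  bins <- split(seq_len(600), ceiling(seq_len(600) / 10))
  for (i in 1:25) {
    sm <- devnetdyn:::exchange_within_bins(m, bins)
    expect_identical(rowSums(sm), rowSums(m))
    expect_identical(colSums(sm), colSums(m))
  }
})

test_that("population coupling flags a cell locked to the population peak", {
  # the bin-exchange surrogate controls for bin-scale rate comodulation,
  # so significance requires finer-than-bin coupling: plant a cell that
  # always fires at the busiest frame of each burst window
  set.seed(17)
  n_cells <- 20; n <- 4000
  mat <- matrix(0L, n_cells, n)
  for (i in 2:n_cells) mat[i, sample.int(n, 15)] <- 1L
  for (s in seq(20, n - 20, by = 40)) {
    win <- s:(s + 6)
    for (i in 2:n_cells) if (runif(1) < 0.7) mat[i, sample(win, 1)] <- 1L
    peak <- win[which.max(colSums(mat[, win, drop = FALSE]))]
    mat[1, peak] <- 1L
  }
  r <- event_raster(mat, 11.63)
  pc <- population_coupling(r, n_shuffles = 200, seed = 9)
  expect_true(pc$significant[1])
  expect_gt(pc$popc[1], 0)
  # the exchangeable background cells stay near the nominal 5% rate
  expect_lt(mean(pc$significant[-1]), 0.25)
  # cells below the event-count floor are excluded
  r$mat[3, ] <- 0L; r$mat[3, c(10, 50)] <- 1L
  pc2 <- population_coupling(r, n_shuffles = 20, seed = 9)
  expect_false(pc2$analyzed[3])
  expect_true(is.na(pc2$raw[3]))
})

test_that("matching index matches set arithmetic and excludes silent bins", {
  expect_equal(matching_index(c(1, 1, 1, 0), c(1, 1, 1, 0)), 1)
  expect_equal(matching_index(c(1, 0, 0, 0), c(0, 0, 1, 1)), 0)
  a <- c(1, 1, 1, 0); b <- c(0, 1, 1, 1)   # {1,2,3} vs {2,3,4}
  expect_equal(matching_index(a, b), 2 / 3, tolerance = 1e-12)
  set.seed(18)
  for (i in 1:100) {
    x <- rbinom(12, 1, 0.4); y <- rbinom(12, 1, 0.4)
    if (sum(x) + sum(y) == 0) next
    expect_equal(matching_index(x, y), mi_brute(x, y), tolerance = 1e-9)
  }
  mat <- matrix(0L, 4, 40)
  mat[1:2, 5] <- 1L; mat[2:3, 15] <- 1L    # bins 3 and 4 silent
  mim <- matching_index_matrix(event_raster(mat, 10), bin = 10)
  expect_equal(ncol(mim$mi), 2)
  expect_equal(diag(mim$mi), c(1, 1))
  expect_equal(mim$mi[1, 2], 2 * 1 / (2 + 2))
})

test_that("motif detection finds planted patterns and stays quiet on noise", {
  pat <- matrix(0L, 20, 1); pat[seq(1, 16, by = 2), 1] <- 1L
  r <- simulate_raster(20, 2000, rate = 4,
                       motif_spec = list(patterns = pat, repeats = 25,
                                         bin = 10), seed = 19)
  mr <- detect_motifs(r, bin = 10, n_shuffles = 100, seed = 2)
  expect_gte(mr$n_motifs, 1)
  planted <- match(attr(r, "motif_windows")$bin, mr$bin_index)
  planted <- planted[!is.na(planted)]
  lead_motif <- mr$membership[planted]
  expect_gt(mean(lead_motif == 1, na.rm = TRUE), 0.7)
  expect_gt(mr$global_similarity, 1)
  # pure Poisson rasters: no motifs, global similarity at the null level
  cnt <- vapply(1:4, function(k)
    detect_motifs(simulate_raster(20, 2000, rate = 4, seed = 30 + k),
                  bin = 10, n_shuffles = 60, seed = 3)$n_motifs, 0L)
  expect_true(all(cnt == 0))
  mr0 <- detect_motifs(simulate_raster(20, 2000, rate = 4, seed = 23),
                       bin = 10, n_shuffles = 100, seed = 2)
  expect_equal(mr0$global_similarity, 1, tolerance = 0.15)
})
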