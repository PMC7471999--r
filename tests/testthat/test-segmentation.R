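test_that("energy equals the channel-summed square, smoothed or not", {
  rec <- recording(matrix(0, 50, 8))
  expect_equal(compute_energy(rec)$values, rep(0, 50))
  # one constant channel, no smoothing: energy = c^2 everywhere
  x <- matrix(0, 50, 8); x[, 3] <- 0.4
  expect_equal(compute_energy(recording(x), smooth_s = 0)$values,
               rep(0.16, 50))
  # random signal vs brute-force sum of squares
  set.seed(1)
  x <- matrix(rnorm(400), 50, 8)
  e <- compute_energy(recording(x), smooth_s = 0)$values
  bf <- vapply(1:50, function(i) sum(x[i, ]^2), 1)
  expect_equal(e, bf, tolerance = 1e-12)
  # smoothing preserves the total mean on a flat-ish interior
  e2 <- compute_energy(recording(x), smooth_s = 0.05)$values
  expect_length(e2, 50)
  expect_true(all(e2 >= 0))
})

test_that("double-threshold detection confirms long bursts and rejects short ones", {
  fs <- 200
  base <- rep(0, 1000)
  # rectangular 1.3 s pulse: exactly one activation spanning it
  v <- base; v[201:460] <- 1
  a <- detect_activations(make_energy(v, fs))
  expect_equal(nrow(a), 1)
  expect_equal(a$t_start, 1.0)
  expect_equal(a$t_end, 2.3)
  # 100 ms pulse (20 samples < 150 ms): rejected as a false trigger
  v <- base; v[201:220] <- 1
  expect_equal(nrow(detect_activations(make_energy(v, fs))), 0)
  # a sub-refractory dip inside a burst is bridged
  v <- base; v[201:460] <- 1; v[300:310] <- 0
  a <- detect_activations(make_energy(v, fs))
  expect_equal(nrow(a), 1)
  # all-zero energy: empty result, not an error
  expect_equal(nrow(detect_activations(make_energy(base, fs))), 0)
  expect_error(detect_activations(make_energy(numeric(0), fs)), "empty")
})

test_that("detection recovers the annotated activations of a synthetic trial", {
  rec <- small_dataset(n_subjects = 1, n_trials = 1, n_classes = 26,
                       n_dynamic = 6, seed = 42)[[1]]
  a <- detect_activations(compute_energy(rec))
  ann <- rec$annotations[rec$annotations$phase == "active", ]
  expect_equal(nrow(a), nrow(ann))
  for (i in seq_len(nrow(a))) {
    ovl <- pmin(a$t_end[i], ann$t_end) - pmax(a$t_start[i], ann$t_start)
    expect_gte(max(ovl) / 1.3, 0.8)
  }
})

test_that("window starts follow the overlap-fraction formula", {
  fs <- 200
  # boundary: activation exactly one window long
  for (phi in c(1, 0.5, 0.125))
    expect_equal(window_starts(200, 1, phi, fs), 0L)
  # phi = 1 tiles disjointly
  expect_equal(window_starts(600, 1, 1, fs), c(0L, 200L, 400L))
  # L = 400, W = 1 s, phi = 0.125: k = 25, 9 segments
  s <- window_starts(400, 1, 0.125, fs)
  expect_length(s, 9)
  expect_equal(s, seq(0L, 200L, by = 25L))
  # shorter than a window: none
  expect_length(window_starts(150, 1, 1, fs), 0)
  expect_error(window_starts(100, 1, 0, fs), "phi")
  expect_error(window_starts(100, 1, 1.5, fs), "phi")
  expect_error(window_starts(100, -1, 1, fs), "W must be")
})

test_that("window starts equal exhaustive enumeration on 1000 random cases", {
  set.seed(99)
  for (i in 1:1000) {
    L <- sample(1:1200, 1)
    W <- runif(1, 0.05, 2.5)
    phi <- runif(1, 0.01, 1)
    got <- window_starts(L, W, phi, 200)
    want <- bf_window_starts(L, W, phi, 200)
    expect_identical(got, as.integer(want))
  }
})

test_that("segment counts are monotone in W and phi", {
  set.seed(5)
  for (i in 1:50) {
    L <- sample(100:1000, 1)
    Ws <- sort(runif(2, 0.1, 2))
    phis <- sort(runif(2, 0.05, 1))
    expect_lte(length(window_starts(L, Ws[2], phis[1], 200)),
               length(window_starts(L, Ws[1], phis[1], 200)))
    expect_lte(length(window_starts(L, Ws[1], phis[2], 200)),
               length(window_starts(L, Ws[1], phis[1], 200)))
  }
})

test_that("segments stay inside their activation and carry its label", {
  recs <- small_dataset(n_subjects = 1, n_trials = 2, n_classes = 4,
                        seed = 31)
  segs <- segment_recording(recs[[1]], W = 0.5, phi = 0.5)
  expect_gt(length(segs), 0)
  a <- detect_activations(compute_energy(recs[[1]]))
  for (i in seq_along(segs$label)) {
    k <- segs$activation[i]
    expect_gte(segs$start_s[i] + 1e-9, a$t_start[k])
    expect_lte(segs$start_s[i] + 0.5, a$t_end[k] + 1e-9)
    expect_equal(nrow(segs$windows[[i]]), 100)
  }
  ann <- recs[[1]]$annotations
  for (i in seq_along(segs$label)) {
    k <- segs$activation[i]
    expect_identical(segs$label[i],
                     ann$label[which.max(pmin(a$t_end[k], ann$t_end) -
                                           pmax(a$t_start[k], ann$t_start))])
  }
})

test_that("window lengths beyond the activations discard with a log", {
  recs <- small_dataset(n_subjects = 1, n_trials = 1, n_classes = 4,
                        seed = 37)
  # cues are 1.3 s; a 2.25 s window cannot fit in any activation
  segs <- segment_recording(recs[[1]], W = 2.25, phi = 1)
  expect_length(segs, 0)
  expect_gt(nrow(segs$discarded), 0)
  # with W = 1.25 s each ~1.1-1.3 s detected activation gives at most one segment
  segs2 <- segment_recording(recs[[1]], W = 1, phi = 1)
  expect_equal(unname(table(segs2$activation)), rep(1L, 4), ignore_attr = TRUE)
})

test_that("halving phi roughly doubles the per-activation segment count", {
  set.seed(8)
  L <- 900; W <- 1; fs <- 200
  n1 <- length(window_starts(L, W, 0.25, fs))
  n2 <- length(window_starts(L, W, 0.125, fs))
  expect_lte(abs(n2 - 2 * n1), 2)
  # and segment_dataset keys the grid cells
  recs <- small_dataset(n_subjects = 1, n_trials = 1, n_classes = 3, seed = 3)
  grid <- segment_dataset(recs, run_config(), windows = c(0.5, 1),
                          overlaps = c(1, 0.5))
  expect_setequal(names(grid),
                  c("W0.5_phi1", "W0.5_phi0.5", "W1_phi1", "W1_phi0.5"))
  expect_s3_class(grid[[1]], "semg_segments")
})
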