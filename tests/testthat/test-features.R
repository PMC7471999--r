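test_that("registry exposes 33 features: 24 time-domain, 9 frequency-domain", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 33)
  expect_equal(sum(reg$domain == "time"), 24)
  expect_equal(sum(reg$domain == "frequency"), 9)
  expect_equal(sum(reg$arity), 47)     # 30 scalars + HIST(9) + AR4(4) + CEPS(4)
  expect_false(anyDuplicated(reg$name) > 0)
})

test_that("closed forms hold for constant, sinusoidal, and alternating windows", {
  x <- rep(0.5, 200)
  expect_equal(extract_time(x, "MAV"), 0.5)
  expect_equal(extract_time(x, "RMS"), 0.5)
  expect_equal(extract_time(x, "IEMG"), 100)
  expect_equal(extract_time(x, "WL"), 0)
  expect_equal(extract_time(x, "ZC"), 0)
  expect_equal(extract_time(x, "SSC"), 0)
  expect_equal(extract_time(x, "DASDV"), 0)
  expect_equal(extract_time(x, "SampEn"), 0)   # sigma = 0 convention
  expect_equal(extract_time(x, "VAREMG"), sum(x^2) / 199)
  expect_equal(extract_time(x, "HIST"), c(200, rep(0, 8)))

  t <- seq(0, 1 - 1 / 200, by = 1 / 200)
  s <- sin(2 * pi * 5 * t)            # whole periods on the grid
  expect_equal(extract_time(s, "RMS"), 1 / sqrt(2), tolerance = 1e-9)
  expect_equal(extract_time(s, "MAV"), 2 / pi, tolerance = 1e-2)

  a <- rep(c(0.5, -0.5), 100)
  expect_equal(extract_time(a, "ZC"), 199)
  expect_equal(extract_time(a, "WAMP"), 199)
  expect_equal(extract_time(a, "MYOP"), 1.0)
})

test_that("every time-domain extractor matches its brute-force oracle on 100 seeded windows", {
  set.seed(1234)
  scalars <- c("MAV", "MAV1", "MAV2", "IEMG", "RMS", "VAREMG", "WL", "DASDV",
               "MFL", "LOGDEC", "MSR", "VORDER", "TM3", "TM4", "TM5", "LS",
               "ZC", "WAMP", "MYOP", "SSC")
  for (i in 1:100) {
    n <- sample(60:250, 1)
    x <- rnorm(n, sd = runif(1, 0.01, 0.3))
    bf <- bf_time_features(x)
    for (f in scalars)
      expect_equal(extract_time(x, f), bf[[f]], tolerance = 1e-9, label = f)
    expect_equal(extract_time(x, "HIST"), bf$HIST, label = "HIST")
  }
})

test_that("sample entropy equals the O(n^2) reference and behaves at the edges", {
  set.seed(77)
  for (i in 1:20) {
    x <- rnorm(120, sd = 0.1)
    expect_equal(sample_entropy(x), bf_sample_entropy(x), tolerance = 1e-12)
  }
  # strictly periodic signal: far more predictable than white noise (~2.3)
  xp <- rep(sin(2 * pi * (1:20) / 20), 10)
  expect_lt(sample_entropy(xp), 0.3)
  expect_equal(sample_entropy(xp), bf_sample_entropy(xp), tolerance = 1e-12)
  expect_equal(sample_entropy(rep(1, 50)), 0)
  expect_error(sample_entropy(c(1, 2, 3), m = 2), "at least")
})

test_that("AR coefficients recover a known process and white noise gives near-zero", {
  set.seed(55)
  a_true <- c(0.4, -0.3, 0.2, -0.1)
  x <- as.numeric(arima.sim(list(ar = a_true), n = 20000))
  expect_lt(max(abs(ar_coefficients(x, 4) - a_true)), 0.05)
  w <- rnorm(20000)
  expect_lt(max(abs(ar_coefficients(w, 4))), 0.05)
  expect_equal(ar_coefficients(rep(2, 100), 4), rep(0, 4))
  expect_error(ar_coefficients(1:3, 4), "more than 4")
})

test_that("cepstral recursion satisfies its identities", {
  expect_equal(cepstral_from_ar(c(0, 0, 0, 0)), c(0, 0, 0, 0))
  # order-1 and order-2 closed forms
  expect_equal(cepstral_from_ar(0.5), -0.5)
  a <- c(0.5, 0.2)
  c1 <- -0.5
  c2 <- -a[2] - (1 - 1 / 2) * a[1] * c1
  expect_equal(cepstral_from_ar(a), c(c1, c2))
})

test_that("psd places a spectral line on the nearest grid point and respects Parseval", {
  t <- seq(0, 1 - 1 / 200, by = 1 / 200)
  x <- sin(2 * pi * 50 * t)
  ps <- compute_psd(x, 200, n_fft = 2000)
  expect_equal(ps$freqs[which.max(ps$power)], 50, tolerance = 0.1)
  expect_equal(compute_psd(rep(0, 100), 200)$power, rep(0, 1001))
  # one-sided sum = (n_fft * sum(x^2) + DC + Nyquist) / 2 for real input
  set.seed(2)
  y <- rnorm(150, sd = 0.2)
  ps2 <- compute_psd(y, 200, n_fft = 256)
  expected <- (256 * sum(y^2) + ps2$power[1] + ps2$power[length(ps2$power)]) / 2
  expect_equal(sum(ps2$power), expected, tolerance = 1e-9)
  expect_error(compute_psd(rnorm(300), 200, n_fft = 256), "truncate")
  expect_equal(compute_psd(rnorm(300), 200, n_fft = 256,
                           truncate = TRUE)$n_fft, 256L)
})

test_that("frequency features follow their definitions on constructed spectra", {
  # delta spectrum at 50 Hz
  f <- seq(0, 100, by = 0.5)
  p <- numeric(length(f)); p[f == 50] <- 3
  ps <- make_psd(f, p)
  expect_equal(extract_freq(ps, "MNF"), 50)
  expect_equal(extract_freq(ps, "MDF"), 50)
  expect_equal(extract_freq(ps, "PKF"), 50)
  # flat spectrum
  pf <- make_psd(f, rep(2, length(f)))
  expect_equal(extract_freq(pf, "MNP"), 2)
  expect_equal(extract_freq(pf, "TTP"), 2 * length(f))
  expect_equal(extract_freq(pf, "SM1"), 2 * sum(f))
  expect_equal(extract_freq(pf, "SM2"), 2 * sum(f^2))
  # equal power at 30 and 80 Hz: FR = 1
  p2 <- numeric(length(f)); p2[f == 30] <- 5; p2[f == 80] <- 5
  expect_equal(extract_freq(make_psd(f, p2), "FR"), 1)
  # degenerate zero spectrum errors for the normalized features
  expect_error(extract_freq(make_psd(f, numeric(length(f))), "MNF"),
               "degenerate")
})

test_that("frequency extractors match the direct-DFT oracle", {
  set.seed(31)
  for (i in 1:5) {
    x <- rnorm(60, sd = 0.2)
    ps <- compute_psd(x, 200, n_fft = 128)
    bfp <- bf_psd(x, 200, 128)
    expect_equal(ps$power, bfp$power, tolerance = 1e-6)
    bf <- bf_freq_features(ps$freqs, ps$power)
    for (f in names(bf))
      expect_equal(extract_freq(ps, f), bf[[f]], tolerance = 1e-6, label = f)
  }
})

test_that("scaling laws hold for gains above the thresholds", {
  set.seed(17)
  x <- rnorm(200, sd = 0.2)
  g <- 3.7
  lin <- c("MAV", "RMS", "IEMG", "WL", "DASDV", "LS", "VORDER")
  for (f in lin)
    expect_equal(extract_time(g * x, f), g * extract_time(x, f),
                 tolerance = 1e-9, label = f)
  expect_equal(extract_time(g * x, "MSR"), sqrt(g) * extract_time(x, "MSR"),
               tolerance = 1e-9)
  expect_equal(extract_time(g * x, "VAREMG"), g^2 * extract_time(x, "VAREMG"),
               tolerance = 1e-9)
  expect_equal(extract_time(g * x, "SampEn"), extract_time(x, "SampEn"),
               tolerance = 1e-9)
  # threshold-count features: invariant when amplitudes clear the thresholds
  xa <- rep(c(1, -1), 100) * runif(200, 0.1, 0.5)
  for (f in c("ZC", "SSC", "WAMP", "MYOP"))
    expect_equal(extract_time(g * xa, f), extract_time(xa, f),
                 tolerance = 1e-9, label = f)
  expect_equal(extract_time(g * x, "AR4"), extract_time(x, "AR4"),
               tolerance = 1e-6)
  ps1 <- compute_psd(x, 200); psg <- compute_psd(g * x, 200)
  for (f in c("MNF", "MDF", "PKF", "FR"))
    expect_equal(extract_freq(psg, f), extract_freq(ps1, f),
                 tolerance = 1e-9, label = f)
  for (f in c("TTP", "MNP", "SM1", "SM2", "SM3"))
    expect_equal(extract_freq(psg, f), g^2 * extract_freq(ps1, f),
                 tolerance = 1e-9, label = f)
})

test_that("the feature table has deterministic shape, order, and no missing values", {
  recs <- small_dataset(n_subjects = 1, n_trials = 1, n_classes = 3, seed = 3)
  segs <- segment_recording(recs[[1]], W = 1, phi = 1)
  tab1 <- extract_table(segs, "MAV")
  expect_equal(length(feature_cols(tab1)), 8)
  expect_equal(feature_cols(tab1), paste0("MAV_ch", 1:8))
  full <- extract_table(segs, "all")
  expect_equal(length(feature_cols(full)), 376)   # 47 components x 8 channels
  expect_false(anyNA(full))
  # column order: registry order, channels contiguous per component
  expect_equal(feature_cols(full)[1:8], paste0("AR4_1_ch", 1:8))
  # row order permutation-invariance
  perm <- c(2, 1, 3)
  segs2 <- segs
  segs2$windows <- segs$windows[perm]
  segs2$label <- segs$label[perm]
  segs2$subject <- segs$subject[perm]
  segs2$trial <- segs$trial[perm]
  segs2$activation <- segs$activation[perm]
  segs2$start_s <- segs$start_s[perm]
  full2 <- extract_table(segs2, "all")
  expect_equal(full2[order(full2$activation), feature_cols(full2)],
               full[order(full$activation), feature_cols(full)],
               ignore_attr = TRUE)
  expect_error(extract_table(segs, "NOPE"), "unknown feature")
})
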