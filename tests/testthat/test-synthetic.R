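test_that("templates are pairwise distinct and deterministic under seed", {
  set.seed(3); t1 <- make_templates(26, n_dynamic = 6)
  set.seed(3); t2 <- make_templates(26, n_dynamic = 6)
  expect_identical(t1, t2)
  expect_length(t1, 26)
  expect_setequal(vapply(t1, `[[`, "", "label"), LETTERS)
  expect_equal(sum(vapply(t1, `[[`, TRUE, "dynamic")), 6)
  g <- t(vapply(t1, `[[`, numeric(8), "channel_gains"))
  d <- as.matrix(dist(g)); diag(d) <- Inf
  expect_gte(min(d), 0.3)
  expect_error(make_templates(1), ">= 2")
})

test_that("templates honour a configured minimum separation", {
  set.seed(9)
  tp <- make_templates(2, min_separation = 0.8)
  d <- sqrt(sum((tp[[1]]$channel_gains - tp[[2]]$channel_gains)^2))
  expect_gte(d, 0.8)
})

test_that("a trial follows the cue schedule: duration, count, balance", {
  cfg <- synth_config(n_classes = 26, seed = 5)
  set.seed(5)
  tpl <- make_templates(26, n_dynamic = 6)
  rec <- synthesize_trial(tpl, cfg)
  # 26 gestures alternating with rest at 1.3 s cues: 26 * 2 * 1.3 = 67.6 s
  expect_equal(nrow(rec$samples) / rec$fs, 67.6)
  expect_equal(nrow(rec$annotations), 52)
  act <- rec$annotations[rec$annotations$phase == "active", ]
  expect_setequal(act$label, LETTERS)
  expect_equal(act$t_end - act$t_start, rep(1.3, 26))
  expect_error(synthesize_trial(list(), cfg), "non-empty")
})

test_that("snr scaling matches its definition at 0 and 20 dB", {
  cfg0 <- synth_config(n_classes = 4, snr_db = 0, seed = 11)
  set.seed(11)
  tpl <- make_templates(4)
  rec0 <- synthesize_trial(tpl, cfg0)
  act <- rec0$annotations[rec0$annotations$phase == "active", ]
  in_active <- rep(FALSE, nrow(rec0$samples))
  for (i in seq_len(nrow(act))) {
    idx <- (round(act$t_start[i] * rec0$fs) + 1):round(act$t_end[i] * rec0$fs)
    in_active[idx] <- TRUE
  }
  p_act <- mean(rec0$samples[in_active, ]^2)
  p_rest <- mean(rec0$samples[!in_active, ]^2)
  expect_equal(p_act / p_rest, 1, tolerance = 0.05)

  cfg20 <- synth_config(n_classes = 4, snr_db = 20, seed = 11)
  set.seed(11)
  rec20 <- synthesize_trial(tpl, cfg20)
  # every channel has positive gain, so active RMS dominates rest RMS
  for (ch in 1:8) {
    expect_gt(sqrt(mean(rec20$samples[in_active, ch]^2)),
              sqrt(mean(rec20$samples[!in_active, ch]^2)))
  }
  # and overall power sits close to the 20 dB target
  expect_equal(mean(rec20$samples[in_active, ]^2) /
                 mean(rec20$samples[!in_active, ]^2),
               100, tolerance = 0.15)
})

test_that("active-segment spectra concentrate in the template band", {
  recs <- small_dataset(n_subjects = 1, n_trials = 2, n_classes = 4,
                        n_dynamic = 0, seed = 13)
  band <- c(20, 90)
  frac <- c()
  for (rec in recs) {
    act <- rec$annotations[rec$annotations$phase == "active", ]
    for (i in seq_len(nrow(act))) {
      idx <- (round(act$t_start[i] * rec$fs) + 1):round(act$t_end[i] * rec$fs)
      for (ch in 1:8) {
        ps <- compute_psd(rec$samples[idx, ch], rec$fs, n_fft = 512,
                          truncate = TRUE)
        inb <- ps$freqs >= band[1] & ps$freqs <= band[2]
        frac <- c(frac, sum(ps$power[inb]) / sum(ps$power))
      }
    }
  }
  expect_gte(mean(frac), 0.80)
})

test_that("label balance holds across a dataset and jitter-free subjects share gain maps", {
  recs <- small_dataset(n_subjects = 2, n_trials = 3, n_classes = 5,
                        seed = 17)
  expect_length(recs, 6)
  for (s in c("S01", "S02")) {
    labs <- unlist(lapply(recs[vapply(recs, `[[`, "", "subject_id") == s],
                          function(r)
                            r$annotations$label[r$annotations$phase == "active"]))
    expect_equal(unname(table(labs)), rep(3L, 5), ignore_attr = TRUE)
  }
  # subject_jitter = 0: per-class mean channel RMS patterns agree across subjects
  rms_by <- function(rec) {
    act <- rec$annotations[rec$annotations$phase == "active", ]
    t(vapply(seq_len(nrow(act)), function(i) {
      idx <- (round(act$t_start[i] * rec$fs) + 1):round(act$t_end[i] * rec$fs)
      sqrt(colMeans(rec$samples[idx, ]^2))
    }, numeric(8)))
  }
  r1 <- rms_by(recs[[1]]); r2 <- rms_by(recs[[4]])
  o1 <- order(recs[[1]]$annotations$label[recs[[1]]$annotations$phase == "active"])
  o2 <- order(recs[[4]]$annotations$label[recs[[4]]$annotations$phase == "active"])
  expect_gt(cor(as.vector(r1[o1, ]), as.vector(r2[o2, ])), 0.95)
})

test_that("collapsing all gain maps to one template removes class separability", {
  cfg <- synth_config(n_subjects = 1, n_trials = 20, n_classes = 6,
                      n_dynamic = 0, seed = 53)
  set.seed(53)
  tpl <- make_templates(6)
  for (i in seq_along(tpl)) {
    tpl[[i]]$channel_gains <- tpl[[1]]$channel_gains
    tpl[[i]]$gains_end <- tpl[[1]]$channel_gains
  }
  recs <- lapply(1:20, function(tr)
    synthesize_trial(tpl, cfg, trial_id = sprintf("T%02d", tr)))
  # disjoint windows: within-activation sample sharing cannot leak labels
  segs <- combine_segments(lapply(recs, segment_recording, W = 0.5,
                                  phi = 1, cfg = run_config()))
  tab <- extract_table(segs, resolve_set("G9")$members)
  ev <- evaluate_cv(tab, "RF", folds = 5, seed = 53)
  # identical class signatures: accuracy falls to the 1/6 chance floor
  expect_lt(abs(ev$accuracy - 1 / 6), 0.1)
})

test_that("dataset generation is reproducible and writes byte-identical annotations", {
  cfg <- synth_config(n_subjects = 1, n_trials = 2, n_classes = 3, seed = 23)
  td1 <- withr::local_tempdir(); td2 <- withr::local_tempdir()
  idx1 <- generate_dataset(cfg, td1)
  idx2 <- generate_dataset(cfg, td2)
  expect_equal(nrow(idx1), 2)
  for (i in seq_len(nrow(idx1)))
    expect_identical(readLines(idx1$annotations[i]),
                     readLines(idx2$annotations[i]))
  back <- read_dataset(td1)
  expect_length(back, 2)
  expect_s3_class(back[[1]], "semg_recording")
})
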