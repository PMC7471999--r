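#' Synthetic acquisition configuration
#'
#' Parameters of the synthetic armband protocol: `n_subjects` subjects
#' each perform `n_classes` alphabet gestures per trial, cued at a fixed
#' cadence (`cue_s` seconds of gesture, `cue_s` seconds of rest, i.e.
#' 45 bpm at the default 1.3 s), and repeat the sequence `n_trials`
#' times. Signals are 8-channel at `fs` samples/s on a normalized
#' `[-1, 1]` scale.
#'
#' The activation model is amplitude-modulated band-limited Gaussian
#' noise: each gesture class has a per-channel gain vector (its "muscle
#' map"), a rise/plateau/fall envelope, and a spectral band; a subset of
#' classes (`n_dynamic`, default 6) is dynamic, with a gain trajectory
#' that drifts across channels during the gesture. The rest floor is
#' white noise of amplitude `rest_amplitude` (1% of full scale by
#' default, so a 10% energy threshold cleanly separates activations).
#' `snr_db` sets the ratio of mean signal power inside active intervals
#' to the rest-floor power.
#'
#' @param n_subjects,n_trials,n_classes protocol counts (defaults 12, 20, 26).
#' @param cue_s cue duration in seconds (default 1.3).
#' @param fs sampling rate, samples/s.
#' @param snr_db active-to-rest power ratio in dB.
#' @param subject_jitter relative s.d. of the per-subject, per-channel
#'   multiplicative gain perturbation (0 = identical subjects).
#' @param rest_amplitude rest-floor noise s.d. on the normalized scale.
#' @param n_dynamic number of dynamic-gesture classes (taken from the end
#'   of the class list).
#' @param band two-element spectral support (Hz) of the activation noise.
#' @param min_separation minimum pairwise Euclidean distance between
#'   class gain vectors.
#' @param order `"random"` or `"alphabetical"` gesture order per trial.
#' @param seed integer seed.
#' @return A list of class `semg_synth_config`.
#' @export
synth_config <- function(n_subjects = 12, n_trials = 20, n_classes = 26,
                         cue_s = 1.3, fs = 200, snr_db = 20,
                         subject_jitter = 0, rest_amplitude = 0.01,
                         n_dynamic = min(6, n_classes), band = c(20, 90),
                         min_separation = 0.3,
                         order = c("random", "alphabetical"), seed = 1L) {
  order <- match.arg(order)
  stopifnot(n_subjects >= 1, n_trials >= 1, n_classes >= 1, cue_s > 0,
            fs > 0, is.finite(snr_db), subject_jitter >= 0,
            rest_amplitude > 0, n_dynamic >= 0, n_dynamic <= n_classes)
  if (!(band[1] > 0 && band[1] < band[2] && band[2] <= fs / 2))
    stop("band must satisfy 0 < low < high <= fs/2")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_trials = as.integer(n_trials),
                 n_classes = as.integer(n_classes), cue_s = cue_s, fs = fs,
                 snr_db = snr_db, subject_jitter = subject_jitter,
                 rest_amplitude = rest_amplitude,
                 n_dynamic = as.integer(n_dynamic), band = band,
                 min_separation = min_separation, order = order,
                 seed = as.integer(seed)),
            class = "semg_synth_config")
}

class_labels <- function(n) {
  if (n <= 26) LETTERS[seq_len(n)] else sprintf("C%02d", seq_len(n))
}

#' Gesture templates
#'
#' Draw `n_classes` gesture templates with pairwise-distinct 8-channel
#' gain vectors (uniform on \[0.2, 1\], resampled until every pairwise
#' Euclidean distance is at least `min_separation`). The last `n_dynamic`
#' classes are dynamic: their gain vector drifts toward a
#' channel-rotated copy over the course of the gesture. Deterministic
#' given the RNG state.
#'
#' @param n_classes number of gesture classes (>= 2).
#' @param n_dynamic number of dynamic classes.
#' @param band spectral support (Hz) shared by all templates.
#' @param min_separation minimum pairwise gain distance.
#' @param n_channels number of channels.
#' @return A list of `GestureTemplate` lists with fields `label`,
#'   `channel_gains`, `gains_end`, `band`, `envelope`, `dynamic`.
#' @export
make_templates <- function(n_classes, n_dynamic = 0, band = c(20, 90),
                           min_separation = 0.3, n_channels = 8) {
  if (n_classes < 2) stop("n_classes must be >= 2")
  gains <- matrix(runif(n_classes * n_channels, 0.2, 1), n_classes)
  for (iter in seq_len(1000)) {
    d <- as.matrix(dist(gains))
    diag(d) <- Inf
    worst <- which(apply(d, 1, min) < min_separation)
    if (!length(worst)) break
    gains[worst[1], ] <- runif(n_channels, 0.2, 1)
    if (iter == 1000)
      stop("could not place ", n_classes, " templates with min_separation ",
           min_separation)
  }
  labs <- class_labels(n_classes)
  dynamic <- seq_len(n_classes) > n_classes - n_dynamic
  lapply(seq_len(n_classes), function(i) {
    g <- gains[i, ]
    list(label = labs[i], channel_gains = g,
         gains_end = if (dynamic[i]) g[c(seq_len(n_channels)[-1], 1)] else g,
         band = band, envelope = c(rise = 0.10, plateau = 0.80, fall = 0.10),
         dynamic = dynamic[i])
  })
}

activation_envelope <- function(n, env) {
  r <- max(1, round(env[["rise"]] * n))
  f <- max(1, round(env[["fall"]] * n))
  e <- rep(1, n)
  e[seq_len(r)] <- seq(0, 1, length.out = r + 1)[-1]
  e[n - f + seq_len(f)] <- seq(1, 0, length.out = f + 1)[-1]
  e
}

band_noise <- function(n, n_channels, band, fs) {
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  x <- matrix(rnorm(n * n_channels), n, n_channels)
  for (j in seq_len(n_channels))
    x[, j] <- signal::filtfilt(bf, x[, j])
  # unit per-channel power so template gains set relative channel strength
  sweep(x, 2, sqrt(colMeans(x^2)), "/")
}

#' Synthesize one cued acquisition trial
#'
#' Emits a [recording()] with alternating active/rest cue intervals of
#' `cue_s` seconds, one active interval per gesture class, in random or
#' alphabetical order. Active intervals carry band-limited Gaussian noise
#' shaped by the template envelope and per-channel gains; the whole trial
#' sits on a white rest-noise floor. The activation component is scaled
#' so that the total mean power inside active intervals is
#' `10^(snr_db/10)` times the rest-floor power (at 0 dB the activation
#' component vanishes and active intervals equal the floor). Annotations
#' exactly describe the cue schedule. Uses the current RNG state.
#'
#' @param templates list from [make_templates()].
#' @param cfg a [synth_config()].
#' @param subject_gains optional per-channel multiplicative factors for
#'   this subject (length `n_channels`), applied to every template.
#' @param subject_id,trial_id identifiers stored in the recording.
#' @return A [recording()].
#' @export
synthesize_trial <- function(templates, cfg, subject_gains = NULL,
                             subject_id = "S01", trial_id = "T01") {
  if (!length(templates)) stop("templates must be non-empty")
  n_classes <- length(templates)
  n_channels <- length(templates[[1]]$channel_gains)
  fs <- cfg$fs
  cue_n <- round(cfg$cue_s * fs)
  n <- n_classes * 2L * cue_n
  ord <- if (cfg$order == "random") sample.int(n_classes) else seq_len(n_classes)

  gain <- matrix(0, n, n_channels)
  ann <- vector("list", 2L * n_classes)
  for (k in seq_along(ord)) {
    tpl <- templates[[ord[k]]]
    i0 <- (k - 1L) * 2L * cue_n            # active starts here (0-based)
    idx <- i0 + seq_len(cue_n)
    env <- activation_envelope(cue_n, tpl$envelope)
    g0 <- tpl$channel_gains
    g1 <- tpl$gains_end
    if (!is.null(subject_gains)) {
      g0 <- g0 * subject_gains
      g1 <- g1 * subject_gains
    }
    u <- if (tpl$dynamic) seq(0, 1, length.out = cue_n) else rep(0, cue_n)
    gain[idx, ] <- env * ((1 - u) %o% g0 + u %o% g1)
    t_act <- i0 / fs
    ann[[2L * k - 1L]] <- list(tpl$label, t_act, t_act + cfg$cue_s, "active")
    ann[[2L * k]] <- list(REST_LABEL, t_act + cfg$cue_s,
                          t_act + 2 * cfg$cue_s, REST_LABEL)
  }
  ann <- do.call(rbind.data.frame, ann)
  names(ann) <- c("label", "t_start", "t_end", "phase")

  noise <- band_noise(n, n_channels, templates[[1]]$band, fs)
  act <- gain * noise
  rest_power <- cfg$rest_amplitude^2
  target <- rest_power * 10^(cfg$snr_db / 10)
  active_rows <- rowSums(gain^2) > 0
  p_act <- mean(act[active_rows, ]^2)
  alpha <- if (p_act > 0) sqrt(max(target - rest_power, 0) / p_act) else 0
  samples <- alpha * act +
    matrix(rnorm(n * n_channels, sd = cfg$rest_amplitude), n, n_channels)
  recording(samples, fs = fs, subject_id = subject_id, trial_id = trial_id,
            annotations = ann, n_channels = n_channels)
}

#' Generate a full synthetic dataset
#'
#' Draws one template set from the seed, one gain-perturbation vector per
#' subject (applied consistently across that subject's trials), and
#' synthesizes `n_subjects * n_trials` recordings. Fully reproducible
#' from `cfg$seed`. With `out_dir` set, each recording is written via
#' [write_recording()] under `out_dir/<subject>/` and an index of file
#' paths is returned; otherwise the recordings are returned as a list.
#'
#' @param cfg a [synth_config()].
#' @param out_dir optional output directory.
#' @return A list of [recording()]s, or (with `out_dir`) a `data.frame`
#'   index with columns `subject_id`, `trial_id`, `signal`, `annotations`.
#' @export
generate_dataset <- function(cfg, out_dir = NULL) {
  set.seed(cfg$seed)
  templates <- make_templates(cfg$n_classes, n_dynamic = cfg$n_dynamic,
                              band = cfg$band,
                              min_separation = cfg$min_separation)
  subj_ids <- sprintf("S%02d", seq_len(cfg$n_subjects))
  jit <- lapply(seq_len(cfg$n_subjects), function(i)
    pmax(0.05, 1 + cfg$subject_jitter * rnorm(length(templates[[1]]$channel_gains))))
  recs <- vector("list", cfg$n_subjects * cfg$n_trials)
  k <- 0L
  for (s in seq_len(cfg$n_subjects)) {
    for (tr in seq_len(cfg$n_trials)) {
      k <- k + 1L
      recs[[k]] <- synthesize_trial(templates, cfg, subject_gains = jit[[s]],
                                    subject_id = subj_ids[s],
                                    trial_id = sprintf("T%02d", tr))
    }
  }
  if (is.null(out_dir)) return(recs)
  idx <- lapply(recs, function(r) {
    dir.create(file.path(out_dir, r$subject_id), recursive = TRUE,
               showWarnings = FALSE)
    stem <- file.path(out_dir, r$subject_id, paste0(r$trial_id, "_signal.csv"))
    annp <- file.path(out_dir, r$subject_id, paste0(r$trial_id, "_annotations.csv"))
    write_recording(r, stem, annp)
    data.frame(subject_id = r$subject_id, trial_id = r$trial_id,
               signal = stem, annotations = annp, stringsAsFactors = FALSE)
  })
  do.call(rbind, idx)
}

#' Read back a dataset written by [generate_dataset()]
#'
#' @param dir dataset root directory (one subdirectory per subject).
#' @return A list of [recording()]s.
#' @export
read_dataset <- function(dir) {
  sigs <- sort(list.files(dir, pattern = "_signal\\.csv$", recursive = TRUE,
                          full.names = TRUE))
  if (!length(sigs)) stop("no *_signal.csv files under '", dir, "'")
  lapply(sigs, function(p)
    read_recording(p, sub("_signal\\.csv$", "_annotations.csv", p)))
}
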