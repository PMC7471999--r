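#' Aggregate signal energy
#'
#' Per-sample energy summed over the channels (squared amplitude), then
#' smoothed with a centered, edge-truncated moving average of
#' `smooth_s` seconds. The smoothed series drives the onset detector;
#' smoothing stabilizes the threshold crossing on stochastic sEMG.
#'
#' @param rec a [recording()].
#' @param smooth_s moving-average length in seconds (0 disables smoothing).
#' @return An object of class `semg_energy` with fields `values` and `fs`.
#' @export
compute_energy <- function(rec, smooth_s = 0.050) {
  stopifnot(inherits(rec, "semg_recording"), smooth_s >= 0)
  if (nrow(rec$samples) == 0) stop("empty recording")
  e <- rowSums(rec$samples^2)
  w <- round(smooth_s * rec$fs)
  if (w > 1) {
    n <- length(e)
    left <- (w - 1L) %/% 2L
    right <- w - 1L - left
    cs <- c(0, cumsum(e))
    i <- seq_len(n)
    lo <- pmax(1L, i - left)
    hi <- pmin(n, i + right)
    e <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  structure(list(values = e, fs = rec$fs), class = "semg_energy")
}

#' Double-threshold onset detection
#'
#' Detect muscle activations on an energy series using one amplitude
#' threshold and one duration threshold: the amplitude threshold is
#' `threshold_fraction` of the maximum energy of the trial (10% by
#' default); a candidate onset (upward crossing) is confirmed only if the
#' energy stays at or above the threshold for at least `refractory_s`
#' (150 ms by default), and an activation ends only when the energy stays
#' below the threshold for at least `refractory_s` (shorter dips are
#' bridged). Bursts shorter than the duration threshold are rejected as
#' false triggers.
#'
#' @param energy a `semg_energy` from [compute_energy()].
#' @param threshold_fraction amplitude threshold as a fraction of the
#'   maximum energy, in (0, 1).
#' @param refractory_s duration threshold in seconds.
#' @return A `data.frame` with columns `t_start`, `t_end` (seconds,
#'   half-open intervals); zero rows if the energy is identically zero.
#' @export
detect_activations <- function(energy, threshold_fraction = 0.10,
                               refractory_s = 0.150) {
  stopifnot(inherits(energy, "semg_energy"),
            threshold_fraction > 0, threshold_fraction < 1)
  v <- energy$values
  if (!length(v)) stop("empty energy series")
  empty <- data.frame(t_start = numeric(), t_end = numeric())
  if (max(v) <= 0) return(empty)
  thr <- threshold_fraction * max(v)
  refr_n <- round(refractory_s * energy$fs)
  r <- rle(v >= thr)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out_s <- integer(0); out_e <- integer(0)
  open_start <- NA_integer_; open_end <- NA_integer_
  for (i in seq_along(r$lengths)) {
    if (r$values[i]) {
      if (is.na(open_start)) {
        if (r$lengths[i] >= refr_n) {       # confirmed onset
          open_start <- starts[i]
          open_end <- ends[i]
        }                                    # else: false trigger, ignore
      } else {
        open_end <- ends[i]                  # extend current activation
      }
    } else if (!is.na(open_start) && r$lengths[i] >= refr_n) {
      out_s <- c(out_s, open_start); out_e <- c(out_e, open_end)
      open_start <- NA_integer_
    }                                        # short dip: bridged
  }
  if (!is.na(open_start)) {
    out_s <- c(out_s, open_start); out_e <- c(out_e, open_end)
  }
  data.frame(t_start = (out_s - 1L) / energy$fs, t_end = out_e / energy$fs)
}

#' Sliding-window starts under an overlap fraction
#'
#' For an activation of `L` samples, window length `W` seconds and
#' overlap fraction `phi = k/W` (step-to-length ratio), windows of
#' `round(W * fs)` samples start at 0, `k_samp`, `2 k_samp`, ... with
#' `k_samp = round(phi * W * fs)` (at least 1 sample), while the window
#' still fits inside the activation. `phi = 1` tiles the activation with
#' disjoint ("disruptive") windows; smaller `phi` yields denser
#' overlapping windows.
#'
#' @param L activation length in samples.
#' @param W window length in seconds.
#' @param phi overlap fraction in (0, 1].
#' @param fs sampling rate.
#' @return Integer vector of 0-based start samples (empty if `L` is
#'   shorter than the window).
#' @export
window_starts <- function(L, W, phi, fs) {
  if (W <= 0) stop("W must be positive")
  if (phi <= 0 || phi > 1) stop("phi must lie in (0, 1]")
  if (L < 1) stop("activation length must be >= 1 sample")
  w_samp <- round(W * fs)
  k_samp <- max(1L, round(phi * W * fs))
  if (L < w_samp) return(integer(0))
  seq.int(0L, by = k_samp, length.out = (L - w_samp) %/% k_samp + 1L)
}

#' Cut an activation into fixed-length windows
#'
#' @param samples activation samples, an `L x n_channels` matrix.
#' @inheritParams window_starts
#' @return A list of `round(W * fs) x n_channels` matrices with an
#'   attribute `starts` (0-based start samples).
#' @export
slide_windows <- function(samples, W, phi, fs) {
  samples <- as.matrix(samples)
  starts <- window_starts(nrow(samples), W, phi, fs)
  w_samp <- round(W * fs)
  out <- lapply(starts, function(s) samples[s + seq_len(w_samp), , drop = FALSE])
  attr(out, "starts") <- starts
  out
}

# label for an activation: annotation with the largest temporal overlap,
# ties broken by the earliest annotation; NA when nothing overlaps
activation_label <- function(t_start, t_end, annotations) {
  if (!nrow(annotations)) return(NA_character_)
  ovl <- pmin(t_end, annotations$t_end) - pmax(t_start, annotations$t_start)
  if (max(ovl) <= 0) return(NA_character_)
  # earliest annotation wins ties (to within fp jitter of the cue times)
  annotations$label[which(ovl >= max(ovl) - 1e-9)[1]]
}

new_segments <- function(windows, label, subject, trial, activation, start_s,
                         W, phi, fs, discarded) {
  structure(list(windows = windows, label = label, subject = subject,
                 trial = trial, activation = activation, start_s = start_s,
                 window_s = W, overlap = phi, fs = fs, discarded = discarded),
            class = "semg_segments")
}

#' @export
print.semg_segments <- function(x, ...) {
  cat(sprintf("<semg_segments> %d segments (W = %g s, phi = %g), %d discarded activations\n",
              length(x$windows), x$window_s, x$overlap, nrow(x$discarded)))
  invisible(x)
}

#' @export
length.semg_segments <- function(x) length(x$windows)

#' Segment one recording
#'
#' Runs [compute_energy()] and [detect_activations()], labels each
#' activation by majority temporal overlap with the recording's
#' annotations, and windows it with [slide_windows()]. Windows are
#' anchored at the detected onset and never cross activation boundaries.
#' Activations shorter than the window are discarded and logged in the
#' `discarded` field.
#'
#' @param rec a [recording()].
#' @param W window length, seconds.
#' @param phi overlap fraction in (0, 1].
#' @param cfg a [run_config()] supplying the onset parameters.
#' @return A `semg_segments` object.
#' @export
segment_recording <- function(rec, W, phi, cfg = run_config()) {
  energy <- compute_energy(rec, smooth_s = cfg$smooth_s)
  acts <- detect_activations(energy, cfg$energy_threshold_fraction,
                             cfg$refractory_s)
  windows <- list(); label <- character(); activation <- integer()
  start_s <- numeric(); disc <- list()
  for (i in seq_len(nrow(acts))) {
    i0 <- round(acts$t_start[i] * rec$fs)
    i1 <- round(acts$t_end[i] * rec$fs)
    seg <- slide_windows(rec$samples[(i0 + 1L):i1, , drop = FALSE], W, phi, rec$fs)
    if (!length(seg)) {
      disc[[length(disc) + 1L]] <-
        data.frame(subject = rec$subject_id, trial = rec$trial_id,
                   activation = i, length_s = acts$t_end[i] - acts$t_start[i])
      next
    }
    lab <- activation_label(acts$t_start[i], acts$t_end[i], rec$annotations)
    windows <- c(windows, seg)
    label <- c(label, rep(lab, length(seg)))
    activation <- c(activation, rep(i, length(seg)))
    start_s <- c(start_s, acts$t_start[i] + attr(seg, "starts") / rec$fs)
  }
  n <- length(windows)
  disc <- if (length(disc)) do.call(rbind, disc) else
    data.frame(subject = character(), trial = character(),
               activation = integer(), length_s = numeric())
  new_segments(windows, label, rep(rec$subject_id, n), rep(rec$trial_id, n),
               activation, start_s, W, phi, rec$fs, disc)
}

#' Concatenate segment collections sharing one (W, phi) cell
#'
#' @param seg_list list of `semg_segments` objects.
#' @return A single `semg_segments`.
#' @export
combine_segments <- function(seg_list) {
  seg_list <- seg_list[vapply(seg_list, function(s) !is.null(s), TRUE)]
  one <- seg_list[[1]]
  new_segments(do.call(c, lapply(seg_list, `[[`, "windows")),
               do.call(c, lapply(seg_list, `[[`, "label")),
               do.call(c, lapply(seg_list, `[[`, "subject")),
               do.call(c, lapply(seg_list, `[[`, "trial")),
               do.call(c, lapply(seg_list, `[[`, "activation")),
               do.call(c, lapply(seg_list, `[[`, "start_s")),
               one$window_s, one$overlap, one$fs,
               do.call(rbind, lapply(seg_list, `[[`, "discarded")))
}

#' Segment a dataset over a (W, phi) grid
#'
#' Applies [segment_recording()] to every recording for every
#' combination of the requested window lengths and overlap fractions.
#'
#' @param recordings list of [recording()]s.
#' @param cfg a [run_config()].
#' @param windows,overlaps grid axes (default: from `cfg`).
#' @return A named list of `semg_segments`, keys `"W<W>_phi<phi>"`.
#' @export
segment_dataset <- function(recordings, cfg = run_config(),
                            windows = cfg$window_lengths,
                            overlaps = cfg$overlap_fractions) {
  out <- list()
  for (W in windows) for (phi in overlaps) {
    key <- sprintf("W%g_phi%g", W, phi)
    out[[key]] <- combine_segments(
      lapply(recordings, segment_recording, W = W, phi = phi, cfg = cfg))
  }
  out
}
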