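#' semgbench: benchmarking sEMG gesture-recognition pipelines
#'
#' Tools to study how segmentation, feature extraction, and classifier
#' choice influence surface-electromyography (sEMG) gesture recognition
#' with an 8-channel armband sampled at 200 samples/s. The package covers
#' the full chain: synthetic cued-protocol recordings
#' ([synthesize_trial()], [generate_dataset()]), double-threshold energy
#' onset detection and overlap-parameterized windowing
#' ([detect_activations()], [slide_windows()]), a 33-feature bank
#' ([extract_table()]), feature-set construction and reduction
#' ([rank_individual_features()], [greedy_reduction()]), cross-validated
#' multi-classifier evaluation ([evaluate_cv()], [sweep_grid()]), and the
#' Friedman/Tukey/Nemenyi/Wilcoxon comparison layer
#' ([friedman_posthoc()], [cd_diagram_data()]).
#'
#' @importFrom stats aov TukeyHSD ar.burg fft median pchisq predict qtukey
#'   rnorm runif sd var wilcox.test aggregate quantile
#' @importFrom utils read.csv write.csv head tail str
#' @keywords internal
"_PACKAGE"

REST_LABEL <- "rest"

#' Cue interval annotations
#'
#' Build and validate the annotation table attached to a [recording()]:
#' one row per cue interval with columns `label`, `t_start`, `t_end`
#' (seconds) and `phase` (`"active"` or `"rest"`). Intervals are half-open
#' `[t_start, t_end)`, must be time-ordered and non-overlapping; active
#' intervals carry a gesture label, rest intervals the reserved label
#' `"rest"`.
#'
#' @param label character vector of gesture labels.
#' @param t_start,t_end numeric vectors, seconds.
#' @param phase character vector, `"active"` or `"rest"`.
#' @return A `data.frame` with the four annotation columns, time-sorted.
#' @export
cue_intervals <- function(label = character(), t_start = numeric(),
                          t_end = numeric(), phase = character()) {
  ann <- data.frame(label = as.character(label),
                    t_start = as.numeric(t_start),
                    t_end = as.numeric(t_end),
                    phase = as.character(phase),
                    stringsAsFactors = FALSE)
  validate_annotations(ann)
}

validate_annotations <- function(ann) {
  stopifnot(is.data.frame(ann))
  need <- c("label", "t_start", "t_end", "phase")
  missing_cols <- setdiff(need, names(ann))
  if (length(missing_cols))
    stop("annotation table lacks column(s): ", paste(missing_cols, collapse = ", "))
  ann <- ann[need]
  if (nrow(ann) == 0) return(ann)
  bad <- which(!(ann$phase %in% c("active", REST_LABEL)))
  if (length(bad))
    stop("annotation row ", bad[1], ": phase must be 'active' or 'rest', got '",
         ann$phase[bad[1]], "'")
  bad <- which(!(ann$t_end > ann$t_start))
  if (length(bad))
    stop("annotation row ", bad[1], " ('", ann$label[bad[1]],
         "'): t_end must exceed t_start")
  bad <- which(ann$phase == REST_LABEL & ann$label != REST_LABEL)
  if (length(bad))
    stop("annotation row ", bad[1], ": rest intervals must carry label '",
         REST_LABEL, "'")
  bad <- which(ann$phase == "active" & (is.na(ann$label) | ann$label == "" |
                                          ann$label == REST_LABEL))
  if (length(bad))
    stop("annotation row ", bad[1], ": active intervals need a gesture label")
  ann <- ann[order(ann$t_start), , drop = FALSE]
  rownames(ann) <- NULL
  if (nrow(ann) > 1) {
    ovl <- which(ann$t_start[-1] < ann$t_end[-nrow(ann)] - 1e-9)
    if (length(ovl))
      stop("annotations overlap: interval ", ovl[1], " ('", ann$label[ovl[1]],
           "') extends past the start of interval ", ovl[1] + 1)
  }
  ann
}

#' Multi-channel sEMG recording
#'
#' Container for one acquisition trial: a time-by-channel amplitude
#' matrix on a normalized `[-1, 1]` full scale, the sampling rate, the
#' subject/trial identity, and the cue annotations. The armband layout is
#' 8 channels at 200 samples/s by default; other channel counts are
#' accepted but flagged against `n_channels`.
#'
#' @param samples numeric matrix, rows are time steps, columns channels.
#' @param fs sampling rate in samples/s (default 200).
#' @param subject_id,trial_id identifiers (coerced to character).
#' @param annotations annotation table as built by [cue_intervals()].
#' @param n_channels expected channel count (default 8).
#' @return An object of class `semg_recording`.
#' @export
recording <- function(samples, fs = 200, subject_id = "s1", trial_id = "t1",
                      annotations = cue_intervals(), n_channels = 8) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("fs must be a single positive number")
  if (ncol(samples) != n_channels)
    stop("recording has ", ncol(samples), " channels; expected ", n_channels)
  annotations <- validate_annotations(annotations)
  dur <- nrow(samples) / fs
  if (nrow(annotations)) {
    bad <- which(annotations$t_start < -1e-9 | annotations$t_end > dur + 1e-9)
    if (length(bad))
      stop("annotation '", annotations$label[bad[1]], "' [",
           annotations$t_start[bad[1]], ", ", annotations$t_end[bad[1]],
           ") lies outside the signal duration of ", signif(dur, 6), " s")
  }
  structure(list(samples = samples, fs = fs,
                 subject_id = as.character(subject_id),
                 trial_id = as.character(trial_id),
                 annotations = annotations),
            class = "semg_recording")
}

#' @export
print.semg_recording <- function(x, ...) {
  cat(sprintf("<semg_recording> subject %s trial %s: %d samples x %d ch @ %g Hz (%.2f s), %d annotations\n",
              x$subject_id, x$trial_id, nrow(x$samples), ncol(x$samples),
              x$fs, nrow(x$samples) / x$fs, nrow(x$annotations)))
  invisible(x)
}

recording_duration <- function(rec) nrow(rec$samples) / rec$fs

#' Read a recording from delimited text
#'
#' The signal file is comma-delimited with a header `t,ch1,...,chN`; the
#' annotation file has columns `label,t_start,t_end,phase`. A key-value
#' metadata sidecar (default: signal path with extension replaced by
#' `_meta.txt`) supplies `subject_id`, `trial_id`, and `fs`; when absent
#' the defaults of [recording()] apply.
#'
#' @param signal_path,annotation_path paths to the two delimited files.
#' @param meta_path optional path to the metadata sidecar.
#' @return A [recording()].
#' @export
read_recording <- function(signal_path, annotation_path,
                           meta_path = default_meta_path(signal_path)) {
  sig <- read.csv(signal_path, check.names = FALSE)
  if (names(sig)[1] != "t")
    stop("malformed signal header in '", signal_path,
         "': first column must be 't', got '", names(sig)[1], "'")
  ch_cols <- names(sig)[-1]
  if (!all(grepl("^ch[0-9]+$", ch_cols)))
    stop("malformed signal header in '", signal_path,
         "': channel columns must be ch1..chN")
  for (j in seq_along(sig)) {
    if (!is.numeric(sig[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(sig[[j]]))))[1]
      stop("non-numeric cell in '", signal_path, "', column '", names(sig)[j],
           "', data row ", if (is.na(bad)) "?" else bad)
    }
  }
  ann <- read.csv(annotation_path, stringsAsFactors = FALSE)
  meta <- list(subject_id = "s1", trial_id = "t1", fs = 200)
  if (!is.null(meta_path) && file.exists(meta_path)) {
    kv <- read_keyvalue(meta_path)
    meta[names(kv)] <- kv
  }
  recording(as.matrix(sig[ch_cols]), fs = as.numeric(meta$fs),
            subject_id = meta$subject_id, trial_id = meta$trial_id,
            annotations = ann, n_channels = length(ch_cols))
}

default_meta_path <- function(signal_path)
  paste0(sub("\\.[^.]+$", "", signal_path), "_meta.txt")

read_keyvalue <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, ":", fixed = TRUE)
  vals <- lapply(parts, function(p) trimws(paste(p[-1], collapse = ":")))
  names(vals) <- vapply(parts, function(p) trimws(p[1]), "")
  vals
}

#' Write a recording to delimited text
#'
#' Inverse of [read_recording()]: emits the signal table (>= 6 significant
#' digits), the annotation table, and the metadata sidecar carrying
#' `subject_id`, `trial_id`, and `fs`.
#'
#' @param rec a [recording()].
#' @inheritParams read_recording
#' @return Invisibly, the signal path.
#' @export
write_recording <- function(rec, signal_path, annotation_path,
                            meta_path = default_meta_path(signal_path)) {
  stopifnot(inherits(rec, "semg_recording"))
  n <- nrow(rec$samples)
  sig <- data.frame(t = signif((seq_len(n) - 1) / rec$fs, 9),
                    signif(rec$samples, 9), check.names = FALSE)
  names(sig) <- c("t", paste0("ch", seq_len(ncol(rec$samples))))
  write.csv(sig, signal_path, row.names = FALSE, quote = FALSE)
  write.csv(rec$annotations, annotation_path, row.names = FALSE, quote = FALSE)
  writeLines(c(paste0("subject_id: ", rec$subject_id),
               paste0("trial_id: ", rec$trial_id),
               paste0("fs: ", format(rec$fs))), meta_path)
  invisible(signal_path)
}

#' Run configuration
#'
#' Assemble the configuration driving segmentation, feature extraction,
#' and evaluation. Defaults mirror the acquisition/processing protocol
#' this package emulates: windows 0.25–2.25 s in 0.25 s steps, overlap
#' fractions 1, 0.5, 0.25, 0.125, onset threshold at 10% of the per-trial
#' maximum energy held for 150 ms, a 2000-point frequency transform, and
#' 10-fold cross-validation.
#'
#' @param window_lengths window lengths W in seconds.
#' @param overlap_fractions overlap fractions phi in (0, 1]; phi = 1 is a
#'   disjoint ("disruptive") window, phi = k/W the step-to-length ratio.
#' @param energy_threshold_fraction onset threshold as a fraction of the
#'   maximum smoothed energy of the trial.
#' @param refractory_s minimum duration (s) the energy must stay on one
#'   side of the threshold to confirm an onset/offset.
#' @param smooth_s energy moving-average length in seconds.
#' @param n_fft transform length for the power spectrum.
#' @param feature_sets names of feature sets to evaluate (see
#'   [resolve_set()]).
#' @param classifiers classifier names (see [classifier_spec()]).
#' @param cv_folds number of cross-validation folds.
#' @param scheme `"pooled"`, `"per_subject"`, or `"trial_grouped"`.
#' @param seed integer root seed.
#' @return A list of class `semg_config`.
#' @export
run_config <- function(window_lengths = seq(0.25, 2.25, by = 0.25),
                       overlap_fractions = c(1, 0.5, 0.25, 0.125),
                       energy_threshold_fraction = 0.10,
                       refractory_s = 0.150,
                       smooth_s = 0.050,
                       n_fft = 2000,
                       feature_sets = paste0("G", 1:9),
                       classifiers = c("KNN", "LDA", "NB", "MLP", "QDA",
                                       "RF", "ELM", "SVMLin", "SVMRBF"),
                       cv_folds = 10,
                       scheme = c("pooled", "per_subject", "trial_grouped"),
                       seed = 1L) {
  scheme <- match.arg(scheme)
  if (any(window_lengths <= 0)) stop("window_lengths must be positive")
  if (any(overlap_fractions <= 0 | overlap_fractions > 1))
    stop("overlap_fractions must lie in (0, 1]")
  if (energy_threshold_fraction <= 0 || energy_threshold_fraction >= 1)
    stop("energy_threshold_fraction must lie in (0, 1)")
  if (refractory_s < 0) stop("refractory_s must be >= 0")
  if (n_fft < 2) stop("n_fft must be >= 2")
  if (cv_folds < 2) stop("cv_folds must be >= 2")
  structure(list(window_lengths = window_lengths,
                 overlap_fractions = overlap_fractions,
                 energy_threshold_fraction = energy_threshold_fraction,
                 refractory_s = refractory_s,
                 smooth_s = smooth_s,
                 n_fft = as.integer(n_fft),
                 feature_sets = feature_sets,
                 classifiers = classifiers,
                 cv_folds = as.integer(cv_folds),
                 scheme = scheme,
                 seed = as.integer(seed)),
            class = "semg_config")
}

#' Load a run configuration from a YAML file
#'
#' Keys absent from the file keep the defaults of [run_config()]; unknown
#' keys and out-of-range values raise an error naming the key.
#'
#' @param path path to a YAML key-value file (an empty file yields the
#'   full default configuration).
#' @return A [run_config()].
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, raw)
}
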