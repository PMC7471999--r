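# Shared fixtures, generated in code. The full-protocol dataset is
# expensive, so it is built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

# full default protocol: 12 subjects x 20 trials x 26 classes, snr 20 dB,
# no inter-subject jitter
default_dataset <- function() {
  if (is.null(.fixture_env$default)) {
    .fixture_env$default <- generate_dataset(synth_config(seed = 42))
  }
  .fixture_env$default
}

# G9 feature table of the default dataset at (W = 1 s, phi = 1)
default_g9_table <- function() {
  if (is.null(.fixture_env$g9_tab)) {
    segs <- combine_segments(lapply(default_dataset(), segment_recording,
                                    W = 1, phi = 1, cfg = run_config()))
    .fixture_env$g9_tab <- extract_table(segs, resolve_set("G9")$members)
  }
  .fixture_env$g9_tab
}

small_dataset <- function(n_subjects = 2, n_trials = 4, n_classes = 6,
                          n_dynamic = 2, seed = 7, ...) {
  generate_dataset(synth_config(n_subjects = n_subjects, n_trials = n_trials,
                                n_classes = n_classes, n_dynamic = n_dynamic,
                                seed = seed, ...))
}

# feature table with hand-built columns; label and feature columns only
fake_table <- function(label, ...) {
  cols <- list(...)
  tab <- data.frame(label = label, subject = "S01", trial = "T01",
                    activation = seq_along(label), start_s = 0,
                    stringsAsFactors = FALSE)
  for (nm in names(cols)) tab[[nm]] <- cols[[nm]]
  attr(tab, "feature_cols") <- names(cols)
  tab
}

make_energy <- function(values, fs = 200) {
  structure(list(values = values, fs = fs), class = "semg_energy")
}

make_psd <- function(freqs, power) {
  structure(list(freqs = freqs, power = power, n_fft = 2L * (length(freqs) - 1L)),
            class = "semg_psd")
}
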