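#' The sEMG feature registry
#'
#' The 33 canonical features computed by [extract_table()]: 24
#' time-domain and 9 frequency-domain, in the fixed registry order used
#' for all column layouts. Multi-component features are the 4th-order
#' autoregressive coefficients (`AR4`, 4 components), the cepstral
#' coefficients derived from them (`CEPS`, 4), and the 9-bin amplitude
#' histogram (`HIST`, 9); every other feature is scalar.
#'
#' @return A `data.frame` with columns `name`, `domain`
#'   (`"time"`/`"frequency"`), and `arity`.
#' @export
feature_registry <- function() {
  data.frame(
    name = c("AR4", "CEPS", "DASDV", "HIST", "IEMG", "LOGDEC", "LS", "MAV",
             "MAV1", "MAV2", "MFL", "MSR", "MYOP", "RMS", "SampEn", "SSC",
             "TM3", "TM4", "TM5", "VAREMG", "VORDER", "WAMP", "WL", "ZC",
             "FR", "MDF", "MNF", "MNP", "PKF", "SM1", "SM2", "SM3", "TTP"),
    domain = rep(c("time", "frequency"), c(24, 9)),
    arity = c(4, 4, 1, 9, rep(1, 20), rep(1, 9)),
    stringsAsFactors = FALSE)
}

#' Default feature parameters
#'
#' Thresholds are interpreted on the normalized `[-1, 1]` amplitude
#' scale. `amp_threshold` (1e-2) gates ZC, WAMP, and MYOP;
#' `slope_threshold` (1e-4) gates SSC; sample entropy uses embedding
#' dimension `sampen_m = 2` and tolerance `sampen_r_coef` times the
#' window's standard deviation; the frequency ratio compares the 10-50 Hz
#' band against 51-100 Hz.
#'
#' @param ... overrides for any default.
#' @return Named list of parameters.
#' @export
feature_params <- function(...) {
  p <- list(ar_order = 4L, hist_bins = 9L, amp_threshold = 1e-2,
            slope_threshold = 1e-4, sampen_m = 2L, sampen_r_coef = 0.2,
            vorder = 3, fr_low = c(10, 50), fr_high = c(51, 100),
            n_fft = 2000L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) stop("unknown feature parameter(s): ",
                            paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  p
}

#' One-sided power spectrum by zero-padded transform
#'
#' Transforms the window at `n_fft` points (zero-padded; truncation of
#' longer windows requires `truncate = TRUE`) and returns the squared
#' magnitude on the one-sided grid with spacing `fs / n_fft`. No
#' detrending or tapering is applied.
#'
#' @param x single-channel window (numeric vector, length >= 2).
#' @param fs sampling rate.
#' @param n_fft transform length.
#' @param truncate allow `n_fft < length(x)`.
#' @return An object of class `semg_psd` with fields `freqs`, `power`,
#'   `n_fft`.
#' @export
compute_psd <- function(x, fs, n_fft = 2000, truncate = FALSE) {
  if (length(x) < 2) stop("window must have at least 2 samples")
  if (n_fft < length(x)) {
    if (!truncate) stop("n_fft (", n_fft, ") shorter than the window (",
                        length(x), "); pass truncate = TRUE to allow")
    x <- x[seq_len(n_fft)]
  }
  xp <- c(x, rep(0, n_fft - length(x)))
  X <- fft(xp)
  half <- seq_len(floor(n_fft / 2) + 1L)
  structure(list(freqs = (half - 1L) * fs / n_fft,
                 power = Mod(X[half])^2, n_fft = as.integer(n_fft)),
            class = "semg_psd")
}

#' Autoregressive coefficients (Burg)
#'
#' Fits an AR model of the given order by the Burg method (stable on the
#' short windows typical of sEMG segmentation; Yule-Walker available via
#' `method`). A constant (zero-variance) window yields a zero vector
#' when `zero_on_constant = TRUE`, otherwise an error.
#'
#' @param x numeric vector, `length(x) > order`.
#' @param order model order (default 4).
#' @param method `"burg"` or `"yule-walker"`.
#' @param zero_on_constant behavior for zero-variance input.
#' @return Numeric vector of `order` coefficients `phi` in the convention
#'   `x_t = sum(phi_k x_(t-k)) + e_t`.
#' @export
ar_coefficients <- function(x, order = 4, method = c("burg", "yule-walker"),
                            zero_on_constant = TRUE) {
  method <- match.arg(method)
  if (length(x) <= order)
    stop("AR", order, " needs more than ", order, " samples, got ", length(x))
  if (var(x) == 0) {
    if (zero_on_constant) return(rep(0, order))
    stop("AR coefficients undefined for constant input")
  }
  fit <- if (method == "burg")
    ar.burg(x, aic = FALSE, order.max = order, demean = TRUE)
  else
    stats::ar.yw(x, aic = FALSE, order.max = order, demean = TRUE)
  phi <- fit$ar
  if (length(phi) < order) phi <- c(phi, rep(0, order - length(phi)))
  phi
}

#' Cepstral coefficients from AR coefficients
#'
#' Standard AR-to-cepstrum recursion `c_1 = -a_1`,
#' `c_p = -a_p - sum_{l=1}^{p-1} (1 - l/p) a_l c_{p-l}`, where `a` are
#' the prediction-polynomial coefficients (`a_k = -phi_k` for the
#' [ar_coefficients()] convention).
#'
#' @param a prediction-polynomial coefficients.
#' @return Numeric vector of the same length.
#' @export
cepstral_from_ar <- function(a) {
  p <- length(a)
  cc <- numeric(p)
  if (p == 0) return(cc)
  cc[1] <- -a[1]
  for (k in seq_len(p)[-1]) {
    l <- seq_len(k - 1)
    cc[k] <- -a[k] - sum((1 - l / k) * a[l] * cc[k - l])
  }
  cc
}

#' Sample entropy
#'
#' `-ln(A/B)` where `B` counts template pairs of length `m` within
#' Chebyshev distance `r` (self-matches excluded) and `A` the pairs still
#' matching at length `m + 1`. A constant window is defined as 0 (the
#' tolerance `r = r_coef * sd(x)` degenerates); if no pairs match at
#' either length the largest finite value `ln(n_pairs)` is returned
#' (reported via a message) rather than an error.
#'
#' @param x numeric vector, `length(x) >= m + 2`.
#' @param m embedding dimension.
#' @param r tolerance; default `0.2 * sd(x)`.
#' @return A single non-negative number.
#' @export
sample_entropy <- function(x, m = 2, r = 0.2 * sd(x)) {
  n <- length(x)
  if (n < m + 2) stop("sample entropy needs at least m + 2 samples")
  if (sd(x) == 0) return(0)
  nm <- n - m
  D <- abs(outer(x, x, "-"))
  M <- D[seq_len(nm), seq_len(nm)]
  for (s in seq_len(m - 1))
    M <- pmax(M, D[s + seq_len(nm), s + seq_len(nm)])
  Ma <- pmax(M, D[m + seq_len(nm), m + seq_len(nm)])
  B <- (sum(M <= r) - nm) / 2
  A <- (sum(Ma <= r) - nm) / 2
  n_pairs <- nm * (nm - 1) / 2
  if (B == 0 || A == 0) {
    message("sample_entropy: no template matches; returning ln(", n_pairs, ")")
    return(log(n_pairs))
  }
  -log(A / B)
}

# second sample L-moment, l2 = 2*b1 - b0 (order-statistics estimator)
l_scale <- function(x) {
  n <- length(x)
  xs <- sort(x)
  b0 <- mean(xs)
  b1 <- sum((seq_len(n) - 1) * xs) / (n * (n - 1))
  2 * b1 - b0
}

#' Extract one time-domain feature
#'
#' Computes the named feature from the registry (see [feature_registry()])
#' under the canonical sEMG definitions, with parameters from
#' [feature_params()]. Multi-component features return vectors (`AR4`,
#' `CEPS`: 4; `HIST`: `hist_bins`).
#'
#' @param x single-channel window.
#' @param name feature name.
#' @param params list from [feature_params()].
#' @return Numeric vector of the feature's arity.
#' @export
extract_time <- function(x, name, params = feature_params()) {
  n <- length(x)
  if (n < 2) stop(name, ": window must have at least 2 samples")
  dx <- diff(x)
  thr <- params$amp_threshold
  out <- switch(
    name,
    AR4 = ar_coefficients(x, params$ar_order),
    CEPS = cepstral_from_ar(-ar_coefficients(x, params$ar_order)),
    DASDV = sqrt(mean(dx^2)),
    HIST = {
      rng <- range(x)
      if (rng[1] == rng[2]) c(n, rep(0, params$hist_bins - 1))
      else {
        br <- seq(rng[1], rng[2], length.out = params$hist_bins + 1)
        as.numeric(hist(x, breaks = br, plot = FALSE)$counts)
      }
    },
    IEMG = sum(abs(x)),
    LOGDEC = exp(mean(log(pmax(abs(x), 1e-12)))),
    LS = l_scale(x),
    MAV = mean(abs(x)),
    MAV1 = {
      i <- seq_len(n)
      w <- ifelse(i >= 0.25 * n & i <= 0.75 * n, 1, 0.5)
      mean(w * abs(x))
    },
    MAV2 = {
      i <- seq_len(n)
      w <- ifelse(i < 0.25 * n, 4 * i / n,
                  ifelse(i > 0.75 * n, 4 * (n - i) / n, 1))
      mean(w * abs(x))
    },
    MFL = log10(sqrt(sum(dx^2))),
    MSR = mean(sqrt(abs(x))),
    MYOP = mean(abs(x) >= thr),
    RMS = sqrt(mean(x^2)),
    SampEn = sample_entropy(x, m = params$sampen_m,
                            r = params$sampen_r_coef * sd(x)),
    SSC = {
      if (n < 3) 0
      else sum(dx[-(n - 1)] * -dx[-1] >= params$slope_threshold)
    },
    TM3 = abs(mean(x^3)),
    TM4 = abs(mean(x^4)),
    TM5 = abs(mean(x^5)),
    VAREMG = sum(x^2) / (n - 1),
    VORDER = mean(abs(x)^params$vorder)^(1 / params$vorder),
    WAMP = sum(abs(dx) >= thr),
    WL = sum(abs(dx)),
    ZC = sum(x[-n] * x[-1] < 0 & abs(dx) >= thr),
    stop("unknown time-domain feature: ", name)
  )
  if (any(!is.finite(out))) stop(name, ": non-finite feature value")
  out
}

#' Extract one frequency-domain feature
#'
#' Spectral features on a [compute_psd()] spectrum: mean/median/peak
#' frequency, mean and total power, spectral moments
#' `SMn = sum(f^n * P)`, and the low/high frequency ratio over the bands
#' in [feature_params()] (inclusive grid membership).
#'
#' @param ps a `semg_psd`.
#' @param name feature name.
#' @param params list from [feature_params()].
#' @return A single number.
#' @export
extract_freq <- function(ps, name, params = feature_params()) {
  f <- ps$freqs; P <- ps$power
  tot <- sum(P)
  if (tot == 0 && name %in% c("FR", "MDF", "MNF"))
    stop(name, ": degenerate segment with zero total power")
  out <- switch(
    name,
    FR = {
      lo <- sum(P[f >= params$fr_low[1] & f <= params$fr_low[2]])
      hi <- sum(P[f >= params$fr_high[1] & f <= params$fr_high[2]])
      if (hi == 0) stop("FR: zero power in the high band")
      lo / hi
    },
    MDF = f[which(cumsum(P) >= tot / 2)[1]],
    MNF = sum(f * P) / tot,
    MNP = mean(P),
    PKF = f[which.max(P)],
    SM1 = sum(f * P),
    SM2 = sum(f^2 * P),
    SM3 = sum(f^3 * P),
    TTP = tot,
    stop("unknown frequency-domain feature: ", name)
  )
  if (!is.finite(out)) stop(name, ": non-finite feature value")
  out
}

component_names <- function(features) {
  reg <- feature_registry()
  unlist(lapply(features, function(f) {
    a <- reg$arity[reg$name == f]
    if (a == 1) f else paste0(f, "_", seq_len(a))
  }), use.names = FALSE)
}

# all requested features for one channel, sharing the PSD
extract_channel <- function(x, features, fs, params) {
  reg <- feature_registry()
  need_psd <- any(reg$domain[match(features, reg$name)] == "frequency")
  ps <- if (need_psd) compute_psd(x, fs, params$n_fft,
                                  truncate = length(x) > params$n_fft)
  unlist(lapply(features, function(f) {
    if (reg$domain[reg$name == f] == "time") extract_time(x, f, params)
    else extract_freq(ps, f, params)
  }), use.names = FALSE)
}

#' Feature table for a segment collection
#'
#' Applies every requested feature to every channel of every segment and
#' assembles the rows into a data frame: provenance columns (`label`,
#' `subject`, `trial`, `activation`, `start_s`) followed by one numeric
#' column per feature component and channel, named `FEAT[_k]_chN`, in
#' registry order with channels contiguous per component. The full
#' 33-feature registry yields 47 components x 8 channels = 376 numeric
#' columns.
#'
#' @param segments a `semg_segments` from [segment_recording()] or
#'   [segment_dataset()].
#' @param features character vector of registry names, or `"all"`.
#' @param params list from [feature_params()].
#' @return A `data.frame`; numeric feature columns carry the attribute
#'   `feature_cols`.
#' @export
extract_table <- function(segments, features = "all",
                          params = feature_params()) {
  stopifnot(inherits(segments, "semg_segments"))
  if (!length(segments)) stop("no segments to extract features from")
  reg <- feature_registry()
  if (identical(features, "all")) features <- reg$name
  unknown <- setdiff(features, reg$name)
  if (length(unknown))
    stop("unknown feature(s): ", paste(unknown, collapse = ", "))
  features <- reg$name[reg$name %in% features]   # registry order
  n_ch <- ncol(segments$windows[[1]])
  comp <- component_names(features)
  cols <- paste0(rep(comp, each = n_ch), "_ch", seq_len(n_ch))
  n <- length(segments)
  M <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  for (i in seq_len(n)) {
    w <- segments$windows[[i]]
    row <- tryCatch(
      vapply(seq_len(n_ch), function(j)
        extract_channel(w[, j], features, segments$fs, params),
        numeric(length(comp))),
      error = function(e)
        stop("feature extraction failed for segment ", i, " (subject ",
             segments$subject[i], ", trial ", segments$trial[i],
             ", activation ", segments$activation[i], "): ",
             conditionMessage(e), call. = FALSE))
    M[i, ] <- as.vector(t(row))   # component-major, channels contiguous
  }
  out <- data.frame(label = segments$label, subject = segments$subject,
                    trial = segments$trial, activation = segments$activation,
                    start_s = segments$start_s, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(M))
  attr(out, "feature_cols") <- cols
  out
}

#' Numeric feature columns of a feature table
#'
#' @param table a table from [extract_table()].
#' @return Character vector of feature column names.
#' @export
feature_cols <- function(table) {
  fc <- attr(table, "feature_cols")
  if (!is.null(fc)) return(fc)
  setdiff(names(table), c("label", "subject", "trial", "activation", "start_s"))
}
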