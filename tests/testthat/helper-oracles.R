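# Independent brute-force oracles, written as plain loops so they share no
# code path with the package implementations they check.

bf_time_features <- function(x, thr = 1e-2, slope_thr = 1e-4) {
  n <- length(x)
  out <- list()
  out$MAV <- sum(abs(x)) / n
  w1 <- numeric(n); w2 <- numeric(n)
  for (i in 1:n) {
    w1[i] <- if (i >= 0.25 * n && i <= 0.75 * n) 1 else 0.5
    w2[i] <- if (i < 0.25 * n) 4 * i / n else if (i > 0.75 * n) 4 * (n - i) / n else 1
  }
  out$MAV1 <- sum(w1 * abs(x)) / n
  out$MAV2 <- sum(w2 * abs(x)) / n
  out$IEMG <- sum(abs(x))
  out$RMS <- sqrt(sum(x^2) / n)
  out$VAREMG <- sum(x^2) / (n - 1)
  wl <- 0; da <- 0; mfl2 <- 0
  for (i in 1:(n - 1)) {
    d <- x[i + 1] - x[i]
    wl <- wl + abs(d); da <- da + d^2; mfl2 <- mfl2 + d^2
  }
  out$WL <- wl
  out$DASDV <- sqrt(da / (n - 1))
  out$MFL <- log10(sqrt(mfl2))
  out$LOGDEC <- exp(sum(log(pmax(abs(x), 1e-12))) / n)
  out$MSR <- sum(sqrt(abs(x))) / n
  out$VORDER <- (sum(abs(x)^3) / n)^(1 / 3)
  out$TM3 <- abs(sum(x^3) / n)
  out$TM4 <- abs(sum(x^4) / n)
  out$TM5 <- abs(sum(x^5) / n)
  # second L-moment as half the Gini mean difference over all pairs
  s <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) s <- s + abs(x[i] - x[j])
  out$LS <- s / choose(n, 2) / 2
  zc <- 0; wamp <- 0; myop <- 0
  for (i in 1:(n - 1)) {
    if (x[i] * x[i + 1] < 0 && abs(x[i + 1] - x[i]) >= thr) zc <- zc + 1
    if (abs(x[i + 1] - x[i]) >= thr) wamp <- wamp + 1
  }
  for (i in 1:n) if (abs(x[i]) >= thr) myop <- myop + 1
  out$ZC <- zc; out$WAMP <- wamp; out$MYOP <- myop / n
  ssc <- 0
  for (i in 2:(n - 1))
    if ((x[i] - x[i - 1]) * (x[i] - x[i + 1]) >= slope_thr) ssc <- ssc + 1
  out$SSC <- ssc
  rng <- range(x)
  cnt <- numeric(9)
  if (rng[1] == rng[2]) cnt[1] <- n else {
    br <- seq(rng[1], rng[2], length.out = 10)
    for (v in x) {
      b <- 9
      for (k in 1:9) if (v <= br[k + 1]) { b <- k; break }
      cnt[b] <- cnt[b] + 1
    }
  }
  out$HIST <- cnt
  out
}

bf_sample_entropy <- function(x, m = 2, r = 0.2 * sd(x)) {
  n <- length(x)
  if (sd(x) == 0) return(0)
  nm <- n - m
  cheb <- function(i, j, len) {
    d <- 0
    for (s in 0:(len - 1)) d <- max(d, abs(x[i + s] - x[j + s]))
    d
  }
  A <- 0; B <- 0
  for (i in 1:(nm - 1)) for (j in (i + 1):nm) {
    if (cheb(i, j, m) <= r) B <- B + 1
    if (cheb(i, j, m + 1) <= r) A <- A + 1
  }
  if (B == 0 || A == 0) return(log(nm * (nm - 1) / 2))
  -log(A / B)
}

# direct DFT power spectrum (one-sided), O(n * n_fft)
bf_psd <- function(x, fs, n_fft) {
  xp <- c(x, rep(0, n_fft - length(x)))
  half <- 0:(n_fft %/% 2)
  power <- numeric(length(half))
  for (k in seq_along(half)) {
    re <- 0; im <- 0
    for (t in seq_along(xp)) {
      ang <- -2 * pi * half[k] * (t - 1) / n_fft
      re <- re + xp[t] * cos(ang); im <- im + xp[t] * sin(ang)
    }
    power[k] <- re^2 + im^2
  }
  list(freqs = half * fs / n_fft, power = power)
}

bf_freq_features <- function(freqs, power, lo = c(10, 50), hi = c(51, 100)) {
  tot <- sum(power)
  cum <- cumsum(power)
  list(MNF = sum(freqs * power) / tot,
       MDF = freqs[which(cum >= tot / 2)[1]],
       PKF = freqs[which.max(power)],
       MNP = mean(power),
       TTP = tot,
       SM1 = sum(freqs * power),
       SM2 = sum(freqs^2 * power),
       SM3 = sum(freqs^3 * power),
       FR = sum(power[freqs >= lo[1] & freqs <= lo[2]]) /
         sum(power[freqs >= hi[1] & freqs <= hi[2]]))
}

# exhaustive enumeration of sliding-window starts
bf_window_starts <- function(L, W, phi, fs) {
  w <- round(W * fs)
  k <- max(1, round(phi * W * fs))
  starts <- integer(0)
  s <- 0
  while (s + w <= L) { starts <- c(starts, s); s <- s + k }
  starts
}

# exhaustive two-sided rank-sum permutation test (no ties assumed)
bf_ranksum_perm <- function(a, b) {
  n <- length(a); m <- length(b)
  r <- rank(c(a, b))
  obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2   # Mann-Whitney U of sample a
  idx <- utils::combn(n + m, n)
  u <- apply(idx, 2, function(ii) sum(r[ii]) - n * (n + 1) / 2)
  mu <- n * m / 2
  if (obs > mu) {
    p <- 2 * mean(u >= obs)
  } else if (obs < mu) {
    p <- 2 * mean(u <= obs)
  } else p <- 1
  min(p, 1)
}

# Friedman chi-square by direct rank arithmetic (no tie correction needed
# for continuous data)
bf_friedman_stat <- function(acc) {
  g <- nrow(acc); b <- ncol(acc)
  R <- matrix(0, g, b)
  for (j in seq_len(b)) R[, j] <- rank(acc[, j])
  Rs <- rowSums(R)
  12 / (b * g * (g + 1)) * sum((Rs - b * (g + 1) / 2)^2)
}
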