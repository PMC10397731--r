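# Independent oracles and small fixture builders shared across the suite.
# Everything here is deliberately naive (double loops, direct DFT sums) so
# the package's vectorised/compiled paths are checked against code that
# shares none of their machinery.

# Direct double-sum evaluation of the discrete WVD of an analytic block:
# W[k, n] = sum_tau z[n+tau] conj(z[n-tau]) exp(-2 pi i k tau / nfft),
# |tau| <= min(n, N-1-n, nfft/2 - 1).
wvd_bruteforce <- function(z, nfft = length(z)) {
  n_len <- length(z)
  W <- matrix(0, nfft, n_len)
  for (n in 0:(n_len - 1L)) {
    taumax <- min(n, n_len - 1L - n, nfft %/% 2L - 1L)
    for (k in 0:(nfft - 1L)) {
      acc <- 0 + 0i
      for (tau in -taumax:taumax)
        acc <- acc + z[n + tau + 1L] * Conj(z[n - tau + 1L]) *
          exp(-2i * pi * k * tau / nfft)
      W[k + 1L, n + 1L] <- Re(acc)
    }
  }
  W
}

# Direct O(N^2) DFT construction of the analytic signal: zero the negative
# frequencies of the (mean-removed) input and invert by explicit sums.
analytic_bruteforce <- function(x) {
  x <- x - mean(x)
  n <- length(x)
  idx <- 0:(n - 1L)
  X <- vapply(idx, function(k) sum(x * exp(-2i * pi * k * idx / n)),
              complex(1))
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2L == 0L) { h[n / 2L + 1L] <- 1; h[2:(n / 2L)] <- 2 }
  else h[2:((n + 1L) / 2L)] <- 2
  vapply(idx, function(t) sum(X * h * exp(2i * pi * idx * t / n)) / n,
         complex(1))
}

make_tone <- function(f0, fs = 128, dur = 2, amp = 1)
  eeg_segment(amp * cos(2 * pi * f0 * (0:(round(dur * fs) - 1L)) / fs), fs)

# linear chirp f0 -> f1 over dur seconds
make_chirp <- function(f0, f1, fs = 128, dur = 2) {
  t <- (0:(round(dur * fs) - 1L)) / fs
  eeg_segment(cos(2 * pi * (f0 * t + (f1 - f0) / (2 * dur) * t^2)), fs)
}

# Renyi-type concentration: sum of squared normalised magnitudes.
concentration <- function(values) {
  a <- abs(values)
  p <- a / sum(a)
  sum(p^2)
}

# Literal sliding-window tally, string comparison per window.
count_codes_bruteforce <- function(symbols) {
  ch <- strsplit(symbols, "")[[1L]]
  codes <- all_codes()
  counts <- stats::setNames(integer(125), codes)
  for (i in seq_len(length(ch) - 2L)) {
    w <- paste(ch[i:(i + 2L)], collapse = "")
    counts[w] <- counts[w] + 1L
  }
  counts
}

random_symbols <- function(n) paste(sample(RHYTHM_ALPHABET, n, replace = TRUE),
                                    collapse = "")

# Sequences for a full subject built directly (no signal synthesis): one
# rhythm_sequence per (trial, channel).
make_subject_sequences <- function(n_trials, channels, len = 150,
                                   labels = rep(c("low", "high"),
                                                length.out = n_trials)) {
  out <- list()
  for (i in seq_len(n_trials)) for (ch in channels)
    out[[length(out) + 1L]] <- rhythm_sequence(
      random_symbols(len), channel = ch,
      trial_id = sprintf("trial%03d", i), subject_id = "subjA",
      label = labels[i])
  out
}
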