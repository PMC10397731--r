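test_that("analytic signal: zero/DC cases, one-sided DFT oracle", {
  fs <- 128
  expect_equal(analytic_signal(eeg_segment(numeric(64), fs)),
               complex(64, rep(0, 64)))
  # constant input is pure DC: zero after mean removal
  expect_equal(analytic_signal(eeg_segment(rep(3.7, 64), fs)),
               complex(64, rep(0, 64)))

  seg <- make_tone(10, fs, 2)
  z <- analytic_signal(seg)
  expect_equal(Re(z), seg$samples - mean(seg$samples), tolerance = 1e-10)
  expect_equal(Mod(z[30:220]), rep(1, 191), tolerance = 1e-6)
  # against the direct DFT construction on a small crop
  x <- seg$samples[1:48]
  expect_equal(analytic_signal(eeg_segment(x, fs)), analytic_bruteforce(x),
               tolerance = 1e-9)

  expect_error(analytic_signal(c(1, NA, 3, 4)), "non-finite")
  expect_error(analytic_signal(c(1, 2, 3)), "at least 4")
})

test_that("WVD matches the brute-force double-sum on small instances", {
  fs <- 128
  withr::with_seed(7, {
    for (sig in list(make_tone(10, fs, 0.5)$samples[1:48],
                     rnorm(40),
                     make_chirp(5, 25, fs, 0.5)$samples[1:64])) {
      seg <- eeg_segment(sig, fs)
      z <- analytic_signal(seg)
      expected <- wvd_bruteforce(z)
      got <- compute_wvd(seg, block_s = NULL)$values
      expect_lt(max(abs(got - expected)) / max(abs(expected)), 1e-9)
    }
  })
})

test_that("WVD localises tones and shows midpoint cross-terms", {
  fs <- 128
  expect_equal(max(abs(compute_wvd(eeg_segment(numeric(256), fs))$values)), 0)

  p <- compute_wvd(make_tone(10, fs, 2), block_s = NULL)
  expect_equal(p$freqs[which.max(rowSums(p$values))], 10,
               tolerance = fs / (2 * length(p$freqs)))

  # two tones: oscillatory cross-term energy near the 13 Hz midpoint
  t <- (0:255) / fs
  both <- eeg_segment(cos(2 * pi * 6 * t) + cos(2 * pi * 20 * t), fs)
  mid <- function(plane) {
    sel <- plane$freqs >= 12 & plane$freqs <= 14
    sum(abs(plane$values[sel, ]))
  }
  w_both <- compute_wvd(both, block_s = NULL)
  expect_gt(mid(w_both), mid(compute_wvd(make_tone(6, fs, 2), block_s = NULL)))
  expect_gt(mid(w_both), mid(compute_wvd(make_tone(20, fs, 2),
                                         block_s = NULL)))

  # smoothing shrinks the cross-term
  s_both <- compute_spwvd(both, default_smoothing(256, fs), block_s = NULL)
  expect_lt(mid(s_both), mid(w_both))
})

test_that("SPWVD with unit windows equals the WVD; zero in, zero out", {
  fs <- 128
  seg <- make_chirp(5, 25, fs, 0.5)
  w <- compute_wvd(seg, block_s = NULL)$values
  s <- compute_spwvd(seg, smoothing_spec(1, 1), block_s = NULL)$values
  expect_lt(max(abs(s - w)) / max(abs(w)), 1e-9)

  expect_equal(max(abs(compute_spwvd(eeg_segment(numeric(128), fs),
                                     smoothing_spec(1, 1))$values)), 0)
  expect_error(smoothing_spec(hamming_window(4), 1), "odd")
})

test_that("reassignment coordinates: tone frequency, zero-signal identity", {
  fs <- 128
  spec <- default_smoothing(256, fs)
  seg <- make_tone(10, fs, 2)
  co <- reassignment_coordinates(seg, spec, block_s = NULL)
  p <- compute_spwvd(seg, spec, block_s = NULL)
  hi <- p$values >= 0.5 * max(p$values)
  # exclude columns where the smoothing windows are truncated by the
  # segment edge: centre-of-gravity estimates are only exact with full
  # window support
  edge <- (length(spec$g) + length(spec$h)) %/% 2
  hi[, c(seq_len(edge), ncol(hi) - seq_len(edge) + 1L)] <- FALSE
  bin <- fs / (2 * length(p$freqs))
  expect_lt(max(abs(co$f_hat[hi] - 10)), bin + 1e-9)

  z <- eeg_segment(numeric(128), fs)
  co0 <- reassignment_coordinates(z, spec)
  expect_equal(co0$t_hat, matrix(rep(co0$times, each = 128), 128, 128))
  expect_equal(co0$f_hat, matrix(rep(co0$freqs, 128), 128, 128))
})

test_that("reassignment tracks a chirp's instantaneous frequency", {
  fs <- 128
  dur <- 2
  seg <- make_chirp(5, 25, fs, dur)
  spec <- default_smoothing(256, fs)
  p <- compute_spwvd(seg, spec, block_s = NULL)
  co <- reassignment_coordinates(seg, spec, block_s = NULL)
  f_inst <- function(t) 5 + (25 - 5) / dur * t
  top <- p$values >= stats::quantile(p$values[p$values > 0], 0.9)
  grid_f <- matrix(rep(p$freqs, length(p$times)), nrow = length(p$freqs))
  grid_t <- matrix(rep(p$times, each = length(p$freqs)),
                   nrow = length(p$freqs))
  err_re <- mean(abs(co$f_hat[top] - f_inst(co$t_hat[top])))
  err_un <- mean(abs(grid_f[top] - f_inst(grid_t[top])))
  expect_lt(err_re, err_un)
})

test_that("reassigned plane conserves energy and concentrates", {
  fs <- 128
  spec <- default_smoothing(256, fs)
  withr::with_seed(11, {
    for (seg in list(make_tone(10, fs, 2), make_chirp(5, 25, fs, 2),
                     eeg_segment(rnorm(256), fs))) {
      s <- compute_spwvd(seg, spec, block_s = NULL)
      r <- compute_rspwvd(seg, spec, block_s = NULL)
      expect_lt(abs(sum(r$values) - sum(s$values)) /
                  max(abs(sum(s$values)), 1e-12), 1e-6)
    }
  })
  expect_equal(max(abs(compute_rspwvd(eeg_segment(numeric(128), fs),
                                      spec = smoothing_spec(1, 1))$values)),
               0)
  # concentration strictly increases for a chirp
  chirp <- make_chirp(5, 25, fs, 2)
  expect_gt(concentration(compute_rspwvd(chirp, spec, block_s = NULL)$values),
            concentration(compute_spwvd(chirp, spec, block_s = NULL)$values))
})

test_that("time-shift covariance: delayed input shifts the ridge", {
  fs <- 128
  k <- 9
  t <- (0:255) / fs
  env <- exp(-((t - 0.6)^2) / (2 * 0.1^2))       # localised burst
  x <- env * cos(2 * pi * 15 * t)
  y <- c(numeric(k), x[1:(256 - k)])
  spec <- default_smoothing(256, fs)
  prof <- function(sig) colSums(pmax(
    compute_rspwvd(eeg_segment(sig, fs), spec, block_s = NULL)$values, 0))
  px <- prof(x); py <- prof(y)
  lags <- 0:20
  cc <- vapply(lags, function(l)
    sum(px[1:(256 - l)] * py[(1 + l):256]), numeric(1))
  expect_equal(lags[which.max(cc)], k)
})

test_that("block processing keeps grids consistent and energy conserved", {
  fs <- 128
  seg <- make_tone(10, fs, 5)           # 5 s: 2 full blocks + remainder
  p <- compute_rspwvd(seg)              # default 2 s blocks
  expect_equal(length(p$times), 640)
  expect_equal(length(p$freqs), 256)
  s <- compute_spwvd(seg)
  expect_lt(abs(sum(p$values) - sum(s$values)) / abs(sum(s$values)), 1e-6)
  # tone still localised with blocks
  expect_equal(p$freqs[which.max(rowSums(p$values))], 10, tolerance = 0.5)
  expect_error(compute_rspwvd(seg, block_s = 0.35), "multiple")
})
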