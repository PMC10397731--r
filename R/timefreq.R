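#' Analytic signal of an EEG segment
#'
#' Removes the mean and suppresses negative frequencies via the FFT one-sided
#' multiplier, so the quadratic time-frequency transforms are free of
#' positive/negative-frequency interference.  The real part of the result
#' equals the mean-removed input.
#'
#' @param seg an [eeg_segment()] (length >= 4).
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(seg) {
  x <- if (inherits(seg, "eeg_segment")) seg$samples else as.numeric(seg)
  if (any(!is.finite(x)))
    stop("invalid input: non-finite samples", call. = FALSE)
  n <- length(x)
  if (n < 4) stop("invalid input: need at least 4 samples", call. = FALSE)
  x <- x - mean(x)
  X <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2L == 0L) {
    h[n / 2L + 1L] <- 1
    if (n > 2) h[2:(n / 2L)] <- 2
  } else {
    h[2:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# ---- block machinery ------------------------------------------------------

# Non-overlapping processing blocks, 0.2 s-aligned so that sequencing
# timestamps never straddle a block edge.  The trailing remainder (if any)
# becomes a shorter final block evaluated on the same nfft-bin frequency grid.
tf_blocks <- function(n, fs, block_s) {
  if (!is.null(block_s)) {
    if (abs(block_s / 0.2 - round(block_s / 0.2)) > 1e-9)
      stop("block_s must be a multiple of the 0.2 s timestamp interval",
           call. = FALSE)
    blen <- round(block_s * fs)
  } else blen <- n
  blen <- min(blen, n)
  starts <- seq.int(1L, n, by = blen)
  lapply(starts, function(s) seq.int(s, min(s + blen - 1L, n)))
}

tf_freqs <- function(nfft, fs) (seq_len(nfft) - 1L) * fs / (2 * nfft)

# Pure-R discrete WVD of an analytic block on an nfft-bin half-sample-lag
# frequency grid.  Kept independent of the C++ SPWVD path so the
# unit-window equivalence test compares two implementations.
wvd_block <- function(z, nfft) {
  n <- length(z)
  K <- matrix(0 + 0i, nfft, n)
  taucap <- min(nfft %/% 2L - 1L, (n - 1L) %/% 2L)
  for (tau in 0:taucap) {
    valid <- seq.int(tau + 1L, n - tau)
    p <- z[valid + tau] * Conj(z[valid - tau])
    K[tau + 1L, valid] <- p
    if (tau > 0L) K[nfft - tau + 1L, valid] <- Conj(p)
  }
  Re(stats::mvfft(K))
}

#' Discrete Wigner-Ville distribution
#'
#' Evaluates the WVD of the analytic signal via the instantaneous
#' autocorrelation and an FFT over lag.  Long segments are processed in
#' non-overlapping 0.2 s-aligned blocks (default 2 s) to bound the quadratic
#' cost; the frequency grid has one bin per sample of the block, tiling
#' `[0, fs/2)`.
#'
#' @param seg an [eeg_segment()].
#' @param block_s block length in seconds (multiple of 0.2), or `NULL` to
#'   process the whole segment in one block.
#' @return a [tf_plane()].
#' @export
compute_wvd <- function(seg, block_s = 2) {
  stopifnot(inherits(seg, "eeg_segment"))
  z <- analytic_signal(seg)
  blocks <- tf_blocks(length(z), seg$fs, block_s)
  nfft <- length(blocks[[1L]])
  vals <- do.call(cbind, lapply(blocks, function(ix) wvd_block(z[ix], nfft)))
  tf_plane(vals, tf_freqs(nfft, seg$fs),
           (seq_along(z) - 1L) / seg$fs, seg$fs)
}

# Shared SPWVD machinery: returns the real SPWVD plane plus the reassigned
# (time sample, frequency bin) 0-based target indices for every grid point.
spwvd_internal <- function(seg, spec, block_s, want_coords = TRUE) {
  stopifnot(inherits(seg, "eeg_segment"))
  z <- analytic_signal(seg)
  n <- length(z)
  blocks <- tf_blocks(n, seg$fs, block_s)
  nfft <- length(blocks[[1L]])
  if (is.null(spec)) spec <- default_smoothing(nfft, seg$fs)
  if (!inherits(spec, "smoothing_spec"))
    stop("spec must be a smoothing_spec", call. = FALSE)
  if (length(spec$g) >= nfft || length(spec$h) >= nfft)
    stop("smoothing windows must be shorter than the processed block (",
         nfft, " samples)", call. = FALSE)

  parts <- lapply(blocks, function(ix)
    spwvd_block_cpp(z[ix], spec$g, spec$h, spec$D_h, nfft))
  spw <- do.call(cbind, lapply(parts, function(p) Re(p$spw)))
  out <- list(spw = spw, nfft = nfft, fs = seg$fs, n = n)
  if (!want_coords) return(out)

  eps <- 1e-12 * max(abs(spw), 0)
  t_idx <- matrix(0L, nfft, n)
  k_idx <- matrix(0L, nfft, n)
  row0 <- matrix(seq_len(nfft) - 1L, nfft, 1L)
  for (b in seq_along(blocks)) {
    ix <- blocks[[b]]
    off <- ix[1L] - 1L
    nb <- length(ix)
    den <- Re(parts[[b]]$spw)
    low <- abs(den) < eps | den == 0
    dt <- Re(parts[[b]]$spw_tg) / den
    dk <- nfft / (2 * pi) * Im(parts[[b]]$spw_dh) / den
    dt[low] <- 0; dk[low] <- 0
    col0 <- matrix(rep(seq_len(nb) - 1L, each = nfft), nfft, nb)
    th <- round(col0 + dt) + off
    kh <- round(col0 * 0 + row0[, rep(1L, nb)] - dk)
    t_idx[, ix] <- pmin(pmax(th, off), off + nb - 1L)   # clamp within block
    k_idx[, ix] <- pmin(pmax(kh, 0), nfft - 1L)
  }
  out$t_idx <- t_idx
  out$k_idx <- k_idx
  out
}

#' Smoothed pseudo-Wigner-Ville distribution
#'
#' Separable time (`g`) and lag (`h`) smoothing of the WVD.  With length-1
#' unit windows the result equals [compute_wvd()].
#'
#' @inheritParams compute_wvd
#' @param spec a [smoothing_spec()]; `NULL` uses [default_smoothing()] for the
#'   processed block length.
#' @return a [tf_plane()].
#' @export
compute_spwvd <- function(seg, spec = NULL, block_s = 2) {
  r <- spwvd_internal(seg, spec, block_s, want_coords = FALSE)
  tf_plane(r$spw, tf_freqs(r$nfft, r$fs), (seq_len(r$n) - 1L) / r$fs, r$fs)
}

#' Reassignment coordinates of the SPWVD
#'
#' For every grid point `(t, f)`, the local centre of gravity `(t_hat, f_hat)`
#' of the smoothed energy, computed from the ratios of the `tau_g`- and
#' `D_h`-kernel SPWVDs to the plain SPWVD.  Where the SPWVD magnitude is
#' below `1e-12` of its maximum the point maps to itself.
#'
#' @inheritParams compute_spwvd
#' @return list with matrices `t_hat` (seconds) and `f_hat` (Hz), both
#'   `nfft x n`, plus the `freqs`/`times` grids.
#' @export
reassignment_coordinates <- function(seg, spec = NULL, block_s = 2) {
  r <- spwvd_internal(seg, spec, block_s)
  freqs <- tf_freqs(r$nfft, r$fs)
  times <- (seq_len(r$n) - 1L) / r$fs
  list(t_hat = matrix(times[r$t_idx + 1L], r$nfft, r$n),
       f_hat = matrix(freqs[r$k_idx + 1L], r$nfft, r$n),
       freqs = freqs, times = times)
}

#' Reassigned smoothed pseudo-Wigner-Ville distribution
#'
#' Relocates every SPWVD value to the grid bin nearest its reassignment
#' coordinates (clamped to the grid) and accumulates.  The total sum of the
#' plane is preserved, so the transform respects energy conservation.
#'
#' @inheritParams compute_spwvd
#' @return a [tf_plane()].
#' @export
compute_rspwvd <- function(seg, spec = NULL, block_s = 2) {
  stopifnot(inherits(seg, "eeg_segment"))
  z <- analytic_signal(seg)
  blocks <- tf_blocks(length(z), seg$fs, block_s)
  nfft <- length(blocks[[1L]])
  if (is.null(spec)) spec <- default_smoothing(nfft, seg$fs)
  if (!inherits(spec, "smoothing_spec"))
    stop("spec must be a smoothing_spec", call. = FALSE)
  if (length(spec$g) >= nfft || length(spec$h) >= nfft)
    stop("smoothing windows must be shorter than the processed block (",
         nfft, " samples)", call. = FALSE)
  vals <- do.call(cbind, lapply(blocks, function(ix)
    rspwvd_block_cpp(z[ix], spec$g, spec$h, spec$D_h, nfft)$rsp))
  tf_plane(vals, tf_freqs(nfft, seg$fs),
           (seq_along(z) - 1L) / seg$fs, seg$fs)
}
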