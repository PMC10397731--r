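#' Construct a single-channel EEG segment
#'
#' One channel of one trial: an amplitude series (microvolts) with its
#' sampling rate and identifying metadata.  The segment must be long enough
#' to hold at least one 0.2 s sequencing timestamp.
#'
#' @param samples numeric vector of amplitudes (uV); all values finite.
#' @param fs sampling rate in Hz (> 0).
#' @param channel channel name in 10-20 nomenclature (e.g. "FP1").
#' @param trial_id,subject_id identifiers carried through the pipeline.
#' @return an object of class `eeg_segment`.
#' @export
eeg_segment <- function(samples, fs, channel = "CH1", trial_id = "t1",
                        subject_id = "s1") {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number", call. = FALSE)
  if (any(!is.finite(samples)))
    stop("invalid input: non-finite samples in segment", call. = FALSE)
  if (length(samples) < ceiling(0.2 * fs))
    stop("segment too short: need at least one 0.2 s timestamp (",
         ceiling(0.2 * fs), " samples at fs = ", fs, ")", call. = FALSE)
  structure(list(samples = samples, fs = fs, channel = channel,
                 trial_id = trial_id, subject_id = subject_id),
            class = "eeg_segment")
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment> %s/%s channel %s: %d samples @ %g Hz (%.2f s)\n",
              x$subject_id, x$trial_id, x$channel, length(x$samples), x$fs,
              length(x$samples) / x$fs))
  invisible(x)
}

seg_duration <- function(seg) length(seg$samples) / seg$fs

#' Hamming window
#'
#' `0.54 - 0.46 cos(2 pi k / (n - 1))`; a length-1 window is the scalar 1.
#' @param n window length.
#' @return numeric vector of length `n`.
#' @export
hamming_window <- function(n) {
  if (n < 1) stop("window length must be >= 1", call. = FALSE)
  if (n == 1) return(1)
  k <- seq_len(n) - 1L
  0.54 - 0.46 * cos(2 * pi * k / (n - 1))
}

#' Time/lag smoothing specification for the SPWVD
#'
#' Holds the time-smoothing window `g` (normalised to unit sum), the lag
#' (frequency-) smoothing window `h` (peak-normalised), and the derived
#' reassignment kernels `tau_g = t * g(t)` (on the centred sample-index grid)
#' and `D_h = dh/dt` (central differences).  Both windows must be odd-length,
#' real and symmetric; a length-1 window means "no smoothing" in that
#' direction.
#'
#' @param g time-smoothing window (odd length, symmetric).
#' @param h lag-smoothing window (odd length, symmetric).
#' @return an object of class `smoothing_spec`.
#' @seealso [default_smoothing()]
#' @export
smoothing_spec <- function(g = 1, h = 1) {
  g <- as.numeric(g); h <- as.numeric(h)
  for (w in list(g = g, h = h)) {
    if (length(w) %% 2L == 0L)
      stop("invalid smoothing spec: windows must have odd length",
           call. = FALSE)
    if (any(!is.finite(w)))
      stop("invalid smoothing spec: non-finite window values", call. = FALSE)
    if (max(abs(w - rev(w))) > 1e-8 * max(abs(w), 1))
      stop("invalid smoothing spec: windows must be symmetric", call. = FALSE)
  }
  g <- g / sum(g)                      # unit sum
  h <- h / h[(length(h) + 1L) / 2L]    # peak-normalised
  Lg2 <- (length(g) - 1L) / 2L
  tau_g <- (seq_along(g) - 1L - Lg2) * g
  # centred-difference derivative of h; one-sided at the edges
  dh <- if (length(h) == 1L) 0 else {
    d <- numeric(length(h))
    d[1] <- h[2] - h[1]
    d[length(h)] <- h[length(h)] - h[length(h) - 1L]
    if (length(h) > 2L) {
      i <- 2:(length(h) - 1L)
      d[i] <- (h[i + 1L] - h[i - 1L]) / 2
    }
    d
  }
  structure(list(g = g, h = h, tau_g = tau_g, D_h = dh),
            class = "smoothing_spec")
}

#' Default smoothing windows for a block of n samples
#'
#' Hamming windows of length ~ n/10 (time) and ~ n/4 (lag), rounded to the
#' nearest odd integers -- conventional SPWVD defaults.  When the sampling
#' rate is known, the lag window is additionally capped at one sequencing
#' timestamp (`interval * fs` samples): the instantaneous autocorrelation
#' reaches `lag/2` samples to each side, and a lag window longer than a
#' timestamp lets quadratic "bridge" auto-terms form between two same-band
#' timestamps flanking a different one, corrupting the dominant-band
#' readout at the 0.2 s resolution.
#'
#' @param n number of samples in the processed block.
#' @param fs sampling rate (Hz); `NULL` skips the timestamp cap.
#' @param interval sequencing timestamp length (s).
#' @return a [smoothing_spec()].
#' @export
default_smoothing <- function(n, fs = NULL, interval = 0.2) {
  odd <- function(m) { m <- max(1L, round(m)); if (m %% 2L == 0L) m + 1L else m }
  lh <- odd(n / 4)
  if (!is.null(fs)) {
    cap <- floor(interval * fs)
    if (cap %% 2 == 0) cap <- cap - 1
    lh <- min(lh, max(3L, as.integer(cap)))
  }
  smoothing_spec(hamming_window(odd(n / 10)), hamming_window(lh))
}

#' Time-frequency plane container
#'
#' Power-density values on a frequency x time grid.  Rows are frequency bins
#' (ascending, covering `[0, fs/2)`), columns are time samples at `1/fs`.
#'
#' @param values numeric matrix, `length(freqs)` x `length(times)`.
#' @param freqs ascending frequency grid (Hz).
#' @param times ascending time grid (s).
#' @param fs sampling rate (Hz).
#' @return an object of class `tf_plane`.
#' @export
tf_plane <- function(values, freqs, times, fs) {
  values <- as.matrix(values)
  if (nrow(values) != length(freqs) || ncol(values) != length(times))
    stop("tf_plane dimensions must match the grids", call. = FALSE)
  if (is.unsorted(freqs, strictly = TRUE) || is.unsorted(times, strictly = TRUE))
    stop("tf_plane grids must be strictly increasing", call. = FALSE)
  structure(list(values = values, freqs = freqs, times = times, fs = fs),
            class = "tf_plane")
}

#' @export
print.tf_plane <- function(x, ...) {
  cat(sprintf("<tf_plane> %d freq bins [0, %.3g] Hz x %d time samples (%.2f s)\n",
              length(x$freqs), max(x$freqs), length(x$times),
              max(x$times) - min(x$times) + 1 / x$fs))
  invisible(x)
}

#' Export a time-frequency plane as gzipped delimited text
#'
#' Writes two header lines (`# freqs: ...`, `# times: ...`) followed by the
#' tab-delimited value matrix; intended for inspection and plotting only.
#' @param plane a [tf_plane()].
#' @param path output path (".gz" recommended).
#' @return `path`, invisibly.
#' @export
write_tf_plane <- function(plane, path) {
  con <- gzfile(path, "wt")
  on.exit(close(con))
  writeLines(c(paste("# freqs:", paste(format(plane$freqs, digits = 10),
                                       collapse = "\t")),
               paste("# times:", paste(format(plane$times, digits = 10),
                                       collapse = "\t"))), con)
  utils::write.table(plane$values, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
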