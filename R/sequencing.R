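#' The five canonical EEG band partition
#'
#' delta `[0,4)`, theta `[4,8)`, alpha `[8,13)`, beta `[13,30)`,
#' gamma `[30,50]` Hz.  Intervals are half-open with bin membership decided
#' by bin-centre frequency; gamma is closed at 50 Hz.
#'
#' @param edges numeric vector of 6 ascending band edges (Hz).
#' @return object of class `band_partition`.
#' @export
band_partition <- function(edges = c(0, 4, 8, 13, 30, 50)) {
  if (length(edges) != 6L || is.unsorted(edges, strictly = TRUE))
    stop("band edges must be 6 ascending values", call. = FALSE)
  structure(list(edges = edges, names = rhythm_band_names,
                 symbols = RHYTHM_ALPHABET),
            class = "band_partition")
}

#' Timestamp grid over a segment
#'
#' Uniform timestamps of `interval` seconds (default 0.2 s, the average
#' neuronal reaction time used for sequencing).  A trailing partial
#' timestamp is dropped: `n_stamps = floor(duration / interval)`.
#'
#' @param duration segment duration in seconds.
#' @param interval timestamp length in seconds (> 0).
#' @return object of class `timestamp_grid` with `interval`, `n_stamps`,
#'   `edges`.
#' @export
timestamp_grid <- function(duration, interval = 0.2) {
  if (interval <= 0) stop("interval must be > 0", call. = FALSE)
  n <- floor(duration / interval + 1e-9)
  if (n < 1) stop("segment shorter than one timestamp", call. = FALSE)
  structure(list(interval = interval, n_stamps = n,
                 edges = (0:n) * interval),
            class = "timestamp_grid")
}

#' Mean band power per timestamp box
#'
#' Clips negative plane values to zero (the quadratic transforms are not
#' sign-definite but are read as instantaneous power), then averages over
#' each timestamp x band box.
#'
#' @param plane a [tf_plane()].
#' @param bands a [band_partition()]; its top edge must not exceed the
#'   plane's frequency range.
#' @param grid a [timestamp_grid()]; `NULL` derives it from the plane span.
#' @return `n_stamps x 5` matrix (class `band_power_table`), columns in
#'   delta..gamma order.
#' @export
band_power <- function(plane, bands = band_partition(), grid = NULL) {
  stopifnot(inherits(plane, "tf_plane"))
  dur <- length(plane$times) / plane$fs
  if (is.null(grid)) grid <- timestamp_grid(dur, 0.2)
  if (grid$edges[length(grid$edges)] > dur + 1e-9)
    stop("plane does not cover the timestamp grid", call. = FALSE)
  e <- bands$edges
  if (e[6] > max(plane$freqs) + 1e-9)
    stop("configuration error: gamma upper edge ", e[6],
         " Hz exceeds the plane's frequency range", call. = FALSE)

  # band id per frequency bin (bin-centre membership; gamma closed at top)
  f <- plane$freqs
  band_id <- rep(NA_integer_, length(f))
  for (b in 1:5) {
    inb <- if (b < 5) f >= e[b] & f < e[b + 1] else f >= e[5] & f <= e[6]
    band_id[inb] <- b
  }
  for (b in 1:5) if (!any(band_id == b, na.rm = TRUE))
    stop("configuration error: no frequency bins fall in band ",
         bands$names[b], call. = FALSE)

  # timestamp id per time column, relative to segment start
  t0 <- plane$times - plane$times[1]
  stamp_id <- floor(t0 / grid$interval + 1e-9) + 1L
  keep_t <- stamp_id >= 1L & stamp_id <= grid$n_stamps
  keep_f <- !is.na(band_id)

  v <- pmax(plane$values[keep_f, keep_t, drop = FALSE], 0)
  fb <- band_id[keep_f]
  st <- stamp_id[keep_t]
  sums <- rowsum(t(rowsum(v, fb)), st)             # n_stamps x 5 box sums
  cnt <- outer(tabulate(st, grid$n_stamps), tabulate(fb, 5L))
  m <- sums / cnt
  colnames(m) <- bands$symbols
  structure(m, class = c("band_power_table", class(m)))
}

#' Dominant-rhythm sequence from a band-power table
#'
#' Per timestamp, the band with maximal mean power; ties go to the
#' lower-frequency band (delta < theta < alpha < beta < gamma).
#'
#' @param table `n_stamps x 5` band-power matrix (delta..gamma columns).
#' @param interval timestamp interval in seconds.
#' @param channel,trial_id,subject_id,label metadata carried on the sequence.
#' @return a `rhythm_sequence` object.
#' @export
dominant_sequence <- function(table, interval = 0.2, channel = "CH1",
                              trial_id = "t1", subject_id = "s1",
                              label = NA_character_) {
  m <- unclass(as.matrix(table))
  if (ncol(m) != 5L) stop("band-power table must have 5 columns", call. = FALSE)
  if (any(rowSums(is.finite(m)) == 0L))
    stop("invalid input: a timestamp row has no finite band power",
         call. = FALSE)
  m[!is.finite(m)] <- -Inf
  sym <- RHYTHM_ALPHABET[max.col(m, ties.method = "first")]
  rhythm_sequence(paste(sym, collapse = ""), interval, channel, trial_id,
                  subject_id, label)
}

#' Construct a rhythm sequence object
#'
#' @param symbols single string over the alphabet `D T A B G`.
#' @inheritParams dominant_sequence
#' @return object of class `rhythm_sequence`.
#' @export
rhythm_sequence <- function(symbols, interval = 0.2, channel = "CH1",
                            trial_id = "t1", subject_id = "s1",
                            label = NA_character_) {
  symbols <- as.character(symbols)
  stopifnot(length(symbols) == 1L)
  chars <- strsplit(symbols, "")[[1L]]
  if (length(chars) && !all(chars %in% RHYTHM_ALPHABET))
    stop("sequence contains symbols outside {D,T,A,B,G}", call. = FALSE)
  structure(list(symbols = symbols, interval = interval, channel = channel,
                 trial_id = trial_id, subject_id = subject_id, label = label),
            class = "rhythm_sequence")
}

#' @export
print.rhythm_sequence <- function(x, ...) {
  cat(sprintf("<rhythm_sequence> %s/%s %s (%d symbols @ %g s)%s\n",
              x$subject_id, x$trial_id, x$channel, nchar(x$symbols),
              x$interval,
              if (is.na(x$label)) "" else paste0(" label=", x$label)))
  cat(" ", x$symbols, "\n")
  invisible(x)
}

#' Restrict a segment to the trailing analysis window
#'
#' Trials longer than `window_s` are cut to their final `window_s` seconds
#' (the tail of a trial is the steadier emotional period); shorter trials
#' are rejected so every extracted feature vector comes from the same
#' amount of data.
#'
#' @param seg an [eeg_segment()].
#' @param window_s analysis window in seconds (default 30).
#' @return an [eeg_segment()] of exactly `window_s` seconds.
#' @export
apply_analysis_window <- function(seg, window_s = 30) {
  stopifnot(inherits(seg, "eeg_segment"))
  need <- round(window_s * seg$fs)
  n <- length(seg$samples)
  if (n < need)
    stop("trial ", seg$trial_id, " (channel ", seg$channel, ") is shorter (",
         sprintf("%.2f", n / seg$fs), " s) than the ", window_s,
         " s analysis window", call. = FALSE)
  seg$samples <- seg$samples[(n - need + 1L):n]
  seg
}

#' Sequence one trial segment end to end
#'
#' RSPWVD -> box-averaged band power -> dominant band per 0.2 s timestamp.
#'
#' @inheritParams compute_rspwvd
#' @param bands a [band_partition()].
#' @param interval timestamp interval (s).
#' @return a `rhythm_sequence` with the segment's metadata attached.
#' @export
sequence_trial <- function(seg, spec = NULL, bands = band_partition(),
                           interval = 0.2, block_s = 2, label = NA_character_) {
  plane <- compute_rspwvd(seg, spec, block_s)
  grid <- timestamp_grid(length(seg$samples) / seg$fs, interval)
  bp <- band_power(plane, bands, grid)
  dominant_sequence(bp, interval, seg$channel, seg$trial_id, seg$subject_id,
                    label)
}

# ---- FASTA-like sequence I/O ---------------------------------------------

#' Write rhythm sequences as FASTA-like text
#'
#' One record per sequence, header
#' `>subject|trial|channel|label|interval=<s>`, body the symbol string.
#' @param seqs list of `rhythm_sequence` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(seqs, path) {
  if (inherits(seqs, "rhythm_sequence")) seqs <- list(seqs)
  lines <- unlist(lapply(seqs, function(s)
    c(sprintf(">%s|%s|%s|%s|interval=%g", s$subject_id, s$trial_id,
              s$channel, ifelse(is.na(s$label), "NA", s$label), s$interval),
      s$symbols)))
  writeLines(lines, path)
  invisible(path)
}

#' Read rhythm sequences written by [write_sequences()]
#' @param path input file.
#' @return list of `rhythm_sequence` objects.
#' @export
read_sequences <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  lapply(seq_along(hdr), function(i) {
    fields <- strsplit(sub("^>", "", lines[hdr[i]]), "|", fixed = TRUE)[[1L]]
    body_end <- if (i < length(hdr)) hdr[i + 1L] - 1L else length(lines)
    body <- paste(lines[(hdr[i] + 1L):body_end], collapse = "")
    interval <- as.numeric(sub("interval=", "", fields[5]))
    lab <- if (fields[4] == "NA") NA_character_ else fields[4]
    rhythm_sequence(body, interval, channel = fields[3], trial_id = fields[2],
                    subject_id = fields[1], label = lab)
  })
}
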