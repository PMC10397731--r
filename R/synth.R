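#' Configuration for the synthetic EEG generator
#'
#' The generator states a simple, fully known world: per 0.2 s timestamp the
#' scheduled dominant band's carrier sinusoid plays at `amp_dominant` while
#' the other four band carriers play at `amp_background`, all phase
#' continuous across timestamps, plus white Gaussian noise.  One designated
#' channel carries a class-conditional 3-symbol code motif planted into its
#' schedule at per-timestamp insertion rates `r0`/`r1` (class 1 / class 2).
#'
#' @param fs sampling rate (Hz), default 128 (the common down-sampled EEG
#'   rate).
#' @param channels channel names (10-20 style).
#' @param carriers named carrier frequencies (Hz), one per band, strictly
#'   inside their bands; defaults delta 2, theta 6, alpha 10, beta 20,
#'   gamma 40.
#' @param amp_dominant,amp_background carrier amplitudes (uV);
#'   `amp_dominant > amp_background >= 0`.
#' @param noise_sd white-noise standard deviation (uV).
#' @param duration_s trial duration in seconds (default 30, the analysis
#'   window).
#' @param planted_channel channel receiving the motif (default the first).
#' @param planted_code 3-symbol motif string (default "TGB").
#' @param r0,r1 per-timestamp motif insertion probabilities for the first
#'   and second class.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(fs = 128,
                         channels = c("FP1", "FP2", "F3", "F4", "C3", "C4",
                                      "P3", "O1"),
                         carriers = c(D = 2, T = 6, A = 10, B = 20, G = 40),
                         amp_dominant = 10, amp_background = 2,
                         noise_sd = 1, duration_s = 30,
                         planted_channel = channels[1L],
                         planted_code = "TGB", r0 = 0.05, r1 = 0.35) {
  edges <- band_partition()$edges
  for (b in 1:5) {
    f <- carriers[[RHYTHM_ALPHABET[b]]]
    if (is.null(f) || f <= edges[b] || f >= edges[b + 1])
      stop("config error: carrier for band ", RHYTHM_ALPHABET[b],
           " must lie strictly inside [", edges[b], ", ", edges[b + 1], ") Hz",
           call. = FALSE)
  }
  if (!(amp_dominant > amp_background && amp_background >= 0))
    stop("config error: need amp_dominant > amp_background >= 0",
         call. = FALSE)
  if (r0 < 0 || r0 > 1 || r1 < 0 || r1 > 1)
    stop("config error: insertion rates must lie in [0, 1]", call. = FALSE)
  if (!planted_channel %in% channels)
    stop("config error: planted channel '", planted_channel,
         "' is not in the channel list", call. = FALSE)
  code_index(planted_code)   # validates the motif
  structure(list(fs = fs, channels = channels, carriers = carriers,
                 amp_dominant = amp_dominant,
                 amp_background = amp_background, noise_sd = noise_sd,
                 duration_s = duration_s, planted_channel = planted_channel,
                 planted_code = planted_code, r0 = r0, r1 = r1),
            class = "synth_config")
}

#' Random dominant-band schedule with realistic dwell times
#'
#' Successive rhythm bouts draw a fresh band (never repeating the previous
#' one) and persist for `min_dwell` plus a geometric number of timestamps
#' (mean `mean_dwell`).  Real EEG rhythms persist for several hundred
#' milliseconds, and a dominance epoch must span at least ~0.4 s for the
#' time-bandwidth product to make the dominant band identifiable at the
#' 0.2 s sequencing resolution (a 0.2 s delta epoch holds < half a cycle of
#' its carrier), so per-timestamp i.i.d. schedules would be physically
#' unrecoverable, not merely noisy.
#'
#' @param n_stamps number of 0.2 s timestamps.
#' @param min_dwell minimum bout length in timestamps (default 2).
#' @param mean_dwell mean bout length in timestamps (default 3).
#' @return character vector of symbols over `D T A B G`.
#' @export
random_schedule <- function(n_stamps, min_dwell = 2, mean_dwell = 3) {
  out <- character(0)
  prev <- ""
  while (length(out) < n_stamps) {
    s <- sample(setdiff(RHYTHM_ALPHABET, prev), 1L)
    d <- min_dwell + stats::rgeom(1L, 1 / (mean_dwell - min_dwell + 1))
    out <- c(out, rep(s, d))
    prev <- s
  }
  out[seq_len(n_stamps)]
}

# Plant the motif: scan left to right; an insertion at timestamp t
# overwrites t..t+2 and the scan resumes at t+3, so overlaps are resolved
# in favour of the leftmost insertion and motifs never interleave.
# (Allowing later insertions to overwrite earlier tails would plant a whole
# family of interleaved patterns -- TGT, TTG, ... -- at rates comparable to
# the motif itself, defeating the single-informative-feature design.)
insert_motif <- function(schedule, motif, r) {
  m <- strsplit(motif, "")[[1L]]
  L <- length(schedule)
  if (L < 3L || r <= 0) return(schedule)
  t <- 1L
  while (t <= L - 2L) {
    if (stats::runif(1L) < r) {
      schedule[t:(t + 2L)] <- m
      t <- t + 3L
    } else t <- t + 1L
  }
  schedule
}

#' Synthesise one channel segment from a schedule
#'
#' @param schedule character vector of per-timestamp dominant-band symbols.
#' @param cfg a [synth_config()].
#' @param seed optional integer; when given, generation is wrapped in
#'   [withr::with_seed()] so identical calls are bit-identical.
#' @param channel,trial_id,subject_id metadata for the segment.
#' @return an [eeg_segment()].
#' @export
synth_segment <- function(schedule, cfg = synth_config(), seed = NULL,
                          channel = "CH1", trial_id = "t1",
                          subject_id = "s1") {
  gen <- function() {
    n_stamps <- length(schedule)
    n <- round(n_stamps * 0.2 * cfg$fs)
    t <- (seq_len(n) - 1L) / cfg$fs
    stamp <- pmin(floor(t / 0.2) + 1L, n_stamps)
    x <- numeric(n)
    phases <- stats::runif(5L, 0, 2 * pi)
    for (b in 1:5) {
      sym <- RHYTHM_ALPHABET[b]
      amp <- ifelse(schedule[stamp] == sym, cfg$amp_dominant,
                    cfg$amp_background)
      x <- x + amp * sin(2 * pi * cfg$carriers[[sym]] * t + phases[b])
    }
    if (cfg$noise_sd > 0) x <- x + stats::rnorm(n, 0, cfg$noise_sd)
    x
  }
  x <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  eeg_segment(x, cfg$fs, channel, trial_id, subject_id)
}

#' Synthesise a labelled multichannel dataset
#'
#' Non-planted channels receive class-independent random schedules; the
#' planted channel's schedule gets the configured motif inserted at the
#' class-conditional rate, so exactly one (channel, code) feature carries
#' class signal.  Everything is derived from `seed` for full
#' reproducibility.
#'
#' @param cfg a [synth_config()].
#' @param n_per_class trials per class (a vector recycles over classes).
#' @param classes class labels (2 or 3).
#' @param seed integer seed.
#' @param subject_id subject identifier.
#' @return object of class `synth_dataset`: `segments` (list of trials, each
#'   a named list of [eeg_segment()]s), `labels` (factor), `schedules`,
#'   `cfg`, `seed`.
#' @export
synth_dataset <- function(cfg = synth_config(), n_per_class = 20,
                          classes = c("low", "high"), seed = 1,
                          subject_id = "s1") {
  if (length(classes) < 2L || length(classes) > 3L)
    stop("two or three classes are supported", call. = FALSE)
  n_per_class <- rep_len(n_per_class, length(classes))
  rates <- rep_len(c(cfg$r0, cfg$r1), length(classes))
  labels <- factor(rep(classes, n_per_class), levels = classes)
  n_trials <- length(labels)
  n_stamps <- round(cfg$duration_s / 0.2)

  build <- function() {
    segs <- vector("list", n_trials)
    scheds <- vector("list", n_trials)
    for (i in seq_len(n_trials)) {
      trial <- sprintf("trial%03d", i)
      r <- rates[as.integer(labels[i])]
      scheds[[i]] <- lapply(stats::setNames(cfg$channels, cfg$channels),
        function(ch) {
          s <- random_schedule(n_stamps)
          if (ch == cfg$planted_channel) s <- insert_motif(s,
                                                           cfg$planted_code, r)
          s
        })
      segs[[i]] <- lapply(stats::setNames(cfg$channels, cfg$channels),
        function(ch) synth_segment(scheds[[i]][[ch]], cfg, seed = NULL,
                                   channel = ch, trial_id = trial,
                                   subject_id = subject_id))
    }
    list(segs = segs, scheds = scheds)
  }
  built <- withr::with_seed(as.integer(seed), build())
  structure(list(segments = built$segs, schedules = built$scheds,
                 labels = labels,
                 trials = sprintf("trial%03d", seq_len(n_trials)),
                 cfg = cfg, seed = as.integer(seed),
                 subject_id = subject_id),
            class = "synth_dataset")
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf(
    "<synth_dataset> %s: %d trials x %d channels, %g s @ %g Hz (seed %d)\n",
    x$subject_id, length(x$trials), length(x$cfg$channels),
    x$cfg$duration_s, x$cfg$fs, x$seed))
  cat(sprintf("  planted %s on %s at r = %s per class\n", x$cfg$planted_code,
              x$cfg$planted_channel,
              paste(rep_len(c(x$cfg$r0, x$cfg$r1), nlevels(x$labels)),
                    collapse = "/")))
  invisible(x)
}

#' Sequence every (trial, channel) of a dataset
#'
#' @param ds a `synth_dataset` (or compatible list of segments + labels).
#' @param ... passed to [sequence_trial()].
#' @return flat list of `rhythm_sequence` objects.
#' @export
sequence_dataset <- function(ds, ...) {
  out <- list()
  for (i in seq_along(ds$segments)) {
    lab <- as.character(ds$labels[i])
    for (seg in ds$segments[[i]])
      out[[length(out) + 1L]] <- sequence_trial(seg, label = lab, ...)
  }
  out
}
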