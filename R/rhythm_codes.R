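#' Index of a 3-base rhythm code
#'
#' Fixed bijection between symbol triples and 0..124 by base-5 positional
#' indexing with delta=0, theta=1, alpha=2, beta=3, gamma=4:
#' `index = 25*b1 + 5*b2 + b3`.  So "DDD" -> 0 and "GGG" -> 124.
#'
#' @param code character vector of 3-letter code strings (e.g. "TGB"), or a
#'   length-3 vector of single symbols.
#' @return integer vector of indices in 0..124.
#' @export
code_index <- function(code) {
  if (length(code) == 3L && all(nchar(code) == 1L))
    code <- paste(code, collapse = "")
  if (any(nchar(code) != 3L))
    stop("rhythm codes are exactly 3 symbols", call. = FALSE)
  chars <- matrix(unlist(strsplit(code, "")), nrow = 3L)
  v <- matrix(match(chars, RHYTHM_ALPHABET) - 1L, nrow = 3L)
  if (any(is.na(v)))
    stop("invalid symbol: codes use the alphabet {D,T,A,B,G}", call. = FALSE)
  as.integer(25L * v[1, ] + 5L * v[2, ] + v[3, ])
}

#' Symbol string of a code index
#' @param index integer vector in 0..124.
#' @return character vector of 3-letter code strings.
#' @export
code_symbols <- function(index) {
  index <- as.integer(index)
  if (any(index < 0L | index > 124L))
    stop("code index must lie in 0..124", call. = FALSE)
  paste0(RHYTHM_ALPHABET[index %/% 25L + 1L],
         RHYTHM_ALPHABET[(index %/% 5L) %% 5L + 1L],
         RHYTHM_ALPHABET[index %% 5L + 1L])
}

#' All 125 code strings in index order
#' @return character vector of length 125 ("DDD" ... "GGG").
#' @export
all_codes <- function() code_symbols(0:124)

#' Number of distinct rhythms in a code
#'
#' A code such as "BBB" involves one rhythmic type, "DTD" two, "TGB" three.
#' @param code character vector of 3-letter code strings.
#' @return integer vector in 1..3.
#' @export
rhythm_type_count <- function(code) {
  vapply(strsplit(code, ""), function(ch) {
    if (length(ch) != 3L || !all(ch %in% RHYTHM_ALPHABET))
      stop("invalid symbol: codes use the alphabet {D,T,A,B,G}",
           call. = FALSE)
    length(unique(ch))
  }, integer(1))
}

#' Count 3-base rhythm codes in a sequence
#'
#' Slides a window of three symbols with step one along the sequence and
#' tallies each of the 125 possible codes; a length-L sequence yields
#' exactly `L - 2` windows.  Codes that never occur keep an explicit zero.
#'
#' @param seq a `rhythm_sequence` or a symbol string.
#' @return named integer vector of length 125 (class `code_feature_vector`)
#'   with attributes `seq_length`, `channel`, `trial_id`, `subject_id`.
#' @export
extract_codes <- function(seq) {
  if (inherits(seq, "rhythm_sequence")) {
    s <- seq$symbols
    meta <- seq[c("channel", "trial_id", "subject_id")]
  } else {
    s <- as.character(seq)
    meta <- list(channel = NA, trial_id = NA, subject_id = NA)
  }
  ch <- strsplit(s, "")[[1L]]
  L <- length(ch)
  if (L < 3L)
    stop("sequence too short: need at least 3 symbols for one code",
         call. = FALSE)
  v <- match(ch, RHYTHM_ALPHABET) - 1L
  if (any(is.na(v)))
    stop("invalid symbol: sequence uses the alphabet {D,T,A,B,G}",
         call. = FALSE)
  idx <- 25L * v[1:(L - 2L)] + 5L * v[2:(L - 1L)] + v[3:L]   # 0..124
  counts <- tabulate(idx + 1L, nbins = 125L)
  names(counts) <- all_codes()
  structure(counts, seq_length = L, channel = meta$channel,
            trial_id = meta$trial_id, subject_id = meta$subject_id,
            class = c("code_feature_vector", "integer"))
}

#' Assemble the trials x (channel, code) feature table
#'
#' One row per trial, 125 count columns per channel (so 32 channels give
#' 4000 columns and 62 give 7750), named `<CH>:<code>`.  All trials must
#' share the same channel set and sequence length; per channel every row
#' sums to `L - 2`.
#'
#' @param sequences list of `rhythm_sequence` objects covering every
#'   (trial, channel) pair.
#' @param labels optional named vector of per-trial class labels; if absent,
#'   labels are taken from the sequences themselves.
#' @return object of class `feature_table`: list with `counts` (matrix),
#'   `labels` (factor), `trials`, `channels`, `subject`, `seq_length`.
#' @export
build_feature_table <- function(sequences, labels = NULL) {
  stopifnot(length(sequences) > 0L)
  meta <- data.frame(
    trial = vapply(sequences, `[[`, "", "trial_id"),
    channel = vapply(sequences, `[[`, "", "channel"),
    subject = vapply(sequences, `[[`, "", "subject_id"),
    label = vapply(sequences, function(s) as.character(s$label), ""),
    len = vapply(sequences, function(s) nchar(s$symbols), 0L),
    stringsAsFactors = FALSE)
  trials <- unique(meta$trial)
  channels <- unique(meta$channel)
  if (length(unique(meta$len)) != 1L)
    stop("inconsistency: sequences have unequal lengths (",
         paste(unique(meta$len), collapse = ", "),
         "); equalise the analysis window upstream", call. = FALSE)
  key <- paste(meta$trial, meta$channel, sep = "\r")
  if (anyDuplicated(key))
    stop("inconsistency: duplicated (trial, channel) sequences", call. = FALSE)
  full <- as.vector(outer(trials, channels, paste, sep = "\r"))
  if (!setequal(key, full)) {
    missing <- setdiff(full, key)
    stop("inconsistency: ragged channel sets; missing (trial, channel) pairs: ",
         paste(gsub("\r", "/", utils::head(missing, 5L)), collapse = ", "),
         call. = FALSE)
  }

  counts <- matrix(0L, nrow = length(trials),
                   ncol = length(channels) * 125L,
                   dimnames = list(trials,
                                   as.vector(t(outer(channels, all_codes(),
                                                     paste, sep = ":")))))
  for (i in seq_along(sequences)) {
    s <- sequences[[i]]
    cols <- (match(s$channel, channels) - 1L) * 125L + 1:125
    counts[match(s$trial_id, trials), cols] <- as.integer(extract_codes(s))
  }

  if (is.null(labels)) {
    lab <- meta$label[match(trials, meta$trial)]
  } else {
    lab <- as.character(labels[trials])
    if (any(is.na(lab)))
      stop("labels missing for trials: ",
           paste(trials[is.na(lab)], collapse = ", "), call. = FALSE)
  }
  structure(list(counts = counts, labels = factor(lab), trials = trials,
                 channels = channels, subject = meta$subject[1L],
                 seq_length = meta$len[1L]),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table> subject %s: %d trials x %d channels x 125 codes = %d columns (L = %d)\n",
    x$subject, length(x$trials), length(x$channels), ncol(x$counts),
    x$seq_length))
  cat("  labels:", paste(sprintf("%s=%d", levels(x$labels),
                                 tabulate(x$labels)), collapse = " "), "\n")
  invisible(x)
}

#' Write a feature table as CSV
#'
#' Header `subject,trial,label,<CH>:<code>,...`; integer counts round-trip
#' bit-exactly through [read_feature_table()].
#' @param ftable a `feature_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ftable, path) {
  df <- data.frame(subject = ftable$subject, trial = ftable$trials,
                   label = as.character(ftable$labels),
                   ftable$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path input CSV.
#' @return a `feature_table`.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  cnt <- as.matrix(df[, -(1:3), drop = FALSE])
  storage.mode(cnt) <- "integer"
  rownames(cnt) <- df$trial
  channels <- unique(sub(":.*$", "", colnames(cnt)))
  L <- sum(cnt[1L, 1:125]) + 2L
  structure(list(counts = cnt, labels = factor(df$label), trials = df$trial,
                 channels = channels, subject = df$subject[1L],
                 seq_length = L),
            class = "feature_table")
}
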