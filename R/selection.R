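#' One-way fixed-effects ANOVA screen
#'
#' F statistic and p-value for a scalar feature against the class labels,
#' with `(k - 1, N - k)` degrees of freedom.  Identical groups (zero
#' between-group variance) give `F = 0, p = 1`; a perfectly separated
#' feature with zero within-group variance gives `F = Inf, p = 0`.
#' Screening is reported, not enforced: a feature failing `p <= 0.05` is
#' flagged downstream, never removed.
#'
#' @param x per-trial feature values.
#' @param labels per-trial class labels (>= 2 groups of >= 2 trials each).
#' @return list with `F`, `p`, `df1`, `df2`.
#' @export
anova_screen <- function(x, labels) {
  labels <- droplevels(if (is.factor(labels)) labels else factor(labels))
  k <- nlevels(labels)
  n <- length(x)
  if (k < 2L) stop("ANOVA needs at least 2 groups", call. = FALSE)
  if (any(tabulate(labels, k) < 2L))
    stop("every group needs at least 2 trials", call. = FALSE)
  gm <- tapply(x, labels, mean)
  gn <- tabulate(labels, k)
  ssb <- sum(gn * (gm - mean(x))^2)
  ssw <- sum((x - gm[as.integer(labels)])^2)
  df1 <- k - 1L
  df2 <- n - k
  if (ssb <= 0) return(list(F = 0, p = 1, df1 = df1, df2 = df2))
  if (ssw <= 0) return(list(F = Inf, p = 0, df1 = df1, df2 = df2))
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}

#' Scalp region of a 10-20/10-10 channel name
#'
#' Deterministic prefix mapping, longest prefix first, midline `Z` and
#' digits ignored: FP/AF/F -> frontal, FC/C -> central, CP/P -> parietal,
#' FT/TP/T -> temporal, PO/O -> occipital.
#'
#' @param channel character vector of channel names.
#' @return character vector of regions.
#' @export
scalp_region <- function(channel) {
  map <- c(FP = "frontal", AF = "frontal", FT = "temporal", TP = "temporal",
           FC = "central", CP = "parietal", PO = "occipital",
           F = "frontal", C = "central", P = "parietal", T = "temporal",
           O = "occipital")
  vapply(channel, function(ch) {
    base <- gsub("[0-9ZHz]+$", "", toupper(ch))
    hit <- names(map)[match(base, names(map))]
    if (is.na(hit))
      stop("unmapped channel: no scalp region for '", ch, "'", call. = FALSE)
    unname(map[hit])
  }, character(1), USE.NAMES = FALSE)
}

#' Best code on one channel
#'
#' From that channel's 125 accuracy records, the argmax by accuracy; ties go
#' to the lowest code index.
#'
#' @param records data.frame of accuracy records (as from
#'   [evaluate_features()]) for a single channel and classifier.
#' @return one-row data.frame: the channel-specific feature.
#' @export
best_code_per_channel <- function(records) {
  if (length(unique(records$channel)) != 1L)
    stop("records must cover exactly one channel", call. = FALSE)
  if (!setequal(records$code, all_codes()) || nrow(records) != 125L)
    stop("incomplete evaluation: expected one record per 125 codes, got ",
         nrow(records), call. = FALSE)
  ord <- order(-records$accuracy, code_index(records$code))
  records[ord[1L], , drop = FALSE]
}

#' The single optimal channel-specific feature
#'
#' Argmax by accuracy across the channel-specific features; ties go to the
#' channel appearing earlier in `channel_order`, then to the lower code
#' index.
#'
#' @param channel_features data.frame with one row per channel (from
#'   [best_code_per_channel()]).
#' @param channel_order recording's channel order used for tie-breaking
#'   (default: order of appearance).
#' @return one-row data.frame.
#' @export
optimal_feature <- function(channel_features,
                            channel_order = unique(channel_features$channel)) {
  if (nrow(channel_features) < 1L)
    stop("no channel-specific features to select from", call. = FALSE)
  ord <- order(-channel_features$accuracy,
               match(channel_features$channel, channel_order),
               code_index(channel_features$code))
  channel_features[ord[1L], , drop = FALSE]
}

#' Two-phase selection with ANOVA screening
#'
#' Phase 1: the best code per channel.  Phase 2: the best channel-specific
#' feature overall.  Each selected feature is screened by [anova_screen()]
#' at `alpha` (reported via `significant`, never removed).
#'
#' @param records data.frame from [evaluate_features()].
#' @param ftable the `feature_table` the records were computed from.
#' @param alpha significance level for the screen (default 0.05).
#' @return object of class `selection_report`: `per_channel` (data.frame
#'   with ANOVA columns), `optimal` (one row), `alpha`.
#' @export
select_features <- function(records, ftable, alpha = 0.05) {
  stopifnot(inherits(ftable, "feature_table"))
  per_channel <- do.call(rbind, lapply(ftable$channels, function(ch)
    best_code_per_channel(records[records$channel == ch, , drop = FALSE])))
  rownames(per_channel) <- NULL
  an <- lapply(seq_len(nrow(per_channel)), function(i) {
    col <- paste0(per_channel$channel[i], ":", per_channel$code[i])
    anova_screen(ftable$counts[, col], ftable$labels)
  })
  per_channel$anova_F <- vapply(an, `[[`, numeric(1), "F")
  per_channel$anova_p <- vapply(an, `[[`, numeric(1), "p")
  per_channel$significant <- per_channel$anova_p <= alpha
  opt <- optimal_feature(per_channel, ftable$channels)
  structure(list(per_channel = per_channel, optimal = opt, alpha = alpha,
                 subject = ftable$subject),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> subject %s: %d channels\n", x$subject,
              nrow(x$per_channel)))
  cat(sprintf(
    "  optimal feature: %s:%s (%s), LOTO accuracy %.3f, ANOVA p = %.3g%s\n",
    x$optimal$channel, x$optimal$code, x$optimal$classifier,
    x$optimal$accuracy, x$optimal$anova_p,
    if (x$optimal$significant) "" else sprintf(" (fails %.2f screen)",
                                               x$alpha)))
  invisible(x)
}

#' Region and rhythm-type tallies over selected features
#'
#' Summarises optimal channel-specific features across subjects the way a
#' cohort table would: percentage of features per scalp region and per
#' number of distinct rhythmic types (1, 2 or 3).  Each table sums to 100%.
#'
#' @param selected data.frame with `channel` and `code` columns, one row per
#'   selected feature (subject).
#' @return list with `n`, `region` and `rhythm_types` percentage tables.
#' @export
summarize_selection <- function(selected) {
  if (nrow(selected) < 1L) stop("no selected features", call. = FALSE)
  regions <- c("frontal", "central", "parietal", "temporal", "occipital")
  reg <- factor(scalp_region(selected$channel), levels = regions)
  types <- factor(rhythm_type_count(selected$code), levels = 1:3)
  list(n = nrow(selected),
       region = 100 * table(reg) / nrow(selected),
       rhythm_types = 100 * table(types) / nrow(selected))
}
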