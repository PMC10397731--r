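#' Classifier specification
#'
#' The four classical classifiers used to score rhythm-code features.
#' Multiclass handling: one-vs-one pairwise voting for `svm_rbf` and `lda`,
#' inherent softmax for `logreg`, inherent neighbour vote for `knn`.
#'
#' @param kind one of `"svm_rbf"`, `"knn"`, `"lda"`, `"logreg"`.
#' @param k neighbours for k-NN (positive odd; 5 suits 40/45-trial designs,
#'   3 suits 20-trial designs).
#' @param C soft-margin cost for the SVM (> 0).
#' @param gamma RBF width; `NULL` uses `1 / (n_features * var(train))` on the
#'   standardised training values.
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("svm_rbf", "knn", "lda", "logreg"),
                            k = 5, C = 1, gamma = NULL) {
  kind <- match.arg(kind)
  if (kind == "knn" && (k < 1 || k %% 2 == 0))
    stop("k must be a positive odd integer", call. = FALSE)
  if (C <= 0 || (!is.null(gamma) && gamma <= 0))
    stop("C and gamma must be > 0", call. = FALSE)
  structure(list(kind = kind, k = as.integer(k), C = C, gamma = gamma),
            class = "classifier_spec")
}

#' Recommended k-NN neighbourhood size for a trial design
#'
#' Near the square root of the training-set size, odd: 5 for 40- and
#' 45-trial designs, 3 for 20-trial designs.
#' @param n_trials trials in the design.
#' @return odd integer.
#' @export
default_k <- function(n_trials) {
  k <- round(sqrt(n_trials - 1))
  k <- if (k %% 2 == 0) k - 1 else k
  max(3L, as.integer(k))
}

#' Leave-one-trial-out folds
#'
#' `n_trials` folds; fold `i` trains on every trial except `i` and tests on
#' `i`, so each trial is the test set exactly once.
#' @param n_trials number of trials (>= 3).
#' @return list of `list(train, test)` index sets.
#' @export
loto_folds <- function(n_trials) {
  if (n_trials < 3) stop("too few trials: LOTO-CV needs at least 3",
                         call. = FALSE)
  lapply(seq_len(n_trials), function(i)
    list(train = setdiff(seq_len(n_trials), i), test = i))
}

# majority class of a factor; ties resolved to the lowest class index
majority_label <- function(y) levels(y)[which.max(tabulate(y, nlevels(y)))]

# ---- individual classifiers (scalar features, pre-standardised) ----------

predict_knn <- function(xtr, ytr, xte, k) {
  k <- min(k, length(xtr))
  lev <- levels(ytr)
  vapply(xte, function(x0) {
    d <- abs(xtr - x0)
    nb <- order(d)[seq_len(k)]            # stable: distance ties by index
    votes <- tabulate(ytr[nb], length(lev))
    top <- which(votes == max(votes))
    if (length(top) > 1L) {               # vote tie: smallest summed distance
      sums <- vapply(top, function(cl) sum(d[nb][ytr[nb] == lev[cl]]),
                     numeric(1))
      top <- top[sums == min(sums)]
    }
    lev[top[1L]]                          # remaining ties: lowest class index
  }, character(1))
}

predict_svm_binary <- function(xtr, ytr, xte, C, gamma) {
  lev <- levels(ytr)
  y <- ifelse(as.integer(ytr) == 1L, -1, 1)
  if (is.null(gamma)) {
    v <- stats::var(xtr)
    gamma <- if (v > 0) 1 / v else 1
  }
  dec <- svm_rbf_decision_cpp(xtr, y, xte, C, gamma)
  ifelse(dec > 0, lev[2L], lev[1L])
}

predict_lda_binary <- function(xtr, ytr, xte) {
  lev <- levels(ytr)
  n <- length(xtr)
  mu <- vapply(lev, function(l) mean(xtr[ytr == l]), numeric(1))
  nc <- tabulate(ytr, 2L)
  ss <- vapply(lev, function(l) sum((xtr[ytr == l] - mean(xtr[ytr == l]))^2),
               numeric(1))
  s2 <- sum(ss) / (n - 2L)
  if (!is.finite(s2) || s2 <= 0) return(rep(majority_label(ytr), length(xte)))
  sc <- outer(xte, mu / s2) - rep(mu^2 / (2 * s2), each = length(xte)) +
    rep(log(nc / n), each = length(xte))
  lev[max.col(sc, ties.method = "first")]
}

predict_logreg <- function(xtr, ytr, xte, tol = 1e-8, max_iter = 1000L) {
  lev <- levels(ytr)
  K <- length(lev)
  X <- cbind(1, xtr)
  Y <- outer(as.integer(ytr), 2:K, `==`) * 1          # n x (K-1)
  B <- matrix(0, 2L, K - 1L)
  for (iter in seq_len(max_iter)) {
    eta <- pmin(pmax(X %*% B, -30), 30)
    E <- exp(eta)
    P <- E / (1 + rowSums(E))                         # n x (K-1)
    G <- as.vector(crossprod(X, Y - P))               # gradient, 2(K-1)
    H <- matrix(0, 2 * (K - 1L), 2 * (K - 1L))
    for (j in seq_len(K - 1L)) for (l in seq_len(K - 1L)) {
      w <- if (j == l) P[, j] * (1 - P[, j]) else -P[, j] * P[, l]
      H[(2 * j - 1):(2 * j), (2 * l - 1):(2 * l)] <-
        crossprod(X, X * w)
    }
    step <- tryCatch(solve(H + diag(1e-10, nrow(H)), G),
                     error = function(e) rep(0, length(G)))
    B <- B + matrix(step, 2L, K - 1L)
    if (max(abs(step)) < tol) break
  }
  eta <- pmin(pmax(cbind(1, xte) %*% B, -30), 30)
  probs <- cbind(1, exp(eta)) / (1 + rowSums(exp(eta)))
  lev[max.col(probs, ties.method = "first")]
}

# one-vs-one pairwise voting; vote ties go to the lowest class index
predict_ovo <- function(binary_fn, xtr, ytr, xte) {
  lev <- levels(ytr)
  votes <- matrix(0L, length(xte), length(lev))
  for (a in 1:(length(lev) - 1L)) for (b in (a + 1L):length(lev)) {
    sel <- ytr %in% lev[c(a, b)]
    ysub <- factor(as.character(ytr[sel]), levels = lev[c(a, b)])
    pred <- binary_fn(xtr[sel], ysub, xte)
    votes[, a] <- votes[, a] + (pred == lev[a])
    votes[, b] <- votes[, b] + (pred == lev[b])
  }
  lev[max.col(votes, ties.method = "first")]
}

#' Train on one fold and predict held-out trials
#'
#' Scalar feature values are standardised by the training fold's mean and
#' standard deviation (no leakage).  Degenerate folds -- a zero-variance
#' training feature, or a single-class training fold -- fall back to the
#' training majority label (lowest class index on ties) with a warning.
#'
#' @param spec a [classifier_spec()].
#' @param train_x,train_y training feature values and labels (factor).
#' @param test_x held-out feature value(s).
#' @return character vector of predicted labels.
#' @export
fit_predict <- function(spec, train_x, train_y, test_x) {
  stopifnot(inherits(spec, "classifier_spec"))
  train_y <- if (is.factor(train_y)) droplevels(train_y) else factor(train_y)
  if (nlevels(train_y) < 2L) {
    warning("single-class training fold: predicting the majority label",
            call. = FALSE)
    return(rep(as.character(train_y[1L]), length(test_x)))
  }
  mu <- mean(train_x)
  s <- stats::sd(train_x)
  if (!is.finite(s) || s == 0) {
    warning("zero-variance training feature: predicting the majority label",
            call. = FALSE)
    return(rep(majority_label(train_y), length(test_x)))
  }
  xtr <- (train_x - mu) / s
  xte <- (test_x - mu) / s
  switch(spec$kind,
    knn = predict_knn(xtr, train_y, xte, spec$k),
    svm_rbf = if (nlevels(train_y) == 2L)
      predict_svm_binary(xtr, train_y, xte, spec$C, spec$gamma)
    else
      predict_ovo(function(a, b, c)
        predict_svm_binary(a, b, c, spec$C, spec$gamma), xtr, train_y, xte),
    lda = if (nlevels(train_y) == 2L)
      predict_lda_binary(xtr, train_y, xte)
    else
      predict_ovo(predict_lda_binary, xtr, train_y, xte),
    logreg = predict_logreg(xtr, train_y, xte))
}

#' LOTO-CV accuracy of one scalar feature
#'
#' Runs [loto_folds()] over the trials, fitting the classifier on each
#' training fold and predicting the held-out trial; accuracy is the exact
#' fraction of correctly predicted folds.
#'
#' @param x per-trial feature values (one code's counts).
#' @param labels per-trial class labels (>= 2 classes).
#' @param spec a [classifier_spec()].
#' @param channel,code metadata recorded on the result.
#' @return object of class `accuracy_record`: `accuracy`, `predictions`,
#'   `n_trials`, `n_degenerate`, plus metadata.
#' @export
loto_cv_accuracy <- function(x, labels, spec, channel = NA, code = NA) {
  labels <- if (is.factor(labels)) labels else factor(labels)
  n <- length(x)
  if (length(labels) != n) stop("labels must match trials", call. = FALSE)
  if (nlevels(droplevels(labels)) < 2L)
    stop("label set has a single class; refusing to evaluate", call. = FALSE)
  folds <- loto_folds(n)
  preds <- character(n)
  ndeg <- 0L
  if (stats::sd(x) == 0) {
    # constant feature: every fold is degenerate, prediction is the majority
    # of the remaining n-1 labels (ties to the lowest class index)
    ndeg <- n
    cnt <- tabulate(labels, nlevels(labels))
    for (i in seq_len(n)) {
      ci <- cnt
      ci[as.integer(labels[i])] <- ci[as.integer(labels[i])] - 1L
      preds[i] <- levels(labels)[which.max(ci)]
    }
  } else {
    for (f in folds) {
      p <- withCallingHandlers(
        fit_predict(spec, x[f$train], labels[f$train], x[f$test]),
        warning = function(w) {
          ndeg <<- ndeg + 1L
          invokeRestart("muffleWarning")
        })
      preds[f$test] <- p
    }
  }
  structure(list(accuracy = mean(preds == as.character(labels)),
                 predictions = preds, n_trials = n, n_degenerate = ndeg,
                 channel = channel, code = code, classifier = spec$kind),
            class = "accuracy_record")
}

#' Score every (channel, code) feature of a table
#'
#' One LOTO-CV accuracy per feature column.  Identical columns are evaluated
#' once and the record reused.
#'
#' @param ftable a `feature_table`.
#' @param spec a [classifier_spec()].
#' @param channels optional subset of channels to score.
#' @return data.frame `channel, code, classifier, accuracy, n_trials,
#'   n_degenerate` with the per-feature fold predictions attached as the
#'   `"predictions"` attribute (trials x features character matrix).
#' @export
evaluate_features <- function(ftable, spec = classifier_spec("svm_rbf"),
                              channels = NULL) {
  stopifnot(inherits(ftable, "feature_table"))
  if (is.null(channels)) channels <- ftable$channels
  cols <- as.vector(t(outer(channels, all_codes(), paste, sep = ":")))
  m <- ftable$counts[, cols, drop = FALSE]
  labels <- ftable$labels
  cache <- new.env(parent = emptyenv())
  n <- nrow(m)
  preds <- matrix(NA_character_, n, ncol(m), dimnames = list(NULL, cols))
  acc <- numeric(ncol(m))
  ndeg <- integer(ncol(m))
  for (j in seq_len(ncol(m))) {
    key <- paste(m[, j], collapse = ",")
    rec <- cache[[key]]
    if (is.null(rec)) {
      rec <- loto_cv_accuracy(m[, j], labels, spec)
      cache[[key]] <- rec
    }
    acc[j] <- rec$accuracy
    ndeg[j] <- rec$n_degenerate
    preds[, j] <- rec$predictions
  }
  out <- data.frame(
    channel = rep(channels, each = 125L),
    code = rep(all_codes(), length(channels)),
    classifier = spec$kind, accuracy = acc, n_trials = n,
    n_degenerate = ndeg, stringsAsFactors = FALSE)
  attr(out, "predictions") <- preds
  out
}

#' Majority vote over all features
#'
#' The all-features baseline: per trial, the modal predicted class across
#' every feature's LOTO prediction (ties to the lowest class index).
#'
#' @param predictions trials x features character matrix of fold
#'   predictions (the `"predictions"` attribute of [evaluate_features()]).
#' @param labels per-trial true labels.
#' @return list with `predictions` (per-trial vote winners) and `accuracy`.
#' @export
majority_vote_all_features <- function(predictions, labels) {
  labels <- if (is.factor(labels)) labels else factor(labels)
  lev <- levels(labels)
  voted <- apply(predictions, 1L, function(p) {
    lev[which.max(tabulate(factor(p, levels = lev), length(lev)))]
  })
  list(predictions = voted, accuracy = mean(voted == as.character(labels)))
}

#' Write accuracy records as CSV
#' @param records data.frame from [evaluate_features()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_accuracy_records <- function(records, path) {
  utils::write.csv(records[, c("channel", "code", "classifier", "accuracy",
                               "n_trials")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
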