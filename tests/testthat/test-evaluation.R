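test_that("LOTO folds partition trials with train size n - 1", {
  f3 <- loto_folds(3)
  expect_equal(f3, list(list(train = c(2L, 3L), test = 1L),
                        list(train = c(1L, 3L), test = 2L),
                        list(train = c(1L, 2L), test = 3L)))
  f40 <- loto_folds(40)
  expect_length(f40, 40)
  expect_true(all(vapply(f40, function(f) length(f$train), 0L) == 39L))
  expect_equal(sort(vapply(f40, `[[`, 0L, "test")), 1:40)
  expect_error(loto_folds(2), "too few")
})

test_that("classifiers recover perfectly separated scalars", {
  withr::with_seed(31, {
    x <- c(rnorm(20, 0, 0.3), rnorm(20, 10, 0.3))
    y <- factor(rep(c("lo", "hi"), each = 20), levels = c("lo", "hi"))
    for (kind in c("knn", "svm_rbf", "lda", "logreg")) {
      spec <- classifier_spec(kind, k = 5)
      expect_equal(fit_predict(spec, x, y, c(-0.1, 10.2)), c("lo", "hi"),
                   info = kind)
      rec <- loto_cv_accuracy(x, y, spec)
      expect_equal(rec$accuracy, 1, info = kind)
    }
  })
})

test_that("degenerate folds fall back to the training majority", {
  y <- factor(c("a", "a", "b", "a"), levels = c("a", "b"))
  spec <- classifier_spec("svm_rbf")
  expect_warning(p <- fit_predict(spec, rep(2, 4), y, 5), "zero-variance")
  expect_equal(p, "a")
  expect_warning(p1 <- fit_predict(spec, 1:3, factor(rep("b", 3)), 2),
                 "single-class")
  expect_equal(p1, "b")

  # balanced constant feature under LOTO: the held-out trial's class is
  # always the training minority, so every fold is predicted wrong
  yb <- factor(rep(c("a", "b"), each = 20))
  rec <- loto_cv_accuracy(rep(1, 40), yb, classifier_spec("knn", k = 5))
  expect_equal(rec$accuracy, 0)
  expect_equal(rec$n_degenerate, 40L)
})

test_that("three-class OVO matches an independent pairwise-vote tally", {
  withr::with_seed(41, {
    x <- c(rnorm(12, 0, 0.4), rnorm(12, 6, 0.4), rnorm(12, 12, 0.4))
    y <- factor(rep(c("neg", "neu", "pos"), each = 12),
                levels = c("neg", "neu", "pos"))
    xte <- c(0.1, 6.2, 11.8)
    for (kind in c("svm_rbf", "lda")) {
      spec <- classifier_spec(kind)
      got <- fit_predict(spec, x, y, xte)
      expect_equal(got, c("neg", "neu", "pos"), info = kind)
      # independent tally: run each pairwise binary fit through
      # fit_predict on the two-class subset and count votes by hand
      lev <- levels(y)
      votes <- matrix(0, length(xte), 3, dimnames = list(NULL, lev))
      for (a in 1:2) for (b in (a + 1):3) {
        sel <- y %in% lev[c(a, b)]
        p <- fit_predict(spec, x[sel],
                         factor(as.character(y[sel]), levels = lev[c(a, b)]),
                         xte)
        for (i in seq_along(p)) votes[i, p[i]] <- votes[i, p[i]] + 1
      }
      expect_equal(lev[apply(votes, 1, which.max)], got, info = kind)
    }
  })
})

test_that("two-class OVO reduces to the plain binary classifier", {
  withr::with_seed(43, {
    x <- rnorm(30)
    y <- factor(rep(c("a", "b"), 15), levels = c("a", "b"))
    xte <- rnorm(10)
    xs <- (x - mean(x)) / sd(x)
    xts <- (xte - mean(x)) / sd(x)
    expect_equal(
      rhythmcode:::predict_ovo(function(a, b, c)
        rhythmcode:::predict_svm_binary(a, b, c, 1, NULL), xs, y, xts),
      rhythmcode:::predict_svm_binary(xs, y, xts, 1, NULL))
    expect_equal(rhythmcode:::predict_ovo(rhythmcode:::predict_lda_binary,
                                          xs, y, xts),
                 rhythmcode:::predict_lda_binary(xs, y, xts))
  })
})

test_that("no spurious skill on permuted labels (one-sided chance band)", {
  # LOTO is pessimistically biased for uninformative features (the held-out
  # class is under-represented in training), so permuted-label accuracy sits
  # at or BELOW chance; spurious skill above the chance band would be a bug.
  withr::with_seed(47, {
    x <- rnorm(20)
    y <- factor(rep(c("a", "b"), 10))
    for (kind in c("knn", "svm_rbf", "lda", "logreg")) {
      spec <- classifier_spec(kind, k = 5)
      accs <- replicate(50, loto_cv_accuracy(x, sample(y), spec)$accuracy)
      band <- 2.576 * sqrt(0.25 / (50 * 20))
      expect_lte(mean(accs), 0.5 + band)
    }
  })
})

test_that("accuracy records are deterministic and exact fractions", {
  withr::with_seed(53, {
    x <- rpois(24, 4)
    y <- factor(rep(c("a", "b"), 12))
    for (kind in c("knn", "svm_rbf", "lda", "logreg")) {
      spec <- classifier_spec(kind, k = 3)
      r1 <- loto_cv_accuracy(x, y, spec)
      r2 <- loto_cv_accuracy(x, y, spec)
      expect_identical(r1, r2, info = kind)
      expect_equal(r1$accuracy, mean(r1$predictions == as.character(y)))
      expect_gte(r1$accuracy, 0); expect_lte(r1$accuracy, 1)
    }
    expect_error(loto_cv_accuracy(x, factor(rep("a", 24)),
                                  classifier_spec("knn")), "single class")
  })
})

test_that("majority vote tallies modal predictions with declared ties", {
  y <- factor(c("a", "b"), levels = c("a", "b"))
  unan <- matrix("b", 2, 5)
  expect_equal(majority_vote_all_features(unan, y)$predictions,
               c("b", "b"))
  tie <- matrix(c("a", "b", "b", "a"), 2, 2)   # one vote each per trial
  expect_equal(majority_vote_all_features(tie, y)$predictions, c("a", "a"))
  expect_equal(majority_vote_all_features(tie, y)$accuracy, 0.5)
})

test_that("feature-table scan returns one record per (channel, code)", {
  withr::with_seed(59, {
    ft <- build_feature_table(make_subject_sequences(12, c("FP1", "O1"), 60))
    rec <- evaluate_features(ft, classifier_spec("knn", k = 3))
    expect_equal(nrow(rec), 250L)
    expect_equal(unique(rec$n_trials), 12L)
    expect_true(all(rec$accuracy >= 0 & rec$accuracy <= 1))
    preds <- attr(rec, "predictions")
    expect_equal(dim(preds), c(12L, 250L))
    # spot-check one column against a direct evaluation
    col <- "FP1:DTA"
    direct <- loto_cv_accuracy(ft$counts[, col], ft$labels,
                               classifier_spec("knn", k = 3))
    expect_equal(rec$accuracy[rec$channel == "FP1" & rec$code == "DTA"],
                 direct$accuracy)
  })
})
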