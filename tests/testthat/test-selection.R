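test_that("ANOVA screen: degenerate cases and the F = t^2 identity", {
  y <- factor(rep(c("a", "b"), each = 10))
  r <- anova_screen(rep(2, 20), y)
  expect_equal(r$F, 0)
  expect_equal(r$p, 1)

  withr::with_seed(61, {
    for (i in 1:20) {
      x <- rnorm(20, mean = rep(c(0, runif(1, 0, 2)), each = 10))
      r <- anova_screen(x, y)
      tt <- stats::t.test(x[1:10], x[11:20], var.equal = TRUE)
      expect_equal(r$F, unname(tt$statistic)^2, tolerance = 1e-10)
      expect_equal(r$p, tt$p.value, tolerance = 1e-10)
    }
  })
  expect_error(anova_screen(1:5, factor(c("a", "a", "a", "a", "b"))),
               "at least 2 trials")
  expect_error(anova_screen(1:5, factor(rep("a", 5))), "2 groups")
})

test_that("ANOVA null p-values are uniform; planted shifts match power", {
  y <- factor(rep(c("a", "b"), each = 20))
  withr::with_seed(67, {
    ps <- replicate(500, anova_screen(rnorm(40), y)$p)
    expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)

    # mean shift of 1.5 sd: rejection rate within the 95% band around the
    # analytic power of the equal-variance two-sample t test
    rej <- mean(replicate(200,
      anova_screen(rnorm(40, rep(c(0, 1.5), each = 20)), y)$p <= 0.05))
    pow <- stats::power.t.test(n = 20, delta = 1.5, sd = 1,
                               sig.level = 0.05)$power
    expect_lt(abs(rej - pow), 1.96 * sqrt(pow * (1 - pow) / 200) + 1e-9)
  })
})

test_that("scalp regions map by declared channel-name prefixes", {
  expect_equal(scalp_region(c("FP1", "AF3", "F7", "FZ")), rep("frontal", 4))
  expect_equal(scalp_region(c("FC1", "C3", "CZ")), rep("central", 3))
  expect_equal(scalp_region(c("CP2", "P8", "PZ")), rep("parietal", 3))
  expect_equal(scalp_region(c("T7", "FT9", "TP10")), rep("temporal", 3))
  expect_equal(scalp_region(c("O1", "OZ", "PO4")), rep("occipital", 3))
  expect_error(scalp_region("XX3"), "unmapped")
})

test_that("per-channel best and overall optimum follow declared tie rules", {
  recs <- data.frame(channel = "FP1", code = all_codes(),
                     classifier = "svm_rbf", accuracy = 0.5,
                     n_trials = 40, stringsAsFactors = FALSE)
  recs$accuracy[recs$code == "TGB"] <- 0.9
  expect_equal(best_code_per_channel(recs)$code, "TGB")
  # tie: base-5 ordering is D<T<A<B<G, so DTA (index 7) < TGB (index 48)
  recs$accuracy[recs$code == "DTA"] <- 0.9
  expect_equal(best_code_per_channel(recs)$code, "DTA")
  expect_error(best_code_per_channel(recs[-1, ]), "incomplete")

  cf <- data.frame(channel = c("CP2", "FP1", "O1"),
                   code = c("TGB", "AAA", "DDD"),
                   accuracy = c(0.8, 0.8, 0.6), stringsAsFactors = FALSE)
  # tie between CP2 and FP1: recording order decides
  expect_equal(optimal_feature(cf, c("FP1", "CP2", "O1"))$channel, "FP1")
  expect_equal(optimal_feature(cf, c("CP2", "FP1", "O1"))$channel, "CP2")
  expect_equal(optimal_feature(cf[3, , drop = FALSE])$channel, "O1")
  expect_error(optimal_feature(cf[0, ]), "no channel")

  # adding channels never lowers the selected optimum
  withr::with_seed(71, {
    accs <- runif(20)
    cf2 <- data.frame(channel = sprintf("C%02d", 1:20),
                      code = sample(all_codes(), 20), accuracy = accs,
                      stringsAsFactors = FALSE)
    best <- -Inf
    for (k in 1:20) {
      cur <- optimal_feature(cf2[1:k, , drop = FALSE])$accuracy
      expect_gte(cur, best)
      best <- cur
    }
  })
})

test_that("selection reports carry ANOVA screening and summaries tally", {
  withr::with_seed(73, {
    ft <- build_feature_table(make_subject_sequences(12, c("FP1", "O1"), 60))
    rec <- evaluate_features(ft, classifier_spec("knn", k = 3))
    rep <- select_features(rec, ft)
    expect_equal(nrow(rep$per_channel), 2L)
    expect_true(all(rep$per_channel$anova_p >= 0 &
                      rep$per_channel$anova_p <= 1))
    expect_equal(rep$optimal$accuracy, max(rep$per_channel$accuracy))
  })

  s <- summarize_selection(data.frame(channel = "FP1", code = "TGB",
                                      stringsAsFactors = FALSE))
  expect_equal(unname(s$region["frontal"]), 100)
  expect_equal(sum(s$region), 100)
  s3 <- summarize_selection(data.frame(
    channel = c("FP1", "CP2", "O1"), code = c("TGB", "AAA", "DTD"),
    stringsAsFactors = FALSE))
  expect_equal(unname(as.vector(s3$rhythm_types)),
               c(100 / 3, 100 / 3, 100 / 3))
  expect_equal(unname(s3$region[c("frontal", "parietal", "occipital")]),
               rep(100 / 3, 3), ignore_attr = TRUE)
})
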