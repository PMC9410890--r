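test_that("ROC hand fixtures reproduce the rank statistic", {
  # perfectly separated classes
  roc1 <- roc_curve(c(0.2, 0.4, 0.9, 1.6),
                    c("diffuse", "diffuse", "aggregated", "aggregated"))
  expect_equal(roc1$auc, 1.0)
  # one discordant pair among 2x2: AUC = 3/4 (Mann-Whitney identity)
  roc2 <- roc_curve(c(0.2, 0.4, 0.9, 1.6),
                    c("diffuse", "aggregated", "diffuse", "aggregated"))
  expect_equal(roc2$auc, 0.75)
  expect_equal(pairwise_auc(c(0.2, 0.4, 0.9, 1.6),
                            c("diffuse", "aggregated", "diffuse",
                              "aggregated")), 0.75)
  # curve endpoints and monotonicity of the sweep
  pts <- roc2$points
  expect_equal(pts$tpr[nrow(pts)], 0); expect_equal(pts$fpr[nrow(pts)], 0)
  expect_equal(pts$tpr[1], 1); expect_equal(pts$fpr[1], 1)
  expect_true(all(diff(pts$tpr) <= 0))
  expect_true(all(diff(pts$fpr) <= 0))
  expect_error(roc_curve(c(1, 2), c("aggregated", "aggregated")),
               "both")
})

test_that("labels independent of scores give AUC near one half", {
  set.seed(1)
  cv <- runif(2000, 0, 3)
  lab <- sample(c("aggregated", "diffuse"), 2000, replace = TRUE)
  expect_lt(abs(roc_curve(cv, lab)$auc - 0.5), 0.05)
})

test_that("trapezoid AUC equals brute-force pair counting on all small sets", {
  # exhaustive over every score assignment from a 3-value grid (which
  # forces heavy ties) for every class split up to 6 ROIs, plus random
  # real-valued sets up to 8 ROIs
  grid <- c(0.2, 1.0, 1.7)
  for (n in 2:6) {
    combos <- as.matrix(expand.grid(rep(list(grid), n)))
    for (na in 1:(n - 1)) {
      lab <- rep(c("aggregated", "diffuse"), c(na, n - na))
      worst <- max(apply(combos, 1, function(cv) {
        abs(roc_curve(cv, lab)$auc - pairwise_auc(cv, lab))
      }))
      expect_equal(worst, 0)
    }
  }
  set.seed(1)
  for (rep in 1:50) {
    n <- sample(4:8, 1)
    na <- sample(seq_len(n - 1), 1)
    cv <- round(runif(n, 0, 2), 1)
    lab <- sample(rep(c("aggregated", "diffuse"), c(na, n - na)))
    expect_equal(roc_curve(cv, lab)$auc, pairwise_auc(cv, lab))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(2)
  cv <- c(rnorm(60, 1.4, 0.4), rnorm(80, 0.7, 0.3))
  cv <- pmax(cv, 0)
  lab <- rep(c("aggregated", "diffuse"), c(60, 80))
  ours <- roc_curve(cv, lab)$auc
  ref <- suppressMessages(pROC::auc(pROC::roc(
    response = factor(lab, levels = c("diffuse", "aggregated")),
    predictor = cv, quiet = TRUE)))
  expect_equal(ours, as.numeric(ref))
})

test_that("Youden selection breaks ties toward the larger threshold", {
  # separated gap (0.6, 1.4]: every candidate inside is optimal, the rule
  # returns 1.4
  cv <- c(0.1, 0.3, 0.6, 1.4, 1.9, 2.4)
  lab <- rep(c("diffuse", "aggregated"), each = 3)
  expect_equal(youden_threshold(roc_curve(cv, lab)), 1.4)
  # single distinct score: degenerate curve returns that threshold
  expect_equal(youden_threshold(roc_curve(c(1.2, 1.2),
                                          c("aggregated", "diffuse"))), 1.2)
})

test_that("ROI classification applies the boundary convention exactly", {
  expect_identical(as.character(classify_roi(0)), "diffuse")
  expect_identical(as.character(classify_roi(1.0)), "aggregated")
  expect_identical(as.character(classify_roi(sqrt(27) / 3)), "aggregated")
  # idempotent and a pure function of (cv, threshold)
  expect_identical(classify_roi(c(0.4, 1.0, 2)), classify_roi(c(0.4, 1.0, 2)))
  expect_identical(as.character(classify_roi(0.99, threshold = 0.5)),
                   "aggregated")
  expect_error(classify_roi(NA_real_), "undefined CV")
})

test_that("raising the threshold trades sensitivity for specificity", {
  set.seed(3)
  cv <- c(rnorm(100, 1.5, 0.5), rnorm(100, 0.5, 0.3))
  cv <- pmax(cv, 0)
  lab <- rep(c("aggregated", "diffuse"), each = 100)
  prev <- NULL
  for (t in seq(0, 3, by = 0.1)) {
    cm <- confusion_metrics(classify_roi(cv, t), lab)
    if (!is.null(prev)) {
      expect_lte(cm$sensitivity, prev$sensitivity + 1e-12)
      expect_gte(cm$specificity, prev$specificity - 1e-12)
    }
    prev <- cm
  }
})

test_that("confusion metrics count the published way", {
  lab <- rep(c("aggregated", "diffuse"), each = 50)
  expect_equal(confusion_metrics(lab, lab),
               list(sensitivity = 1, specificity = 1))
  inv <- ifelse(lab == "aggregated", "diffuse", "aggregated")
  expect_equal(confusion_metrics(inv, lab),
               list(sensitivity = 0, specificity = 0))
  # 2 false negatives and 3 false positives on a 50/50 set
  calls <- lab
  calls[1:2] <- "diffuse"
  calls[51:53] <- "aggregated"
  expect_equal(confusion_metrics(calls, lab),
               list(sensitivity = 0.96, specificity = 0.94))
  expect_error(confusion_metrics(lab, rep("diffuse", 100)), "both classes")
})

test_that("a neuron is aggregate-bearing iff any live ROI crosses threshold", {
  tracks <- data.frame(track_id = rep(1:3, each = 4), timepoint = rep(1:4, 3),
                       cv = c(0.3, 0.4, 0.2, 0.5,     # always diffuse
                              0.3, 1.2, 0.4, 0.3,     # one crossing
                              0.2, 0.3, 5.0, 9.9),    # crossings after death
                       tracking_mean = 50)
  deaths <- data.frame(track_id = 1:3, x1 = 0, y1 = 0,
                       death_interval = c(NA, NA, 3L),
                       censored = c(TRUE, TRUE, FALSE),
                       last_alive = c(4L, 4L, 2L), has_t1 = TRUE)
  calls <- classify_neurons(tracks, deaths)
  expect_identical(calls$aggregated, c(FALSE, TRUE, FALSE))
  # no usable ROI: flagged NA, not dropped
  tracks$cv[tracks$track_id == 1] <- NA
  calls2 <- classify_neurons(tracks, deaths)
  expect_true(is.na(calls2$aggregated[1]))
  expect_identical(calls2$n_usable[1], 0L)
})
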