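disc_frame <- function(h, w, cx, cy, r, value, background = 0) {
  m <- matrix(background, h, w)
  for (i in 1:h) for (j in 1:w) {
    if ((i - 1 - cy)^2 + (j - 1 - cx)^2 <= r^2) m[i, j] <- m[i, j] + value
  }
  m
}

test_that("background subtraction removes the global median and clips", {
  expect_equal(subtract_background(matrix(7, 10, 10)), matrix(0, 10, 10))
  expect_equal(subtract_background(matrix(0, 5, 5)), matrix(0, 5, 5))
  # bright disc under 50% of pixels on constant background b: disc pixels
  # are reduced by exactly b
  b <- 12
  fr <- disc_frame(40, 40, 20, 20, 8, 100, background = b)
  out <- subtract_background(fr)
  expect_equal(out[fr > b], rep(100, sum(fr > b)))
  expect_true(all(out[fr == b] == 0))
  expect_error(subtract_background(matrix(c(-1, 1, 1, 1), 2, 2)),
               "non-negative")
  expect_error(subtract_background(matrix(c(NA, 1, 1, 1), 2, 2)),
               "finite")
})

test_that("CV is the population sd over the mean, with fixed conventions", {
  expect_equal(compute_cv(rep(7, 9)), 0)
  expect_equal(compute_cv(c(1, 3)), 0.5)             # mean 2, pop sd 1
  expect_equal(compute_cv(c(0, 0, 0, 12)), sqrt(27) / 3)  # ~1.732
  # gain invariance: multiplying by any positive scalar leaves CV unchanged
  set.seed(1)
  for (rep in 1:20) {
    v <- runif(30, 1, 10)
    g <- runif(1, 0.01, 100)
    expect_equal(compute_cv(g * v), compute_cv(v))
  }
  expect_error(compute_cv(c(0, 0, 0)), "not positive")
  expect_error(compute_cv(5), "at least 2")
})

test_that("segmentation recovers well-separated planted somata", {
  expect_identical(nrow(segment_frame(matrix(0, 64, 64))), 0L)
  cfg <- generator_config(groups = list(cohort_group("g", 0, 0)),
                          n_neurons_per_group = 12, neurons_per_field = 12,
                          n_timepoints = 1, seed = 4)
  truth <- sample_cohort(cfg)
  m <- render_movie(truth, cfg, truth$neurons$field[1])
  rois <- segment_frame(m$pixels[, , 1, 1], m$pixels[, , 2, 1])
  expect_identical(nrow(rois), 12L)
  p1 <- truth$paths[truth$paths$timepoint == 1, ]
  for (k in seq_len(nrow(p1))) {
    d <- sqrt(min((rois$x - p1$x[k])^2 + (rois$y - p1$y[k])^2))
    expect_lt(d, 2)
  }
})

test_that("two somata closer than a pixel merge into one component", {
  fr <- disc_frame(60, 60, 20, 30, 6, 50) + disc_frame(60, 60, 32, 30, 6, 50)
  rois <- segment_frame(fr, fr, min_area = 30, max_area = 400)
  expect_identical(nrow(rois), 1L)
  expect_gt(rois$area, 150)  # larger than a single r = 6 disc
})

test_that("a static ROI links into a single full-length track", {
  fr <- disc_frame(48, 48, 24, 24, 6, 50)
  rois <- lapply(1:10, function(t) segment_frame(fr, fr))
  tr <- link_tracks(rois)
  expect_identical(unique(tr$track_id), 1L)
  expect_identical(tr$timepoint, 1:10)
  de <- call_death(tr, 10)
  expect_true(de$censored)
  expect_true(is.na(de$death_interval))
})

test_that("well-separated neurons never swap identities", {
  f1 <- disc_frame(60, 90, 20, 30, 5, 50) + disc_frame(60, 90, 70, 30, 5, 90)
  f2 <- disc_frame(60, 90, 24, 33, 5, 50) + disc_frame(60, 90, 66, 27, 5, 90)
  rois <- list(segment_frame(f1, f1), segment_frame(f2, f2))
  tr <- link_tracks(rois, max_displacement = 10)
  expect_identical(length(unique(tr$track_id)), 2L)
  for (id in unique(tr$track_id)) {
    g <- tr[tr$track_id == id, ]
    expect_identical(nrow(g), 2L)
    expect_lt(abs(diff(g$x)), 6)  # stayed on its own side
    expect_identical(anyDuplicated(g$timepoint), 0L)
  }
})

test_that("a planted one-frame signal drop is called at the right interval", {
  fr <- disc_frame(48, 48, 24, 24, 6, 50)
  blank <- matrix(0, 48, 48)
  rois <- lapply(1:10, function(t) {
    segment_frame(if (t < 6) fr else blank, fr)
  })
  tr <- link_tracks(rois)
  de <- call_death(tr, 10)
  expect_identical(de$death_interval, 6L)
  expect_false(de$censored)
})

test_that("the imaging chain recovers the planted cohort", {
  cfg <- generator_config(groups = list(cohort_group("g", 0.485, 0.04, 2.5)),
                          n_neurons_per_group = 100, seed = 1)
  res <- run_cohort_vs_truth(cfg)
  truth <- attr(res, "truth")
  # mutual-NN linking: one ROI per timepoint per track was asserted above;
  # here: recovery and death-interval accuracy against ground truth
  alive_t1 <- sum(is.na(truth$neurons$death_interval) |
                    truth$neurons$death_interval > 1)
  expect_gte(sum(!is.na(res$neuron_id)) / alive_t1, 0.99)
  ok <- !is.na(res$neuron_id)
  exact <- mapply(function(a, b) identical(as.integer(a), as.integer(b)) ||
                    (is.na(a) && is.na(b)),
                  res$death_interval[ok], res$true_death_interval[ok])
  expect_gte(mean(exact), 0.98)
  # and >= 95% of neurons recovered with exactly correct death intervals
  expect_gte(sum(exact) / alive_t1, 0.95)
  # no truth neuron claimed twice
  expect_identical(anyDuplicated(stats::na.omit(res$neuron_id)), 0L)
})
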