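test_that("record construction maps intervals to hours and logs exclusions", {
  deaths <- data.frame(track_id = 1:4, x1 = 0, y1 = 0,
                       death_interval = c(6L, NA, 2L, NA),
                       censored = c(FALSE, TRUE, FALSE, TRUE),
                       last_alive = c(5L, 10L, 1L, 10L),
                       has_t1 = c(TRUE, TRUE, TRUE, FALSE))
  calls <- data.frame(track_id = 1:4, n_live = 5, n_usable = c(5, 5, 0, 5),
                      aggregated = c(TRUE, FALSE, NA, FALSE))
  out <- build_records(deaths, calls, "CGG", n_timepoints = 10)
  expect_identical(nrow(out$records), 2L)
  expect_equal(out$records$time, c(144, 240))
  expect_identical(out$records$event, c(TRUE, FALSE))
  expect_identical(out$records$aggregated, c(TRUE, FALSE))
  # bookkeeping: tracked = analyzed + excluded, with reasons
  expect_identical(nrow(out$records) + nrow(out$exclusions), nrow(deaths))
  expect_setequal(out$exclusions$reason,
                  c("no usable CV", "no timepoint-1 ROI"))
})

test_that("Kaplan-Meier product-limit arithmetic is exact", {
  km0 <- kaplan_meier(rep(240, 8), rep(FALSE, 8))
  expect_true(all(km0$table$surv == 1))
  km1 <- kaplan_meier(c(24, rep(240, 9)), c(TRUE, rep(FALSE, 9)))
  expect_equal(km1$table$surv[km1$table$time == 24], 0.9)
  expect_equal(km1$table$cumrisk[km1$table$time == 24], 0.1)
  expect_true(all(diff(km1$table$surv) <= 0))
})

test_that("KM matches the geometric closed form on a planted cohort", {
  cfg <- generator_config(groups = list(cohort_group("g", 0, 0.1)),
                          n_neurons_per_group = 5000, seed = 1)
  truth <- sample_cohort(cfg)
  di <- truth$neurons$death_interval
  km <- kaplan_meier(ifelse(is.na(di), 240, di * 24), !is.na(di))
  s240 <- km$table$surv[km$table$time == 240]
  target <- 0.9^10
  expect_lt(abs(s240 - target), 3 * sqrt(target * (1 - target) / 5000))
})

test_that("KM agrees with the survival package on tied, censored data", {
  set.seed(1)
  d <- sim_two_groups(150, 0.08, 0.15)
  km <- kaplan_meier(d$time, d$event)
  sf <- survival::survfit(survival::Surv(d$time, d$event) ~ 1)
  at <- km$table$time %in% sf$time
  expect_equal(km$table$surv[at], sf$surv[match(km$table$time[at], sf$time)])
})

test_that("Newton-Raphson matches grid maximization on a no-ties toy set", {
  time <- c(3, 5, 7, 11, 13, 17)
  event <- c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE)
  x <- c(1, 0, 1, 0, 1, 0)
  fit <- cox_ph(time, event, cbind(x = x))
  grid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(grid, naive_cox_loglik, numeric(1), time, event, x)
  expect_lte(abs(fit$coef - grid[which.max(ll)]), 1e-4)
  expect_equal(fit$loglik, max(ll), tolerance = 1e-8)
  # Efron and Breslow coincide exactly without ties
  fb <- cox_ph(time, event, cbind(x = x), ties = "breslow")
  expect_identical(fit$coef, fb$coef)
  expect_identical(fit$loglik, fb$loglik)
})

test_that("exchangeable groups give a near-zero log hazard ratio", {
  set.seed(1)
  d <- sim_two_groups(1000, 0.08, 0.08)
  fit <- cox_ph(d$time, d$event, cbind(g = d$x))
  expect_lt(abs(fit$coef), 3 * fit$se)
  # a perfectly symmetric dataset gives beta exactly 0 and Wald p = 1
  t2 <- rep(c(24, 48, 72), 2); e2 <- rep(TRUE, 6); x2 <- rep(0:1, each = 3)
  f0 <- cox_ph(t2, e2, cbind(g = x2))
  expect_equal(unname(f0$coef), 0)
  expect_equal(unname(f0$wald_p), 1)
})

test_that("Efron and Breslow fits match the survival package exactly", {
  set.seed(1)
  d <- sim_two_groups(300, 0.05, 0.12)
  X <- cbind(g = d$x)
  for (tie in c("efron", "breslow")) {
    fit <- cox_ph(d$time, d$event, X, ties = tie)
    ref <- survival::coxph(survival::Surv(time, event) ~ x, data = d,
                           ties = tie)
    expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-7)
    expect_equal(unname(fit$se), sqrt(unname(stats::vcov(ref)[1, 1])),
                 tolerance = 1e-7)
    expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-7)
    expect_equal(fit$loglik_null, ref$loglik[1], tolerance = 1e-7)
  }
})

test_that("estimates are invariant to monotone time transformations", {
  set.seed(1)
  d <- sim_two_groups(200, 0.06, 0.12)
  f1 <- cox_ph(d$time, d$event, cbind(g = d$x))
  f2 <- cox_ph(d$time^2, d$event, cbind(g = d$x))
  expect_equal(f1$coef, f2$coef, tolerance = 1e-8)
  expect_equal(f1$se, f2$se, tolerance = 1e-8)
})

test_that("the log partial likelihood is concave along a line through the
          optimum", {
  set.seed(1)
  d <- sim_two_groups(100, 0.06, 0.12)
  fit <- cox_ph(d$time, d$event, cbind(g = d$x))
  ll <- vapply(seq(-2, 2, length.out = 41) + unname(fit$coef), function(b) {
    naive_cox_loglik(b, d$time, d$event, d$x)
  }, numeric(1))
  expect_lte(max(diff(ll, differences = 2)), 1e-9)
  expect_equal(which.max(ll), 21L)  # maximum at beta-hat
})

test_that("degenerate designs are rejected with informative errors", {
  expect_error(cox_ph(c(10, 20), c(FALSE, FALSE), cbind(x = c(0, 1))),
               "no observed events")
  expect_error(cox_ph(c(10, 20, 30), c(TRUE, TRUE, FALSE),
                      cbind(a = c(1, 0, 1), b = c(2, 0, 2))),
               "collinear")
  # monotone likelihood: the covariate perfectly separates events
  expect_error(cox_ph(c(1, 2, 3, 10, 10, 10),
                      c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                      cbind(x = c(1, 1, 1, 0, 0, 0))),
               "monotone|separate|diverging")
})

test_that("Wald and likelihood-ratio tests behave at their null points", {
  set.seed(1)
  d <- sim_two_groups(150, 0.08, 0.2)
  full <- cox_ph(d$time, d$event, cbind(g = d$x))
  self <- lr_test(full, full)
  expect_equal(self$statistic, 0)
  expect_identical(self$df, 0L)
  expect_equal(self$p, 1)
  against_null <- lr_test(full)
  expect_equal(against_null$statistic, 2 * (full$loglik - full$loglik_null))
  expect_identical(against_null$df, 1L)
  wt <- wald_test(full)
  expect_identical(wt$term, "g")
  expect_equal(wt$p, 2 * pnorm(-abs(wt$z)))
  other <- cox_ph(d$time, d$event, cbind(h = 1 - d$x))
  expect_error(lr_test(full, other), "not nested")
})

test_that("null simulations hold the Wald type-I error at its level", {
  set.seed(1)
  rej <- replicate(1000, {
    d <- sim_two_groups(100, 0.1, 0.1)
    cox_ph(d$time, d$event, cbind(g = d$x))$wald_p[1] < 0.05
  })
  se3 <- 3 * sqrt(0.05 * 0.95 / 1000)
  expect_lt(abs(mean(rej) - 0.05), se3)
})

test_that("planted hazard ratios are recovered with nominal CI coverage", {
  # generative oracle for discrete geometric hazards grouped from a
  # proportional-hazards process: theta = log(1 - h1) / log(1 - h0)
  theta <- log(log(1 - 0.10) / log(1 - 0.05))
  set.seed(1)
  d <- sim_two_groups(2000, 0.05, 0.10)
  fit <- cox_ph(d$time, d$event, cbind(g = d$x))
  expect_lt(abs(unname(fit$coef) - theta), 3 * unname(fit$se))
  set.seed(1)
  covered <- replicate(200, {
    d <- sim_two_groups(500, 0.05, 0.10)
    f <- cox_ph(d$time, d$event, cbind(g = d$x))
    abs(unname(f$coef) - theta) <= qnorm(0.975) * unname(f$se)
  })
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})
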