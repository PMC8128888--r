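test_that("baseline normalization uses the -5 to +5 min window mean", {
  s <- amp_series(seq(-10, 20), rep(40, 31))
  expect_equal(normalize_to_baseline(s)$normalized, rep(1, 31))
  s2 <- amp_series(c(-2, 2, 10), c(38, 42, 20))
  n2 <- normalize_to_baseline(s2)
  expect_equal(n2$baseline_uv, 40)
  expect_equal(n2$normalized[3], 0.5)
  expect_equal(mean(n2$normalized[1:2]), 1)
  expect_error(normalize_to_baseline(amp_series(c(10, 11, 12), c(1, 1, 1))),
               "baseline window")
})

test_that("reduction time interpolates a sustained downward crossing", {
  s <- amp_series(0:20, c(rep(1, 10), rep(0, 11)))
  s$normalized <- s$amplitudes_uv
  expect_equal(as.numeric(reduction_time(s, 0.5)), 9.5)
  # a sample exactly at the fraction is taken as the crossing time
  s2 <- amp_series(0:4, c(1, 1, 0.5, 0.2, 0.1))
  s2$normalized <- s2$amplitudes_uv
  expect_equal(as.numeric(reduction_time(s2, 0.5)), 2)
  # flat trace never crosses
  s3 <- normalize_to_baseline(amp_series(-5:20, rep(40, 26)))
  r3 <- reduction_time(s3, 0.5)
  expect_true(is.na(r3))
  expect_equal(attr(r3, "reason"), "no reduction")
})

test_that("single-sample dips are rejected by the sustained-crossing rule", {
  a <- c(1, 1, 1, 0.3, 1, 1, 0.9, 0.4, 0.2, 0.1, 0.05)
  s <- amp_series(0:10, a)
  s$normalized <- a
  r <- as.numeric(reduction_time(s, 0.5, k = 2))
  # the isolated dip at t=3 is skipped; crossing is between t=6 and t=7
  expect_gt(r, 6)
  expect_lt(r, 7)
  # with k = 1 the dip itself is the crossing
  expect_lt(as.numeric(reduction_time(s, 0.5, k = 1)), 4)
})

test_that("logistic crossings match the closed-form inversion", {
  # kainic-acid style decline A(t) = 1/(1+exp((t-10)/1)); fine sampling so
  # linear interpolation is within 0.02 min of the exact inverse
  s <- normalize_to_baseline(
    logistic_series(10, slope = 1, times = seq(-10, 45, by = 0.25)))
  expect_equal(as.numeric(reduction_time(s, 0.5)), 10, tolerance = 0.02)
  expect_equal(as.numeric(reduction_time(s, 0.8)), 10 - log(4),
               tolerance = 0.02)
  expect_equal(as.numeric(reduction_time(s, 0.2)), 10 + log(4),
               tolerance = 0.02)
})

test_that("reduction times are ordered and shift-equivariant", {
  for (t50 in c(8.2, 14.7, 21.3)) {
    s <- normalize_to_baseline(logistic_series(t50, slope = 0.8))
    t80 <- as.numeric(reduction_time(s, 0.8))
    t50e <- as.numeric(reduction_time(s, 0.5))
    t20 <- as.numeric(reduction_time(s, 0.2))
    expect_true(t80 <= t50e && t50e <= t20)
    # shifting the clock shifts every crossing by the same amount
    sh <- s
    sh$times_min <- sh$times_min + 3.25
    expect_equal(as.numeric(reduction_time(sh, 0.5)), t50e + 3.25)
  }
})

test_that("tuning curves take the 50% tip at 10 dB SL and 80/20 edges above", {
  mk <- function(level, t80, t20) {
    centre <- (t80 + t20) / 2
    slope <- (t20 - t80) / (2 * log(4))
    normalize_to_baseline(logistic_series(
      centre, slope = slope, level_db_sl = level, ear_id = "e1",
      group = "control", freq_khz = 4))
  }
  tc <- build_tuning_curve(list(
    mk(10, 13, 17), mk(20, 12, 18.5), mk(30, 11, 20.5)))
  expect_s3_class(tc, "rt_tuning_curve")
  expect_equal(tc$tip_time_min, 15, tolerance = 0.05)
  expect_equal(tc$edges$level_db_sl, c(20, 30))
  expect_true(all(diff(tc$edges$t80_min) < 0))   # apical edge earlier
  expect_true(all(diff(tc$edges$t20_min) > 0))   # basal edge later
  expect_true(all(tc$edges$t80_min <= tc$edges$t20_min))
  # tip-only curve when just 10 dB SL exists
  tc0 <- build_tuning_curve(list(mk(10, 13, 17)))
  expect_equal(nrow(tc0$edges), 0)
  expect_error(build_tuning_curve(list(mk(20, 12, 18))), "10 dB SL")
})

test_that("levels whose 20% crossing never happens are omitted with warning", {
  good <- normalize_to_baseline(logistic_series(15, level_db_sl = 10))
  t <- seq(-10, 45)
  shallow <- amp_series(t, 40 * (1 - pmin(0.6, pmax(0, (t - 10) / 20))),
                        level_db_sl = 20)
  shallow <- normalize_to_baseline(shallow)
  expect_warning(tc <- build_tuning_curve(list(good, shallow)),
                 "omitted")
  expect_equal(nrow(tc$edges), 0)
})

test_that("group averages report SEM only with two or more ears", {
  mk_tc <- function(tip, ear) {
    s10 <- normalize_to_baseline(logistic_series(
      tip, level_db_sl = 10, ear_id = ear, group = "control", freq_khz = 4))
    s20 <- normalize_to_baseline(logistic_series(
      tip, slope = 1.6, level_db_sl = 20, ear_id = ear, group = "control",
      freq_khz = 4))
    build_tuning_curve(list(s10, s20))
  }
  a <- mk_tc(14, "e1"); b <- mk_tc(16, "e2")
  avg <- group_average_tc(list(a, b))
  expect_equal(avg$tip$mean, 15, tolerance = 0.05)
  expect_equal(avg$tip$sem, 1, tolerance = 0.05)
  expect_equal(avg$tip$n, 2)
  same <- group_average_tc(list(a, a))
  expect_equal(same$tip$mean, a$tip_time_min)
  expect_equal(same$tip$sem, 0)
  one <- group_average_tc(list(a))
  expect_true(is.na(one$tip$sem))
  expect_error(group_average_tc(list(a), group = "operated"), "no tuning")
})
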