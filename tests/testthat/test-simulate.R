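test_that("noiseless generator reproduces the configured shifts exactly", {
  cfg <- sim_config(ear_sd_min = 0, resid_sd_min = 0, responder_prob = 1)
  st <- simulate_t50_table(cfg, seed = 1)
  d <- colMeans(st$table$t50[st$table$group == "control", ]) -
    colMeans(st$table$t50[st$table$group == "operated", ])
  expect_equal(unname(d), c(5.8, 3.8, 4.3, 2.4, 3.4))
  # control ears sit on the map's arrival times
  expect_equal(unname(st$table$t50[6, ]), time_from_cf(c(2, 4, 6, 8, 12)))
})

test_that("responder_prob 0 yields an exchangeable null", {
  cfg <- sim_config(responder_prob = 0)
  set.seed(1)
  d <- replicate(200, {
    st <- simulate_t50_table(cfg, seed = sample.int(1e6, 1))
    set_difference(st$table, 2)
  })
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)))
})

test_that("same seed gives identical output; different seeds differ", {
  cfg <- sim_config()
  a <- simulate_t50_table(cfg, seed = 5)
  b <- simulate_t50_table(cfg, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a$truth,
                         simulate_t50_table(cfg, seed = 6)$truth))
  s1 <- simulate_trajectories(sim_config(levels_db_sl = 10,
                                         freqs_khz = 2,
                                         group_shift_min = 5.8), seed = 2)
  s2 <- simulate_trajectories(sim_config(levels_db_sl = 10,
                                         freqs_khz = 2,
                                         group_shift_min = 5.8), seed = 2)
  expect_identical(s1$series, s2$series)
})

test_that("shared ear effects induce high across-frequency correlation", {
  cfg <- sim_config(ear_sd_min = 2, resid_sd_min = 0.3,
                    responder_prob = 1)
  st <- simulate_t50_table(cfg, seed = 8)
  ctl <- st$table$t50[st$table$group == "control", ]
  cors <- cor(ctl)
  expect_gt(min(cors[upper.tri(cors)]), 0.8)
})

test_that("expected group differences match the configured shifts", {
  # default config (responder_prob 0.8, per-responder shift scaled up):
  # the mean control-minus-operated difference converges on the configured
  # per-frequency shifts
  cfg <- sim_config()
  d <- t(vapply(1:400, function(i) {
    st <- simulate_t50_table(cfg, seed = 2000 + i)
    vapply(cfg$freqs_khz, function(f) set_difference(st$table, f),
           numeric(1))
  }, numeric(5)))
  se <- apply(d, 2, sd) / sqrt(nrow(d))
  expect_true(all(abs(colMeans(d) - cfg$group_shift_min) < 3 * se))
})

test_that("non-responding operated ears look like controls at all frequencies", {
  cfg <- sim_config(ear_sd_min = 0.5, resid_sd_min = 0.2)
  base <- time_from_cf(cfg$freqs_khz, cfg$model, cfg$map)
  dev_nr <- NULL
  dev_rsp <- NULL
  for (i in 1:60) {
    st <- simulate_t50_table(cfg, seed = 3000 + i)
    op <- st$table$group == "operated"
    nr <- op & !st$responder
    if (any(nr))
      dev_nr <- rbind(dev_nr, sweep(st$truth[nr, , drop = FALSE], 2, base))
    rsp <- op & st$responder
    dev_rsp <- rbind(dev_rsp, sweep(st$truth[rsp, , drop = FALSE], 2, base))
  }
  expect_gt(nrow(dev_nr), 5)
  # non-responders scatter around the control baseline at every frequency
  expect_true(all(abs(colMeans(dev_nr)) < 0.5))
  # responders are clearly earlier at every frequency (shift/0.8 >= 3 min)
  expect_true(all(colMeans(dev_rsp) < -2))
})

test_that("noiseless trajectories return the ground-truth 50% times", {
  cfg <- sim_config(noise_sd = 0, levels_db_sl = 10,
                    ear_sd_min = 1, resid_sd_min = 0.3)
  st <- simulate_trajectories(cfg, seed = 4)
  for (s in st$series[seq(1, length(st$series), by = 7)]) {
    s <- normalize_to_baseline(s)
    truth <- st$truth_t50[s$ear_id, as.character(s$freq_khz)]
    expect_equal(as.numeric(reduction_time(s, 0.5)), truth,
                 tolerance = 0.05)
  }
})

test_that("trajectory baselines are near 1 and edges widen with level", {
  cfg <- sim_config(noise_sd = 0.02, freqs_khz = 4, group_shift_min = 3.8)
  st <- simulate_trajectories(cfg, seed = 6)
  s <- st$series[[1]]
  pre <- s$amplitudes_uv[s$times_min < 0] / cfg$baseline_uv
  expect_equal(mean(pre), 1, tolerance = 0.05)
  # noiseless edges move apart with level, high side more than low side
  cfg0 <- sim_config(noise_sd = 0, freqs_khz = 4, group_shift_min = 3.8,
                     ear_sd_min = 0, resid_sd_min = 0, responder_prob = 1)
  st0 <- simulate_trajectories(cfg0, seed = 6)
  ctl <- Filter(function(s) s$ear_id == "ear06", st0$series)
  lv <- vapply(ctl, function(s) s$level_db_sl, numeric(1))
  rt <- function(s, f) as.numeric(reduction_time(normalize_to_baseline(s), f))
  t80 <- vapply(ctl, rt, numeric(1), f = 0.8)
  t20 <- vapply(ctl, rt, numeric(1), f = 0.2)
  o <- order(lv[lv > 10])
  hi <- which(lv > 10)
  expect_true(all(diff(t80[hi][o]) < 0))
  expect_true(all(diff(t20[hi][o]) > 0))
  d80 <- abs(diff(t80[hi][o])); d20 <- abs(diff(t20[hi][o]))
  expect_true(all(d20 > d80))
})

test_that("synthetic CAP pairs scale and cancel as constructed", {
  pr <- simulate_cap_pair(50)
  expect_equal(cap_amplitude(average_alternating(pr$pos, pr$neg)), 50,
               tolerance = 0.5)
  half <- simulate_cap_pair(25)
  expect_equal(cap_amplitude(average_alternating(half$pos, half$neg)), 25,
               tolerance = 0.5)
  # the microphonic is present in single polarities but not the average
  avg <- average_alternating(pr$pos, pr$neg)
  late <- function(w) max(abs(w$samples[round(0.008 * w$fs):
                                          round(0.012 * w$fs)]))
  expect_gt(late(pr$pos), 1)
  expect_lt(late(avg), 1e-9)
})
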