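test_that("the observed set difference is control mean minus operated mean", {
  tab <- toy_table()
  expect_equal(set_difference(tab, 2), 9.5 - 2)
  swapped <- t50_table(tab$t50, ifelse(tab$group == "operated", "control",
                                       "operated"), 2)
  expect_equal(set_difference(swapped, 2), -7.5)
  eq <- t50_table(cbind(rep(5, 6)), rep(c("operated", "control"), 3), 2)
  expect_equal(set_difference(eq, 2), 0)
  expect_error(set_difference(tab, 99), "not in table")
})

test_that("exact enumeration reproduces the brute-force permutation p", {
  tab <- toy_table()
  res <- exact_perm_test(tab, 2)
  expect_equal(res$n_perm, choose(7, 3))
  expect_equal(res$p, 1 / 35)
  expect_equal(res$p, brute_force_p(tab$t50[, 1], tab$group))
  res2 <- exact_perm_test(tab, 2, "two")
  expect_equal(res2$p, brute_force_p(tab$t50[, 1], tab$group, "two"))
  # a study-sized 5 + 8 table agrees with brute force too
  st <- study_table(seed = 7)
  ex <- exact_perm_test(st, 4)
  expect_equal(ex$n_perm, 1287)
  expect_equal(ex$p, brute_force_p(st$t50[, "4"], st$group))
})

test_that("degenerate tables give p = 1 and p is bounded below", {
  eq <- t50_table(cbind(rep(3, 13)),
                  rep(c("operated", "control"), c(5, 8)), 2)
  expect_equal(exact_perm_test(eq, 2)$p, 1)
  # the observed assignment is always enumerated
  extreme <- t50_table(cbind(c(1:5, 101:108)),
                       rep(c("operated", "control"), c(5, 8)), 2)
  expect_equal(exact_perm_test(extreme, 2)$p, 1 / 1287)
})

test_that("Monte-Carlo p converges to the exact p and is seed-reproducible", {
  tab <- toy_table()
  p_exact <- exact_perm_test(tab, 2)$p
  mc <- mc_perm_test(tab, 2, n_perm = 1e5, seed = 11)
  tol <- 3 * sqrt(p_exact * (1 - p_exact) / 1e5)
  expect_lt(abs(mc$p - p_exact), tol)
  mc2 <- mc_perm_test(tab, 2, n_perm = 1e5, seed = 11)
  expect_identical(mc$p, mc2$p)
  expect_false(identical(mc$p,
                         mc_perm_test(tab, 2, n_perm = 1e5, seed = 12)$p))
  # plus-one estimator can never return zero
  small <- mc_perm_test(tab, 2, n_perm = 10, seed = 1,
                        estimator = "plus_one")
  expect_gt(small$p, 0)
})

test_that("MC tests do not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(mc_perm_test(toy_table(), 2, n_perm = 100, seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("one-sided p <= two-sided p when the OSD is positive", {
  st <- study_table(seed = 3)
  for (f in c(2, 6, 12)) {
    if (set_difference(st, f) <= 0) next
    expect_lte(exact_perm_test(st, f, "one")$p,
               exact_perm_test(st, f, "two")$p)
  }
})

test_that("swapping group labels tests the opposite tail", {
  st <- study_table(seed = 5)
  swapped <- t50_table(st$t50, ifelse(st$group == "operated", "control",
                                      "operated"), st$freqs_khz)
  p_fwd <- exact_perm_test(st, 2)$p
  p_rev <- exact_perm_test(swapped, 2)$p
  # together the two tails cover the enumeration, overlapping only at ties
  expect_gte(p_fwd + p_rev, 1)
})

test_that("grand method 2 equals the single-frequency p on identical columns", {
  st <- study_table(seed = 13)
  v <- st$t50[, 1]
  rep5 <- t50_table(matrix(v, nrow = length(v), ncol = 5),
                    st$group, c(2, 4, 6, 8, 12))
  g2 <- grand_perm_test(rep5, method = "common", n_perm = 2e4, seed = 21)
  mc1 <- mc_perm_test(st, 2, n_perm = 2e4, seed = 21)
  expect_equal(g2$p, mc1$p)
  expect_equal(g2$osd, 5 * mc1$osd)
})

test_that("grand tests reduce to the single-frequency test for one column", {
  st <- study_table(seed = 17)
  one <- t50_table(st$t50[, "6", drop = FALSE], st$group, 6)
  mc <- mc_perm_test(one, 6, n_perm = 1e4, seed = 8)
  g2 <- grand_perm_test(one, method = "common", n_perm = 1e4, seed = 8)
  expect_equal(g2$p, mc$p)
  g1 <- grand_perm_test(one, method = "independent", n_perm = 1e4, seed = 8)
  tol <- 3 * sqrt(max(mc$p * (1 - mc$p), 0.01) / 1e4)
  expect_lt(abs(g1$p - mc$p), tol + 1e-12)
})

test_that("method 1 is insensitive to frequency order; all-equal data give p = 1", {
  st <- study_table(seed = 19)
  a <- grand_perm_test(st, freqs = c(2, 4, 6, 8, 12),
                       method = "independent", n_perm = 5e3, seed = 4)
  b <- grand_perm_test(st, freqs = c(12, 8, 6, 4, 2),
                       method = "independent", n_perm = 5e3, seed = 4)
  expect_equal(a$p, b$p)
  eq <- t50_table(matrix(3, 13, 2), rep(c("operated", "control"), c(5, 8)),
                  c(2, 4))
  expect_equal(grand_perm_test(eq, method = "independent", n_perm = 1e3,
                               seed = 1)$p, 1)
  expect_equal(grand_perm_test(eq, method = "common", n_perm = 1e3,
                               seed = 1)$p, 1)
})

test_that("correlated ear effects make the common-permutation method conservative", {
  # strong shared ear effects: method 2 preserves them under permutation,
  # method 1 destroys them, so method 2's p should be the larger in median
  cfg <- sim_config(ear_sd_min = 3, resid_sd_min = 0.3)
  p1 <- p2 <- numeric(20)
  for (i in 1:20) {
    tab <- simulate_t50_table(cfg, seed = 100 + i)$table
    p1[i] <- grand_perm_test(tab, method = "independent", n_perm = 2000,
                             seed = i)$p
    p2[i] <- grand_perm_test(tab, method = "common", n_perm = 2000,
                             seed = i)$p
  }
  expect_lt(median(p1), median(p2))
})

test_that("the full inference report is complete and deterministic", {
  st <- study_table(seed = 23)
  inf <- run_full_inference(st, n_perm = 2000, seed = 9)
  expect_s3_class(inf, "capmap_inference")
  expect_equal(nrow(inf$per_freq), 5)
  expect_equal(nrow(inf$grand), 2)
  expect_true(all(inf$per_freq$p_exact_one >= 1 / 1287))
  expect_true(all(inf$per_freq$p_exact_one <= 1))
  inf2 <- run_full_inference(st, n_perm = 2000, seed = 9)
  expect_identical(inf, inf2)
  out <- capture.output(print(inf))
  expect_true(any(grepl("Grand average", out)))
})
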