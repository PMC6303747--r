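test_that("brown-egg reallocation shifts clears to hatched and conserves totals", {
  re <- brown_reallocate(50, 50, 100, 0.046)
  expect_equal(re$brown_est, 4.6)
  expect_equal(re$hatched_corr, 54.6)
  expect_equal(re$clear_corr, 45.4)
  # no correction
  expect_equal(brown_reallocate(50, 50, 100, 0),
               list(hatched_corr = 50, clear_corr = 50, brown_est = 0))
  # clamped at the observed clear count
  re2 <- brown_reallocate(98, 2, 100, 0.046)
  expect_equal(re2$brown_est, 2)
  expect_equal(re2$clear_corr, 0)
  # conservation under random inputs
  set.seed(1)
  for (i in 1:50) {
    tot <- sample(10:500, 1); h <- sample(0:tot, 1)
    r <- brown_reallocate(h, tot - h, tot, runif(1, 0, 0.2))
    expect_equal(r$hatched_corr + r$clear_corr, tot)
  }
  expect_error(brown_reallocate(5, 4, 10, 0.05), "must equal")
  expect_error(brown_reallocate(-1, 11, 10, 0.05), "non-negative")
})

test_that("mixture inversion satisfies both boundary conditions and the worked value", {
  expect_equal(invert_boorman_parker(0.988, 0.988, 0.068), 0)
  expect_equal(invert_boorman_parker(0.068, 0.988, 0.068), 1)
  expect_equal(invert_boorman_parker(0.528, 0.988, 0.068), 0.5)
  expect_error(invert_boorman_parker(0.5, 0.05, 0.9), "exceed")
})

test_that("forward then inverse recovers the sterile-male share to machine precision", {
  P_R <- seq(0, 1, length.out = 50)
  p <- seq(0.02, 1, length.out = 50)
  z <- seq(0, 0.98, length.out = 50)
  grid <- expand.grid(P_R = P_R, p = p, z = z)
  grid <- grid[grid$p - grid$z >= 0.01, ]
  back <- invert_boorman_parker(
    expected_hatch(grid$P_R, grid$p, grid$z), grid$p, grid$z)
  expect_lt(max(abs(back - grid$P_R)), 1e-12)
})

test_that("the inversion is strictly decreasing in the hatch proportion", {
  x <- seq(0, 1, by = 0.01)
  pr <- invert_boorman_parker(x, 0.97, 0.05)
  expect_true(all(diff(pr) < 0))
})

test_that("mixture inversion agrees with a grid-search oracle on random trials", {
  set.seed(7)
  for (i in 1:1000) {
    p <- runif(1, 0.5, 1); z <- runif(1, 0, p - 0.05)
    x <- runif(1, z, p)
    pr_grid <- seq(0, 1, by = 1e-4)
    oracle <- pr_grid[which.min(abs(x - (pr_grid * z + (1 - pr_grid) * p)))]
    expect_lt(abs(invert_boorman_parker(x, p, z) - oracle), 1e-4)
  }
})

test_that("sterilization order maps the sterile share to second-male paternity", {
  expect_equal(p_r_to_p2(0.7, "NR"), 0.7)
  expect_equal(p_r_to_p2(0.7, "RN"), 0.3)
  expect_equal(p_r_to_p2(1.2, "RN"), -0.2)  # bounds pass through for flagging
  expect_error(p_r_to_p2(0.5, "MN"), "NR")
})

test_that("egg attribution rounds half away from zero and conserves totals", {
  at <- attribute_eggs(0.79, 368)
  expect_equal(at$eggs_m2, 291L)  # 290.72 rounds up
  expect_equal(at$eggs_m1, 77L)
  expect_equal(attribute_eggs(1, 57), list(eggs_m1 = 0L, eggs_m2 = 57L))
  expect_equal(attribute_eggs(0.5, 3)$eggs_m2, 2L)  # 1.5 -> 2, away from zero
  expect_error(attribute_eggs(1.2, 100), "clamp or exclude")
  set.seed(2)
  for (i in 1:100) {
    tot <- sample(1:400, 1); a <- attribute_eggs(runif(1), tot)
    expect_equal(a$eggs_m1 + a$eggs_m2, tot)
  }
})

test_that("low egg counts are flagged and unattributed", {
  ft <- example_factors()
  tr <- data.frame(female_id = "F1", mating_order = "MP",
                   sterilization_order = "NR", interval_h = 0,
                   eggs_total = 8, eggs_hatched_obs = 4, eggs_clear_obs = 4)
  est <- estimate_trials(tr, ft)
  expect_true(has_flag(est, "low_eggs"))
  expect_false(est$kept)
  expect_true(is.na(est$eggs_m2))
})

test_that("a trial whose corrected hatch equals normal fertility gives P2 of exactly zero", {
  ft <- fertility_table(data.frame(
    sterilization_order = "NR", interval_h = 0, p_num = 652, p_den = 660,
    z_num = 43, z_den = 637, brown_num = 0, brown_den = 1297))
  h <- round(660 * 652 / 660)  # 652 of 660: x_corrected = p exactly
  tr <- data.frame(female_id = "F1", mating_order = "MP",
                   sterilization_order = "NR", interval_h = 0,
                   eggs_total = 660, eggs_hatched_obs = h,
                   eggs_clear_obs = 660 - h)
  est <- estimate_trials(tr, ft)
  expect_identical(est$P2, 0)
  expect_equal(est$eggs_m2, 0L)
})

test_that("out-of-bounds estimates are excluded, overridden, or clamped per policy", {
  ft <- example_factors()
  # all clear eggs at NR/0: x ~ brown only, far below z -> P_R > 1
  tr <- data.frame(
    female_id = c("F1", "F2", "F3", "F4", "F5"),
    mating_order = "MP", sterilization_order = "NR", interval_h = 0,
    eggs_total = 50,
    eggs_hatched_obs = c(0L, 0L, 0L, 50L, 25L),
    eggs_clear_obs = c(50L, 50L, 50L, 0L, 25L))
  # F4: all hatched, x_corrected > p -> P_R < 0 -> flagged below 0
  est <- estimate_trials(tr, ft)
  expect_true(all(has_flag(est, "p2_above_1")[1:3]))
  expect_true(has_flag(est, "p2_below_0")[4])
  ex <- apply_exclusions(est)
  expect_equal(nrow(ex$excluded), 4)
  expect_equal(nrow(ex$kept), 1)
  expect_setequal(ex$log$female_id, c("F1", "F2", "F3", "F4"))
  # one override is retained with a clamped attribution
  pol <- exclusion_policy(overrides = "F2")
  est2 <- estimate_trials(tr, ft, pol)
  ex2 <- apply_exclusions(est2, pol)
  expect_equal(nrow(ex2$excluded), 3)
  expect_true(has_flag(ex2$kept[ex2$kept$female_id == "F2", ],
                       "kept_by_override"))
  expect_equal(est2$P2_attr[est2$female_id == "F2"], 1)
  # clamp mode keeps everything within [0, 1]
  est3 <- estimate_trials(tr, ft, exclusion_policy(out_of_bounds = "clamp"))
  expect_true(all(est3$kept))
  expect_true(all(est3$P2_attr >= 0 & est3$P2_attr <= 1))
  # absent override id warns, not errors
  expect_warning(apply_exclusions(est, exclusion_policy(overrides = "nope")),
                 "nope")
})

test_that("empty estimate sets partition to empty", {
  ft <- example_factors()
  sim <- small_sim(seed = 1, n = 4)
  est <- estimate_trials(sim$trials, ft)
  ex <- apply_exclusions(est[0, ])
  expect_equal(nrow(ex$kept), 0)
  expect_equal(nrow(ex$excluded), 0)
})

test_that("pooled P2 is the ratio of summed attributions", {
  est <- data.frame(interval_h = 0, mating_order = "MP",
                    eggs_m2 = c(10L, 20L), eggs_total = c(20L, 20L))
  pooled <- pool_p2(est)
  expect_equal(pooled$P2_pooled, 30 / 40)
  expect_equal(pooled$n_females, 2)
  # no keys: grand totals
  expect_equal(pool_p2(est, keys = character(0))$P2_pooled, 0.75)
})

test_that("estimated P2 approaches the latent truth as egg counts grow", {
  sim <- small_sim(seed = 11, n = 200, egg_mean = 10000,
                   egg_dispersion = 50, assay_eggs_per_cell = 20000)
  est <- estimate_trials(sim$trials, sim$factors,
                         exclusion_policy(out_of_bounds = "clamp"))
  expect_lt(mean(abs(est$P2 - est$true_P2)), 0.01)
})
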