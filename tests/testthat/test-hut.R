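# Tilt-protocol segmentation and cohort statistics.

test_that("segmentation yields half-open windows covering the protocol", {
  conc <- conc_series(0:2999, hb = 1, hbo2 = 2)
  seg <- segment_series(conc)
  expect_named(seg, c("baseline", "tilt", "recovery"))
  expect_equal(nrow(seg$baseline), 600)
  expect_equal(nrow(seg$tilt), 1800)
  expect_equal(nrow(seg$recovery), 600)
  expect_equal(range(seg$tilt$time_s), c(600, 2399))
  # windows partition the recording
  expect_equal(sum(vapply(seg, nrow, integer(1))), nrow(conc))

  # 10 Hz: windows scale with the rate
  conc10 <- conc_series(seq(0, 3000 - 0.1, by = 0.1))
  seg10 <- segment_series(conc10)
  expect_equal(nrow(seg10$tilt), 18000)
})

test_that("a short recording is refused with the missing-sample count", {
  expect_error(segment_series(conc_series(0:2499)), "500 missing samples")
})

test_that("segment averages match hand-computed mean and standard error", {
  sub <- conc_series(0:599, hb = 3, hbo2 = 3)
  a <- segment_average(sub)
  expect_equal(a$mean_uM, c(3, 3, 0, 6))  # Hb, HbO2, dOxy, dBV
  expect_equal(a$se_uM, rep(0, 4))

  two <- conc_series(0:1, hb = c(1, 3), hbo2 = c(1, 3))
  a2 <- segment_average(two)
  hb <- a2[a2$signal == "dC_Hb_uM", ]
  expect_equal(hb$mean_uM, 2)
  expect_equal(hb$se_uM, 1)  # sd/sqrt(n) = sqrt(2)/sqrt(2)
  expect_error(segment_average(two[1, , drop = FALSE]), "at least 2")
})

test_that("rate of change recovers exact and noisy line slopes", {
  tt <- 600:1199
  sub <- conc_series(tt, hb = 0.5 * (tt - 600) / 60)  # 0.5 uM/min
  attr(sub, "segment_start_s") <- 600
  r <- rate_of_change(sub)
  expect_equal(r$slope_uM_per_min[r$signal == "dC_Hb_uM"], 0.5,
               tolerance = 1e-12)

  set.seed(11)
  y <- 0.3 * (tt - 600) / 60 + rnorm(length(tt), 0, 0.2)
  sub2 <- conc_series(tt, hb = y)
  attr(sub2, "segment_start_s") <- 600
  got <- rate_of_change(sub2)$slope_uM_per_min[1]
  X <- cbind(1, (tt - 600) / 60)
  expect_equal(got, normal_equations_oracle(X, y)[2], tolerance = 1e-9)
  expect_error(rate_of_change(sub2[1:2, ]), "at least 3")
})

test_that("tilt AUC integrates constants, ramps, and is linear", {
  tt <- seq(600, 2400)  # a full 30-min span
  const <- conc_series(tt, hb = 1)
  a <- auc_tilt(const)
  expect_equal(a$auc_uM_min[a$signal == "dC_Hb_uM"], 30, tolerance = 1e-12)

  ramp <- conc_series(tt, hb = 2 * (tt - 600) / 1800)  # 0 -> 2 uM triangle
  a2 <- auc_tilt(ramp)
  expect_equal(a2$auc_uM_min[1], 30, tolerance = 1e-12)

  both <- conc_series(tt, hb = 1 + 2 * (tt - 600) / 1800)
  expect_equal(auc_tilt(both)$auc_uM_min[1],
               a$auc_uM_min[1] + a2$auc_uM_min[1], tolerance = 1e-12)
  expect_error(auc_tilt(const[1, , drop = FALSE]), "at least 2")
})

test_that("group test matches the textbook pooled-variance formula", {
  o <- pooled_t_oracle(c(1, 2, 3), c(4, 5, 6))
  g <- group_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(g$t, o$t, tolerance = 1e-9)
  expect_equal(g$p, o$p, tolerance = 1e-9)
  expect_equal(g$df, o$df)

  same <- group_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  degen <- group_test(c(1, 1), c(2, 2))
  expect_equal(degen$p, 0)
  expect_true(degen$degenerate)
})

test_that("group test is symmetric under swapping groups", {
  set.seed(5)
  for (i in 1:10) {
    a <- rnorm(6); b <- rnorm(6, 1)
    g1 <- group_test(a, b); g2 <- group_test(b, a)
    expect_equal(g1$t, -g2$t, tolerance = 1e-12)
    expect_equal(g1$p, g2$p, tolerance = 1e-12)
  }
})

test_that("device correlation: exact affine map gives R^2 = 1, shuffles near 0", {
  tt <- 0:599
  x <- sin(tt / 50) + tt / 600
  r <- device_correlation(tt, x, tt, 2 * x + 5)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  expect_equal(r$slope, 2, tolerance = 1e-9)

  # permutation oracle: expected R^2 of an unrelated trace ~ 1/(n-1)
  set.seed(9)
  r2s <- replicate(100, {
    device_correlation(tt, x, tt, sample(x))$r_squared
  })
  expect_lt(mean(r2s), 0.02)

  flat <- device_correlation(tt, rep(1, 600), tt, 2 * x)
  expect_true(flat$degenerate)
  expect_true(is.na(flat$r_squared))
})

test_that("heart-rate criterion applies the age-dependent strict threshold", {
  expect_true(pots_criterion(list(age = 14, hr_baseline_max = 76,
                                  hr_tilt_max = 123)))     # +47 > 40
  expect_false(pots_criterion(list(age = 22, hr_baseline_max = 66,
                                   hr_tilt_max = 85)))     # +19 < 30
  expect_false(pots_criterion(list(age = 25, hr_baseline_max = 70,
                                   hr_tilt_max = 100)))    # +30, strict
  expect_true(pots_criterion(list(age = 25, hr_baseline_max = 70,
                                  hr_tilt_max = 101)))
  expect_false(pots_criterion(list(age = 17, hr_baseline_max = 70,
                                   hr_tilt_max = 110)))    # +40, strict, child
  expect_error(pots_criterion(list(age = 20, hr_baseline_max = NA,
                                   hr_tilt_max = 100)), "non-missing")
  expect_error(pots_criterion(list(age = 20, hr_baseline_max = 10,
                                   hr_tilt_max = 100)), "physiological")
})

test_that("packaged subject table reproduces the group criterion split", {
  subj <- read_subjects()
  expect_equal(nrow(subj), 12)
  res <- vapply(seq_len(nrow(subj)), function(i)
    pots_criterion(as.list(subj[i, ])), logical(1))
  expect_true(all(res[subj$group == "POTS"]))
  expect_false(any(res[subj$group == "control"]))
})
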