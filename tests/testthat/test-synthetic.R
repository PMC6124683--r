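# Synthetic cohort generator: calibration, round trips, reproducibility.

test_that("template amplitudes follow the closed-form AUC calibration", {
  expect_equal(calibrate_amplitude(52, 4), 52 / 28)
  expect_equal(calibrate_amplitude(113, 30), 113 / 15)  # rises all tilt
  expect_equal(calibrate_amplitude(0, 5), 0)
  expect_error(calibrate_amplitude(-10, 5), "amplitude")
  expect_error(calibrate_amplitude(50, 31), "rise time")

  tpl <- default_templates()
  # amplitude * (30 - rise/2) gives back every AUC target
  expect_equal(tpl$plateau_uM * (30 - tpl$rise_min / 2), tpl$auc_target)
})

test_that("template trajectories are continuous, zero at baseline, and relax in recovery", {
  tt <- 0:2999
  y <- nirstilt:::template_trajectory(tt, plateau_uM = 2, rise_min = 4,
                                      recovery_tau_min = 2)
  expect_true(all(y[tt < 600] == 0))
  expect_lt(max(abs(diff(y))), 0.02)  # no jumps anywhere
  ramp <- tt > 600 & tt <= 600 + 4 * 60
  expect_equal(max(diff(y)[ramp[-1]]), 2 / (4 * 60), tolerance = 1e-9)
  expect_equal(y[tt == 840], 2)           # plateau reached at 4 min
  expect_equal(y[tt == 2399], 2)          # held to tilt end
  expect_equal(y[tt == 2400 + 120], 2 * exp(-1), tolerance = 1e-9)
})

test_that("with zero noise the generator inverts back to the templates", {
  spec <- cohort_spec(seed = 1, noise = noise_model(0, 0, 0))
  s <- generate_subject(spec, "POTS", subject_seed = 123)
  conc <- process_recording(s$recording, eps = spec$eps, path = spec$path)
  expect_lt(max(abs(conc$dC_Hb_uM - s$truth$dC_Hb_uM)), 1e-6)
  expect_lt(max(abs(conc$dC_HbO2_uM - s$truth$dC_HbO2_uM)), 1e-6)

  # the forward optical model cancels: a different extinction table and
  # pathlength still round-trip exactly
  eps2 <- extinction_table(c(735, 805, 850), c(1.2, 0.9, 0.7),
                           c(0.5, 0.95, 1.2))
  spec2 <- cohort_spec(seed = 1, noise = noise_model(0, 0, 0), eps = eps2,
                       path = pathlength_spec(2.5, 5.5))
  s2 <- generate_subject(spec2, "control", subject_seed = 99)
  conc2 <- process_recording(s2$recording, eps = eps2, path = spec2$path)
  expect_lt(max(abs(conc2$dC_Hb_uM - s2$truth$dC_Hb_uM)), 1e-6)
})

test_that("subject and cohort generation are seed-reproducible", {
  spec <- cohort_spec(seed = 42)
  a <- generate_subject(spec, "POTS", subject_seed = 7)
  b <- generate_subject(spec, "POTS", subject_seed = 7)
  expect_identical(a, b)
  c2 <- generate_subject(spec, "POTS", subject_seed = 8)
  expect_false(identical(a$recording$data$intensity,
                         c2$recording$data$intensity))

  coh1 <- generate_cohort(spec)
  coh2 <- generate_cohort(cohort_spec(seed = 42))
  expect_identical(coh1$subjects, coh2$subjects)
  expect_identical(coh1$manifest, coh2$manifest)
})

test_that("generation does not disturb R's global RNG stream", {
  set.seed(1234)
  before <- .Random.seed
  invisible(generate_cohort(cohort_spec(seed = 5, n_per_group = 2)))
  expect_identical(.Random.seed, before)
})

test_that("default subjects satisfy the heart-rate criterion by group", {
  coh <- generate_cohort(cohort_spec(seed = 42))
  for (s in coh$subjects) {
    got <- pots_criterion(s$meta)
    expect_identical(got, s$meta$group == "POTS")
  }
})

test_that("a written cohort has a stable manifest and re-readable files", {
  coh <- generate_cohort(cohort_spec(seed = 11, n_per_group = 2))
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  write_cohort(coh, d1)
  write_cohort(coh, d2)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_setequal(f1, f2)
  sum1 <- tools::md5sum(file.path(d1, sort(f1)))
  sum2 <- tools::md5sum(file.path(d2, sort(f2)))
  expect_identical(unname(sum1), unname(sum2))
  expect_error(write_cohort(coh, d1), "already contains")

  rec <- read_recording(file.path(d1, "POTS-1_recording.tsv"))
  expect_s3_class(rec, "raw_recording")
  expect_equal(nrow(rec$data), nrow(coh$subjects[["POTS-1"]]$recording$data))
})

test_that("a minimum-size cohort runs through the whole pipeline", {
  coh <- generate_cohort(cohort_spec(seed = 3, n_per_group = 2))
  res <- analyze_cohort(process_cohort(coh))
  expect_s3_class(res, "cohort_result")
  expect_true(all(is.finite(vapply(res$tests, `[[`, numeric(1), "p"))))
})

test_that("group trajectory shapes separate as designed on default cohorts", {
  coh <- generate_cohort(cohort_spec(seed = 42))
  res <- analyze_cohort(process_cohort(coh))

  sm <- res$segment_means
  tilt_hb <- sm[sm$segment == "tilt" & sm$signal == "dC_Hb_uM", ]
  expect_gt(tilt_hb$mean_uM[tilt_hb$group == "POTS"],
            tilt_hb$mean_uM[tilt_hb$group == "control"])

  # the control oxyhemoglobin upstroke is steeper over the first 2 min of
  # tilt (the initial-rise window), even though the 10-min window slope is
  # dominated by the later plateau
  proc <- process_cohort(coh)
  early <- vapply(proc, function(s) {
    seg <- segment_series(s$conc)
    r <- rate_of_change(seg$tilt, window_min = 2)
    r$slope_uM_per_min[r$signal == "dC_HbO2_uM"]
  }, numeric(1))
  groups <- vapply(proc, function(s) s$meta$group, character(1))
  expect_gt(mean(early[groups == "control"]), mean(early[groups == "POTS"]))
})
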