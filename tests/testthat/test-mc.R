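# Photon-transport kernel: conservation, boundaries, determinism, and the
# detected-photon statistics.

test_that("photon weight is conserved for a variety of models and seeds", {
  models <- list(
    default_tissue_model(805),
    default_tissue_model(735),
    tissue_model(list(optical_layer(Inf, 0.05, 5, g = 0.8, n = 1.4))),
    tissue_model(list(optical_layer(2, 0.02, 10, g = 0.9, n = 1.4),
                      optical_layer(Inf, 0.01, 2, g = 0, n = 1.33))),
    tissue_model(list(optical_layer(5, 0.1, 1, g = 0, n = 1.5)))  # finite slab
  )
  geom <- probe_geometry(1.0)
  for (i in seq_along(models)) {
    s <- simulate_probe(models[[i]], geom, n_photons = 2e4, seed = 100 + i)
    bal <- s$total_reflected + s$total_transmitted + s$total_absorbed
    expect_lt(abs(bal - s$launched_weight) / s$launched_weight, 1e-6)
    expect_true(all(s$fluence >= 0))
  }
})

test_that("an absorption-free slab reflects or transmits all weight", {
  slab <- tissue_model(list(optical_layer(3, 0, 5, g = 0.7, n = 1.0)),
                       n_ambient = 1.0)
  s <- simulate_probe(slab, probe_geometry(1.0), n_photons = 2e4, seed = 5)
  expect_equal(s$total_absorbed / s$launched_weight, 0, tolerance = 1e-12)
  expect_equal((s$total_reflected + s$total_transmitted) / s$launched_weight,
               1, tolerance = 1e-9)
})

test_that("matched refractive indices produce zero specular reflection", {
  m <- tissue_model(list(optical_layer(Inf, 0.01, 1, g = 0, n = 1.0)),
                    n_ambient = 1.0)
  s <- simulate_probe(m, probe_geometry(1.0), n_photons = 1e3, seed = 2)
  expect_identical(s$specular_reflected, 0)
  # mismatched index gives the normal-incidence Fresnel fraction
  m2 <- tissue_model(list(optical_layer(Inf, 0.01, 1, g = 0, n = 1.4)),
                     n_ambient = 1.0)
  s2 <- simulate_probe(m2, probe_geometry(1.0), n_photons = 1e3, seed = 2)
  expect_equal(s2$specular_reflected / s2$n_launched,
               ((1 - 1.4) / (1 + 1.4))^2, tolerance = 1e-12)
})

test_that("identical seed and inputs reproduce the simulation bit-identically", {
  m <- default_tissue_model(850)
  g <- probe_geometry(c(1, 2))
  s1 <- simulate_probe(m, g, n_photons = 1e4, seed = 99)
  s2 <- simulate_probe(m, g, n_photons = 1e4, seed = 99)
  expect_identical(s1, s2)
  s3 <- simulate_probe(m, g, n_photons = 1e4, seed = 100)
  expect_false(identical(s1$total_absorbed, s3$total_absorbed))
})

test_that("non-physical layer properties are rejected", {
  expect_error(optical_layer(1, -0.1, 1), "mu_a")
  expect_error(optical_layer(1, 0.1, -1), "mu_s")
  expect_error(optical_layer(1, 0.1, 1, g = 1), "anisotropy")
  expect_error(optical_layer(1, 0, 0), "zero total interaction")
  expect_error(tissue_model(list(optical_layer(Inf, 0.1, 1),
                                 optical_layer(1, 0.1, 1))),
               "only the last layer")
  expect_error(probe_geometry(c(1, 1.1)), "overlap")
  expect_error(probe_geometry(0.1, detector_radius_mm = 1.5), "source")
})

test_that("penetration statistics summarise detected max depth correctly", {
  # constant-depth records give that depth back for every statistic
  d <- data.frame(exit_weight = runif(200, 0.1, 1), exit_radius_cm = 2,
                  max_depth_cm = 0.5, total_path_mm = 80,
                  path_muscle_mm = 80)
  s <- fake_mc_summary(d)
  p <- penetration_stats(s, 1)
  expect_equal(p$median_cm, 0.5)
  expect_equal(p$mean_cm, 0.5)
  expect_equal(p$q95_cm, 0.5)
  # insufficient statistics are refused with the count in the message
  s2 <- fake_mc_summary(d[1:7, ])
  expect_error(penetration_stats(s2, 1), "only 7 photons")
})

test_that("mean pathlength reduces to the single record and sums partials", {
  d <- data.frame(exit_weight = 1, exit_radius_cm = 2, max_depth_cm = 0.5,
                  total_path_mm = 33, path_dermis_mm = 1,
                  path_subdermis_mm = 2, path_muscle_mm = 30)
  pl <- mean_pathlength(fake_mc_summary(d), 1, min_n = 1)
  expect_equal(pl$total_mm, 33)
  expect_equal(unname(pl$per_layer_mm), c(1, 2, 30))
  expect_equal(pl$dpf, 33 / 20)
})

test_that("recorded partial paths sum to the total trajectory length", {
  m <- default_tissue_model(805)
  s <- simulate_probe(m, probe_geometry(1.0), n_photons = 5e4, seed = 21)
  d <- s$detected[[1]]
  expect_gt(nrow(d), 50)
  sums <- rowSums(d[, grep("^path_", names(d))])
  expect_lt(max(abs(sums - d$total_path_mm)), 1e-9)
})

test_that("separation scan: duplicated separations give identical rows and
           counts fall while depth grows with separation", {
  m <- default_tissue_model(805)
  dup <- separation_scan(m, c(2, 2), n_photons = 3e4, seed = 13)
  expect_equal(dup[1, ], dup[2, ], ignore_attr = TRUE)

  scan <- separation_scan(m, c(1, 2), n_photons = 2e5, seed = 17)
  expect_true(all(diff(scan$n_detected) < 0))
  expect_true(all(diff(scan$median_depth_cm) > 0))

  # the scan reproduces a dedicated single-separation run at the same seed
  solo <- simulate_probe(m, probe_geometry(2.0), n_photons = 2e5, seed = 17)
  expect_identical(attr(scan, "summary")$detected[[2]], solo$detected[[1]])
})

test_that("differential pathlength factor lies in the literature band for muscle", {
  m <- default_tissue_model(805)
  s <- simulate_probe(m, probe_geometry(2.0), n_photons = 5e5, seed = 7)
  dpf <- mean_pathlength(s, 1)$dpf
  expect_gt(dpf, 3)
  expect_lt(dpf, 6)
})
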