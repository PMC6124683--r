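# Independent oracles and small fixture builders. Nothing here calls the
# package's own computational path for the quantity it checks.

# Steady-state diffusion-approximation diffuse reflectance of a pencil beam
# on a semi-infinite homogeneous medium with matched boundary (dipole
# source, extrapolated boundary at 2D for A = 1). Per mm^2 per launched
# photon; rho in mm, coefficients in mm^-1.
diffusion_reflectance <- function(rho_mm, mu_a, mu_sp) {
  mu_tp <- mu_a + mu_sp
  z0 <- 1 / mu_tp
  D <- 1 / (3 * mu_tp)
  mu_eff <- sqrt(3 * mu_a * mu_tp)
  zb <- 2 * D
  r1 <- sqrt(z0^2 + rho_mm^2)
  r2 <- sqrt((z0 + 2 * zb)^2 + rho_mm^2)
  (1 / (4 * pi)) * (z0 * (mu_eff + 1 / r1) * exp(-mu_eff * r1) / r1^2 +
    (z0 + 2 * zb) * (mu_eff + 1 / r2) * exp(-mu_eff * r2) / r2^2)
}

# Textbook pooled-variance two-sample t-test (equal variances, two-sided).
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, df = na + nb - 2, p = 2 * pt(-abs(t), na + nb - 2))
}

# Brute-force normal-equations least squares: solve (X'X) b = X'y.
normal_equations_oracle <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# Forward modified Beer-Lambert model: attenuation from known
# concentration pairs (uM), built directly from the published relation,
# independent of the package's solver.
forward_attenuation <- function(c_hb_uM, c_hbo2_uM, eps, path,
                                time_s = seq_along(c_hb_uM) - 1,
                                detector = "D1") {
  wl <- c(735, 805, 850)
  sub <- eps[match(wl, eps$wavelength_nm), ]
  rows <- lapply(seq_along(wl), function(j) {
    dA <- unname(path$L_cm[j]) * (sub$eps_hb[j] * c_hb_uM +
                                    sub$eps_hbo2[j] * c_hbo2_uM) / 1000
    data.frame(time_s = time_s, detector = detector,
               wavelength_nm = wl[j], delta_A = dA)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("attenuation_series", "data.frame")
  out
}

# Constant-intensity recording fixture (all three wavelengths, one or two
# detectors).
flat_recording <- function(n = 20, intensity = 100, detectors = "D1",
                           baseline_window = c(0, 10)) {
  g <- expand.grid(time_s = seq_len(n) - 1, detector = detectors,
                   wavelength_nm = c(735, 805, 850),
                   stringsAsFactors = FALSE)
  g$intensity <- intensity
  raw_recording(g, baseline_window = baseline_window)
}

# A minimal mc_summary stand-in for testing the detected-photon statistics
# paths on controlled records.
fake_mc_summary <- function(detected_df, separation_cm = 2) {
  structure(list(detected = list(detected_df),
                 geometry = list(separations_cm = separation_cm),
                 n_launched = nrow(detected_df),
                 launched_weight = nrow(detected_df)),
            class = "mc_summary")
}

# Concentration series on the default protocol grid from explicit signals.
conc_series <- function(time_s, hb = 0, hbo2 = 0) {
  d <- data.frame(time_s = time_s,
                  dC_Hb_uM = rep_len(hb, length(time_s)),
                  dC_HbO2_uM = rep_len(hbo2, length(time_s)))
  derive_oxy_bv(d)
}
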