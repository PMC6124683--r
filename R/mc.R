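#' Monte Carlo photon transport in a layered tissue model
#'
#' Weighted (implicit-capture) Monte Carlo simulation of photon propagation:
#' hop-drop-spin transport with Henyey-Greenstein scattering, unpolarised
#' Fresnel reflection/refraction at every refractive-index boundary,
#' absorbed-weight deposition into a cylindrical (r, z) fluence grid, a
#' radial diffuse-reflectance histogram, and Russian-roulette termination of
#' low-weight photons. Photons escaping through the surface inside a
#' detector aperture are recorded individually (exit weight, exit radius,
#' maximum depth reached, per-layer partial path), which is what makes
#' penetration-depth and pathlength statistics per detector possible.
#'
#' The roulette renormalisation is folded into the absorbed-weight ledger so
#' that `total_reflected + total_transmitted + total_absorbed` equals the
#' launched weight to floating-point rounding for every run.
#'
#' @param model a [tissue_model()].
#' @param geometry a [probe_geometry()].
#' @param n_photons number of photons to launch (>= 1).
#' @param seed integer RNG seed; identical seed and inputs give
#'   bit-identical results (the kernel has its own seeded generator and does
#'   not touch R's RNG state).
#' @param wavelength_nm optional label recorded in the summary.
#' @param roulette_threshold,roulette_survive Russian-roulette weight
#'   threshold and survival probability.
#' @param fluence_dr_mm,fluence_dz_mm,fluence_rmax_mm,fluence_zmax_mm
#'   fluence-grid voxel size and extent.
#' @param refl_dr_mm radial bin width of the diffuse-reflectance histogram.
#' @return an `mc_summary` list: totals (`total_reflected`, including the
#'   specular component, `total_transmitted`, `total_absorbed`,
#'   `launched`), `detected` (one data frame per detector with columns
#'   `exit_weight`, `exit_radius_cm`, `max_depth_cm`, `total_path_mm` and
#'   one `path_*_mm` column per layer), `reflectance` (radial histogram with
#'   `R_per_mm2`, diffuse reflectance per unit area per launched photon),
#'   `fluence` (matrix, rows = depth voxels), and the inputs echoed.
#' @examples
#' m <- default_tissue_model(805)
#' s <- simulate_probe(m, probe_geometry(2.0), n_photons = 1e4, seed = 1)
#' s$total_reflected + s$total_transmitted + s$total_absorbed  # == launched
#' @export
simulate_probe <- function(model, geometry, n_photons = 1e6, seed = 1,
                           wavelength_nm = NA_real_,
                           roulette_threshold = 1e-4, roulette_survive = 0.1,
                           fluence_dr_mm = 0.1, fluence_dz_mm = 0.1,
                           fluence_rmax_mm = 40, fluence_zmax_mm = 20,
                           refl_dr_mm = 0.5) {
  stopifnot(inherits(model, "tissue_model"), inherits(geometry, "probe_geometry"))
  if (n_photons < 1) stop("n_photons must be >= 1")
  seed <- as.numeric(seed)
  if (seed < 0) stop("seed must be a non-negative integer")

  nl <- length(model$layers)
  props <- t(vapply(seq_len(nl), function(i) {
    L <- model$layers[[i]]
    c(model$z_top_mm[i], model$z_bot_mm[i], L$mu_a, L$mu_s, L$g, L$n)
  }, numeric(6)))

  nr <- as.integer(round(fluence_rmax_mm / fluence_dr_mm))
  nz <- as.integer(round(fluence_zmax_mm / fluence_dz_mm))
  nb <- as.integer(round(100 / refl_dr_mm))  # histogram out to 100 mm

  raw <- .mc_run(props, model$n_ambient, geometry$separations_cm * 10,
                 geometry$detector_radius_mm, as.numeric(n_photons), seed,
                 roulette_threshold, roulette_survive,
                 nr, nz, fluence_dr_mm, fluence_dz_mm, nb, refl_dr_mm)

  layer_names <- vapply(seq_len(nl), function(i) {
    nm <- model$layers[[i]]$name
    if (is.na(nm)) paste0("layer", i) else nm
  }, character(1))

  detected <- lapply(raw$detected, function(m) {
    d <- as.data.frame(m)
    names(d) <- c("exit_weight", "exit_radius_mm", "max_depth_mm",
                  "total_path_mm", paste0("path_", layer_names, "_mm"))
    d$exit_radius_cm <- d$exit_radius_mm / 10
    d$max_depth_cm <- d$max_depth_mm / 10
    d[, c("exit_weight", "exit_radius_cm", "max_depth_cm", "total_path_mm",
          paste0("path_", layer_names, "_mm"))]
  })

  hist_w <- raw$refl_hist
  n_bins <- length(hist_w) - 1L
  r_lo <- (seq_len(n_bins) - 1) * refl_dr_mm
  r_hi <- r_lo + refl_dr_mm
  area <- pi * (r_hi^2 - r_lo^2)
  reflectance <- data.frame(r_lo_mm = r_lo, r_hi_mm = r_hi,
                            weight = hist_w[seq_len(n_bins)],
                            R_per_mm2 = hist_w[seq_len(n_bins)] /
                              (n_photons * area))

  structure(list(
    n_launched = n_photons,
    launched_weight = n_photons,
    total_reflected = raw$total_reflected,
    specular_reflected = raw$specular,
    total_transmitted = raw$total_transmitted,
    total_absorbed = raw$total_absorbed,
    detected = detected,
    reflectance = reflectance,
    reflectance_overflow_weight = hist_w[n_bins + 1L],
    fluence = raw$fluence,
    fluence_dr_mm = fluence_dr_mm, fluence_dz_mm = fluence_dz_mm,
    seed = seed, wavelength_nm = wavelength_nm,
    model = model, geometry = geometry),
    class = "mc_summary")
}

#' @export
print.mc_summary <- function(x, ...) {
  cat("<mc_summary>", format(x$n_launched, big.mark = ","), "photons, seed",
      x$seed, "\n")
  cat(sprintf("  reflected %.4f  transmitted %.4f  absorbed %.4f (fractions)\n",
              x$total_reflected / x$launched_weight,
              x$total_transmitted / x$launched_weight,
              x$total_absorbed / x$launched_weight))
  for (i in seq_along(x$detected))
    cat(sprintf("  detector %d at %.1f cm: %d photons, weight %.3g\n", i,
                x$geometry$separations_cm[i], nrow(x$detected[[i]]),
                sum(x$detected[[i]]$exit_weight)))
  invisible(x)
}

# weighted quantile (type-4-like, linear interpolation on the weighted ECDF)
weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) - w / 2
  cw <- cw / sum(w)
  vapply(probs, function(p) {
    if (p <= cw[1]) return(x[1])
    if (p >= cw[length(cw)]) return(x[length(x)])
    approx(cw, x, xout = p, ties = "ordered")$y
  }, numeric(1))
}

detector_records <- function(summary, detector_index, min_n = 100) {
  stopifnot(inherits(summary, "mc_summary"))
  if (detector_index < 1 || detector_index > length(summary$detected))
    stop("no detector with index ", detector_index)
  d <- summary$detected[[detector_index]]
  if (nrow(d) < min_n)
    stop("insufficient statistics: only ", nrow(d),
         " photons detected at detector ", detector_index,
         " (need >= ", min_n, ")")
  d
}

#' Penetration-depth statistics of detected photons
#'
#' Exit-weight-weighted median, mean and 95th percentile of the maximum
#' depth reached by the photons collected at one detector — the standard
#' summary of how deep a reflectance measurement interrogates.
#'
#' @param summary an `mc_summary` from [simulate_probe()].
#' @param detector_index which detector.
#' @param min_n minimum detected-photon count below which the statistics
#'   are refused as unreliable.
#' @return list with `median_cm`, `mean_cm`, `q95_cm`, `n_detected`.
#' @export
penetration_stats <- function(summary, detector_index = 1, min_n = 100) {
  d <- detector_records(summary, detector_index, min_n)
  w <- d$exit_weight
  list(median_cm = weighted_quantile(d$max_depth_cm, w, 0.5),
       mean_cm = sum(w * d$max_depth_cm) / sum(w),
       q95_cm = weighted_quantile(d$max_depth_cm, w, 0.95),
       n_detected = nrow(d))
}

#' Mean optical path length and differential pathlength factor
#'
#' Exit-weight-weighted mean of the total and per-layer path lengths of the
#' photons collected at one detector, and the differential pathlength
#' factor DPF = mean total path / source-detector separation.
#'
#' @inheritParams penetration_stats
#' @return list with `total_mm`, `per_layer_mm` (named), `dpf`,
#'   `n_detected`.
#' @export
mean_pathlength <- function(summary, detector_index = 1, min_n = 100) {
  d <- detector_records(summary, detector_index, min_n)
  w <- d$exit_weight / sum(d$exit_weight)
  path_cols <- grep("^path_.*_mm$", names(d), value = TRUE)
  per_layer <- vapply(path_cols, function(cl) sum(w * d[[cl]]), numeric(1))
  names(per_layer) <- sub("^path_(.*)_mm$", "\\1", path_cols)
  total <- sum(w * d$total_path_mm)
  sep_mm <- summary$geometry$separations_cm[detector_index] * 10
  list(total_mm = total, per_layer_mm = per_layer, dpf = total / sep_mm,
       n_detected = nrow(d))
}

#' Source-detector separation scan
#'
#' One simulation scored simultaneously at several separations: detected
#' photon count falls and median penetration depth grows with separation,
#' which is the trade-off that fixes the probe geometry.
#'
#' @param model a [tissue_model()].
#' @param separations_cm two or more detector separations, cm.
#' @param n_photons,seed passed to [simulate_probe()].
#' @param detector_radius_mm aperture radius, mm.
#' @param ... further arguments to [simulate_probe()].
#' @return data frame with one row per separation: `separation_cm`,
#'   `n_detected`, `detected_weight`, `median_depth_cm`, `dpf`.
#' @export
separation_scan <- function(model, separations_cm, n_photons = 1e6, seed = 1,
                            detector_radius_mm = 1.5, ...) {
  if (length(separations_cm) < 2)
    stop("a separation scan needs at least 2 separations")
  geom <- probe_geometry(separations_cm, detector_radius_mm)
  s <- simulate_probe(model, geom, n_photons = n_photons, seed = seed, ...)
  rows <- lapply(seq_along(separations_cm), function(i) {
    d <- s$detected[[i]]
    data.frame(separation_cm = separations_cm[i],
               n_detected = nrow(d),
               detected_weight = sum(d$exit_weight),
               median_depth_cm = if (nrow(d) >= 1)
                 weighted_quantile(d$max_depth_cm, d$exit_weight, 0.5)
               else NA_real_,
               dpf = if (nrow(d) >= 1)
                 sum(d$exit_weight * d$total_path_mm) /
                   sum(d$exit_weight) / (separations_cm[i] * 10)
               else NA_real_)
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <- s
  out
}

#' Write detected-photon records to a TSV file
#'
#' @param summary an `mc_summary`.
#' @param file output path.
#' @param detector_index which detector's records to write.
#' @export
write_detected <- function(summary, file, detector_index = 1) {
  stopifnot(inherits(summary, "mc_summary"))
  write.table(summary$detected[[detector_index]], file, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(file)
}
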