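#' Raw three-wavelength reflectance recording
#'
#' Container for a detected-intensity time series in long format: one row
#' per (time, detector, wavelength). Intensities are arbitrary linear
#' units; only ratios to the baseline enter the analysis.
#'
#' @param data data frame with columns `time_s`, `detector`,
#'   `wavelength_nm`, `intensity`.
#' @param baseline_window length-2 numeric, the `[start, end)` interval in
#'   seconds whose mean intensity defines the incident reference I_o
#'   (default the 10-min supine baseline).
#' @param sample_rate Hz; inferred from the time axis when `NULL`.
#' @return a `raw_recording` object.
#' @export
raw_recording <- function(data, baseline_window = c(0, 600),
                          sample_rate = NULL) {
  need <- c("time_s", "detector", "wavelength_nm", "intensity")
  if (!all(need %in% names(data)))
    stop("recording needs columns: ", paste(need, collapse = ", "))
  bad <- which(data$intensity <= 0)
  if (length(bad))
    stop("non-positive intensity at row(s) ", paste(head(bad, 5), collapse = ", "))
  wl <- sort(unique(data$wavelength_nm))
  if (!all(device_wavelengths() %in% wl))
    stop("recording must contain all three device wavelengths (735/805/850 nm)")
  if (length(baseline_window) != 2 || diff(baseline_window) <= 0)
    stop("baseline_window must be an increasing [start, end) pair in seconds")
  key <- interaction(data$detector, data$wavelength_nm, drop = TRUE)
  for (k in levels(key)) {
    tt <- data$time_s[key == k]
    if (is.unsorted(tt, strictly = TRUE))
      stop("time axis must be strictly increasing within each ",
           "detector/wavelength trace")
  }
  if (is.null(sample_rate)) {
    tt <- sort(unique(data$time_s))
    sample_rate <- 1 / median(diff(tt))
  }
  structure(list(data = data, baseline_window = baseline_window,
                 sample_rate = sample_rate),
            class = "raw_recording")
}

#' Attenuation change from a raw recording
#'
#' For each detector and wavelength, the incident reference I_o is the mean
#' detected intensity over the baseline window, and the attenuation change
#' is the decadic optical density `delta_A(t) = -log10(I(t) / I_o)`. The
#' decadic convention is paired with decadic extinction coefficients in
#' [solve_concentrations()]; the choice of base cancels as long as the two
#' are consistent.
#'
#' @param rec a [raw_recording()].
#' @return an `attenuation_series`: data frame `time_s`, `detector`,
#'   `wavelength_nm`, `delta_A`, with the per-trace I_o table in
#'   `attr(, "baseline_intensity")`.
#' @examples
#' d <- expand.grid(time_s = 0:9, detector = "D1",
#'                  wavelength_nm = c(735, 805, 850))
#' d$intensity <- 100
#' rec <- raw_recording(d, baseline_window = c(0, 5))
#' all(delta_attenuation(rec)$delta_A == 0)
#' @export
delta_attenuation <- function(rec) {
  stopifnot(inherits(rec, "raw_recording"))
  d <- rec$data
  bw <- rec$baseline_window
  in_base <- d$time_s >= bw[1] & d$time_s < bw[2]
  if (sum(in_base) < 2 * length(unique(d$detector)) * 3)
    stop("baseline window must contain at least 2 samples per trace")
  key <- paste(d$detector, d$wavelength_nm)
  io <- tapply(d$intensity[in_base], key[in_base], mean)
  if (anyNA(io[unique(key)]))
    stop("baseline window is empty for at least one detector/wavelength trace")
  out <- data.frame(time_s = d$time_s, detector = d$detector,
                    wavelength_nm = d$wavelength_nm,
                    delta_A = -log10(d$intensity / io[key]))
  rownames(out) <- NULL
  io_tab <- data.frame(key = names(io), I_o = as.numeric(io))
  structure(out, baseline_intensity = io_tab,
            class = c("attenuation_series", "data.frame"))
}

#' Optical pathlength specification
#'
#' The effective optical path L that scales attenuation into concentration:
#' L = DPF x source-detector separation, per wavelength. The differential
#' pathlength factor can be a single value (default 4, mid-range for
#' muscle) or one value per wavelength, e.g. taken from
#' [mean_pathlength()] output.
#'
#' @param separation_cm source-detector separation, cm.
#' @param dpf differential pathlength factor, scalar or one per wavelength.
#' @param wavelengths_nm wavelengths the DPF values refer to.
#' @return a `pathlength_spec` with `L_cm` per wavelength.
#' @export
pathlength_spec <- function(separation_cm = 2.0, dpf = 4.0,
                            wavelengths_nm = device_wavelengths()) {
  if (separation_cm <= 0) stop("separation must be positive")
  if (any(dpf <= 0)) stop("DPF must be positive")
  dpf <- rep_len(dpf, length(wavelengths_nm))
  structure(list(separation_cm = separation_cm,
                 dpf = setNames(dpf, wavelengths_nm),
                 wavelengths_nm = wavelengths_nm,
                 L_cm = setNames(dpf * separation_cm, wavelengths_nm)),
            class = "pathlength_spec")
}

#' Solve the three-wavelength system for concentration changes
#'
#' Per time point, the attenuation changes at 735/805/850 nm form three
#' linear equations in the two unknown concentration changes
#' (deoxyhemoglobin and oxyhemoglobin):
#' `delta_A(lambda) = L(lambda) * (eps_Hb(lambda) dC_Hb +
#' eps_HbO2(lambda) dC_HbO2)`. The over-determined system is solved by
#' ordinary least squares; the per-time-point residual norm is reported for
#' quality control.
#'
#' @param att an `attenuation_series` from [delta_attenuation()].
#' @param eps an [extinction_table()] covering the device wavelengths.
#' @param path a [pathlength_spec()].
#' @param detector `"mean"` (default) to average the attenuation of all
#'   detectors before inversion, or a detector label to use one detector.
#' @return a `concentration_series`: data frame `time_s`, `dC_Hb_uM`,
#'   `dC_HbO2_uM` (micromolar) and `residual` (the least-squares residual
#'   norm in optical-density units, a per-time-point fit diagnostic).
#' @export
solve_concentrations <- function(att, eps = default_extinction(),
                                 path = pathlength_spec(),
                                 detector = "mean") {
  stopifnot(inherits(att, "attenuation_series"))
  wl <- device_wavelengths()
  if (!all(wl %in% att$wavelength_nm))
    stop("attenuation series must contain all three device wavelengths")
  sub <- validate_extinction(eps, wl)

  agg <- if (identical(detector, "mean")) att else {
    sub_det <- att[att$detector == detector, , drop = FALSE]
    if (nrow(sub_det) == 0) stop("no detector labelled '", detector, "'")
    sub_det
  }
  # wide: rows = time, cols = wavelengths (mean over detectors per cell)
  tt <- sort(unique(agg$time_s))
  it <- match(agg$time_s, tt)
  iw <- match(agg$wavelength_nm, wl)
  idx <- it + (iw - 1L) * length(tt)
  sums <- counts <- numeric(length(tt) * length(wl))
  sums <- unname(rowsum(agg$delta_A, idx, reorder = TRUE))[, 1]
  counts <- as.vector(table(idx))
  if (length(sums) != length(tt) * length(wl) || any(counts == 0))
    stop("missing attenuation samples on the common time grid")
  A <- matrix(sums / counts, nrow = length(tt), ncol = length(wl))
  if (anyNA(A)) stop("missing attenuation samples on the common time grid")

  # design: delta_A = D %*% c, concentrations in mM (eps in cm^-1 mM^-1)
  D <- diag(path$L_cm[as.character(wl)]) %*% cbind(sub$eps_hb, sub$eps_hbo2)
  cond <- kappa(D, exact = TRUE)
  if (!is.finite(cond) || cond > 1e8)
    stop("extinction design is rank-deficient (condition number ",
         format(cond, digits = 3), ")")
  # least squares for all time points at once: C = pinv(D) %*% t(A)
  P <- solve(crossprod(D), t(D))
  C_mM <- t(P %*% t(A))                  # n x 2
  fitted <- C_mM %*% t(D)
  resid <- sqrt(rowSums((A - fitted)^2))

  out <- data.frame(time_s = tt,
                    dC_Hb_uM = C_mM[, 1] * 1000,
                    dC_HbO2_uM = C_mM[, 2] * 1000,
                    residual = resid)
  structure(out, condition_number = cond,
            class = c("concentration_series", "data.frame"))
}

#' Derive oxygenation and blood-volume indices
#'
#' Adds the two derived signals to a concentration series: the oxygenation
#' change `dOxy = dC_HbO2 - dC_Hb` (negative values mean oxygen is consumed
#' faster than it is supplied) and the blood-volume surrogate
#' `dBV = dC_HbO2 + dC_Hb` (total hemoglobin change).
#'
#' @param conc a `concentration_series` with `dC_Hb_uM`, `dC_HbO2_uM`.
#' @return the series with `dOxy_uM` and `dBV_uM` columns filled.
#' @export
derive_oxy_bv <- function(conc) {
  if (!all(c("dC_Hb_uM", "dC_HbO2_uM") %in% names(conc)))
    stop("concentration series must have dC_Hb_uM and dC_HbO2_uM")
  conc$dOxy_uM <- conc$dC_HbO2_uM - conc$dC_Hb_uM
  conc$dBV_uM <- conc$dC_HbO2_uM + conc$dC_Hb_uM
  if (!inherits(conc, "concentration_series"))
    class(conc) <- c("concentration_series", class(conc))
  conc
}

#' Full recording-to-concentration pipeline
#'
#' [delta_attenuation()], [solve_concentrations()] and [derive_oxy_bv()]
#' chained.
#'
#' @inheritParams solve_concentrations
#' @param rec a [raw_recording()].
#' @return a `concentration_series` with all four signals.
#' @export
process_recording <- function(rec, eps = default_extinction(),
                              path = pathlength_spec(), detector = "mean") {
  derive_oxy_bv(solve_concentrations(delta_attenuation(rec), eps, path,
                                     detector = detector))
}
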