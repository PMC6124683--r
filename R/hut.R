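#' Head-up-tilt protocol definition
#'
#' The standard protocol: 10 min supine baseline at 0 degrees, 30 min
#' tilted at 70 degrees, 10 min supine recovery; the posture change takes
#' about 5 s and is assigned to the segment it initiates.
#'
#' @param segments data frame with columns `label`, `angle_deg`,
#'   `duration_min`.
#' @param transition_s nominal posture-transition time, seconds.
#' @return a `protocol_definition`.
#' @export
protocol_definition <- function(segments = data.frame(
                                  label = c("baseline", "tilt", "recovery"),
                                  angle_deg = c(0, 70, 0),
                                  duration_min = c(10, 30, 10)),
                                transition_s = 5) {
  stopifnot(all(c("label", "angle_deg", "duration_min") %in% names(segments)))
  if (any(segments$duration_min <= 0)) stop("segment durations must be positive")
  if (anyDuplicated(segments$label)) stop("segment labels must be unique")
  structure(list(segments = segments, transition_s = transition_s,
                 total_min = sum(segments$duration_min)),
            class = "protocol_definition")
}

signal_columns <- function(x)
  intersect(c("dC_Hb_uM", "dC_HbO2_uM", "dOxy_uM", "dBV_uM"), names(x))

#' Segment a concentration series by the tilt protocol
#'
#' Splits the series into half-open time windows `[start, end)` per
#' protocol segment; the windows partition the full protocol duration, and
#' the 5 s posture transition belongs to the segment it starts.
#'
#' @param conc a `concentration_series` (any data frame with `time_s`).
#' @param proto a [protocol_definition()].
#' @return named list of sub-series, one per segment label, each with a
#'   `segment_start_s` attribute.
#' @export
segment_series <- function(conc, proto = protocol_definition()) {
  stopifnot("time_s" %in% names(conc))
  tt <- conc$time_s
  dt <- median(diff(sort(unique(tt))))
  total_s <- proto$total_min * 60
  n_expected <- round(total_s / dt)
  if (length(tt) < n_expected)
    stop("recording shorter than the protocol: ", n_expected - length(tt),
         " missing samples (", n_expected, " expected at ",
         format(1 / dt, digits = 3), " Hz)")
  bounds <- cumsum(c(0, proto$segments$duration_min * 60))
  out <- lapply(seq_len(nrow(proto$segments)), function(i) {
    sel <- tt >= bounds[i] & tt < bounds[i + 1]
    sub <- conc[sel, , drop = FALSE]
    attr(sub, "segment_start_s") <- bounds[i]
    attr(sub, "segment_label") <- proto$segments$label[i]
    sub
  })
  names(out) <- proto$segments$label
  out
}

#' Mean and standard error of each signal over a segment
#'
#' @param sub one segment from [segment_series()] (>= 2 samples).
#' @return data frame with `signal`, `mean_uM`, `se_uM`, `n`.
#' @export
segment_average <- function(sub) {
  if (nrow(sub) < 2) stop("segment must contain at least 2 samples")
  cols <- signal_columns(sub)
  if (!length(cols)) stop("no concentration signal columns found")
  data.frame(signal = cols,
             mean_uM = vapply(cols, function(cl) mean(sub[[cl]]), numeric(1)),
             se_uM = vapply(cols, function(cl)
               sd(sub[[cl]]) / sqrt(nrow(sub)), numeric(1)),
             n = nrow(sub), row.names = NULL)
}

#' Rate of change after a posture change
#'
#' Ordinary least-squares slope of each signal against time over the first
#' `window_min` minutes of a segment (default 10 min, the window used to
#' compare the post-tilt and post-recline responses). Note that a long
#' window dilutes a fast early upstroke that plateaus; pass a shorter
#' window to quantify the initial rise itself.
#'
#' @param sub one segment from [segment_series()].
#' @param window_min slope window from the segment start, minutes.
#' @return data frame with `signal`, `slope_uM_per_min`.
#' @export
rate_of_change <- function(sub, window_min = 10) {
  t0 <- attr(sub, "segment_start_s")
  if (is.null(t0)) t0 <- min(sub$time_s)
  sel <- sub$time_s >= t0 & sub$time_s < t0 + window_min * 60
  w <- sub[sel, , drop = FALSE]
  if (nrow(w) < 3) stop("slope window must contain at least 3 samples")
  t_min <- (w$time_s - t0) / 60
  if (sd(t_min) == 0) stop("degenerate time axis in slope window")
  cols <- signal_columns(w)
  data.frame(signal = cols,
             slope_uM_per_min = vapply(cols, function(cl)
               unname(coef(lm(w[[cl]] ~ t_min))[2]), numeric(1)),
             row.names = NULL)
}

#' Area under the curve over the tilt segment
#'
#' Trapezoidal integral of each concentration-change signal over the tilt
#' window, time in minutes; units micromolar x minutes. The signals are
#' already changes from baseline, so the integrand is used as-is.
#'
#' @param sub the tilt segment from [segment_series()].
#' @return data frame with `signal`, `auc_uM_min`.
#' @export
auc_tilt <- function(sub) {
  if (nrow(sub) < 2) stop("AUC needs at least 2 samples")
  t_min <- sub$time_s / 60
  cols <- signal_columns(sub)
  data.frame(signal = cols,
             auc_uM_min = vapply(cols, function(cl)
               pracma::trapz(t_min, sub[[cl]]), numeric(1)),
             row.names = NULL)
}

#' Two-sample Student t-test between groups
#'
#' Equal-variance two-tailed Student t-test on per-subject statistics, the
#' comparison used for every group contrast here (significance threshold
#' alpha = 0.01 per signal, no multiplicity correction). Welch's unequal-
#' variance form is available behind `var_equal = FALSE`.
#'
#' @param values_a,values_b per-subject statistics (>= 2 each).
#' @param alpha significance threshold.
#' @param var_equal pool the variances (classical Student form)?
#' @return list with `t`, `df`, `p`, `significant`, `degenerate`.
#' @export
group_test <- function(values_a, values_b, alpha = 0.01, var_equal = TRUE) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("each group needs at least 2 subjects")
  if (sd(values_a) == 0 && sd(values_b) == 0) {
    if (isTRUE(all.equal(mean(values_a), mean(values_b))))
      return(list(t = 0, df = length(values_a) + length(values_b) - 2, p = 1,
                  significant = FALSE, degenerate = TRUE))
    return(list(t = Inf, df = length(values_a) + length(values_b) - 2, p = 0,
                significant = TRUE, degenerate = TRUE))
  }
  ht <- t.test(values_a, values_b, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, significant = ht$p.value < alpha, degenerate = FALSE)
}

#' Cross-device correlation of oxygenation traces
#'
#' Coefficient of determination (R^2) of a simple linear regression of a
#' reference oximeter's oxygenation trace on the device's dOxy series over
#' the tilt window. The reference is resampled onto the device time grid by
#' linear interpolation; the unit mismatch (percent vs micromolar) is
#' absorbed by the regression and does not affect R^2.
#'
#' @param device_time_s,device_oxy device dOxy series (time s, micromolar).
#' @param ref_time_s,ref_oxy reference trace (time s, percent units).
#' @param window optional `[start, end)` time window in seconds (e.g. the
#'   tilt segment); `NULL` uses the overlap of the two series.
#' @return list with `r_squared`, `slope`, `intercept`, `n`, `degenerate`.
#' @export
device_correlation <- function(device_time_s, device_oxy, ref_time_s, ref_oxy,
                               window = NULL) {
  if (is.null(window))
    window <- c(max(min(device_time_s), min(ref_time_s)),
                min(max(device_time_s), max(ref_time_s)) + 1e-9)
  sel <- device_time_s >= window[1] & device_time_s < window[2] &
    device_time_s >= min(ref_time_s) & device_time_s <= max(ref_time_s)
  td <- device_time_s[sel]
  if (length(td) < 3) stop("need at least 3 overlapping points")
  x <- device_oxy[sel]
  y <- approx(ref_time_s, ref_oxy, xout = td)$y
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r_squared = NA_real_, slope = NA_real_,
                intercept = NA_real_, n = length(td), degenerate = TRUE))
  fit <- lm(y ~ x)
  list(r_squared = cor(x, y)^2, slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]), n = length(td), degenerate = FALSE)
}

#' Postural-tachycardia heart-rate criterion
#'
#' TRUE when the heart-rate rise from the supine baseline maximum to the
#' tilt maximum exceeds the age-dependent threshold: strictly greater than
#' 40 bpm for children (< 18 years), strictly greater than 30 bpm for
#' adults.
#'
#' @param subject list or one-row data frame with `age`,
#'   `hr_baseline_max`, `hr_tilt_max`.
#' @return logical.
#' @examples
#' pots_criterion(list(age = 14, hr_baseline_max = 76, hr_tilt_max = 123))
#' @export
pots_criterion <- function(subject) {
  need <- c("age", "hr_baseline_max", "hr_tilt_max")
  vals <- lapply(need, function(f) subject[[f]])
  if (any(vapply(vals, function(v) is.null(v) || is.na(v), logical(1))))
    stop("subject record needs non-missing: ", paste(need, collapse = ", "))
  hr <- c(subject$hr_baseline_max, subject$hr_tilt_max)
  if (any(hr < 30 | hr > 250))
    stop("heart-rate values outside the physiological range 30-250 bpm")
  delta <- subject$hr_tilt_max - subject$hr_baseline_max
  threshold <- if (subject$age < 18) 40 else 30
  delta > threshold
}

#' Group-level analysis of a processed cohort
#'
#' Runs the full tilt analysis on per-subject concentration series:
#' per-group segment means +/- SE, post-tilt and post-recline 10-min
#' slopes, tilt AUCs (subject-wise, averaged per group, plus the AUC of the
#' group-mean curve), equal-variance t-tests of the tilt-segment averages
#' per signal, the heart-rate criterion per subject, and (when reference
#' traces are present) the per-subject cross-device R^2 over the tilt.
#'
#' @param subjects list of subjects; each a list with elements `conc`
#'   (a `concentration_series` incl. derived signals), `meta` (with `id`,
#'   `group`, `age`, `hr_baseline_max`, `hr_tilt_max`) and optionally
#'   `reference` (data frame `time_s`, `oxy_pct`).
#' @param proto a [protocol_definition()].
#' @param alpha significance threshold for the group tests.
#' @param var_equal pooled-variance t-test (see [group_test()]).
#' @return a `cohort_result` list: `segment_means`, `slopes`, `auc`
#'   (subject-wise), `auc_group` (group means, both variants), `tests`,
#'   `hr_criterion`, `device_r2`.
#' @export
analyze_cohort <- function(subjects, proto = protocol_definition(),
                           alpha = 0.01, var_equal = TRUE) {
  stopifnot(length(subjects) >= 2)
  per <- lapply(subjects, function(s) {
    seg <- segment_series(s$conc, proto)
    tilt_avg <- segment_average(seg$tilt)
    rows <- do.call(rbind, lapply(names(seg), function(lb) {
      a <- segment_average(seg[[lb]])
      a$segment <- lb
      a
    }))
    auc <- auc_tilt(seg$tilt)
    sl_tilt <- rate_of_change(seg$tilt); sl_tilt$phase <- "post_tilt"
    sl_rec <- rate_of_change(seg$recovery); sl_rec$phase <- "post_recline"
    r2 <- if (!is.null(s$reference)) {
      bounds <- cumsum(c(0, proto$segments$duration_min * 60))
      device_correlation(s$conc$time_s, s$conc$dOxy_uM,
                         s$reference$time_s, s$reference$oxy_pct,
                         window = bounds[2:3])$r_squared
    } else NA_real_
    list(id = s$meta$id, group = s$meta$group, seg_avg = rows,
         tilt_avg = tilt_avg, auc = auc, slopes = rbind(sl_tilt, sl_rec),
         pots = pots_criterion(s$meta), r2 = r2)
  })

  groups <- vapply(per, `[[`, character(1), "group")
  sig <- per[[1]]$tilt_avg$signal

  long <- do.call(rbind, lapply(per, function(p) {
    cbind(p$seg_avg, id = p$id, group = p$group)
  }))
  segment_means <- stats::aggregate(mean_uM ~ group + segment + signal,
                                    data = long, FUN = mean)
  segment_means$se_uM <- stats::aggregate(
    mean_uM ~ group + segment + signal, data = long,
    FUN = function(v) sd(v) / sqrt(length(v)))$mean_uM

  auc_long <- do.call(rbind, lapply(per, function(p)
    cbind(p$auc, id = p$id, group = p$group)))
  auc_group <- stats::aggregate(auc_uM_min ~ group + signal, data = auc_long,
                                FUN = mean)

  slope_long <- do.call(rbind, lapply(per, function(p)
    cbind(p$slopes, id = p$id, group = p$group)))
  slope_group <- stats::aggregate(slope_uM_per_min ~ group + phase + signal,
                                  data = slope_long, FUN = mean)

  tests <- lapply(setNames(sig, sig), function(s) {
    vals <- vapply(per, function(p)
      p$tilt_avg$mean_uM[p$tilt_avg$signal == s], numeric(1))
    group_test(vals[groups == "POTS"], vals[groups == "control"],
               alpha = alpha, var_equal = var_equal)
  })

  structure(list(
    segment_means = segment_means,
    slopes = slope_group, slopes_by_subject = slope_long,
    auc = auc_long, auc_group = auc_group,
    tests = tests,
    hr_criterion = data.frame(id = vapply(per, `[[`, character(1), "id"),
                              group = groups,
                              pots = vapply(per, `[[`, logical(1), "pots")),
    device_r2 = data.frame(id = vapply(per, `[[`, character(1), "id"),
                           group = groups,
                           r_squared = vapply(per, `[[`, numeric(1), "r2")),
    alpha = alpha), class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("<cohort_result>\n")
  cat("Group-mean tilt AUC (uM*min):\n")
  print(x$auc_group, row.names = FALSE)
  cat("Tilt-average group tests (alpha =", x$alpha, "):\n")
  for (s in names(x$tests))
    cat(sprintf("  %-10s t = %7.3f  p = %.3g%s\n", s, x$tests[[s]]$t,
                x$tests[[s]]$p,
                if (x$tests[[s]]$significant) "  *" else ""))
  invisible(x)
}
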