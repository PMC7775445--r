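#' Define an ERP component measurement window
#'
#' A component window fixes the electrode, time window, polarity, and the
#' condition contrast (critical minus reference) for one ERP measure.
#'
#' @param name Component name, e.g. `"inhibition_P3"`.
#' @param electrode Channel label.
#' @param t_start,t_end Window in ms (`t_start < t_end`).
#' @param polarity `"positive"` or `"negative"`.
#' @param critical,reference Condition labels of the contrast.
#' @return An object of class `cpt_component_window`.
#' @export
component_window <- function(name, electrode, t_start, t_end,
                             polarity = c("positive", "negative"),
                             critical, reference = "StandardGo") {
  polarity <- match.arg(polarity)
  if (t_start >= t_end) stop("t_start must be < t_end", call. = FALSE)
  structure(list(name = name, electrode = electrode, t_start = t_start,
                 t_end = t_end, polarity = polarity, critical = critical,
                 reference = reference),
            class = "cpt_component_window")
}

#' Published component windows of the Salience CPT analysis
#'
#' Inhibition-P3 (NoGo minus StandardGo, 300-600 ms, positive) and
#' salience-P3 (SalientGo minus StandardGo, 350-600 ms, positive) at POz
#' with Pz replications, and salience-N2 (SalientGo minus StandardGo,
#' 250-350 ms, negative) at Fz.
#'
#' @return Named list of [component_window()] objects.
#' @export
default_component_windows <- function() {
  list(
    inhibition_P3_POz = component_window("inhibition_P3", "POz", 300, 600,
                                         "positive", "NoGo"),
    inhibition_P3_Pz = component_window("inhibition_P3", "Pz", 300, 600,
                                        "positive", "NoGo"),
    salience_P3_POz = component_window("salience_P3", "POz", 350, 600,
                                       "positive", "SalientGo"),
    salience_P3_Pz = component_window("salience_P3", "Pz", 350, 600,
                                      "positive", "SalientGo"),
    salience_N2_Fz = component_window("salience_N2", "Fz", 250, 350,
                                      "negative", "SalientGo")
  )
}

# correct-response label for a condition
.usable_label <- function(condition) {
  if (condition == "NoGo") "CorrectInhibition" else "HIT"
}

#' Condition-average ERP
#'
#' Arithmetic mean over the trials of one condition.  With
#' `exclude_errors = TRUE` (requires an outcome `label` column in the
#' epoch metadata, see [attach_outcomes()]) only correct trials enter: HITs
#' for Go conditions, correct inhibitions for NoGo.
#'
#' @param epochs A `cpt_epochs` object.
#' @param condition Condition label.
#' @param exclude_errors Drop error trials before averaging.
#' @return Channels x samples matrix with attributes `times` and
#'   `channels`.
#' @export
condition_average <- function(epochs, condition, exclude_errors = TRUE) {
  sel <- epochs$metadata$condition == condition
  if (exclude_errors && !is.null(epochs$metadata$label))
    sel <- sel & epochs$metadata$label == .usable_label(condition)
  if (!any(sel))
    stop("empty average: no usable trials in condition ", condition,
         call. = FALSE)
  avg <- apply(epochs$data[sel, , , drop = FALSE], c(2, 3), mean)
  rownames(avg) <- epochs$channels
  attr(avg, "times") <- epochs$times
  attr(avg, "n_trials") <- sum(sel)
  avg
}

#' Difference wave between two condition averages
#'
#' @param critical_avg,reference_avg Channels x samples matrices from
#'   [condition_average()] with matching axes.
#' @return Pointwise difference (critical minus reference), same shape.
#' @export
difference_wave <- function(critical_avg, reference_avg) {
  if (!identical(dim(critical_avg), dim(reference_avg)) ||
      !isTRUE(all.equal(attr(critical_avg, "times"),
                        attr(reference_avg, "times"))))
    stop("structural error: channel/time axes do not match", call. = FALSE)
  out <- critical_avg - reference_avg
  attr(out, "times") <- attr(critical_avg, "times")
  out
}

# Extract the waveform at the window's electrode + the rectified segment.
# Window edges are snapped to the nearest sample.
.window_segment <- function(x, times, window) {
  if (is.matrix(x)) {
    if (!window$electrode %in% rownames(x))
      stop("channel error: electrode ", window$electrode, " not present",
           call. = FALSE)
    times <- times %||% attr(x, "times")
    x <- x[window$electrode, ]
  }
  if (window$t_start < times[1] - 1e-9 ||
      window$t_end > times[length(times)] + 1e-9)
    stop("parameter error: window outside the epoch", call. = FALSE)
  i0 <- which.min(abs(times - window$t_start))
  i1 <- which.min(abs(times - window$t_end))
  seg <- x[i0:i1]
  rect <- if (window$polarity == "positive") pmax(seg, 0) else pmax(-seg, 0)
  list(t = times[i0:i1], rect = rect)
}

#' Signed-area amplitude
#'
#' Integral of the polarity-consistent part of the waveform over the
#' component window (trapezoid rule on the sampling grid, window edges
#' snapped to the nearest sample), reported as a positive magnitude in
#' uV.ms: for positive polarity the area above zero, for negative polarity
#' the magnitude of the area below zero.
#'
#' @param x Waveform: numeric vector (with `times`) or channels x samples
#'   matrix from [condition_average()]/[difference_wave()].
#' @param window A [component_window()].
#' @param times Sample times in ms (taken from the matrix attribute when
#'   `x` is a matrix).
#' @return Area in uV.ms (>= 0).
#' @export
signed_area_amplitude <- function(x, window, times = NULL) {
  s <- .window_segment(x, times, window)
  trapz(s$t, s$rect)
}

#' Fractional-area latency
#'
#' The time at which the cumulative polarity-rectified area within the
#' window reaches `fraction` of the total window area.  The rectified
#' waveform is treated as piecewise linear between samples, so the
#' cumulative area is piecewise quadratic; the crossing is solved exactly
#' within the bracketing sample interval.  Returns `NA` when the total
#' rectified area is zero (undefined latency).
#'
#' @inheritParams signed_area_amplitude
#' @param fraction Area fraction, default 0.5.
#' @return Latency in ms, or `NA_real_` when undefined.
#' @export
fractional_area_latency <- function(x, window, fraction = 0.5,
                                    times = NULL) {
  s <- .window_segment(x, times, window)
  tt <- s$t; r <- s$rect
  n <- length(tt)
  cum <- cumtrapz(tt, r)
  total <- cum[n]
  if (total <= 0) return(NA_real_)
  need <- fraction * total
  k <- which(cum >= need - 1e-12)[1]
  if (k == 1L) return(tt[1])
  # solve within [tt[k-1], tt[k]]: area(tau) = r1*tau + (r2-r1)*tau^2/(2h)
  h <- tt[k] - tt[k - 1]
  r1 <- r[k - 1]; r2 <- r[k]
  rem <- need - cum[k - 1]
  a <- (r2 - r1) / (2 * h)
  if (abs(a) < 1e-12) {
    tau <- if (r1 > 0) rem / r1 else h
  } else {
    disc <- r1^2 + 4 * a * rem
    tau <- (-r1 + sqrt(max(disc, 0))) / (2 * a)
    if (is.na(tau) || tau < 0 || tau > h + 1e-9)
      tau <- rem / max((r1 + r2) / 2, 1e-12)
  }
  tt[k - 1] + min(max(tau, 0), h)
}

#' Per-trial component measures of the critical condition
#'
#' Applies [signed_area_amplitude()] and [fractional_area_latency()] to
#' every usable single trial of the window's critical condition at the
#' component electrode.  Trial-to-trial temporal variability is the SD of
#' these per-trial values; trials with undefined latency are flagged and
#' excluded from the latency SD only.
#'
#' @param epochs A `cpt_epochs` object (with outcome labels for error
#'   exclusion).
#' @param window A [component_window()].
#' @param exclude_errors Drop error trials.
#' @param trial_lowpass Optional low-pass cutoff (Hz) applied to each trial
#'   before measurement (off by default).
#' @return Data.frame with columns `trial`, `amplitude` (uV.ms), `latency`
#'   (ms, `NA` when undefined).
#' @export
single_trial_measures <- function(epochs, window, exclude_errors = TRUE,
                                  trial_lowpass = NULL) {
  sel <- epochs$metadata$condition == window$critical
  if (exclude_errors && !is.null(epochs$metadata$label))
    sel <- sel & epochs$metadata$label == .usable_label(window$critical)
  idx <- which(sel)
  if (length(idx) < 2L)
    stop("variability undefined: fewer than 2 usable trials", call. = FALSE)
  ch <- match(window$electrode, epochs$channels)
  if (is.na(ch))
    stop("channel error: electrode ", window$electrode, " not present",
         call. = FALSE)
  lp <- if (!is.null(trial_lowpass))
    signal::butter(4, trial_lowpass / (epochs$sfreq / 2), type = "low")
  amp <- lat <- numeric(length(idx))
  for (j in seq_along(idx)) {
    v <- epochs$data[idx[j], ch, ]
    if (!is.null(lp)) v <- signal::filtfilt(lp, v)
    amp[j] <- signed_area_amplitude(v, window, times = epochs$times)
    lat[j] <- fractional_area_latency(v, window, times = epochs$times)
  }
  data.frame(trial = epochs$metadata$index[idx], amplitude = amp,
             latency = lat)
}

#' Component measures for one subject
#'
#' Mean signed-area amplitude and 50% fractional-area latency are taken
#' from the average difference wave (critical minus reference condition,
#' correct trials only); temporal variability (`amp_sd`, `lat_sd`) is the
#' SD of the per-trial measures of the critical condition at the component
#' electrode (reference subtraction applies only at the average level,
#' since difference waves do not exist per trial).
#'
#' @inheritParams single_trial_measures
#' @return An object of class `cpt_component_measures`: list with
#'   `mean_amplitude` (uV.ms), `mean_latency` (ms), `amp_sd`, `lat_sd`,
#'   `n_trials_used`, `n_latency_undefined`.
#' @export
component_measures <- function(epochs, window, exclude_errors = TRUE,
                               trial_lowpass = NULL) {
  crit <- condition_average(epochs, window$critical, exclude_errors)
  ref <- condition_average(epochs, window$reference, exclude_errors)
  dw <- difference_wave(crit, ref)
  st <- single_trial_measures(epochs, window, exclude_errors, trial_lowpass)
  lat_ok <- !is.na(st$latency)
  structure(list(
    name = window$name, electrode = window$electrode,
    mean_amplitude = signed_area_amplitude(dw, window),
    mean_latency = fractional_area_latency(dw, window),
    amp_sd = stats::sd(st$amplitude),
    lat_sd = if (sum(lat_ok) >= 2) stats::sd(st$latency[lat_ok]) else
      NA_real_,
    n_trials_used = nrow(st),
    n_latency_undefined = sum(!lat_ok)
  ), class = "cpt_component_measures")
}

#' @export
print.cpt_component_measures <- function(x, ...) {
  cat(sprintf(paste0("%s @ %s: area %.1f uV.ms (trial SD %.1f), ",
                     "latency %.1f ms (trial SD %.1f), n = %d\n"),
              x$name, x$electrode, x$mean_amplitude, x$amp_sd,
              x$mean_latency, x$lat_sd, x$n_trials_used))
  invisible(x)
}

#' Attach behavioral outcome labels to an epochs set
#'
#' @param epochs A `cpt_epochs` object.
#' @param outcomes Output of [classify_trials()] for the same sequence.
#' @return The epochs with a `label` metadata column.
#' @export
attach_outcomes <- function(epochs, outcomes) {
  m <- match(epochs$metadata$index, outcomes$index)
  if (anyNA(m))
    stop("structural error: outcomes do not cover all epochs", call. = FALSE)
  epochs$metadata$label <- outcomes$label[m]
  epochs
}
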