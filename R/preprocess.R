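#' Re-reference EEG data
#'
#' `linked_mastoids` subtracts the per-sample mean of M1 and M2 from every
#' channel; `common_average` subtracts the per-sample mean over all
#' channels excluding the mastoids.  Works on a `cpt_epochs` object or a
#' channels x samples matrix with row names.
#'
#' @param x `cpt_epochs` or matrix (channels x samples, rownames =
#'   channel labels).
#' @param scheme `"linked_mastoids"` or `"common_average"`.
#' @return Object of the same shape, re-referenced.
#' @export
rereference <- function(x, scheme = c("linked_mastoids", "common_average")) {
  scheme <- match.arg(scheme)
  if (inherits(x, "cpt_epochs")) {
    ref <- .reference_signal(aperm(x$data, c(2, 3, 1)), x$channels, scheme)
    # ref: samples x trials
    for (ch in seq_along(x$channels))
      x$data[, ch, ] <- x$data[, ch, ] - t(ref)
    return(x)
  }
  chans <- rownames(x)
  if (scheme == "linked_mastoids") {
    if (!all(c("M1", "M2") %in% chans))
      stop("channel error: linked-mastoid reference requires M1 and M2",
           call. = FALSE)
    ref <- (x["M1", ] + x["M2", ]) / 2
  } else {
    keep <- setdiff(chans, c("M1", "M2"))
    ref <- colMeans(x[keep, , drop = FALSE])
  }
  sweep(x, 2, ref, "-")
}

# channels x samples x trials array -> samples x trials reference signal
.reference_signal <- function(arr, chans, scheme) {
  if (scheme == "linked_mastoids") {
    if (!all(c("M1", "M2") %in% chans))
      stop("channel error: linked-mastoid reference requires M1 and M2",
           call. = FALSE)
    (arr[match("M1", chans), , ] + arr[match("M2", chans), , ]) / 2
  } else {
    keep <- match(setdiff(chans, c("M1", "M2")), chans)
    apply(arr[keep, , , drop = FALSE], c(2, 3), mean)
  }
}

#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth filtering: a 2nd-order
#' high-pass at `lo` Hz cascaded with a 4th-order low-pass at `hi` Hz, each
#' applied with [signal::filtfilt()] so component latencies are preserved.
#'
#' @param x Numeric vector, channels x samples matrix, or `cpt_epochs`.
#' @param lo,hi Band edges in Hz (defaults 0.1 and 30).
#' @param sfreq Sampling rate in Hz (taken from the object for
#'   `cpt_epochs`).
#' @return Filtered object of the same shape.
#' @export
bandpass <- function(x, lo = 0.1, hi = 30, sfreq = NULL) {
  if (inherits(x, "cpt_epochs")) {
    sfreq <- x$sfreq
    .check_band(lo, hi, sfreq)
    for (tr in seq_len(dim(x$data)[1]))
      for (ch in seq_len(dim(x$data)[2]))
        x$data[tr, ch, ] <- .bandpass_vec(x$data[tr, ch, ], lo, hi, sfreq)
    return(x)
  }
  if (is.null(sfreq)) stop("sfreq is required", call. = FALSE)
  .check_band(lo, hi, sfreq)
  if (is.matrix(x)) {
    t(apply(x, 1, .bandpass_vec, lo = lo, hi = hi, sfreq = sfreq))
  } else {
    .bandpass_vec(x, lo, hi, sfreq)
  }
}

.check_band <- function(lo, hi, sfreq) {
  if (hi >= sfreq / 2)
    stop("parameter error: high cutoff must be below the Nyquist frequency",
         call. = FALSE)
  if (lo <= 0 || lo >= hi)
    stop("parameter error: need 0 < lo < hi", call. = FALSE)
}

.bandpass_vec <- function(v, lo, hi, sfreq) {
  hp <- signal::butter(2, lo / (sfreq / 2), type = "high")
  lp <- signal::butter(4, hi / (sfreq / 2), type = "low")
  signal::filtfilt(lp, signal::filtfilt(hp, v))
}

#' Anti-aliased downsampling
#'
#' Applies a zero-phase Butterworth low-pass at 0.45 x target rate, then
#' decimates by the (integer) ratio `sfreq / target`.
#'
#' @param x Numeric vector or channels x samples matrix.
#' @param sfreq Current sampling rate, Hz.
#' @param target Target sampling rate, Hz (default 200); must divide
#'   `sfreq`.
#' @return Downsampled data (same class as the input).
#' @export
downsample <- function(x, sfreq, target = 200) {
  if (target > sfreq)
    stop("parameter error: upsampling is not supported", call. = FALSE)
  if (target == sfreq) return(x)
  fac <- sfreq / target
  if (abs(fac - round(fac)) > 1e-9)
    stop("parameter error: target rate must divide the sampling rate",
         call. = FALSE)
  fac <- as.integer(round(fac))
  lp <- signal::butter(8, 0.45 * target / (sfreq / 2), type = "low")
  dec <- function(v) {
    signal::filtfilt(lp, v)[seq(1, length(v), by = fac)]
  }
  if (is.matrix(x)) t(apply(x, 1, dec)) else dec(x)
}

#' Epoch continuous data and apply baseline correction
#'
#' Cuts epochs of `window` ms (half-open at the right edge: 220 samples at
#' 200 Hz for -200..900 ms) around each event and subtracts the per-trial,
#' per-channel mean over the `baseline` interval (closed on both ends,
#' sample inclusion by nearest-sample rounding) from the whole epoch.
#' Events too close to the recording edges are dropped with a warning.
#'
#' @param continuous Channels x samples matrix (rownames = channel labels)
#'   or the list returned by [simulate_continuous()].
#' @param events Onset sample indices (1-based); taken from the object if
#'   `continuous` is a [simulate_continuous()] result.
#' @param sfreq Sampling rate, Hz.
#' @param window Epoch window in ms relative to onset.
#' @param baseline Baseline interval in ms.
#' @param conditions Optional per-event condition labels.
#' @return A `cpt_epochs` object (baseline-corrected).
#' @export
epoch_and_baseline <- function(continuous, events = NULL, sfreq = NULL,
                               window = c(-200, 900), baseline = c(-200, 0),
                               conditions = NULL) {
  if (is.list(continuous) && !is.null(continuous$data)) {
    events <- events %||% continuous$events
    sfreq <- sfreq %||% continuous$sfreq
    conditions <- conditions %||% continuous$conditions
    continuous <- continuous$data
  }
  if (is.null(events) || is.null(sfreq))
    stop("events and sfreq are required", call. = FALSE)
  dt <- 1000 / sfreq
  pre <- as.integer(round(-window[1] / dt))
  n_ep <- as.integer(round((window[2] - window[1]) / dt))
  n_sp <- ncol(continuous)
  keep <- (events - pre) >= 1L & (events - pre + n_ep - 1L) <= n_sp
  if (any(!keep))
    warning(sum(!keep), " event(s) too close to the recording edge; dropped")
  events_k <- events[keep]
  n_tr <- length(events_k)
  chans <- rownames(continuous) %||%
    paste0("ch", seq_len(nrow(continuous)))
  data <- array(0, dim = c(n_tr, nrow(continuous), n_ep),
                dimnames = list(NULL, chans, NULL))
  for (k in seq_len(n_tr)) {
    sl <- (events_k[k] - pre):(events_k[k] - pre + n_ep - 1L)
    data[k, , ] <- continuous[, sl]
  }
  times <- window[1] + (seq_len(n_ep) - 1L) * dt
  ep <- structure(list(data = data, sfreq = sfreq, t0 = times[1],
                       times = times, channels = chans,
                       metadata = data.frame(
                         index = which(keep) - 1L,
                         condition = if (is.null(conditions))
                           NA_character_ else conditions[keep],
                         stringsAsFactors = FALSE),
                       ground_truth = NULL, baseline_corrected = FALSE),
                  class = "cpt_epochs")
  baseline_correct(ep, baseline)
}

#' Baseline-correct an epochs set
#'
#' Subtracts the per-trial, per-channel mean amplitude over the baseline
#' interval (closed on both ends) from the whole epoch.
#'
#' @param epochs A `cpt_epochs` object.
#' @param interval Baseline interval in ms, default -200..0.
#' @return The baseline-corrected `cpt_epochs`.
#' @export
baseline_correct <- function(epochs, interval = c(-200, 0)) {
  idx <- which(epochs$times >= interval[1] - 1e-9 &
                 epochs$times <= interval[2] + 1e-9)
  if (!length(idx)) stop("baseline interval outside the epoch", call. = FALSE)
  bl <- apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(bl)   # recycles over samples
  epochs$baseline_corrected <- TRUE
  epochs
}

#' @export
print.cpt_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(paste0("EEG epochs: %d trials x %d channels x %d samples ",
                     "(%.0f Hz, %g..%g ms)%s\n"),
              d[1], d[2], d[3], x$sfreq, x$times[1],
              x$times[length(x$times)],
              if (isTRUE(x$baseline_corrected)) ", baseline-corrected" else ""))
  invisible(x)
}

#' Full continuous-data preprocessing chain
#'
#' Average reference (excluding mastoids) -> anti-aliased downsampling ->
#' zero-phase 0.1-30 Hz band-pass -> linked-mastoid re-reference ->
#' epoching with baseline correction.  Artifact-component removal is out of
#' scope for synthetic data; `ica_hook` accepts a function
#' `(matrix, sfreq) -> matrix` applied between the band-pass and the
#' mastoid re-reference for real-data use.
#'
#' @param continuous Channels x samples matrix (rownames = labels) or a
#'   [simulate_continuous()] result.
#' @param events,sfreq,conditions See [epoch_and_baseline()].
#' @param target_sfreq Rate after downsampling, Hz.
#' @param band Band-pass edges, Hz.
#' @param window,baseline Epoch and baseline intervals, ms.
#' @param ica_hook Optional artifact-removal function; default no-op.
#' @return A `cpt_epochs` object.
#' @export
preprocess_raw <- function(continuous, events = NULL, sfreq = NULL,
                           conditions = NULL, target_sfreq = 200,
                           band = c(0.1, 30), window = c(-200, 900),
                           baseline = c(-200, 0), ica_hook = NULL) {
  if (is.list(continuous) && !is.null(continuous$data)) {
    events <- events %||% continuous$events
    sfreq <- sfreq %||% continuous$sfreq
    conditions <- conditions %||% continuous$conditions
    continuous <- continuous$data
  }
  x <- rereference(continuous, "common_average")
  fac <- sfreq / target_sfreq
  x <- downsample(x, sfreq, target_sfreq)
  events <- as.integer(round((events - 1) / fac)) + 1L
  x <- bandpass(x, band[1], band[2], target_sfreq)
  if (!is.null(ica_hook)) x <- ica_hook(x, target_sfreq)
  x <- rereference(x, "linked_mastoids")
  epoch_and_baseline(x, events, target_sfreq, window, baseline, conditions)
}
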