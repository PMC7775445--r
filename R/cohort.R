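#' Target effect structure for the synthetic cohort
#'
#' Defines the target correlations between the ADHD index and each latent
#' subject parameter (neural component means/variabilities and behavioral
#' parameters).  Subjects are generated from a single-factor Gaussian
#' copula: each latent parameter loads on the subject's latent severity
#' score with loading equal to the target correlation, so every target is
#' reproduced exactly on the latent scale and the implied correlation
#' matrix is positive definite for any set of loadings in (-1, 1).
#' Marginal transforms (gamma + rounding for the ADHD index, truncation for
#' variances and probabilities) attenuate Pearson correlations on the
#' observed scale slightly (about 0.02 at the default marginals).
#'
#' The default targets carry the published coefficient pattern: negative
#' associations of the ADHD index with salience-P3 amplitude (-0.44) and
#' with the trial-to-trial amplitude variability of both P3 components
#' (-0.51 each), a positive association with salience-P3 latency
#' variability (+0.46), and small coefficients elsewhere.
#'
#' @param targets Named numeric vector of target correlations, all in
#'   (-1, 1).  Names must match latent parameter columns of
#'   [simulate_profiles()].
#' @param noise Noise settings for the EEG forward model: list with
#'   `pink_sd` (uV), `white_sd` (uV), `exponent` (1/f exponent),
#'   `alpha_amp` (uV, optional alpha oscillation, 0 = off).
#' @return An object of class `cpt_effect_config`.
#' @export
effect_config <- function(targets = default_effect_targets(),
                          noise = list(pink_sd = 0.5, white_sd = 0.3,
                                       exponent = 1, alpha_amp = 0)) {
  if (length(targets) && (is.null(names(targets)) || any(!nzchar(names(targets)))))
    stop("targets must be a named vector", call. = FALSE)
  if (any(abs(targets) >= 1))
    stop("configuration error: target correlations must lie in (-1, 1); ",
         "the implied covariance would not be positive definite",
         call. = FALSE)
  structure(list(targets = targets, noise = noise),
            class = "cpt_effect_config")
}

#' @rdname effect_config
#' @export
default_effect_targets <- function() {
  c(inh_p3_amp = -0.34, inh_p3_lat = 0.38,
    inh_p3_amp_sd = -0.51, inh_p3_lat_sd = 0.11,
    sal_p3_amp = -0.44, sal_p3_lat = 0.28,
    sal_p3_amp_sd = -0.51, sal_p3_lat_sd = 0.46,
    sal_n2_amp = -0.02, sal_n2_lat = -0.09,
    sal_n2_amp_sd = 0.08, sal_n2_lat_sd = 0.22,
    fa_p = 0.15, miss_p = 0.12,
    rt_sd_salient = 0.04, salience_rt_effect = -0.20)
}

#' @rdname effect_config
#' @export
null_effect_targets <- function() {
  t <- default_effect_targets()
  t[] <- 0
  t
}

# Marginal definitions for every latent subject parameter:
# value = mu + sd * u (u standard normal), then clipped to [min, max].
# Means and spreads emulate the published cohort descriptives (RT 390/423,
# RT SD 160/163, omission .04, commission .41) and the component geometry
# (P3 peaks near 460/455 ms at POz, N2 near 300 ms at Fz; peak amplitudes
# chosen so the Gaussian areas in the analysis windows sit near the printed
# mean signed areas of 919, 799, and 78 uV.ms).
cohort_marginals <- function() {
  list(
    inh_p3_amp    = list(mu = 6.1,  sd = 1.2,  min = 1,    max = Inf),
    inh_p3_lat    = list(mu = 460,  sd = 15,   min = 390,  max = 530),
    inh_p3_amp_sd = list(mu = 2.0,  sd = 0.7,  min = 0.3,  max = Inf),
    inh_p3_lat_sd = list(mu = 20,   sd = 7,    min = 3,    max = Inf),
    sal_p3_amp    = list(mu = 5.3,  sd = 1.4,  min = 1,    max = Inf),
    sal_p3_lat    = list(mu = 455,  sd = 15,   min = 390,  max = 530),
    sal_p3_amp_sd = list(mu = 2.0,  sd = 0.7,  min = 0.3,  max = Inf),
    sal_p3_lat_sd = list(mu = 20,   sd = 7,    min = 3,    max = Inf),
    sal_n2_amp    = list(mu = 1.05, sd = 0.25, min = 0.2,  max = Inf),
    sal_n2_lat    = list(mu = 300,  sd = 10,   min = 270,  max = 330),
    sal_n2_amp_sd = list(mu = 0.5,  sd = 0.15, min = 0.05, max = Inf),
    sal_n2_lat_sd = list(mu = 12,   sd = 4,    min = 2,    max = Inf),
    rt_mean_standard    = list(mu = 390, sd = 78, min = 250, max = Inf),
    salience_rt_effect  = list(mu = 33,  sd = 30, min = -Inf, max = Inf),
    rt_sd_standard      = list(mu = 160, sd = 39, min = 50, max = Inf),
    rt_sd_salient       = list(mu = 163, sd = 48, min = 50, max = Inf),
    miss_p = list(mu = 0.04, sd = 0.045, min = 0.001, max = 0.6),
    fa_p   = list(mu = 0.41, sd = 0.18,  min = 0.02,  max = 0.95)
  )
}

#' Simulate a cohort of subject profiles with known ground-truth effects
#'
#' Each subject carries covariates (age, sex, IQ raw score), an ADHD index,
#' and latent neural/behavioral parameters whose correlation with the
#' latent ADHD severity equals the configured targets (single-factor
#' Gaussian copula; see [effect_config()]).  The observed `adhd_index` is a
#' rounded gamma transform of the latent severity matching the published
#' descriptives (mean 5.32, SD 4.36, floor 0); `adhd_latent` retains the
#' untransformed score.  Covariates are generated independently of the
#' severity factor.
#'
#' @param n_subjects Number of subjects.
#' @param effects An [effect_config()].
#' @param seed Integer seed; the roster is deterministic given the seed.
#' @return A data.frame with one row per subject (class `cpt_profiles`),
#'   carrying the effect configuration as attribute `effects`.
#' @export
#' @examples
#' prof <- simulate_profiles(31, effect_config(), seed = 1)
#' cor(prof$adhd_latent, prof$sal_p3_amp)
simulate_profiles <- function(n_subjects, effects = effect_config(),
                              seed = 1L) {
  marg <- cohort_marginals()
  targets <- effects$targets
  unknown <- setdiff(names(targets), names(marg))
  if (length(unknown))
    stop("configuration error: unknown effect target(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)

  with_seed(seed, {
    z <- stats::rnorm(n_subjects)                 # latent ADHD severity
    # gamma marginal matching the published ADHD index mean/SD
    shape <- (5.32 / 4.36)^2
    scale <- 4.36^2 / 5.32
    adhd_index <- pmin(round(stats::qgamma(stats::pnorm(z), shape = shape,
                                           scale = scale)), 30)

    prof <- data.frame(
      subject_id = sprintf("S%03d", seq_len(n_subjects)),
      age = pmin(pmax(stats::rnorm(n_subjects, 10.7, 0.53), 9), 11.9),
      sex = stats::rbinom(n_subjects, 1, 14 / 31),
      iq_raw = round(pmin(pmax(stats::rnorm(n_subjects, 97.38, 11.66),
                               60), 140)),
      adhd_latent = z,
      adhd_index = adhd_index,
      stringsAsFactors = FALSE
    )

    for (nm in names(marg)) {
      r <- if (nm %in% names(targets)) unname(targets[nm]) else 0
      u <- r * z + sqrt(1 - r^2) * stats::rnorm(n_subjects)
      m <- marg[[nm]]
      prof[[nm]] <- pmin(pmax(m$mu + m$sd * u, m$min), m$max)
    }
    # salient-condition RT mean: standard mean plus the salience effect
    prof$rt_mean_salient <- prof$rt_mean_standard + prof$salience_rt_effect
    attr(prof, "effects") <- effects
    class(prof) <- c("cpt_profiles", "data.frame")
    prof
  })
}

#' ERP forward model for the synthetic cohort
#'
#' Components are Gaussians in time with fixed per-channel topographic
#' weights.  Every condition shares a deterministic visual P1/N1 and a base
#' parietal P3; NoGo trials additionally receive the subject's inhibition-P3
#' and SalientGo trials the subject's salience-P3 and salience-N2, whose
#' per-trial peak amplitude and latency are drawn around the subject's
#' latent means with the subject's latent trial-SDs.  Noise is channel-
#' independent 1/f (exponent ~1) plus white noise.
#'
#' @param sfreq Sampling rate in Hz.
#' @param channels Channel labels; must include the analysis sites POz, Pz,
#'   Fz, the occipital sites, and the mastoids M1/M2 (signal-free, noise
#'   only).
#' @param widths Named Gaussian widths (ms) of the driven components.
#' @param noise Noise settings (overridden by the effect config's noise in
#'   [simulate_epochs()] when supplied there).
#' @return An object of class `cpt_forward_model`.
#' @export
erp_forward_model <- function(sfreq = 200,
                              channels = c("Fz", "Cz", "Pz", "POz",
                                           "O1", "Oz", "O2", "M1", "M2"),
                              widths = c(inh_p3 = 55, sal_p3 = 55,
                                         sal_n2 = 30),
                              noise = list(pink_sd = 0.5, white_sd = 0.3,
                                           exponent = 1, alpha_amp = 0)) {
  w <- function(...) {
    v <- stats::setNames(rep(0, length(channels)), channels)
    upd <- c(...)
    v[names(upd)] <- upd
    v
  }
  if (any(widths <= 0)) stop("component widths must be > 0", call. = FALSE)
  shared <- list(
    P1 = list(peak = 120, width = 25, amp = 4,
              weights = w(O1 = 1, O2 = 1, Oz = 1, POz = 0.7, Pz = 0.4,
                          Cz = 0.1)),
    N1 = list(peak = 170, width = 30, amp = -3,
              weights = w(O1 = 1, O2 = 1, Oz = 1, POz = 0.7, Pz = 0.4)),
    base_P3 = list(peak = 400, width = 70, amp = 1.5,
                   weights = w(Pz = 1, POz = 0.9, Cz = 0.5, Oz = 0.4,
                               Fz = 0.2))
  )
  p3_topo <- w(POz = 1, Pz = 0.8, Oz = 0.6, O1 = 0.5, O2 = 0.5, Cz = 0.3,
               Fz = 0.1)
  driven <- list(
    inh_p3 = list(condition = "NoGo", width = unname(widths["inh_p3"]),
                  sign = 1, weights = p3_topo),
    sal_p3 = list(condition = "SalientGo", width = unname(widths["sal_p3"]),
                  sign = 1, weights = p3_topo),
    sal_n2 = list(condition = "SalientGo", width = unname(widths["sal_n2"]),
                  sign = -1,
                  weights = w(Fz = 1, Cz = 0.7, Pz = 0.2, POz = 0.1))
  )
  structure(list(sfreq = sfreq, channels = channels, shared = shared,
                 driven = driven, noise = noise),
            class = "cpt_forward_model")
}

#' Analytic signed area of a driven component at an electrode
#'
#' For a Gaussian component of peak amplitude `amp_peak` (uV) and width `w`
#' (ms), the total area is `amp_peak * weight * w * sqrt(2*pi)` in uV.ms.
#' Used as the ground-truth oracle for area recovery tests.
#'
#' @param model A `cpt_forward_model`.
#' @param component Driven component name.
#' @param electrode Channel label.
#' @param amp_peak Peak amplitude(s) in uV (magnitude).
#' @return Area(s) in uV.ms.
#' @export
ground_truth_area <- function(model, component, electrode, amp_peak) {
  comp <- model$driven[[component]]
  abs(amp_peak) * comp$weights[[electrode]] * comp$width * sqrt(2 * pi)
}

.epoch_times <- function(sfreq, window = c(-200, 900)) {
  n <- round((window[2] - window[1]) * sfreq / 1000)
  window[1] + (seq_len(n) - 1L) * 1000 / sfreq
}

# Draw per-trial component parameters for one subject. Returns a list per
# driven component: trial indices (1-based positions in seq), amp, lat.
.draw_trial_params <- function(profile, seq, model) {
  cond <- seq$trials$condition
  out <- list()
  for (nm in names(model$driven)) {
    comp <- model$driven[[nm]]
    idx <- which(cond == comp$condition)
    n <- length(idx)
    amp <- stats::rnorm(n, profile[[paste0(nm, "_amp")]],
                        profile[[paste0(nm, "_amp_sd")]])
    lat <- stats::rnorm(n, profile[[paste0(nm, "_lat")]],
                        profile[[paste0(nm, "_lat_sd")]])
    out[[nm]] <- list(idx = idx, amp = amp, lat = lat)
  }
  out
}

# Render the deterministic shared template (channels x samples).
.shared_template <- function(model, times) {
  tmpl <- matrix(0, length(model$channels), length(times),
                 dimnames = list(model$channels, NULL))
  for (comp in model$shared) {
    g <- comp$amp * exp(-0.5 * ((times - comp$peak) / comp$width)^2)
    tmpl <- tmpl + outer(comp$weights, g)
  }
  tmpl
}

#' Simulate EEG epochs for one subject
#'
#' Renders per-trial waveforms from the forward model (shared template plus
#' condition-specific components with per-trial amplitude/latency draws)
#' and adds 1/f + white noise.  The epoch window is -200..900 ms sampled at
#' `model$sfreq` (220 samples at 200 Hz); data are in uV and are *not*
#' baseline-corrected (see [baseline_correct()]).  The per-trial true
#' component amplitudes (peak uV and analysis-electrode area uV.ms) and
#' latencies are returned alongside as ground truth.
#'
#' @param profile One-row subject profile (see [simulate_profiles()]).
#' @param seq A `cpt_sequence`.
#' @param model A [erp_forward_model()].
#' @param seed Integer seed.
#' @param noise Optional override of `model$noise` (set `pink_sd` and
#'   `white_sd` to 0 for noise-free data).
#' @return A `cpt_epochs` object: list with `data` (trials x channels x
#'   samples array), `sfreq`, `times` (ms), `channels`, `metadata`
#'   (data.frame: `index`, `condition`), and `ground_truth` (data.frame:
#'   `trial`, `component`, `amp_peak`, `latency`).
#' @export
simulate_epochs <- function(profile, seq, model = erp_forward_model(),
                            seed = 1L, noise = NULL) {
  noise <- noise %||% model$noise
  times <- .epoch_times(model$sfreq)
  n_tr <- nrow(seq$trials)
  n_ch <- length(model$channels)
  n_sp <- length(times)

  with_seed(seed, {
    draws <- .draw_trial_params(profile, seq, model)
    data <- array(0, dim = c(n_tr, n_ch, n_sp),
                  dimnames = list(NULL, model$channels, NULL))
    tmpl <- .shared_template(model, times)
    for (ch in seq_len(n_ch))
      data[, ch, ] <- matrix(tmpl[ch, ], n_tr, n_sp, byrow = TRUE)

    gt <- list()
    for (nm in names(model$driven)) {
      comp <- model$driven[[nm]]
      d <- draws[[nm]]
      if (length(d$idx)) {
        # (trials x samples) component waveform, rows scaled by trial amp
        G <- exp(-0.5 * (outer(d$lat, times, "-") / comp$width)^2) *
          (comp$sign * d$amp)
        for (ch in which(comp$weights != 0))
          data[d$idx, ch, ] <- data[d$idx, ch, ] + comp$weights[ch] * G
        gt[[nm]] <- data.frame(trial = d$idx - 1L, component = nm,
                               amp_peak = d$amp, latency = d$lat,
                               stringsAsFactors = FALSE)
      }
    }
    gt <- do.call(rbind, gt)
    rownames(gt) <- NULL

    data <- data + .epoch_noise(noise, n_tr, n_ch, n_sp, model$sfreq, times)

    structure(list(data = data, sfreq = model$sfreq, t0 = times[1],
                   times = times, channels = model$channels,
                   metadata = data.frame(index = seq$trials$index,
                                         condition = seq$trials$condition,
                                         stringsAsFactors = FALSE),
                   ground_truth = gt, baseline_corrected = FALSE),
              class = "cpt_epochs")
  })
}

.epoch_noise <- function(noise, n_tr, n_ch, n_sp, sfreq, times) {
  out <- array(0, dim = c(n_tr, n_ch, n_sp))
  if ((noise$white_sd %||% 0) > 0)
    out <- out + stats::rnorm(n_tr * n_ch * n_sp, sd = noise$white_sd)
  if ((noise$pink_sd %||% 0) > 0) {
    pk <- pink_noise_matrix(n_sp, n_tr * n_ch,
                            exponent = noise$exponent %||% 1) * noise$pink_sd
    out <- out + aperm(array(pk, dim = c(n_sp, n_tr, n_ch)), c(2, 3, 1))
  }
  if ((noise$alpha_amp %||% 0) > 0) {
    ph <- stats::runif(n_tr * n_ch, 0, 2 * pi)
    osc <- noise$alpha_amp *
      sin(outer(ph, 2 * pi * 10 * times / 1000, "+"))
    out <- out + aperm(array(t(osc), dim = c(n_sp, n_tr, n_ch)), c(2, 3, 1))
  }
  out
}

#' Simulate a continuous recording for one subject
#'
#' Renders the same per-trial waveforms as [simulate_epochs()] (identical
#' draws for an identical seed) on a continuous timeline, for exercising
#' the continuous-data preprocessing path ([epoch_and_baseline()]).  Noise
#' is generated on the continuous timeline, so only the noise-free signal
#' is sample-identical to the direct-epoch output.
#'
#' @inheritParams simulate_epochs
#' @return List with `data` (channels x samples matrix), `sfreq`, `times`
#'   (ms relative to first stimulus onset), `channels`, `events` (onset
#'   sample indices, 1-based), `conditions`.
#' @export
simulate_continuous <- function(profile, seq, model = erp_forward_model(),
                                seed = 1L, noise = NULL) {
  noise <- noise %||% model$noise
  sfreq <- model$sfreq
  dt <- 1000 / sfreq
  trial_dur <- seq$params$stim_duration + seq$params$isi
  n_tr <- nrow(seq$trials)
  t_start <- -200
  t_end <- (n_tr - 1) * trial_dur + 900
  times <- seq(t_start, t_end - dt / 2, by = dt)
  n_sp <- length(times)
  n_ch <- length(model$channels)
  events <- as.integer(round((seq$trials$onset_ms - t_start) / dt)) + 1L

  with_seed(seed, {
    draws <- .draw_trial_params(profile, seq, model)
    data <- matrix(0, n_ch, n_sp, dimnames = list(model$channels, NULL))
    ep_times <- .epoch_times(sfreq)
    tmpl <- .shared_template(model, ep_times)
    n_ep <- length(ep_times)
    for (k in seq_len(n_tr)) {
      sl <- (events[k] - 40L):(events[k] - 41L + n_ep)
      data[, sl] <- data[, sl] + tmpl
    }
    for (nm in names(model$driven)) {
      comp <- model$driven[[nm]]
      d <- draws[[nm]]
      for (j in seq_along(d$idx)) {
        k <- d$idx[j]
        sl <- (events[k] - 40L):(events[k] - 41L + n_ep)
        g <- comp$sign * d$amp[j] *
          exp(-0.5 * ((ep_times - d$lat[j]) / comp$width)^2)
        data[, sl] <- data[, sl] + outer(comp$weights, g)
      }
    }
    if ((noise$white_sd %||% 0) > 0)
      data <- data + stats::rnorm(n_ch * n_sp, sd = noise$white_sd)
    if ((noise$pink_sd %||% 0) > 0)
      data <- data + t(pink_noise_matrix(n_sp, n_ch,
                                         exponent = noise$exponent %||% 1)) *
        noise$pink_sd
    list(data = data, sfreq = sfreq, times = times,
         channels = model$channels, events = events,
         conditions = seq$trials$condition)
  })
}

#' Simulate behavioral responses for one subject
#'
#' Go trials are answered with probability `1 - miss_p`; NoGo trials are
#' (incorrectly) answered with probability `fa_p`.  Response times follow a
#' shifted lognormal (shift 150 ms) whose mean and SD match the subject's
#' condition-specific latent RT parameters, truncated at the trial duration
#' (rare tail responses beyond the 1500 ms registration window survive, to
#' exercise the response-window filter).
#'
#' @inheritParams simulate_epochs
#' @return Data.frame with columns `index`, `responded` (logical), `rt`
#'   (ms, `NA` when no response).
#' @export
simulate_behavior <- function(profile, seq, seed = 1L) {
  shift <- 150
  trial_dur <- seq$params$stim_duration + seq$params$isi
  rln <- function(n, m, s) {
    # lognormal matching mean m, sd s after shifting
    m0 <- m - shift
    sdlog2 <- log(1 + (s / m0)^2)
    meanlog <- log(m0) - sdlog2 / 2
    shift + stats::rlnorm(n, meanlog, sqrt(sdlog2))
  }
  with_seed(seed, {
    cond <- seq$trials$condition
    n <- length(cond)
    responded <- logical(n)
    rt <- rep(NA_real_, n)
    is_std <- cond == "StandardGo"
    is_sal <- cond == "SalientGo"
    is_nogo <- cond == "NoGo"
    responded[is_std | is_sal] <-
      stats::runif(sum(is_std | is_sal)) > profile$miss_p
    responded[is_nogo] <- stats::runif(sum(is_nogo)) < profile$fa_p
    k <- responded & is_std
    rt[k] <- rln(sum(k), profile$rt_mean_standard, profile$rt_sd_standard)
    k <- responded & is_sal
    rt[k] <- rln(sum(k), profile$rt_mean_salient, profile$rt_sd_salient)
    k <- responded & is_nogo
    rt[k] <- rln(sum(k), profile$rt_mean_standard, profile$rt_sd_standard)
    rt <- pmin(rt, trial_dur - 1)
    data.frame(index = seq$trials$index, responded = responded, rt = rt)
  })
}
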