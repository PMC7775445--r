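# Shared fixtures: all built in code, no stored data.

# small, fast task design (2 blocks of 20; 4 NoGo + 2 SalientGo per block)
tiny_params <- function(...) {
  cpt_task_params(n_blocks = 2, trials_per_block = 20, frac_nogo = 0.2,
                  frac_salient = 0.1, ...)
}

no_noise <- list(pink_sd = 0, white_sd = 0, exponent = 1, alpha_amp = 0)

# deterministic one-row subject profile (population means, no draws)
fixed_profile <- function(...) {
  p <- data.frame(
    subject_id = "T001", age = 10.7, sex = 1, iq_raw = 97,
    adhd_latent = 0, adhd_index = 5,
    inh_p3_amp = 6.1, inh_p3_lat = 460, inh_p3_amp_sd = 2,
    inh_p3_lat_sd = 20,
    sal_p3_amp = 5.3, sal_p3_lat = 455, sal_p3_amp_sd = 2,
    sal_p3_lat_sd = 20,
    sal_n2_amp = 1.05, sal_n2_lat = 300, sal_n2_amp_sd = 0.5,
    sal_n2_lat_sd = 12,
    rt_mean_standard = 390, rt_mean_salient = 423, rt_sd_standard = 160,
    rt_sd_salient = 163, salience_rt_effect = 33,
    miss_p = 0.04, fa_p = 0.41,
    stringsAsFactors = FALSE
  )
  over <- list(...)
  for (nm in names(over)) p[[nm]] <- over[[nm]]
  p
}

# forward model with no shared (condition-unspecific) components, for tests
# that isolate the driven-component measurement machinery
bare_model <- function(...) {
  m <- erp_forward_model(...)
  m$shared <- list()
  m
}

# independent separation-constraint scanner (brute force over the full
# concatenated sequence; deliberately not using validate_sequence)
scan_separation <- function(seq) {
  cond <- seq$trials$condition
  spec <- which(cond != "StandardGo")
  if (length(spec) < 2L) return(TRUE)
  g_same <- seq$params$min_standard_between_specials
  g_cross <- seq$params$min_standard_cross
  for (k in seq_len(length(spec) - 1L)) {
    a <- spec[k]; b <- spec[k + 1L]
    req <- if (cond[a] == cond[b]) g_same else g_cross
    if (b - a - 1L < req) return(FALSE)
  }
  TRUE
}

# brute-force fractional-area latency: rectify at samples, linearly
# interpolate onto a dense grid, cumulative-sum search
dense_fal <- function(x, times, window, fraction = 0.5, step = 0.01) {
  i0 <- which.min(abs(times - window$t_start))
  i1 <- which.min(abs(times - window$t_end))
  t <- times[i0:i1]
  r <- if (window$polarity == "positive") pmax(x[i0:i1], 0) else
    pmax(-x[i0:i1], 0)
  tg <- seq(t[1], t[length(t)], by = step)
  rg <- stats::approx(t, r, xout = tg)$y
  cum <- cumsum((rg[-1] + rg[-length(rg)]) / 2 * step)
  total <- cum[length(cum)]
  if (total <= 0) return(NA_real_)
  tg[which(cum >= fraction * total)[1] + 1L]
}

# partial correlation via the precision-matrix identity (independent oracle)
precision_partial <- function(x, y, Z, method = "pearson") {
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  M <- cbind(x = x, y = y, Z)
  P <- solve(stats::cov(M))
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# subject-level records with null measures, for battery-only tests
null_records <- function(n, seed) {
  withr::with_seed(seed, {
    prof <- simulate_profiles(n, effect_config(targets = null_effect_targets()),
                              seed = seed)
    rec <- prof[, c("subject_id", "age", "sex", "iq_raw", "adhd_index")]
    for (sc in c("inhibition_P3_POz", "inhibition_P3_Pz", "salience_P3_POz",
                 "salience_P3_Pz", "salience_N2_Fz"))
      for (ms in c("amp", "lat", "amp_sd", "lat_sd")) {
        comp <- sub("_(POz|Pz|Fz)$", "", sc)
        lat_col <- paste0(c(inhibition_P3 = "inh_p3", salience_P3 = "sal_p3",
                            salience_N2 = "sal_n2")[[comp]], "_", ms)
        rec[[paste0(sc, "_", ms)]] <- prof[[lat_col]]
      }
    rec
  })
}
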