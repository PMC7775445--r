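# waveform helpers on the native 200 Hz grid
grid200 <- function(t0 = -200, t1 = 895) seq(t0, t1, by = 5)

win_pos <- component_window("inhibition_P3", "POz", 300, 600, "positive",
                            "NoGo")

test_that("condition averages exclude error trials and average correctly", {
  prof <- fixed_profile(inh_p3_amp_sd = 0, inh_p3_lat_sd = 0,
                        sal_p3_amp_sd = 0, sal_p3_lat_sd = 0,
                        sal_n2_amp_sd = 0, sal_n2_lat_sd = 0)
  seqn <- generate_sequence(tiny_params(), seed = 1)
  ep <- simulate_epochs(prof, seqn, erp_forward_model(), seed = 2,
                        noise = no_noise)
  # noise-free with zero trial SDs: average equals any single trial
  avg <- condition_average(ep, "NoGo", exclude_errors = FALSE)
  k <- which(ep$metadata$condition == "NoGo")[1]
  expect_equal(avg["POz", ], ep$data[k, "POz", ], tolerance = 1e-12)

  # +1/-1 constant trials cancel
  ep2 <- ep
  ep2$data[] <- 0
  idx <- which(ep2$metadata$condition == "NoGo")
  ep2$data[idx[1], , ] <- 1
  ep2$data[idx[2], , ] <- -1
  ep2$metadata <- ep2$metadata[, c("index", "condition")]
  avg2 <- condition_average(ep2, "NoGo", exclude_errors = FALSE)
  n_nogo <- length(idx)
  expect_equal(max(abs(avg2)), 0, tolerance = 1e-12)
  # labels gate trials: flagging one trial as error changes n
  ep2$metadata$label <- "CorrectInhibition"
  ep2$metadata$label[ep2$metadata$condition != "NoGo"] <- "HIT"
  ep2$metadata$label[idx[1]] <- "FA"
  avg3 <- condition_average(ep2, "NoGo", exclude_errors = TRUE)
  expect_equal(attr(avg3, "n_trials"), n_nogo - 1L)
  expect_error(condition_average(ep2, "Bogus"), "empty average")
})

test_that("difference waves are pointwise and antisymmetric", {
  t <- grid200()
  a <- matrix(rnorm(2 * length(t)), 2, dimnames = list(c("POz", "Fz"), NULL))
  attr(a, "times") <- t
  b <- matrix(rnorm(2 * length(t)), 2, dimnames = list(c("POz", "Fz"), NULL))
  attr(b, "times") <- t
  expect_equal(max(abs(difference_wave(a, a))), 0)
  expect_equal(difference_wave(a, b), -difference_wave(b, a))
  g <- a
  g["POz", ] <- a["POz", ] + 5 * exp(-0.5 * ((t - 460) / 40)^2)
  expect_equal(difference_wave(g, a)["POz", ],
               5 * exp(-0.5 * ((t - 460) / 40)^2))
  bad <- b[, -1]
  attr(bad, "times") <- t[-1]
  expect_error(difference_wave(a, bad), "structural")
})

test_that("signed-area amplitude matches closed forms", {
  t <- grid200()
  # constant +1 uV across the 300 ms window -> 300 uV.ms
  x <- rep(1, length(t))
  expect_equal(signed_area_amplitude(x, win_pos, times = t), 300)
  # constant -2 uV has no positive area
  expect_equal(signed_area_amplitude(rep(-2, length(t)), win_pos,
                                     times = t), 0)
  # negative polarity reports the magnitude
  win_neg <- component_window("salience_N2", "Fz", 300, 600, "negative",
                              "SalientGo")
  expect_equal(signed_area_amplitude(rep(-2, length(t)), win_neg,
                                     times = t), 600)
  # half-sine peak 10 uV spanning exactly 300-600 ms: area (2/pi)*10*300
  hs <- ifelse(t >= 300 & t <= 600, 10 * sin(pi * (t - 300) / 300), 0)
  expect_equal(signed_area_amplitude(hs, win_pos, times = t),
               2 / pi * 10 * 300, tolerance = 2e-3)
  # window outside the epoch is a parameter error
  w_out <- component_window("x", "POz", 800, 1000, "positive", "NoGo")
  expect_error(signed_area_amplitude(x, w_out, times = t), "window outside")
})

test_that("fractional-area latency matches closed forms", {
  t <- grid200()
  # rectangular pulse exactly filling 300-500 ms -> midpoint 400 ms
  win45 <- component_window("x", "POz", 300, 500, "positive", "NoGo")
  pulse <- ifelse(t >= 300 & t <= 500, 1, 0)
  expect_equal(fractional_area_latency(pulse, win45, times = t), 400)
  # symmetric Gaussian centered at 460 ms -> 460 within one sample
  g <- exp(-0.5 * ((t - 460) / 40)^2)
  expect_lt(abs(fractional_area_latency(g, win_pos, times = t) - 460), 5)
  # right-triangle ramp 0 at 300 to peak at 600: (t-300)^2 = .5*300^2
  ramp <- ifelse(t >= 300 & t <= 600, (t - 300) / 300, 0)
  expect_equal(fractional_area_latency(ramp, win_pos, times = t),
               300 + 300 / sqrt(2), tolerance = 1e-6)
  # zero total area -> undefined latency propagates as NA
  expect_true(is.na(fractional_area_latency(rep(-1, length(t)), win_pos,
                                            times = t)))
})

test_that("latency agrees with a dense-grid brute force on random waves", {
  t <- grid200()
  set.seed(99)
  for (i in 1:200) {
    x <- rep(0, length(t))
    for (k in 1:sample(2:5, 1))
      x <- x + runif(1, -5, 10) *
        exp(-0.5 * ((t - runif(1, 250, 650)) / runif(1, 20, 80))^2)
    fal <- fractional_area_latency(x, win_pos, times = t)
    oracle <- dense_fal(x, t, win_pos)
    if (is.na(fal)) expect_true(is.na(oracle)) else
      expect_lt(abs(fal - oracle), 0.1)
  }
})

test_that("scaling and window nesting behave as area measures must", {
  t <- grid200()
  set.seed(5)
  x <- abs(rnorm(length(t)))
  for (c in c(0.5, 2, 7)) {
    expect_equal(signed_area_amplitude(c * x, win_pos, times = t),
                 c * signed_area_amplitude(x, win_pos, times = t))
    expect_equal(fractional_area_latency(c * x, win_pos, times = t),
                 fractional_area_latency(x, win_pos, times = t))
  }
  narrow <- component_window("x", "POz", 350, 550, "positive", "NoGo")
  y <- rnorm(length(t))
  expect_gte(signed_area_amplitude(y, win_pos, times = t),
             signed_area_amplitude(y, narrow, times = t))
})

test_that("single-trial measures recover injected variability (noise-free)", {
  # amplitude jitter only: latencies all equal the template latency
  prof <- fixed_profile(inh_p3_amp_sd = 2, inh_p3_lat_sd = 0)
  p <- cpt_task_params(n_blocks = 2, trials_per_block = 100)
  seqn <- generate_sequence(p, seed = 11)
  model <- bare_model()
  ep <- simulate_epochs(prof, seqn, model, seed = 12, noise = no_noise)
  st <- single_trial_measures(ep, win_pos, exclude_errors = FALSE)
  expect_lt(diff(range(st$latency)), 1e-6)
  expect_equal(st$latency[1], 460, tolerance = 1)
  # SD of extracted amplitudes vs injected SD after area scaling
  inj_sd <- 2 * ground_truth_area(model, "inh_p3", "POz", 1)
  expect_lt(abs(sd(st$amplitude) - inj_sd) / inj_sd, 0.15)
  # agreement with the stored ground truth, trial by trial
  gt <- ep$ground_truth[ep$ground_truth$component == "inh_p3", ]
  gt_area <- ground_truth_area(model, "inh_p3", "POz", gt$amp_peak)
  m <- match(st$trial, gt$trial)
  expect_gt(cor(st$amplitude, gt_area[m]), 0.999)
})

test_that("injected latency jitter is recovered from single trials", {
  prof <- fixed_profile(inh_p3_amp_sd = 0, inh_p3_lat_sd = 20)
  p <- cpt_task_params(n_blocks = 2, trials_per_block = 100)
  seqn <- generate_sequence(p, seed = 13)
  ep <- simulate_epochs(prof, seqn, bare_model(), seed = 14,
                        noise = no_noise)
  st <- single_trial_measures(ep, win_pos, exclude_errors = FALSE)
  gt <- ep$ground_truth[ep$ground_truth$component == "inh_p3", ]
  expect_lt(abs(sd(st$latency) - 20) / 20, 0.15)
  m <- match(st$trial, gt$trial)
  expect_gt(cor(st$latency, gt$latency[m]), 0.95)
})

test_that("duplicated trials give zero variability", {
  prof <- fixed_profile()
  seqn <- generate_sequence(tiny_params(), seed = 15)
  ep <- simulate_epochs(prof, seqn, erp_forward_model(), seed = 16,
                        noise = no_noise)
  k <- which(ep$metadata$condition == "NoGo")
  for (j in k) ep$data[j, , ] <- ep$data[k[1], , ]
  st <- single_trial_measures(ep, win_pos, exclude_errors = FALSE)
  expect_equal(sd(st$amplitude), 0, tolerance = 1e-10)
  expect_equal(sd(st$latency), 0, tolerance = 1e-10)
})

test_that("component measures recover the forward model analytically", {
  prof <- fixed_profile(inh_p3_amp_sd = 0, inh_p3_lat_sd = 0,
                        sal_p3_amp_sd = 0, sal_p3_lat_sd = 0,
                        sal_n2_amp_sd = 0, sal_n2_lat_sd = 0)
  seqn <- generate_sequence(tiny_params(), seed = 17)
  model <- erp_forward_model()
  ep <- baseline_correct(simulate_epochs(prof, seqn, model, seed = 18,
                                         noise = no_noise))
  cm <- component_measures(ep, win_pos, exclude_errors = FALSE)
  analytic <- ground_truth_area(model, "inh_p3", "POz", 6.1)
  expect_lt(abs(cm$mean_amplitude - analytic) / analytic, 0.02)
  expect_lt(abs(cm$mean_latency - 460), 5)
  # reference identical to critical: zero difference, zero area
  ep0 <- ep
  ep0$metadata$condition <- "NoGo"
  idx <- seq_len(nrow(ep0$metadata))
  half <- idx[seq_len(floor(length(idx) / 2))]
  ep0$metadata$condition[half] <- "StandardGo"
  ep0$data[half, , ] <- ep0$data[-half, , ][seq_along(half), , ]
  cm0 <- component_measures(ep0, win_pos, exclude_errors = FALSE)
  expect_equal(cm0$mean_amplitude, 0, tolerance = 1e-9)
  # doubling all component amplitudes doubles the signed area
  prof2 <- prof
  for (cn in c("inh_p3_amp", "sal_p3_amp", "sal_n2_amp"))
    prof2[[cn]] <- 2 * prof2[[cn]]
  model2 <- model
  for (cn in names(model2$shared)) model2$shared[[cn]]$amp <-
    2 * model2$shared[[cn]]$amp
  ep2 <- baseline_correct(simulate_epochs(prof2, seqn, model2, seed = 18,
                                          noise = no_noise))
  cm2 <- component_measures(ep2, win_pos, exclude_errors = FALSE)
  expect_equal(cm2$mean_amplitude, 2 * cm$mean_amplitude, tolerance = 1e-6)
})
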