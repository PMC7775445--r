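#' Classify trials into HIT / MISS / FA / CorrectInhibition
#'
#' Responses are registered only between `window_lo` and `window_hi` ms
#' after stimulus onset (closed interval, default 200-1500 ms); a response
#' outside the window is treated as no response.  Go trials (StandardGo,
#' SalientGo) with an in-window response are HITs, otherwise MISSes; NoGo
#' trials with an in-window response are false alarms (FA), otherwise
#' correct inhibitions.
#'
#' @param seq A `cpt_sequence`.
#' @param responses Data.frame with columns `index`, `responded`, `rt`
#'   (see [simulate_behavior()]), aligned 1:1 with the trials.
#' @param window_lo,window_hi Response registration window, ms.
#' @return Data.frame with columns `index`, `condition`, `label`, `rt`
#'   (`NA` unless the label is HIT or FA).
#' @export
classify_trials <- function(seq, responses, window_lo = 200,
                            window_hi = 1500) {
  tr <- seq$trials
  if (nrow(responses) != nrow(tr) || any(responses$index != tr$index))
    stop("responses are not aligned with the trial sequence", call. = FALSE)
  in_window <- responses$responded & !is.na(responses$rt) &
    responses$rt >= window_lo & responses$rt <= window_hi
  is_go <- tr$condition %in% c("StandardGo", "SalientGo")
  label <- ifelse(is_go,
                  ifelse(in_window, "HIT", "MISS"),
                  ifelse(in_window, "FA", "CorrectInhibition"))
  rt <- ifelse(label %in% c("HIT", "FA"), responses$rt, NA_real_)
  data.frame(index = tr$index, condition = tr$condition, label = label,
             rt = rt, stringsAsFactors = FALSE)
}

#' Commission error ratio
#'
#' False alarms divided by the total number of inhibition (NoGo) trials,
#' i.e. FA / (FA + CorrectInhibition).
#'
#' @param outcomes Output of [classify_trials()].
#' @return Proportion in \[0, 1\].
#' @export
commission_ratio <- function(outcomes) {
  nogo <- outcomes$label %in% c("FA", "CorrectInhibition")
  if (!any(nogo)) stop("undefined ratio: no NoGo trials", call. = FALSE)
  sum(outcomes$label == "FA") / sum(nogo)
}

#' Omission error ratio
#'
#' Missed trials divided by the total number of Go trials (StandardGo and
#' SalientGo pooled), i.e. MISS / (MISS + HIT).
#'
#' @inheritParams commission_ratio
#' @return Proportion in \[0, 1\].
#' @export
omission_ratio <- function(outcomes) {
  go <- outcomes$label %in% c("HIT", "MISS")
  if (!any(go)) stop("undefined ratio: no Go trials", call. = FALSE)
  sum(outcomes$label == "MISS") / sum(go)
}

#' Reaction-time mean and variability for one condition
#'
#' Arithmetic mean and sample standard deviation (n-1 denominator) of the
#' reaction times of HIT trials in the given condition.  With fewer than
#' two HITs the SD is reported as `NA` (absent), not zero.
#'
#' @inheritParams commission_ratio
#' @param condition `"StandardGo"` or `"SalientGo"`.
#' @return List with `mean`, `sd`, `n`.
#' @export
rt_summary <- function(outcomes, condition) {
  rts <- outcomes$rt[outcomes$condition == condition &
                       outcomes$label == "HIT"]
  list(mean = if (length(rts)) mean(rts) else NA_real_,
       sd = if (length(rts) >= 2) stats::sd(rts) else NA_real_,
       n = length(rts))
}

#' One-row behavioral summary for a subject
#'
#' @inheritParams commission_ratio
#' @return Data.frame with `rt_mean_standard`, `rt_mean_salient`,
#'   `rt_sd_standard`, `rt_sd_salient`, `omission_ratio`,
#'   `commission_ratio`, `salience_rt_effect` (salient minus standard HIT
#'   mean RT, ms).
#' @export
behavioral_summary <- function(outcomes) {
  std <- rt_summary(outcomes, "StandardGo")
  sal <- rt_summary(outcomes, "SalientGo")
  data.frame(rt_mean_standard = std$mean, rt_mean_salient = sal$mean,
             rt_sd_standard = std$sd, rt_sd_salient = sal$sd,
             omission_ratio = omission_ratio(outcomes),
             commission_ratio = commission_ratio(outcomes),
             salience_rt_effect = sal$mean - std$mean)
}
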