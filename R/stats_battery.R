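#' Outlier exclusion by the 3-SD rule
#'
#' Flags values more than 3 SD above or below the full-sample mean of the
#' variable (single pass; mean/SD are not recomputed after removal).  With
#' zero variance nothing is excluded.
#'
#' @param values Numeric vector (length >= 3).
#' @param n_sd Exclusion threshold in SD units.
#' @return Logical keep-mask of the same length.
#' @export
exclude_outliers <- function(values, n_sd = 3) {
  if (length(values) < 3L) stop("need at least 3 values", call. = FALSE)
  s <- stats::sd(values)
  if (is.na(s) || s == 0) return(rep(TRUE, length(values)))
  abs(values - mean(values)) <= n_sd * s
}

#' Normality-gated correlation method choice
#'
#' Spearman's rank correlation is used when the Shapiro-Wilk test indicates
#' a significant (p < `alpha`) deviation from normality for either
#' variable; Pearson's correlation otherwise.  Constant input (for which
#' Shapiro-Wilk is undefined) falls back to Spearman.
#'
#' @param x,y Numeric vectors (after outlier exclusion).
#' @param alpha Gate level.
#' @return List with `method` (`"pearson"`/`"spearman"`) and the two
#'   Shapiro-Wilk p-values (`NA` when undefined).
#' @export
choose_method <- function(x, y, alpha = 0.05) {
  swp <- function(v) {
    if (length(unique(v)) < 3L) return(NA_real_)
    tryCatch(stats::shapiro.test(v)$p.value, error = function(e) NA_real_)
  }
  px <- swp(x); py <- swp(y)
  nonnormal <- (is.na(px) || px < alpha) || (is.na(py) || py < alpha)
  list(method = if (nonnormal) "spearman" else "pearson",
       shapiro_x = px, shapiro_y = py)
}

#' Partial correlation controlling for covariates
#'
#' Pearson: the correlation of the residuals of `x` and `y` after linear
#' regression on the covariates (with intercept).  Spearman: `x` and `y`
#' are rank-transformed first, then the same residual procedure is applied.
#' The two-tailed p-value comes from `t = r sqrt(df / (1 - r^2))` with
#' `df = n - 2 - k` (k = number of covariates).
#'
#' @param x,y Numeric vectors.
#' @param covariates Numeric matrix or data.frame of covariates (n x k).
#' @param method `"pearson"` or `"spearman"`.
#' @return List with `estimate`, `p_value`, `df`, `method`, `n`.
#' @export
partial_correlation <- function(x, y, covariates,
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  Z <- as.matrix(covariates)
  storage.mode(Z) <- "double"
  n <- length(x)
  k <- ncol(Z)
  if (n <= k + 2)
    stop("need n > k + 2 observations for ", k, " covariates", call. = FALSE)
  if (qr(cbind(1, Z))$rank < k + 1) {
    cn <- colnames(Z) %||% paste0("cov", seq_len(k))
    stop("rank-deficient covariates (collinear column among: ",
         paste(cn, collapse = ", "), ")", call. = FALSE)
  }
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
  }
  rx <- stats::lm.fit(cbind(1, Z), x)$residuals
  ry <- stats::lm.fit(cbind(1, Z), y)$residuals
  # a variable fully explained by the covariates leaves numerically zero
  # residuals: its partial correlation is 0 by convention
  if (stats::sd(rx) <= 1e-10 * max(stats::sd(x), 1) ||
      stats::sd(ry) <= 1e-10 * max(stats::sd(y), 1)) {
    return(list(estimate = 0, p_value = 1, df = n - 2 - k, method = method,
                n = n))
  }
  r <- stats::cor(rx, ry)
  df <- n - 2 - k
  tval <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tval), df)
  list(estimate = r, p_value = p, df = df, method = method, n = n)
}

#' One-sample t-test with effect size
#'
#' Standard two-tailed one-sample t-test plus Cohen's d (mean difference
#' over SD).  The Shapiro-Wilk normality gate is evaluated and reported;
#' when it fails the test is still computed but a caveat is flagged.
#'
#' @param values Numeric vector (n >= 2).
#' @param mu Null-hypothesis mean.
#' @return List with `t`, `df`, `p`, `mean_diff`, `ci` (95%), `d`,
#'   `shapiro_p`, `normality_ok`.
#' @export
one_sample_t <- function(values, mu = 0) {
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  swp <- if (length(unique(values)) >= 3L)
    stats::shapiro.test(values)$p.value else NA_real_
  s <- stats::sd(values)
  if (s == 0) {
    md <- mean(values) - mu
    return(list(t = if (md == 0) 0 else sign(md) * Inf,
                df = length(values) - 1L, p = if (md == 0) 1 else 0,
                mean_diff = md, ci = c(md, md), d = if (md == 0) 0 else
                  sign(md) * Inf, shapiro_p = swp,
                normality_ok = !is.na(swp) && swp > 0.05))
  }
  tt <- stats::t.test(values, mu = mu)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = mean(values) - mu,
       ci = unname(tt$conf.int),
       d = (mean(values) - mu) / s,
       shapiro_p = swp, normality_ok = !is.na(swp) && swp > 0.05)
}

#' Extreme-group contrast on the ADHD index
#'
#' Compares the upper versus lower third of the ADHD index distribution on
#' `variable` with an independent-samples t-test.  Group membership uses a
#' stable sort on (ADHD index, subject id), so boundary ties break
#' deterministically; group sizes are `floor(n/3)` each.  Homoskedasticity
#' is checked with Levene's test; when it fails (p <= 0.05) Welch's t-test
#' is used instead of the pooled-variance test and flagged.
#'
#' @param records Data.frame with `adhd_index`, `subject_id`, and the
#'   outcome variable.
#' @param variable Name of the outcome column.
#' @return List with `t`, `df`, `p`, `ci`, `d` (Cohen's d, pooled SD),
#'   `levene_p`, `pooled` (logical), `group_sizes`.
#' @export
independent_t_extreme_groups <- function(records, variable) {
  n <- nrow(records)
  if (n < 6L) stop("grouping error: need at least 6 subjects", call. = FALSE)
  ord <- order(records$adhd_index, records$subject_id)
  k <- floor(n / 3)
  lower <- records[[variable]][ord[seq_len(k)]]
  upper <- records[[variable]][ord[seq(n - k + 1L, n)]]
  g <- factor(rep(c("lower", "upper"), c(k, k)))
  lev <- car::leveneTest(c(lower, upper), g)
  lev_p <- lev[1, "Pr(>F)"]
  pooled <- is.na(lev_p) || lev_p > 0.05
  tt <- stats::t.test(upper, lower, var.equal = pooled)
  sp <- sqrt(((k - 1) * stats::var(upper) + (k - 1) * stats::var(lower)) /
               (2 * k - 2))
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       ci = unname(tt$conf.int),
       d = if (sp > 0) (mean(upper) - mean(lower)) / sp else NA_real_,
       levene_p = lev_p, pooled = pooled, group_sizes = c(k, k))
}

#' R-squared of a logarithmic, quadratic, or cubic fit
#'
#' Least-squares fit of the stated form; for the logarithmic form `x` is
#' shifted positive when needed (`x - min(x) + 1`).
#'
#' @param x,y Numeric vectors.
#' @param form `"log"`, `"quadratic"`, or `"cubic"`.
#' @return R-squared (`1 - SS_res / SS_tot`).
#' @export
polynomial_fit_r2 <- function(x, y, form = c("log", "quadratic", "cubic")) {
  form <- match.arg(form)
  if (stats::sd(x) == 0) stop("degenerate design: constant x", call. = FALSE)
  X <- switch(form,
              log = {
                xs <- if (min(x) <= 0) x - min(x) + 1 else x
                cbind(log(xs))
              },
              quadratic = cbind(x, x^2),
              cubic = cbind(x, x^2, x^3))
  fit <- stats::lm.fit(cbind(1, X), y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise level.
#' @param m Number of tests (4 per ERP component in the published battery:
#'   amplitude, latency, and their two variability measures).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 4) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  alpha / m
}

#' Minimum detectable correlation at given power
#'
#' Fisher-z approximation:
#' `r = tanh((z_{1-alpha/2} + z_{power}) / sqrt(n - 3))`.
#' At n = 31 this gives 0.48 (two decimals): only large correlations are
#' detectable with 80% power in a sample of that size.
#'
#' @param n Sample size (> 3).
#' @param alpha Two-tailed significance level.
#' @param power Target power.
#' @return Minimum detectable correlation.
#' @export
#' @examples
#' round(min_detectable_r(31), 2)  # 0.48
min_detectable_r <- function(n, alpha = 0.05, power = 0.80) {
  if (n <= 3) stop("need n > 3", call. = FALSE)
  tanh((stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) / sqrt(n - 3))
}

#' Run the covariate-adjusted correlation battery
#'
#' For every component/site/measure cell: pairwise outlier exclusion (3-SD
#' rule on the ADHD index and the measure; covariates never trigger
#' exclusion), Shapiro-Wilk method gate, partial correlation controlling
#' for age, sex, and IQ, and significance flags at `alpha` and at the
#' Bonferroni-corrected threshold `alpha / m`.
#'
#' @param records Subject-level data.frame: `adhd_index`, covariates, and
#'   measure columns named `<component>_<site>_<measure>` (as produced by
#'   [simulate_cohort_records()]).
#' @param alpha Uncorrected level.
#' @param m Number of tests per component for the Bonferroni correction.
#' @param covariates Covariate column names.
#' @param measures Measure suffixes to test.
#' @return Data.frame (class `cpt_battery`) with one row per cell:
#'   `component`, `site`, `measure`, `primary` (FALSE for Pz
#'   replications), `method`, `coefficient`, `p`, `sig_unc`, `sig_bonf`,
#'   `n`, `n_outliers`, `shapiro_x`, `shapiro_y`.
#' @export
run_correlation_battery <- function(records, alpha = 0.05, m = 4,
                                    covariates = c("age", "sex", "iq_raw"),
                                    measures = c("amp", "lat", "amp_sd",
                                                 "lat_sd")) {
  cells <- expand.grid(
    site_comp = c("inhibition_P3_POz", "inhibition_P3_Pz",
                  "salience_P3_POz", "salience_P3_Pz", "salience_N2_Fz"),
    measure = measures, stringsAsFactors = FALSE)
  thr <- bonferroni_threshold(alpha, m)
  Z <- as.matrix(records[, covariates])
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    col <- paste0(cells$site_comp[i], "_", cells$measure[i])
    if (!col %in% names(records))
      stop("missing measure column: ", col, call. = FALSE)
    x <- records$adhd_index
    y <- records[[col]]
    keep <- exclude_outliers(x) & exclude_outliers(y)
    xg <- x[keep]; yg <- y[keep]
    gate <- choose_method(xg, yg, alpha)
    Zk <- Z[keep, , drop = FALSE]
    # covariates that are constant in the retained sample carry no shared
    # variance; drop them rather than abort (matters in small cohorts)
    Zk <- Zk[, apply(Zk, 2, stats::sd) > 0, drop = FALSE]
    pc <- partial_correlation(xg, yg, Zk, method = gate$method)
    site <- sub("^.*_(POz|Pz|Fz)$", "\\1", cells$site_comp[i])
    comp <- sub("_(POz|Pz|Fz)$", "", cells$site_comp[i])
    out[[i]] <- data.frame(
      component = comp, site = site, measure = cells$measure[i],
      primary = site %in% c("POz", "Fz"), method = pc$method,
      coefficient = pc$estimate, p = pc$p_value,
      sig_unc = pc$p_value < alpha, sig_bonf = pc$p_value < thr,
      n = pc$n, n_outliers = sum(!keep),
      shapiro_x = gate$shapiro_x, shapiro_y = gate$shapiro_y,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "alpha") <- alpha
  attr(res, "bonferroni_threshold") <- thr
  class(res) <- c("cpt_battery", "data.frame")
  res
}
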