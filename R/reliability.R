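#' Cross-sectional area of a binary mask in mm^2
#'
#' Foreground pixel count times pixel_spacing^2. By default the count is
#' restricted to the largest 4-connected component: the nerve is a single
#' structure, and stray false-positive islands in a predicted mask would
#' otherwise corrupt the area.
#'
#' @param mask 0/1 matrix.
#' @param pixel_spacing mm/pixel (> 0).
#' @param largest_component_only restrict to the largest component.
#' @return area in mm^2.
#' @export
csa_mm2 <- function(mask, pixel_spacing, largest_component_only = TRUE) {
  if (pixel_spacing <= 0) stop("pixel_spacing must be positive")
  if (!all(mask %in% c(0, 1))) stop("mask must be binary 0/1")
  if (largest_component_only) mask <- largest_component(mask)
  sum(mask) * pixel_spacing^2
}

#' Paired-difference inference from summary statistics
#'
#' t = mean / (SD / sqrt(n)) with n - 1 degrees of freedom; two-sided p;
#' 95 percent CI = mean +/- t_{0.975, n-1} * SD / sqrt(n). This is the entry
#' point for recomputing printed agreement statistics from reported
#' mean +/- SD summaries.
#'
#' @param mean_diff mean of the paired differences.
#' @param sd_diff sample SD of the differences.
#' @param n number of pairs (>= 2).
#' @param conf confidence level (default 0.95).
#' @return list(mean_diff, sd_diff, t_stat, df, p_value, ci_low, ci_high);
#'   `t_stat` is NA when sd_diff is 0 (degenerate spread).
#' @export
paired_diff_from_summary <- function(mean_diff, sd_diff, n, conf = 0.95) {
  if (n < 2) stop("need n >= 2")
  se <- sd_diff / sqrt(n)
  df <- n - 1
  if (sd_diff == 0) {
    t_stat <- NA_real_; p <- NA_real_
    ci <- c(mean_diff, mean_diff)
  } else {
    t_stat <- mean_diff / se
    p <- 2 * stats::pt(-abs(t_stat), df)
    tq <- stats::qt(1 - (1 - conf) / 2, df)
    ci <- mean_diff + c(-1, 1) * tq * se
  }
  list(mean_diff = mean_diff, sd_diff = sd_diff, t_stat = t_stat, df = df,
       p_value = p, ci_low = ci[1], ci_high = ci[2])
}

#' Paired-difference inference on manual vs predicted CSA lists
#'
#' Differences are manual - predicted, so a positive mean means manual
#' measurements exceed the automated ones.
#'
#' @param manual,predicted numeric vectors of equal length n >= 2 (mm^2).
#' @return as [paired_diff_from_summary()].
#' @export
paired_difference_inference <- function(manual, predicted) {
  if (length(manual) != length(predicted)) stop("length mismatch")
  if (length(manual) < 2) stop("need at least 2 pairs")
  d <- manual - predicted
  paired_diff_from_summary(mean(d), stats::sd(d), length(d))
}

#' Pearson correlation with a Fisher-z confidence interval
#'
#' z = atanh(r), z +/- z_{0.975} / sqrt(n - 3), back-transformed with tanh.
#' atanh input is clamped to |r| <= 1 - 1e-12 so perfect correlation yields
#' a degenerate interval at 1 instead of infinities.
#'
#' @param x,y numeric vectors, n >= 4, both with nonzero variance.
#' @param conf confidence level.
#' @return list(r, ci_low, ci_high, n).
#' @export
pearson_with_fisher_ci <- function(x, y, conf = 0.95) {
  if (length(x) != length(y)) stop("length mismatch")
  n <- length(x)
  if (n < 4) stop("need n >= 4")
  if (stats::var(x) == 0 || stats::var(y) == 0) stop("constant input")
  r <- stats::cor(x, y)
  fisher_ci_for_r(r, n, conf)
}

#' Fisher-z interval for a given correlation and sample size
#' @param r correlation in \[-1, 1\].
#' @param n sample size (> 3).
#' @param conf confidence level.
#' @return list(r, ci_low, ci_high, n).
#' @export
fisher_ci_for_r <- function(r, n, conf = 0.95) {
  if (n <= 3) stop("need n > 3 for a Fisher-z interval")
  rc <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  z <- atanh(rc)
  hw <- stats::qnorm(1 - (1 - conf) / 2) / sqrt(n - 3)
  list(r = r, ci_low = tanh(z - hw), ci_high = tanh(z + hw), n = n)
}

#' Intraclass correlation ICC(2,1) with F-based confidence interval
#'
#' Two-way random-effects, absolute-agreement, single-rater form:
#' ICC(2,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE)), where MSR,
#' MSC and MSE are the rows (subjects), columns (methods) and error mean
#' squares of the two-way ANOVA. The interval uses the F-based procedure
#' with Satterthwaite degrees of freedom (Shrout-Fleiss / McGraw-Wong).
#'
#' @param ratings n x k numeric matrix: n subjects rated by k methods, no
#'   missing cells, n >= 5, k >= 2.
#' @param conf confidence level.
#' @return list(icc, ci_low, ci_high, ms = list(MSR, MSC, MSE), n, k).
#' @export
icc_2_1 <- function(ratings, conf = 0.95) {
  ratings <- as.matrix(ratings)
  if (any(is.na(ratings))) stop("missing cells are not supported")
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 5 || k < 2) stop("need at least 5 subjects and 2 raters")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((ratings - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  alpha <- 1 - conf
  if (mse <= 0 && msc <= msr) {
    # degenerate: perfect agreement
    return(list(icc = 1, ci_low = 1, ci_high = 1,
                ms = list(MSR = msr, MSC = msc, MSE = mse), n = n, k = k))
  }
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  list(icc = icc, ci_low = lo, ci_high = hi,
       ms = list(MSR = msr, MSC = msc, MSE = mse), n = n, k = k)
}

#' Bland-Altman agreement analysis
#'
#' bias = mean(x - y); limits of agreement = bias +/- 1.96 * sample SD of
#' the differences.
#'
#' @param x,y numeric vectors of equal length n >= 2.
#' @return list(bias, loa_low, loa_high, data = data.frame(mean, diff)).
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 2) stop("need at least 2 pairs")
  d <- x - y
  s <- stats::sd(d)
  bias <- mean(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       data = data.frame(mean = (x + y) / 2, diff = d))
}

#' Full manual-vs-automated CSA agreement report
#'
#' Paired-difference inference (manual - predicted), Pearson correlation
#' with Fisher-z interval, ICC(2,1) with F-based interval, and Bland-Altman
#' limits of agreement.
#'
#' @param manual,predicted CSA vectors in mm^2, equal length n >= 5.
#' @return object of class `agreement_report` (a named list).
#' @export
agreement_report <- function(manual, predicted) {
  pd <- paired_difference_inference(manual, predicted)
  pr <- pearson_with_fisher_ci(manual, predicted)
  ic <- icc_2_1(cbind(manual, predicted))
  ba <- bland_altman(manual, predicted)
  structure(list(n = length(manual),
                 mean_diff = pd$mean_diff, sd_diff = pd$sd_diff,
                 t_stat = pd$t_stat, df = pd$df, p_value = pd$p_value,
                 ci_low = pd$ci_low, ci_high = pd$ci_high,
                 pearson_r = pr$r, r_ci_low = pr$ci_low, r_ci_high = pr$ci_high,
                 icc21 = ic$icc, icc_ci_low = ic$ci_low,
                 icc_ci_high = ic$ci_high,
                 ba_bias = ba$bias, ba_loa_low = ba$loa_low,
                 ba_loa_high = ba$loa_high, ba_data = ba$data),
            class = "agreement_report")
}

#' CSA records for a list of predicted pairs
#'
#' Manual CSA comes from the simulated-rater mask (`manual_mask`), predicted
#' CSA from the network mask (`pred`).
#'
#' @param pairs pairs carrying `manual_mask` and `pred`.
#' @param largest_component_only see [csa_mm2()].
#' @return data.frame (image_id, site, manual_csa, predicted_csa,
#'   pixel_spacing).
#' @export
csa_records <- function(pairs, largest_component_only = TRUE) {
  do.call(rbind, lapply(pairs, function(p) {
    ps <- p$meta$pixel_spacing
    data.frame(image_id = p$id,
               site = if (!is.null(p$meta$site)) p$meta$site else NA_character_,
               manual_csa = csa_mm2(p$manual_mask, ps, largest_component_only),
               predicted_csa = csa_mm2(p$pred, ps, largest_component_only),
               pixel_spacing = ps, stringsAsFactors = FALSE)
  }))
}
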