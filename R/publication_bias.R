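#' Compare two groups of study-level means
#'
#' Welch's t-test (equal variances not assumed, Satterthwaite degrees of
#' freedom) plus a Mann-Whitney U test, as used to contrast published and
#' unpublished study means or sample sizes.
#'
#' @param a,b Numeric vectors (each length >= 2).
#' @return List with `welch_t`, `satterthwaite_df`, `p`, `mean_difference`
#'   (`mean(a) - mean(b)`), `ci95` (Welch CI of the difference),
#'   `mann_whitney_u` and `p_mw`.
#' @export
group_compare <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("each group needs >= 2 values")
  tt <- stats::t.test(a, b, var.equal = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL))
  list(welch_t = unname(tt$statistic),
       satterthwaite_df = unname(tt$parameter),
       p = tt$p.value,
       mean_difference = mean(a) - mean(b),
       ci95 = unname(tt$conf.int),
       mann_whitney_u = unname(wt$statistic),
       p_mw = wt$p.value)
}

#' Random-effects weighted mean of study amplitudes
#'
#' DerSimonian-Laird random-effects meta-analysis of per-study means and
#' standard errors: weights `1 / (se^2 + tau^2)`, pooled mean with 95% CI,
#' Cochran's Q and I-squared heterogeneity. A single study degenerates to
#' that study's mean with a normal-theory CI.
#'
#' @param mean Per-study mean amplitudes (microvolts).
#' @param se Per-study standard errors (all positive).
#' @param method `"DL"` (default, DerSimonian-Laird) or `"FE"` (fixed
#'   effect).
#' @return An object of class `meta_estimate`: `k`, `weighted_mean`,
#'   `ci_low`, `ci_high`, `tau_squared`, `q_statistic`, `i_squared`
#'   (fraction in `[0, 1]`).
#' @export
random_effects_mean <- function(mean, se, method = c("DL", "FE")) {
  method <- match.arg(method)
  if (length(mean) != length(se)) stop("length mismatch")
  if (length(mean) < 1L) stop("need at least one study")
  if (any(se <= 0)) stop("all standard errors must be positive")
  if (length(mean) == 1L) {
    return(structure(
      list(k = 1L, weighted_mean = mean, ci_low = mean - 1.96 * se,
           ci_high = mean + 1.96 * se, tau_squared = 0,
           q_statistic = 0, i_squared = 0),
      class = "meta_estimate"))
  }
  fit <- metafor::rma(yi = mean, sei = se, method = method)
  structure(
    list(k = fit$k, weighted_mean = as.numeric(fit$beta),
         ci_low = fit$ci.lb, ci_high = fit$ci.ub,
         tau_squared = fit$tau2, q_statistic = fit$QE,
         i_squared = fit$I2 / 100),
    class = "meta_estimate")
}

#' @export
print.meta_estimate <- function(x, ...) {
  cat(sprintf(
    "<meta_estimate> k=%d  mean=%.3f uV [%.3f; %.3f]  tau^2=%.4f  I^2=%.1f%%\n",
    x$k, x$weighted_mean, x$ci_low, x$ci_high, x$tau_squared,
    100 * x$i_squared))
  invisible(x)
}

#' Egger regression test for funnel-plot asymmetry
#'
#' The classic formulation: ordinary least squares of the standardized
#' effect (`mean / se`) on precision (`1 / se`); the intercept estimates the
#' asymmetry (equivalently, a regression of effect on standard error
#' weighted by inverse variance). A two-tailed t-test on the intercept gives
#' the p-value.
#'
#' @param mean Per-study means.
#' @param se Per-study standard errors (k >= 3).
#' @return List with `intercept`, `intercept_se`, `t`, `df`, `p`.
#' @export
egger_test <- function(mean, se) {
  if (length(mean) != length(se)) stop("length mismatch")
  if (length(mean) < 3L) stop("Egger's test needs at least 3 studies")
  if (any(se <= 0)) stop("all standard errors must be positive")
  snd <- mean / se
  prec <- 1 / se
  fit <- stats::lm(snd ~ prec)
  s <- summary(fit)$coefficients
  list(intercept = s[1L, 1L], intercept_se = s[1L, 2L],
       t = s[1L, 3L], df = fit$df.residual, p = s[1L, 4L])
}

#' Cumulative distribution of study amplitudes with confidence bands
#'
#' Studies sorted ascending by mean amplitude, each with a 95% CI
#' (`mean +/- t_{0.975, n-1} * se`) and a significance flag: significant
#' when the CI excludes zero (upper CI below zero for negative effects,
#' lower CI above zero for positive ones) — equivalent to the two-tailed
#' one-sample t-test at the 5% level.
#'
#' @param summaries Data frame with columns `mean`, `se`, `n` (e.g. from
#'   [catalogue_summaries()]); extra columns are carried through.
#' @return The input rows sorted by `mean` with added `ci_low`, `ci_high`,
#'   `significant` and `rank`.
#' @export
cumulative_distribution <- function(summaries) {
  need <- c("mean", "se", "n")
  if (!all(need %in% names(summaries))) {
    stop("summaries must have columns mean, se, n")
  }
  if (any(summaries$n < 2)) stop("every summary needs n >= 2")
  tq <- stats::qt(0.975, summaries$n - 1)
  out <- summaries
  out$ci_low <- out$mean - tq * out$se
  out$ci_high <- out$mean + tq * out$se
  out$significant <- out$ci_high < 0 | out$ci_low > 0
  out <- out[order(out$mean), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Funnel-plot points from per-study summaries
#'
#' @param summaries Data frame with columns `mean`, `se` and optionally
#'   `published`.
#' @return Data frame with `mean`, `se`, `published` and significance flags
#'   at the 5% and 1% levels (normal critical values, the funnel-contour
#'   convention).
#' @export
funnel_points <- function(summaries) {
  z <- abs(summaries$mean) / summaries$se
  data.frame(mean = summaries$mean, se = summaries$se,
             published = if ("published" %in% names(summaries)) {
               summaries$published
             } else NA,
             significant_05 = z > stats::qnorm(0.975),
             significant_01 = z > stats::qnorm(0.995))
}

#' Funnel plot of study means against standard errors
#'
#' @param points Data frame from [funnel_points()].
#' @param ... Passed to [plot()].
#' @return Invisibly, `points`.
#' @export
plot_funnel <- function(points, ...) {
  ylim <- rev(range(points$se) * c(0.95, 1.05))
  plot(points$mean, points$se, ylim = ylim,
       xlab = "mean amplitude (µV)", ylab = "standard error (µV)",
       pch = 19,
       col = ifelse(points$published %in% TRUE, "darkgreen", "firebrick"),
       ...)
  semax <- max(points$se) * 1.05
  for (q in c(stats::qnorm(0.975), stats::qnorm(0.995))) {
    segments(0, 0, -q * semax, semax, lty = 2, col = "steelblue")
    segments(0, 0, q * semax, semax, lty = 2, col = "steelblue")
  }
  abline(v = 0, col = "grey60")
  invisible(points)
}

#' Cumulative amplitude distribution plot
#'
#' @param dist Data frame from [cumulative_distribution()].
#' @param ... Passed to [plot()].
#' @return Invisibly, `dist`.
#' @export
plot_cumulative <- function(dist, ...) {
  plot(dist$rank, dist$mean, type = "l", lwd = 2, col = "steelblue",
       ylim = range(c(dist$ci_low, dist$ci_high, 0)),
       xlab = "rank (weakest to strongest)",
       ylab = "mean amplitude (µV)", ...)
  graphics::lines(dist$rank, dist$ci_low, col = "grey40")
  graphics::lines(dist$rank, dist$ci_high, col = "grey40")
  abline(h = 0, col = "grey70", lty = 2)
  invisible(dist)
}
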