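#' Cohen's d_z for paired differences
#'
#' The within-subject effect size: mean of the paired differences divided by
#' their standard deviation (denominator n - 1).
#'
#' @param diffs Numeric vector of per-participant differences (length >= 2).
#' @return Dimensionless effect size.
#' @examples
#' cohens_dz(c(-2, -1, 0, -3))  # -1.16190
#' @export
cohens_dz <- function(diffs) {
  if (length(diffs) < 2L) stop("need at least 2 differences")
  s <- stats::sd(diffs)
  if (s == 0) stop("zero standard deviation: d_z undefined")
  mean(diffs) / s
}

#' Fit the quadratic amplitude-to-effect-size model
#'
#' Ordinary least squares fit of `d_z = a * x^2 + b * x + c` with `x` the
#' grand-average SPN amplitude in microvolts. The quadratic captures the
#' levelling-off of effect size for strong SPNs.
#'
#' @param amplitude Numeric vector of amplitudes (microvolts).
#' @param d_z Numeric vector of matching effect sizes.
#' @return An object of class `effect_size_model` with coefficients `a`,
#'   `b`, `c`, fit `r_squared` and `n_points`.
#' @export
fit_effect_model <- function(amplitude, d_z) {
  if (length(amplitude) != length(d_z)) stop("length mismatch")
  if (length(amplitude) < 3L || length(unique(amplitude)) < 3L) {
    stop("need at least 3 points with 3 distinct amplitudes")
  }
  fit <- stats::lm(d_z ~ amplitude + I(amplitude^2))
  if (anyNA(stats::coef(fit))) stop("rank-deficient design")
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((d_z - mean(d_z))^2)
  effect_size_model(a = unname(stats::coef(fit)[3L]),
                    b = unname(stats::coef(fit)[2L]),
                    c = unname(stats::coef(fit)[1L]),
                    r_squared = 1 - sse / sst,
                    n_points = length(amplitude))
}

#' Construct an effect-size model from known coefficients
#'
#' @param a,b,c Quadratic coefficients of `d_z = a x^2 + b x + c`.
#' @param r_squared Fit R-squared in `[0, 1]` (`NA` when unknown).
#' @param n_points Number of points behind the fit.
#' @return An object of class `effect_size_model`.
#' @export
effect_size_model <- function(a, b, c, r_squared = NA_real_, n_points = 3L) {
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1)) {
    stop("r_squared must lie in [0, 1]")
  }
  structure(list(a = a, b = b, c = c, r_squared = r_squared,
                 n_points = as.integer(n_points)),
            class = "effect_size_model")
}

#' @export
print.effect_size_model <- function(x, ...) {
  cat(sprintf("<effect_size_model> d_z = %.4g x^2 + %.4g x + %.4g  (R^2 = %.3f, n = %d)\n",
              x$a, x$b, x$c, x$r_squared, x$n_points))
  invisible(x)
}

#' Predict effect size from amplitude
#'
#' @param model An `effect_size_model`.
#' @param amplitude Amplitude(s) in microvolts.
#' @return Predicted d_z value(s).
#' @export
predict_dz <- function(model, amplitude) {
  model$a * amplitude^2 + model$b * amplitude + model$c
}

#' Power of the one-sample (paired) t-test
#'
#' Exact power via the noncentral t distribution with noncentrality
#' `|d| * sqrt(n)` and `n - 1` degrees of freedom. The two-tailed version
#' accounts for both rejection regions.
#'
#' @param d Effect size (Cohen's d_z; magnitude used).
#' @param n Sample size (>= 2).
#' @param alpha Significance level (default 0.05).
#' @param tails 1 or 2 (default 2).
#' @return Power in `[0, 1]`.
#' @examples
#' power_one_sample_t(0.469, 24)  # ~0.595, i.e. 60%
#' @export
power_one_sample_t <- function(d, n, alpha = 0.05, tails = 2) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (any(n < 2)) stop("n must be at least 2")
  if (!tails %in% c(1, 2)) stop("tails must be 1 or 2")
  df <- n - 1
  ncp <- abs(d) * sqrt(n)
  if (tails == 2) {
    tc <- stats::qt(1 - alpha / 2, df)
    stats::pt(tc, df, ncp, lower.tail = FALSE) + stats::pt(-tc, df, ncp)
  } else {
    tc <- stats::qt(1 - alpha, df)
    stats::pt(tc, df, ncp, lower.tail = FALSE)
  }
}

#' Smallest sample size reaching a target power
#'
#' Minimal integer `n` in `[2, 1e6]` such that the exact one-sample t power
#' reaches `target_power`. Power is monotone in `n`, so the solver brackets
#' by doubling and then bisects; a final boundary check guarantees
#' `power(n) >= target` and `power(n - 1) < target`.
#'
#' @param d Effect size (nonzero; magnitude used).
#' @param target_power Target power in `(0, 1)` (default 0.8).
#' @param alpha Significance level (default 0.05).
#' @param tails 1 or 2 (default 2).
#' @return Integer sample size.
#' @examples
#' required_n(0.469)  # 38
#' required_n(0.4)    # 52
#' @export
required_n <- function(d, target_power = 0.8, alpha = 0.05, tails = 2) {
  if (d == 0) stop("d = 0: target power is unreachable")
  if (target_power <= 0 || target_power >= 1) {
    stop("target_power must lie in (0, 1)")
  }
  pw <- function(n) power_one_sample_t(d, n, alpha, tails)
  lo <- 2L
  if (pw(lo) >= target_power) return(lo)
  hi <- 4L
  while (pw(hi) < target_power) {
    lo <- hi
    hi <- hi * 2L
    if (hi > 1e6) stop("required n exceeds 1e6")
  }
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (pw(mid) >= target_power) hi <- mid else lo <- mid
  }
  stopifnot(pw(hi) >= target_power, pw(hi - 1L) < target_power)
  hi
}

#' Critical count for the two-tailed exact sign (binomial) test
#'
#' For `X ~ Binomial(n, 1/2)`, the smallest `k` such that the tail-doubled
#' two-tailed p-value `2 * P(X >= k)` is at most `alpha`; `NA` when no
#' `k <= n` qualifies. This is the minimum number of participants who must
#' show the directional effect for a significant sign test.
#'
#' @param n Number of participants (>= 1).
#' @param alpha Significance level (default 0.05).
#' @param method `"doubling"` (default) doubles the upper tail; `"exact"`
#'   sums the probabilities of all outcomes no more likely than `k`
#'   (the small-p-method two-tailed convention).
#' @return Integer critical count, or `NA` if unattainable.
#' @examples
#' binomial_critical_count(24)  # 18
#' binomial_critical_count(48)  # 32
#' @export
binomial_critical_count <- function(n, alpha = 0.05,
                                    method = c("doubling", "exact")) {
  method <- match.arg(method)
  if (n < 1L) stop("n must be at least 1")
  k <- 0:n
  upper <- stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)  # P(X >= k)
  p <- if (method == "doubling") {
    pmin(1, 2 * upper)
  } else {
    dens <- stats::dbinom(k, n, 0.5)
    vapply(k, function(ki) sum(dens[dens <= dens[ki + 1L] + 1e-12]),
           numeric(1))
  }
  ok <- which(p <= alpha)
  if (!length(ok)) return(NA_integer_)
  as.integer(k[min(ok)])
}

#' Required-sample-size table over a grid of amplitudes
#'
#' Row-wise composition of `predict_dz` and `required_n`: for each
#' amplitude, the predicted effect size and the smallest n giving the target
#' power. Rows whose predicted `d_z` is 0 get `NA` (unreachable).
#'
#' @param amplitudes Numeric vector of SPN amplitudes (microvolts).
#' @param model An `effect_size_model`.
#' @param target_power,alpha,tails Passed to [required_n()].
#' @return Data frame with columns `amplitude`, `d_z`, `required_n`.
#' @export
power_table <- function(amplitudes, model, target_power = 0.8, alpha = 0.05,
                        tails = 2) {
  dz <- predict_dz(model, amplitudes)
  rn <- vapply(dz, function(d) {
    if (d == 0) NA_integer_ else required_n(d, target_power, alpha, tails)
  }, integer(1))
  data.frame(amplitude = amplitudes, d_z = dz, required_n = rn)
}

#' Two-predictor amplitude regression (W-load and task relevance)
#'
#' Ordinary least squares of grand-average SPN amplitude on W-load and task
#' relevance (both on a 0-1 scale), as used to summarize what drives SPN
#' amplitude across a catalogue.
#'
#' @param amplitude Per-experiment mean amplitudes (microvolts).
#' @param w_load Per-experiment W-load values in `[0, 1]`.
#' @param task_relevant Per-experiment 0/1 task-relevance codes.
#' @return List with `intercept`, `coef_w`, `coef_task`, `r_squared`, `n`,
#'   and the underlying `lm` fit.
#' @export
amplitude_regression <- function(amplitude, w_load, task_relevant) {
  if (length(amplitude) < 4L) stop("need at least 4 experiments")
  if (length(unique(w_load)) < 2L || length(unique(task_relevant)) < 2L) {
    stop("rank-deficient design: a predictor is constant")
  }
  fit <- stats::lm(amplitude ~ w_load + task_relevant)
  if (anyNA(stats::coef(fit))) stop("collinear predictors")
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((amplitude - mean(amplitude))^2)
  list(intercept = unname(stats::coef(fit)[1L]),
       coef_w = unname(stats::coef(fit)[2L]),
       coef_task = unname(stats::coef(fit)[3L]),
       r_squared = 1 - sse / sst,
       n = length(amplitude),
       fit = fit)
}
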