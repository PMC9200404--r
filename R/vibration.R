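#' Default a priori electrode clusters for vibration analysis
#'
#' Three bilateral posterior clusters commonly used for SPN extraction:
#' `Cluster1` = PO7/O1/O2/PO8, `Cluster2` = PO7/PO8, and `Cluster3` = the
#' 16-electrode bilateral posterior set (P1-P9/PO7/PO3/O1 and mirrors).
#'
#' @return Named list of electrode-label vectors.
#' @export
default_clusters <- function() {
  list(Cluster1 = c("PO7", "O1", "O2", "PO8"),
       Cluster2 = c("PO7", "PO8"),
       Cluster3 = c("P1", "P3", "P5", "P7", "P9", "PO7", "PO3", "O1",
                    "P2", "P4", "P6", "P8", "P10", "PO8", "PO4", "O2"))
}

#' Recompute SPNs across alternative electrode clusters
#'
#' The "vibration of effects" analysis: every experiment's SPN is
#' recomputed for each named cluster over a shared window, plus the
#' experiment's own original cluster, and significance (two-tailed 5%) is
#' tallied per cluster.
#'
#' @param catalogue An `spn_catalogue`.
#' @param clusters Named list of electrode-label vectors (default
#'   [default_clusters()]).
#' @param window `(start_ms, end_ms)` shared across clusters (default
#'   `c(300, 1000)`).
#' @param include_original Also evaluate each experiment's
#'   `original_cluster` under the name `"Original"` (default `TRUE`).
#' @param alpha Significance level for the per-experiment one-sample t-test.
#' @return An object of class `vibration_report`: `summaries` (data frame,
#'   one row per experiment and cluster), `significance_counts`,
#'   `correlation_matrix` (Pearson, over per-experiment mean amplitudes),
#'   `clusters`, `window`, `alpha`.
#' @export
recompute_clusters <- function(catalogue, clusters = default_clusters(),
                               window = c(300, 1000),
                               include_original = TRUE, alpha = 0.05) {
  if (is.null(names(clusters)) || any(names(clusters) == "")) {
    stop("clusters must be a named list")
  }
  for (nm in names(clusters)) {
    bad <- setdiff(clusters[[nm]], catalogue$montage$labels)
    if (length(bad)) {
      stop("cluster '", nm, "' contains unknown electrode(s): ",
           paste(bad, collapse = ", "))
    }
  }
  sets <- clusters
  rows <- list()
  for (exp in catalogue$experiments) {
    per <- sets
    if (include_original) per <- c(list(Original = exp$original_cluster), per)
    for (nm in names(per)) {
      s <- spn_summary(exp, cluster = per[[nm]], window = window)
      row <- as.data.frame(s)
      row$cluster_name <- nm
      rows[[length(rows) + 1L]] <- row
    }
  }
  summaries <- do.call(rbind, rows)
  rownames(summaries) <- NULL
  summaries$significant <- summaries$p_two_tailed < alpha
  counts <- tapply(summaries$significant, summaries$cluster_name, sum)
  amp <- stats::reshape(
    summaries[, c("experiment_id", "cluster_name", "mean")],
    direction = "wide", idvar = "experiment_id", timevar = "cluster_name")
  ampmat <- as.matrix(amp[, -1L, drop = FALSE])
  colnames(ampmat) <- sub("^mean\\.", "", colnames(ampmat))
  cormat <- if (nrow(ampmat) >= 3L) stats::cor(ampmat) else NULL
  structure(
    list(summaries = summaries,
         significance_counts = counts[unique(summaries$cluster_name)],
         correlation_matrix = cormat,
         clusters = sets, window = window, alpha = alpha),
    class = "vibration_report")
}

#' @export
print.vibration_report <- function(x, ...) {
  cat("<vibration_report> ", length(unique(x$summaries$experiment_id)),
      " experiments x ", length(unique(x$summaries$cluster_name)),
      " clusters\n significant: ",
      paste(names(x$significance_counts), x$significance_counts,
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Pearson chi-square test of independence
#'
#' The Pearson statistic without continuity correction, with
#' `df = (r - 1)(c - 1)`, as used to compare significance counts across
#' electrode clusters.
#'
#' @param table Matrix of non-negative counts (>= 2 rows and columns, no
#'   all-zero row or column).
#' @return List with `statistic`, `df`, `p`.
#' @examples
#' # significant vs non-significant modulations across four clusters
#' chi_square_independence(cbind(c(38, 33, 35, 29), 40 - c(38, 33, 35, 29)))
#' @export
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(!is.finite(table))) {
    stop("counts must be finite and non-negative")
  }
  if (nrow(table) < 2L || ncol(table) < 2L) {
    stop("need at least a 2 x 2 table")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("degenerate table: all-zero row or column")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Cross-cluster Pearson correlations of SPN amplitude
#'
#' @param report A `vibration_report`.
#' @return Symmetric correlation matrix of per-experiment mean amplitudes
#'   across clusters.
#' @export
cross_cluster_correlation <- function(report) {
  if (is.null(report$correlation_matrix)) {
    stop("need at least 3 experiments for correlations")
  }
  v <- apply(report$correlation_matrix, 2L, function(x) any(!is.finite(x)))
  if (any(v)) stop("zero-variance amplitude vector in cluster(s): ",
                   paste(names(v)[v], collapse = ", "))
  report$correlation_matrix
}

#' One-way repeated-measures ANOVA with observed power
#'
#' Fits a one-way within-subject ANOVA (participant as blocking factor) via
#' [stats::aov()] and reports the condition effect together with its
#' observed (post-hoc) power, computed from the noncentral F distribution
#' with `ncp = F * df1` at the 5% level — the convention of common
#' statistical packages. Observed power is descriptive, not inferential.
#'
#' @param amplitudes Numeric matrix, participants by conditions, complete.
#' @param alpha Level for the observed-power computation (default 0.05).
#' @return List with `F`, `df1`, `df2`, `p`, `partial_eta_sq`,
#'   `observed_power`.
#' @export
rm_anova_oneway <- function(amplitudes, alpha = 0.05) {
  amplitudes <- as.matrix(amplitudes)
  if (any(!is.finite(amplitudes))) stop("incomplete or non-finite matrix")
  n <- nrow(amplitudes)
  k <- ncol(amplitudes)
  if (n < 2L || k < 2L) stop("need >= 2 participants and >= 2 conditions")
  d <- data.frame(
    y = as.vector(amplitudes),
    pid = factor(rep(seq_len(n), times = k)),
    cond = factor(rep(seq_len(k), each = n)))
  fit <- stats::aov(y ~ cond + Error(pid), data = d)
  tab <- summary(fit)[["Error: Within"]][[1L]]
  rownames(tab) <- trimws(rownames(tab))
  df1 <- tab["cond", "Df"]
  df2 <- tab["Residuals", "Df"]
  ss_cond <- tab["cond", "Sum Sq"]
  ss_err <- tab["Residuals", "Sum Sq"]
  Fv <- tab["cond", "F value"]
  ss_total <- sum((amplitudes - mean(amplitudes))^2)
  tol <- 1e-10 * max(ss_total, 1e-300)
  degenerate <- ss_cond <= tol && ss_err <= tol
  if (degenerate) {  # conditions identical per participant
    return(list(F = 0, df1 = df1, df2 = df2, p = 1,
                partial_eta_sq = 0, observed_power = alpha))
  }
  if (!is.finite(Fv)) {
    stop("zero residual variance with a nonzero condition effect")
  }
  ncp <- Fv * df1
  crit <- stats::qf(1 - alpha, df1, df2)
  list(F = Fv, df1 = df1, df2 = df2,
       p = tab["cond", "Pr(>F)"],
       partial_eta_sq = ss_cond / (ss_cond + ss_err),
       observed_power = stats::pf(crit, df1, df2, ncp, lower.tail = FALSE))
}
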