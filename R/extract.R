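#' Map a half-open ms window to 1-based sample indices
#'
#' Windows are half-open `[start, end)` in ms. With epoch start `t0` and
#' sampling rate `r` Hz the selected 0-based sample range is
#' `ceil((start - t0) * r / 1000)` up to but excluding
#' `ceil((end - t0) * r / 1000)`; this function returns the corresponding
#' 1-based indices. For an epoch starting at -200 ms sampled at 128 Hz the
#' window `[300, 1000)` maps to 0-based samples 64..153 (90 samples).
#'
#' @param window Length-2 numeric, ms.
#' @param epoch_start Epoch start, ms.
#' @param sampling_rate Hz.
#' @param n_samples Number of samples in the epoch.
#' @return Integer vector of 1-based sample indices.
#' @export
window_to_samples <- function(window, epoch_start, sampling_rate, n_samples) {
  if (length(window) != 2L || window[1L] >= window[2L]) {
    stop("window must be (start, end) with start < end")
  }
  i0 <- ceiling((window[1L] - epoch_start) * sampling_rate / 1000)
  i1 <- ceiling((window[2L] - epoch_start) * sampling_rate / 1000)
  if (i0 < 0 || i1 > n_samples) {
    stop("window [", window[1L], ", ", window[2L],
         ") lies outside the epoch")
  }
  if (i1 <= i0) stop("window contains no samples")
  seq.int(i0 + 1L, i1)
}

#' Mean amplitude over an electrode cluster and time window
#'
#' The arithmetic mean, in microvolts, of all (electrode, sample) values in
#' the given cluster and half-open ms window.
#'
#' @param erp An `erp_epoch`.
#' @param electrodes Character vector of electrode labels (non-empty).
#' @param window Length-2 numeric `(start_ms, end_ms)`.
#' @return Mean amplitude (microvolts).
#' @examples
#' \dontrun{window_mean(erp, c("PO7", "O1", "O2", "PO8"), c(300, 1000))}
#' @export
window_mean <- function(erp, electrodes, window) {
  if (length(electrodes) == 0L) stop("electrode cluster is empty")
  bad <- setdiff(electrodes, rownames(erp$data))
  if (length(bad)) {
    stop("unknown electrode(s): ", paste(bad, collapse = ", "))
  }
  idx <- window_to_samples(window, erp$epoch_start, erp$sampling_rate,
                           ncol(erp$data))
  mean(erp$data[electrodes, idx, drop = FALSE])
}

#' Per-experiment SPN summary statistics
#'
#' Computes per-participant regular-minus-random difference amplitudes over a
#' cluster and window, then the one-sample statistics used throughout the
#' catalogue analyses: mean, SD, SE, Cohen's d_z (mean / SD of differences),
#' t statistic, two-tailed p against zero, and the directional proportion
#' (fraction of participants with difference below zero; exact zeros count as
#' non-directional).
#'
#' @param exp An `spn_experiment`.
#' @param cluster Electrode labels; default the experiment's original cluster.
#' @param window `(start_ms, end_ms)`; default the original window.
#' @return An object of class `spn_summary`.
#' @export
spn_summary <- function(exp, cluster = exp$original_cluster,
                        window = exp$original_window) {
  if (exp$n < 2L) stop("need at least 2 participants")
  reg <- exp$contrast[["regular"]]
  ran <- exp$contrast[["random"]]
  diffs <- vapply(exp$participants, function(p) {
    window_mean(p[[reg]], cluster, window) -
      window_mean(p[[ran]], cluster, window)
  }, numeric(1))
  summarize_diffs(diffs, experiment_id = exp$id, cluster = cluster,
                  window = window)
}

#' Summary statistics from a vector of paired differences
#'
#' @param diffs Per-participant difference amplitudes (microvolts).
#' @param experiment_id,cluster,window Carried through to the result.
#' @return An object of class `spn_summary` with fields `n`, `diffs`, `mean`,
#'   `sd`, `se`, `d_z`, `t`, `df`, `p_two_tailed`, `prop_directional`.
#' @export
summarize_diffs <- function(diffs, experiment_id = NA_character_,
                            cluster = character(), window = c(NA, NA)) {
  n <- length(diffs)
  if (n < 2L) stop("need at least 2 differences")
  s <- stats::sd(diffs)
  if (s == 0) stop("degenerate sample: all differences identical (sd = 0)")
  m <- mean(diffs)
  se <- s / sqrt(n)
  tval <- m / se
  structure(
    list(experiment_id = experiment_id, cluster = cluster, window = window,
         n = n, diffs = diffs, mean = m, sd = s, se = se,
         d_z = m / s, t = tval, df = n - 1L,
         p_two_tailed = 2 * stats::pt(-abs(tval), df = n - 1L),
         prop_directional = mean(diffs < 0)),
    class = "spn_summary")
}

#' @export
print.spn_summary <- function(x, ...) {
  cat(sprintf(
    "<spn_summary> %s  n=%d  mean=%.3f uV  d_z=%.3f  t(%d)=%.3f  p=%.4g\n",
    x$experiment_id, x$n, x$mean, x$d_z, x$df, x$t, x$p_two_tailed))
  invisible(x)
}

#' @export
as.data.frame.spn_summary <- function(x, ...) {
  data.frame(experiment_id = x$experiment_id,
             cluster = paste(x$cluster, collapse = ","),
             window_start = x$window[1L], window_end = x$window[2L],
             n = x$n, mean = x$mean, sd = x$sd, se = x$se, d_z = x$d_z,
             t = x$t, df = x$df, p_two_tailed = x$p_two_tailed,
             prop_directional = x$prop_directional,
             stringsAsFactors = FALSE)
}

#' Grand-average ERP across participants
#'
#' Pointwise mean over participants of one condition's epochs.
#'
#' @param exp An `spn_experiment`.
#' @param condition Condition label.
#' @return An `erp_epoch` whose `participant_id` is `"grand_average"`.
#' @export
grand_average <- function(exp, condition) {
  if (!condition %in% exp$conditions) {
    stop("condition '", condition, "' not present in experiment '",
         exp$id, "'")
  }
  mats <- lapply(exp$participants, function(p) p[[condition]]$data)
  ref <- exp$participants[[1L]][[condition]]
  erp_epoch("grand_average", condition, Reduce(`+`, mats) / length(mats),
            sampling_rate = ref$sampling_rate, epoch_start = ref$epoch_start)
}

#' Peak or trough amplitude of the cluster-averaged waveform
#'
#' The cluster average is taken first (plain arithmetic mean over
#' electrodes), then the maximum (`"peak"`) or minimum (`"trough"`) within
#' the window is returned — the standard ERP convention, and deterministic.
#'
#' @param erp An `erp_epoch`.
#' @param electrodes Electrode labels.
#' @param window `(start_ms, end_ms)`, half-open.
#' @param mode `"peak"` or `"trough"`.
#' @return Amplitude in microvolts.
#' @export
component_amplitude <- function(erp, electrodes, window,
                                mode = c("peak", "trough")) {
  mode <- match.arg(mode)
  bad <- setdiff(electrodes, rownames(erp$data))
  if (length(bad)) stop("unknown electrode(s): ", paste(bad, collapse = ", "))
  idx <- window_to_samples(window, erp$epoch_start, erp$sampling_rate,
                           ncol(erp$data))
  wave <- colMeans(erp$data[electrodes, idx, drop = FALSE])
  if (mode == "peak") max(wave) else min(wave)
}

#' Export per-experiment summaries as a data frame
#'
#' One row per experiment, computed with a shared cluster and window (or
#' each experiment's original choices when `cluster`/`window` are `NULL`).
#'
#' @param catalogue An `spn_catalogue`.
#' @param cluster Electrode labels, or `NULL` for per-experiment originals.
#' @param window `(start_ms, end_ms)`, or `NULL` for originals.
#' @return Data frame of `spn_summary` rows plus experiment metadata
#'   (`w_load`, `task_relevant`, `published`).
#' @export
catalogue_summaries <- function(catalogue, cluster = NULL, window = NULL) {
  rows <- lapply(catalogue$experiments, function(exp) {
    s <- spn_summary(exp,
                     cluster = cluster %||% exp$original_cluster,
                     window = window %||% exp$original_window)
    cbind(as.data.frame(s),
          data.frame(w_load = exp$w_load, task_relevant = exp$task_relevant,
                     published = exp$published, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
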