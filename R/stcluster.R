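#' Per-participant difference epochs (regular minus random)
#'
#' @param exp An `spn_experiment`.
#' @return List of `erp_epoch` objects, one per participant, holding the
#'   pointwise regular-minus-random difference wave.
#' @export
difference_epochs <- function(exp) {
  reg <- exp$contrast[["regular"]]
  ran <- exp$contrast[["random"]]
  lapply(exp$participants, function(p) {
    a <- p[[reg]]
    erp_epoch(a$participant_id, "difference", a$data - p[[ran]]$data,
              sampling_rate = a$sampling_rate, epoch_start = a$epoch_start)
  })
}

# Flattened grid index: point (electrode e, sample s) -> (s - 1) * E + e.
# Connected components of a supra-threshold point set under the relation
# (e1,s1) ~ (e2,s2)  iff  (e1 == e2 and |s1 - s2| == 1)
#                      or (s1 == s2 and e1 adjacent e2 in the montage).
# Returns an integer component label per point of `idx` (labels 1..k).
grid_components <- function(idx, n_electrodes, n_samples, adj_list) {
  k <- length(idx)
  labels <- integer(k)
  if (!k) return(labels)
  p <- n_electrodes * n_samples
  inmask <- logical(p)
  inmask[idx] <- TRUE
  comp <- integer(p)
  stack <- integer(k)
  cid <- 0L
  for (start in idx) {
    if (comp[start]) next
    cid <- cid + 1L
    comp[start] <- cid
    stack[1L] <- start
    top <- 1L
    while (top > 0L) {
      i <- stack[top]
      top <- top - 1L
      e <- (i - 1L) %% n_electrodes + 1L
      base <- i - e  # (s-1)*E
      nb <- base + adj_list[[e]]
      if (base >= n_electrodes) nb <- c(nb, i - n_electrodes)
      if (base < p - n_electrodes) nb <- c(nb, i + n_electrodes)
      for (j in nb) {
        if (inmask[j] && !comp[j]) {
          comp[j] <- cid
          top <- top + 1L
          stack[top] <- j
        }
      }
    }
  }
  comp[idx]
}

# Electrode adjacency as a list of integer neighbour indices, in montage
# order restricted to `labels`.
electrode_adj_list <- function(montage, labels) {
  A <- montage_adjacency(montage)[labels, labels, drop = FALSE]
  lapply(seq_along(labels), function(i) which(A[i, ]))
}

# Largest positive cluster mass and largest |negative| cluster mass of one
# t-map (0 when no supra-threshold cluster of that sign exists).
max_cluster_masses <- function(tv, thr, n_electrodes, n_samples, adj_list) {
  pos <- which(tv >= thr)
  neg <- which(tv <= -thr)
  mp <- 0
  mn <- 0
  if (length(pos)) {
    lab <- grid_components(pos, n_electrodes, n_samples, adj_list)
    mp <- max(vapply(split(tv[pos], lab), sum, numeric(1)))
  }
  if (length(neg)) {
    lab <- grid_components(neg, n_electrodes, n_samples, adj_list)
    mn <- max(abs(vapply(split(tv[neg], lab), sum, numeric(1))))
  }
  c(mp, mn)
}

#' Spatio-temporal cluster-based permutation test
#'
#' Identifies electrode-by-time clusters where the paired difference departs
#' from zero, without pre-selecting electrodes or windows. A one-sample t
#' statistic is computed across participants at every (electrode, sample)
#' point; points exceeding the two-tailed critical t at `cluster_alpha`
#' (df = n - 1) are grouped into connected components (temporal adjacency:
#' consecutive samples at the same electrode; spatial adjacency: montage
#' neighbours at the same sample). Each cluster's mass is the sum of its t
#' values. The null distribution of the maximum cluster mass — separately
#' for positive and negative clusters — is built by randomly flipping the
#' sign of each participant's difference wave; the permutation p-value is
#' `(count of null masses >= observed + 1) / (n_permutations + 1)`.
#'
#' @param diff_epochs List of per-participant difference `erp_epoch`s (all
#'   aligned: same electrodes, sampling rate and epoch start), e.g. from
#'   [difference_epochs()].
#' @param montage An `spn_montage` supplying electrode adjacency.
#' @param cluster_alpha Cluster-forming threshold level (default 0.05).
#' @param n_permutations Number of sign-flip permutations (default 1000).
#' @param seed Integer seed; identical seeds give identical results.
#' @return An object of class `cluster_test_result`: `clusters` (list of
#'   `spatio_temporal_cluster`, sorted by decreasing `|mass|`), the forming
#'   threshold, permutation count, seed, and null max-mass quantiles.
#' @export
cluster_permutation_test <- function(diff_epochs, montage,
                                     cluster_alpha = 0.05,
                                     n_permutations = 1000, seed = 1L) {
  n <- length(diff_epochs)
  if (n < 2L) stop("need at least 2 participants")
  ref <- diff_epochs[[1L]]
  labels <- rownames(ref$data)
  for (d in diff_epochs) {
    if (!identical(rownames(d$data), labels) ||
        ncol(d$data) != ncol(ref$data) ||
        d$sampling_rate != ref$sampling_rate ||
        d$epoch_start != ref$epoch_start) {
      stop("difference epochs are not aligned")
    }
  }
  bad <- setdiff(labels, montage$labels)
  if (length(bad)) stop("epoch electrode(s) not in montage: ",
                        paste(bad, collapse = ", "))
  E <- length(labels)
  S <- ncol(ref$data)
  p <- E * S
  adj_list <- electrode_adj_list(montage, labels)
  # participants x points; column j holds grid point ((j-1) %% E + 1,
  # (j-1) %/% E + 1)
  X <- t(vapply(diff_epochs, function(d) as.vector(d$data), numeric(p)))
  thr <- stats::qt(1 - cluster_alpha / 2, df = n - 1)
  css <- colSums(X^2)
  tstat <- function(m) {
    v <- pmax((css - n * m^2) / (n - 1), 0)
    tv <- m / sqrt(v / n)
    tv[is.nan(tv)] <- 0  # 0/0: constant-zero column
    tv
  }
  t_obs <- tstat(colMeans(X))

  # observed clusters, both signs
  clusters <- list()
  for (sgn in c(1, -1)) {
    idx <- if (sgn > 0) which(t_obs >= thr) else which(t_obs <= -thr)
    if (!length(idx)) next
    lab <- grid_components(idx, E, S, adj_list)
    for (g in split(idx, lab)) {
      clusters[[length(clusters) + 1L]] <- list(
        members = data.frame(
          electrode = labels[(g - 1L) %% E + 1L],
          sample = as.integer((g - 1L) %/% E + 1L),
          stringsAsFactors = FALSE),
        mass = sum(t_obs[g]),
        sign = if (sgn > 0) "positive" else "negative")
    }
  }

  # permutation null: max positive mass and max |negative| mass
  null_pos <- numeric(n_permutations)
  null_neg <- numeric(n_permutations)
  if (n_permutations >= 1L) {
    with_seed(seed, {
      chunk <- 200L
      done <- 0L
      while (done < n_permutations) {
        b <- min(chunk, n_permutations - done)
        Sg <- matrix(sample(c(-1, 1), b * n, replace = TRUE), b, n)
        M <- (Sg %*% X) / n
        for (r in seq_len(b)) {
          mm <- max_cluster_masses(tstat(M[r, ]), thr, E, S, adj_list)
          null_pos[done + r] <- mm[1L]
          null_neg[done + r] <- mm[2L]
        }
        done <- done + b
      }
    })
  }
  for (i in seq_along(clusters)) {
    cl <- clusters[[i]]
    null <- if (cl$sign == "positive") null_pos else null_neg
    cl$p <- (sum(null >= abs(cl$mass)) + 1) / (n_permutations + 1)
    class(cl) <- "spatio_temporal_cluster"
    clusters[[i]] <- cl
  }
  ord <- order(-vapply(clusters, function(cl) abs(cl$mass), numeric(1)))
  structure(
    list(clusters = clusters[ord],
         cluster_alpha = cluster_alpha,
         forming_threshold = thr,
         n_permutations = n_permutations,
         seed = seed,
         n_participants = n,
         electrodes = labels,
         n_samples = S,
         sampling_rate = ref$sampling_rate,
         epoch_start = ref$epoch_start,
         null_distribution_summary = list(
           positive = stats::quantile(null_pos, c(0.5, 0.9, 0.95, 0.99)),
           negative = stats::quantile(null_neg, c(0.5, 0.9, 0.95, 0.99)))),
    class = "cluster_test_result")
}

#' @export
print.cluster_test_result <- function(x, ...) {
  cat("<cluster_test_result> ", length(x$clusters), " clusters, n=",
      x$n_participants, ", ", x$n_permutations, " permutations\n", sep = "")
  for (cl in x$clusters[seq_len(min(5L, length(x$clusters)))]) {
    cat(sprintf("  %s  mass=%.1f  points=%d  p=%.4g\n", cl$sign, cl$mass,
                nrow(cl$members), cl$p))
  }
  invisible(x)
}

#' Extract the most significant negative cluster
#'
#' Among negative clusters with permutation p below `alpha`, the one with
#' the largest absolute mass; ties are broken by earliest onset sample,
#' then by lexicographically smallest electrode label. `NULL` when no
#' negative cluster is significant.
#'
#' @param result A `cluster_test_result`.
#' @param alpha Significance level (default 0.05).
#' @return A `spatio_temporal_cluster`, or `NULL`.
#' @export
most_significant_negative_cluster <- function(result, alpha = 0.05) {
  neg <- Filter(function(cl) cl$sign == "negative" && cl$p < alpha,
                result$clusters)
  if (!length(neg)) return(NULL)
  key <- vapply(neg, function(cl) abs(cl$mass), numeric(1))
  onset <- vapply(neg, function(cl) min(cl$members$sample), numeric(1))
  first_lab <- vapply(neg, function(cl) min(cl$members$electrode),
                      character(1))
  ord <- order(-key, onset, first_lab)
  neg[[ord[1L]]]
}

#' Electrode occurrence proportions across extracted clusters
#'
#' For a list of most-significant clusters (one per experiment, `NULL` where
#' no significant cluster was found), the proportion of non-`NULL` clusters
#' containing each electrode.
#'
#' @param clusters List of `spatio_temporal_cluster` or `NULL` entries.
#' @param labels Electrode labels to report (default: all electrodes seen).
#' @return Named numeric vector of proportions in `[0, 1]`.
#' @export
electrode_occurrence <- function(clusters, labels = NULL) {
  present <- Filter(Negate(is.null), clusters)
  if (!length(present)) stop("no clusters to summarize")
  seen <- lapply(present, function(cl) unique(cl$members$electrode))
  labels <- labels %||% sort(unique(unlist(seen)))
  counts <- vapply(labels, function(l) {
    sum(vapply(seen, function(s) l %in% s, logical(1)))
  }, numeric(1))
  counts / length(present)
}

#' Recompute an SPN with a data-driven cluster and window
#'
#' Uses the electrodes of a spatio-temporal cluster and its sample span
#' (converted to a half-open ms window) as the extraction parameters for
#' [spn_summary()].
#'
#' @param exp An `spn_experiment`.
#' @param cluster A non-empty `spatio_temporal_cluster`.
#' @return An `spn_summary`.
#' @export
cluster_window_spn <- function(exp, cluster) {
  if (is.null(cluster) || !nrow(cluster$members)) stop("empty cluster")
  ref <- exp$participants[[1L]][[1L]]
  electrodes <- intersect(rownames(ref$data),
                          unique(cluster$members$electrode))
  smin <- min(cluster$members$sample)
  smax <- max(cluster$members$sample)
  dt <- 1000 / ref$sampling_rate
  window <- c(ref$epoch_start + (smin - 1) * dt,
              ref$epoch_start + smax * dt)
  spn_summary(exp, cluster = electrodes, window = window)
}
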