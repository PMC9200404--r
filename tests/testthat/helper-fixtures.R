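# Shared fixtures, built in code.

posterior16 <- c("P1", "P3", "P5", "P7", "P9", "PO7", "PO3", "O1",
                 "P2", "P4", "P6", "P8", "P10", "PO8", "PO4", "O2")
cluster4 <- c("PO7", "O1", "O2", "PO8")

# Six electrodes spaced 30 degrees apart along the equator: a path graph
# under the default 0.55 rad adjacency threshold.
tiny_montage <- function(n = 6) {
  th <- (seq_len(n) - 1) * pi / 6
  build_montage(positions = data.frame(
    label = paste0("E", seq_len(n)),
    x = cos(th), y = sin(th), z = 0))
}

# Epoch with every (electrode, sample) set to `value` (or a full matrix).
flat_epoch <- function(value, labels, n_samples = 64, pid = "p1",
                       condition = "regular", sampling_rate = 128,
                       epoch_start = -200) {
  data <- if (is.matrix(value)) value else
    matrix(value, length(labels), n_samples, dimnames = list(labels, NULL))
  erp_epoch(pid, condition, data, sampling_rate, epoch_start)
}

# Experiment whose per-participant SPN difference is exactly diffs[i]:
# regular epochs hold the constant diffs[i], random epochs are zero.
diff_experiment <- function(diffs, labels, id = "exp1", ...) {
  participants <- stats::setNames(lapply(seq_along(diffs), function(i) {
    pid <- paste0("p", i)
    list(regular = flat_epoch(diffs[i], labels, pid = pid),
         random = flat_epoch(0, labels, pid = pid, condition = "random"))
  }), paste0("p", seq_along(diffs)))
  spn_experiment(id = id, participants = participants,
                 contrast = c("regular", "random"),
                 original_cluster = labels[1:2],
                 original_window = c(0, 300), ...)
}

# Small, fast synthetic config for integration-style tests.
small_synth <- function(n_experiments = 6, n_range = c(6, 10), seed = 42,
                        ...) {
  synth_config(n_experiments = n_experiments, n_range = n_range, seed = seed,
               ...)
}

# Cached bundled montage (building it is cheap but used everywhere).
bundled_montage <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- build_montage()
    m
  }
})

# Independent connected-components oracle over cluster members (breadth-
# first search on the declared adjacency relation).
members_connected <- function(members, montage) {
  k <- nrow(members)
  if (k <= 1) return(TRUE)
  adj <- montage_adjacency(montage)
  seen <- logical(k)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    i <- queue[1L]
    queue <- queue[-1L]
    for (j in which(!seen)) {
      same_e <- members$electrode[i] == members$electrode[j] &&
        abs(members$sample[i] - members$sample[j]) == 1L
      same_s <- members$sample[i] == members$sample[j] &&
        adj[members$electrode[i], members$electrode[j]]
      if (same_e || same_s) {
        seen[j] <- TRUE
        queue <- c(queue, j)
      }
    }
  }
  all(seen)
}
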