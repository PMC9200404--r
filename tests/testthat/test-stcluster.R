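# Difference epochs restricted to the 16-electrode posterior subset keep
# the permutation tests fast while exercising real montage adjacency.
posterior_diffs <- function(exp) {
  lapply(difference_epochs(exp), function(d) {
    erp_epoch(d$participant_id, "difference", d$data[posterior16, ],
              sampling_rate = d$sampling_rate, epoch_start = d$epoch_start)
  })
}

# Generator confined to the a priori cluster: unit weights at PO7/O1/O2/PO8,
# zero elsewhere, sharp-edged plateau over the canonical window.
confined_config <- function(...) {
  m <- bundled_montage()
  topo <- stats::setNames(as.numeric(m$labels %in% cluster4), m$labels)
  synth_config(topography = topo,
               waveform = list(spn_onset = 300, spn_offset = 1000,
                               spn_ramp = 0),
               ...)
}

test_that("a strong planted signal is recovered with minimal p-value", {
  m <- bundled_montage()
  cfg <- confined_config(noise_sd = 0.2, n_trials = 1, between_sd = 0.1,
                         seed = 1)
  ex <- generate_experiment(list(n = 24, w_load = 0, task_relevant = 0,
                                 true_amp = -3), cfg, m, seed = 101)
  res <- cluster_permutation_test(posterior_diffs(ex), m,
                                  n_permutations = 200, seed = 5)
  best <- most_significant_negative_cluster(res)
  expect_false(is.null(best))
  expect_equal(best$p, 1 / 201)

  # injected points: the 4 cluster electrodes over samples 65..154
  planted <- paste(rep(cluster4, each = 90), rep(65:154, times = 4))
  got <- paste(best$members$electrode, best$members$sample)
  expect_gte(mean(planted %in% got), 0.8)

  # all member t-values share the cluster's sign
  tv_sign <- best$mass < 0
  expect_true(tv_sign)
  expect_true(all(best$members$sample >= 1))

  # Data-driven re-extraction: at the default forming threshold the cluster
  # accretes zero-signal neighbours (each electrode bordering the detected
  # component gets ~90 chances to join at the pointwise rate), so the
  # rectangle mean understates the planted amplitude. A strict forming
  # threshold suppresses accretion and the planted amplitude is recovered.
  strict <- cluster_permutation_test(posterior_diffs(ex), m,
                                     cluster_alpha = 0.001,
                                     n_permutations = 200, seed = 5)
  s <- cluster_window_spn(ex, most_significant_negative_cluster(strict))
  expect_lt(abs(s$mean - (-3)) / 3, 0.1)
})

test_that("results are deterministic given the seed", {
  m <- bundled_montage()
  cfg <- confined_config(noise_sd = 1, n_trials = 10, between_sd = 0.5,
                         seed = 2)
  ex <- generate_experiment(list(n = 8, w_load = 0, task_relevant = 0,
                                 true_amp = -1.5), cfg, m, seed = 55)
  r1 <- cluster_permutation_test(posterior_diffs(ex), m,
                                 n_permutations = 100, seed = 9)
  r2 <- cluster_permutation_test(posterior_diffs(ex), m,
                                 n_permutations = 100, seed = 9)
  expect_identical(lapply(r1$clusters, function(cl) cl$mass),
                   lapply(r2$clusters, function(cl) cl$mass))
  expect_identical(lapply(r1$clusters, function(cl) cl$p),
                   lapply(r2$clusters, function(cl) cl$p))
})

test_that("every reported cluster is connected under the declared relation", {
  m <- bundled_montage()
  cfg <- confined_config(noise_sd = 3, n_trials = 1, between_sd = 0.3,
                         seed = 3)
  ex <- generate_experiment(list(n = 10, w_load = 0, task_relevant = 0,
                                 true_amp = -1), cfg, m, seed = 77)
  res <- cluster_permutation_test(posterior_diffs(ex), m,
                                  n_permutations = 20, seed = 3)
  expect_gt(length(res$clusters), 0)
  for (cl in res$clusters) {
    expect_true(members_connected(cl$members, m))
    expect_gte(cl$p, 1 / 21)
  }
})

test_that("input validation rejects degenerate or misaligned inputs", {
  m <- bundled_montage()
  cfg <- confined_config(seed = 4)
  ex <- generate_experiment(list(n = 2, w_load = 0, task_relevant = 0,
                                 true_amp = -1), cfg, m, seed = 1)
  d <- posterior_diffs(ex)
  expect_error(cluster_permutation_test(d[1], m), "2 participants")
  d2 <- d
  d2[[2]] <- erp_epoch("p2", "difference", d2[[2]]$data, sampling_rate = 64)
  expect_error(cluster_permutation_test(d2, m), "aligned")
})

test_that("equal-mass negative clusters break ties by earliest onset", {
  m <- tiny_montage()
  n <- 12
  S <- 60
  f <- matrix(0, 6, S, dimnames = list(m$labels, NULL))
  f["E1", 10:19] <- -1
  f["E1", 30:39] <- -1  # identical later twin
  b <- 1 + 0.1 * seq_len(n)
  diffs <- lapply(seq_len(n), function(i) {
    erp_epoch(paste0("p", i), "difference", b[i] * f)
  })
  res <- cluster_permutation_test(diffs, m, n_permutations = 400, seed = 2)
  neg <- Filter(function(cl) cl$sign == "negative", res$clusters)
  expect_length(neg, 2)
  expect_equal(neg[[1]]$mass, neg[[2]]$mass, tolerance = 1e-9)
  best <- most_significant_negative_cluster(res)
  expect_false(is.null(best))
  expect_equal(min(best$members$sample), 10)
})

test_that("no significant negative cluster yields NULL", {
  m <- tiny_montage()
  set.seed(6)
  diffs <- lapply(1:8, function(i) {
    erp_epoch(paste0("p", i),
              "difference", matrix(rnorm(6 * 40), 6, 40,
                                   dimnames = list(m$labels, NULL)))
  })
  res <- cluster_permutation_test(diffs, m, n_permutations = 150, seed = 8)
  best <- most_significant_negative_cluster(res, alpha = 1 / 152)
  expect_null(best)
})

test_that("electrode occurrence counts non-null clusters only", {
  mk <- function(electrodes) {
    list(members = data.frame(electrode = electrodes,
                              sample = seq_along(electrodes)),
         mass = -1, sign = "negative", p = 0.01)
  }
  clusters <- c(lapply(1:3, function(i) mk(c("O1", "PO8"))),
                lapply(1:7, function(i) mk("PO8")),
                list(NULL, NULL))
  occ <- electrode_occurrence(clusters)
  expect_equal(unname(occ["PO8"]), 1.0)
  expect_equal(unname(occ["O1"]), 0.3)
  expect_error(electrode_occurrence(list(NULL, NULL)), "no clusters")
})

test_that("cluster_window_spn equals spn_summary on the matching rectangle", {
  m <- bundled_montage()
  cfg <- confined_config(noise_sd = 1, n_trials = 20, between_sd = 0.8,
                         seed = 5)
  ex <- generate_experiment(list(n = 6, w_load = 0.5, task_relevant = 0),
                            cfg, m, seed = 21)
  rect <- list(members = data.frame(
    electrode = rep(cluster4, each = 90),
    sample = rep(65:154, times = 4)))
  s1 <- cluster_window_spn(ex, rect)
  s2 <- spn_summary(ex, cluster4, c(300, 1000))
  expect_equal(s1$diffs, s2$diffs, tolerance = 1e-12)
  expect_equal(s1$mean, s2$mean, tolerance = 1e-12)
  expect_error(cluster_window_spn(ex, list(members = data.frame())),
               "empty")
})

test_that("growing the planted amplitude never shrinks the top cluster mass", {
  m <- bundled_montage()
  masses <- vapply(c(-0.8, -1.6, -3.2), function(amp) {
    cfg <- confined_config(noise_sd = 0.5, n_trials = 1, between_sd = 0.2,
                           seed = 6)
    ex <- generate_experiment(list(n = 12, w_load = 0, task_relevant = 0,
                                   true_amp = amp), cfg, m, seed = 42)
    res <- cluster_permutation_test(posterior_diffs(ex), m,
                                    n_permutations = 30, seed = 7)
    neg <- Filter(function(cl) cl$sign == "negative", res$clusters)
    max(vapply(neg, function(cl) abs(cl$mass), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(masses) >= 0))
})

test_that("data-driven and a priori amplitudes correlate strongly", {
  m <- bundled_montage()
  cfg <- synth_config(n_experiments = 10, n_range = c(8, 12),
                      noise_sd = 1, n_trials = 30, between_sd = 1,
                      experiment_sd = 0.9, seed = 13)
  cat1 <- generate_catalogue(cfg)
  apriori <- numeric(0)
  datadriven <- numeric(0)
  for (i in seq_along(cat1$experiments)) {
    exp <- cat1$experiments[[i]]
    res <- cluster_permutation_test(posterior_diffs(exp), m,
                                    n_permutations = 100, seed = 1000 + i)
    best <- most_significant_negative_cluster(res)
    if (is.null(best)) next
    apriori <- c(apriori, spn_summary(exp, cluster4, c(300, 1000))$mean)
    datadriven <- c(datadriven, cluster_window_spn(exp, best)$mean)
  }
  expect_gte(length(apriori), 5)
  expect_gte(cor(apriori, datadriven), 0.7)
})
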