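test_that("window_mean matches brute-force summation", {
  m <- tiny_montage()
  # constant field
  e <- flat_epoch(-2, m$labels, n_samples = 282)
  expect_identical(window_mean(e, c("E1", "E3"), c(300, 1000)), -2)

  # linear ramp: value at sample s is s, for every electrode
  ramp <- matrix(rep(1:282, each = 6), 6, 282,
                 dimnames = list(m$labels, NULL))
  er <- flat_epoch(ramp, m$labels, n_samples = 282)
  # brute force from first principles: half-open window on the time axis
  tms <- epoch_times(er)
  keep <- which(tms >= 300 & tms < 1000)
  expect_identical(keep, 65:154)  # 0-based 64..153
  expect_equal(window_mean(er, m$labels, c(300, 1000)), mean(keep))

  expect_error(window_mean(er, m$labels, c(-300, 0)), "outside")
  expect_error(window_mean(er, c("E1", "NOPE"), c(0, 100)), "unknown")
  expect_error(window_mean(er, character(0), c(0, 100)), "empty")
})

test_that("spn_summary reproduces hand-computed statistics", {
  m <- tiny_montage()
  ex <- diff_experiment(c(-2, -1, 0, -3), m$labels)
  s <- spn_summary(ex, cluster = c("E1", "E2"), window = c(0, 300))
  # hand computation: sd = sqrt(5/3); p frozen from the t CDF with df 3
  expect_equal(s$mean, -1.5)
  expect_equal(s$sd, sqrt(5 / 3), tolerance = 1e-12)
  expect_equal(s$se, sqrt(5 / 3) / 2, tolerance = 1e-12)
  expect_equal(s$d_z, -1.5 / sqrt(5 / 3), tolerance = 1e-12)
  expect_equal(s$t, -2.323790008, tolerance = 1e-8)
  expect_identical(s$df, 3L)
  expect_equal(s$p_two_tailed, 0.102728079, tolerance = 1e-8)
  expect_equal(s$prop_directional, 0.75)

  # invariant identities
  expect_equal(s$se, s$sd / sqrt(s$n), tolerance = 1e-12)
  expect_equal(s$d_z, s$mean / s$sd, tolerance = 1e-12)
  expect_equal(s$t, s$mean / s$se, tolerance = 1e-9)
})

test_that("directional proportion follows the regular < random convention", {
  m <- tiny_montage()
  expect_equal(spn_summary(diff_experiment(c(1, 2, 3), m$labels),
                           c("E1", "E2"), c(0, 300))$prop_directional, 0)
  # ties (exact zeros) count as non-directional
  expect_equal(spn_summary(diff_experiment(c(0, -1, -2), m$labels),
                           c("E1", "E2"), c(0, 300))$prop_directional, 2 / 3)
  expect_error(spn_summary(diff_experiment(c(1, 1, 1), m$labels),
                           c("E1", "E2"), c(0, 300)), "degenerate")
})

test_that("grand_average equals the elementwise mean across participants", {
  m <- tiny_montage()
  set.seed(5)
  mats <- lapply(1:3, function(i) matrix(rnorm(6 * 64), 6, 64,
                                         dimnames = list(m$labels, NULL)))
  eps <- stats::setNames(lapply(1:3, function(i) {
    list(regular = flat_epoch(mats[[i]], m$labels, pid = paste0("p", i)),
         random = flat_epoch(0, m$labels, pid = paste0("p", i),
                             condition = "random"))
  }), paste0("p", 1:3))
  ex <- spn_experiment("g", participants = eps,
                       contrast = c("regular", "random"),
                       original_cluster = "E1", original_window = c(0, 100))
  ga <- grand_average(ex, "regular")
  expect_equal(ga$data, (mats[[1]] + mats[[2]] + mats[[3]]) / 3)
  expect_error(grand_average(ex, "absent"), "absent")

  # two participants with +1 / -1 cancel
  ex2 <- diff_experiment(c(1, -1), m$labels)
  expect_equal(max(abs(grand_average(ex2, "regular")$data)), 0)
})

test_that("component_amplitude finds peaks and troughs of the cluster average", {
  m <- tiny_montage()
  tms <- -200 + (0:281) * 1000 / 128
  bump <- function(h, mu, w) h * exp(-0.5 * ((tms - mu) / w)^2)
  wave <- bump(3, 400, 30) + bump(4, 700, 30)
  data <- matrix(rep(wave, each = 6), 6, 282, dimnames = list(m$labels, NULL))
  e <- flat_epoch(data, m$labels, n_samples = 282)
  # brute-force maximum over the windowed samples
  keep <- tms >= 200 & tms < 1000
  expect_equal(component_amplitude(e, m$labels, c(200, 1000), "peak"),
               max(wave[keep]))
  expect_equal(component_amplitude(e, m$labels, c(200, 1000), "peak"), 4,
               tolerance = 1e-2)
  en <- flat_epoch(-data, m$labels, n_samples = 282)
  expect_equal(component_amplitude(en, m$labels, c(200, 1000), "trough"),
               min(-wave[keep]))
})

test_that("cluster mean is linear: equals the mean of per-electrode means", {
  m <- tiny_montage()
  set.seed(11)
  for (rep in 1:3) {
    data <- matrix(rnorm(6 * 64), 6, 64, dimnames = list(m$labels, NULL))
    e <- flat_epoch(data, m$labels)
    cl <- sample(m$labels, 3)
    per_elec <- vapply(cl, function(l) window_mean(e, l, c(0, 300)),
                       numeric(1))
    expect_equal(window_mean(e, cl, c(0, 300)), mean(per_elec),
                 tolerance = 1e-12)
  }
})

test_that("negating the regular condition flips mean and d_z exactly", {
  m <- tiny_montage()
  ex <- diff_experiment(c(-2, -1, -3, -0.5), m$labels)
  s <- spn_summary(ex, c("E1", "E2"), c(0, 300))
  exn <- diff_experiment(c(2, 1, 3, 0.5), m$labels)
  sn <- spn_summary(exn, c("E1", "E2"), c(0, 300))
  expect_equal(sn$mean, -s$mean)
  expect_equal(sn$d_z, -s$d_z)
  expect_equal(sn$p_two_tailed, s$p_two_tailed)
  expect_equal(sn$prop_directional + mean(s$diffs < 0), 1)
})
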