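#' Configuration for the synthetic SPN catalogue generator
#'
#' The generator emulates stage-v data: condition averages (regular vs
#' random) per participant, on a 64-channel posterior-weighted montage, with
#' P1/N1 transients, a sustained regular-minus-random negativity over a
#' raised-cosine-edged plateau, between-participant amplitude variability,
#' and trial-average measurement noise. Expected grand-average SPN amplitude
#' follows the two-predictor regression
#' `amplitude = intercept + coef_w * W + coef_task * Task` (microvolts, both
#' predictors on a 0-1 scale), with defaults `(0.071, -1.669, -0.416)`.
#'
#' @param n_experiments Number of experiments to generate (default 40).
#' @param n_range Integer range of per-experiment sample sizes, drawn
#'   uniformly (default `c(12, 48)`).
#' @param amplitude_model Named numeric `c(intercept, coef_w, coef_task)`,
#'   microvolts.
#' @param experiment_sd SD (microvolts) of the between-experiment residual
#'   around the regression prediction. The default 0.75 leaves the two
#'   predictors explaining roughly a third of grand-average amplitude
#'   variance. Set 0 for noise-free parameter-recovery experiments.
#' @param between_sd Between-participant SD of true amplitude, microvolts.
#' @param noise_sd Single-trial noise SD, microvolts; condition averages get
#'   independent Gaussian noise with SD `noise_sd / sqrt(n_trials)` per
#'   sample and electrode.
#' @param n_trials Effective trials per condition (default 60).
#' @param heteroscedasticity Slope linking `between_sd` to `|true amplitude|`:
#'   the participant-level SD is `between_sd * (1 + h * |amp|)`. Default 0;
#'   positive values recreate the curvature of the amplitude-to-effect-size
#'   relationship.
#' @param waveform List of waveform parameters: `p1_latency`, `p1_width`,
#'   `p1_amplitude`, `n1_latency`, `n1_width`, `n1_amplitude` (Gaussian
#'   bumps, ms / microvolts), `spn_onset`, `spn_offset`, `spn_ramp`
#'   (plateau support and raised-cosine edge length, ms).
#' @param topography Named per-electrode weights in `[0, 1]`, or `NULL` for
#'   the default posterior-focused map (maximum 1 at PO7/O1/O2/PO8, falling
#'   off with angular distance).
#' @param published_rule Function mapping true grand-average amplitude
#'   (microvolts) to the probability of the experiment being flagged
#'   published. The default favours stronger (more negative) SPNs.
#' @param sampling_rate,epoch_start,epoch_end Epoch geometry (Hz, ms, ms).
#' @param calibration_cluster,calibration_window Cluster and half-open
#'   window over which an injected amplitude is calibrated: with zero noise
#'   the windowed cluster mean of the difference wave equals the requested
#'   amplitude exactly.
#' @param seed Integer root seed; per-experiment child seeds are derived
#'   deterministically so experiment subsets are stable.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_experiments = 40,
                         n_range = c(12, 48),
                         amplitude_model = c(intercept = 0.071,
                                             coef_w = -1.669,
                                             coef_task = -0.416),
                         experiment_sd = 0.75,
                         between_sd = 1.6,
                         noise_sd = 1.0,
                         n_trials = 60,
                         heteroscedasticity = 0,
                         waveform = list(),
                         topography = NULL,
                         published_rule = NULL,
                         sampling_rate = 128,
                         epoch_start = -200,
                         epoch_end = 2000,
                         calibration_cluster = c("PO7", "O1", "O2", "PO8"),
                         calibration_window = c(300, 1000),
                         seed = 1L) {
  wf <- list(p1_latency = 110, p1_width = 25, p1_amplitude = 5,
             n1_latency = 170, n1_width = 25, n1_amplitude = -8,
             spn_onset = 250, spn_offset = 1000, spn_ramp = 50)
  wf[names(waveform)] <- waveform
  if (is.null(published_rule)) {
    published_rule <- function(true_amp) stats::plogis(-2 * (true_amp + 1))
  }
  cfg <- structure(
    list(n_experiments = as.integer(n_experiments),
         n_range = as.integer(n_range),
         amplitude_model = amplitude_model,
         experiment_sd = experiment_sd, between_sd = between_sd,
         noise_sd = noise_sd, n_trials = n_trials,
         heteroscedasticity = heteroscedasticity,
         waveform = wf, topography = topography,
         published_rule = published_rule,
         sampling_rate = sampling_rate, epoch_start = epoch_start,
         epoch_end = epoch_end,
         calibration_cluster = calibration_cluster,
         calibration_window = calibration_window,
         seed = as.integer(seed)),
    class = "synth_config")
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$n_range[1L] < 2L || cfg$n_range[2L] > 10000L ||
      cfg$n_range[1L] > cfg$n_range[2L]) {
    stop("n_range must be an increasing range within [2, 10000]")
  }
  if (cfg$between_sd < 0 || cfg$noise_sd < 0 || cfg$experiment_sd < 0) {
    stop("standard deviations must be non-negative")
  }
  if (cfg$waveform$spn_onset >= cfg$waveform$spn_offset) {
    stop("spn_onset must precede spn_offset")
  }
  if (!is.null(cfg$topography) &&
      (any(cfg$topography < 0) || any(cfg$topography > 1))) {
    stop("topography weights must lie in [0, 1]")
  }
  if (is.na(cfg$seed)) stop("a seed is required")
  invisible(cfg)
}

#' Default posterior topography weights for a montage
#'
#' Weight 1 at PO7/O1/O2/PO8, decaying as a Gaussian of great-circle
#' distance to the nearest of those four electrodes (scale 0.5 rad).
#'
#' @param montage An `spn_montage`.
#' @return Named numeric vector of weights in `[0, 1]`.
#' @export
default_topography <- function(montage) {
  foci <- intersect(c("PO7", "O1", "O2", "PO8"), montage$labels)
  if (!length(foci)) stop("montage has none of PO7/O1/O2/PO8")
  P <- montage$positions
  d <- sapply(foci, function(f) {
    acos(pmin(1, pmax(-1, P %*% P[f, ])))
  })
  dmin <- apply(d, 1L, min)
  w <- exp(-dmin^2 / (2 * 0.5^2))
  stats::setNames(as.numeric(w), montage$labels)
}

# Evaluate run state once per experiment: common waveform (shared by both
# conditions) and a unit SPN template whose calibration-cluster window mean
# is exactly 1, so injected amplitudes are exact by construction.
synth_templates <- function(config, montage) {
  n_samples <- round((config$epoch_end - config$epoch_start) *
                       config$sampling_rate / 1000)
  tms <- config$epoch_start + (seq_len(n_samples) - 1) *
    1000 / config$sampling_rate
  wf <- config$waveform
  if (wf$spn_onset < config$epoch_start || wf$spn_offset > config$epoch_end) {
    stop("SPN plateau lies outside the epoch")
  }
  topo <- config$topography %||% default_topography(montage)
  if (!identical(sort(names(topo)), sort(montage$labels))) {
    stop("topography must name every montage electrode")
  }
  topo <- topo[montage$labels]
  common_t <- wf$p1_amplitude * exp(-0.5 * ((tms - wf$p1_latency) / wf$p1_width)^2) +
    wf$n1_amplitude * exp(-0.5 * ((tms - wf$n1_latency) / wf$n1_width)^2)
  plateau <- raised_cosine_plateau(tms, wf$spn_onset, wf$spn_offset,
                                   wf$spn_ramp)
  common <- outer(topo, common_t)
  spn <- outer(topo, plateau)
  rownames(common) <- rownames(spn) <- montage$labels
  idx <- window_to_samples(config$calibration_window, config$epoch_start,
                           config$sampling_rate, n_samples)
  cal <- mean(spn[config$calibration_cluster, idx, drop = FALSE])
  if (cal == 0) stop("SPN plateau does not overlap the calibration window")
  list(common = common, spn_unit = spn / cal, n_samples = n_samples,
       times = tms)
}

# Plateau of height 1 over [onset, offset] with raised-cosine edges of
# length `ramp` inside the support.
raised_cosine_plateau <- function(t, onset, offset, ramp) {
  ramp <- min(ramp, (offset - onset) / 2)
  y <- numeric(length(t))
  full <- t >= onset + ramp & t <= offset - ramp
  y[full] <- 1
  if (ramp > 0) {
    up <- t >= onset & t < onset + ramp
    y[up] <- 0.5 * (1 - cos(pi * (t[up] - onset) / ramp))
    dn <- t > offset - ramp & t <= offset
    y[dn] <- 0.5 * (1 - cos(pi * (offset - t[dn]) / ramp))
  }
  y
}

#' Synthesize one participant's regular/random condition pair
#'
#' With `noise_sd = 0` the windowed calibration-cluster mean of the
#' difference wave (regular minus random) equals `true_spn` exactly. Both
#' epochs carry the configured P1/N1 transients and are baseline-corrected
#' over `[epoch_start, 0)`.
#'
#' @param true_spn Target difference amplitude, microvolts (negative for a
#'   typical SPN).
#' @param config A `synth_config`.
#' @param montage An `spn_montage`.
#' @param participant_id Participant id for the returned epochs.
#' @param templates Precomputed result of the internal template builder;
#'   callers generating many participants pass it to avoid recomputation.
#' @return List with `erp_epoch` elements `regular` and `random`.
#' @export
synthesize_pair <- function(true_spn, config, montage,
                            participant_id = "p1", templates = NULL) {
  if (!is.finite(true_spn)) stop("true_spn must be finite")
  tpl <- templates %||% synth_templates(config, montage)
  sd_avg <- config$noise_sd / sqrt(config$n_trials)
  dims <- dim(tpl$common)
  noise <- function() {
    if (sd_avg == 0) 0 else matrix(stats::rnorm(prod(dims), 0, sd_avg),
                                   dims[1L], dims[2L])
  }
  reg <- tpl$common + true_spn * tpl$spn_unit + noise()
  ran <- tpl$common + noise()
  if (config$epoch_start < 0) {
    base <- window_to_samples(c(config$epoch_start, 0), config$epoch_start,
                              config$sampling_rate, tpl$n_samples)
    reg <- reg - rowMeans(reg[, base, drop = FALSE])
    ran <- ran - rowMeans(ran[, base, drop = FALSE])
  }
  rownames(reg) <- rownames(ran) <- montage$labels
  list(regular = erp_epoch(participant_id, "regular", reg,
                           config$sampling_rate, config$epoch_start),
       random = erp_epoch(participant_id, "random", ran,
                          config$sampling_rate, config$epoch_start))
}

#' Generate one synthetic experiment
#'
#' Per-participant true amplitudes are drawn
#' `Normal(true_amp, between_sd * (1 + heteroscedasticity * |true_amp|))`;
#' each participant then gets a regular/random epoch pair. The generating
#' truth is attached as attribute `"truth"` so simulations can recover it.
#'
#' @param truth List with `n`, `w_load`, `task_relevant`, and optionally
#'   `true_amp` (microvolts); when `true_amp` is absent it is derived from
#'   the configured amplitude regression. Optional `id`, `published`.
#' @param config A `synth_config`.
#' @param montage An `spn_montage`; built from the bundled 64-channel layout
#'   when omitted.
#' @param seed Integer seed for this experiment.
#' @return An `spn_experiment`.
#' @export
generate_experiment <- function(truth, config, montage = NULL, seed = config$seed) {
  montage <- montage %||% build_montage()
  n <- as.integer(truth$n)
  if (is.na(n) || n < 2L) stop("truth$n must be an integer >= 2")
  am <- config$amplitude_model
  true_amp <- truth$true_amp %||%
    (am[["intercept"]] + am[["coef_w"]] * truth$w_load +
       am[["coef_task"]] * truth$task_relevant)
  tpl <- synth_templates(config, montage)
  psd <- config$between_sd * (1 + config$heteroscedasticity * abs(true_amp))
  exp <- with_seed(seed, {
    amps <- stats::rnorm(n, true_amp, psd)
    pids <- sprintf("p%02d", seq_len(n))
    participants <- stats::setNames(lapply(seq_len(n), function(i) {
      synthesize_pair(amps[i], config, montage, participant_id = pids[i],
                      templates = tpl)
    }), pids)
    ex <- spn_experiment(
      id = truth$id %||% "exp1", project = truth$project %||% "synthetic",
      participants = participants, contrast = c("regular", "random"),
      w_load = truth$w_load, task_relevant = truth$task_relevant,
      published = isTRUE(truth$published),
      original_cluster = config$calibration_cluster,
      original_window = config$calibration_window)
    attr(ex, "truth") <- list(true_amp = true_amp, participant_amps = amps)
    ex
  })
  exp
}

#' Generate a full synthetic catalogue
#'
#' Experiment-level design: sample size uniform over `n_range`, W-load
#' uniform on `[0, 1]`, task relevance Bernoulli(1/2), true amplitude from
#' the configured regression plus a `Normal(0, experiment_sd)` residual, and
#' the published flag drawn from `published_rule`. One root seed drives
#' everything; each experiment uses a deterministically derived child seed,
#' so regenerating with the same config is bitwise reproducible.
#'
#' @param config A `synth_config`.
#' @param montage Optional `spn_montage` (default: bundled 64-channel layout).
#' @return An `spn_catalogue`; the generating truth per experiment is kept in
#'   each experiment's `"truth"` attribute.
#' @export
generate_catalogue <- function(config, montage = NULL) {
  validate_synth_config(config)
  montage <- montage %||% build_montage()
  k <- config$n_experiments
  am <- config$amplitude_model
  design <- with_seed(config$seed, {
    rng <- seq.int(config$n_range[1L], config$n_range[2L])
    n <- rng[sample.int(length(rng), k, replace = TRUE)]
    w <- stats::runif(k)
    task <- stats::rbinom(k, 1L, 0.5)
    amp <- am[["intercept"]] + am[["coef_w"]] * w + am[["coef_task"]] * task +
      stats::rnorm(k, 0, config$experiment_sd)
    pub <- stats::runif(k) < config$published_rule(amp)
    list(n = n, w = w, task = task, amp = amp, pub = pub)
  })
  experiments <- lapply(seq_len(k), function(i) {
    generate_experiment(
      truth = list(id = sprintf("exp%03d", i), n = design$n[i],
                   w_load = design$w[i], task_relevant = design$task[i],
                   true_amp = design$amp[i], published = design$pub[i]),
      config = config, montage = montage,
      seed = child_seed(config$seed, i))
  })
  spn_catalogue(montage, experiments,
                provenance = sprintf("synthetic catalogue (seed %d)",
                                     config$seed))
}

# Deterministic child seed derivation (stable under subsetting).
child_seed <- function(seed, i) {
  ((abs(as.numeric(seed)) %% 2147483647) * 16807 + i * 2654435) %% 2147483647
}

# Evaluate code under a temporary RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  has <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = env)
  on.exit({
    if (has) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}
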