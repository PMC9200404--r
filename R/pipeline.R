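#' Pipeline run configuration
#'
#' @param out_dir Output directory (created; must differ from any input
#'   catalogue directory).
#' @param stages Character vector of stages to run, in order, from
#'   `simulate`, `extract`, `power`, `bias`, `vibration`, `stcluster`.
#' @param catalogue_path Path to an existing catalogue directory, or `NULL`
#'   when the `simulate` stage provides one.
#' @param synth A `synth_config` for the `simulate` stage.
#' @param seed Global seed; overrides the synth config seed and seeds the
#'   stochastic stages.
#' @param cluster,window Extraction cluster/window (`NULL` = per-experiment
#'   originals).
#' @param amplitude_grid Amplitude grid (microvolts) for the power table.
#' @param n_permutations Permutations per experiment in the `stcluster`
#'   stage.
#' @param verbose Emit progress messages to stderr.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, stages = c("simulate", "extract", "power",
                                           "bias", "vibration", "stcluster"),
                       catalogue_path = NULL, synth = synth_config(),
                       seed = synth$seed, cluster = NULL, window = NULL,
                       amplitude_grid = seq(-3.5, -0.25, by = 0.25),
                       n_permutations = 200, verbose = FALSE) {
  known <- c("simulate", "extract", "power", "bias", "vibration", "stcluster")
  if (!length(stages) || !all(stages %in% known)) {
    stop("stages must be a non-empty subset of: ",
         paste(known, collapse = ", "))
  }
  if (is.null(catalogue_path) && !"simulate" %in% stages &&
      length(setdiff(stages, character(0)))) {
    stop("no input: provide catalogue_path or include the 'simulate' stage")
  }
  if (!is.null(catalogue_path) &&
      normalizePath(out_dir, mustWork = FALSE) ==
        normalizePath(catalogue_path, mustWork = FALSE)) {
    stop("out_dir must differ from the input catalogue directory")
  }
  needs_extract <- intersect(stages, c("power", "bias", "vibration"))
  if (length(needs_extract) && !"extract" %in% stages) {
    stop("stage(s) ", paste(needs_extract, collapse = ", "),
         " require the 'extract' stage")
  }
  structure(list(out_dir = out_dir, stages = stages,
                 catalogue_path = catalogue_path, synth = synth,
                 seed = as.integer(seed), cluster = cluster, window = window,
                 amplitude_grid = amplitude_grid,
                 n_permutations = n_permutations, verbose = verbose),
            class = "run_config")
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the catalogue-evaluation pipeline
#'
#' Executes the configured stages in order, writing each stage's tables
#' under `out_dir/<stage>/`, machine-readable metrics to
#' `out_dir/metrics.json`, and a run manifest (`manifest.json`) recording
#' the package version, seed, configuration checksum and completed stages.
#' Rerunning with an identical configuration reproduces identical outputs.
#' If a stage fails, earlier stages' outputs are kept and a
#' `FAILED_<stage>` marker file is written before the error propagates.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with the catalogue, summaries and metrics.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (config$verbose) message("[spnmeta] ", ...)
  metrics <- list(package_version =
                    as.character(utils::packageVersion("spnmeta")),
                  seed = config$seed, stages = list())
  completed <- character(0)
  catalogue <- NULL
  summaries <- NULL

  run_stage <- function(name, fn) {
    say("stage ", name)
    sdir <- file.path(config$out_dir, name)
    dir.create(sdir, showWarnings = FALSE)
    tryCatch(fn(sdir), error = function(e) {
      writeLines(conditionMessage(e),
                 file.path(config$out_dir, paste0("FAILED_", name)))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    completed <<- c(completed, name)
  }

  if (!is.null(config$catalogue_path)) {
    catalogue <- load_catalogue(config$catalogue_path)
  }

  for (stage in config$stages) {
    if (stage == "simulate") run_stage("simulate", function(sdir) {
      cfg <- config$synth
      cfg$seed <- config$seed
      catalogue <<- generate_catalogue(cfg)
      save_catalogue(catalogue, file.path(sdir, "catalogue"))
      metrics$stages$simulate <<- list(
        n_experiments = length(catalogue$experiments),
        n_participants = sum(vapply(catalogue$experiments,
                                    function(e) e$n, numeric(1))))
    })
    if (stage == "extract") run_stage("extract", function(sdir) {
      summaries <<- catalogue_summaries(catalogue, cluster = config$cluster,
                                        window = config$window)
      write_tsv(summaries, file.path(sdir, "summaries.tsv"))
      metrics$stages$extract <<- list(
        n_summaries = nrow(summaries),
        mean_amplitude = mean(summaries$mean),
        n_significant = sum(summaries$p_two_tailed < 0.05))
    })
    if (stage == "power") run_stage("power", function(sdir) {
      model <- fit_effect_model(summaries$mean, summaries$d_z)
      tab <- power_table(config$amplitude_grid, model)
      write_tsv(tab, file.path(sdir, "required_n.tsv"))
      reg <- amplitude_regression(summaries$mean, summaries$w_load,
                                  summaries$task_relevant)
      metrics$stages$power <<- list(
        model_a = model$a, model_b = model$b, model_c = model$c,
        model_r_squared = model$r_squared,
        regression_intercept = reg$intercept,
        regression_coef_w = reg$coef_w,
        regression_coef_task = reg$coef_task,
        regression_r_squared = reg$r_squared)
    })
    if (stage == "bias") run_stage("bias", function(sdir) {
      pub <- summaries$published
      strata <- list(all = summaries,
                     published = summaries[pub, , drop = FALSE],
                     unpublished = summaries[!pub, , drop = FALSE])
      meta <- lapply(strata, function(s) {
        if (nrow(s) >= 1L) random_effects_mean(s$mean, s$se) else NULL
      })
      dist <- cumulative_distribution(summaries)
      write_tsv(dist, file.path(sdir, "cumulative.tsv"))
      write_tsv(funnel_points(summaries), file.path(sdir, "funnel.tsv"))
      bias_metrics <- list()
      for (nm in names(meta)) {
        if (is.null(meta[[nm]])) next
        bias_metrics[[paste0("weighted_mean_", nm)]] <-
          meta[[nm]]$weighted_mean
      }
      if (sum(pub) >= 2L && sum(!pub) >= 2L) {
        gc <- group_compare(summaries$mean[pub], summaries$mean[!pub])
        bias_metrics$welch_t <- gc$welch_t
        bias_metrics$welch_p <- gc$p
      }
      if (nrow(summaries) >= 3L) {
        eg <- egger_test(summaries$mean, summaries$se)
        bias_metrics$egger_intercept <- eg$intercept
        bias_metrics$egger_p <- eg$p
      }
      metrics$stages$bias <<- bias_metrics
    })
    if (stage == "vibration") run_stage("vibration", function(sdir) {
      rep <- recompute_clusters(catalogue, window = config$window %||%
                                  c(300, 1000))
      write_tsv(rep$summaries, file.path(sdir, "cluster_summaries.tsv"))
      counts <- rep$significance_counts
      k <- length(unique(rep$summaries$experiment_id))
      write_tsv(data.frame(cluster = names(counts),
                           significant = as.integer(counts),
                           total = k),
                file.path(sdir, "significance_counts.tsv"))
      vib <- list()
      for (nm in names(counts)) {
        vib[[paste0("significant_", nm)]] <- as.integer(counts[[nm]])
      }
      if (length(counts) >= 2L && all(counts > 0) && any(counts < k)) {
        cs <- chi_square_independence(cbind(as.integer(counts),
                                            k - as.integer(counts)))
        vib$chi_square <- cs$statistic
        vib$chi_square_p <- cs$p
      }
      if (!is.null(rep$correlation_matrix)) {
        cm <- rep$correlation_matrix
        write_tsv(data.frame(cluster = rownames(cm), cm,
                             check.names = FALSE),
                  file.path(sdir, "correlations.tsv"))
        off <- cm[upper.tri(cm)]
        vib$min_cross_cluster_r <- min(off)
        vib$max_cross_cluster_r <- max(off)
      }
      metrics$stages$vibration <<- vib
    })
    if (stage == "stcluster") run_stage("stcluster", function(sdir) {
      rows <- list()
      occ_clusters <- list()
      for (exp in catalogue$experiments) {
        res <- cluster_permutation_test(
          difference_epochs(exp), catalogue$montage,
          n_permutations = config$n_permutations,
          seed = child_seed(config$seed, match(exp$id,
                                               names(catalogue$experiments))))
        best <- most_significant_negative_cluster(res)
        occ_clusters[exp$id] <- list(best)  # keeps NULL entries
        if (!is.null(best)) {
          s <- cluster_window_spn(exp, best)
          rows[[exp$id]] <- data.frame(
            experiment_id = exp$id, mass = best$mass, p = best$p,
            n_points = nrow(best$members),
            n_electrodes = length(unique(best$members$electrode)),
            window_start = s$window[1L], window_end = s$window[2L],
            data_driven_mean = s$mean, stringsAsFactors = FALSE)
        }
      }
      found <- !vapply(occ_clusters, is.null, logical(1))
      if (any(found)) {
        write_tsv(do.call(rbind, rows), file.path(sdir, "clusters.tsv"))
        occ <- electrode_occurrence(occ_clusters,
                                    labels = catalogue$montage$labels)
        write_tsv(data.frame(electrode = names(occ), proportion = occ),
                  file.path(sdir, "electrode_occurrence.tsv"))
      }
      metrics$stages$stcluster <<- list(
        n_with_cluster = sum(found),
        n_experiments = length(occ_clusters),
        yield = mean(found))
    })
  }

  cfg_file <- file.path(config$out_dir, "config.json")
  cfg_ser <- config
  cfg_ser$synth$published_rule <- NULL  # functions do not serialize
  jsonlite::write_json(cfg_ser, cfg_file, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  metrics_file <- file.path(config$out_dir, "metrics.json")
  jsonlite::write_json(metrics, metrics_file, auto_unbox = TRUE, digits = NA)
  validate_metrics(jsonlite::read_json(metrics_file))
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("spnmeta")),
         seed = config$seed,
         config_md5 = unname(tools::md5sum(cfg_file)),
         stages_completed = completed,
         timestamp = "unset"),
    file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(catalogue = catalogue, summaries = summaries,
                 metrics = metrics))
}

#' Validate pipeline metrics against the shipped schema
#'
#' Checks the metrics object against the JSON schema in
#' `inst/schema/metrics-schema.json` (required fields and basic types; a
#' lightweight structural check, not a full JSON-Schema engine).
#'
#' @param metrics A list as read from `metrics.json`.
#' @return `TRUE`, invisibly, if valid; otherwise an error.
#' @export
validate_metrics <- function(metrics) {
  schema <- jsonlite::read_json(
    system.file("schema", "metrics-schema.json", package = "spnmeta"))
  for (field in schema$required) {
    if (is.null(metrics[[field]])) stop("metrics missing field '", field, "'")
  }
  if (!is.character(metrics$package_version) &&
      !is.character(unlist(metrics$package_version))) {
    stop("package_version must be a string")
  }
  if (!is.numeric(unlist(metrics$seed))) stop("seed must be a number")
  if (!is.list(metrics$stages)) stop("stages must be an object")
  for (st in metrics$stages) {
    if (!all(vapply(st, function(v) is.numeric(v) || is.character(v) ||
                      is.logical(v), logical(1)))) {
      stop("stage metrics must be scalar values")
    }
  }
  invisible(TRUE)
}
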